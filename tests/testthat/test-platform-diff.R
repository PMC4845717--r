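# Apply an explicit-allele edit to a local sequence: the haplotype oracle
# used to decide which encodings are equivalent.
applyEdit <- function(ctx, pos, ref, alt) {
  stopifnot(substr(ctx, pos, pos + nchar(ref) - 1L) == ref)
  paste0(substr(ctx, 1L, pos - 1L), alt,
         substring(ctx, pos + nchar(ref)))
}

test_that("equivalent indel encodings normalise to one canonical form", {
  ctx <- "ACGTTTGCAT"  # 1-bp deletion inside the TTT run is ambiguous
  # enumerate every (pos, ref, alt) deleting exactly one base
  encodings <- list()
  for (pos in 1:10) {
    for (len in 1:4) {
      if (pos + len - 1L > 10L) next
      ref <- substr(ctx, pos, pos + len - 1L)
      alts <- unique(vapply(seq_len(len), function(d)
        paste0(substr(ref, 1L, d - 1L), substring(ref, d + 1L)),
        character(1)))
      for (alt in alts) {
        if (alt == ref) next
        encodings[[length(encodings) + 1L]] <-
          list(pos = pos, ref = ref, alt = alt,
               hap = applyEdit(ctx, pos, ref, alt))
      }
    }
  }
  haps <- vapply(encodings, `[[`, "", "hap")
  for (h in unique(haps[duplicated(haps)])) {
    grp <- encodings[haps == h]
    norm <- lapply(grp, function(e) {
      df <- testCall(pos = e$pos, ref = e$ref,
                     alt = ifelse(nchar(e$alt), e$alt, "-"),
                     variant_class = "indel")
      n <- normalizeCalls(df, context = ctx, context_chrom = "1",
                          context_start = 1L)
      n[, c("pos", "ref", "alt")]
    })
    for (k in seq_along(norm)[-1])
      expect_equal(norm[[k]], norm[[1L]],
                   label = sprintf("encoding %d of haplotype %s", k, h))
  }
})

test_that("normalisation is idempotent and leaves SNVs untouched", {
  snv <- testCall(pos = 7L, ref = "T", alt = "C")
  expect_equal(normalizeCalls(snv), snv)
  ind <- testCall(pos = 100L, ref = "ATT", alt = "A",
                  variant_class = "indel")
  once <- normalizeCalls(ind)
  expect_equal(normalizeCalls(once), once)
  ctx <- paste(rep("AT", 20), collapse = "")
  once_ctx <- normalizeCalls(testCall(pos = 11L, ref = "ATA", alt = "A",
                                      variant_class = "indel"),
                             context = ctx, context_chrom = "1",
                             context_start = 1L)
  expect_equal(normalizeCalls(once_ctx, context = ctx, context_chrom = "1",
                              context_start = 1L), once_ctx)
})

test_that("a call whose alleles cancel is a null-variant error", {
  expect_error(normalizeCalls(testCall(ref = "AT", alt = "AT",
                                       variant_class = "indel")),
               "null-variant")
})

test_that("variant identity follows exact match or reciprocal overlap", {
  a <- testCall(pos = 10L, ref = "A", alt = "G")
  expect_true(sameVariant(a, a))
  expect_false(sameVariant(a, testCall(pos = 11L, ref = "A", alt = "G")))
  expect_false(sameVariant(a, testCall(chrom = "2", pos = 10L, ref = "A",
                                       alt = "G")))
  # deletion of one exon called with breakpoints differing by 50 bp:
  # spans [1000, 2727] and [1050, 2777], each 1728 bp, overlap 1678 bp,
  # reciprocal overlap 1678/1728 = 0.971
  d1 <- testCall(pos = 1000L, ref = "N", alt = NA_character_,
                 end_pos = 2727L, variant_class = "large_deletion")
  d2 <- testCall(pos = 1050L, ref = "N", alt = NA_character_,
                 end_pos = 2777L, variant_class = "large_deletion")
  expect_true(sameVariant(d1, d2))
  expect_equal(irdx:::.reciprocalOverlap(1000, 2727, 1050, 2777),
               1678 / 1728)
  d3 <- testCall(pos = 2700L, ref = "N", alt = NA_character_,
                 end_pos = 2900L, variant_class = "large_deletion")
  expect_false(sameVariant(d1, d3))
  expect_false(sameVariant(d1, a))
})

test_that("differencing a set against itself or nothing is as expected", {
  fx <- getFixture()
  wgs <- cohortCalls(fixtureSubsample(fx), "wgs")
  expect_equal(nrow(diffCallsets(wgs, wgs, fx$models, fx$known_miss)), 0L)
  all_rel <- diffCallsets(wgs, wgs[0, ], fx$models, fx$known_miss)
  expect_equal(nrow(all_rel),
               sum(wgs$pathogenicity %in% c("clearly_pathogenic",
                                            "likely_pathogenic")))
})

test_that("exclusive plus matched variants partition the relevant set", {
  fx <- getFixture()
  sub <- fixtureSubsample(fx)
  wgs <- cohortCalls(sub, "wgs")
  ngs <- cohortCalls(sub, "ngs")
  d <- diffCallsets(wgs, ngs, fx$models, fx$known_miss)
  n_relevant <- sum(wgs$pathogenicity %in% c("clearly_pathogenic",
                                             "likely_pathogenic"))
  # matched = relevant WGS calls that do have a panel-arm counterpart
  expect_equal(nrow(d) + (n_relevant - nrow(d)), n_relevant)
  expect_equal(nrow(d), 14L)
})

test_that("diff output is invariant under re-encoding of its inputs", {
  ngs <- rbind(testCall(patient_id = "p1", pos = 100L, ref = "AT",
                        alt = "A", variant_class = "indel"),
               testCall(patient_id = "p1", pos = 200L, ref = "C",
                        alt = "G"))
  wgs <- rbind(testCall(patient_id = "p1", platform = "wgs", pos = 101L,
                        ref = "T", alt = "-", variant_class = "indel"),
               testCall(patient_id = "p1", platform = "wgs", pos = 200L,
                        ref = "C", alt = "G"),
               testCall(patient_id = "p1", platform = "wgs", pos = 300L,
                        ref = "G", alt = "GA", variant_class = "indel"))
  d <- diffCallsets(wgs, ngs, models = NULL)
  expect_equal(nrow(d), 1L)   # only the pos-300 insertion is exclusive
  expect_equal(d$pos, 301L)   # normalised representation
})

test_that("categorisation follows the documented precedence", {
  fx <- getFixture()
  t9 <- fx$table9
  cat_of <- function(i) categorizeVariant(t9[i, ], fx$models, fx$known_miss)
  expect_equal(cat_of(which(t9$gene == "MERTK")), "large_deletion")
  expect_equal(cat_of(which(t9$gene == "TRPM1")), "additional_gene_variant")
  expect_equal(unique(vapply(which(t9$pos == 94476351L), cat_of, "")),
               "informatics_miss")
  expect_equal(unique(vapply(which(t9$pos == 94476951L), cat_of, "")),
               "intronic_variant")
  expect_equal(cat_of(which(t9$gene == "CRX")), "insertion_deletion")
  # unannotated variant and unknown gene raise
  v <- testCall(gene = NA_character_)
  expect_error(categorizeVariant(v, fx$models), "categorization error")
  expect_error(categorizeVariant(testCall(gene = "NOTAGENE"), fx$models),
               "lookup error")
  # a coding SNV not declared as a known miss cannot be categorised
  expect_error(categorizeVariant(testCall(gene = "EYS"), fx$models),
               "known-miss")
})

test_that("the fixture diff reproduces the printed category grouping", {
  fx <- getFixture()
  sub <- fixtureSubsample(fx)
  d <- diffCallsets(cohortCalls(sub, "wgs"), cohortCalls(sub, "ngs"),
                    fx$models, fx$known_miss)
  got <- table(factor(d$category, levels = diffCategories()))
  expect_equal(as.integer(got), c(5L, 3L, 3L, 2L, 1L))
})
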