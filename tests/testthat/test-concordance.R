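# Hand-enumerated classification oracle over truth-genotype x pipeline-call
# combinations (the exhaustive small truth table for one site).
test_that("site classification matches the enumerated genotype-pair oracle", {
  cases <- list(
    list(gt = "hom_ref", calls = character(), zyg = character(),
         want = "tn"),
    list(gt = "hom_ref", calls = "G", zyg = "het", want = "fp"),
    list(gt = "hom_ref", calls = "G", zyg = "hom", want = "fp"),
    list(gt = "het", calls = character(), zyg = character(), want = "fn"),
    list(gt = "het", calls = "G", zyg = "het", want = "tp"),
    list(gt = "het", calls = "G", zyg = "hom", want = "tp"),  # detection-first
    list(gt = "het", calls = "T", zyg = "het", want = "fn"),  # wrong allele
    list(gt = "hom_alt", calls = "G", zyg = "hom", want = "tp"),
    list(gt = "hom_alt", calls = "G", zyg = "het", want = "tp"),
    list(gt = "hom_alt", calls = character(), zyg = character(),
         want = "fn"))
  for (cs in cases) {
    calls <- if (length(cs$calls))
      testCall(chrom = "1", pos = 50L, alt = cs$calls, zygosity = cs$zyg)
    else testCall()[0, ]
    got <- classifySite(list(chrom = "1", pos = 50L, alt_allele = "G",
                             genotype_class = cs$gt), calls)
    expect_equal(got, cs$want,
                 label = sprintf("truth %s / call %s", cs$gt,
                                 paste(cs$calls, collapse = ",")))
  }
})

test_that("strict genotype scoring demotes zygosity mismatches", {
  truth <- list(chrom = "1", pos = 50L, alt_allele = "G",
                genotype_class = "het")
  call_hom <- testCall(chrom = "1", pos = 50L, alt = "G", zygosity = "hom")
  expect_equal(classifySite(truth, call_hom), "tp")
  expect_equal(classifySite(truth, call_hom, genotype_strict = TRUE), "fn")
})

test_that("unknown truth genotype classes are an input error", {
  expect_error(classifySite(list(chrom = "1", pos = 1L, alt_allele = "G",
                                 genotype_class = "weird"), testCall()[0, ]),
               "input error")
})

test_that("half-open region boundaries are honoured when restricting", {
  bed <- tempfile(fileext = ".bed")
  writeLines("chr1\t100\t200", bed)
  regions <- readRegions(bed)
  sites <- GenotypeSites(data.frame(
    chrom = "chr1", pos = c(101L, 150L, 200L, 201L), ref_allele = "A",
    alt_allele = "G", genotype_class = "het"))
  kept <- siteTable(restrictSites(sites, regions))
  expect_equal(kept$pos, c(101L, 150L, 200L))
})

test_that("fixture tables reproduce the worked sensitivity/specificity", {
  fx <- getFixture()
  wgs <- buildConcordance(fx$truth_wgs, fx$calls_wgs, fx$panel)
  expect_equal(wgs@tp + wgs@fn, 928L)
  expect_equal(wgs@tn + wgs@fp, 3238L)
  expect_equal(wgs@fp, 3L)
  expect_equal(round(100 * sensitivity(wgs), 1), 100.0)
  expect_equal(round(100 * specificity(wgs), 1), 99.9)
  ngs <- buildConcordance(fx$truth_ngs, fx$calls_ngs, fx$panel)
  expect_equal(round(100 * sensitivity(ngs), 1), 100.0)
  expect_equal(round(100 * specificity(ngs), 1), 100.0)
})

test_that("empty truth sets flag both metrics undefined", {
  tab <- buildConcordance(GenotypeSites(), testCall()[0, ])
  expect_equal(tab@tp + tab@fn + tab@tn + tab@fp, 0L)
  expect_true(is.na(sensitivity(tab)))
  expect_true(is.na(specificity(tab)))
})

test_that("build_table equals a naive per-site double loop on random data", {
  for (seed in 1:3) {
    set.seed(seed)
    n <- 200L
    pos <- sample.int(500L, n)
    gt <- sample(c("het", "hom_alt", "hom_ref"), n, replace = TRUE)
    truth <- GenotypeSites(data.frame(
      chrom = "1", pos = pos, ref_allele = "A",
      alt_allele = ifelse(gt == "hom_ref", NA, "G"), genotype_class = gt))
    called_at <- sample(pos, 120L)
    calls <- do.call(rbind, lapply(called_at, function(p)
      testCall(chrom = "1", pos = p, alt = sample(c("G", "T"), 1L),
               zygosity = sample(c("het", "hom"), 1L))))
    tab <- buildConcordance(truth, calls)
    # independent oracle: literal per-site scan
    naive <- c(tp = 0L, fn = 0L, tn = 0L, fp = 0L)
    for (i in seq_len(n)) {
      hit <- calls[calls$pos == pos[i], , drop = FALSE]
      cls <- if (gt[i] == "hom_ref") {
        if (nrow(hit)) "fp" else "tn"
      } else {
        if (any(hit$alt == "G")) "tp" else "fn"
      }
      naive[cls] <- naive[cls] + 1L
    }
    expect_equal(c(tp = tab@tp, fn = tab@fn, tn = tab@tn, fp = tab@fp),
                 naive)
    # order independence
    perm <- sample.int(n)
    tab2 <- buildConcordance(GenotypeSites(siteTable(truth)[perm, ]),
                             calls[sample.int(nrow(calls)), ])
    expect_equal(c(tab2@tp, tab2@fn, tab2@tn, tab2@fp),
                 c(tab@tp, tab@fn, tab@tn, tab@fp))
  }
})

test_that("adjudication reclassifies within rows and reports the rate", {
  # 1000 truth SNVs, none called: fn = 1000 discordances
  truth <- GenotypeSites(data.frame(
    chrom = "1", pos = 1:1000, ref_allele = "A", alt_allele = "G",
    genotype_class = "het"))
  tab <- buildConcordance(truth, testCall()[0, ])
  expect_equal(tab@fn, 1000L)
  records <- data.frame(
    chrom = "1", pos = 1:1000,
    resolution = c(rep("pipeline_correct", 21),
                   rep("unresolved", 6),
                   rep("truth_correct", 973)))
  adj <- adjustWithAdjudication(tab, records)
  # independent recount: 21 of 1000 move fn -> tp
  expect_equal(adj@adjusted@tp, 21L)
  expect_equal(adj@adjusted@fn, 979L)
  expect_equal(round(100 * adj@truthErrorRate, 1), 2.1)
  expect_equal(adj@nUnresolved, 6L)
  # count conservation within rows
  expect_equal(adj@adjusted@tp + adj@adjusted@fn, tab@tp + tab@fn)
  expect_equal(adj@adjusted@tn + adj@adjusted@fp, tab@tn + tab@fp)
})

test_that("degenerate and empty adjudication cases behave as specified", {
  truth <- GenotypeSites(data.frame(
    chrom = "1", pos = 1:2, ref_allele = "A", alt_allele = "G",
    genotype_class = "het"))
  tab <- buildConcordance(truth, testCall()[0, ])
  adj <- adjustWithAdjudication(tab, data.frame(
    chrom = "1", pos = 1:2, resolution = "pipeline_correct"))
  expect_equal(sensitivity(adj), 1.0)
  expect_equal(adj@truthErrorRate, 1.0)

  none <- adjustWithAdjudication(tab, NULL)
  expect_true(is.na(none@truthErrorRate))
  expect_equal(none@adjusted@fn, tab@fn)

  expect_error(adjustWithAdjudication(tab, data.frame(
    chrom = "1", pos = 999L, resolution = "pipeline_correct")),
    "concordant site")
})

test_that("pipeline_correct resolutions never decrease either metric", {
  set.seed(11)
  truth <- GenotypeSites(data.frame(
    chrom = "1", pos = 1:60, ref_allele = "A",
    alt_allele = c(rep("G", 30), rep(NA, 30)),
    genotype_class = c(rep("het", 30), rep("hom_ref", 30))))
  calls <- rbind(
    do.call(rbind, lapply(1:20, function(p) testCall(pos = p, alt = "G"))),
    do.call(rbind, lapply(31:35, function(p) testCall(pos = p, alt = "G"))))
  tab <- buildConcordance(truth, calls)
  disc <- tab@discordant[tab@discordant$kind %in% c("fn", "fp"), ]
  prev_sens <- sensitivity(tab)
  prev_spec <- specificity(tab)
  for (k in seq_len(nrow(disc))) {
    adj <- adjustWithAdjudication(tab, data.frame(
      chrom = disc$chrom[seq_len(k)], pos = disc$pos[seq_len(k)],
      resolution = "pipeline_correct"))
    expect_gte(sensitivity(adj), prev_sens)
    expect_gte(specificity(adj), prev_spec)
    prev_sens <- sensitivity(adj)
    prev_spec <- specificity(adj)
  }
})
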