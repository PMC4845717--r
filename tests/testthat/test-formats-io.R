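test_that("VCF records parse with 1-based positions and INFO annotations", {
  path <- writeTestVcf(vcfLine(
    "chr1", 94476951, "T", "C",
    "GENE=ABCA4;CDNA=c.5461-10T>C;PATH_CLASS=likely_pathogenic;REGION_CLASS=intronic"))
  calls <- readCallset(path, platform = "wgs")
  df <- callTable(calls)
  expect_equal(nrow(df), 1L)
  expect_equal(df$pos, 94476951L)
  expect_equal(df$zygosity, "het")
  expect_equal(df$variant_class, "snv")
  expect_equal(df$gene, "ABCA4")
  expect_equal(df$region_class, "intronic")
  expect_equal(df$platform, "wgs")
})

test_that("symbolic deletions span the 1-based inclusive segment", {
  path <- writeTestVcf(vcfLine(
    "chr10", 56094632, "N", "<DEL>",
    "END=56613219;GENE=PCDH15;PATH_CLASS=likely_pathogenic;REGION_CLASS=coding"))
  df <- callTable(readCallset(path))
  expect_equal(df$variant_class, "large_deletion")
  expect_equal(df$end_pos - df$pos + 1L, 518588L)
  expect_true(is.na(df$alt))
})

test_that("an empty VCF body yields an empty call set", {
  path <- writeTestVcf(character())
  expect_equal(length(readCallset(path)), 0L)
})

test_that("unknown annotation vocabulary raises instead of defaulting", {
  path <- writeTestVcf(vcfLine(
    "chr1", 100, "T", "C",
    "GENE=ABCA4;PATH_CLASS=totally_benign_probably;REGION_CLASS=coding"))
  expect_error(readCallset(path), "pathogenicity")
})

test_that("genotype strings map to zygosities including hemizygous", {
  path <- writeTestVcf(c(
    vcfLine("chrX", 100, "T", "C", "GENE=RP2;PATH_CLASS=uncertain;REGION_CLASS=coding",
            gt = "1"),
    vcfLine("chr2", 200, "G", "A", "GENE=EYS;PATH_CLASS=uncertain;REGION_CLASS=coding",
            gt = "1/1")))
  df <- callTable(readCallset(path))
  expect_equal(df$zygosity[df$pos == 100L], "hemi")
  expect_equal(df$zygosity[df$pos == 200L], "hom")
})

test_that("TSV dialect is read and schema errors are reported", {
  df <- testCall(gene = "ABCA4", pos = 94476951L)
  path <- tempfile(fileext = ".tsv")
  writeCallset(df, path)
  back <- callTable(readCallset(path, platform = "ngs"))
  expect_equal(back$pos, df$pos)
  expect_equal(back$gene, df$gene)
  bad <- df[, setdiff(names(df), "pathogenicity")]
  path2 <- tempfile(fileext = ".tsv")
  utils::write.table(bad, path2, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(readCallset(path2), "schema error.*pathogenicity")
})

test_that("truth tables parse, permit hom_ref rows, and flag duplicates", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("chrom\tpos\tref\talt\tgenotype_class",
               "chr5\t89924371\tC\tG\thet",
               "chr5\t89924400\tA\t\thom_ref",
               "chr5\t89924371\tC\tG\thet"), path)
  sites <- readTruthTable(path)
  df <- siteTable(sites)
  expect_equal(nrow(df), 3L)           # duplicates retained
  expect_equal(df$genotype_class[2L], "hom_ref")
  expect_true(is.na(df$alt_allele[2L]))
  expect_length(sites@warnings, 1L)
  expect_match(sites@warnings, "duplicated")
})

test_that("truth rows with unknown genotype classes are schema errors", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("chrom\tpos\tref\talt\tgenotype_class",
               "chr5\t100\tC\tG\theterozygous"), path)
  expect_error(readTruthTable(path), "schema error")
})

test_that("BED intervals convert to 1-based inclusive and back unchanged", {
  path <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t200", "chr1\t300\t400", "chr2\t0\t50"), path)
  gr <- readRegions(path)
  expect_equal(GenomicRanges::start(gr)[1L], 101L)
  expect_equal(GenomicRanges::end(gr)[1L], 200L)
  out <- tempfile(fileext = ".bed")
  writeRegions(gr, out)
  expect_identical(readLines(out), readLines(path))
})

test_that("abutting intervals merge only when requested", {
  path <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t200", "chr1\t200\t300"), path)
  expect_equal(length(readRegions(path)), 2L)
  merged <- readRegions(path, merge = TRUE)
  expect_equal(length(merged), 1L)
  # brute-force membership: merged covers exactly 1-based 101..300
  covered <- 90:310 %in% (GenomicRanges::start(merged):
                            GenomicRanges::end(merged))
  expect_identical(covered, 90:310 >= 101 & 90:310 <= 300)
})

test_that("empty and malformed BED inputs are handled", {
  empty <- tempfile(fileext = ".bed")
  file.create(empty)
  expect_equal(length(readRegions(empty)), 0L)
  bad <- tempfile(fileext = ".bed")
  writeLines("chr1\t200\t200", bad)
  expect_error(readRegions(bad), "end <= start")
})

test_that("reports round-trip the counts used downstream", {
  tab <- ConcordanceTable(tp = 928L, fn = 0L, tn = 3235L, fp = 3L)
  path <- tempfile(fileext = ".yaml")
  writeReport(tab, path)
  back <- readReport(path)
  expect_identical(back$counts, list(tp = 928L, fn = 0L, tn = 3235L,
                                     fp = 3L))
  expect_equal(back$metrics$sensitivity_pct, 100)
  expect_equal(back$metrics$specificity_pct, 99.9)

  est <- simulateCI(data.frame(pop_count = 281, sample_size = 33,
                               new_diag = 11), 281, n_sims = 200, seed = 9,
                    simulate_prevalence = FALSE)
  writeReport(est, path)
  back2 <- readReport(path)
  expect_equal(back2$point, round(est@point, 4))
  expect_equal(back2$n_sims, 200L)
  expect_equal(back2$seed, 9L)
})

test_that("undefined metrics serialise as flagged, never as 0 or 1", {
  tab <- ConcordanceTable()
  path <- tempfile(fileext = ".yaml")
  writeReport(tab, path)
  back <- readReport(path)
  expect_false(back$metrics$sensitivity_defined)
  expect_true(is.na(back$metrics$sensitivity_pct))
})

test_that("the fixture's printed deletion spans fall in the known range", {
  fx <- getFixture()
  dels <- fx$table9[fx$table9$variant_class == "large_deletion", ]
  expect_equal(nrow(dels), 5L)
  spans <- dels$end_pos - dels$pos + 1L
  expect_true(all(spans >= 1727L & spans <= 518588L))
  expect_equal(max(spans), 518588L)
})
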