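rp <- "RP or rod-cone dystrophy"
usher <- "Usher syndrome"

test_that("a phenotype-mismatched carrier does not contribute to diagnosis", {
  models <- testModels()
  v <- testCall(gene = "IDH3B", zygosity = "het",
                pathogenicity = "likely_pathogenic")
  fit <- geneFit(v, models[models$gene == "IDH3B", ], phenotype = usher)
  expect_equal(fit$fit, "none")
  expect_true(fit$carrier)
  # same variant for an RP patient is a relevant carrier state
  fit_rp <- geneFit(v, models[models$gene == "IDH3B", ], phenotype = rp)
  expect_equal(fit_rp$fit, "partial")
})

test_that("two heterozygous hits in trans complete a recessive diagnosis", {
  models <- testModels()
  v <- rbind(
    testCall(gene = "GPR98", pos = 89924371L, zygosity = "het",
             pathogenicity = "likely_pathogenic", region_class = "intronic"),
    testCall(gene = "GPR98", pos = 90109981L, end_pos = 90111708L,
             ref = "N", alt = NA_character_, zygosity = "het",
             pathogenicity = "likely_pathogenic",
             variant_class = "large_deletion"))
  fit <- geneFit(v, models[models$gene == "GPR98", ], phenotype = usher)
  expect_equal(fit$fit, "full")
  expect_equal(fit$moi, "AR_comphet")
  # an explicit cis flag collapses the pair to a carrier state
  v$cis <- TRUE
  fit_cis <- geneFit(v, models[models$gene == "GPR98", ], phenotype = usher)
  expect_equal(fit_cis$fit, "partial")
})

test_that("homozygous and hemizygous genotypes satisfy their modes", {
  models <- testModels()
  hom <- testCall(gene = "TRPM1", zygosity = "hom",
                  pathogenicity = "clearly_pathogenic")
  expect_equal(geneFit(hom, models[models$gene == "TRPM1", ],
                       "Other (indication not included in this list, or not defined)")$fit,
               "full")
  xl <- testCall(gene = "RP2", zygosity = "het",
                 pathogenicity = "clearly_pathogenic")
  m_rp2 <- models[models$gene == "RP2", ]
  # unknown sex: heterozygous-coded X-linked call is only a carrier state
  expect_equal(geneFit(xl, m_rp2, rp)$fit, "partial")
  expect_equal(geneFit(xl, m_rp2, rp, sex = "male")$fit, "full")
  xl$zygosity <- "hemi"
  expect_equal(geneFit(xl, m_rp2, rp)$fit, "full")
})

test_that("a full fit in one gene retains carrier findings in others", {
  models <- testModels()
  v <- rbind(
    testCall(gene = "EYS", pos = 10L, zygosity = "het",
             pathogenicity = "clearly_pathogenic"),
    testCall(gene = "EYS", pos = 20L, zygosity = "het",
             pathogenicity = "likely_pathogenic"),
    testCall(gene = "RPGRIP1", pos = 30L, zygosity = "het",
             pathogenicity = "likely_pathogenic"))
  out <- classifyPatient(v, models, phenotype = rp)
  expect_equal(out$category, "diagnosed_confirmed")
  expect_equal(out$diagnosis$gene, "EYS")
  expect_equal(out$diagnosis$moi, "AR_comphet")
  expect_equal(out$carrier_findings$gene, "RPGRIP1")
})

test_that("patients with no qualifying variants are undiagnosed", {
  models <- testModels()
  expect_equal(classifyPatient(testCall()[0, ], models, rp)$category,
               "undiagnosed")
  vus <- testCall(pathogenicity = "uncertain")
  expect_equal(classifyPatient(vus, models, rp)$category, "undiagnosed")
})

test_that("variants in unmodelled genes raise a lookup error", {
  expect_error(classifyPatient(testCall(gene = "NOTAGENE"), testModels(),
                               rp), "lookup error.*NOTAGENE")
})

test_that("classification is invariant to variant order", {
  models <- testModels()
  set.seed(4)
  v <- rbind(
    testCall(gene = "EYS", pos = 10L, zygosity = "het"),
    testCall(gene = "EYS", pos = 20L, zygosity = "het",
             pathogenicity = "likely_pathogenic"),
    testCall(gene = "USH2A", pos = 30L, zygosity = "hom",
             pathogenicity = "likely_pathogenic"),
    testCall(gene = "IDH3B", pos = 40L, zygosity = "het",
             pathogenicity = "likely_pathogenic"))
  base <- classifyPatient(v, models, rp)
  for (i in 1:5) {
    perm <- classifyPatient(v[sample.int(nrow(v)), ], models, rp)
    expect_equal(perm$category, base$category)
    expect_equal(perm$diagnosis$gene, base$diagnosis$gene)
  }
})

test_that("adding a clearly pathogenic variant never undiagnoses", {
  models <- testModels()
  set.seed(5)
  genes <- c("EYS", "USH2A", "RHO", "IDH3B")
  for (i in 1:20) {
    n <- sample.int(3L, 1L)
    v <- do.call(rbind, lapply(seq_len(n), function(j)
      testCall(gene = sample(genes, 1L), pos = 10L * j,
               zygosity = sample(c("het", "hom"), 1L),
               pathogenicity = sample(c("clearly_pathogenic",
                                        "likely_pathogenic",
                                        "uncertain"), 1L))))
    before <- classifyPatient(v, models, rp)$category
    extra <- testCall(gene = sample(genes, 1L), pos = 999L,
                      zygosity = sample(c("het", "hom"), 1L))
    after <- classifyPatient(rbind(v, extra), models, rp)$category
    if (grepl("^diagnosed", before))
      expect_match(after, "^diagnosed")
  }
})

test_that("merging keeps the union and lets the second platform win", {
  models <- testModels()
  patients <- data.frame(patient_id = "p1", phenotype = usher)
  ngs <- testCall(patient_id = "p1", gene = "USH2A", pos = 100L,
                  zygosity = "hom", pathogenicity = "likely_pathogenic")
  wgs <- rbind(
    testCall(patient_id = "p1", platform = "wgs", gene = "USH2A",
             pos = 100L, zygosity = "het",
             pathogenicity = "likely_pathogenic"),
    testCall(patient_id = "p1", platform = "wgs", gene = "USH2A",
             pos = 500L, end_pos = 1500L, ref = "N", alt = NA_character_,
             zygosity = "het", pathogenicity = "likely_pathogenic",
             variant_class = "large_deletion"))
  cohort <- Cohort(patients, rbind(ngs, wgs))
  merged <- mergePlatforms(cohort)
  mc <- cohortCalls(merged, "merged")
  expect_equal(nrow(mc), 2L)
  expect_equal(sort(mc$zygosity), c("het", "het"))
  expect_length(attr(merged@calls, "zygosity_notes"), 1L)
  # the refined genotype turns the homozygous diagnosis into a compound het
  out_ngs <- classifyCohort(cohort, models, "ngs")
  out_merged <- classifyCohort(merged, models, "merged")
  expect_equal(out_ngs$moi, "AR_hom")
  expect_equal(out_merged$moi, "AR_comphet")
  expect_match(out_merged$category, "^diagnosed")
})

test_that("merging identical call sets is the identity, and idempotent", {
  patients <- data.frame(patient_id = "p1", phenotype = rp)
  ngs <- testCall(patient_id = "p1", gene = "EYS", pos = 100L)
  wgs <- ngs
  wgs$platform <- "wgs"
  cohort <- Cohort(patients, rbind(ngs, wgs))
  m1 <- mergePlatforms(cohort)
  expect_equal(nrow(cohortCalls(m1, "merged")), 1L)
  m2 <- mergePlatforms(m1)   # merged set replaced, not duplicated
  expect_equal(cohortCalls(m2, "merged"), cohortCalls(m1, "merged"))
})

test_that("cohort summaries partition patients and count carriers", {
  fx <- getFixture()
  out <- classifyCohort(fx$cohort, fx$models, "ngs")
  s <- cohortSummary(out)
  expect_equal(Reduce(`+`, s$categories), s$n)
  expect_equal(s$n_carrier_diagnosed + s$n_carrier_undiagnosed,
               s$n_carrier_patients)
  # degenerate cohort: nobody diagnosed
  empty <- data.frame(patient_id = c("a", "b"), platform = "ngs",
                      category = "undiagnosed", gene = NA, moi = NA,
                      pathogenicity = NA, n_causal = 0L,
                      n_carrier_findings = 0L, carrier_genes = "")
  expect_equal(cohortSummary(empty)$yield_pct, 0L)
})
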