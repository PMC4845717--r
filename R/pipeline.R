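.CONFIG_KEYS <- c("version", "cohort", "genes", "ngs_calls", "wgs_calls",
                  "panel", "truth", "pipeline_calls", "adjudications",
                  "strata", "known_miss", "out", "seed", "genotype_strict",
                  "simulate_prevalence", "overlap_threshold", "n_sims",
                  "absolute_uplift", "baseline_diagnosed", "pop_total")

#' Run the end-to-end diagnostic comparison
#'
#' Wires the analysis stages into the study's complete comparison:
#' classification of the panel arm, per-patient merge of genome-arm calls
#' and reclassification, cross-platform differencing, cohort summaries,
#' concordance benchmarking (when truth data are configured) and the
#' stratified uplift projection. One structured report is written per stage
#' plus a combined summary; every classified patient emits one audit line
#' in \code{log.txt}. Identical configuration and seed produce a
#' byte-identical output bundle. Any stage error aborts the run with the
#' stage name attached and removes partial outputs.
#'
#' The configuration is a flat key/value list (or path to a YAML file with
#' the same keys), schema version 1: file paths \code{cohort, genes,
#' ngs_calls, wgs_calls} (TSV dialects), optional \code{truth,
#' pipeline_calls, adjudications, panel, strata, known_miss}; switches
#' \code{genotype_strict, simulate_prevalence, overlap_threshold, n_sims,
#' absolute_uplift}; referral-population overrides \code{baseline_diagnosed,
#' pop_total} for when the classified cohort is a subsample of the
#' population the strata describe; \code{seed}; output directory
#' \code{out}. Unknown keys are errors.
#'
#' @param config Named list or path to a YAML config file.
#' @return Invisibly, the combined summary list.
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  unknown <- setdiff(names(config), .CONFIG_KEYS)
  if (length(unknown))
    stop("config error: unknown key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (!identical(as.integer(config$version %||% 1L), 1L))
    stop("config error: unsupported schema version", call. = FALSE)
  for (key in c("cohort", "genes", "ngs_calls", "out"))
    if (is.null(config[[key]]))
      stop("config error: missing required key: ", key, call. = FALSE)
  seed <- as.integer(config$seed %||% 1L)
  out_dir <- config$out
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  emit <- function(obj, name) {
    path <- file.path(out_dir, name)
    if (is.data.frame(obj))
      utils::write.table(obj, path, sep = "\t", quote = FALSE,
                         row.names = FALSE, na = "")
    else writeReport(obj, path)
    written <<- c(written, path)
    path
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      unlink(written)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  models <- stage("inputs", readGeneModels(config$genes))
  cohort <- stage("inputs", {
    patients <- readCohortTable(config$cohort)
    ngs <- callTable(readCallset(config$ngs_calls, platform = "ngs"))
    wgs <- if (!is.null(config$wgs_calls))
      callTable(readCallset(config$wgs_calls, platform = "wgs"))
    else ngs[integer(0), , drop = FALSE]
    if (nrow(patients) == 0L)
      stop("empty cohort table", call. = FALSE)
    Cohort(patients, rbind(ngs, wgs))
  })

  out_ngs <- stage("classify_ngs", classifyCohort(cohort, models, "ngs"))
  merged <- stage("merge", mergePlatforms(
    cohort, overlap_threshold = config$overlap_threshold %||% 0.8))
  out_merged <- stage("classify_merged",
                      classifyCohort(merged, models, "merged"))
  emit(out_ngs, "outcomes_ngs.tsv")
  emit(out_merged, "outcomes_merged.tsv")

  log_lines <- c(
    sprintf("seed=%d", seed),
    sprintf("patient=%s platform=ngs category=%s gene=%s moi=%s",
            out_ngs$patient_id, out_ngs$category,
            ifelse(is.na(out_ngs$gene), "-", out_ngs$gene),
            ifelse(is.na(out_ngs$moi), "-", out_ngs$moi)),
    sprintf("patient=%s platform=merged category=%s gene=%s moi=%s",
            out_merged$patient_id, out_merged$category,
            ifelse(is.na(out_merged$gene), "-", out_merged$gene),
            ifelse(is.na(out_merged$moi), "-", out_merged$moi)))

  sum_ngs <- cohortSummary(out_ngs)
  sum_merged <- cohortSummary(out_merged)
  emit(c(sum_ngs, list(seed = seed)), "summary_ngs.yaml")
  emit(c(sum_merged, list(seed = seed)), "summary_merged.yaml")

  known_miss <- if (!is.null(config$known_miss)) .readTsv(config$known_miss)
  diff_rec <- stage("diff", diffCallsets(
    cohortCalls(cohort, "wgs"), cohortCalls(cohort, "ngs"), models,
    known_miss = known_miss,
    overlap_threshold = config$overlap_threshold %||% 0.8))
  emit(diff_rec, "platform_diff.tsv")

  conc <- NULL
  if (!is.null(config$truth) && !is.null(config$pipeline_calls)) {
    conc <- stage("concordance", {
      truth <- readTruthTable(config$truth)
      pcalls <- readCallset(config$pipeline_calls, platform = "pipeline")
      regions <- if (!is.null(config$panel))
        readRegions(config$panel, merge = TRUE)
      tab <- buildConcordance(truth, pcalls, regions,
                              genotype_strict =
                                isTRUE(config$genotype_strict))
      adj <- if (!is.null(config$adjudications))
        .readTsv(config$adjudications)
      adjustWithAdjudication(tab, if (!is.null(adj)) {
        adj$pos <- as.integer(adj$pos)
        adj
      })
    })
    emit(conc, "concordance.yaml")
  }

  uplift <- NULL
  if (!is.null(config$strata)) {
    uplift <- stage("uplift", {
      strata <- readStrata(config$strata)
      # the strata describe the referral population, which may be larger
      # than the cohort classified here; explicit config keys override the
      # cohort-derived defaults
      simulateCI(strata,
                 baseline_diagnosed =
                   config$baseline_diagnosed %||% sum_ngs$n_diagnosed,
                 pop_total = config$pop_total %||% sum(strata$pop_count),
                 n_sims = config$n_sims %||% 10000,
                 seed = seed,
                 simulate_prevalence =
                   !isFALSE(config$simulate_prevalence),
                 absolute = isTRUE(config$absolute_uplift))
    })
    emit(uplift, "uplift.yaml")
  }

  # combined summary: every number traceable to a stage report
  combined <- list(
    type = "combined_summary", schema_version = 1L, seed = seed,
    n_patients = sum_ngs$n,
    ngs = list(n_diagnosed = sum_ngs$n_diagnosed,
               yield_pct = sum_ngs$yield_pct,
               n_carrier_patients = sum_ngs$n_carrier_patients),
    merged = list(n_diagnosed = sum_merged$n_diagnosed,
                  yield_pct = sum_merged$yield_pct),
    n_new_diagnoses = sum_merged$n_diagnosed - sum_ngs$n_diagnosed,
    n_platform_exclusive_variants = nrow(diff_rec),
    concordance = if (!is.null(conc)) .concordanceAsList(conc@adjusted),
    uplift = if (!is.null(uplift))
      list(point = round(uplift@point, 4),
           ci_low = round(uplift@ciLow, 4),
           ci_high = round(uplift@ciHigh, 4)))
  combined <- combined[!vapply(combined, is.null, logical(1))]
  emit(combined, "combined_summary.yaml")
  writeLines(log_lines, file.path(out_dir, "log.txt"))
  invisible(combined)
}

#' Write the study fixture as an on-disk input bundle
#'
#' Materialises \code{\link{studyFixture}} in the package's TSV/BED
#' dialects so the pipeline (or external tools) can be run against it:
#' cohort and gene tables, per-platform call sets, panel regions, truth
#' tables and pipeline call sets for both arms, the known-miss list, and
#' both strata tables. A ready-to-run pipeline config
#' (\code{config.yaml}) pointing at the written files is included.
#'
#' @param dir Output directory (created if needed).
#' @param seed Seed recorded in the config.
#' @return Invisibly, the fixture bundle list with a \code{paths} element.
#' @export
writeFixtureBundle <- function(dir, seed = 1) {
  fx <- studyFixture()
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  sub <- fixtureSubsample(fx)
  utils::write.table(patientTable(sub), p("cohort46.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "")
  utils::write.table(patientTable(fx$cohort), p("cohort562.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "")
  utils::write.table(fx$models, p("genes.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  writeCallset(cohortCalls(sub, "ngs"), p("ngs_calls.tsv"))
  writeCallset(cohortCalls(sub, "wgs"), p("wgs_calls.tsv"))
  writeCallset(cohortCalls(fx$cohort, "ngs"), p("ngs_calls562.tsv"))
  writeRegions(fx$panel, p("panel.bed"))
  tt <- function(x, f) {
    df <- siteTable(x)
    names(df)[names(df) == "ref_allele"] <- "ref"
    names(df)[names(df) == "alt_allele"] <- "alt"
    utils::write.table(df, p(f), sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "")
  }
  tt(fx$truth_ngs, "truth_ngs.tsv")
  tt(fx$truth_wgs, "truth_wgs.tsv")
  writeCallset(fx$calls_ngs, p("pipeline_calls_ngs.tsv"))
  writeCallset(fx$calls_wgs, p("pipeline_calls_wgs.tsv"))
  utils::write.table(fx$known_miss, p("known_miss.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "")
  utils::write.table(fx$strata, p("strata.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  utils::write.table(fx$strata3, p("strata3.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  config <- list(version = 1L, cohort = p("cohort46.tsv"),
                 genes = p("genes.tsv"), ngs_calls = p("ngs_calls.tsv"),
                 wgs_calls = p("wgs_calls.tsv"), panel = p("panel.bed"),
                 truth = p("truth_wgs.tsv"),
                 pipeline_calls = p("pipeline_calls_wgs.tsv"),
                 strata = p("strata.tsv"),
                 known_miss = p("known_miss.tsv"),
                 baseline_diagnosed = fx$baseline_diagnosed,
                 pop_total = fx$pop_total,
                 out = p("results"), seed = as.integer(seed))
  yaml::write_yaml(config, p("config.yaml"))
  fx$paths <- c(lapply(config, identity), list(config = p("config.yaml")))
  invisible(fx)
}
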