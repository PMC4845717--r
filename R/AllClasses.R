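# Controlled vocabularies used across the package. Genotype classes follow
# array-reporting convention; zygosity/pathogenicity follow clinical-report
# convention rather than VCF GT strings.
.GENOTYPE_CLASSES <- c("hom_ref", "het", "hom_alt")
.ZYGOSITIES <- c("het", "hom", "hemi")
.VARIANT_CLASSES <- c("snv", "indel", "complex_indel", "large_deletion")
.REGION_CLASSES <- c("coding", "intronic", "other_noncoding")
.PATHOGENICITY <- c("clearly_pathogenic", "likely_pathogenic", "uncertain",
                    "likely_benign", "benign")
.INHERITANCE <- c("AD", "AR", "XLD", "XLR")
.PANELS <- c("panel105", "panel180_only", "off_panel")
.OUTCOME_CATEGORIES <- c("diagnosed_confirmed", "diagnosed_provisional",
                         "undiagnosed_carrier_relevant",
                         "undiagnosed_carrier_other", "undiagnosed")
.MOI <- c("AD", "AR_hom", "AR_comphet", "XLD", "XLR")
.DIFF_CATEGORIES <- c("large_deletion", "intronic_variant",
                      "insertion_deletion", "informatics_miss",
                      "additional_gene_variant")
.RESOLUTIONS <- c("pipeline_correct", "truth_correct", "unresolved")

#' Outcome category vocabulary
#'
#' The five mutually exclusive clinical outcome categories a patient can be
#' assigned after diagnostic variant interpretation: a confirmed molecular
#' diagnosis, a provisional molecular diagnosis, no diagnosis but a single
#' pathogenic heterozygous variant in a recessive gene relevant to the
#' patient's own phenotype (carrier of the relevant trait), the same for a
#' gene unrelated to the phenotype, or no reportable finding at all.
#'
#' @return Character vector of category labels, in fixed order.
#' @export
outcomeCategories <- function() .OUTCOME_CATEGORIES

#' Platform-difference category vocabulary
#'
#' Categories for clinically relevant variants found by whole genome
#' sequencing but not by the targeted panel: large deletions encapsulating
#' coding regions, intronic/noncoding variants outside the capture design,
#' complex insertion-deletion events, variants missed through informatics
#' (analysable but not called/reported), and variants in genes absent from
#' the first-tier panel.
#'
#' @return Character vector of category labels, in fixed order.
#' @export
diffCategories <- function() .DIFF_CATEGORIES

# Canonical column set for a variant-call table. `end_pos` is NA except for
# symbolic/large deletions, where [pos, end_pos] is the 1-based inclusive
# deleted segment. `cis` marks a variant as known to lie on the same
# haplotype as another variant in the same gene (phase information).
.CALL_COLUMNS <- c(patient_id = "character", platform = "character",
                   chrom = "character", pos = "integer", end_pos = "integer",
                   ref = "character", alt = "character",
                   zygosity = "character", gene = "character",
                   cdna = "character", variant_class = "character",
                   region_class = "character", pathogenicity = "character",
                   cis = "logical")

.SITE_COLUMNS <- c(chrom = "character", pos = "integer",
                   ref_allele = "character", alt_allele = "character",
                   genotype_class = "character", source = "character")

# Build a zero-row data.frame with the canonical types for `cols`.
.emptyFrame <- function(cols) {
  out <- lapply(cols, function(ty) vector(ty, 0L))
  as.data.frame(out, stringsAsFactors = FALSE)
}

# Coerce a user-supplied data.frame onto the canonical column set: missing
# optional columns are added as NA/default, types are cast, extras dropped.
.canonicalizeFrame <- function(df, cols, defaults = list()) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  for (nm in names(cols)) {
    if (!nm %in% names(df)) {
      fill <- if (nm %in% names(defaults)) defaults[[nm]] else
        vector(cols[[nm]], 1L)[NA]
      df[[nm]] <- rep(fill, length.out = nrow(df))
    }
    df[[nm]] <- switch(cols[[nm]],
                       character = as.character(df[[nm]]),
                       integer   = as.integer(df[[nm]]),
                       numeric   = as.numeric(df[[nm]]),
                       logical   = as.logical(df[[nm]]))
  }
  df[names(cols)]
}

.checkVocab <- function(x, vocab, what, na_ok = FALSE) {
  bad <- if (na_ok) !is.na(x) & !x %in% vocab else is.na(x) | !x %in% vocab
  if (any(bad))
    sprintf("invalid %s value(s): %s", what,
            paste(unique(x[bad]), collapse = ", "))
  else NULL
}

#' @title Set of annotated variant calls
#'
#' @description An S4 container for annotated variant calls, the unit of
#' clinical interpretation and cross-platform differencing. Each row is one
#' call with 1-based coordinates, explicit REF/ALT (or a deleted-segment end
#' for large deletions), zygosity, gene symbol, variant class (snv, indel,
#' complex_indel, large_deletion), region class (coding, intronic,
#' other_noncoding) and a five-tier pathogenicity annotation carried over
#' from clinical review.
#'
#' @slot calls data.frame with the canonical call columns.
#' @export
setClass("VariantCalls", representation(calls = "data.frame"))

setValidity("VariantCalls", function(object) {
  df <- object@calls
  missing_cols <- setdiff(names(.CALL_COLUMNS), names(df))
  if (length(missing_cols))
    return(paste("missing columns:", paste(missing_cols, collapse = ", ")))
  msgs <- c(
    .checkVocab(df$zygosity, .ZYGOSITIES, "zygosity"),
    .checkVocab(df$variant_class, .VARIANT_CLASSES, "variant_class"),
    .checkVocab(df$region_class, .REGION_CLASSES, "region_class", na_ok = TRUE),
    .checkVocab(df$pathogenicity, .PATHOGENICITY, "pathogenicity")
  )
  if (any(!is.na(df$pos) & df$pos < 1L))
    msgs <- c(msgs, "positions must be >= 1")
  isdel <- df$variant_class == "large_deletion"
  if (any(isdel & is.na(df$end_pos)))
    msgs <- c(msgs, "large_deletion requires end_pos")
  if (any(!isdel & !is.na(df$end_pos)))
    msgs <- c(msgs, "end_pos only allowed for large_deletion")
  if (any(isdel & !is.na(df$end_pos) & df$end_pos < df$pos))
    msgs <- c(msgs, "large_deletion end_pos must be >= pos")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Construct a VariantCalls object
#'
#' @param calls data.frame of calls; missing optional columns (patient_id,
#'   platform, end_pos, gene, cdna, cis) are filled with NA/FALSE.
#' @return A \linkS4class{VariantCalls} object.
#' @examples
#' VariantCalls(data.frame(chrom = "1", pos = 94476951L, ref = "T",
#'   alt = "C", zygosity = "het", gene = "ABCA4", variant_class = "snv",
#'   region_class = "intronic", pathogenicity = "likely_pathogenic"))
#' @export
VariantCalls <- function(calls = .emptyFrame(.CALL_COLUMNS)) {
  df <- .canonicalizeFrame(calls, .CALL_COLUMNS, defaults = list(cis = FALSE))
  df$cis[is.na(df$cis)] <- FALSE
  rownames(df) <- NULL
  methods::new("VariantCalls", calls = df)
}

#' @describeIn VariantCalls-class Number of calls.
#' @param x A VariantCalls object.
#' @export
setMethod("length", "VariantCalls", function(x) nrow(x@calls))

#' Extract the call table from a VariantCalls object
#'
#' @param x A \linkS4class{VariantCalls} object.
#' @return data.frame with one row per call.
#' @export
callTable <- function(x) {
  stopifnot(methods::is(x, "VariantCalls"))
  x@calls
}

setMethod("show", "VariantCalls", function(object) {
  df <- object@calls
  cat(sprintf("VariantCalls with %d call(s)\n", nrow(df)))
  if (nrow(df)) {
    cat(sprintf("  platforms: %s\n",
                paste(unique(stats::na.omit(df$platform)), collapse = ", ")))
    cat(sprintf("  genes: %s\n",
                paste(utils::head(unique(stats::na.omit(df$gene)), 8),
                      collapse = ", ")))
    print(utils::head(df[c("chrom", "pos", "ref", "alt", "zygosity", "gene",
                           "variant_class", "pathogenicity")], 5))
    if (nrow(df) > 5) cat("  ...\n")
  }
})

#' @title Array-genotyped truth sites
#'
#' @description Genotype classes (hom_ref, het, hom_alt) at prespecified
#' genomic positions, as produced by a genotyping microarray, used as the
#' reference standard for concordance benchmarking. Homozygous-reference
#' sites have no ALT allele.
#'
#' @slot sites data.frame with columns chrom, pos, ref_allele, alt_allele,
#'   genotype_class, source.
#' @slot warnings character vector of parse-time warnings (e.g. duplicated
#'   positions).
#' @export
setClass("GenotypeSites",
         representation(sites = "data.frame", warnings = "character"))

setValidity("GenotypeSites", function(object) {
  df <- object@sites
  missing_cols <- setdiff(names(.SITE_COLUMNS), names(df))
  if (length(missing_cols))
    return(paste("missing columns:", paste(missing_cols, collapse = ", ")))
  msgs <- .checkVocab(df$genotype_class, .GENOTYPE_CLASSES, "genotype_class")
  if (any(df$pos < 1L)) msgs <- c(msgs, "positions must be >= 1")
  homref <- df$genotype_class == "hom_ref"
  alt_absent <- is.na(df$alt_allele) | df$alt_allele == ""
  if (any(homref & !alt_absent))
    msgs <- c(msgs, "hom_ref sites must have no alt allele")
  if (any(!homref & alt_absent))
    msgs <- c(msgs, "het/hom_alt sites require an alt allele")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Construct a GenotypeSites object
#'
#' @param sites data.frame with columns chrom, pos, ref_allele, alt_allele,
#'   genotype_class and optionally source.
#' @param warnings character vector of warnings to attach.
#' @return A \linkS4class{GenotypeSites} object.
#' @export
GenotypeSites <- function(sites = .emptyFrame(.SITE_COLUMNS),
                          warnings = character()) {
  df <- .canonicalizeFrame(sites, .SITE_COLUMNS,
                           defaults = list(source = "array"))
  df$alt_allele[!is.na(df$alt_allele) & df$alt_allele == ""] <- NA_character_
  rownames(df) <- NULL
  methods::new("GenotypeSites", sites = df, warnings = warnings)
}

#' @describeIn GenotypeSites-class Number of truth sites.
#' @param x A GenotypeSites object.
#' @export
setMethod("length", "GenotypeSites", function(x) nrow(x@sites))

#' Extract the site table from a GenotypeSites object
#'
#' @param x A \linkS4class{GenotypeSites} object.
#' @return data.frame with one row per truth site.
#' @export
siteTable <- function(x) {
  stopifnot(methods::is(x, "GenotypeSites"))
  x@sites
}

setMethod("show", "GenotypeSites", function(object) {
  df <- object@sites
  cat(sprintf("GenotypeSites with %d site(s): %s\n", nrow(df),
              paste(sprintf("%s=%d", names(table(df$genotype_class)),
                            as.integer(table(df$genotype_class))),
                    collapse = ", ")))
  if (length(object@warnings))
    cat(sprintf("  %d parse warning(s)\n", length(object@warnings)))
})

#' @title Genotype concordance confusion table
#'
#' @description Confusion-matrix counts from comparing a sequencing
#' pipeline's calls against array truth genotypes within target regions.
#' Truth single-nucleotide variants detected by the pipeline are true
#' positives; missed ones are false negatives. Truth homozygous-reference
#' sites with no variant call are true negatives; called ones are false
#' positives. Sensitivity = tp/(tp+fn); specificity = tn/(tn+fp).
#'
#' @slot tp,fn,tn,fp integer counts.
#' @slot discordant data.frame of discordant (and zygosity-mismatched) sites
#'   with columns chrom, pos, truth_genotype, pipeline_genotype, kind.
#' @export
setClass("ConcordanceTable",
         representation(tp = "integer", fn = "integer", tn = "integer",
                        fp = "integer", discordant = "data.frame"))

setValidity("ConcordanceTable", function(object) {
  cnt <- c(object@tp, object@fn, object@tn, object@fp)
  if (any(is.na(cnt)) || any(cnt < 0L)) "counts must be non-negative" else TRUE
})

#' Construct a ConcordanceTable
#'
#' @param tp,fn,tn,fp Non-negative integer counts.
#' @param discordant data.frame of discordant-site records.
#' @return A \linkS4class{ConcordanceTable}.
#' @export
ConcordanceTable <- function(tp = 0L, fn = 0L, tn = 0L, fp = 0L,
                             discordant = .emptyDiscordant()) {
  methods::new("ConcordanceTable", tp = as.integer(tp), fn = as.integer(fn),
               tn = as.integer(tn), fp = as.integer(fp),
               discordant = discordant)
}

.emptyDiscordant <- function() {
  data.frame(chrom = character(), pos = integer(),
             truth_genotype = character(), pipeline_genotype = character(),
             kind = character(), stringsAsFactors = FALSE)
}

#' @title Adjudication-adjusted concordance
#'
#' @description Concordance estimates after orthogonal (Sanger-style)
#' adjudication of discordant sites. Discordances the gold standard resolves
#' in the pipeline's favour are errors of the truth set, not the pipeline;
#' they are reclassified (fn to tp, fp to tn) and summarised as the truth-set
#' error rate: the fraction of adjudicated discordances where the array was
#' wrong.
#'
#' @slot raw,adjusted \linkS4class{ConcordanceTable} before/after
#'   reclassification.
#' @slot truthErrorRate numeric proportion in [0,1], NA when nothing was
#'   adjudicated.
#' @slot nAdjudicated,nPipelineCorrect,nUnresolved integer summary counts.
#' @export
setClass("AdjustedConcordance",
         representation(raw = "ConcordanceTable", adjusted = "ConcordanceTable",
                        truthErrorRate = "numeric", nAdjudicated = "integer",
                        nPipelineCorrect = "integer", nUnresolved = "integer"))

setValidity("AdjustedConcordance", function(object) {
  e <- object@truthErrorRate
  if (!is.na(e) && (e < 0 || e > 1)) "truthErrorRate outside [0,1]" else TRUE
})

#' @title Patient cohort with per-platform variant calls
#'
#' @description A referral cohort: one row per patient (id, phenotype label,
#' optional sex and syndromic features) plus the annotated variant calls
#' observed for each patient on each platform.
#'
#' @slot patients data.frame with columns patient_id, phenotype, sex,
#'   syndromic_features.
#' @slot calls data.frame in the canonical call-table layout, with
#'   patient_id and platform filled in.
#' @export
setClass("Cohort", representation(patients = "data.frame",
                                  calls = "data.frame"))

setValidity("Cohort", function(object) {
  p <- object@patients
  if (!all(c("patient_id", "phenotype") %in% names(p)))
    return("patients needs patient_id and phenotype columns")
  if (anyDuplicated(p$patient_id))
    return("patient_id must be unique within a cohort")
  orphan <- setdiff(object@calls$patient_id, p$patient_id)
  if (length(orphan))
    return(paste("calls reference unknown patients:",
                 paste(utils::head(orphan, 5), collapse = ", ")))
  TRUE
})

#' Construct a Cohort
#'
#' @param patients data.frame with columns patient_id, phenotype and
#'   optionally sex ("male"/"female"/"unknown") and syndromic_features
#'   (semicolon-separated labels).
#' @param calls data.frame of variant calls carrying patient_id and
#'   platform columns, or a \linkS4class{VariantCalls} object.
#' @return A \linkS4class{Cohort}.
#' @export
Cohort <- function(patients, calls = .emptyFrame(.CALL_COLUMNS)) {
  patients <- as.data.frame(patients, stringsAsFactors = FALSE)
  if (!"sex" %in% names(patients)) patients$sex <- "unknown"
  patients$sex[is.na(patients$sex)] <- "unknown"
  if (!"syndromic_features" %in% names(patients))
    patients$syndromic_features <- NA_character_
  if (methods::is(calls, "VariantCalls")) calls <- callTable(calls)
  calls <- callTable(VariantCalls(calls))
  rownames(patients) <- NULL
  methods::new("Cohort", patients = patients[, c("patient_id", "phenotype",
                                                 "sex", "syndromic_features")],
               calls = calls)
}

#' @describeIn Cohort-class Number of patients.
#' @param x A Cohort object.
#' @export
setMethod("length", "Cohort", function(x) nrow(x@patients))

#' Accessors for Cohort contents
#'
#' @param x A \linkS4class{Cohort}.
#' @return \code{patientTable} returns the per-patient data.frame;
#'   \code{cohortCalls} returns the call table, optionally restricted to one
#'   platform.
#' @param platform Optional platform label to filter calls by.
#' @export
patientTable <- function(x) {
  stopifnot(methods::is(x, "Cohort"))
  x@patients
}

#' @rdname patientTable
#' @export
cohortCalls <- function(x, platform = NULL) {
  stopifnot(methods::is(x, "Cohort"))
  df <- x@calls
  if (!is.null(platform)) df <- df[df$platform %in% platform, , drop = FALSE]
  rownames(df) <- NULL
  df
}

setMethod("show", "Cohort", function(object) {
  cat(sprintf("Cohort with %d patient(s), %d call(s) [platforms: %s]\n",
              nrow(object@patients), nrow(object@calls),
              paste(unique(object@calls$platform), collapse = ", ")))
  tb <- sort(table(object@patients$phenotype), decreasing = TRUE)
  cat("  phenotypes: ",
      paste(sprintf("%s (%d)", utils::head(names(tb), 4),
                    utils::head(as.integer(tb), 4)), collapse = ", "),
      if (length(tb) > 4) ", ..." else "", "\n", sep = "")
})

#' @title Diagnostic-yield uplift estimate
#'
#' @description A stratified weighted projection of the gain in molecular
#' diagnoses a new assay would deliver across a referral population,
#' expressed by default as a percentage of the baseline number of diagnoses,
#' with a binomial-simulation percentile confidence interval.
#'
#' @slot point numeric point estimate (percent).
#' @slot ciLow,ciHigh numeric percentile CI bounds (NA before simulation).
#' @slot expectedNew numeric expected number of newly diagnosed patients.
#' @slot nSims,seed integer simulation count and RNG seed (NA for the
#'   point-only estimate).
#' @slot absolute logical; TRUE when point is percentage points of absolute
#'   yield rather than percent of baseline diagnoses.
#' @slot replicates numeric vector of simulated uplift replicates (empty for
#'   the point-only estimate).
#' @export
setClass("UpliftEstimate",
         representation(point = "numeric", ciLow = "numeric",
                        ciHigh = "numeric", expectedNew = "numeric",
                        nSims = "integer", seed = "integer",
                        absolute = "logical", replicates = "numeric"))

setValidity("UpliftEstimate", function(object) {
  if (!is.na(object@ciLow) && !is.na(object@ciHigh) &&
      object@ciLow > object@ciHigh) "ciLow > ciHigh" else TRUE
})

setMethod("show", "UpliftEstimate", function(object) {
  unit <- if (object@absolute) "percentage points" else "% of baseline"
  cat(sprintf("UpliftEstimate: %.1f %s", object@point, unit))
  if (!is.na(object@ciLow))
    cat(sprintf(" (95%% CI %.1f-%.1f, %d sims, seed %d)",
                object@ciLow, object@ciHigh, object@nSims, object@seed))
  cat(sprintf("\n  expected new diagnoses: %.2f\n", object@expectedNew))
})
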