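.splitLabels <- function(x) {
  if (is.na(x) || x == "") character() else strsplit(x, ";", fixed = TRUE)[[1L]]
}

#' Fit of a gene's variants to a patient's disease
#'
#' Decides whether the qualifying (clearly or likely pathogenic) variants
#' observed in one gene explain the patient's disease under the gene's mode
#' of inheritance. A \code{full} fit requires both a sufficient genotype
#' (AD/XLD: at least one variant; AR: homozygous, or two heterozygous
#' variants assumed in trans unless flagged cis; XLR: homozygous or
#' hemizygous, with heterozygous-coded calls promoted to hemizygous for male
#' patients) and a phenotype match between the patient's clinical indication
#' and the gene's known disease associations. A single heterozygous variant
#' in a recessive (AR/XLR) gene is a carrier state: \code{partial} when the
#' gene matches the phenotype, otherwise \code{none}. A genotype-sufficient
#' gene whose phenotypes do not include the patient's indication is
#' \code{none} for diagnosis (an incidental finding).
#'
#' @param variants data.frame of qualifying variant calls, all in this gene.
#' @param model One row of a gene-model table.
#' @param phenotype The patient's clinical-indication label.
#' @param sex "male", "female" or "unknown".
#' @return A list with elements \code{fit} ("full", "partial", "none"),
#'   \code{moi} (mode of inheritance used: AD, AR_hom, AR_comphet, XLD, XLR,
#'   or NA), \code{causal} (row indices of the causal variants),
#'   \code{carrier} (TRUE when the gene holds a single-heterozygote carrier
#'   state regardless of phenotype match) and \code{phenotype_match}.
#' @examples
#' model <- data.frame(gene = "IDH3B", inheritance = "AR",
#'   phenotypes = "RP or rod-cone dystrophy", panel = "panel105")
#' v <- data.frame(chrom = "20", pos = 2638573L, ref = "C", alt = "A",
#'   zygosity = "het", gene = "IDH3B", variant_class = "snv",
#'   region_class = "coding", pathogenicity = "likely_pathogenic")
#' geneFit(v, model, phenotype = "Usher syndrome")$fit  # "none": mismatch
#' @export
geneFit <- function(variants, model, phenotype, sex = "unknown") {
  if (nrow(variants) == 0L)
    return(list(fit = "none", moi = NA_character_, causal = integer(),
                carrier = FALSE, phenotype_match = FALSE))
  stopifnot(length(unique(variants$gene)) == 1L)
  pheno_match <- phenotype %in% .splitLabels(model$phenotypes[1L])
  inh <- model$inheritance[1L]
  zyg <- variants$zygosity
  cis <- if ("cis" %in% names(variants)) variants$cis %in% TRUE
         else rep(FALSE, nrow(variants))
  hom_idx <- which(zyg == "hom")
  hemi_idx <- which(zyg == "hemi")
  het_idx <- which(zyg == "het")
  # Phase: het variants flagged cis share a haplotype and jointly count as
  # one allele when forming a compound heterozygote.
  n_trans_alleles <- sum(zyg == "het" & !cis) + as.integer(any(cis))

  moi <- NA_character_
  causal <- integer()
  sufficient <- FALSE
  carrier <- FALSE
  if (inh %in% c("AD", "XLD")) {
    sufficient <- TRUE
    moi <- inh
    causal <- seq_len(nrow(variants))[order(match(
      variants$pathogenicity, .PATHOGENICITY))][1L]
  } else if (inh == "AR") {
    if (length(hom_idx)) {
      sufficient <- TRUE
      moi <- "AR_hom"
      causal <- hom_idx[1L]
    } else if (n_trans_alleles >= 2L) {
      sufficient <- TRUE
      moi <- "AR_comphet"
      causal <- het_idx
    } else if (length(het_idx) >= 1L) {
      carrier <- TRUE
    }
  } else if (inh == "XLR") {
    promoted_hemi <- if (identical(sex, "male")) het_idx else integer()
    if (length(hom_idx) || length(hemi_idx) || length(promoted_hemi)) {
      sufficient <- TRUE
      moi <- "XLR"
      causal <- c(hemi_idx, hom_idx, promoted_hemi)[1L]
    } else if (length(het_idx) >= 1L) {
      carrier <- TRUE
    }
  } else {
    stop(sprintf("input error: unknown inheritance '%s'", inh), call. = FALSE)
  }

  fit <- if (sufficient && pheno_match) "full"
         else if (carrier && pheno_match) "partial"
         else "none"
  list(fit = fit, moi = if (fit == "full") moi else NA_character_,
       causal = causal, carrier = carrier, phenotype_match = pheno_match)
}

# Default confirmed/provisional policy: a diagnosis is confirmed when at
# least one causal variant is clearly pathogenic and none falls below likely
# pathogenic; causal sets of likely-pathogenic variants only are
# provisional. Replaceable via the `policy` argument of classifyPatient().
confirmedPolicy <- function(causal_pathogenicity) {
  if (any(causal_pathogenicity == "clearly_pathogenic") &&
      all(causal_pathogenicity %in% c("clearly_pathogenic",
                                      "likely_pathogenic")))
    "diagnosed_confirmed"
  else "diagnosed_provisional"
}

#' Classify one patient's clinical outcome
#'
#' Applies the diagnostic decision logic to a patient's annotated variant
#' calls: variants are filtered to the clearly/likely pathogenic tiers,
#' grouped by gene, and each gene's fit to the patient's phenotype is
#' assessed with \code{\link{geneFit}}. A fully fitting gene yields a
#' molecular diagnosis (confirmed or provisional per the pathogenicity
#' policy); with several fully fitting genes the one with the higher
#' pathogenicity tier, then the alphabetically first, is selected.
#' Otherwise a phenotype-matching carrier state yields
#' \code{undiagnosed_carrier_relevant}; a carrier state in a
#' phenotype-unrelated recessive gene yields
#' \code{undiagnosed_carrier_other}; otherwise \code{undiagnosed}. Carrier
#' states in non-selected genes are always retained as reportable carrier
#' findings, for diagnosed patients too.
#'
#' @param variants data.frame of the patient's calls on one platform.
#' @param models Gene-model data.frame.
#' @param phenotype Clinical-indication label.
#' @param sex "male", "female" or "unknown".
#' @param policy Function mapping the causal variants' pathogenicity vector
#'   to "diagnosed_confirmed" or "diagnosed_provisional".
#' @return A list with \code{category} (one of
#'   \code{\link{outcomeCategories}}), \code{diagnosis} (NULL or a list with
#'   gene, moi, causal_variants data.frame) and \code{carrier_findings}
#'   (data.frame of reportable non-causal carrier variants).
#' @export
classifyPatient <- function(variants, models, phenotype, sex = "unknown",
                            policy = confirmedPolicy) {
  v <- variants[variants$pathogenicity %in% c("clearly_pathogenic",
                                              "likely_pathogenic") &
                  !is.na(variants$gene), , drop = FALSE]
  genes <- unique(v$gene)
  missing_models <- setdiff(genes, models$gene)
  if (length(missing_models))
    stop(sprintf("lookup error: gene(s) absent from gene-model table: %s",
                 paste(missing_models, collapse = ", ")), call. = FALSE)
  genes <- sort(genes)  # deterministic, order-independent
  fits <- lapply(genes, function(g) {
    geneFit(v[v$gene == g, , drop = FALSE],
            models[models$gene == g, , drop = FALSE], phenotype, sex)
  })
  names(fits) <- genes

  full_genes <- genes[vapply(fits, function(f) f$fit == "full", logical(1))]
  selected <- NULL
  if (length(full_genes)) {
    tier <- vapply(full_genes, function(g) {
      causal <- v[v$gene == g, , drop = FALSE][fits[[g]]$causal, ,
                                               drop = FALSE]
      min(match(causal$pathogenicity, .PATHOGENICITY))
    }, numeric(1))
    selected <- full_genes[order(tier, full_genes)][1L]
  }

  carrier_rows <- do.call(rbind, lapply(genes, function(g) {
    if (!is.null(selected) && g == selected) return(NULL)
    if (fits[[g]]$carrier)
      v[v$gene == g & v$zygosity == "het", , drop = FALSE][1L, , drop = FALSE]
    else NULL
  }))
  if (is.null(carrier_rows)) carrier_rows <- v[integer(0), , drop = FALSE]
  rownames(carrier_rows) <- NULL

  if (!is.null(selected)) {
    f <- fits[[selected]]
    causal <- v[v$gene == selected, , drop = FALSE][f$causal, , drop = FALSE]
    rownames(causal) <- NULL
    return(list(category = policy(causal$pathogenicity),
                diagnosis = list(gene = selected, moi = f$moi,
                                 causal_variants = causal),
                carrier_findings = carrier_rows))
  }
  any_partial <- any(vapply(fits, function(f)
    f$fit == "partial", logical(1)))
  any_carrier <- any(vapply(fits, function(f) f$carrier, logical(1)))
  category <- if (any_partial) "undiagnosed_carrier_relevant"
              else if (any_carrier) "undiagnosed_carrier_other"
              else "undiagnosed"
  list(category = category, diagnosis = NULL, carrier_findings = carrier_rows)
}

#' Classify every patient of a cohort on one platform
#'
#' @param cohort A \linkS4class{Cohort}.
#' @param models Gene-model data.frame.
#' @param platform Platform label whose calls to interpret ("ngs", "wgs",
#'   "merged", ...). Patients without calls on the platform are classified
#'   from an empty variant list.
#' @param policy See \code{\link{classifyPatient}}.
#' @return data.frame with one row per patient: patient_id, platform,
#'   category, gene, moi, pathogenicity (of the causal set: "clearly",
#'   "likely" or NA), n_causal, n_carrier_findings, carrier_genes
#'   (semicolon-separated).
#' @export
classifyCohort <- function(cohort, models, platform = "ngs",
                           policy = confirmedPolicy) {
  patients <- patientTable(cohort)
  calls <- cohortCalls(cohort, platform)
  by_patient <- split(seq_len(nrow(calls)), calls$patient_id)
  res <- lapply(seq_len(nrow(patients)), function(i) {
    pid <- patients$patient_id[i]
    v <- calls[by_patient[[pid]] %||% integer(0), , drop = FALSE]
    out <- classifyPatient(v, models, patients$phenotype[i],
                           sex = patients$sex[i], policy = policy)
    data.frame(
      patient_id = pid, platform = platform, category = out$category,
      gene = if (is.null(out$diagnosis)) NA_character_ else
        out$diagnosis$gene,
      moi = if (is.null(out$diagnosis)) NA_character_ else out$diagnosis$moi,
      pathogenicity = if (is.null(out$diagnosis)) NA_character_ else
        if (any(out$diagnosis$causal_variants$pathogenicity ==
                "clearly_pathogenic")) "clearly" else "likely",
      n_causal = if (is.null(out$diagnosis)) 0L else
        nrow(out$diagnosis$causal_variants),
      n_carrier_findings = nrow(out$carrier_findings),
      carrier_genes = paste(out$carrier_findings$gene, collapse = ";"),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Merge two platforms' calls for every patient
#'
#' Builds the per-patient union of the two call sets after normalisation,
#' collapsing duplicates by \code{\link{sameVariant}}. When the same variant
#' is observed with conflicting zygosity the second platform's call wins
#' (consecutive screening: the later assay re-evaluates the earlier
#' genotype) and a note is recorded. The merged calls are stored under the
#' platform label \code{"merged"}.
#'
#' @param cohort A \linkS4class{Cohort} holding calls for both platforms.
#' @param platforms Character(2): the earlier and later platform labels.
#' @param overlap_threshold Deletion-identity threshold for
#'   \code{\link{sameVariant}}.
#' @return The cohort with \code{"merged"} calls appended (replacing any
#'   previous merged set). Attribute \code{"zygosity_notes"} on the call
#'   table records resolved conflicts.
#' @export
mergePlatforms <- function(cohort, platforms = c("ngs", "wgs"),
                           overlap_threshold = 0.8) {
  first <- normalizeCalls(cohortCalls(cohort, platforms[1L]))
  second <- normalizeCalls(cohortCalls(cohort, platforms[2L]))
  notes <- character()
  merged <- lapply(unique(c(first$patient_id, second$patient_id)),
                   function(pid) {
    f <- first[first$patient_id == pid, , drop = FALSE]
    s <- second[second$patient_id == pid, , drop = FALSE]
    keep <- rep(TRUE, nrow(f))
    for (i in seq_len(nrow(f))) {
      for (j in seq_len(nrow(s))) {
        if (sameVariant(f[i, ], s[j, ], overlap_threshold)) {
          keep[i] <- FALSE
          if (!identical(f$zygosity[i], s$zygosity[j]))
            notes <<- c(notes, sprintf(
              "%s %s:%d zygosity %s (%s) superseded by %s (%s)", pid,
              f$chrom[i], f$pos[i], f$zygosity[i], platforms[1L],
              s$zygosity[j], platforms[2L]))
          break
        }
      }
    }
    rbind(s, f[keep, , drop = FALSE])
  })
  merged <- do.call(rbind, merged)
  if (is.null(merged)) merged <- first[integer(0), , drop = FALSE]
  merged$platform <- "merged"
  old <- cohort@calls[cohort@calls$platform != "merged", , drop = FALSE]
  out <- Cohort(patientTable(cohort), rbind(old, merged))
  attr(out@calls, "zygosity_notes") <- notes
  out
}

#' Summarise clinical outcomes across a cohort
#'
#' @param outcomes data.frame from \code{\link{classifyCohort}}.
#' @return A named list: cohort size, per-category counts, number
#'   diagnosed, diagnostic yield as a whole-number percentage, carrier
#'   accounting (patients with at least one carrier finding, split by
#'   diagnosed/undiagnosed), the mode-of-inheritance breakdown of
#'   diagnoses, and causal-variant totals under both homozygote-counting
#'   conventions (each homozygous genotype counted as one variant, or as
#'   two alleles).
#' @export
cohortSummary <- function(outcomes) {
  if (any(is.na(outcomes$category)))
    stop("state error: unclassified record in outcomes", call. = FALSE)
  n <- nrow(outcomes)
  cat_counts <- as.list(table(factor(outcomes$category,
                                     levels = .OUTCOME_CATEGORIES)))
  cat_counts <- lapply(cat_counts, as.integer)
  diagnosed <- outcomes$category %in% c("diagnosed_confirmed",
                                        "diagnosed_provisional")
  has_carrier <- outcomes$n_carrier_findings > 0L
  moi_counts <- as.list(table(factor(outcomes$moi[diagnosed],
                                     levels = .MOI)))
  moi_counts <- lapply(moi_counts, as.integer)
  n_hom_once <- sum(outcomes$n_causal)
  n_hom_genotypes <- sum(diagnosed & outcomes$moi %in% c("AR_hom"))
  list(n = n,
       categories = cat_counts,
       n_diagnosed = as.integer(sum(diagnosed)),
       yield_pct = as.integer(round(100 * sum(diagnosed) / max(n, 1L))),
       n_carrier_patients = as.integer(sum(has_carrier)),
       n_carrier_diagnosed = as.integer(sum(has_carrier & diagnosed)),
       n_carrier_undiagnosed = as.integer(sum(has_carrier & !diagnosed)),
       moi = moi_counts,
       n_causal_variants_hom_once = as.integer(n_hom_once),
       n_causal_variants_hom_twice = as.integer(n_hom_once +
                                                  n_hom_genotypes))
}
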