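#' Restrict truth sites to target regions
#'
#' Keeps exactly the truth sites whose 1-based position falls inside one of
#' the target intervals, preserving input order. Chromosome labels are
#' compared on a normalised key (leading "chr" ignored).
#'
#' @param sites A \linkS4class{GenotypeSites} object.
#' @param regions A \code{GRanges} of target regions (see
#'   \code{\link{readRegions}}).
#' @return A \linkS4class{GenotypeSites} containing the retained sites.
#' @export
restrictSites <- function(sites, regions) {
  df <- siteTable(sites)
  if (nrow(df) == 0L || length(regions) == 0L)
    return(GenotypeSites(df[integer(0), ], warnings = sites@warnings))
  site_gr <- GenomicRanges::GRanges(.chromKey(df$chrom),
                                    IRanges::IRanges(df$pos, df$pos))
  reg_gr <- GenomicRanges::GRanges(
    .chromKey(as.character(GenomicRanges::seqnames(regions))),
    IRanges::IRanges(GenomicRanges::start(regions),
                     GenomicRanges::end(regions)))
  hit <- GenomicRanges::countOverlaps(site_gr, reg_gr,
                                      ignore.strand = TRUE) > 0L
  GenotypeSites(df[hit, , drop = FALSE], warnings = sites@warnings)
}

# Classify one truth site against the variant calls at its position.
# Detection-oriented scoring: a truth SNV is a tp when any call carries the
# truth alt allele at that position, regardless of zygosity agreement;
# genotype_strict additionally requires zygosity concordance (truth het with
# call het; truth hom_alt with call hom/hemi).
.classifyOne <- function(genotype_class, alt_allele, call_alts,
                         call_zygosities, genotype_strict = FALSE) {
  if (!genotype_class %in% .GENOTYPE_CLASSES)
    stop(sprintf("input error: unknown genotype_class '%s'", genotype_class),
         call. = FALSE)
  if (genotype_class == "hom_ref")
    return(if (length(call_alts)) "fp" else "tn")
  match_idx <- which(call_alts == alt_allele)
  if (!length(match_idx)) return("fn")
  if (genotype_strict) {
    want <- if (genotype_class == "het") "het" else c("hom", "hemi")
    if (!any(call_zygosities[match_idx] %in% want)) return("fn")
  }
  "tp"
}

#' Classify a single truth site
#'
#' Scores one array-genotyped site against the variant calls made at the
#' same position: a truth SNV (het or hom_alt) detected by any call carrying
#' its alternate allele is a true positive, otherwise a false negative; a
#' truth homozygous-reference site is a true negative unless any variant was
#' called there, in which case it is a false positive.
#'
#' @param truth One-row data.frame (or list) with fields chrom, pos,
#'   alt_allele, genotype_class.
#' @param calls A \linkS4class{VariantCalls} object or canonical call
#'   data.frame; only calls at the truth site's (chrom, pos) are considered.
#' @param genotype_strict Require zygosity concordance for a tp.
#' @return One of \code{"tp"}, \code{"fn"}, \code{"tn"}, \code{"fp"}.
#' @export
classifySite <- function(truth, calls, genotype_strict = FALSE) {
  df <- if (methods::is(calls, "VariantCalls")) callTable(calls) else calls
  here <- .chromKey(df$chrom) == .chromKey(truth$chrom) & df$pos == truth$pos
  .classifyOne(truth$genotype_class, truth$alt_allele, df$alt[here],
               df$zygosity[here], genotype_strict)
}

#' Build a concordance confusion table
#'
#' Restricts the truth sites to the target regions, classifies each site
#' against the call set with \code{\link{classifySite}} semantics, and
#' accumulates the confusion-matrix counts. Discordant sites (fn, fp) are
#' recorded individually for downstream adjudication; zygosity mismatches at
#' detected sites are recorded too but scored as tp unless
#' \code{genotype_strict}.
#'
#' @param truth A \linkS4class{GenotypeSites} object.
#' @param calls A \linkS4class{VariantCalls} object or call data.frame.
#' @param regions Optional \code{GRanges}; when NULL all truth sites are
#'   used.
#' @param genotype_strict Require zygosity concordance for a tp.
#' @return A \linkS4class{ConcordanceTable}.
#' @examples
#' truth <- GenotypeSites(data.frame(chrom = "1", pos = c(100L, 200L),
#'   ref_allele = "A", alt_allele = c("G", NA),
#'   genotype_class = c("het", "hom_ref")))
#' calls <- VariantCalls(data.frame(chrom = "1", pos = 100L, ref = "A",
#'   alt = "G", zygosity = "het", variant_class = "snv",
#'   pathogenicity = "uncertain"))
#' sensitivity(buildConcordance(truth, calls))
#' @export
buildConcordance <- function(truth, calls, regions = NULL,
                             genotype_strict = FALSE) {
  if (!is.null(regions)) truth <- restrictSites(truth, regions)
  tdf <- siteTable(truth)
  cdf <- if (methods::is(calls, "VariantCalls")) callTable(calls) else calls
  ckey <- paste(.chromKey(cdf$chrom), cdf$pos)
  tkey <- paste(.chromKey(tdf$chrom), tdf$pos)
  calls_by_site <- split(seq_len(nrow(cdf)), ckey)
  tp <- fn <- tn <- fp <- 0L
  disc <- vector("list", nrow(tdf))
  for (i in seq_len(nrow(tdf))) {
    idx <- calls_by_site[[tkey[i]]]
    cls <- .classifyOne(tdf$genotype_class[i], tdf$alt_allele[i],
                        cdf$alt[idx], cdf$zygosity[idx], genotype_strict)
    pg <- if (length(idx)) paste(unique(cdf$zygosity[idx]), collapse = ",")
          else "no_call"
    if (cls == "tp") {
      tp <- tp + 1L
      want <- if (tdf$genotype_class[i] == "het") "het" else c("hom", "hemi")
      matched <- cdf$zygosity[idx][cdf$alt[idx] == tdf$alt_allele[i]]
      if (length(matched) && !any(matched %in% want))
        disc[[i]] <- data.frame(chrom = tdf$chrom[i], pos = tdf$pos[i],
                                truth_genotype = tdf$genotype_class[i],
                                pipeline_genotype = pg,
                                kind = "zygosity_mismatch",
                                stringsAsFactors = FALSE)
    } else if (cls == "tn") {
      tn <- tn + 1L
    } else {
      if (cls == "fn") fn <- fn + 1L else fp <- fp + 1L
      disc[[i]] <- data.frame(chrom = tdf$chrom[i], pos = tdf$pos[i],
                              truth_genotype = tdf$genotype_class[i],
                              pipeline_genotype = pg, kind = cls,
                              stringsAsFactors = FALSE)
    }
  }
  disc <- disc[!vapply(disc, is.null, logical(1))]
  discordant <- if (length(disc)) do.call(rbind, disc) else .emptyDiscordant()
  ConcordanceTable(tp = tp, fn = fn, tn = tn, fp = fp,
                   discordant = discordant)
}

#' @rdname sensitivity
#' @export
setMethod("sensitivity", "ConcordanceTable", function(object) {
  if (object@tp + object@fn == 0L) NA_real_
  else object@tp / (object@tp + object@fn)
})

#' @rdname specificity
#' @export
setMethod("specificity", "ConcordanceTable", function(object) {
  if (object@tn + object@fp == 0L) NA_real_
  else object@tn / (object@tn + object@fp)
})

#' @rdname sensitivity
#' @export
setMethod("sensitivity", "AdjustedConcordance",
          function(object) sensitivity(object@adjusted))

#' @rdname specificity
#' @export
setMethod("specificity", "AdjustedConcordance",
          function(object) specificity(object@adjusted))

.fmtPct <- function(p) if (is.na(p)) "undefined" else
  sprintf("%.1f%%", 100 * p)

setMethod("show", "ConcordanceTable", function(object) {
  cat(sprintf("ConcordanceTable: tp=%d fn=%d tn=%d fp=%d\n",
              object@tp, object@fn, object@tn, object@fp))
  cat(sprintf("  sensitivity %s, specificity %s, %d discordant site(s)\n",
              .fmtPct(sensitivity(object)), .fmtPct(specificity(object)),
              nrow(object@discordant)))
})

#' Adjust a concordance table using adjudicated discordances
#'
#' Discordant sites re-examined with an orthogonal gold-standard assay
#' (Sanger sequencing) resolve either in the pipeline's favour (the array
#' genotype was wrong), in the truth set's favour, or remain unresolved.
#' Each \code{pipeline_correct} resolution reclassifies its discordance
#' within its truth row (an fn becomes a tp contribution, an fp a tn), so
#' row totals tp+fn and tn+fp are conserved. The truth-set error rate is the
#' fraction of adjudicated discordances resolved \code{pipeline_correct};
#' unresolved and \code{truth_correct} discordances remain errors charged to
#' the pipeline.
#'
#' @param table A \linkS4class{ConcordanceTable}.
#' @param records data.frame of adjudications with columns chrom, pos,
#'   resolution (pipeline_correct, truth_correct, unresolved). Every record
#'   must refer to a discordant (fn/fp) site of \code{table}.
#' @return An \linkS4class{AdjustedConcordance}.
#' @export
adjustWithAdjudication <- function(table, records = NULL) {
  disc <- table@discordant
  disc <- disc[disc$kind %in% c("fn", "fp"), , drop = FALSE]
  if (is.null(records) || nrow(records) == 0L) {
    return(methods::new("AdjustedConcordance", raw = table, adjusted = table,
                        truthErrorRate = NA_real_, nAdjudicated = 0L,
                        nPipelineCorrect = 0L, nUnresolved = 0L))
  }
  if (!all(records$resolution %in% .RESOLUTIONS))
    stop("input error: unknown adjudication resolution", call. = FALSE)
  dkey <- paste(.chromKey(disc$chrom), disc$pos, disc$kind)
  rkey_fn <- paste(.chromKey(records$chrom), records$pos, "fn")
  rkey_fp <- paste(.chromKey(records$chrom), records$pos, "fp")
  is_fn <- rkey_fn %in% dkey
  is_fp <- rkey_fp %in% dkey
  if (any(!is_fn & !is_fp))
    stop(sprintf("input error: adjudication refers to concordant site %s:%s",
                 records$chrom[!is_fn & !is_fp][1],
                 records$pos[!is_fn & !is_fp][1]), call. = FALSE)
  correct <- records$resolution == "pipeline_correct"
  d_fn <- sum(correct & is_fn)
  d_fp <- sum(correct & is_fp)
  adjusted <- ConcordanceTable(tp = table@tp + d_fn, fn = table@fn - d_fn,
                               tn = table@tn + d_fp, fp = table@fp - d_fp,
                               discordant = table@discordant)
  methods::new("AdjustedConcordance", raw = table, adjusted = adjusted,
               truthErrorRate = sum(correct) / nrow(records),
               nAdjudicated = nrow(records),
               nPipelineCorrect = as.integer(sum(correct)),
               nUnresolved = as.integer(
                 sum(records$resolution == "unresolved")))
}

setMethod("show", "AdjustedConcordance", function(object) {
  cat("AdjustedConcordance\n  raw:      ")
  cat(sprintf("tp=%d fn=%d tn=%d fp=%d (sens %s, spec %s)\n",
              object@raw@tp, object@raw@fn, object@raw@tn, object@raw@fp,
              .fmtPct(sensitivity(object@raw)),
              .fmtPct(specificity(object@raw))))
  cat("  adjusted: ")
  cat(sprintf("tp=%d fn=%d tn=%d fp=%d (sens %s, spec %s)\n",
              object@adjusted@tp, object@adjusted@fn, object@adjusted@tn,
              object@adjusted@fp, .fmtPct(sensitivity(object@adjusted)),
              .fmtPct(specificity(object@adjusted))))
  ter <- if (is.na(object@truthErrorRate)) "undefined"
         else sprintf("%.2f%%", 100 * object@truthErrorRate)
  cat(sprintf("  truth-set error rate %s over %d adjudicated (%d unresolved)\n",
              ter, object@nAdjudicated, object@nUnresolved))
})
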