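# Trim the shared suffix then shared prefix from a ref/alt pair, advancing
# pos for each trimmed leading base. Returns list(pos, ref, alt).
.trimAlleles <- function(pos, ref, alt) {
  while (nchar(ref) > 0L && nchar(alt) > 0L &&
         substr(ref, nchar(ref), nchar(ref)) ==
         substr(alt, nchar(alt), nchar(alt))) {
    ref <- substr(ref, 1L, nchar(ref) - 1L)
    alt <- substr(alt, 1L, nchar(alt) - 1L)
  }
  while (nchar(ref) > 0L && nchar(alt) > 0L &&
         substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
    ref <- substring(ref, 2L)
    alt <- substring(alt, 2L)
    pos <- pos + 1L
  }
  list(pos = pos, ref = ref, alt = alt)
}

# Left-shift a trimmed pure insertion/deletion against a local reference
# context (parsimony-style left alignment). `context` covers 1-based
# positions context_start .. context_start+nchar(context)-1.
.leftShift <- function(pos, ref, alt, context, context_start) {
  ctx <- function(p) {
    i <- p - context_start + 1L
    if (i < 1L || i > nchar(context)) NA_character_
    else substr(context, i, i)
  }
  seq_ <- if (nchar(ref) > 0L) ref else alt   # the indel sequence
  while (pos > context_start) {
    prev <- ctx(pos - 1L)
    last <- substr(seq_, nchar(seq_), nchar(seq_))
    if (is.na(prev) || prev != last) break
    seq_ <- paste0(prev, substr(seq_, 1L, nchar(seq_) - 1L))
    pos <- pos - 1L
  }
  if (nchar(ref) > 0L) list(pos = pos, ref = seq_, alt = alt)
  else list(pos = pos, ref = ref, alt = seq_)
}

#' Normalise variant representations
#'
#' Puts every explicit-allele call into a canonical minimal form so that
#' equivalent encodings of the same event compare equal: shared prefix and
#' suffix bases are trimmed (a "-" or empty allele denotes a pure
#' insertion/deletion), and, when a local reference context is supplied,
#' pure indels are shifted to their leftmost equivalent position. SNVs and
#' symbolic large deletions pass through unchanged. The operation is
#' idempotent. A call whose ref equals its alt after trimming is a null
#' variant and raises an error.
#'
#' @param x A \linkS4class{VariantCalls} object or canonical call
#'   data.frame.
#' @param context Optional local reference sequence used for left-shifting;
#'   when NULL, trimming alone is performed (no-reference mode).
#' @param context_chrom,context_start Chromosome and 1-based position of the
#'   first base of \code{context}.
#' @return An object of the same kind as \code{x} with normalised calls.
#' @examples
#' v <- data.frame(chrom = "1", pos = 100L, ref = "AT", alt = "A",
#'   zygosity = "het", variant_class = "indel", region_class = "coding",
#'   pathogenicity = "uncertain")
#' callTable(normalizeCalls(VariantCalls(v)))[, c("pos", "ref", "alt")]
#' @export
normalizeCalls <- function(x, context = NULL, context_chrom = NULL,
                           context_start = 1L) {
  was_s4 <- methods::is(x, "VariantCalls")
  df <- if (was_s4) callTable(x) else x
  for (i in seq_len(nrow(df))) {
    if (df$variant_class[i] %in% c("snv", "large_deletion")) next
    ref <- toupper(df$ref[i])
    alt <- df$alt[i]
    alt <- if (is.na(alt) || alt == "-") "" else toupper(alt)
    tr <- .trimAlleles(df$pos[i], ref, alt)
    if (tr$ref == tr$alt)
      stop(sprintf("null-variant error: ref == alt after trimming at %s:%d",
                   df$chrom[i], df$pos[i]), call. = FALSE)
    if (!is.null(context) && xor(nchar(tr$ref) == 0L, nchar(tr$alt) == 0L) &&
        (is.null(context_chrom) ||
         .chromKey(context_chrom) == .chromKey(df$chrom[i])))
      tr <- .leftShift(tr$pos, tr$ref, tr$alt, toupper(context),
                       as.integer(context_start))
    df$pos[i] <- tr$pos
    df$ref[i] <- tr$ref
    df$alt[i] <- tr$alt
    df$variant_class[i] <- if (nchar(tr$ref) == 1L && nchar(tr$alt) == 1L)
      "snv" else if (nchar(tr$ref) > 0L && nchar(tr$alt) > 0L)
      "complex_indel" else "indel"
  }
  if (was_s4) VariantCalls(df) else df
}

# Reciprocal overlap of two 1-based inclusive intervals.
.reciprocalOverlap <- function(s1, e1, s2, e2) {
  ov <- min(e1, e2) - max(s1, s2) + 1L
  if (ov <= 0L) return(0)
  min(ov / (e1 - s1 + 1L), ov / (e2 - s2 + 1L))
}

#' Test whether two calls describe the same variant
#'
#' Sequence variants (both calls normalised, see
#' \code{\link{normalizeCalls}}) are identical when chromosome, position,
#' ref and alt all match. Large deletions are identified by interval
#' similarity instead: the reciprocal overlap of their deleted segments must
#' reach \code{overlap_threshold}, the standard tolerance for imprecise
#' structural-variant breakpoints. Zygosity is deliberately not compared.
#'
#' @param a,b Single calls (one-row data.frames or lists with the canonical
#'   call fields).
#' @param overlap_threshold Minimum reciprocal overlap for deletion
#'   identity (default 0.8).
#' @return Logical.
#' @export
sameVariant <- function(a, b, overlap_threshold = 0.8) {
  if (.chromKey(a$chrom) != .chromKey(b$chrom)) return(FALSE)
  a_del <- a$variant_class == "large_deletion"
  b_del <- b$variant_class == "large_deletion"
  if (a_del != b_del) return(FALSE)
  if (a_del)
    return(.reciprocalOverlap(a$pos, a$end_pos, b$pos, b$end_pos) >=
           overlap_threshold)
  isTRUE(a$pos == b$pos) && isTRUE(a$ref == b$ref) && isTRUE(a$alt == b$alt)
}

#' Categorise a platform-exclusive variant
#'
#' Assigns one of the five difference categories, applying the precedence:
#' large deletion; variant in a gene outside the first-tier panel;
#' informatics miss (the variant appears in the explicit known-miss list of
#' previously analysable but uncalled/unreported variants); intronic
#' variant (by region class); complex insertion/deletion otherwise. The
#' known-miss list is the only route into \code{informatics_miss}: noncoding
#' variants are classified by their region class even when they fall inside
#' the capture design's intronic flanks. A panel-gene coding SNV found by
#' one platform only is, within this taxonomy, necessarily an undeclared
#' informatics miss and raises an error rather than being guessed.
#'
#' @param v A single call (one-row data.frame or list).
#' @param models Gene-model data.frame (see \code{\link{readGeneModels}}).
#' @param known_miss Optional data.frame with columns chrom, pos and
#'   optionally alt identifying known informatics misses.
#' @return A category label from \code{\link{diffCategories}}.
#' @export
categorizeVariant <- function(v, models, known_miss = NULL) {
  if (is.na(v$gene))
    stop(sprintf("categorization error: unannotated variant at %s:%d",
                 v$chrom, v$pos), call. = FALSE)
  m <- models[models$gene == v$gene, , drop = FALSE]
  if (nrow(m) == 0L)
    stop(sprintf("lookup error: gene '%s' absent from gene-model table",
                 v$gene), call. = FALSE)
  if (v$variant_class == "large_deletion") return("large_deletion")
  if (m$panel[1L] %in% c("panel180_only", "off_panel"))
    return("additional_gene_variant")
  if (.inKnownMiss(v, known_miss)) return("informatics_miss")
  if (!is.na(v$region_class) && v$region_class == "intronic")
    return("intronic_variant")
  if (v$variant_class %in% c("indel", "complex_indel"))
    return("insertion_deletion")
  stop(sprintf(paste0("categorization error: coding %s at %s:%d is not in ",
                      "the known-miss list"), v$variant_class, v$chrom,
               v$pos), call. = FALSE)
}

.inKnownMiss <- function(v, known_miss) {
  if (is.null(known_miss) || nrow(known_miss) == 0L) return(FALSE)
  hit <- .chromKey(known_miss$chrom) == .chromKey(v$chrom) &
    as.integer(known_miss$pos) == v$pos
  if ("alt" %in% names(known_miss))
    hit <- hit & (is.na(known_miss$alt) | known_miss$alt == v$alt)
  any(hit)
}

#' Difference two platforms' call sets
#'
#' Returns the clinically relevant variants (pathogenicity clearly or
#' likely pathogenic, by default) present in the first platform's calls and
#' absent from the second's, after normalisation, matched per patient when
#' patient identifiers are present and by \code{\link{sameVariant}}
#' semantics. Each exclusive variant is categorised when a gene-model table
#' is supplied. Output rows are ordered by (chromosome, position).
#'
#' @param wgs,ngs \linkS4class{VariantCalls} objects or call data.frames:
#'   the set searched for exclusive variants and the comparator set.
#' @param models Optional gene-model data.frame; enables categorisation.
#' @param known_miss Optional known-miss data.frame (see
#'   \code{\link{categorizeVariant}}).
#' @param relevance Pathogenicity classes considered clinically relevant.
#' @param overlap_threshold Reciprocal-overlap threshold for deletion
#'   identity.
#' @param normalize Normalise both call sets before comparing.
#' @return data.frame of difference records: patient_id, the variant
#'   columns, category (NA when \code{models} is NULL) and rationale.
#' @export
diffCallsets <- function(wgs, ngs, models = NULL, known_miss = NULL,
                         relevance = c("clearly_pathogenic",
                                       "likely_pathogenic"),
                         overlap_threshold = 0.8, normalize = TRUE) {
  wdf <- if (methods::is(wgs, "VariantCalls")) callTable(wgs) else wgs
  ndf <- if (methods::is(ngs, "VariantCalls")) callTable(ngs) else ngs
  if (normalize) {
    wdf <- normalizeCalls(wdf)
    ndf <- normalizeCalls(ndf)
  }
  wdf <- wdf[wdf$pathogenicity %in% relevance, , drop = FALSE]
  per_patient <- !all(is.na(wdf$patient_id)) || !all(is.na(ndf$patient_id))
  keep <- logical(nrow(wdf))
  for (i in seq_len(nrow(wdf))) {
    cand <- if (per_patient)
      which(ndf$patient_id == wdf$patient_id[i]) else seq_len(nrow(ndf))
    matched <- FALSE
    for (j in cand) {
      if (sameVariant(wdf[i, ], ndf[j, ], overlap_threshold)) {
        matched <- TRUE
        break
      }
    }
    keep[i] <- !matched
  }
  out <- wdf[keep, , drop = FALSE]
  if (nrow(out)) {
    rationale <- sprintf("present in %s calls only",
                         ifelse(is.na(out$platform), "first-platform",
                                out$platform))
    out$category <- vapply(seq_len(nrow(out)), function(i) {
      if (is.null(models)) return(NA_character_)
      tryCatch(categorizeVariant(out[i, ], models, known_miss),
               error = function(e) {
                 rationale[i] <<- conditionMessage(e)
                 NA_character_
               })
    }, character(1))
    out$rationale <- rationale
    out <- out[order(.chromKey(out$chrom), out$pos), , drop = FALSE]
  } else {
    out$category <- character(0)
    out$rationale <- character(0)
  }
  rownames(out) <- NULL
  out
}
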