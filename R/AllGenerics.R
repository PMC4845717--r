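#' Sensitivity of a concordance table
#'
#' Fraction of truth-set single-nucleotide variants detected by the
#' sequencing pipeline, tp/(tp+fn). Undefined (no truth SNVs) is reported as
#' NA, never as 0 or 1.
#'
#' @param object A \linkS4class{ConcordanceTable} or
#'   \linkS4class{AdjustedConcordance}.
#' @return Numeric proportion in [0,1], or NA when undefined.
#' @export
setGeneric("sensitivity", function(object) standardGeneric("sensitivity"))

#' Specificity of a concordance table
#'
#' Fraction of truth-set homozygous-reference sites at which the pipeline
#' makes no variant call, tn/(tn+fp). Undefined (no truth hom-ref sites) is
#' reported as NA, never as 0 or 1.
#'
#' @inheritParams sensitivity
#' @return Numeric proportion in [0,1], or NA when undefined.
#' @export
setGeneric("specificity", function(object) standardGeneric("specificity"))

#' Write a stage result as a structured, machine-readable report
#'
#' Serialises a result object to a YAML document with stable key order so
#' that counts round-trip exactly through \code{\link{readReport}}.
#'
#' @param object A result object (\linkS4class{ConcordanceTable},
#'   \linkS4class{AdjustedConcordance}, \linkS4class{UpliftEstimate}, or a
#'   named list such as a cohort summary).
#' @param path File path to write.
#' @return Invisibly, the list that was serialised.
#' @export
setGeneric("writeReport", function(object, path) standardGeneric("writeReport"))
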