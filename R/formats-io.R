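# Chromosome labels are compared on a normalised key (leading "chr"
# stripped); readers can additionally rewrite the stored label.
.chromKey <- function(chrom) sub("^chr", "", chrom)

.applyChromStyle <- function(chrom, style = c("keep", "strip", "add")) {
  style <- match.arg(style)
  switch(style,
         keep  = chrom,
         strip = .chromKey(chrom),
         add   = paste0("chr", .chromKey(chrom)))
}

.readTsv <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t",
                    colClasses = "character", comment.char = "#",
                    na.strings = c("NA", ""), stringsAsFactors = FALSE)
}

.requireColumns <- function(df, cols, path) {
  missing_cols <- setdiff(cols, names(df))
  if (length(missing_cols))
    stop(sprintf("schema error in '%s': missing required column(s) %s",
                 path, paste(missing_cols, collapse = ", ")), call. = FALSE)
}

# Derive the variant class from explicit alleles (symbolic deletions are
# classed before this is reached).
.classifyAlleles <- function(ref, alt) {
  ifelse(nchar(ref) == 1L & nchar(alt) == 1L, "snv",
         ifelse(nchar(ref) > 1L & nchar(alt) > 1L & nchar(ref) != nchar(alt),
                "complex_indel", "indel"))
}

#' Read a variant call set (VCF or TSV dialect)
#'
#' Reads one patient/platform call set from either a VCF 4.x file restricted
#' to a documented subset (explicit SNV/indel records with a GT genotype,
#' plus symbolic \code{<DEL>} records carrying an \code{END} INFO key), or
#' from the package's tab-separated dialect. Clinical annotations travel in
#' the INFO keys \code{GENE}, \code{CDNA}, \code{PATH_CLASS} and
#' \code{REGION_CLASS} (VCF) or in like-named columns (TSV). Positions are
#' 1-based throughout; a symbolic deletion spans the 1-based inclusive
#' segment \code{[pos, end_pos]}. Unknown annotation vocabulary values are
#' an error, never silently defaulted.
#'
#' The TSV dialect has header columns \code{chrom, pos, ref, alt, zygosity,
#' gene, cdna, variant_class, region_class, pathogenicity} and optionally
#' \code{end_pos, patient_id, cis}.
#'
#' @param path Path to a \code{.vcf} or \code{.tsv} file.
#' @param platform Platform label stored on every call (e.g. "ngs", "wgs").
#' @param chrom_style How to store chromosome labels: "keep" (as read),
#'   "strip" (remove any "chr" prefix) or "add".
#' @return A \linkS4class{VariantCalls} object.
#' @examples
#' vcf <- file.path(tempdir(), "ex.vcf")
#' writeLines(c("##fileformat=VCFv4.2",
#'   "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene\">",
#'   "##INFO=<ID=PATH_CLASS,Number=1,Type=String,Description=\"Class\">",
#'   "##INFO=<ID=REGION_CLASS,Number=1,Type=String,Description=\"Region\">",
#'   "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
#'   "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1",
#'   paste("chr1", 94476951, ".", "T", "C", ".", ".",
#'     "GENE=ABCA4;PATH_CLASS=likely_pathogenic;REGION_CLASS=intronic",
#'     "GT", "0/1", sep = "\t")), vcf)
#' readCallset(vcf, platform = "wgs")
#' @export
readCallset <- function(path, platform = "ngs",
                        chrom_style = c("keep", "strip", "add")) {
  chrom_style <- match.arg(chrom_style)
  ext <- tolower(tools::file_ext(path))
  df <- if (ext %in% c("vcf", "gz")) .readCallsVcf(path)
        else .readCallsTsv(path)
  df$platform <- rep(platform, nrow(df))
  df$chrom <- .applyChromStyle(df$chrom, chrom_style)
  bad <- !is.na(df$end_pos) & df$end_pos < df$pos
  if (any(bad))
    stop(sprintf("parse error in '%s': deletion end < start at %s:%d", path,
                 df$chrom[bad][1], df$pos[bad][1]), call. = FALSE)
  VariantCalls(df)
}

.readCallsVcf <- function(path) {
  vcf <- VariantAnnotation::readVcf(path, genome = "hg19")
  n <- length(vcf)
  rr <- SummarizedExperiment::rowRanges(vcf)
  info <- VariantAnnotation::info(vcf)
  geno <- VariantAnnotation::geno(vcf)
  if (!"GT" %in% names(geno) || ncol(vcf) < 1L) {
    if (n > 0L)
      stop(sprintf("schema error in '%s': GT genotype field required", path),
           call. = FALSE)
    gt <- character(0)
  } else {
    gt <- as.character(geno$GT[, 1L])
  }
  infoCol <- function(key) {
    if (key %in% names(info)) {
      v <- info[[key]]
      if (is(v, "List")) v <- vapply(v, function(x)
        if (length(x)) as.character(x[[1L]]) else NA_character_, character(1))
      as.character(v)
    } else rep(NA_character_, n)
  }
  alt_list <- VariantAnnotation::alt(vcf)
  alt_chr <- lapply(seq_len(n), function(i) as.character(alt_list[[i]]))
  idx <- rep(seq_len(n), times = lengths(alt_chr))
  alt <- as.character(unlist(alt_chr, use.names = FALSE))
  if (n == 0L) alt <- character(0)
  end_info <- if ("END" %in% names(info)) suppressWarnings(
    as.integer(as.character(info$END))) else rep(NA_integer_, n)
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(rr))[idx],
    pos = GenomicRanges::start(rr)[idx],
    ref = as.character(VariantAnnotation::ref(vcf))[idx],
    alt = alt,
    gene = infoCol("GENE")[idx],
    cdna = infoCol("CDNA")[idx],
    region_class = infoCol("REGION_CLASS")[idx],
    pathogenicity = infoCol("PATH_CLASS")[idx],
    end_pos = end_info[idx],
    zygosity = vapply(gt[idx], .gtToZygosity, character(1), USE.NAMES = FALSE),
    stringsAsFactors = FALSE)
  symbolic <- df$alt == "<DEL>"
  df$variant_class <- ifelse(symbolic, "large_deletion",
                             .classifyAlleles(df$ref, df$alt))
  if (any(symbolic & is.na(df$end_pos)))
    stop(sprintf("parse error in '%s': symbolic <DEL> without END", path),
         call. = FALSE)
  df$end_pos[!symbolic] <- NA_integer_
  df$alt[symbolic] <- NA_character_
  df
}

.gtToZygosity <- function(gt) {
  if (is.na(gt)) stop("schema error: missing GT genotype", call. = FALSE)
  alleles <- strsplit(gt, "[/|]")[[1L]]
  nonref <- sum(alleles != "0" & alleles != ".")
  if (length(alleles) == 1L) return("hemi")
  if (nonref >= length(alleles)) "hom" else "het"
}

.readCallsTsv <- function(path) {
  df <- .readTsv(path)
  .requireColumns(df, c("chrom", "pos", "ref", "alt", "zygosity", "gene",
                        "variant_class", "region_class", "pathogenicity"),
                  path)
  df$pos <- as.integer(df$pos)
  if ("end_pos" %in% names(df)) df$end_pos <- as.integer(df$end_pos)
  df
}

#' Read an array truth genotype table
#'
#' Reads a tab-separated table of array-genotyped sites with columns
#' \code{chrom, pos, ref, alt, genotype_class}. Homozygous-reference rows
#' carry an empty \code{alt}. Input order is preserved; rows duplicating a
#' (chrom, pos) key are retained and flagged in the object's warnings.
#'
#' @param path Path to the TSV file.
#' @param chrom_style See \code{\link{readCallset}}.
#' @return A \linkS4class{GenotypeSites} object.
#' @export
readTruthTable <- function(path, chrom_style = c("keep", "strip", "add")) {
  chrom_style <- match.arg(chrom_style)
  df <- .readTsv(path)
  .requireColumns(df, c("chrom", "pos", "ref", "alt", "genotype_class"), path)
  bad <- !df$genotype_class %in% .GENOTYPE_CLASSES
  if (any(bad))
    stop(sprintf("schema error in '%s': unknown genotype_class '%s'", path,
                 df$genotype_class[bad][1]), call. = FALSE)
  df <- data.frame(chrom = .applyChromStyle(df$chrom, chrom_style),
                   pos = as.integer(df$pos), ref_allele = df$ref,
                   alt_allele = df$alt, genotype_class = df$genotype_class,
                   source = if ("source" %in% names(df)) df$source else "array",
                   stringsAsFactors = FALSE)
  key <- paste(.chromKey(df$chrom), df$pos)
  dups <- unique(key[duplicated(key)])
  warnings <- if (length(dups))
    sprintf("duplicated site(s): %s", paste(dups, collapse = "; "))
  else character()
  GenotypeSites(df, warnings = warnings)
}

#' Read target regions from a BED file
#'
#' Reads a BED file (0-based half-open intervals) into a
#' \code{\link[GenomicRanges]{GRanges}} using 1-based inclusive coordinates
#' internally, sorted by (chromosome, start). Overlapping or abutting
#' intervals are merged only when \code{merge = TRUE}.
#'
#' @param path Path to the BED file.
#' @param merge Merge overlapping/abutting intervals.
#' @param chrom_style See \code{\link{readCallset}}.
#' @param assembly Genome assembly label recorded in the object metadata.
#' @return A sorted \code{GRanges}.
#' @export
readRegions <- function(path, merge = FALSE,
                        chrom_style = c("keep", "strip", "add"),
                        assembly = "hg19") {
  chrom_style <- match.arg(chrom_style)
  raw <- if (file.size(path) > 0)
    utils::read.table(path, header = FALSE, sep = "\t",
                      colClasses = "character")
  else data.frame()
  if (nrow(raw) && ncol(raw) < 3L)
    stop(sprintf("parse error in '%s': BED needs >= 3 columns", path),
         call. = FALSE)
  if (nrow(raw) == 0L) {
    gr <- GenomicRanges::GRanges()
  } else {
    start0 <- as.numeric(raw[[2L]])
    end0 <- as.numeric(raw[[3L]])
    bad <- which(end0 <= start0 | start0 < 0)
    if (length(bad))
      stop(sprintf("parse error in '%s' line %d: end <= start", path, bad[1]),
           call. = FALSE)
    gr <- GenomicRanges::GRanges(
      .applyChromStyle(raw[[1L]], chrom_style),
      IRanges::IRanges(start = as.integer(start0) + 1L,
                       end = as.integer(end0)))
  }
  gr <- GenomicRanges::sort(gr, ignore.strand = TRUE)
  if (merge) gr <- GenomicRanges::reduce(gr)
  S4Vectors::metadata(gr)$assembly <- assembly
  gr
}

#' Write target regions to a BED file
#'
#' Inverse of \code{\link{readRegions}}: 1-based inclusive internal
#' intervals are emitted as 0-based half-open BED records. For sorted,
#' non-overlapping input the read/write round trip is byte-identical.
#'
#' @param regions A \code{GRanges}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
writeRegions <- function(regions, path) {
  lines <- sprintf("%s\t%d\t%d",
                   as.character(GenomicRanges::seqnames(regions)),
                   GenomicRanges::start(regions) - 1L,
                   GenomicRanges::end(regions))
  writeLines(lines, path)
  invisible(path)
}

#' Read a gene-model table
#'
#' Tab-separated with columns \code{gene} (symbol), \code{inheritance} (AD,
#' AR, XLD, XLR), \code{phenotypes} (semicolon-separated disease labels the
#' gene is known to cause) and \code{panel} (panel105, panel180_only,
#' off_panel).
#'
#' @param path Path to the TSV file.
#' @return data.frame with one row per gene.
#' @export
readGeneModels <- function(path) {
  df <- .readTsv(path)
  .requireColumns(df, c("gene", "inheritance", "phenotypes", "panel"), path)
  msg <- c(.checkVocab(df$inheritance, .INHERITANCE, "inheritance"),
           .checkVocab(df$panel, .PANELS, "panel"))
  if (length(msg)) stop(sprintf("schema error in '%s': %s", path,
                                paste(msg, collapse = "; ")), call. = FALSE)
  if (anyDuplicated(df$gene))
    stop(sprintf("schema error in '%s': duplicated gene symbols", path),
         call. = FALSE)
  df
}

#' Read a cohort table
#'
#' Tab-separated with columns \code{patient_id, phenotype} and optionally
#' \code{sex, syndromic_features} (semicolon-separated labels).
#'
#' @param path Path to the TSV file.
#' @return data.frame with one row per patient.
#' @export
readCohortTable <- function(path) {
  df <- .readTsv(path)
  .requireColumns(df, c("patient_id", "phenotype"), path)
  df
}

#' Read a sampling-strata table
#'
#' Tab-separated with columns \code{label, pop_count, sample_size,
#' new_diag}: for each stratum of the referral population, its size, the
#' number of patients re-sequenced, and the number of those gaining a new
#' molecular diagnosis.
#'
#' @param path Path to the TSV file.
#' @return data.frame with one row per stratum.
#' @export
readStrata <- function(path) {
  df <- .readTsv(path)
  .requireColumns(df, c("label", "pop_count", "sample_size", "new_diag"), path)
  df$pop_count <- as.integer(df$pop_count)
  df$sample_size <- as.integer(df$sample_size)
  df$new_diag <- as.integer(df$new_diag)
  bad <- df$new_diag < 0 | df$new_diag > df$sample_size | df$pop_count < 0
  if (any(bad))
    stop(sprintf("schema error in '%s': invalid stratum '%s'", path,
                 df$label[bad][1]), call. = FALSE)
  df
}

#' Write a variant call set in the package's TSV dialect
#'
#' @param x A \linkS4class{VariantCalls} or canonical call data.frame.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
writeCallset <- function(x, path) {
  df <- if (methods::is(x, "VariantCalls")) callTable(x) else x
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

.pct1 <- function(x) if (is.na(x)) NA else round(100 * x, 1)

.concordanceAsList <- function(object) {
  sens <- sensitivity(object)
  spec <- specificity(object)
  list(type = "concordance",
       counts = list(tp = object@tp, fn = object@fn, tn = object@tn,
                     fp = object@fp),
       metrics = list(sensitivity_pct = .pct1(sens),
                      specificity_pct = .pct1(spec),
                      sensitivity_defined = !is.na(sens),
                      specificity_defined = !is.na(spec)),
       n_discordant = nrow(object@discordant))
}

#' @rdname writeReport
#' @export
setMethod("writeReport", "ConcordanceTable", function(object, path) {
  .writeReportList(.concordanceAsList(object), path)
})

#' @rdname writeReport
#' @export
setMethod("writeReport", "AdjustedConcordance", function(object, path) {
  x <- list(type = "adjusted_concordance",
            raw = .concordanceAsList(object@raw),
            adjusted = .concordanceAsList(object@adjusted),
            truth_error_rate_pct = .pct1(object@truthErrorRate),
            truth_error_rate_defined = !is.na(object@truthErrorRate),
            n_adjudicated = object@nAdjudicated,
            n_pipeline_correct = object@nPipelineCorrect,
            n_unresolved = object@nUnresolved)
  .writeReportList(x, path)
})

#' @rdname writeReport
#' @export
setMethod("writeReport", "UpliftEstimate", function(object, path) {
  x <- list(type = "uplift",
            point = round(object@point, 4),
            ci_low = if (is.na(object@ciLow)) NA else round(object@ciLow, 4),
            ci_high = if (is.na(object@ciHigh)) NA else round(object@ciHigh, 4),
            expected_new_diagnoses = round(object@expectedNew, 4),
            n_sims = if (is.na(object@nSims)) NA else object@nSims,
            seed = if (is.na(object@seed)) NA else object@seed,
            absolute = object@absolute)
  .writeReportList(x, path)
})

#' @rdname writeReport
#' @export
setMethod("writeReport", "list", function(object, path) {
  .writeReportList(object, path)
})

.writeReportList <- function(x, path) {
  con <- tryCatch(file(path, "w"), error = function(e)
    stop(sprintf("I/O error: cannot write '%s'", path), call. = FALSE))
  on.exit(close(con))
  yaml::write_yaml(x, con)
  invisible(x)
}

#' Read back a structured report
#'
#' @param path Path written by \code{\link{writeReport}}.
#' @return The deserialised named list.
#' @export
readReport <- function(path) yaml::read_yaml(path)
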