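# Phenotype vocabulary (clinical-indication labels used in cohort tables).
.PHENO <- c(RP   = "RP or rod-cone dystrophy",
            LCA  = "Leber congenital amaurosis or early onset rod-cone dystrophy",
            OTH  = "Other (indication not included in this list, or not defined)",
            STAR = "Stargardt disease or macular dystrophy",
            USH  = "Usher syndrome",
            CRD  = "Cone-rod dystrophy",
            ACHM = "Achromatopsia or cone dystrophy",
            CIL  = "Syndromic ciliopathies",
            FEVR = "Familial exudative vitreoretinopathy",
            CHOR = "Choroideremia")

# Referral-cohort phenotype counts and the re-sequenced subsample's counts.
.PHENO_N <- c(RP = 268L, LCA = 78L, OTH = 43L, STAR = 49L, USH = 41L,
              CRD = 39L, ACHM = 27L, CIL = 8L, FEVR = 5L, CHOR = 4L)

# Illustrative disease-gene models: symbol, inheritance, associated
# phenotypes, panel tier. A compact stand-in for the clinical gene lists;
# phenotype assignments follow the field's usual gene-disease associations.
.fxGeneModels <- function() {
  p <- .PHENO
  rows <- list(
    c("RHO",     "AD",  p[["RP"]],                          "panel105"),
    c("PRPF31",  "AD",  p[["RP"]],                          "panel105"),
    c("RPGR",    "XLD", p[["RP"]],                          "panel105"),
    c("RP2",     "XLR", p[["RP"]],                          "panel105"),
    c("USH2A",   "AR",  paste(p[["RP"]], p[["USH"]], sep = ";"), "panel105"),
    c("EYS",     "AR",  p[["RP"]],                          "panel105"),
    c("PDE6B",   "AR",  p[["RP"]],                          "panel105"),
    c("MERTK",   "AR",  p[["RP"]],                          "panel105"),
    c("IDH3B",   "AR",  p[["RP"]],                          "panel105"),
    c("RPGRIP1", "AR",  paste(p[["LCA"]], p[["RP"]], sep = ";"), "panel105"),
    c("CRX",     "AD",  paste(p[["LCA"]], p[["CRD"]], sep = ";"), "panel105"),
    c("CEP290",  "AR",  paste(p[["LCA"]], p[["CIL"]], sep = ";"), "panel105"),
    c("GUCY2D",  "AR",  p[["LCA"]],                         "panel105"),
    c("ABCA4",   "AR",  paste(p[["STAR"]], p[["CRD"]], sep = ";"), "panel105"),
    c("ELOVL4",  "AD",  p[["STAR"]],                        "panel105"),
    c("MYO7A",   "AR",  p[["USH"]],                         "panel105"),
    c("GPR98",   "AR",  p[["USH"]],                         "panel105"),
    c("PCDH15",  "AR",  p[["USH"]],                         "panel105"),
    c("GUCA1A",  "AD",  p[["CRD"]],                         "panel105"),
    c("CNGA3",   "AR",  p[["ACHM"]],                        "panel105"),
    c("CNGB3",   "AR",  p[["ACHM"]],                        "panel105"),
    c("BBS1",    "AR",  p[["CIL"]],                         "panel105"),
    c("FZD4",    "AD",  p[["FEVR"]],                        "panel105"),
    c("LRP5",    "AR",  p[["FEVR"]],                        "panel105"),
    c("CHM",     "XLR", p[["CHOR"]],                        "panel105"),
    c("TRPM1",   "AR",  p[["OTH"]],                         "panel180_only"))
  df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(df) <- c("gene", "inheritance", "phenotypes", "panel")
  df
}

# Synthetic gene loci: one 10 kb interval per gene on invented coordinates
# (real hg19 coordinates appear only in the printed exclusive-variant
# records). Variant "slots" 1..4 sit at start + 10*slot; concordance truth
# sites are placed from start + 5000 upward, so the two never collide.
.fxLoci <- function(models) {
  n <- nrow(models)
  data.frame(gene = models$gene,
             chrom = as.character(((seq_len(n) - 1L) %% 22L) + 1L),
             start = 1000000L + 100000L * (seq_len(n) - 1L),
             stringsAsFactors = FALSE)
}

.fxPanel <- function(loci, models) {
  in105 <- models$panel == "panel105"
  gr <- GenomicRanges::GRanges(
    loci$chrom[in105],
    IRanges::IRanges(loci$start[in105], loci$start[in105] + 9999L))
  # the additionally captured noncoding region near CEP290, as its own
  # interval next to the gene's locus
  cep <- loci[loci$gene == "CEP290", ]
  gr <- c(gr, GenomicRanges::GRanges(
    cep$chrom, IRanges::IRanges(cep$start + 20000L, cep$start + 21999L)))
  gr <- GenomicRanges::sort(gr, ignore.strand = TRUE)
  S4Vectors::metadata(gr)$assembly <- "hg19"
  gr
}

.SLOT_ALLELES <- list(c("A", "T"), c("C", "G"), c("G", "A"), c("T", "C"))

# One synthetic variant row for `gene` at its slot position.
.fxVar <- function(loci, pid, platform, gene, zygosity, pathogenicity,
                   slot = 1L, variant_class = "snv", region_class = "coding",
                   cdna = NA_character_) {
  loc <- loci[loci$gene == gene, ]
  al <- .SLOT_ALLELES[[((slot - 1L) %% 4L) + 1L]]
  list(patient_id = pid, platform = platform, chrom = loc$chrom,
       pos = loc$start + 10L * slot, end_pos = NA_integer_, ref = al[1L],
       alt = al[2L], zygosity = zygosity, gene = gene, cdna = cdna,
       variant_class = variant_class, region_class = region_class,
       pathogenicity = pathogenicity, cis = FALSE)
}

# A fully specified variant row (printed records, deletions, indels).
.fxVarAt <- function(pid, platform, chrom, pos, ref, alt, zygosity, gene,
                     pathogenicity, variant_class, region_class,
                     cdna = NA_character_, end_pos = NA_integer_) {
  list(patient_id = pid, platform = platform, chrom = chrom,
       pos = as.integer(pos), end_pos = as.integer(end_pos),
       ref = as.character(ref), alt = as.character(alt),
       zygosity = zygosity, gene = gene, cdna = cdna,
       variant_class = variant_class, region_class = region_class,
       pathogenicity = pathogenicity, cis = FALSE)
}

# The clinically relevant variants identified by the genome pipeline only,
# with their printed hg19 coordinates, attached to their patients.
# Sequence-level ref/alt for the indel/intronic records are synthetic
# reconstructions consistent with the printed cDNA change.
.fxTable9 <- function() {
  v <- .fxVarAt
  list(
    v("12002355", "wgs", "chr10", 56094632, "N", NA, "het", "PCDH15",
      "likely_pathogenic", "large_deletion", "coding",
      "c.-189197_c.610-5166del", 56613219),
    v("065240", "wgs", "chr2", 112648150, "N", NA, "hom", "MERTK",
      "clearly_pathogenic", "large_deletion", "coding",
      "c.-8163_c.1145-1213del", 112739206),
    v("11012351", "wgs", "chr5", 90109981, "N", NA, "het", "GPR98",
      "likely_pathogenic", "large_deletion", "coding",
      "c.16079-1455_c.16196+155del", 90111708),
    v("12008422", "wgs", "chr1", 216167537, "N", NA, "het", "USH2A",
      "likely_pathogenic", "large_deletion", "coding",
      "c.6326-3582_6658-1028del", 216177486),
    v("067429", "wgs", "chr14", 21794817, "N", NA, "het", "RPGRIP1",
      "likely_pathogenic", "large_deletion", "coding",
      "c.2710+485_3238+810del", 21799356),
    v("09006916", "wgs", "chr1", 94476951, "T", "C", "het", "ABCA4",
      "likely_pathogenic", "snv", "intronic", "c.5461-10T>C"),
    v("12007903", "wgs", "chr1", 94476951, "T", "C", "het", "ABCA4",
      "likely_pathogenic", "snv", "intronic", "c.5461-10T>C"),
    v("11012351", "wgs", "chr5", 89924371, "C", "G", "het", "GPR98",
      "likely_pathogenic", "snv", "intronic", "c.1239-8C>G"),
    v("11001193", "wgs", "chr4", 654564, paste(rep("A", 47), collapse = ""),
      "TCTGGG", "het", "PDE6B", "likely_pathogenic", "complex_indel",
      "coding", "c.1923_1969delinsTCTGGG"),
    v("11013807", "wgs", "chr1", 216246601, "G", "TTAACTTGGCAT", "het",
      "USH2A", "likely_pathogenic", "indel", "coding",
      "c.5614delinsTTAACTTGGCAT"),
    v("12003183", "wgs", "chr19", 48342972, "AC", "A", "het", "CRX",
      "clearly_pathogenic", "indel", "coding", "c.648delC"),
    v("065238", "wgs", "chr1", 94476351, "G", "A", "het", "ABCA4",
      "likely_pathogenic", "snv", "intronic", "c.5714+5G>A"),
    v("13012708", "wgs", "chr1", 94476351, "G", "A", "het", "ABCA4",
      "likely_pathogenic", "snv", "intronic", "c.5714+5G>A"),
    v("11012959", "wgs", "chr15", 31358296, "T", "C", "hom", "TRPM1",
      "clearly_pathogenic", "snv", "coding", "c.707T>C"))
}

.fxKnownMiss <- function() {
  data.frame(chrom = "chr1", pos = 94476351L, alt = "A",
             note = "ABCA4 c.5714+5G>A: analysable but unreported",
             stringsAsFactors = FALSE)
}

# Gene cycles used to realise outcome kinds deterministically.
.AD_GENES <- list(RP = c("RHO", "PRPF31"), LCA = "CRX", STAR = "ELOVL4",
                  CRD = c("GUCA1A", "CRX"), FEVR = "FZD4")
.AR_GENES <- list(RP = c("EYS", "PDE6B", "MERTK", "USH2A", "IDH3B"),
                  LCA = c("CEP290", "GUCY2D", "RPGRIP1"), STAR = "ABCA4",
                  USH = c("MYO7A", "GPR98", "PCDH15", "USH2A"),
                  CRD = "ABCA4", ACHM = c("CNGA3", "CNGB3"),
                  CIL = c("BBS1", "CEP290"), FEVR = "LRP5", OTH = "TRPM1")
.XLR_GENES <- list(RP = "RP2", CHOR = "CHM")
# carrier gene guaranteed NOT to match the phenotype
.OTHER_CARRIER <- c(RP = "GPR98", OTH = "USH2A", USH = "IDH3B",
                    CRD = "GUCY2D", ACHM = "ABCA4", STAR = "MYO7A",
                    LCA = "ABCA4", CIL = "USH2A", FEVR = "USH2A",
                    CHOR = "USH2A")

.cycle <- function(v, i) v[((i - 1L) %% length(v)) + 1L]

# Target counts of outcome kinds per phenotype for the 562-patient cohort.
# Kinds: AD, XLD, XLR, AR_hom, AR_comphet (diagnosed), carrier_rel,
# carrier_other, undx. Row sums reproduce the phenotype counts; column sums
# the outcome/inheritance breakdowns.
.fxAlloc <- function() {
  m <- rbind(
    RP   = c(25, 1, 9, 40, 60, 30, 20, 83),
    LCA  = c(8, 0, 0, 20, 25, 8, 0, 17),
    OTH  = c(0, 0, 0, 0, 0, 0, 10, 33),
    STAR = c(8, 0, 0, 8, 10, 6, 0, 17),
    USH  = c(0, 0, 0, 10, 15, 6, 4, 6),
    CRD  = c(8, 0, 0, 5, 5, 4, 2, 15),
    ACHM = c(0, 0, 0, 6, 5, 4, 2, 10),
    CIL  = c(0, 0, 0, 2, 3, 1, 0, 2),
    FEVR = c(4, 0, 0, 0, 0, 0, 0, 1),
    CHOR = c(0, 0, 4, 0, 0, 0, 0, 0))
  colnames(m) <- c("AD", "XLD", "XLR", "AR_hom", "AR_comphet",
                   "carrier_rel", "carrier_other", "undx")
  stopifnot(identical(rowSums(m), structure(as.numeric(.PHENO_N),
                                            names = names(.PHENO_N))),
            all(colSums(m) == c(53, 1, 13, 91, 123, 59, 38, 184)))
  m
}

# Add the NGS-arm calls realising one outcome kind for one patient.
# `idx` deterministically cycles gene choices; `tier` sets the causal
# pathogenicity ("clearly_pathogenic" unless stated).
.realizeKind <- function(loci, pid, pheno_key, kind, idx,
                         tier = "clearly_pathogenic", gene = NULL) {
  vv <- list()
  add <- function(...) vv[[length(vv) + 1L]] <<- .fxVar(loci, pid, "ngs", ...)
  if (kind == "AD") {
    g <- gene %||% .cycle(.AD_GENES[[pheno_key]], idx)
    add(g, "het", tier, slot = 1L)
  } else if (kind == "XLD") {
    add("RPGR", "het", tier, slot = 1L)
  } else if (kind == "XLR") {
    add(gene %||% .XLR_GENES[[pheno_key]], "hemi", tier, slot = 1L)
  } else if (kind == "AR_hom") {
    g <- gene %||% .cycle(.AR_GENES[[pheno_key]], idx)
    add(g, "hom", tier, slot = 1L)
  } else if (kind == "AR_comphet") {
    g <- gene %||% .cycle(.AR_GENES[[pheno_key]], idx)
    add(g, "het", "clearly_pathogenic" , slot = 1L)
    vv[[1L]]$pathogenicity <- tier     # first allele carries the tier
    add(g, "het", if (tier == "clearly_pathogenic") "likely_pathogenic"
        else tier, slot = 2L)
  } else if (kind == "carrier_rel") {
    g <- gene %||% .cycle(.AR_GENES[[pheno_key]], idx)
    add(g, "het", tier, slot = 3L)
  } else if (kind == "carrier_other") {
    add(.OTHER_CARRIER[[pheno_key]], "het", tier, slot = 3L)
  } else if (kind != "undx") {
    stop("unknown kind: ", kind)
  }
  vv
}

# The diagnostic gene realised for a (kind, phenotype, idx) triple; used to
# avoid carrier-finding collisions.
.kindGene <- function(pheno_key, kind, idx) {
  switch(kind,
         AD = .cycle(.AD_GENES[[pheno_key]], idx),
         XLD = "RPGR",
         XLR = .XLR_GENES[[pheno_key]],
         AR_hom = ,
         AR_comphet = .cycle(.AR_GENES[[pheno_key]], idx),
         NA_character_)
}

.carrierGene <- function(pheno_key, exclude) {
  cand <- setdiff(.AR_GENES[[pheno_key]] %||% character(), exclude)
  if (length(cand)) cand[1L]
  else if (!"USH2A" %in% exclude) "USH2A" else "EYS"
}

# Deterministic concordance instance: n_snv truth SNV sites (alternating
# het/hom_alt) and n_homref homozygous-reference sites placed inside the
# panel intervals, with calls at every SNV site and `n_fp` spurious calls at
# the first hom-ref sites.
.fxConcordance <- function(loci, models, platform, n_snv, n_homref, n_fp) {
  in105 <- which(models$panel == "panel105")
  n <- n_snv + n_homref
  gi <- in105[((seq_len(n) - 1L) %% length(in105)) + 1L]
  pos <- loci$start[gi] + 5000L + 2L * ((seq_len(n) - 1L) %/% length(in105))
  is_snv <- seq_len(n) <= n_snv
  gclass <- ifelse(is_snv, ifelse(seq_len(n) %% 2L == 1L, "het", "hom_alt"),
                   "hom_ref")
  truth <- GenotypeSites(data.frame(
    chrom = loci$chrom[gi], pos = pos, ref_allele = "A",
    alt_allele = ifelse(is_snv, "G", NA_character_),
    genotype_class = gclass, source = "array", stringsAsFactors = FALSE))
  call_idx <- c(which(is_snv), which(!is_snv)[seq_len(n_fp)])
  calls <- VariantCalls(data.frame(
    patient_id = NA_character_, platform = platform,
    chrom = loci$chrom[gi][call_idx], pos = pos[call_idx],
    ref = "A", alt = "G",
    zygosity = ifelse(gclass[call_idx] == "hom_alt", "hom", "het"),
    gene = loci$gene[gi][call_idx], variant_class = "snv",
    region_class = "coding", pathogenicity = "uncertain",
    stringsAsFactors = FALSE))
  list(truth = truth, calls = calls)
}

#' Deterministic study fixture
#'
#' Builds, without any randomness, a complete worked-example data bundle
#' with the structure of a two-stage diagnostic comparison study: a
#' 562-patient referral cohort whose panel-sequencing outcomes reproduce the
#' published breakdown (281 diagnosed, of them 53 autosomal dominant, 1
#' X-linked dominant, 13 X-linked recessive, 91 homozygous and 123 compound
#' heterozygous recessive cases; 158 patients with carrier findings, 61 of
#' them diagnosed through other genes, 59 undiagnosed carriers of a
#' phenotype-relevant trait); a 46-patient subsample (13 diagnosed, 33 not)
#' with genome-sequencing call sets that add exactly the 14 printed
#' panel-missed variants (plus companion first alleles where a second hit
#' completes a compound heterozygote), so that merging and reclassifying
#' diagnoses 24 patients, 11 of them newly; concordance truth/call sets
#' with (616 SNV + 2098 hom-ref, 0 false positives) for the panel arm and
#' (928 + 3238, 3 false positives) for the genome arm; and the two- and
#' three-stratum sampling tables for the uplift projection.
#'
#' Two fixed calls produce identical bundles. All per-cohort genomic
#' coordinates are synthetic loci; only the 14 printed exclusive-variant
#' records carry real hg19 coordinates.
#'
#' @return A named list: \code{cohort} (\linkS4class{Cohort}, platforms
#'   "ngs" and "wgs"), \code{subsample_ids}, \code{models},
#'   \code{panel} (GRanges), \code{known_miss}, \code{table9}
#'   (data.frame of the 14 exclusive records), \code{truth_ngs},
#'   \code{calls_ngs}, \code{truth_wgs}, \code{calls_wgs}, \code{strata}
#'   (two-stratum), \code{strata3} (three-stratum),
#'   \code{baseline_diagnosed}, \code{pop_total}.
#' @examples
#' fx <- studyFixture()
#' out <- classifyCohort(fx$cohort, fx$models, "ngs")
#' cohortSummary(out)$yield_pct
#' @export
studyFixture <- function() {
  models <- .fxGeneModels()
  loci <- .fxLoci(models)
  alloc <- .fxAlloc()
  used <- alloc * 0L

  patients <- list()
  calls <- list()
  addPatient <- function(pid, pheno_key, sex = "unknown") {
    patients[[length(patients) + 1L]] <<- data.frame(
      patient_id = pid, phenotype = .PHENO[[pheno_key]], sex = sex,
      syndromic_features = if (pheno_key == "USH") "congenital deafness"
      else NA_character_, stringsAsFactors = FALSE)
  }
  addCalls <- function(vv) calls[[length(calls) + 1L]] <<- vv
  use <- function(pheno_key, kind)
    used[pheno_key, kind] <<- used[pheno_key, kind] + 1L

  ## ---- named subsample patients (printed identifiers) -----------------
  t9 <- .fxTable9()

  # 067429: confirmed compound-het EYS diagnosis from the panel; the genome
  # arm adds a heterozygous RPGRIP1 deletion (carrier finding only).
  addPatient("067429", "RP")
  use("RP", "AR_comphet")
  addCalls(list(.fxVar(loci, "067429", "ngs", "EYS", "het",
                       "clearly_pathogenic", 1L),
                .fxVar(loci, "067429", "ngs", "EYS", "het",
                       "likely_pathogenic", 2L)))

  # 12008422: homozygous likely-pathogenic USH2A missense on the panel arm
  # (provisional diagnosis); the genome arm re-evaluates it as heterozygous
  # in trans with a heterozygous exon deletion.
  addPatient("12008422", "USH")
  use("USH", "AR_hom")
  addCalls(list(.fxVar(loci, "12008422", "ngs", "USH2A", "hom",
                       "likely_pathogenic", 1L)))

  # Newly diagnosed after genome sequencing: patients whose panel arm held
  # a single first allele (companion) or nothing.
  flip_companion <- list(
    list(pid = "12002355", pheno = "USH", gene = "PCDH15"),
    list(pid = "09006916", pheno = "STAR", gene = "ABCA4"),
    list(pid = "12007903", pheno = "STAR", gene = "ABCA4"),
    list(pid = "11001193", pheno = "RP", gene = "PDE6B"),
    list(pid = "11013807", pheno = "USH", gene = "USH2A"),
    list(pid = "065238", pheno = "STAR", gene = "ABCA4"),
    list(pid = "13012708", pheno = "STAR", gene = "ABCA4"))
  for (fc in flip_companion) {
    addPatient(fc$pid, fc$pheno)
    use(fc$pheno, "carrier_rel")
    addCalls(list(.fxVar(loci, fc$pid, "ngs", fc$gene, "het",
                         "clearly_pathogenic", 1L)))
  }
  # panel arm found nothing for these
  addPatient("065240", "RP");    use("RP", "undx")
  addPatient("12003183", "LCA"); use("LCA", "undx")
  addPatient("11012959", "OTH"); use("OTH", "undx")
  # the exemplar case: carrier of a phenotype-unrelated recessive trait
  addPatient("11012351", "USH", sex = "female")
  use("USH", "carrier_other")
  addCalls(list(.fxVar(loci, "11012351", "ngs", "IDH3B", "het",
                       "likely_pathogenic", 1L)))

  named_ids <- c("067429", "12008422", vapply(flip_companion, `[[`, "",
                                              "pid"),
                 "065240", "12003183", "11012959", "11012351")

  ## ---- synthetic subsample members ------------------------------------
  # 11 further panel-diagnosed (9 confirmed, 2 provisional) and 22 further
  # undiagnosed, completing the subsample's phenotype distribution.
  syn_dx <- list(
    list(pheno = "RP", kind = "AD", gene = "RHO", tier = "clearly_pathogenic"),
    list(pheno = "RP", kind = "AR_hom", gene = "EYS",
         tier = "clearly_pathogenic"),
    list(pheno = "RP", kind = "AR_hom", gene = "PDE6B",
         tier = "clearly_pathogenic"),
    list(pheno = "RP", kind = "AR_comphet", gene = "MERTK",
         tier = "clearly_pathogenic"),
    list(pheno = "RP", kind = "AR_comphet", gene = "USH2A",
         tier = "clearly_pathogenic"),
    list(pheno = "RP", kind = "AR_comphet", gene = "EYS",
         tier = "likely_pathogenic"),
    list(pheno = "LCA", kind = "AD", gene = "CRX",
         tier = "clearly_pathogenic"),
    list(pheno = "LCA", kind = "AR_hom", gene = "CEP290",
         tier = "clearly_pathogenic"),
    list(pheno = "USH", kind = "AR_hom", gene = "MYO7A",
         tier = "clearly_pathogenic"),
    list(pheno = "USH", kind = "AR_comphet", gene = "GPR98",
         tier = "likely_pathogenic"),
    list(pheno = "CRD", kind = "AD", gene = "GUCA1A",
         tier = "clearly_pathogenic"))
  syn_undx <- list(
    c("RP", "carrier_rel"), c("RP", "carrier_rel"), c("RP", "carrier_rel"),
    c("RP", "carrier_rel"), c("RP", "carrier_other"),
    c("RP", "carrier_other"), c("RP", "carrier_other"), c("RP", "undx"),
    c("RP", "undx"), c("RP", "undx"), c("RP", "undx"), c("LCA", "undx"),
    c("STAR", "carrier_rel"), c("USH", "carrier_rel"), c("USH", "undx"),
    c("CRD", "carrier_rel"), c("CRD", "undx"), c("OTH", "carrier_other"),
    c("OTH", "carrier_other"), c("OTH", "undx"), c("OTH", "undx"),
    c("ACHM", "undx"))
  syn_ids <- sprintf("W%03d", seq_len(length(syn_dx) + length(syn_undx)))
  for (i in seq_along(syn_dx)) {
    s <- syn_dx[[i]]
    addPatient(syn_ids[i], s$pheno)
    use(s$pheno, s$kind)
    addCalls(.realizeKind(loci, syn_ids[i], s$pheno, s$kind, i,
                          tier = s$tier, gene = s$gene))
  }
  for (j in seq_along(syn_undx)) {
    s <- syn_undx[[j]]
    pid <- syn_ids[length(syn_dx) + j]
    addPatient(pid, s[1L])
    use(s[1L], s[2L])
    addCalls(.realizeKind(loci, pid, s[1L], s[2L], j))
  }
  subsample_ids <- c(named_ids, syn_ids)
  stopifnot(length(subsample_ids) == 46L)

  ## ---- remainder of the referral cohort -------------------------------
  remaining <- alloc - used
  stopifnot(all(remaining >= 0L))
  # Among the remaining diagnosed patients, 61 additionally carry one
  # heterozygous pathogenic variant in another recessive gene: 15 dominant
  # and 46 recessive cases.
  carrier_extra <- list(AD = 15L, AR = 46L)
  sid <- 0L
  for (pheno_key in rownames(remaining)) {
    for (kind in colnames(remaining)) {
      n_k <- remaining[pheno_key, kind]
      for (r in seq_len(n_k)) {
        sid <- sid + 1L
        pid <- sprintf("S%04d", sid)
        sex <- if (kind %in% c("XLD", "XLR")) "male"
               else if (sid %% 2L == 0L) "female" else "male"
        addPatient(pid, pheno_key, sex = sex)
        vv <- .realizeKind(loci, pid, pheno_key, kind, r)
        grab <- if (kind == "AD" && carrier_extra$AD > 0L) "AD"
                else if (kind %in% c("AR_hom", "AR_comphet") &&
                         carrier_extra$AR > 0L) "AR" else NA
        if (!is.na(grab)) {
          carrier_extra[[grab]] <- carrier_extra[[grab]] - 1L
          cg <- .carrierGene(pheno_key, .kindGene(pheno_key, kind, r))
          vv <- c(vv, list(.fxVar(loci, pid, "ngs", cg, "het",
                                  "likely_pathogenic", 4L)))
        }
        addCalls(vv)
      }
    }
  }
  stopifnot(carrier_extra$AD == 0L, carrier_extra$AR == 0L)

  patients <- do.call(rbind, patients)
  ngs_calls <- do.call(rbind, lapply(unlist(calls, recursive = FALSE),
                                     as.data.frame))

  ## ---- genome-arm call sets for the subsample --------------------------
  wgs <- ngs_calls[ngs_calls$patient_id %in% subsample_ids, , drop = FALSE]
  wgs$platform <- "wgs"
  # the genome pipeline re-genotypes the USH2A missense as heterozygous
  wgs$zygosity[wgs$patient_id == "12008422" & wgs$gene == "USH2A"] <- "het"
  t9df <- do.call(rbind, lapply(t9, as.data.frame))
  wgs <- rbind(wgs, t9df)
  cohort <- Cohort(patients, rbind(ngs_calls, wgs))

  ## ---- concordance instances ------------------------------------------
  ngs_conc <- .fxConcordance(loci, models, "ngs", 616L, 2098L, 0L)
  wgs_conc <- .fxConcordance(loci, models, "wgs", 928L, 3238L, 3L)

  ## ---- sampling strata -------------------------------------------------
  strata <- data.frame(
    label = c("ngs_diagnosed", "ngs_undiagnosed"),
    pop_count = c(281L, 281L), sample_size = c(13L, 33L),
    new_diag = c(0L, 11L), stringsAsFactors = FALSE)
  strata3 <- data.frame(
    label = c("ngs_diagnosed", "carrier_relevant", "undiagnosed_other"),
    pop_count = c(281L, 59L, 222L), sample_size = c(13L, 14L, 19L),
    new_diag = c(0L, 7L, 4L), stringsAsFactors = FALSE)

  list(cohort = cohort, subsample_ids = subsample_ids, models = models,
       panel = .fxPanel(loci, models), known_miss = .fxKnownMiss(),
       table9 = t9df, truth_ngs = ngs_conc$truth, calls_ngs = ngs_conc$calls,
       truth_wgs = wgs_conc$truth, calls_wgs = wgs_conc$calls,
       strata = strata, strata3 = strata3, baseline_diagnosed = 281L,
       pop_total = 562L, loci = loci)
}

#' Extract the re-sequenced subsample from the fixture
#'
#' @param fx A bundle from \code{\link{studyFixture}}.
#' @return A \linkS4class{Cohort} restricted to the 46 subsample patients.
#' @export
fixtureSubsample <- function(fx) {
  p <- patientTable(fx$cohort)
  Cohort(p[p$patient_id %in% fx$subsample_ids, , drop = FALSE],
         fx$cohort@calls[fx$cohort@calls$patient_id %in% fx$subsample_ids, ,
                         drop = FALSE])
}

.withSeed <- function(seed, expr) {
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed))
      assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Generate a random synthetic cohort
#'
#' Samples a referral cohort with the statistical structure the analysis
#' assumes: each patient draws a phenotype and an outcome category, and
#' receives a variant list constructed so that the outcome classifier
#' recovers the sampled category exactly (a diagnosed patient gets a causal
#' genotype in a phenotype-matching gene under a sampled inheritance mode; a
#' relevant-trait carrier gets exactly one qualifying heterozygous variant
#' in a matching recessive gene; and so on). Genome-arm call sets start as
#' copies of the panel arm; each undiagnosed patient flips to diagnosed with
#' the stratum's re-diagnosis probability by gaining either a second allele
#' (carriers) or a homozygous causal genotype.
#'
#' Defaults reproduce the reference study's conditions: 562 patients,
#' category probabilities at the published cohort prevalences (with the
#' diagnosed split into confirmed/provisional at the 10:3 subsample ratio),
#' phenotype distribution at the published referral frequencies, and an
#' undiagnosed re-diagnosis probability of 11/33.
#'
#' @param n_patients Cohort size.
#' @param category_probs Named probabilities over
#'   \code{\link{outcomeCategories}()}; must sum to 1.
#' @param phenotype_probs Named probabilities over the phenotype keys
#'   (RP, LCA, OTH, STAR, USH, CRD, ACHM, CIL, FEVR, CHOR).
#' @param rediagnosis_probs Named per-stratum probabilities that an
#'   undiagnosed (resp. diagnosed) patient gains a new diagnosis on the
#'   genome arm.
#' @param seed Integer RNG seed (global RNG state restored on exit).
#' @return A list: \code{cohort} (\linkS4class{Cohort} with "ngs" and "wgs"
#'   platforms), \code{sampled} (data.frame of each patient's drawn
#'   category and flip indicator), \code{params}.
#' @export
generateCohort <- function(n_patients = 562,
                           category_probs = c(
                             diagnosed_confirmed = 281 / 562 * 10 / 13,
                             diagnosed_provisional = 281 / 562 * 3 / 13,
                             undiagnosed_carrier_relevant = 59 / 562,
                             undiagnosed_carrier_other = 38 / 562,
                             undiagnosed = 184 / 562),
                           phenotype_probs = .PHENO_N / sum(.PHENO_N),
                           rediagnosis_probs = c(diagnosed = 0,
                                                 undiagnosed = 11 / 33),
                           seed = 1) {
  if (abs(sum(category_probs) - 1) > 1e-8 || any(category_probs < 0))
    stop("parameter error: category_probs must be non-negative and sum to 1",
         call. = FALSE)
  if (any(phenotype_probs < 0))
    stop("parameter error: phenotype_probs must be non-negative",
         call. = FALSE)
  stopifnot(all(names(category_probs) %in% .OUTCOME_CATEGORIES))
  models <- .fxGeneModels()
  loci <- .fxLoci(models)
  # inheritance-mode mix among diagnosed patients (published breakdown)
  moi_probs <- c(AD = 53, XLD = 1, XLR = 13, AR_hom = 91,
                 AR_comphet = 123) / 281
  .withSeed(seed, {
    pheno_keys <- sample(names(phenotype_probs), n_patients, replace = TRUE,
                         prob = phenotype_probs)
    cats <- sample(names(category_probs), n_patients, replace = TRUE,
                   prob = category_probs)
    flips <- stats::runif(n_patients)
    patients <- list()
    calls <- list()
    sampled <- list()
    for (i in seq_len(n_patients)) {
      pid <- sprintf("G%05d", i)
      pk <- pheno_keys[i]
      cat_i <- cats[i]
      diagnosed <- cat_i %in% c("diagnosed_confirmed",
                                "diagnosed_provisional")
      kind <- if (diagnosed) {
        k <- sample(names(moi_probs), 1L, prob = moi_probs)
        # fall back to a genotype the phenotype's modelled genes support
        if (pk == "CHOR") k <- "XLR"
        if (k == "AD" && is.null(.AD_GENES[[pk]])) k <- "AR_comphet"
        if (k %in% c("XLD", "XLR") && pk != "RP" &&
            is.null(.XLR_GENES[[pk]])) k <- "AR_hom"
        if (k == "XLD" && pk != "RP") k <- "XLR"
        if (k %in% c("AR_hom", "AR_comphet") && is.null(.AR_GENES[[pk]]))
          k <- "AD"
        k
      } else switch(cat_i,
                    undiagnosed_carrier_relevant = "carrier_rel",
                    undiagnosed_carrier_other = "carrier_other",
                    undiagnosed = "undx")
      if (kind == "carrier_rel" && is.null(.AR_GENES[[pk]])) {
        kind <- "carrier_other"
        cat_i <- "undiagnosed_carrier_other"
      }
      tier <- if (cat_i == "diagnosed_provisional") "likely_pathogenic"
              else "clearly_pathogenic"
      sexm <- kind %in% c("XLD", "XLR")
      patients[[i]] <- data.frame(
        patient_id = pid, phenotype = .PHENO[[pk]],
        sex = if (sexm) "male" else c("male", "female")[(i %% 2L) + 1L],
        syndromic_features = NA_character_, stringsAsFactors = FALSE)
      idx <- sample.int(5L, 1L)
      vv <- .realizeKind(loci, pid, pk, kind, idx, tier = tier)
      # genome arm: copy, plus a completing variant for flipped patients
      wv <- lapply(vv, function(v) { v$platform <- "wgs"; v })
      p_flip <- if (diagnosed) rediagnosis_probs[["diagnosed"]]
                else rediagnosis_probs[["undiagnosed"]]
      flipped <- !diagnosed && flips[i] < p_flip
      if (flipped) {
        g <- if (kind == "carrier_rel") vv[[1L]]$gene
             else .cycle(.AR_GENES[[pk]] %||% "USH2A", idx)
        wv <- c(wv, list(.fxVar(loci, pid, "wgs", g,
                                if (kind == "carrier_rel") "het" else "hom",
                                "clearly_pathogenic",
                                if (kind == "carrier_rel") 2L else 1L)))
      }
      calls[[i]] <- c(vv, wv)
      sampled[[i]] <- data.frame(patient_id = pid, category = cat_i,
                                 flipped = flipped, stringsAsFactors = FALSE)
    }
    cohort <- Cohort(do.call(rbind, patients),
                     do.call(rbind, lapply(unlist(calls, recursive = FALSE),
                                           as.data.frame)))
    list(cohort = cohort, sampled = do.call(rbind, sampled),
         params = list(n_patients = n_patients,
                       category_probs = category_probs,
                       phenotype_probs = phenotype_probs,
                       rediagnosis_probs = rediagnosis_probs, seed = seed))
  })
}

#' Generate a synthetic concordance-benchmark instance
#'
#' Plants truth sites, pipeline errors and truth-set (array) errors at
#' known rates, emulating a control-sample comparison: truth SNV sites are
#' missed by the pipeline at \code{fn_rate}, hom-ref sites spuriously
#' called at \code{fp_rate}, and each resulting discordance is, with
#' probability \code{truth_error_rate}, actually an array error — its
#' adjudication record resolves \code{pipeline_correct} (the remainder
#' resolve \code{truth_correct}). Concordance analysis of the instance
#' recovers the planted rates within binomial sampling error.
#'
#' @param n_snv_sites,n_homref_sites Numbers of truth SNV and
#'   homozygous-reference sites.
#' @param fn_rate,fp_rate Pipeline miss and spurious-call probabilities.
#' @param truth_error_rate Probability that a discordance is an array
#'   error (the reference study estimated about 0.0216).
#' @param seed Integer RNG seed (global RNG state restored on exit).
#' @return A list: \code{truth} (\linkS4class{GenotypeSites}), \code{calls}
#'   (\linkS4class{VariantCalls}), \code{adjudications} (data.frame),
#'   \code{regions} (GRanges covering the sites), \code{params}.
#' @export
generateAccuracyInstance <- function(n_snv_sites = 928,
                                     n_homref_sites = 3238, fn_rate = 0,
                                     fp_rate = 0, truth_error_rate = 0,
                                     seed = 1) {
  stopifnot(fn_rate >= 0, fn_rate <= 1, fp_rate >= 0, fp_rate <= 1,
            truth_error_rate >= 0, truth_error_rate <= 1)
  n <- n_snv_sites + n_homref_sites
  pos <- 1000L + 10L * seq_len(n)
  is_snv <- seq_len(n) <= n_snv_sites
  .withSeed(seed, {
    truth <- GenotypeSites(data.frame(
      chrom = "1", pos = pos, ref_allele = "A",
      alt_allele = ifelse(is_snv, "G", NA_character_),
      genotype_class = ifelse(is_snv,
                              ifelse(stats::runif(n) < 0.5, "het", "hom_alt"),
                              "hom_ref"),
      source = "array", stringsAsFactors = FALSE))
    miss <- is_snv & stats::runif(n) < fn_rate
    spurious <- !is_snv & stats::runif(n) < fp_rate
    called <- (is_snv & !miss) | spurious
    tdf <- siteTable(truth)
    calls <- VariantCalls(data.frame(
      patient_id = NA_character_, platform = "pipeline",
      chrom = "1", pos = pos[called], ref = "A", alt = "G",
      zygosity = ifelse(tdf$genotype_class[called] == "hom_alt", "hom",
                        "het"),
      gene = NA_character_, variant_class = "snv", region_class = "coding",
      pathogenicity = "uncertain", stringsAsFactors = FALSE))
    disc_idx <- which(miss | spurious)
    adj <- if (length(disc_idx)) {
      data.frame(chrom = "1", pos = pos[disc_idx],
                 resolution = ifelse(
                   stats::runif(length(disc_idx)) < truth_error_rate,
                   "pipeline_correct", "truth_correct"),
                 stringsAsFactors = FALSE)
    } else {
      data.frame(chrom = character(), pos = integer(),
                 resolution = character(), stringsAsFactors = FALSE)
    }
    regions <- GenomicRanges::GRanges("1", IRanges::IRanges(1L,
                                                            max(pos) + 10L))
    list(truth = truth, calls = calls, adjudications = adj,
         regions = regions,
         params = list(n_snv_sites = n_snv_sites,
                       n_homref_sites = n_homref_sites, fn_rate = fn_rate,
                       fp_rate = fp_rate,
                       truth_error_rate = truth_error_rate, seed = seed))
  })
}
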