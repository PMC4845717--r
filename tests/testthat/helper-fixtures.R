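# Shared fixture helpers. The study fixture is deterministic but not free
# to build, so cache one copy per test run.
.fixture_cache <- new.env(parent = emptyenv())

getFixture <- function() {
  if (is.null(.fixture_cache$fx)) .fixture_cache$fx <- studyFixture()
  .fixture_cache$fx
}

# Minimal VCF writer for reader tests.
writeTestVcf <- function(body_lines, path = tempfile(fileext = ".vcf")) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
    "##INFO=<ID=CDNA,Number=1,Type=String,Description=\"cDNA change\">",
    "##INFO=<ID=PATH_CLASS,Number=1,Type=String,Description=\"Pathogenicity\">",
    "##INFO=<ID=REGION_CLASS,Number=1,Type=String,Description=\"Region\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"Deletion end\">",
    "##ALT=<ID=DEL,Description=\"Deletion\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1")
  writeLines(c(header, body_lines), path)
  path
}

vcfLine <- function(chrom, pos, ref, alt, info, gt = "0/1") {
  paste(chrom, pos, ".", ref, alt, ".", ".", info, "GT", gt, sep = "\t")
}

# A one-row canonical call for unit tests.
testCall <- function(chrom = "1", pos = 100L, ref = "A", alt = "G",
                     zygosity = "het", gene = "EYS",
                     variant_class = "snv", region_class = "coding",
                     pathogenicity = "clearly_pathogenic",
                     end_pos = NA_integer_, patient_id = NA_character_,
                     platform = "ngs", cdna = NA_character_, cis = FALSE) {
  data.frame(patient_id = patient_id, platform = platform, chrom = chrom,
             pos = as.integer(pos), end_pos = as.integer(end_pos),
             ref = ref, alt = alt, zygosity = zygosity, gene = gene,
             cdna = cdna, variant_class = variant_class,
             region_class = region_class, pathogenicity = pathogenicity,
             cis = cis, stringsAsFactors = FALSE)
}

testModels <- function() {
  data.frame(
    gene = c("EYS", "USH2A", "GPR98", "IDH3B", "RHO", "RPGR", "RP2",
             "TRPM1", "ABCA4", "MERTK", "CRX", "RPGRIP1", "PDE6B",
             "PCDH15"),
    inheritance = c("AR", "AR", "AR", "AR", "AD", "XLD", "XLR", "AR", "AR",
                    "AR", "AD", "AR", "AR", "AR"),
    phenotypes = c("RP or rod-cone dystrophy",
                   "RP or rod-cone dystrophy;Usher syndrome",
                   "Usher syndrome",
                   "RP or rod-cone dystrophy",
                   "RP or rod-cone dystrophy",
                   "RP or rod-cone dystrophy",
                   "RP or rod-cone dystrophy",
                   "Other (indication not included in this list, or not defined)",
                   "Stargardt disease or macular dystrophy;Cone-rod dystrophy",
                   "RP or rod-cone dystrophy",
                   "Leber congenital amaurosis or early onset rod-cone dystrophy;Cone-rod dystrophy",
                   "Leber congenital amaurosis or early onset rod-cone dystrophy;RP or rod-cone dystrophy",
                   "RP or rod-cone dystrophy",
                   "Usher syndrome"),
    panel = c(rep("panel105", 7), "panel180_only", rep("panel105", 6)),
    stringsAsFactors = FALSE)
}
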