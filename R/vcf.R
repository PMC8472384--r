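#' Write a stratum's genotypes as a minimal VCF
#'
#' Emits VCF v4.2 text with biallelic records and a GT FORMAT field, one
#' sample column per individual. Indel records are written with
#' placeholder REF/ALT alleles sized from the coding change (the genomic
#' alleles are not modelled); the coding change is carried in the ID
#' column.
#'
#' @param sim A `synthetic_cohort` (see [simulate_cohort()]).
#' @param stratum Stratum name.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_stratum_vcf <- function(sim, stratum, path) {
  stopifnot(inherits(sim, "synthetic_cohort"))
  tab <- sim$genotype_tables[[stratum]]
  if (is.null(tab)) stop_config(sprintf("unknown stratum '%s'", stratum))
  tmpl <- sim$spec$templates
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    sprintf("##source=lofburden simulate (seed %d)", sim$seed),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", tab$individual), collapse = "\t")), con)
  for (v in seq_len(nrow(tmpl))) {
    cc <- parse_coding_change(tmpl$coding_change[v])
    ref_alt <- switch(cc$kind,
      substitution = c(cc$ref_base, cc$alt_bases),
      insertion = c("N", paste0("N", cc$alt_bases)),
      deletion = c(paste0("N", strrep("N", cc$cdna_end - cc$cdna_start + 1L)),
                   "N"))
    g <- tab[[tmpl$coding_change[v]]]
    gt <- ifelse(g == 0L, "0/0", ifelse(g == 1L, "0/1", "1/1"))
    writeLines(paste(c(sub("^chr", "", tmpl$chrom[v]), tmpl$pos[v],
                       tmpl$coding_change[v], ref_alt[1], ref_alt[2], ".",
                       "PASS", ".", "GT", gt), collapse = "\t"), con)
  }
  invisible(path)
}

#' Count carriers from a genotype-level VCF
#'
#' Reads a biallelic VCF with GT fields (via the VariantAnnotation
#' package) and counts, per record, the carrier individuals (any genotype
#' containing the alternate allele; a heterozygote counts once) and the
#' carrier alleles (heterozygote 1, homozygote 2).
#'
#' @param path Path to a VCF file.
#' @return A data.frame with columns `id`, `chrom`, `pos`, `carriers`,
#'   `carrier_alleles`.
#' @export
read_vcf_carrier_counts <- function(path) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE))
    stop_config("reading VCF genotypes requires the VariantAnnotation package")
  if (!file.exists(path))
    stop_config(sprintf("VCF not found: %s", path))
  vcf <- VariantAnnotation::readVcf(path)
  gt <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gt)) stop_validate("VCF lacks a GT FORMAT field")
  alt_dose <- function(g) {
    alleles <- strsplit(g, "[/|]")[[1]]
    sum(alleles == "1")
  }
  dose <- apply(gt, c(1, 2), alt_dose)
  dose <- matrix(dose, nrow = nrow(gt))
  rr <- SummarizedExperiment::rowRanges(vcf)
  data.frame(
    id = rownames(gt),
    chrom = as.character(GenomicRanges::seqnames(rr)),
    pos = GenomicRanges::start(rr),
    carriers = as.integer(rowSums(dose > 0)),
    carrier_alleles = as.integer(rowSums(dose)),
    row.names = NULL, stringsAsFactors = FALSE)
}
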