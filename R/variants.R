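#' Read a cohort variant table
#'
#' Reads the tab-separated variant-table dialect consumed by the pipeline:
#' header columns `chrom`, `pos`, `exon`, `coding_change`, optional
#' `protein_change` and `cadd`, followed by one carrier-count column per
#' cohort stratum. Lines starting with `#` are comments.
#'
#' @param path Path to the TSV file.
#' @param strata Optional character vector of stratum names expected among
#'   the carrier-count columns; missing ones raise a config error.
#' @return A data.frame, one row per variant.
#' @export
read_variant_table <- function(path, strata = NULL) {
  if (!file.exists(path))
    stop_config(sprintf("variant table not found: %s", path))
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                          check.names = FALSE)
  need <- c("chrom", "pos", "coding_change")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_config(sprintf("variant table lacks column(s): %s",
                        paste(miss, collapse = ", ")))
  if (!is.null(strata)) {
    miss <- setdiff(strata, names(df))
    if (length(miss))
      stop_config(sprintf("variant table lacks carrier-count column(s): %s",
                          paste(miss, collapse = ", ")))
  }
  df$pos <- as.integer(df$pos)
  df
}

#' Annotate a variant table against a transcript model
#'
#' Parses each `coding_change`, classifies its consequence (using
#' `protein_change` as authoritative annotation when the model has no CDS
#' sequence), and appends the columns `canonical`, `consequence`, `residue`,
#' `is_lof` and `domains` (comma-joined domain names).
#'
#' @param variants A data.frame as returned by [read_variant_table()].
#' @param model A `transcript_model`.
#' @return The annotated data.frame.
#' @export
annotate_variants <- function(variants, model) {
  stopifnot(is.data.frame(variants), inherits(model, "transcript_model"))
  n <- nrow(variants)
  canonical <- character(n); consequence <- character(n)
  residue <- integer(n); is_lof <- logical(n)
  domains <- character(n); plab <- character(n)
  has_plab <- "protein_change" %in% names(variants)
  for (i in seq_len(n)) {
    cc <- parse_coding_change(variants$coding_change[i])
    supplied <- if (has_plab) variants$protein_change[i] else NULL
    call <- classify_consequence(cc, model, protein_change = supplied)
    canonical[i] <- canonical_coding_change(cc)
    consequence[i] <- call$consequence
    residue[i] <- call$first_affected_residue
    is_lof[i] <- call$is_lof
    domains[i] <- paste(call$domains_hit, collapse = ",")
    plab[i] <- call$protein_change
  }
  variants$canonical <- canonical
  variants$consequence <- consequence
  variants$residue <- residue
  variants$is_lof <- is_lof
  variants$domains <- domains
  if (!has_plab) variants$protein_change <- plab
  variants
}

#' Filter variants to the deleterious set
#'
#' Keeps loss-of-function variants (stop-gain and frameshift) regardless of
#' CADD availability, and missense variants with a CADD score at or above
#' the cutoff (default 25; a missense variant with no score is not
#' deleterious). Rows whose genomic position appears on the exclusion
#' blocklist are removed first.
#'
#' @param variants An annotated variant data.frame (see
#'   [annotate_variants()]).
#' @param cadd_cutoff Non-negative CADD threshold for missense variants.
#' @param exclude_pos Integer vector of genomic positions to drop.
#' @return The filtered data.frame.
#' @export
filter_deleterious <- function(variants, cadd_cutoff = 25,
                               exclude_pos = integer()) {
  stopifnot(is.data.frame(variants), cadd_cutoff >= 0)
  if (!all(c("is_lof", "consequence") %in% names(variants)))
    stop_validate("variants must be annotated before filtering")
  if (length(exclude_pos))
    variants <- variants[!(variants$pos %in% as.integer(exclude_pos)), ,
                         drop = FALSE]
  cadd <- if ("cadd" %in% names(variants))
    suppressWarnings(as.numeric(variants$cadd)) else rep(NA_real_,
                                                         nrow(variants))
  keep <- variants$is_lof |
    (variants$consequence == "missense" & !is.na(cadd) & cadd >= cadd_cutoff)
  variants[keep, , drop = FALSE]
}
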