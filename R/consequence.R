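#' Classify the protein-level consequence of a coding change
#'
#' Indels are classified by net length: a net change that is not a multiple
#' of 3 shifts the reading frame (`frameshift`, LOF); a multiple of 3 is an
#' `inframe_indel` (not LOF). Substitutions are translated against the
#' model's CDS sequence when one is present: a gained stop codon is
#' `stop_gain` (LOF), an amino-acid change `missense`, no change
#' `synonymous`. Without a CDS sequence a substitution is `unknown` unless a
#' trusted protein-change string (e.g. `"p.Q672X"`, `"p.L1264F"`) is
#' supplied, in which case its suffix is honored. The first affected residue
#' is always the codon containing the first edited cDNA base.
#'
#' @param change A `coding_change` (see [parse_coding_change()]).
#' @param model A `transcript_model`.
#' @param protein_change Optional protein-change string used as authoritative
#'   annotation for substitutions when the model carries no sequence.
#' @return An object of class `consequence_call`: list with `consequence`
#'   (one of `stop_gain`, `frameshift`, `inframe_indel`, `missense`,
#'   `synonymous`, `unknown`), `first_affected_residue`, `is_lof`,
#'   `protein_change` and `domains_hit`.
#' @examples
#' m <- transcript_model("NM_005732", 3939,
#'   domains = data.frame(name = "zinc_hook", start = 635, end = 734))
#' classify_consequence(parse_coding_change("c.2165_2166insT"), m)
#' @export
classify_consequence <- function(change, model, protein_change = NULL) {
  stopifnot(inherits(change, "coding_change"),
            inherits(model, "transcript_model"))
  if (change$cdna_start > model$cds_length ||
      (change$kind == "deletion" && change$cdna_end > model$cds_length))
    stop_range(sprintf("change %s outside CDS of length %d",
                       format(change), model$cds_length))
  residue <- codon_index(change$cdna_start, model)
  if (!is.null(protein_change) && (is.na(protein_change) ||
                                   !nzchar(protein_change)))
    protein_change <- NULL

  if (change$kind %in% c("insertion", "deletion")) {
    net <- if (change$kind == "insertion") nchar(change$alt_bases)
           else -(change$cdna_end - change$cdna_start + 1L)
    cons <- if (net %% 3L != 0L) "frameshift" else "inframe_indel"
    plab <- protein_change
    if (is.null(plab) && cons == "frameshift") {
      ref_aa <- translate_codon_at(model, residue)
      plab <- if (is.na(ref_aa)) sprintf("p.%dfs", residue)
              else sprintf("p.%s%dfs", ref_aa, residue)
    }
    return(new_consequence(cons, residue, plab, model))
  }

  # substitution
  if (!is.null(model$cds_sequence)) {
    codon_start <- (residue - 1L) * 3L + 1L
    codon <- substring(model$cds_sequence, codon_start, codon_start + 2L)
    offset <- change$cdna_start - codon_start + 1L
    ref_at <- substring(codon, offset, offset)
    if (!is.na(change$ref_base) && ref_at != change$ref_base)
      stop_validate(sprintf(
        "reference base mismatch at c.%d: change says %s, transcript has %s",
        change$cdna_start, change$ref_base, ref_at))
    mut <- codon
    substring(mut, offset, offset) <- change$alt_bases
    aa_ref <- translate_codon(codon)
    aa_alt <- translate_codon(mut)
    cons <- if (aa_alt == "*" && aa_ref != "*") "stop_gain"
            else if (aa_alt == aa_ref) "synonymous"
            else "missense"
    plab <- sprintf("p.%s%d%s", aa_ref, residue,
                    if (aa_alt == "*") "X" else aa_alt)
    return(new_consequence(cons, residue, plab, model))
  }

  if (!is.null(protein_change)) {
    cons <- consequence_from_protein_label(protein_change)
    return(new_consequence(cons, residue, protein_change, model))
  }
  new_consequence("unknown", residue, NULL, model)
}

consequence_from_protein_label <- function(label) {
  g <- match_groups("^p\\.([A-Z*])([0-9]+)([A-Z*])$", label)
  if (is.null(g)) {
    if (grepl("^p\\.[A-Z]?[0-9]+fs$", label)) return("frameshift")
    return("unknown")
  }
  if (g[3] %in% c("X", "*")) "stop_gain"
  else if (g[1] == g[3]) "synonymous"
  else "missense"
}

new_consequence <- function(cons, residue, plab, model) {
  structure(
    list(consequence = cons,
         first_affected_residue = as.integer(residue),
         is_lof = cons %in% c("stop_gain", "frameshift"),
         protein_change = if (is.null(plab)) NA_character_ else plab,
         domains_hit = assign_domains(residue, model)),
    class = "consequence_call")
}

#' @export
print.consequence_call <- function(x, ...) {
  cat(sprintf("<consequence_call> %s at residue %d%s%s%s\n",
              x$consequence, x$first_affected_residue,
              if (!is.na(x$protein_change)) paste0(" (", x$protein_change, ")")
              else "",
              if (x$is_lof) " [LOF]" else "",
              if (length(x$domains_hit))
                paste0(" in ", paste(x$domains_hit, collapse = ","))
              else ""))
  invisible(x)
}

# single-codon translation with the standard nuclear code
translate_codon <- function(codon) {
  aa <- Biostrings::GENETIC_CODE[[codon]]
  if (is.null(aa)) NA_character_ else aa
}

translate_codon_at <- function(model, residue) {
  if (is.null(model$cds_sequence)) return(NA_character_)
  s <- (residue - 1L) * 3L + 1L
  if (s + 2L > model$cds_length) return(NA_character_)
  translate_codon(substring(model$cds_sequence, s, s + 2L))
}
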