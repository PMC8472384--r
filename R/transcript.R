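#' Construct a transcript model
#'
#' A transcript model carries the coding-sequence geometry needed to map
#' cDNA edits onto protein residues and domains: the CDS length in
#' nucleotides, an optional CDS sequence (required for calling stop-gain /
#' missense / synonymous on substitutions), optional exon intervals in cDNA
#' coordinates, and a table of protein-domain intervals (closed, 1-based
#' residues), e.g. the RAD50 zinc hook at residues 635-734.
#'
#' @param transcript_id Transcript accession, e.g. `"NM_005732"`.
#' @param cds_length CDS length in nucleotides (positive integer).
#' @param domains A data.frame with columns `name`, `start`, `end`
#'   (1-based closed residue intervals), or `NULL` for none.
#' @param cds_sequence Optional CDS nucleotide string of length
#'   `cds_length`; its length must be divisible by 3.
#' @param exons Optional data.frame with columns `exon`, `cdna_start`,
#'   `cdna_end`; carried as metadata and validated for ordering only.
#' @return An object of class `transcript_model`.
#' @examples
#' transcript_model("NM_005732", 3939,
#'   domains = data.frame(name = "zinc_hook", start = 635, end = 734))
#' @export
transcript_model <- function(transcript_id, cds_length, domains = NULL,
                             cds_sequence = NULL, exons = NULL) {
  cds_length <- as.integer(cds_length)
  if (is.na(cds_length) || cds_length < 1L)
    stop_validate("cds_length must be a positive integer")
  if (!is.null(cds_sequence)) {
    cds_sequence <- toupper(as.character(cds_sequence))
    if (nchar(cds_sequence) != cds_length)
      stop_validate(sprintf(
        "cds_sequence length (%d) differs from cds_length (%d)",
        nchar(cds_sequence), cds_length))
    if (cds_length %% 3L != 0L)
      stop_validate("cds_length must be divisible by 3 when a sequence is given")
    if (grepl("[^ACGT]", cds_sequence))
      stop_validate("cds_sequence contains non-ACGT characters")
  }
  if (is.null(domains)) {
    domains <- data.frame(name = character(), start = integer(),
                          end = integer(), stringsAsFactors = FALSE)
  } else {
    domains <- as.data.frame(domains)
    stopifnot(all(c("name", "start", "end") %in% names(domains)))
    domains$start <- as.integer(domains$start)
    domains$end <- as.integer(domains$end)
    if (any(domains$start > domains$end))
      stop_validate("domain intervals must satisfy start <= end")
    if (anyDuplicated(domains$name))
      stop_validate("duplicate domain names")
  }
  if (!is.null(exons)) {
    exons <- as.data.frame(exons)
    stopifnot(all(c("exon", "cdna_start", "cdna_end") %in% names(exons)))
    o <- order(exons$cdna_start)
    exons <- exons[o, , drop = FALSE]
    if (any(exons$cdna_start > exons$cdna_end) ||
        any(diff(c(rbind(exons$cdna_start, exons$cdna_end))) < 0))
      stop_validate("exon intervals must be ordered and non-overlapping")
  }
  structure(
    list(transcript_id = as.character(transcript_id),
         cds_length = cds_length, cds_sequence = cds_sequence,
         exons = exons, domains = domains),
    class = "transcript_model")
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("<transcript_model> %s: CDS %d nt (%s aa)%s, %d domain(s)\n",
              x$transcript_id, x$cds_length,
              format(x$cds_length %/% 3L),
              if (is.null(x$cds_sequence)) ", no sequence" else ", with sequence",
              nrow(x$domains)))
  if (nrow(x$domains))
    cat(sprintf("  %s [%d-%d]\n", x$domains$name, x$domains$start,
                x$domains$end), sep = "")
  invisible(x)
}

#' Read a transcript/domain model from JSON
#'
#' The JSON carries `transcript_id`, `cds_length`, `domains`
#' (`[{name, start, end}]`), optional `exons`, and an optional
#' `cds_fasta` path (resolved relative to the JSON file) from which the CDS
#' sequence is read.
#'
#' @param path Path to the JSON file.
#' @return A `transcript_model`.
#' @export
read_transcript_model <- function(path) {
  if (!file.exists(path))
    stop_config(sprintf("transcript model file not found: %s", path))
  js <- jsonlite::read_json(path, simplifyVector = TRUE)
  seq <- NULL
  if (!is.null(js$cds_fasta)) {
    fa <- js$cds_fasta
    if (!file.exists(fa)) fa <- file.path(dirname(path), js$cds_fasta)
    if (!file.exists(fa))
      stop_config(sprintf("CDS FASTA not found: %s", js$cds_fasta))
    dna <- Biostrings::readDNAStringSet(fa)
    seq <- as.character(dna[[1]])
  }
  transcript_model(js$transcript_id, js$cds_length,
                   domains = js$domains, cds_sequence = seq,
                   exons = js$exons)
}

#' Map a cDNA position to its protein residue
#'
#' Returns the 1-based index of the codon containing a cDNA coding
#' position: `floor((pos - 1) / 3) + 1`. Vectorized over `cdna_pos`.
#'
#' @param cdna_pos Positive integer position(s) on the coding sequence
#'   (1 = first base of the start codon).
#' @param model Optional `transcript_model`; when supplied, positions beyond
#'   `cds_length` raise a range error.
#' @return Integer residue index(es).
#' @examples
#' codon_index(2014) # 672
#' codon_index(3790) # 1264
#' @export
codon_index <- function(cdna_pos, model = NULL) {
  pos <- as.integer(cdna_pos)
  if (any(is.na(pos)) || any(pos < 1L))
    stop_range("cDNA position must be a positive integer")
  if (!is.null(model)) {
    stopifnot(inherits(model, "transcript_model"))
    if (any(pos > model$cds_length))
      stop_range(sprintf("cDNA position %d outside CDS of length %d",
                         max(pos), model$cds_length))
  }
  (pos - 1L) %/% 3L + 1L
}

#' Domains containing a protein residue
#'
#' Returns the names of every domain interval (closed, 1-based) of the
#' model that contains the residue.
#'
#' @param residue Positive integer residue index (scalar).
#' @param model A `transcript_model`.
#' @return Character vector of domain names (possibly empty).
#' @examples
#' m <- transcript_model("NM_005732", 3939,
#'   domains = data.frame(name = "zinc_hook", start = 635, end = 734))
#' assign_domains(672, m) # "zinc_hook"
#' assign_domains(1264, m) # character(0)
#' @export
assign_domains <- function(residue, model) {
  stopifnot(inherits(model, "transcript_model"))
  residue <- as.integer(residue)
  if (length(residue) != 1L || is.na(residue) || residue < 1L)
    stop_range("residue must be a single positive integer")
  d <- model$domains
  d$name[d$start <= residue & residue <= d$end]
}

stop_validate <- function(msg) {
  stop(errorCondition(msg,
    class = c("lofburden_validation_error", "lofburden_error")))
}

stop_range <- function(msg) {
  stop(errorCondition(msg,
    class = c("lofburden_range_error", "lofburden_error")))
}

stop_config <- function(msg) {
  stop(errorCondition(msg,
    class = c("lofburden_config_error", "lofburden_error")))
}
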