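#' Parse a cDNA coding-change string
#'
#' Parses the cDNA-level edit notation used in variant tables into a
#' structured `coding_change` object. Two dialects are accepted for
#' substitutions: standard HGVS (`"c.2014C>T"`) and the annotation-tool
#' dialect that prefixes the reference base (`"c.C2014T"`). Insertions use
#' `"c.2165_2166insT"` and deletions `"c.2980_2983del"` or `"c.1110delA"`.
#'
#' @param text A single coding-change string starting with `"c."`.
#' @return An object of class `coding_change`: a list with fields `kind`
#'   (one of `"substitution"`, `"insertion"`, `"deletion"`), `cdna_start`,
#'   `cdna_end` (closed interval on the coding sequence, 1-based),
#'   `ref_base` (substitutions, and deletions when the deleted bases were
#'   spelled out), `alt_bases` (substitutions and insertions) and `raw`
#'   (the input text).
#' @examples
#' parse_coding_change("c.C2014T")
#' parse_coding_change("c.2165_2166insT")
#' parse_coding_change("c.2980_2983del")
#' @export
parse_coding_change <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text))
    stop_parse(text, "coding change must be a single character string")
  text <- trimws(text)
  if (!startsWith(text, "c.")) {
    tok <- sub("\\..*$", ".", text)
    stop_parse(text, sprintf("expected prefix 'c.', found '%s'", tok))
  }
  body <- substring(text, 3L)

  new_cc <- function(kind, start, end, ref = NA_character_,
                     alt = NA_character_) {
    structure(
      list(kind = kind, cdna_start = as.integer(start),
           cdna_end = as.integer(end), ref_base = ref, alt_bases = alt,
           raw = text),
      class = "coding_change")
  }

  # annotation-tool dialect substitution: C2014T
  m <- regexec("^([ACGT])([0-9]+)([ACGT])$", body)[[1]]
  if (m[1] != -1L) {
    g <- regmatches(body, list(regexec("^([ACGT])([0-9]+)([ACGT])$",
                                       body)[[1]]))[[1]]
    pos <- as.integer(g[3])
    check_pos(text, pos)
    return(new_cc("substitution", pos, pos, ref = g[2], alt = g[4]))
  }
  # HGVS substitution: 2014C>T
  g <- match_groups("^([0-9]+)([ACGT])>([ACGT])$", body)
  if (!is.null(g)) {
    pos <- as.integer(g[1])
    check_pos(text, pos)
    return(new_cc("substitution", pos, pos, ref = g[2], alt = g[3]))
  }
  # insertion: 2165_2166insT
  g <- match_groups("^([0-9]+)_([0-9]+)ins([ACGT]+)$", body)
  if (!is.null(g)) {
    s <- as.integer(g[1]); e <- as.integer(g[2])
    check_pos(text, s)
    if (e != s + 1L)
      stop_parse(text, sprintf(
        "insertion interval '%s_%s' must span adjacent positions", g[1], g[2]))
    return(new_cc("insertion", s, e, alt = g[3]))
  }
  # deletion, range form: 2980_2983del[ACGT...]
  g <- match_groups("^([0-9]+)_([0-9]+)del([ACGT]*)$", body)
  if (!is.null(g)) {
    s <- as.integer(g[1]); e <- as.integer(g[2])
    check_pos(text, s)
    if (e < s)
      stop_parse(text, sprintf("deletion end %d precedes start %d", e, s))
    del <- if (nzchar(g[3])) g[3] else NA_character_
    if (!is.na(del) && nchar(del) != e - s + 1L)
      stop_parse(text, sprintf(
        "deleted bases '%s' do not match interval length %d", del, e - s + 1L))
    return(new_cc("deletion", s, e, ref = del))
  }
  # deletion, single-position form: 1110delA
  g <- match_groups("^([0-9]+)del([ACGT]*)$", body)
  if (!is.null(g)) {
    s <- as.integer(g[1])
    check_pos(text, s)
    del <- if (nzchar(g[2])) g[2] else NA_character_
    if (!is.na(del) && nchar(del) != 1L)
      stop_parse(text, sprintf(
        "single-position deletion cannot remove '%s'", g[2]))
    return(new_cc("deletion", s, s, ref = del))
  }
  stop_parse(text, sprintf("unrecognized edit '%s'", body))
}

match_groups <- function(pattern, x) {
  m <- regexec(pattern, x)[[1]]
  if (m[1] == -1L) return(NULL)
  regmatches(x, list(m))[[1]][-1]
}

check_pos <- function(text, pos) {
  if (is.na(pos) || pos < 1L)
    stop_parse(text, "cDNA positions must be positive integers")
}

stop_parse <- function(text, msg) {
  stop(errorCondition(
    sprintf("cannot parse coding change '%s': %s", as.character(text)[1], msg),
    class = c("lofburden_parse_error", "lofburden_error")))
}

#' @export
format.coding_change <- function(x, ...) {
  switch(x$kind,
    substitution = sprintf("c.%d%s>%s", x$cdna_start, x$ref_base,
                           x$alt_bases),
    insertion = sprintf("c.%d_%dins%s", x$cdna_start, x$cdna_end,
                        x$alt_bases),
    deletion = {
      span <- if (x$cdna_start == x$cdna_end) sprintf("c.%d", x$cdna_start)
              else sprintf("c.%d_%d", x$cdna_start, x$cdna_end)
      paste0(span, "del", if (!is.na(x$ref_base)) x$ref_base else "")
    })
}

#' @export
print.coding_change <- function(x, ...) {
  cat(sprintf("<coding_change> %s (%s, cDNA %d..%d)\n", format(x), x$kind,
              x$cdna_start, x$cdna_end))
  invisible(x)
}

#' Canonical form of a coding change
#'
#' Formats and re-parses, yielding the canonical HGVS-style spelling.
#' Idempotent: both accepted substitution dialects map to the same form.
#'
#' @param change A `coding_change`.
#' @return A single string.
#' @export
canonical_coding_change <- function(change) {
  stopifnot(inherits(change, "coding_change"))
  format(change)
}
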