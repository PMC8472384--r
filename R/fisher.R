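#' Construct a 2x2 allele-count contingency table
#'
#' Cell layout: `a` carrier alleles and `b` non-carrier alleles in group 1
#' (cases), `c` and `d` likewise in group 2 (the comparator). Row totals
#' `a + b` and `c + d` are the allele totals (2N) of the two groups.
#'
#' @param a,b,c,d Non-negative integer cell counts.
#' @param labels Optional character vector of length 2 naming the groups.
#' @return An object of class `contingency_table`.
#' @examples
#' contingency_table(4, 368, 30, 19924)
#' @export
contingency_table <- function(a, b, c, d, labels = c("group1", "group2")) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(is.na(cells)) || any(cells < 0) || any(cells != round(cells)))
    stop_validate("contingency table cells must be non-negative integers")
  structure(list(a = as.numeric(a), b = as.numeric(b), c = as.numeric(c),
                 d = as.numeric(d), labels = labels),
            class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  m <- matrix(c(x$a, x$b, x$c, x$d), 2, byrow = TRUE,
              dimnames = list(x$labels, c("carrier", "non-carrier")))
  print(m)
  invisible(x)
}

#' Unconditional sample odds ratio
#'
#' `(a * d) / (b * c)`, with `Inf` when the comparator carrier cell is
#' empty (`b * c == 0` with `a * d > 0`), `0` when the case carrier cell is
#' empty, and `NA` when both products vanish (not applicable). This is the
#' plain sample estimate, not the conditional MLE, and no continuity
#' correction is applied.
#'
#' @param t A `contingency_table`.
#' @return Non-negative numeric, possibly `Inf` or `NA`.
#' @examples
#' sample_odds_ratio(contingency_table(4, 368, 30, 19924)) # 7.22
#' @export
sample_odds_ratio <- function(t) {
  stopifnot(inherits(t, "contingency_table"))
  ad <- t$a * t$d
  bc <- t$b * t$c
  if (ad == 0 && bc == 0) return(NA_real_)
  if (bc == 0) return(Inf)
  ad / bc
}

#' Two-sided Fisher exact p-value (minimum-likelihood rule)
#'
#' Conditions on both margins and enumerates the hypergeometric support of
#' the top-left cell. The two-sided p-value is the sum of the point
#' probabilities of every table in the support whose probability does not
#' exceed that of the observed table, the comparison being guarded by a
#' relative tolerance of `1 + 1e-7` so that floating-point ties count as
#' ties. This is the convention of the major statistical packages'
#' two-sided Fisher test.
#'
#' @param t A `contingency_table`.
#' @param max_support Guard on the enumeration size (support length);
#'   exceeding it raises an error (the normal approximation is out of
#'   scope).
#' @return p-value in (0, 1].
#' @examples
#' fisher_two_sided(contingency_table(4, 2084, 0, 4490)) # 0.010
#' @export
fisher_two_sided <- function(t, max_support = 1e7) {
  stopifnot(inherits(t, "contingency_table"))
  m <- t$a + t$b          # group-1 alleles
  n <- t$c + t$d          # group-2 alleles
  k <- t$a + t$c          # carrier alleles overall
  lo <- max(0, k - n)
  hi <- min(k, m)
  if (hi - lo + 1 > max_support)
    stop(errorCondition(sprintf(
      "hypergeometric support of %d tables exceeds the enumeration guard (%g); a normal approximation is out of scope",
      hi - lo + 1, max_support),
      class = c("lofburden_enumeration_error", "lofburden_error")))
  support <- lo:hi
  dens <- stats::dhyper(support, m, n, k)
  d_obs <- stats::dhyper(t$a, m, n, k)
  p <- sum(dens[dens <= d_obs * (1 + 1e-7)])
  min(1, p)
}

#' Exact association test on a 2x2 allele-count table
#'
#' Bundles the sample odds ratio and the two-sided exact p-value.
#'
#' @param t A `contingency_table`.
#' @param alpha Significance level for the `significant` flag (default
#'   0.05, no multiplicity adjustment).
#' @return An object of class `association_result`: list with
#'   `odds_ratio`, `p_two_sided`, `significant`, `table`, `labels`.
#' @export
associate <- function(t, alpha = 0.05) {
  stopifnot(inherits(t, "contingency_table"))
  p <- fisher_two_sided(t)
  or <- sample_odds_ratio(t)
  structure(list(odds_ratio = or, p_two_sided = p,
                 significant = p < alpha, table = t, labels = t$labels),
            class = "association_result")
}

#' @export
print.association_result <- function(x, ...) {
  cat(sprintf("<association> %s vs %s: OR %s, p %s%s\n",
              x$labels[1], x$labels[2], format_or(x$odds_ratio),
              format_p(x$p_two_sided), if (x$significant) " *" else ""))
  invisible(x)
}

#' Read a reference-population allele-count table
#'
#' TSV with columns `name` (population), `n_alleles` (total alleles of the
#' population), `variant_set`, `count` (carrier alleles of that set).
#' Counts are frozen values, e.g. exported gnomAD allele counts.
#'
#' @param path Path to the TSV.
#' @return A list of `reference_population` objects keyed by name, each a
#'   list with `name`, `n_alleles`, `counts` (named numeric).
#' @export
read_reference_counts <- function(path) {
  if (!file.exists(path))
    stop_config(sprintf("reference count table not found: %s", path))
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("name", "n_alleles", "variant_set", "count")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_config(sprintf("reference table lacks column(s): %s",
                        paste(miss, collapse = ", ")))
  out <- list()
  for (nm in unique(df$name)) {
    sub <- df[df$name == nm, , drop = FALSE]
    total <- unique(sub$n_alleles)
    if (length(total) != 1L)
      stop_config(sprintf("population '%s' has inconsistent allele totals", nm))
    if (any(sub$count > total))
      stop_validate(sprintf("population '%s' has counts above its allele total",
                            nm))
    counts <- stats::setNames(as.numeric(sub$count), sub$variant_set)
    out[[nm]] <- structure(list(name = nm, n_alleles = as.numeric(total),
                                counts = counts),
                           class = "reference_population")
  }
  out
}

#' Carrier count of a variant set in a comparator
#'
#' A comparator is either a `reference_population` (frozen counts looked up
#' by set name) or a `burden_count` row computed from the cohort table.
#'
#' @param comparator Comparator object.
#' @param set_name Variant-set name.
#' @return List with `count`, `n_alleles`, `name`.
#' @export
comparator_counts <- function(comparator, set_name) {
  if (inherits(comparator, "reference_population")) {
    if (!set_name %in% names(comparator$counts))
      stop_config(sprintf("reference '%s' has no count for variant set '%s'",
                          comparator$name, set_name))
    list(count = unname(comparator$counts[[set_name]]),
         n_alleles = comparator$n_alleles, name = comparator$name)
  } else if (inherits(comparator, "burden_count")) {
    list(count = comparator$carrier_alleles,
         n_alleles = comparator$allele_total, name = comparator$cohort)
  } else stop_validate("comparator must be a reference_population or burden_count")
}

#' Burden scan: exact tests of burden counts against comparators
#'
#' One association per (burden row, comparator): the burden's carrier
#' alleles against the comparator's count for the same variant set, on the
#' allele scale.
#'
#' @param burdens A `burden_count` data.frame (rows from [count_burden()]
#'   or [burden_table()]).
#' @param comparators List of comparators (see [comparator_counts()]).
#' @param alpha Significance level for flags.
#' @return A data.frame with one row per pair: variant set, group names and
#'   counts, `odds_ratio`, `p_two_sided`, `significant`, `n_tests`, plus
#'   the rendered `or_label` and `p_label`.
#' @export
burden_scan <- function(burdens, comparators, alpha = 0.05) {
  stopifnot(is.data.frame(burdens))
  if (inherits(comparators, c("reference_population", "burden_count")))
    comparators <- list(comparators)
  rows <- list()
  for (i in seq_len(nrow(burdens))) {
    b <- burdens[i, ]
    for (cmp in comparators) {
      cc <- comparator_counts(cmp, b$variant_set)
      t <- contingency_table(b$carrier_alleles,
                             b$allele_total - b$carrier_alleles,
                             cc$count, cc$n_alleles - cc$count,
                             labels = c(b$cohort, cc$name))
      res <- associate(t, alpha = alpha)
      rows[[length(rows) + 1L]] <- data.frame(
        variant_set = b$variant_set, group1 = b$cohort, group2 = cc$name,
        carriers1 = b$carrier_alleles, alleles1 = b$allele_total,
        carriers2 = cc$count, alleles2 = cc$n_alleles,
        odds_ratio = res$odds_ratio, p_two_sided = res$p_two_sided,
        significant = res$significant, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$n_tests <- nrow(out)
  out$or_label <- vapply(out$odds_ratio, format_or, character(1))
  out$p_label <- vapply(out$p_two_sided, format_p, character(1))
  rownames(out) <- NULL
  out
}

#' Report rounding for odds ratios: 2 decimals, `"inf"` when infinite
#'
#' @param or Numeric odds ratio.
#' @return Character label.
#' @export
format_or <- function(or) {
  if (is.na(or)) return("NA")
  if (is.infinite(or)) return("inf")
  sprintf("%.2f", or)
}

#' Report rounding for p-values: 2 significant figures, scientific below
#' 1e-3
#'
#' @param p Numeric p-value.
#' @return Character label, e.g. `"0.010"`, `"3.5e-07"`.
#' @export
format_p <- function(p) {
  stopifnot(p >= 0, p <= 1)
  if (p < 1e-3) {
    lab <- formatC(signif(p, 2), format = "e", digits = 1)
    return(lab)
  }
  formatC(signif(p, 2), format = "fg", digits = 2, flag = "#")
}
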