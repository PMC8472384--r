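#' Define a variant set by a deterministic selector
#'
#' A variant set names a predicate over annotated variant rows: all LOF
#' variants, LOF variants inside a named domain, or an explicit list of
#' protein labels.
#'
#' @param name Set name used in reports and reference lookups.
#' @param selector A function taking the annotated variant data.frame and
#'   returning a logical row mask.
#' @return An object of class `variant_set`.
#' @seealso [vs_lof()], [vs_lof_in_domain()], [vs_protein()]
#' @export
variant_set <- function(name, selector) {
  stopifnot(is.character(name), length(name) == 1L, is.function(selector))
  structure(list(name = name, selector = selector), class = "variant_set")
}

#' @rdname variant_set
#' @export
vs_lof <- function(name = "all_lof") {
  variant_set(name, function(v) v$is_lof)
}

#' @param domain Domain name that selected variants' first affected residue
#'   must fall in.
#' @rdname variant_set
#' @export
vs_lof_in_domain <- function(domain, name = paste0("lof_", domain)) {
  variant_set(name, function(v)
    v$is_lof & vapply(strsplit(v$domains, ","), function(d) domain %in% d,
                      logical(1)))
}

#' @param labels Protein-change labels selected verbatim, e.g.
#'   `c("p.Q672X", "p.K722fs")`.
#' @rdname variant_set
#' @export
vs_protein <- function(labels, name = paste(labels, collapse = "/")) {
  force(labels)
  variant_set(name, function(v) v$protein_change %in% labels)
}

#' Aggregate carrier burden of a variant set over a cohort
#'
#' Sums carrier counts of the selected variants over the member strata of
#' the named cohort. Every carrier is heterozygous on the tabular path, so
#' carrier alleles equal carriers; the frequency is computed on the allele
#' scale (carriers / 2N).
#'
#' @param variants Annotated variant data.frame whose carrier-count columns
#'   cover all member strata.
#' @param vset A `variant_set`.
#' @param cohort Name of a stratum or combined set.
#' @param cohorts A `cohort_set`.
#' @return A one-row data.frame of class `burden_count` with columns
#'   `variant_set`, `cohort`, `carriers`, `carrier_alleles`, `allele_total`,
#'   `frequency`.
#' @export
count_burden <- function(variants, vset, cohort, cohorts) {
  stopifnot(is.data.frame(variants), inherits(vset, "variant_set"),
            inherits(cohorts, "cohort_set"))
  members <- cohort_members(cohorts, cohort)
  miss <- setdiff(members, names(variants))
  if (length(miss))
    stop_config(sprintf("variant table lacks carrier-count column(s): %s",
                        paste(miss, collapse = ", ")))
  sel <- vset$selector(variants)
  stopifnot(is.logical(sel), length(sel) == nrow(variants))
  carriers <- 0L
  for (m in members) {
    counts <- suppressWarnings(as.integer(variants[[m]]))
    counts[is.na(counts)] <- 0L
    n_ind <- cohorts$strata$n_individuals[match(m, cohorts$strata$name)]
    if (any(counts > n_ind))
      stop_validate(sprintf(
        "carrier count %d exceeds stratum '%s' size %d",
        max(counts), m, n_ind))
    carriers <- carriers + sum(counts[sel])
  }
  total <- allele_total(cohorts, cohort)
  out <- data.frame(variant_set = vset$name, cohort = cohort,
                    carriers = carriers, carrier_alleles = carriers,
                    allele_total = total, frequency = carriers / total,
                    stringsAsFactors = FALSE)
  class(out) <- c("burden_count", class(out))
  out
}

#' Census of carriers across all strata
#'
#' Summarizes a (typically LOF-filtered) variant table: number of distinct
#' variants observed, total carriers across the given strata, and for each
#' domain of the model the fraction of carriers whose variant maps to it.
#'
#' @param variants Annotated variant data.frame.
#' @param cohorts A `cohort_set`; all of its strata are counted.
#' @return A list with `n_variants`, `n_carriers`, `carriers_per_stratum`
#'   (named integer vector), and `domain_fractions`, a data.frame with
#'   columns `domain`, `carriers`, `fraction`, `percent` (1 decimal place).
#' @export
carrier_census <- function(variants, cohorts) {
  stopifnot(is.data.frame(variants), inherits(cohorts, "cohort_set"))
  strata <- cohorts$strata$name
  miss <- setdiff(strata, names(variants))
  if (length(miss))
    stop_config(sprintf("variant table lacks carrier-count column(s): %s",
                        paste(miss, collapse = ", ")))
  counts <- sapply(strata, function(m) {
    x <- suppressWarnings(as.integer(variants[[m]]))
    x[is.na(x)] <- 0L
    x
  })
  counts <- matrix(counts, nrow = nrow(variants),
                   dimnames = list(NULL, strata))
  per_variant <- rowSums(counts)
  observed <- per_variant > 0
  n_carriers <- sum(per_variant)
  doms <- unique(unlist(strsplit(variants$domains[observed], ",")))
  doms <- doms[nzchar(doms)]
  domain_fractions <- data.frame(domain = character(), carriers = integer(),
                                 fraction = numeric(), percent = numeric(),
                                 stringsAsFactors = FALSE)
  for (d in doms) {
    hit <- vapply(strsplit(variants$domains, ","), function(x) d %in% x,
                  logical(1))
    k <- sum(per_variant[hit])
    domain_fractions <- rbind(domain_fractions, data.frame(
      domain = d, carriers = k, fraction = k / n_carriers,
      percent = round(100 * k / n_carriers, 1), stringsAsFactors = FALSE))
  }
  list(n_variants = sum(observed), n_carriers = n_carriers,
       carriers_per_stratum = colSums(counts),
       domain_fractions = domain_fractions)
}

#' Tidy burden report over variant sets and cohorts
#'
#' One row per (variant set, cohort) pair.
#'
#' @param variants Annotated variant data.frame.
#' @param vsets List of `variant_set` objects.
#' @param cohort_names Character vector of stratum/set names.
#' @param cohorts A `cohort_set`.
#' @return A data.frame with the [count_burden()] columns plus
#'   `frequency_label` in the report's percent style.
#' @export
burden_table <- function(variants, vsets, cohort_names, cohorts) {
  rows <- list()
  for (vs in vsets)
    for (cn in cohort_names)
      rows[[length(rows) + 1L]] <- count_burden(variants, vs, cn, cohorts)
  out <- do.call(rbind, rows)
  out$frequency_label <- vapply(out$frequency, format_percent, character(1))
  rownames(out) <- NULL
  out
}

#' Format an allele frequency as a percent label
#'
#' Mixed report style: below 0.1% the percent is shown to 2 significant
#' figures (`"0.045%"`), otherwise rounded to 2 decimals (`"0.19%"` shown
#' without trailing zeros); zero is `"0%"`.
#'
#' @param x Frequency on the `[0, 1]` scale.
#' @return A percent string.
#' @export
format_percent <- function(x) {
  stopifnot(is.numeric(x), length(x) == 1L, x >= 0, x <= 1)
  p <- 100 * x
  if (p == 0) return("0%")
  lab <- if (p < 0.1) formatC(signif(p, 2), format = "fg", flag = "#")
         else formatC(round(p, 2), format = "fg")
  if (grepl(".", lab, fixed = TRUE))
    lab <- sub("\\.$", "", sub("0+$", "", lab))
  paste0(lab, "%")
}
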