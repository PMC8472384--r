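#' Build cohort strata and combined sets from a configuration
#'
#' A cohort configuration lists sequencing strata (name and number of
#' individuals; allele counts are derived as 2N, everything here being
#' autosomal and diploid) and named combined sets assembled from disjoint
#' strata, e.g. a familial set pooling discovery and validation
#' family-history-positive patients, or a non-familial pool of sporadic
#' cases and controls.
#'
#' @param config A list with elements `strata` (data.frame or list with
#'   `name`, `n_individuals`, optional `role`) and optional `sets`
#'   (list of `{name, members}`).
#' @return An object of class `cohort_set`: list with `strata` (data.frame
#'   `name`, `n_individuals`, `n_alleles`) and `sets` (named list of member
#'   character vectors; every stratum is also addressable by its own name).
#' @examples
#' build_cohorts(list(
#'   strata = data.frame(name = c("discovery_fh", "validation_fh"),
#'                       n_individuals = c(186, 858)),
#'   sets = list(list(name = "familial",
#'                    members = c("discovery_fh", "validation_fh")))))
#' @export
build_cohorts <- function(config) {
  st <- config$strata
  if (is.null(st)) stop_config("cohort configuration lacks 'strata'")
  st <- as.data.frame(st)
  if (!all(c("name", "n_individuals") %in% names(st)))
    stop_config("each stratum needs 'name' and 'n_individuals'")
  st$name <- as.character(st$name)
  st$n_individuals <- as.integer(st$n_individuals)
  if (any(is.na(st$n_individuals)) || any(st$n_individuals < 1L))
    stop_config("stratum sizes must be positive integers")
  if (anyDuplicated(st$name))
    stop_config(sprintf("duplicate stratum name: %s",
                        st$name[duplicated(st$name)][1]))
  st$n_alleles <- 2L * st$n_individuals

  sets <- list()
  for (s in config$sets) {
    nm <- s$name
    members <- unlist(s$members)
    if (is.null(nm) || !length(members))
      stop_config("each set needs a name and at least one member")
    unknown <- setdiff(members, st$name)
    if (length(unknown))
      stop_config(sprintf("set '%s' references unknown stratum '%s'",
                          nm, unknown[1]))
    if (anyDuplicated(members))
      stop_config(sprintf("set '%s' lists a stratum twice", nm))
    if (nm %in% c(st$name, names(sets)))
      stop_config(sprintf("set name '%s' collides with an existing name", nm))
    sets[[nm]] <- as.character(members)
  }
  structure(list(strata = st[, c("name", "n_individuals", "n_alleles")],
                 sets = sets),
            class = "cohort_set")
}

#' Read a cohort configuration from JSON
#'
#' @param path Path to a JSON file with `strata` and optional `sets`.
#' @return A `cohort_set` (see [build_cohorts()]).
#' @export
read_cohort_config <- function(path) {
  if (!file.exists(path))
    stop_config(sprintf("cohort configuration not found: %s", path))
  js <- jsonlite::read_json(path, simplifyVector = TRUE)
  sets <- NULL
  if (!is.null(js$sets)) {
    sets <- if (is.data.frame(js$sets))
      lapply(seq_len(nrow(js$sets)), function(i)
        list(name = js$sets$name[i], members = js$sets$members[[i]]))
    else js$sets
  }
  build_cohorts(list(strata = js$strata, sets = sets))
}

#' @export
print.cohort_set <- function(x, ...) {
  cat(sprintf("<cohort_set> %d strata, %d combined set(s)\n",
              nrow(x$strata), length(x$sets)))
  for (i in seq_len(nrow(x$strata)))
    cat(sprintf("  %-16s %6d individuals  %6d alleles\n", x$strata$name[i],
                x$strata$n_individuals[i], x$strata$n_alleles[i]))
  for (nm in names(x$sets))
    cat(sprintf("  %-16s = %s\n", nm, paste(x$sets[[nm]], collapse = " + ")))
  invisible(x)
}

# resolve a stratum or set name to its member strata
cohort_members <- function(cohorts, name) {
  stopifnot(inherits(cohorts, "cohort_set"))
  if (name %in% names(cohorts$sets)) return(cohorts$sets[[name]])
  if (name %in% cohorts$strata$name) return(name)
  stop_config(sprintf("unknown cohort '%s'", name))
}

#' Allele total of a stratum or combined set
#'
#' @param cohorts A `cohort_set`.
#' @param name Stratum or set name.
#' @return Integer allele count (2 x individuals, summed over members).
#' @export
allele_total <- function(cohorts, name) {
  members <- cohort_members(cohorts, name)
  sum(cohorts$strata$n_alleles[match(members, cohorts$strata$name)])
}
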