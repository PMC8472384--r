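#' Assemble a run configuration
#'
#' Paths to the four inputs plus the filtering knobs. All referenced paths
#' must exist at construction time.
#'
#' @param variant_table Path to the variant TSV.
#' @param cohort_config Path to the cohort JSON.
#' @param transcript_model Path to the transcript/domain JSON.
#' @param reference_counts Path to the reference allele-count TSV.
#' @param cadd_cutoff CADD threshold for deleterious missense (default 25).
#' @param domain_filter Optional domain name restricting reported variant
#'   sets.
#' @param exclude_pos Genomic-position blocklist applied before counting
#'   (default: the one curated exclusion of the study dataset,
#'   chr5:131931451).
#' @param out_dir Output directory (created on demand).
#' @param seed Integer seed recorded in outputs.
#' @return An object of class `run_config`.
#' @export
run_config <- function(variant_table, cohort_config, transcript_model,
                       reference_counts, cadd_cutoff = 25,
                       domain_filter = NULL,
                       exclude_pos = 131931451L,
                       out_dir = NULL, seed = 1L) {
  paths <- c(variant_table = variant_table, cohort_config = cohort_config,
             transcript_model = transcript_model,
             reference_counts = reference_counts)
  for (nm in names(paths))
    if (!file.exists(paths[[nm]]))
      stop_config(sprintf("%s path does not exist: %s", nm, paths[[nm]]))
  if (cadd_cutoff < 0) stop_config("cadd_cutoff must be non-negative")
  structure(list(paths = as.list(paths), cadd_cutoff = cadd_cutoff,
                 domain_filter = domain_filter,
                 exclude_pos = as.integer(exclude_pos),
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "run_config")
}

#' Default packaged inputs
#'
#' Convenience constructor pointing at the fixtures shipped under
#' `inst/extdata/`: the study's printed variant table, cohort definitions,
#' transcript/domain model and frozen gnomAD reference counts.
#'
#' @param ... Overrides passed to [run_config()].
#' @return A `run_config`.
#' @export
default_run_config <- function(...) {
  ext <- function(f) system.file("extdata", f, package = "lofburden",
                                 mustWork = TRUE)
  run_config(variant_table = ext("rad50_variants.tsv"),
             cohort_config = ext("cohorts_henan.json"),
             transcript_model = ext("transcript_nm005732.json"),
             reference_counts = ext("gnomad_reference_counts.tsv"),
             ...)
}

load_run_inputs <- function(config) {
  model <- read_transcript_model(config$paths$transcript_model)
  cohorts <- read_cohort_config(config$paths$cohort_config)
  variants <- read_variant_table(config$paths$variant_table)
  variants <- annotate_variants(variants, model)
  refs <- read_reference_counts(config$paths$reference_counts)
  list(model = model, cohorts = cohorts, variants = variants, refs = refs)
}

# the four report variant sets; restricted when a domain filter is set
report_variant_sets <- function(config) {
  sets <- list(vs_protein("p.Q672X"), vs_protein("p.K722fs"),
               vs_protein(c("p.Q672X", "p.K722fs")), vs_lof("all_lof"))
  if (!is.null(config$domain_filter)) {
    keep <- c("p.Q672X", "p.K722fs", "p.Q672X/p.K722fs")
    sets <- Filter(function(s) s$name %in% keep, sets)
  }
  sets
}

#' Discovery-phase burden report
#'
#' Per-variant and total LOF burden in the discovery stratum, with the
#' exact-test comparison of the total against the East Asian reference
#' population, after applying the CADD filter and the exclusion blocklist.
#'
#' @param config A `run_config`.
#' @return A list of class `lofburden_report` with `per_variant`, `burden`,
#'   `assoc` and `sidecar` (machine-readable raw numbers).
#' @export
run_discovery <- function(config) {
  inp <- load_run_inputs(config)
  lof <- filter_deleterious(inp$variants, config$cadd_cutoff,
                            config$exclude_pos)
  lof <- lof[lof$is_lof, , drop = FALSE]
  disc <- "discovery_fh"
  per_variant <- lof[, c("chrom", "pos", "exon", "coding_change",
                         "protein_change", "consequence", "residue",
                         "domains", disc)]
  per_variant <- per_variant[per_variant[[disc]] > 0, , drop = FALSE]
  burden <- count_burden(lof, vs_lof("all_lof"), disc, inp$cohorts)
  assoc <- NULL
  if (nrow(per_variant) > 0)
    assoc <- burden_scan(burden, inp$refs["gnomad_ea"])
  out <- structure(list(
    title = "Discovery-phase LOF burden",
    per_variant = per_variant, burden = burden, assoc = assoc,
    sidecar = list(config = config_echo(config),
                   burden = as.list(burden),
                   assoc = if (is.null(assoc)) NULL else as_sidecar(assoc))),
    class = "lofburden_report")
  write_report(out, config, "discovery")
  out
}

#' Combined-cohort risk report
#'
#' The combined familial cohort against three comparators — the pooled
#' non-familial population and the East Asian and all-population reference
#' counts — for the four variant sets (the two zinc-hook variants singly,
#' jointly, and all LOF variants), plus the within-study pairings of the
#' discovery table footnotes (familial vs controls, familial vs sporadic,
#' sporadic vs controls on all LOF). Cells are rendered with report
#' rounding (`"inf"` literal, OR to 2 decimals, p to 2 significant
#' figures) and flagged at p < 0.05.
#'
#' @param config A `run_config`.
#' @return A list of class `lofburden_report` with `frequencies` (familial
#'   percent cells), `assoc`, `footnotes` and `sidecar`.
#' @export
run_combined <- function(config) {
  inp <- load_run_inputs(config)
  lof <- filter_deleterious(inp$variants, config$cadd_cutoff,
                            config$exclude_pos)
  lof <- lof[lof$is_lof, , drop = FALSE]
  sets <- report_variant_sets(config)
  burdens <- burden_table(lof, sets, "familial", inp$cohorts)
  nonfam <- burden_table(lof, sets, "nonfamilial", inp$cohorts)
  refs <- inp$refs[c("gnomad_ea", "gnomad_all")]
  if (any(vapply(refs, function(r) r$n_alleles <= 0, logical(1))))
    stop_validate("reference population has a non-positive allele total")
  rows <- list()
  for (i in seq_len(nrow(burdens))) {
    cmp_list <- c(list(nonfam[i, ]), refs)
    rows[[i]] <- burden_scan(burdens[i, ], cmp_list)
  }
  assoc <- do.call(rbind, rows)
  assoc$n_tests <- nrow(assoc)
  foot_sets <- list(vs_lof("all_lof"))
  foot <- rbind(
    burden_scan(burden_table(lof, foot_sets, "familial", inp$cohorts),
                list(count_burden(lof, foot_sets[[1]], "control",
                                  inp$cohorts))),
    burden_scan(burden_table(lof, foot_sets, "familial", inp$cohorts),
                list(count_burden(lof, foot_sets[[1]], "sporadic",
                                  inp$cohorts))),
    burden_scan(burden_table(lof, foot_sets, "sporadic", inp$cohorts),
                list(count_burden(lof, foot_sets[[1]], "control",
                                  inp$cohorts))))
  out <- structure(list(
    title = "Combined-cohort LOF risk",
    frequencies = burdens[, c("variant_set", "cohort", "carriers",
                              "allele_total", "frequency",
                              "frequency_label")],
    assoc = assoc, footnotes = foot,
    sidecar = list(config = config_echo(config),
                   assoc = as_sidecar(assoc), footnotes = as_sidecar(foot))),
    class = "lofburden_report")
  write_report(out, config, "combined")
  out
}

#' Reproduce both study tables
#'
#' Runs [run_discovery()] and [run_combined()] and returns both reports.
#'
#' @param config A `run_config`.
#' @return A list with `discovery` and `combined` reports.
#' @export
reproduce_tables <- function(config) {
  list(discovery = run_discovery(config), combined = run_combined(config))
}

as_sidecar <- function(assoc) {
  lapply(seq_len(nrow(assoc)), function(i) {
    r <- assoc[i, ]
    list(variant_set = r$variant_set, group1 = r$group1, group2 = r$group2,
         table = list(a = r$carriers1, b = r$alleles1 - r$carriers1,
                      c = r$carriers2, d = r$alleles2 - r$carriers2),
         odds_ratio = r$odds_ratio, p_two_sided = r$p_two_sided,
         significant = r$significant)
  })
}

config_echo <- function(config) {
  sums <- vapply(config$paths, function(p)
    unname(tools::md5sum(path.expand(p))), character(1))
  list(paths = config$paths, md5 = as.list(sums),
       cadd_cutoff = config$cadd_cutoff,
       domain_filter = config$domain_filter,
       exclude_pos = config$exclude_pos, seed = config$seed)
}

write_report <- function(report, config, stem) {
  if (is.null(config$out_dir)) return(invisible(NULL))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- file.path(config$out_dir, paste0(stem, "_assoc.tsv"))
  if (!is.null(report$assoc))
    utils::write.table(report$assoc, tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  jsonlite::write_json(report$sidecar,
                       file.path(config$out_dir, paste0(stem, ".json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  md <- file.path(config$out_dir, paste0(stem, ".md"))
  writeLines(render_markdown(report), md)
  invisible(NULL)
}

#' Render a report as a Markdown table
#'
#' @param report A `lofburden_report`.
#' @return Character vector of Markdown lines.
#' @export
render_markdown <- function(report) {
  lines <- c(paste("#", report$title), "")
  a <- report$assoc
  if (!is.null(a) && nrow(a)) {
    lines <- c(lines,
      "| variant set | group 1 | group 2 | carriers 1 | carriers 2 | p | OR |",
      "|---|---|---|---|---|---|---|",
      sprintf("| %s | %s | %s | %d/%d | %d/%d | %s | %s |",
              a$variant_set, a$group1, a$group2,
              a$carriers1, a$alleles1, a$carriers2, a$alleles2,
              ifelse(a$significant, paste0("**", a$p_label, "**"),
                     a$p_label),
              a$or_label))
  } else {
    lines <- c(lines, "(no association rows: empty variant set)")
  }
  lines
}

#' @export
print.lofburden_report <- function(x, ...) {
  cat(render_markdown(x), sep = "\n")
  invisible(x)
}
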