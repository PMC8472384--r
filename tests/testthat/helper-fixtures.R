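# shared fixture builders; all data constructed in code

ext_file <- function(f) system.file("extdata", f, package = "lofburden",
                                    mustWork = TRUE)

study_config <- function(...) default_run_config(...)

study_inputs <- function() {
  cfg <- study_config()
  lofburden:::load_run_inputs(cfg)
}

# LOF-filtered study variants plus cohorts, used across tests
study_lof <- function() {
  inp <- study_inputs()
  lof <- filter_deleterious(inp$variants, 25, 131931451L)
  list(lof = lof[lof$is_lof, , drop = FALSE], cohorts = inp$cohorts,
       refs = inp$refs, variants = inp$variants, model = inp$model)
}

# minimal two-stratum cohort for constructed examples
toy_cohorts <- function(n1 = 10L, n2 = 20L) {
  build_cohorts(list(
    strata = data.frame(name = c("cases", "controls"),
                        n_individuals = c(n1, n2)),
    sets = list(list(name = "all", members = c("cases", "controls")))))
}

ct <- function(a, b, c, d) contingency_table(a, b, c, d)
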