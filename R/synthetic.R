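#' Synthetic transcript model with an engineered CDS
#'
#' The real transcript sequence is not part of the packaged inputs (the
#' tabular pipeline runs without one), so tests and simulations use this
#' synthetic stand-in: a CDS of the declared length whose engineered codons
#' make every printed coding-change/protein-label pair of the study
#' consistent under the standard genetic code (e.g. codon 672 is CAA so
#' that the C>T substitution at cDNA 2014 creates a TAA stop, "p.Q672X"),
#' with the zinc-hook domain interval at residues 635-734. All other codons
#' are a fixed non-stop filler pattern; the sequence is deterministic.
#'
#' @param cds_length CDS length in nucleotides, divisible by 3 (default
#'   3939 = 1312 residues plus the stop codon, the RAD50 CDS length).
#' @return A `transcript_model` with a CDS sequence.
#' @export
synthetic_transcript <- function(cds_length = 3939) {
  stopifnot(cds_length %% 3 == 0, cds_length >= 3)
  n_codon <- cds_length %/% 3L
  filler <- c("GCT", "GAA", "TTG", "AGC", "GAT", "AAG", "CTG", "GGA")
  codons <- rep(filler, length.out = n_codon)
  codons[1L] <- "ATG"
  codons[n_codon] <- "TAA"
  engineered <- c(
    "370"  = "CTA",  # L; c.1110delA removes its third base
    "672"  = "CAA",  # Q; c.C2014T -> TAA stop (p.Q672X)
    "722"  = "AAA",  # K; c.2165_2166insT frameshift (p.K722fs)
    "726"  = "CGC",  # R; c.G2177A -> CAC (p.R726H)
    "763"  = "CGC",  # R; c.C2287T -> TGC (p.R763C)
    "911"  = "CAA",  # Q; c.C2731T -> TAA stop (p.Q911X)
    "994"  = "AAA",  # K; c.2980_2983del frameshift (p.K994fs)
    "1026" = "AAA",  # K; c.3077_3080del frameshift (p.K1026fs)
    "1185" = "CGA",  # R; c.C3553T -> TGA stop (p.R1185X)
    "1239" = "CGA",  # R; c.G3716A -> CAA (p.R1239Q)
    "1264" = "CTT")  # L; c.C3790T -> TTT (p.L1264F)
  for (res in names(engineered)) {
    i <- as.integer(res)
    if (i < n_codon) codons[i] <- engineered[[res]]
  }
  transcript_model(
    "NM_005732-synthetic", cds_length,
    domains = data.frame(name = "zinc_hook", start = 635L, end = 734L,
                         stringsAsFactors = FALSE),
    cds_sequence = paste(codons, collapse = ""))
}

#' Default synthetic variant templates
#'
#' Three templates mirroring the geometry of the study variants: a
#' stop-gain and a frameshift inside the zinc hook, and a missense outside
#' it.
#'
#' @return A data.frame with columns `chrom`, `pos`, `exon`,
#'   `coding_change`, `cadd`.
#' @export
variant_templates <- function() {
  data.frame(
    chrom = "chr5",
    pos = c(131931309L, 131931460L, 131978000L),
    exon = c(13L, 13L, 25L),
    coding_change = c("c.C2014T", "c.2165_2166insT", "c.C3790T"),
    cadd = c(NA, NA, 30),
    stringsAsFactors = FALSE)
}

#' Specify a cohort simulation
#'
#' @param strata A data.frame with columns `name`, `n_individuals`,
#'   `carrier_frequency` (per-allele frequency in `[0, 1]`).
#' @param templates Variant templates (see [variant_templates()]).
#' @param n_replicates Number of Monte-Carlo replicates for calibration.
#' @param seed Integer seed; recorded in every output.
#' @return An object of class `simulation_spec`.
#' @export
simulation_spec <- function(strata, templates = variant_templates(),
                            n_replicates = 5000L, seed = 1L) {
  strata <- as.data.frame(strata)
  stopifnot(all(c("name", "n_individuals", "carrier_frequency") %in%
                  names(strata)))
  if (any(strata$carrier_frequency < 0 | strata$carrier_frequency > 1))
    stop_validate("carrier frequencies must lie in [0, 1]")
  if (any(strata$n_individuals < 1))
    stop_validate("stratum sizes must be positive")
  stopifnot(n_replicates >= 1)
  structure(list(strata = strata, templates = as.data.frame(templates),
                 n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed)),
            class = "simulation_spec")
}

#' Simulate cohort genotype tables
#'
#' Each individual contributes two alleles; each allele is independently a
#' carrier allele with the stratum's per-allele frequency (so homozygous
#' carriers arise with probability f^2 and contribute two alleles but one
#' carrier). Carrier alleles are assigned uniformly at random to the
#' variant templates. Deterministic under a fixed seed.
#'
#' @param spec A `simulation_spec`.
#' @param model Transcript model used to annotate the emitted variant
#'   table (default [synthetic_transcript()]).
#' @return A list of class `synthetic_cohort` with `genotype_tables` (one
#'   data.frame per stratum: `individual` plus one 0/1/2 column per
#'   template), `variant_table` (the TSV dialect consumed by the
#'   annotation/burden pipeline, carrier counts = individuals carrying at
#'   least one allele), `spec` and `seed`.
#' @export
simulate_cohort <- function(spec, model = synthetic_transcript()) {
  stopifnot(inherits(spec, "simulation_spec"))
  set.seed(spec$seed)
  tmpl <- spec$templates
  n_var <- nrow(tmpl)
  geno <- list()
  carrier_cols <- list()
  for (i in seq_len(nrow(spec$strata))) {
    nm <- spec$strata$name[i]
    n <- spec$strata$n_individuals[i]
    f <- spec$strata$carrier_frequency[i]
    alleles <- stats::rbinom(n, 2L, f)     # carrier alleles per individual
    g <- matrix(0L, nrow = n, ncol = n_var)
    carriers <- which(alleles > 0L)
    for (j in carriers) {
      hits <- sample.int(n_var, alleles[j], replace = TRUE)
      for (h in hits) g[j, h] <- g[j, h] + 1L
    }
    tab <- data.frame(individual = sprintf("%s_%04d", nm, seq_len(n)),
                      stringsAsFactors = FALSE)
    for (v in seq_len(n_var)) tab[[tmpl$coding_change[v]]] <- g[, v]
    geno[[nm]] <- tab
    carrier_cols[[nm]] <- colSums(g > 0L)
  }
  vt <- data.frame(chrom = tmpl$chrom, pos = tmpl$pos, exon = tmpl$exon,
                   coding_change = tmpl$coding_change, cadd = tmpl$cadd,
                   stringsAsFactors = FALSE)
  for (nm in names(carrier_cols)) vt[[nm]] <- carrier_cols[[nm]]
  vt <- annotate_variants(vt, model)
  structure(list(genotype_tables = geno, variant_table = vt,
                 spec = spec, seed = spec$seed),
            class = "synthetic_cohort")
}

# Monte-Carlo rejection rate of the exact test: carrier-allele counts per
# replicate are Binomial(2N, f), the aggregate of two Bernoulli draws per
# individual; p-values are memoized over unique count pairs.
mc_rejection_rate <- function(n1_alleles, f1, n2_alleles, f2, alpha,
                              n_replicates, seed) {
  set.seed(seed)
  a <- stats::rbinom(n_replicates, n1_alleles, f1)
  c <- stats::rbinom(n_replicates, n2_alleles, f2)
  key <- paste(a, c)
  uk <- !duplicated(key)
  pu <- vapply(which(uk), function(i)
    fisher_two_sided(contingency_table(a[i], n1_alleles - a[i],
                                       c[i], n2_alleles - c[i])),
    numeric(1))
  p <- pu[match(key, key[uk])]
  rate <- mean(p <= alpha)
  list(rate = rate, se = sqrt(rate * (1 - rate) / n_replicates))
}

new_calibration <- function(alpha, mc, n_replicates) {
  structure(list(nominal_alpha = alpha,
                 empirical_rejection_rate = mc$rate,
                 monte_carlo_se = mc$se,
                 n_replicates = n_replicates),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf(
    "<calibration> alpha %.3g: rejection rate %.4f (MC SE %.4f, %d replicates)\n",
    x$nominal_alpha, x$empirical_rejection_rate, x$monte_carlo_se,
    x$n_replicates))
  invisible(x)
}

#' Type-I error calibration of the exact test under the null
#'
#' Both strata share one per-allele carrier frequency; the empirical
#' rejection rate of the two-sided exact test at level `alpha` is
#' estimated by Monte Carlo. A test rejects when p <= alpha. On discrete
#' support the exact test is conservative, so the rate is expected at or
#' below `alpha`.
#'
#' @param spec A `simulation_spec` with exactly two strata at equal
#'   frequencies.
#' @param alpha Nominal level.
#' @return A `calibration_result` with the empirical rate and its
#'   Monte-Carlo standard error `sqrt(r (1 - r) / B)`.
#' @export
calibrate_type1 <- function(spec, alpha = 0.05) {
  stopifnot(inherits(spec, "simulation_spec"), nrow(spec$strata) == 2L)
  f <- spec$strata$carrier_frequency
  if (f[1] != f[2])
    stop_validate("type-I calibration requires equal frequencies in both strata")
  mc <- mc_rejection_rate(2L * spec$strata$n_individuals[1], f[1],
                          2L * spec$strata$n_individuals[2], f[2],
                          alpha, spec$n_replicates, spec$seed)
  new_calibration(alpha, mc, spec$n_replicates)
}

#' Power of the exact test under an alternative
#'
#' Like [calibrate_type1()] but with differing per-allele frequencies in
#' the two strata; the rejection rate estimates power.
#'
#' @inheritParams calibrate_type1
#' @return A `calibration_result`.
#' @export
estimate_power <- function(spec, alpha = 0.05) {
  stopifnot(inherits(spec, "simulation_spec"), nrow(spec$strata) == 2L)
  f <- spec$strata$carrier_frequency
  mc <- mc_rejection_rate(2L * spec$strata$n_individuals[1], f[1],
                          2L * spec$strata$n_individuals[2], f[2],
                          alpha, spec$n_replicates, spec$seed)
  new_calibration(alpha, mc, spec$n_replicates)
}
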