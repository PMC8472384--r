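test_that("sample odds ratio handles finite, infinite and degenerate cells", {
  expect_equal(round(sample_odds_ratio(ct(4, 368, 30, 19924)), 2), 7.22)
  expect_equal(round(sample_odds_ratio(ct(1, 2087, 1, 282669)), 2), 135.44)
  expect_identical(sample_odds_ratio(ct(4, 2084, 0, 4490)), Inf)
  expect_identical(format_or(Inf), "inf")
  expect_identical(sample_odds_ratio(ct(0, 10, 5, 100)), 0)
  expect_true(is.na(sample_odds_ratio(ct(0, 10, 0, 100))))
  expect_error(contingency_table(-1, 2, 3, 4),
               class = "lofburden_validation_error")
})

test_that("two-sided p-values reproduce the published comparisons", {
  expect_equal(signif(fisher_two_sided(ct(4, 2084, 0, 4490)), 2), 0.010)
  expect_equal(signif(fisher_two_sided(ct(3, 2085, 0, 4490)), 2), 0.032)
  expect_equal(signif(fisher_two_sided(ct(1, 2087, 0, 19954)), 2), 0.095)
  expect_equal(signif(fisher_two_sided(ct(4, 2084, 5, 282665)), 2), 3.5e-7)
  expect_equal(signif(fisher_two_sided(ct(4, 368, 30, 19924)), 2), 3.3e-3)
  expect_identical(fisher_two_sided(ct(0, 50, 0, 80)), 1)
})

test_that("implementation agrees with stats::fisher.test", {
  set.seed(7)
  for (i in 1:50) {
    a <- rpois(1, 3); b <- rpois(1, 40)
    c <- rpois(1, 5); d <- rpois(1, 200)
    p <- fisher_two_sided(ct(a, b, c, d))
    ref <- stats::fisher.test(matrix(c(a, b, c, d), 2, byrow = TRUE))$p.value
    expect_equal(p, min(1, ref), tolerance = 1e-10)
  }
})

test_that("exact rational oracle equivalence on all tables with margins <= 10", {
  for (r1 in 1:10) for (r2 in 1:10) for (a in 0:r1) for (c in 0:r2) {
    p <- fisher_two_sided(ct(a, r1 - a, c, r2 - c))
    p_oracle <- oracle_fisher(a, r1 - a, c, r2 - c)
    expect_equal(p, p_oracle, tolerance = 1e-12,
                 label = sprintf("table (%d,%d,%d,%d)", a, r1 - a, c,
                                 r2 - c))
  }
})

test_that("exact rational oracle equivalence on random tables with margins <= 40", {
  set.seed(4715)
  for (i in 1:200) {
    r1 <- sample(1:40, 1); r2 <- sample(1:40, 1)
    a <- sample(0:r1, 1); c <- sample(0:r2, 1)
    p <- fisher_two_sided(ct(a, r1 - a, c, r2 - c))
    p_oracle <- oracle_fisher(a, r1 - a, c, r2 - c)
    expect_equal(p, p_oracle, tolerance = 1e-12,
                 label = sprintf("table (%d,%d,%d,%d)", a, r1 - a, c,
                                 r2 - c))
  }
})

test_that("group swap inverts the OR and preserves p (property)", {
  set.seed(11)
  for (i in 1:100) {
    a <- rpois(1, 4); b <- rpois(1, 30); c <- rpois(1, 4); d <- rpois(1, 50)
    t1 <- ct(a, b, c, d); t2 <- ct(c, d, a, b)
    or1 <- sample_odds_ratio(t1); or2 <- sample_odds_ratio(t2)
    if (!is.na(or1)) {
      if (is.infinite(or1)) expect_identical(or2, 0)
      else if (or1 == 0) expect_identical(or2, Inf)
      else expect_equal(or2, 1 / or1)
    }
    expect_equal(fisher_two_sided(t2), fisher_two_sided(t1),
                 tolerance = 1e-12)
    # transposition also preserves p
    expect_equal(fisher_two_sided(ct(a, c, b, d)), fisher_two_sided(t1),
                 tolerance = 1e-12)
  }
})

test_that("shifting a carrier into the enriched group never increases p", {
  set.seed(23)
  checked <- 0
  while (checked < 60) {
    a <- rpois(1, 5); b <- rpois(1, 60); c <- rpois(1, 3); d <- rpois(1, 80)
    if (b < 1 || c < 1) next
    if (d == 0 || (a / max(b, 1)) <= (c / d)) next
    p0 <- fisher_two_sided(ct(a, b, c, d))
    p1 <- fisher_two_sided(ct(a + 1, b - 1, c - 1, d + 1))
    expect_lte(p1, p0 + 1e-12)
    checked <- checked + 1
  }
})

test_that("p-values stay in (0, 1] and degenerate margins give 1", {
  expect_identical(fisher_two_sided(ct(0, 0, 0, 5)), 1)
  expect_identical(fisher_two_sided(ct(3, 0, 5, 0)), 1)
  set.seed(5)
  for (i in 1:50) {
    a <- rpois(1, 2); b <- rpois(1, 10); c <- rpois(1, 2); d <- rpois(1, 10)
    p <- fisher_two_sided(ct(a, b, c, d))
    expect_gt(p, 0); expect_lte(p, 1)
  }
})

test_that("the enumeration guard trips instead of approximating", {
  expect_error(fisher_two_sided(ct(3, 2085, 0, 4490), max_support = 2),
               class = "lofburden_enumeration_error")
})

test_that("burden_scan pairs burdens with comparators and flags significance", {
  s <- study_lof()
  hook <- count_burden(s$lof, vs_protein(c("p.Q672X", "p.K722fs"),
                                         name = "p.Q672X/p.K722fs"),
                       "familial", s$cohorts)
  nonfam <- count_burden(s$lof, vs_protein(c("p.Q672X", "p.K722fs"),
                                           name = "p.Q672X/p.K722fs"),
                         "nonfamilial", s$cohorts)
  res <- burden_scan(hook, list(nonfam, s$refs$gnomad_ea,
                                s$refs$gnomad_all))
  expect_identical(nrow(res), 3L)
  expect_identical(res$or_label, c("inf", "9.57", "108.51"))
  expect_identical(res$p_label, c("0.010", "0.0041", "3.5e-07"))
  expect_true(all(res$significant))
  expect_identical(unique(res$n_tests), 3L)
  # comparator lacking the set count errors
  expect_error(
    burden_scan(count_burden(s$lof, vs_protein("p.X1Y", name = "absent"),
                             "familial", s$cohorts),
                s$refs["gnomad_ea"]),
    class = "lofburden_config_error")
})
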