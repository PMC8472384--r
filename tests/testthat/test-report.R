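test_that("the discovery report reproduces the discovery-phase comparison", {
  out <- withr::local_tempdir()
  rep <- run_discovery(study_config(out_dir = out))
  expect_identical(rep$burden$carriers, 4L)
  expect_identical(rep$burden$allele_total, 372L)
  expect_identical(nrow(rep$per_variant), 4L)
  a <- rep$assoc
  expect_equal(c(a$carriers2, a$alleles2), c(30, 19954))
  expect_identical(a$or_label, "7.22")
  expect_identical(a$p_label, "0.0033")
  expect_true(a$significant)
  expect_true(file.exists(file.path(out, "discovery.json")))
  expect_true(file.exists(file.path(out, "discovery.md")))
  # sidecar holds the raw 2x2 table behind the rendered cell
  side <- jsonlite::read_json(file.path(out, "discovery.json"))
  expect_equal(unlist(side$assoc[[1]]$table),
               c(a = 4, b = 368, c = 30, d = 19924))
})

test_that("an empty variant table yields a zero-burden report without tests", {
  out <- withr::local_tempdir()
  empty <- file.path(out, "empty.tsv")
  v <- utils::read.delim(ext_file("rad50_variants.tsv"), comment.char = "#")
  utils::write.table(v[0, ], empty, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  cfg <- run_config(empty, ext_file("cohorts_henan.json"),
                    ext_file("transcript_nm005732.json"),
                    ext_file("gnomad_reference_counts.tsv"),
                    out_dir = out)
  rep <- run_discovery(cfg)
  expect_identical(rep$burden$carriers, 0L)
  expect_null(rep$assoc)
})

test_that("the exclusion list removes a variant from totals end to end", {
  out <- withr::local_tempdir()
  cfg <- study_config(exclude_pos = c(131931451L, 131931309L))
  rep <- run_discovery(cfg)
  # excluding the stop-gain locus drops its discovery carrier
  expect_identical(rep$burden$carriers, 3L)
  expect_false("c.C2014T" %in% rep$per_variant$coding_change)
})

test_that("the combined report reproduces the risk grid", {
  rep <- run_combined(study_config())
  a <- rep$assoc
  expect_identical(nrow(a), 12L)
  grid <- a[, c("variant_set", "group2", "p_label", "or_label")]
  pick <- function(set, cmp) grid[grid$variant_set == set &
                                    grid$group2 == cmp, ]
  expect_identical(pick("p.Q672X", "nonfamilial")$or_label, "inf")
  expect_identical(pick("p.Q672X", "gnomad_all")$p_label, "0.015")
  expect_identical(pick("p.Q672X", "gnomad_all")$or_label, "135.44")
  expect_identical(pick("p.K722fs", "gnomad_ea")$or_label, "7.18")
  expect_identical(pick("p.Q672X/p.K722fs", "nonfamilial")$p_label,
                   "0.010")
  expect_identical(pick("all_lof", "nonfamilial")$or_label, "1.88")
  # familial frequency cells
  freq <- rep$frequencies
  expect_identical(freq$frequency_label[freq$variant_set == "all_lof"],
                   "0.34%")
  # footnote pairings: familial vs control, familial vs sporadic,
  # sporadic vs control on all LOF
  foot <- rep$footnotes
  expect_identical(foot$group2, c("control", "sporadic", "control"))
  expect_identical(foot$or_label, c("1.97", "1.80", "1.09"))
  expect_identical(foot$p_label, c("0.37", "0.38", "1.0"))
  expect_identical(unique(a$n_tests), 12L)
})

test_that("a domain filter restricts the report to zinc-hook sets", {
  rep <- run_combined(study_config(domain_filter = "zinc_hook"))
  expect_setequal(unique(rep$assoc$variant_set),
                  c("p.Q672X", "p.K722fs", "p.Q672X/p.K722fs"))
})

test_that("reports are byte-stable across runs", {
  out1 <- withr::local_tempdir(); out2 <- withr::local_tempdir()
  run_combined(study_config(out_dir = out1))
  run_combined(study_config(out_dir = out2))
  for (f in c("combined_assoc.tsv", "combined.md"))
    expect_identical(readLines(file.path(out1, f)),
                     readLines(file.path(out2, f)))
})

test_that("the CLI runs subcommands and maps error classes to exit codes", {
  out <- withr::local_tempdir()
  expect_identical(
    suppressMessages(lofburden_cli(c("reproduce-tables", "--out-dir", out))),
    0L)
  expect_true(file.exists(file.path(out, "combined_assoc.tsv")))
  expect_identical(
    suppressMessages(lofburden_cli(c("calibrate", "--out-dir", out,
                                     "--n-replicates", "200",
                                     "--seed", "3"))),
    0L)
  expect_true(file.exists(file.path(out, "calibration.json")))
  expect_identical(
    suppressMessages(lofburden_cli(c("simulate", "--out-dir", out,
                                     "--frequency", "0.01", "--seed", "3"))),
    0L)
  expect_true(file.exists(file.path(out, "cases.vcf")))
  # config error: missing input path
  expect_identical(
    suppressMessages(lofburden_cli(c("annotate", "--variant-table",
                                     "no/such.tsv", "--out-dir", out))),
    2L)
  expect_identical(suppressMessages(lofburden_cli(character())), 2L)
  expect_identical(suppressMessages(lofburden_cli("frobnicate")), 2L)
})
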