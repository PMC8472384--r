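syn_model <- synthetic_transcript()

test_that("frameshift and inframe classification follows net indel length", {
  ins <- classify_consequence(parse_coding_change("c.2165_2166insT"),
                              syn_model)
  expect_identical(ins$consequence, "frameshift")
  expect_identical(ins$first_affected_residue, 722L)
  expect_true(ins$is_lof)
  expect_identical(ins$domains_hit, "zinc_hook")
  expect_identical(ins$protein_change, "p.K722fs")

  del <- classify_consequence(parse_coding_change("c.2980_2983del"),
                              syn_model)
  expect_identical(del$consequence, "frameshift")
  expect_identical(del$first_affected_residue, 994L)
  expect_true(del$is_lof)

  inframe <- classify_consequence(parse_coding_change("c.100_102del"),
                                  syn_model)
  expect_identical(inframe$consequence, "inframe_indel")
  expect_false(inframe$is_lof)

  ins3 <- classify_consequence(parse_coding_change("c.100_101insTTT"),
                               syn_model)
  expect_identical(ins3$consequence, "inframe_indel")
})

test_that("substitutions translate against the CDS when present", {
  stop_gain <- classify_consequence(parse_coding_change("c.C2014T"),
                                    syn_model)
  expect_identical(stop_gain$consequence, "stop_gain")
  expect_identical(stop_gain$protein_change, "p.Q672X")
  expect_true(stop_gain$is_lof)
  expect_identical(stop_gain$domains_hit, "zinc_hook")

  mis <- classify_consequence(parse_coding_change("c.C3790T"), syn_model)
  expect_identical(mis$consequence, "missense")
  expect_identical(mis$protein_change, "p.L1264F")
  expect_false(mis$is_lof)

  # third codon position of the CTT codon at residue 1264: CTT -> CTC is
  # still leucine
  syn <- classify_consequence(parse_coding_change("c.3792T>C"), syn_model)
  expect_identical(syn$consequence, "synonymous")
  expect_identical(syn$protein_change, "p.L1264L")
})

test_that("reference-base mismatches against the CDS are rejected", {
  expect_error(classify_consequence(parse_coding_change("c.A2014T"),
                                    syn_model),
               class = "lofburden_validation_error")
})

test_that("without a CDS sequence substitutions fall back to supplied labels", {
  bare <- transcript_model("NM_005732", 3939,
    domains = data.frame(name = "zinc_hook", start = 635, end = 734))
  cc <- parse_coding_change("c.C2014T")
  expect_identical(classify_consequence(cc, bare)$consequence, "unknown")
  trusted <- classify_consequence(cc, bare, protein_change = "p.Q672X")
  expect_identical(trusted$consequence, "stop_gain")
  expect_true(trusted$is_lof)
  expect_identical(
    classify_consequence(parse_coding_change("c.C3790T"), bare,
                         protein_change = "p.L1264F")$consequence,
    "missense")
})

test_that("coordinates outside the model raise a range error", {
  expect_error(classify_consequence(parse_coding_change("c.C4000T"),
                                    syn_model),
               class = "lofburden_range_error")
})

test_that("kind restricts the reachable consequence classes (property)", {
  set.seed(42)
  subs_classes <- c("stop_gain", "missense", "synonymous")
  for (i in 1:200) {
    pos <- sample(3936L, 1)
    codon_start <- ((pos - 1L) %/% 3L) * 3L + 1L
    ref <- substring(syn_model$cds_sequence, pos, pos)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    call <- classify_consequence(
      parse_coding_change(sprintf("c.%d%s>%s", pos, ref, alt)), syn_model)
    expect_true(call$consequence %in% subs_classes)
    expect_identical(call$is_lof, call$consequence == "stop_gain")
    expect_identical(call$first_affected_residue, codon_index(pos))

    len <- sample(1:6, 1)
    dstart <- sample(3900L, 1)
    dcall <- classify_consequence(
      parse_coding_change(sprintf("c.%d_%ddel", dstart, dstart + len - 1L)),
      syn_model)
    expect_true(dcall$consequence %in% c("frameshift", "inframe_indel"))
    expect_identical(dcall$consequence == "frameshift", len %% 3L != 0L)
    expect_identical(dcall$is_lof, dcall$consequence == "frameshift")
  }
})

test_that("all study LOF rows re-derive residue and LOF status from cDNA alone", {
  rows <- list(
    list(cc = "c.C2014T", res = 672L, cons = "stop_gain"),
    list(cc = "c.2165_2166insT", res = 722L, cons = "frameshift"),
    list(cc = "c.2980_2983del", res = 994L, cons = "frameshift"),
    list(cc = "c.3077_3080del", res = 1026L, cons = "frameshift"),
    list(cc = "c.1110delA", res = 370L, cons = "frameshift"),
    list(cc = "c.C2731T", res = 911L, cons = "stop_gain"),
    list(cc = "c.C3553T", res = 1185L, cons = "stop_gain"))
  for (r in rows) {
    call <- classify_consequence(parse_coding_change(r$cc), syn_model)
    expect_identical(call$first_affected_residue, r$res, label = r$cc)
    expect_identical(call$consequence, r$cons, label = r$cc)
    expect_true(call$is_lof, label = r$cc)
  }
})
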