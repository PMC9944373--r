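test_that("the packaged seclusion reconstruction is valid and has the published architecture", {
  skel <- load_seclusion_skeleton()
  iss <- validate_tree(skel)
  expect_false(any(iss$severity == "error"))
  kinds <- vapply(skel$gates, `[[`, character(1), "kind")
  expect_identical(sum(kinds == "AND"), 2L)
  expect_identical(skel$gates$TOP$kind, "AND")
  # prevention failure = failure of both risk assessment and intervention
  expect_setequal(skel$gates$PREVENTION_AND$inputs,
                  c("ASSESSMENT_OR", "INTERVENTION_OR"))
  expect_true(all(c("schizophrenia", "bipolar_disorder",
                    "psychiatric_comorbidity", "alzheimers",
                    "lewy_body_dementia", "personality_disorder")
                  %in% skel$gates$DISORDER_OR$inputs))
  expect_true(all(c("getting_out_of_bed", "seated_to_standing",
                    "getting_to_bed", "slipping", "tripping", "stumbling")
                  %in% skel$gates$MECHANISM_OR$inputs))
  expect_true(all(c("narrow_base_of_support", "obesity", "gait_abnormality")
                  %in% skel$gates$PHYS_REASON_OR$inputs))
  expect_true(all(c("dizziness", "muscle_weakness", "arrhythmia")
                  %in% skel$gates$SIDE_EFFECT_OR$inputs))
  expect_true(isTRUE(skel$metadata$illustrative))

  bare <- load_seclusion_skeleton(with_probabilities = FALSE)
  expect_true(all(vapply(bare$events, function(e) is.null(e$estimate),
                         logical(1))))
})

test_that("every skeleton cut set takes one factor from each of the five branches", {
  skel <- load_seclusion_skeleton()
  mcs <- mocus_cut_sets(skel)
  sets <- collection_sets(mcs)
  expect_true(all(lengths(sets) == 5))
  branches <- list(
    disorder = skel$gates$DISORDER_OR$inputs,
    mechanism = skel$gates$MECHANISM_OR$inputs,
    reason = c(skel$gates$PSYCH_REASON_OR$inputs,
               setdiff(skel$gates$PHYS_REASON_OR$inputs, "SIDE_EFFECT_OR"),
               skel$gates$SIDE_EFFECT_OR$inputs),
    assessment = skel$gates$ASSESSMENT_OR$inputs,
    intervention = skel$gates$INTERVENTION_OR$inputs)
  for (s in sets) {
    hits <- vapply(branches, function(b) sum(s %in% b), numeric(1))
    expect_identical(unname(hits), rep(1, 5))
  }
  expect_length(sets, prod(lengths(branches)))
  # spot-check minimality against the Boolean oracle
  for (s in sets[seq(1, length(sets), by = 97)])
    expect_true(is_minimal(skel, s))
})

test_that("skeleton top probability is interior and responds monotonically to a leaf", {
  skel <- load_seclusion_skeleton()
  r <- top_probability_exact(skel)
  expect_gt(r$exact, 0)
  expect_lt(r$exact, 1)
  p0 <- event_probability(skel$events$schizophrenia)
  up <- pin_event(skel, "schizophrenia", min(1, p0 + 0.1))
  dn <- pin_event(skel, "schizophrenia", max(0, p0 - 0.1))
  expect_gt(top_probability_exact(up)$exact, r$exact)
  expect_lt(top_probability_exact(dn)$exact, r$exact)
})

test_that("the deposited-model adapter honours its contracts", {
  err <- tryCatch(load_deposited_model(file.path(tempdir(), "nope.json")),
                  error = identity)
  expect_s3_class(err, "stpra_io_error")
  expect_match(conditionMessage(err), "10.5281/zenodo.7276312", fixed = TRUE)

  # a native-format file loads identically to parse_model
  f <- tempfile(fileext = ".json")
  writeLines(serialize_model(worked_example_tree(), "json"), f)
  tr <- load_deposited_model(f)
  expect_identical(names(tr$events), c("A", "B", "C"))
  expect_equal(top_probability_exact(tr)$exact, 0.109)

  g <- tempfile(fileext = ".dat")
  writeLines("PROPRIETARY-FTA-EXPORT v3 \x01\x02", g)
  err2 <- tryCatch(load_deposited_model(g), error = identity)
  expect_s3_class(err2, "stpra_adapter_error")
  expect_match(conditionMessage(err2), "adapter required")
  expect_match(conditionMessage(err2), "md5")
})

test_that("reports re-derive engine outputs and are byte-stable", {
  wk <- worked_example_tree()
  rep1 <- build_report(wk, top_k = 5, mc_samples = 1e4, seed = 3)
  rep2 <- build_report(wk, top_k = 5, mc_samples = 1e4, seed = 3)
  expect_identical(report_json(rep1), report_json(rep2))
  expect_equal(rep1$top_event$average$exact, 0.109)
  expect_identical(canon_sets(lapply(rep1$cut_sets$sets, `[[`, "events")),
                   c("A+C", "B"))

  skel <- load_seclusion_skeleton()
  rs <- build_report(skel)
  expect_identical(rs$provenance, "reconstruction — illustrative probabilities")
  expect_identical(rs$cut_sets$shown, 10L)
  expect_identical(rs$underdeveloped_events,
                   c("environmental_hazards_present", "psychiatric_comorbidity"))
  expect_equal(rs$top_event$average$exact,
               top_probability_exact(skel)$exact)
  f <- tempfile(fileext = ".json")
  write_report(rs, f)
  expect_identical(paste(readLines(f), collapse = "\n"), report_json(rs))
})
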