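mk_lit <- function(...) lapply(list(...), source_estimate,
                               provenance = "literature")

test_that("aggregation follows the literature-first low/average/high rule", {
  est <- aggregate_estimates(mk_lit(0.2, 0.3, 0.7))
  expect_equal(est$average, 0.4)
  expect_equal(est$low, 0.25)   # mean without the highest value
  expect_equal(est$high, 0.5)   # mean without the smallest value

  single <- aggregate_estimates(mk_lit(0.4))
  expect_equal(c(single$low, single$average, single$high), c(0.4, 0.4, 0.4))

  mixed <- aggregate_estimates(list(source_estimate(0.1, "literature"),
                                    source_estimate(0.9, "expert")))
  expect_equal(mixed$average, 0.1)  # expert shadowed by literature
  expect_equal(mixed$basis, "literature")
  expect_equal(mixed$shadowed, 0.9)

  expert_only <- aggregate_estimates(list(source_estimate(0.3, "expert")))
  expect_equal(expert_only$basis, "expert")
  expect_equal(expert_only$average, 0.3)

  expect_null(aggregate_estimates(list()))
  expect_error(aggregate_estimates(mk_lit(1.2)), class = "stpra_domain_error")

  # ties: remove exactly one instance of the extreme
  tied <- aggregate_estimates(mk_lit(0.5, 0.5, 0.1))
  expect_equal(tied$low, mean(c(0.5, 0.1)))
  expect_equal(tied$high, mean(c(0.5, 0.5)))
})

test_that("aggregated estimates always satisfy low <= average <= high", {
  for (s in 1:200) {
    set.seed(s)
    n <- sample(1:6, 1)
    src <- lapply(runif(n), source_estimate,
                  provenance = sample(c("literature", "expert"), 1))
    est <- aggregate_estimates(src)
    expect_lte(est$low, est$average)
    expect_lte(est$average, est$high)
    expect_true(est$low >= 0 && est$high <= 1)
  }
})

test_that("models round-trip exactly through JSON, YAML and the minimal tree parses", {
  txt <- '{"name":"m","top":"TOP",
           "gates":[{"id":"TOP","kind":"OR","inputs":["A"]}],
           "events":[{"id":"A","sources":[{"value":0.3,"provenance":"literature"}]}]}'
  tr <- parse_model(txt, "json")
  expect_length(tr$gates, 1)
  expect_length(tr$events, 1)
  expect_equal(tr$events$A$estimate$average, 0.3)

  tr2 <- worked_example_tree(0.018026)
  for (fmt in c("json", "yaml")) {
    back <- parse_model(serialize_model(tr2, fmt), fmt)
    expect_identical(back$top, tr2$top)
    expect_identical(lapply(back$gates, `[[`, "inputs"),
                     lapply(tr2$gates, `[[`, "inputs"))
    expect_identical(lapply(back$gates, `[[`, "kind"),
                     lapply(tr2$gates, `[[`, "kind"))
    # probabilities reparse to full precision
    expect_identical(back$events$A$estimate$average, 0.018026)
    expect_identical(back$events$A$sources[[1]]$value, 0.018026)
  }
})

test_that("round-trip holds for generated trees across all formats", {
  for (s in 1:25) {
    tr <- generate_model(small_config(s))
    for (fmt in c("json", "yaml")) {
      back <- parse_model(serialize_model(tr, fmt), fmt)
      expect_identical(lapply(back$gates, function(g) g[c("kind", "inputs")]),
                       lapply(tr$gates, function(g) g[c("kind", "inputs")]))
      expect_equal(leaf_probabilities(back), leaf_probabilities(tr))
      expect_identical(names(back$events), names(tr$events))
    }
    # Open-PSA is lossy for sources but preserves structure and the
    # average point estimate
    back <- parse_model(serialize_model(tr, "openpsa_xml"), "openpsa_xml")
    expect_identical(lapply(back$gates, function(g) g[c("kind", "inputs")]),
                     lapply(tr$gates, function(g) g[c("kind", "inputs")]))
    expect_equal(leaf_probabilities(back), leaf_probabilities(tr))
    expect_equal(vapply(back$events, `[[`, logical(1), "underdeveloped"),
                 vapply(tr$events, `[[`, logical(1), "underdeveloped"))
  }
})

test_that("parse errors name the offence", {
  expect_error(parse_model("{not json", "json"), class = "stpra_parse_error")
  dangling <- '{"name":"m","top":"TOP",
    "gates":[{"id":"TOP","kind":"OR","inputs":["X"]}],
    "events":[]}'
  expect_error(parse_model(dangling, "json"), "X",
               class = "stpra_structural_error")
  expect_error(parse_model("<opsa-mef/>", "openpsa_xml"),
               class = "stpra_parse_error")
})

test_that("serialization refuses invalid trees", {
  bad <- fault_tree("bad", "TOP",
                    gates = list(gate("TOP", "OR", character())),
                    events = list())
  expect_error(serialize_model(bad, "json"), class = "stpra_validation_error")
})

test_that("validation flags cycles, unreachable nodes and dangling refs deterministically", {
  cyc <- fault_tree("cyc", "G1",
                    gates = list(gate("G1", "OR", c("G2", "A")),
                                 gate("G2", "AND", c("G1", "A"))),
                    events = list(basic_event("A")))
  iss <- validate_tree(cyc)
  expect_true(any(iss$code == "cycle" & iss$severity == "error"))

  unr <- fault_tree("unr", "TOP",
                    gates = list(gate("TOP", "OR", c("A", "B"))),
                    events = list(basic_event("A"), basic_event("B"),
                                  basic_event("orphan")))
  iss <- validate_tree(unr)
  expect_true(any(iss$code == "unreachable" & iss$subject_id == "orphan"))
  expect_false(any(iss$severity == "error"))

  ok <- worked_example_tree()
  expect_identical(nrow(validate_tree(ok)), 0L)
  # idempotent and side-effect free
  expect_identical(validate_tree(unr), validate_tree(unr))

  dup <- fault_tree("dup", "TOP",
                    gates = list(gate("TOP", "OR", c("A", "A"))),
                    events = list(basic_event("A")))
  expect_true(any(validate_tree(dup)$code == "duplicate_input"))
})

test_that("pruning removes exactly the unestimated factors", {
  tr <- fault_tree("p", "TOP",
                   gates = list(gate("TOP", "OR", c("A", "B"))),
                   events = list(
                     basic_event("A", sources = mk_lit(0.2)),
                     basic_event("B")))
  out <- prune_unestimated(tr)
  expect_identical(out$removed, "B")
  expect_identical(names(out$tree$events), "A")
  expect_identical(out$tree$gates$TOP$inputs, "A")

  full <- worked_example_tree()
  out2 <- prune_unestimated(full)
  expect_identical(out2$removed, character())
  expect_identical(out2$tree$gates, full$gates)

  and_tr <- fault_tree("q", "TOP",
                       gates = list(gate("TOP", "AND", c("A", "B"))),
                       events = list(
                         basic_event("A", sources = mk_lit(0.2)),
                         basic_event("B")))
  expect_error(prune_unestimated(and_tr), "TOP",
               class = "stpra_exclusion_error")
})

test_that("exclusion semantics: OR deletion, AND forbid, AND neutralize", {
  tr <- fault_tree("x", "TOP",
                   gates = list(gate("TOP", "OR", c("A", "B"))),
                   events = list(basic_event("A", sources = mk_lit(0.1)),
                                 basic_event("B", sources = mk_lit(0.1))))
  out <- exclude_events(tr, "B")
  expect_identical(out$gates$TOP$inputs, "A")
  expect_false("B" %in% names(out$events))

  # cascading: emptied OR under an AND is forbidden
  casc <- fault_tree("c", "TOP",
                     gates = list(gate("TOP", "AND", c("G1", "G2")),
                                  gate("G1", "OR", "A"),
                                  gate("G2", "OR", c("B", "C"))),
                     events = list(basic_event("A", sources = mk_lit(0.3)),
                                   basic_event("B", sources = mk_lit(0.2)),
                                   basic_event("C", sources = mk_lit(0.2))))
  expect_error(exclude_events(casc, "A", "forbid"),
               class = "stpra_exclusion_error")

  # neutralize: an excluded AND conjunct becomes always-true
  and_tr <- fault_tree("n", "TOP",
                       gates = list(gate("TOP", "AND", c("A", "B"))),
                       events = list(basic_event("A", sources = mk_lit(0.3)),
                                     basic_event("B", sources = mk_lit(0.5))))
  neu <- exclude_events(and_tr, "B", "neutralize")
  expect_equal(top_probability_exact(neu)$exact, 0.3)

  expect_error(exclude_events(tr, c("A", "B")), "empty model",
               class = "stpra_exclusion_error")
  expect_error(exclude_events(tr, "nope"), class = "stpra_domain_error")
})

test_that("excluding an OR leaf never raises the exact top probability", {
  for (s in 1:20) {
    tr <- generate_model(small_config(s, repeat_rate = 0))
    base <- top_probability_exact(tr)$exact
    # pick an OR-gate leaf input that is legal to exclude
    for (g in tr$gates) {
      if (g$kind != "OR" || length(g$inputs) < 2) next
      leaf <- intersect(g$inputs, names(tr$events))
      if (length(leaf) == 0) next
      tr2 <- tryCatch(exclude_events(tr, leaf[1], "forbid"),
                      error = function(e) NULL)
      if (is.null(tr2)) next
      expect_lte(top_probability_exact(tr2)$exact, base + 1e-12)
      break
    }
  }
})
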