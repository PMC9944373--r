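lit1 <- function(p) list(source_estimate(p, "literature"))

test_that("importance measures on hand-checked trees", {
  and_tr <- fault_tree("and", "TOP",
                       gates = list(gate("TOP", "AND", c("A", "B"))),
                       events = list(basic_event("A", sources = lit1(0.3)),
                                     basic_event("B", sources = lit1(0.7))))
  imp <- importance_all(and_tr)
  # in a pure conjunction every failure requires both factors
  expect_equal(imp$criticality, c(1, 1))
  expect_equal(imp$fussell_vesely, c(1, 1))

  wk <- worked_example_tree()
  imp <- importance_all(wk)
  b <- imp[imp$id == "B", ]
  expect_equal(b$fussell_vesely, 0.1 / 0.109, tolerance = 1e-12)
  expect_equal(b$birnbaum, 0.99, tolerance = 1e-12)  # P(G1 or G2 fires via A,C complement)
  expect_equal(b$criticality, 0.99 * 0.1 / 0.109, tolerance = 1e-12)

  # an event in no minimal cut set is irrelevant
  irr <- fault_tree("irr", "TOP",
                    gates = list(gate("TOP", "OR", c("A", "G1")),
                                 gate("G1", "AND", c("A", "C"))),
                    events = list(basic_event("A", sources = lit1(0.2)),
                                  basic_event("C", sources = lit1(0.5))))
  ii <- importance_all(irr)
  cc <- ii[ii$id == "C", ]
  expect_equal(cc$birnbaum, 0)
  expect_equal(cc$criticality, 0)
  expect_equal(cc$fussell_vesely, 0)

  zero <- fault_tree("z", "TOP",
                     gates = list(gate("TOP", "OR", "A")),
                     events = list(basic_event("A", sources = lit1(0))))
  expect_error(importance_all(zero), class = "stpra_degenerate_error")
})

test_that("ranking is descending with lexicographic tie-break and handles empty input", {
  rec <- data.frame(id = c("schizophrenia", "seated_to_standing",
                           "getting_out_of_bed"),
                    probability = 0.1,
                    birnbaum = 0.1,
                    criticality = c(0.209765, 0.334611, 0.345884),
                    fussell_vesely = c(0.21, 0.34, 0.35),
                    stringsAsFactors = FALSE)
  rk <- rank_events(rec, "criticality")
  expect_identical(rk$id, c("getting_out_of_bed", "seated_to_standing",
                            "schizophrenia"))
  expect_identical(rk$criticality, c(0.345884, 0.334611, 0.209765))

  tie <- data.frame(id = c("b", "a"), probability = 0.1, birnbaum = 0.5,
                    criticality = c(0.5, 0.5), fussell_vesely = 0.5)
  expect_identical(rank_events(tie, "criticality")$id, c("a", "b"))
  empty <- rec[0, ]
  expect_identical(nrow(rank_events(empty, "criticality")), 0L)
})

test_that("bound analysis reproduces aggregation arithmetic and coherence", {
  tr <- fault_tree("b", "TOP",
                   gates = list(gate("TOP", "OR", "A")),
                   events = list(basic_event("A", sources = list(
                     source_estimate(0.2, "literature"),
                     source_estimate(0.3, "literature"),
                     source_estimate(0.7, "literature")))))
  tab <- bound_analysis(tr)
  expect_equal(tab$top_probability, c(0.25, 0.4, 0.5))
  expect_equal(tab$delta, c(-0.15, 0, 0.1))

  # degenerate: single-source leaves collapse all three rows
  single <- worked_example_tree()
  tabs <- bound_analysis(single)
  expect_equal(tabs$top_probability, rep(0.109, 3))

  for (s in 1:15) {
    tab <- bound_analysis(generate_model(small_config(s)))
    expect_true(all(diff(tab$top_probability) >= -1e-12))
  }
})

test_that("leave-out analysis reports deltas against the baseline", {
  tr <- fault_tree("lo", "TOP",
                   gates = list(gate("TOP", "OR", c("A", "B"))),
                   events = list(basic_event("A", sources = lit1(0.1)),
                                 basic_event("B", sources = lit1(0.1))))
  tab <- leave_out_analysis(tr, list(none = character(), drop_B = "B"))
  expect_equal(tab$top_probability[tab$scenario == "baseline"], 0.19)
  expect_equal(tab$delta[tab$scenario == "baseline"], 0)
  expect_equal(tab$delta[tab$scenario == "none"], 0)
  drop_b <- tab[tab$scenario == "drop_B", ]
  expect_equal(drop_b$top_probability, 0.1)
  expect_equal(drop_b$delta, -0.09)
  expect_error(leave_out_analysis(tr, list(all = c("A", "B"))),
               class = "stpra_exclusion_error")
})

test_that("Birnbaum matches the central finite difference of the structure polynomial", {
  h <- 1e-4
  for (s in 1:15) {
    tr <- generate_model(small_config(s))
    imp <- importance_all(tr)
    p <- leaf_probabilities(tr)
    e <- imp$id[(s %% nrow(imp)) + 1]
    if (p[[e]] < h || p[[e]] > 1 - h) next
    up <- p; up[[e]] <- p[[e]] + h
    dn <- p; dn[[e]] <- p[[e]] - h
    fd <- (stpra:::exact_prob(tr, up) - stpra:::exact_prob(tr, dn)) / (2 * h)
    expect_equal(imp$birnbaum[imp$id == e], fd, tolerance = 1e-6)
  }
})

test_that("importance invariants hold across the synthetic suite", {
  for (s in 1:25) {
    tr <- generate_model(small_config(s))
    imp <- importance_all(tr)
    # every failure is claimed by at least one risk factor
    expect_gte(sum(imp$fussell_vesely), 1 - 1e-12)
    expect_true(all(imp$criticality <= imp$fussell_vesely + 1e-12))
    expect_true(all(imp$birnbaum >= -1e-12))
    # measures survive a serialization round-trip
    back <- parse_model(serialize_model(tr, "json"), "json")
    imp2 <- importance_all(back)
    expect_equal(imp2$criticality, imp$criticality, tolerance = 1e-12)
    expect_equal(imp2$fussell_vesely, imp$fussell_vesely, tolerance = 1e-12)
  }
})
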