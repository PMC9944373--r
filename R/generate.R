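# Random coherent fault trees for property-based testing.
#
# Generation is top-down: a random gate skeleton is grown first (each new
# gate attaches under an existing one, so every gate is reachable from
# the top), then every basic event is attached to a gate — childless
# gates first, so no gate is left empty — and finally repeated events are
# introduced by giving a leaf a second parent with probability
# repeat_rate. Probabilities emulate elicited fall-risk-factor estimates:
# rare-to-moderate events, several sources per factor with mixed
# literature/expert provenance.

#' Configuration for the synthetic fault-tree generator
#'
#' The defaults mirror the shape of the published seclusion-falls tree:
#' 88 basic events over 24 gates of which 2 are AND gates, with 12
#' underdeveloped events, and leaf probabilities drawn uniformly from
#' \[0.01, 0.5\] (rare-to-moderate fall risk factors).
#'
#' @param n_events number of basic events (>= 1).
#' @param n_gates number of gates (>= 1).
#' @param and_fraction fraction of gates that are AND gates; the count is
#'   `round(and_fraction * n_gates)`.
#' @param max_fanin maximum number of inputs per gate (>= 2).
#' @param repeat_rate probability that a leaf feeds a second gate.
#' @param prob_dist either `list(kind = "uniform", lo, hi)` or
#'   `list(kind = "beta", a, b)`.
#' @param sources_per_event integer range `c(min, max)` of sources drawn
#'   per event.
#' @param expert_fraction probability a source has expert (vs literature)
#'   provenance.
#' @param underdeveloped_fraction fraction of events flagged
#'   underdeveloped.
#' @param seed integer RNG seed.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_events = 88, n_gates = 24,
                             and_fraction = 2 / 24, max_fanin = 8,
                             repeat_rate = 0.05,
                             prob_dist = list(kind = "uniform",
                                              lo = 0.01, hi = 0.5),
                             sources_per_event = c(1, 3),
                             expert_fraction = 0.3,
                             underdeveloped_fraction = 12 / 88,
                             seed = 1) {
  stopifnot(n_events >= 1, n_gates >= 1, max_fanin >= 2,
            and_fraction >= 0, and_fraction <= 1,
            repeat_rate >= 0, repeat_rate <= 1,
            expert_fraction >= 0, expert_fraction <= 1,
            length(sources_per_event) == 2,
            sources_per_event[1] >= 0,
            sources_per_event[2] >= sources_per_event[1])
  if (!prob_dist$kind %in% c("uniform", "beta"))
    stopf("prob_dist kind must be 'uniform' or 'beta'",
          class = "stpra_config_error")
  structure(list(n_events = as.integer(n_events),
                 n_gates = as.integer(n_gates),
                 and_fraction = and_fraction, max_fanin = as.integer(max_fanin),
                 repeat_rate = repeat_rate, prob_dist = prob_dist,
                 sources_per_event = as.integer(sources_per_event),
                 expert_fraction = expert_fraction,
                 underdeveloped_fraction = underdeveloped_fraction,
                 seed = as.integer(seed)),
            class = "generator_config")
}

pick1 <- function(x) x[sample.int(length(x), 1L)]

draw_values <- function(dist, n) {
  switch(dist$kind,
         uniform = stats::runif(n, dist$lo, dist$hi),
         beta = stats::rbeta(n, dist$a, dist$b))
}

# unseeded core used inside generate_tree's RNG scope
draw_sources <- function(config, event_count) {
  lapply(seq_len(event_count), function(i) {
    k <- pick1(config$sources_per_event[1]:config$sources_per_event[2])
    if (k == 0) return(list())
    lapply(seq_len(k), function(j) {
      prov <- if (stats::runif(1) < config$expert_fraction) "expert"
      else "literature"
      source_estimate(draw_values(config$prob_dist, 1), prov,
                      sprintf("synthetic-%s-%d", prov, j))
    })
  })
}

#' Draw multi-source probability estimates
#'
#' Generates per-event source lists with the configured count range,
#' provenance mix and value distribution. Reproducible from the config
#' seed.
#'
#' @param config a [generator_config()].
#' @param event_count number of events to draw sources for.
#' @return A list of length `event_count`; each element a list of
#'   [source_estimate()] objects.
#' @export
generate_sources <- function(config, event_count) {
  with_seed(config$seed, draw_sources(config, event_count))
}

#' Generate a random coherent fault tree
#'
#' @param config a [generator_config()].
#' @return A valid `fault_tree` with exactly `n_events` basic events and
#'   `n_gates` gates, every node reachable from the top, reproducible
#'   from the seed.
#' @examples
#' tr <- generate_tree(generator_config(n_events = 8, n_gates = 3, seed = 42))
#' validate_tree(tr)
#' @export
generate_tree <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  n_g <- config$n_gates
  n_e <- config$n_events
  # capacity check: gate-gate edges use n_g - 1 input slots
  if (n_g * config$max_fanin - (n_g - 1L) < n_e)
    stopf("infeasible config: %d events cannot fit %d gates with max_fanin %d",
          n_e, n_g, config$max_fanin, class = "stpra_config_error")

  with_seed(config$seed, {
    gids <- sprintf("G%d", seq_len(n_g))
    n_and <- round(config$and_fraction * n_g)
    kinds <- rep("OR", n_g)
    if (n_and > 0) kinds[sample.int(n_g, n_and)] <- "AND"
    inputs <- stats::setNames(rep(list(character()), n_g), gids)

    # gate skeleton: each gate after the first hangs under an earlier one
    for (i in seq_len(n_g)[-1]) {
      open <- gids[seq_len(i - 1)][lengths(inputs[seq_len(i - 1)]) <
                                     config$max_fanin]
      if (length(open) == 0)
        stopf("infeasible config: no gate can accept another input",
              class = "stpra_config_error")
      par <- pick1(open)
      inputs[[par]] <- c(inputs[[par]], gids[i])
    }

    # leaves: childless gates first so every gate ends non-empty
    eids <- sprintf("E%d", seq_len(n_e))
    childless <- gids[lengths(inputs) == 0]
    if (length(childless) > n_e)
      stopf("infeasible config: %d childless gates but only %d events",
            length(childless), n_e, class = "stpra_config_error")
    for (i in seq_along(childless))
      inputs[[childless[i]]] <- eids[i]
    if (n_e > length(childless)) {
      for (e in eids[(length(childless) + 1L):n_e]) {
        open <- gids[lengths(inputs) < config$max_fanin]
        if (length(open) == 0)
          stopf("infeasible config: gate capacity exhausted",
                class = "stpra_config_error")
        par <- pick1(open)
        inputs[[par]] <- c(inputs[[par]], e)
      }
    }

    # repeated events: give a leaf a second parent
    if (config$repeat_rate > 0) {
      for (e in eids) {
        if (stats::runif(1) < config$repeat_rate) {
          open <- gids[lengths(inputs) < config$max_fanin &
                         !vapply(inputs, function(x) e %in% x, logical(1))]
          if (length(open) > 0) {
            par <- pick1(open)
            inputs[[par]] <- c(inputs[[par]], e)
          }
        }
      }
    }

    srcs <- draw_sources(config, n_e)
    n_und <- round(config$underdeveloped_fraction * n_e)
    und <- rep(FALSE, n_e)
    if (n_und > 0) und[sample.int(n_e, n_und)] <- TRUE
    themes <- sample(THEMES, n_e, replace = TRUE)

    gates <- lapply(seq_len(n_g), function(i)
      gate(gids[i], kinds[i], inputs[[gids[i]]]))
    events <- lapply(seq_len(n_e), function(i)
      basic_event(eids[i], theme = themes[i], underdeveloped = und[i],
                  sources = srcs[[i]]))
    tr <- fault_tree(sprintf("synthetic-seed-%d", config$seed), gids[1],
                     gates, events,
                     metadata = list(generator = unclass(config)))
    assert_valid(tr, "generation")
    tr
  })
}

#' Generate a random estimated model in one call
#'
#' Convenience wrapper: [generate_tree()] with every event guaranteed at
#' least one source (so the model is fully estimated and analyzable).
#'
#' @param config a [generator_config()]; its `sources_per_event` minimum
#'   is raised to 1.
#' @return A valid, fully estimated `fault_tree`.
#' @export
generate_model <- function(config) {
  if (config$sources_per_event[1] < 1L)
    config$sources_per_event[1] <- 1L
  generate_tree(config)
}
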