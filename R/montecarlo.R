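#' Monte Carlo estimate of the top-event probability
#'
#' Simulation oracle for the Boolean-algebra result: draws `n`
#' independent assignments, each basic event occurring with its selected
#' point probability, and reports the fraction of draws in which the
#' structure function fires, with a normal-approximation 95% half-width
#' `1.96 * sqrt(p_hat (1 - p_hat) / n)`. Reproducible for a given seed;
#' the caller's random stream is left untouched.
#'
#' @param tree a valid `fault_tree` with every leaf estimated.
#' @param selector estimate selector.
#' @param n number of draws (default `1e5`).
#' @param seed integer RNG seed.
#' @param chunk_size draws evaluated per block, bounding memory.
#' @return list with `estimate`, `half_width_95`, `n`, `seed`, `selector`.
#' @examples
#' tr <- worked_example_tree()
#' monte_carlo_top(tr, n = 1e4, seed = 1)
#' @export
monte_carlo_top <- function(tree, selector = c("average", "low", "high"),
                            n = 1e5, seed = 1, chunk_size = 1e5) {
  selector <- match.arg(selector)
  stopifnot(n >= 1)
  assert_valid(tree, "simulation")
  p <- leaf_probabilities(tree, selector)
  ev <- names(p)
  if (anyNA(p))
    stopf("unestimated basic event(s): %s",
          paste(sort(ev[is.na(p)]), collapse = ", "),
          class = "stpra_unestimated_error")
  hits <- with_seed(seed, {
    total <- 0
    remaining <- n
    while (remaining > 0) {
      m <- min(chunk_size, remaining)
      M <- matrix(stats::runif(m * length(ev)), nrow = m) <
        matrix(p, nrow = m, ncol = length(ev), byrow = TRUE)
      colnames(M) <- ev
      total <- total + sum(eval_assignments(tree, M))
      remaining <- remaining - m
    }
    total
  })
  est <- hits / n
  list(estimate = est,
       half_width_95 = 1.96 * sqrt(est * (1 - est) / n),
       n = as.integer(n), seed = as.integer(seed), selector = selector)
}
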