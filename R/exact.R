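# Exact top-event probability.
#
# With independent basic events and no event on more than one root-to-leaf
# path, gate-by-gate bottom-up combination (product / complement-product)
# is exact. A repeated event makes sibling subtrees dependent; the engine
# then applies Shannon factoring: condition the repeated event on
# occurring / not occurring, solve both restricted problems, and mix with
# its probability. Conditioning pins the event to a constant, so the
# dependence it induced disappears; recursion continues until no
# effectively random repeated event remains.

MAX_FACTORING_EVENTS <- 25L

# exact probability of the subtree rooted at `root`, leaf probabilities
# given as a named vector `p` over (at least) the reachable events
exact_prob <- function(tree, p, root = tree$top) {
  if (root %in% names(tree$events)) return(unname(p[[root]]))
  ev <- reachable_events(tree, root)
  bad <- ev[!ev %in% names(p) | is.na(p[ev])]
  if (length(bad) > 0)
    stopf("unestimated basic event(s): %s (run prune_unestimated first)",
          paste(sort(bad), collapse = ", "), class = "stpra_unestimated_error")
  cnt <- path_counts(tree, root)
  repeated <- ev[cnt[ev] > 1]
  post <- gate_postorder(tree, root)

  bottom_up <- function(pv) {
    vals <- new.env(parent = emptyenv())
    for (e in ev) vals[[e]] <- pv[[e]]
    for (g in post) {
      gg <- tree$gates[[g]]
      kids <- vapply(gg$inputs, function(k) vals[[k]], numeric(1))
      vals[[g]] <- if (gg$kind == "AND") prod(kids) else 1 - prod(1 - kids)
    }
    vals[[root]]
  }

  recurse <- function(pv) {
    live <- repeated[pv[repeated] > 0 & pv[repeated] < 1]
    if (length(live) == 0) return(bottom_up(pv))
    # pivot on the most-shared event; ties broken by id for determinism
    ord <- order(-cnt[live], live)
    e <- live[ord[1]]
    pe <- pv[[e]]
    p1 <- pv; p1[[e]] <- 1
    p0 <- pv; p0[[e]] <- 0
    pe * recurse(p1) + (1 - pe) * recurse(p0)
  }

  if (length(repeated) > MAX_FACTORING_EVENTS)
    stopf("factoring over %d repeated events exceeds the supported limit (%d)",
          length(repeated), MAX_FACTORING_EVENTS,
          class = "stpra_resource_error")
  recurse(p[ev])
}

#' Exact and approximate top-event probability
#'
#' Computes the exact probability of the top event under independence of
#' basic events, using bottom-up gate combination on trees without
#' repeated events and Shannon factoring otherwise, together with the two
#' classical cut-set approximations: the rare-event sum
#' (sum of minimal-cut-set probabilities, which may exceed 1 and is then
#' reported unclamped with a flag) and the min-cut upper bound
#' MCUB = `1 - prod(1 - P(cut set))`. On coherent trees with independent
#' leaves, `exact <= mcub <= rare_event_sum`.
#'
#' @param tree a valid `fault_tree` with every leaf estimated.
#' @param selector which point estimate to use: `"low"`, `"average"` or
#'   `"high"`.
#' @param max_cut_order optional truncation order passed to
#'   [mocus_cut_sets()] for the approximations.
#' @return An object of class `top_event_result`: list with `exact`,
#'   `rare_event_sum`, `rare_event_exceeds_one`, `mcub`, `method`
#'   (`"bottom_up"` or `"factoring"`), `selector`, `n_cut_sets`.
#' @examples
#' tr <- worked_example_tree()
#' top_probability_exact(tr)  # exact 0.109
#' @export
top_probability_exact <- function(tree, selector = c("average", "low", "high"),
                                  max_cut_order = NULL) {
  selector <- match.arg(selector)
  assert_valid(tree, "probability analysis")
  p <- leaf_probabilities(tree, selector)
  cnt <- path_counts(tree)
  ev <- reachable_events(tree)
  method <- if (any(cnt[ev] > 1)) "factoring" else "bottom_up"
  exact <- exact_prob(tree, p)

  mcs <- mocus_cut_sets(tree, max_order = max_cut_order, selector = selector)
  csp <- vapply(mcs$cut_sets, `[[`, numeric(1), "probability")
  rare <- sum(csp)
  mcub <- 1 - prod(1 - csp)

  structure(list(exact = exact, rare_event_sum = rare,
                 rare_event_exceeds_one = rare > 1, mcub = mcub,
                 method = method, selector = selector,
                 n_cut_sets = length(csp)),
            class = "top_event_result")
}

#' @export
print.top_event_result <- function(x, ...) {
  cat(sprintf("top event probability (%s estimates, %s): %.6f\n",
              x$selector, x$method, x$exact))
  flag <- if (x$rare_event_exceeds_one) " [exceeds 1: approximation invalid]" else ""
  cat(sprintf("  rare-event sum %.6f%s | MCUB %.6f | %d minimal cut sets\n",
              x$rare_event_sum, flag, x$mcub, x$n_cut_sets))
  invisible(x)
}

#' Exact probability of every gate
#'
#' Each gate's probability is the exact top-event probability of the
#' subtree it roots (factoring applied per subtree where needed). The
#' mapping includes the top gate.
#'
#' @inheritParams top_probability_exact
#' @return named numeric vector, one entry per gate reachable from top
#'   (plus any unreachable gates evaluated on their own subtrees).
#' @export
all_gate_probabilities <- function(tree, selector = c("average", "low", "high")) {
  selector <- match.arg(selector)
  assert_valid(tree, "probability analysis")
  p <- leaf_probabilities(tree, selector)
  vapply(stats::setNames(names(tree$gates), names(tree$gates)),
         function(g) exact_prob(tree, p, root = g), numeric(1))
}
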