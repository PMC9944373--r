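# Importance measures for individual risk factors.
#
# Birnbaum:        B_e  = P_top(p_e = 1) - P_top(p_e = 0)
# Criticality:     C_e  = B_e * p_e / P_top
# Fussell-Vesely:  FV_e = P(union of minimal cut sets containing e) / P_top
#
# Criticality importance is the measure fall-risk reports label
# "criticality": the probability that the adverse event is due to the
# risk factor. Fussell-Vesely is co-reported because the two coincide
# only approximately on trees with repeated events.

# exact probability that at least one of `sets` (conjunctions of
# independent events) occurs: Shannon factoring on events shared between
# sets, with Boolean absorption, decomposition into event-disjoint
# components, and memoization on the canonical subproblem — this keeps
# the cross-product structures typical of AND-of-OR trees polynomial in
# practice rather than exponential in the pivot depth
sets_union_probability <- function(sets, p) {
  memo <- new.env(parent = emptyenv())

  components_of <- function(sets) {
    comp <- seq_along(sets)
    ev2set <- split(rep(seq_along(sets), lengths(sets)),
                    unlist(sets, use.names = FALSE))
    repeat {
      changed <- FALSE
      for (idx in ev2set) {
        m <- min(comp[idx])
        if (any(comp[idx] != m)) {
          comp[comp %in% comp[idx]] <- m
          changed <- TRUE
        }
      }
      if (!changed) break
    }
    split(sets, comp)
  }

  f <- function(sets) {
    if (length(sets) == 0) return(0)
    if (any(lengths(sets) == 0)) return(1)  # empty conjunction is certain
    sets <- minimize_cut_sets(sets)
    key <- paste(vapply(sets, paste, character(1), collapse = ","),
                 collapse = ";")
    use_memo <- nchar(key, type = "bytes") < 9000  # env-name length cap
    if (use_memo) {
      got <- memo[[key]]
      if (!is.null(got)) return(got)
    }
    memb <- unlist(sets, use.names = FALSE)
    tab <- table(memb)
    shared <- names(tab)[tab > 1]
    shared <- shared[p[shared] > 0 & p[shared] < 1]
    val <- if (length(shared) == 0) {
      1 - prod(1 - vapply(sets, function(s) prod(p[s]), numeric(1)))
    } else if (length(sets) > 1 &&
               length(comps <- components_of(sets)) > 1) {
      1 - prod(1 - vapply(comps, f, numeric(1)))
    } else {
      e <- shared[order(-as.numeric(tab[shared]), shared)][1]
      has_e <- vapply(sets, function(s) e %in% s, logical(1))
      # e occurs: drop e from its sets; e absent: those sets cannot fire
      sets1 <- c(lapply(sets[has_e], function(s) setdiff(s, e)),
                 sets[!has_e])
      p[[e]] * f(sets1) + (1 - p[[e]]) * f(sets[!has_e])
    }
    if (use_memo) memo[[key]] <- val
    val
  }
  f(lapply(sets, function(s) sort(as.character(s))))
}

#' Importance measures for every risk factor
#'
#' Computes Birnbaum, criticality and Fussell-Vesely importance for each
#' basic event, using the exact engine with the event's probability
#' pinned to 1 and to 0 (conditional top-event probabilities). All three
#' measures need `P_top > 0`.
#'
#' @param tree a valid `fault_tree`, every leaf estimated.
#' @param selector estimate selector.
#' @return A data frame of class `importance_records` with columns `id`,
#'   `probability`, `birnbaum`, `criticality`, `fussell_vesely`,
#'   `underdeveloped`, one row per basic event (in id order).
#' @examples
#' importance_all(worked_example_tree())
#' @export
importance_all <- function(tree, selector = c("average", "low", "high")) {
  selector <- match.arg(selector)
  assert_valid(tree, "importance analysis")
  p <- leaf_probabilities(tree, selector)
  ptop <- exact_prob(tree, p)
  if (ptop <= 0)
    stopf("degenerate model: top-event probability is 0",
          class = "stpra_degenerate_error")
  mcs <- mocus_cut_sets(tree, selector = selector)
  sets <- lapply(mcs$cut_sets, `[[`, "events")
  reach <- reachable_events(tree)

  ids <- sort(names(tree$events))
  rows <- lapply(ids, function(e) {
    if (!e %in% reach) {
      bi <- 0
    } else {
      p1 <- p; p1[[e]] <- 1
      p0 <- p; p0[[e]] <- 0
      bi <- exact_prob(tree, p1) - exact_prob(tree, p0)
    }
    crit <- bi * p[[e]] / ptop
    with_e <- sets[vapply(sets, function(s) e %in% s, logical(1))]
    fv <- sets_union_probability(with_e, p) / ptop
    data.frame(id = e, probability = unname(p[[e]]), birnbaum = bi,
               criticality = crit, fussell_vesely = fv,
               underdeveloped = isTRUE(tree$events[[e]]$underdeveloped),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "p_top") <- ptop
  attr(out, "selector") <- selector
  class(out) <- c("importance_records", "data.frame")
  out
}

#' Rank risk factors by an importance measure
#'
#' @param records output of [importance_all()].
#' @param measure `"criticality"`, `"fussell_vesely"` or `"birnbaum"`.
#' @return The records reordered: descending by the chosen measure, ties
#'   broken lexicographically by id. Stable across runs.
#' @export
rank_events <- function(records,
                        measure = c("criticality", "fussell_vesely", "birnbaum")) {
  measure <- match.arg(measure)
  if (nrow(records) == 0) return(records)
  out <- records[order(-records[[measure]], records$id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
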