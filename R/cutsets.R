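# Minimal cut sets ("critical paths") by top-down MOCUS expansion.
#
# The working state is a list of rows, each row a set of identifiers whose
# conjunction implies the top event. Expansion repeatedly rewrites the
# first gate found: an AND gate is replaced in-row by its inputs, an OR
# gate splits the row into one copy per input. Rows are kept as
# duplicate-free vectors ({B, B} collapses to {B} eagerly), and Boolean
# absorption (superset removal) runs after expansion.

#' Remove redundant cut sets
#'
#' Applies idempotence and absorption: duplicate sets collapse, and any
#' set containing another as a subset is dropped. Idempotent. Output is
#' ordered by set size, then lexicographically by the sorted member ids.
#'
#' @param raw list of character vectors (each a set of basic-event ids).
#' @return list of sorted character vectors, pairwise non-redundant.
#' @examples
#' minimize_cut_sets(list(c("B"), c("A", "B"), c("A", "C")))
#' @export
minimize_cut_sets <- function(raw) {
  if (length(raw) == 0) return(list())
  sets <- lapply(raw, function(s) sort(unique(as.character(s))))
  keys <- vapply(sets, paste, character(1), collapse = "\r")
  sets <- sets[!duplicated(keys)]
  sizes <- lengths(sets)
  ord <- order(sizes, vapply(sets, paste, character(1), collapse = "\r"))
  sets <- sets[ord]
  sizes <- sizes[ord]
  keep <- rep(TRUE, length(sets))
  for (i in seq_along(sets)) {
    if (!keep[i]) next
    # only strictly larger sets can absorb into sets[[i]]
    for (j in seq_along(sets)) {
      if (j <= i || !keep[j] || sizes[j] <= sizes[i]) next
      if (all(sets[[i]] %in% sets[[j]])) keep[j] <- FALSE
    }
  }
  sets[keep]
}

#' Enumerate minimal cut sets by MOCUS
#'
#' Returns the minimal cut sets of the structure function: the
#' inclusion-minimal combinations of risk factors whose joint occurrence
#' forces the top event (the model's critical paths). Expansion processes
#' gate inputs in declared order and the final ordering is fully
#' specified, so output is stable across runs.
#'
#' @param tree a valid `fault_tree`.
#' @param max_order optional integer: drop cut sets with more than this
#'   many events. Truncation is applied after minimization (truncating
#'   first could delete the absorber of a low-order set).
#' @param selector estimate selector used to fill per-set probabilities
#'   (product of member probabilities); sets containing unestimated
#'   events get `NA`.
#' @param cap resource guard: error if the working row count exceeds this
#'   (default `1e6`).
#' @return An object of class `cut_set_collection`: list with `cut_sets`
#'   (each a list with `events`, sorted ids, and `probability`),
#'   `truncation`, `complete` (`FALSE` iff truncation removed sets), and
#'   `selector`. Sets are sorted by descending probability, ties broken
#'   lexicographically by member ids.
#' @examples
#' mocus_cut_sets(worked_example_tree())  # {B}, {A, C}
#' @export
mocus_cut_sets <- function(tree, max_order = NULL,
                           selector = c("average", "low", "high"),
                           cap = 1e6) {
  selector <- match.arg(selector)
  assert_valid(tree, "cut set enumeration")
  rows <- list(tree$top)
  repeat {
    idx <- 0L
    for (i in seq_along(rows)) {
      if (any(rows[[i]] %in% names(tree$gates))) { idx <- i; break }
    }
    if (idx == 0L) break
    row <- rows[[idx]]
    g <- row[row %in% names(tree$gates)][1]
    gg <- tree$gates[[g]]
    rest <- row[row != g]
    if (gg$kind == "AND") {
      new_rows <- list(unique(c(rest, gg$inputs)))
    } else {
      new_rows <- lapply(gg$inputs, function(k) unique(c(rest, k)))
    }
    rows <- c(rows[seq_len(idx - 1L)], new_rows,
              if (idx < length(rows)) rows[(idx + 1L):length(rows)])
    if (length(rows) > cap)
      stopf("cut set expansion exceeded %g rows; re-run with a max_order truncation",
            cap, class = "stpra_resource_error")
  }

  sets <- minimize_cut_sets(rows)
  complete <- TRUE
  if (!is.null(max_order)) {
    before <- length(sets)
    sets <- sets[lengths(sets) <= max_order]
    complete <- length(sets) == before
  }

  p <- leaf_probabilities(tree, selector)
  probs <- vapply(sets, function(s) {
    v <- p[s]
    if (anyNA(v)) NA_real_ else prod(v)
  }, numeric(1))
  keys <- vapply(sets, paste, character(1), collapse = "\r")
  ord <- order(ifelse(is.na(probs), Inf, -probs), lengths(sets), keys)
  structure(list(
    cut_sets = Map(function(s, pr) list(events = s, probability = pr),
                   sets[ord], probs[ord]),
    truncation = max_order, complete = complete, selector = selector),
    class = "cut_set_collection")
}

#' @export
print.cut_set_collection <- function(x, max = 10, ...) {
  n <- length(x$cut_sets)
  cat(sprintf("%d minimal cut set(s)%s (%s estimates)\n", n,
              if (!x$complete) sprintf(" [truncated at order %d]", x$truncation) else "",
              x$selector))
  for (cs in utils::head(x$cut_sets, max)) {
    cat(sprintf("  {%s}  p = %s\n", paste(cs$events, collapse = ", "),
                if (is.na(cs$probability)) "NA" else
                  formatC(cs$probability, digits = 6, format = "f")))
  }
  if (n > max) cat(sprintf("  ... %d more\n", n - max))
  invisible(x)
}

#' Cut-set verification oracles
#'
#' `is_cut_set()` evaluates the structure function with exactly the named
#' events true and everything else false. `is_minimal()` additionally
#' requires that no proper subset is a cut set; because AND/OR structure
#' functions are monotone, it suffices to check the subsets obtained by
#' dropping one member.
#'
#' @param tree a valid `fault_tree`.
#' @param events character vector of basic-event ids.
#' @return logical scalar.
#' @export
is_cut_set <- function(tree, events) {
  events <- as.character(events)
  missing <- setdiff(events, names(tree$events))
  if (length(missing) > 0)
    stopf("unknown basic event(s): %s", paste(missing, collapse = ", "),
          class = "stpra_domain_error")
  a <- stats::setNames(names(tree$events) %in% events, names(tree$events))
  structure_eval(tree, a)
}

#' @rdname is_cut_set
#' @export
is_minimal <- function(tree, events) {
  events <- unique(as.character(events))
  if (!is_cut_set(tree, events)) return(FALSE)
  if (length(events) == 1) return(TRUE)
  for (i in seq_along(events)) {
    if (is_cut_set(tree, events[-i])) return(FALSE)
  }
  TRUE
}
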