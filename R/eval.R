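# Boolean evaluation of the structure function.

# DFS postorder of gates reachable from `root` (children before parents);
# its reverse is a topological order. The tree is assumed acyclic
# (validated upstream).
gate_postorder <- function(tree, root = tree$top) {
  visited <- new.env(parent = emptyenv())
  order <- character()
  visit <- function(id) {
    if (!is.null(visited[[id]])) return(invisible())
    visited[[id]] <- TRUE
    if (is_gate_id(tree, id)) {
      for (k in tree$gates[[id]]$inputs) visit(k)
      order <<- c(order, id)
    }
    invisible()
  }
  visit(root)
  order
}

# basic events reachable from `root`
reachable_events <- function(tree, root = tree$top) {
  gts <- gate_postorder(tree, root)
  if (length(gts) == 0) {
    return(if (root %in% names(tree$events)) root else character())
  }
  kids <- unlist(lapply(tree$gates[gts], `[[`, "inputs"), use.names = FALSE)
  unique(kids[kids %in% names(tree$events)])
}

# number of distinct root-to-node paths for every reachable node; a basic
# event with count > 1 is a repeated event (it also captures sharing
# introduced by multi-parent gates)
path_counts <- function(tree, root = tree$top) {
  topo <- rev(gate_postorder(tree, root))  # parents before children
  cnt <- new.env(parent = emptyenv())
  cnt[[root]] <- 1
  for (g in topo) {
    cg <- cnt[[g]] %||% 0
    for (k in tree$gates[[g]]$inputs) cnt[[k]] <- (cnt[[k]] %||% 0) + cg
  }
  ids <- ls(cnt)
  stats::setNames(vapply(ids, function(i) cnt[[i]], numeric(1)), ids)
}

#' Evaluate the structure function at one assignment
#'
#' Recursive Boolean evaluation: an AND gate is true iff all inputs are
#' true, an OR gate iff any input is true. The structure function of an
#' AND/OR tree is monotone (coherent): setting all events true yields
#' true, all false yields false.
#'
#' @param tree a valid `fault_tree`.
#' @param assignment named logical vector covering every basic event of
#'   the tree.
#' @return logical scalar: the state of the top event.
#' @examples
#' tr <- fault_tree("demo", "TOP",
#'   gates = list(gate("TOP", "AND", c("G1", "G2")),
#'                gate("G1", "OR", c("A", "B")),
#'                gate("G2", "OR", c("B", "C"))),
#'   events = list(basic_event("A"), basic_event("B"), basic_event("C")))
#' structure_eval(tr, c(A = FALSE, B = TRUE, C = FALSE))  # TRUE
#' @export
structure_eval <- function(tree, assignment) {
  missing <- setdiff(names(tree$events), names(assignment))
  if (length(missing) > 0)
    stopf("assignment is missing event(s): %s",
          paste(missing, collapse = ", "), class = "stpra_domain_error")
  m <- matrix(as.logical(assignment[names(tree$events)]), nrow = 1,
              dimnames = list(NULL, names(tree$events)))
  as.logical(eval_assignments(tree, m))
}

# vectorized evaluation: M is an n x n_events logical matrix with event
# ids as column names; returns a length-n logical vector of top states
eval_assignments <- function(tree, M, root = tree$top) {
  vals <- new.env(parent = emptyenv())
  for (e in colnames(M)) vals[[e]] <- M[, e]
  for (g in gate_postorder(tree, root)) {
    gg <- tree$gates[[g]]
    kids <- lapply(gg$inputs, function(k) vals[[k]])
    vals[[g]] <- if (gg$kind == "AND") Reduce(`&`, kids) else Reduce(`|`, kids)
  }
  vals[[root]]
}

#' Combine independent input probabilities through one gate
#'
#' AND gates multiply occurrence probabilities. OR gates add them and
#' subtract the overlap, which for independent inputs is exactly
#' `1 - prod(1 - p)` (the inclusion-exclusion closed form).
#'
#' @param kind `"AND"` or `"OR"`.
#' @param input_probs numeric vector of probabilities in \[0, 1\].
#' @return numeric probability.
#' @examples
#' gate_probability("AND", c(0.5, 0.5))      # 0.25
#' gate_probability("OR", c(0.5, 0.5))       # 0.75
#' gate_probability("OR", c(0.1, 0.2, 0.3))  # 0.496
#' @export
gate_probability <- function(kind = c("AND", "OR"), input_probs) {
  kind <- match.arg(toupper(kind), c("AND", "OR"))
  assert_probability(input_probs, "gate input probability")
  if (kind == "AND") prod(input_probs) else 1 - prod(1 - input_probs)
}
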