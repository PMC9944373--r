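#' Structurally validate a fault tree
#'
#' Checks the structural invariants of the model: unique identifiers, a
#' resolvable top gate, resolvable gate inputs with no duplicate input
#' within one gate, acyclicity, and reachability of every gate and event
#' from the top. Errors block analysis; warnings (single-input gates,
#' unreachable nodes, expert sources shadowed by literature sources) do
#' not. Issues are deterministic and ordered by subject identifier, so
#' two calls on the same tree return identical tables.
#'
#' @param tree a `fault_tree`.
#' @return A data frame of class `validation_issues` with columns
#'   `severity` (`"error"`/`"warning"`), `code`, `message`, `subject_id`.
#'   Zero rows for a fully clean tree.
#' @examples
#' tr <- fault_tree("ok", "TOP",
#'   gates = list(gate("TOP", "OR", c("A", "B"))),
#'   events = list(basic_event("A", sources = list(source_estimate(0.1, "literature"))),
#'                 basic_event("B", sources = list(source_estimate(0.2, "expert")))))
#' validate_tree(tr)
#' @export
validate_tree <- function(tree) {
  iss <- list()
  add <- function(severity, code, message, subject_id) {
    iss[[length(iss) + 1]] <<- data.frame(
      severity = severity, code = code, message = message,
      subject_id = subject_id, stringsAsFactors = FALSE)
  }

  gids <- names(tree$gates) %||% character()
  eids <- names(tree$events) %||% character()
  all_ids <- c(gids, eids)
  dup <- unique(all_ids[duplicated(all_ids)])
  for (d in sort(dup))
    add("error", "duplicate_id", sprintf("identifier '%s' declared more than once", d), d)

  if (length(tree$top) != 1 || !tree$top %in% gids) {
    add("error", "missing_top",
        sprintf("top gate '%s' is not a declared gate", tree$top), tree$top)
  }

  for (g in tree$gates) {
    if (length(g$inputs) == 0)
      add("error", "empty_gate", sprintf("gate '%s' has no inputs", g$id), g$id)
    else if (length(g$inputs) == 1)
      add("warning", "single_input",
          sprintf("gate '%s' has a single input", g$id), g$id)
    di <- unique(g$inputs[duplicated(g$inputs)])
    for (d in sort(di))
      add("error", "duplicate_input",
          sprintf("gate '%s' lists input '%s' more than once", g$id, d), g$id)
    for (ref in setdiff(g$inputs, all_ids))
      add("error", "dangling_ref",
          sprintf("gate '%s' references undeclared id '%s'", g$id, ref), g$id)
  }

  # cycle and reachability checks on the resolvable part of the edge list
  edges <- do.call(rbind, lapply(tree$gates, function(g) {
    kids <- intersect(g$inputs, all_ids)
    if (length(kids) == 0) NULL else cbind(g$id, kids)
  }))
  if (!is.null(edges) && nrow(edges) > 0) {
    gr <- igraph::graph_from_data_frame(
      data.frame(from = edges[, 1], to = edges[, 2]),
      directed = TRUE,
      vertices = data.frame(name = unique(c(all_ids, edges[, 1], edges[, 2]))))
    if (!igraph::is_dag(gr)) {
      cyc <- sort(unique(unlist(lapply(
        igraph::V(gr)$name,
        function(v) {
          if (v %in% gids &&
              v %in% names(igraph::subcomponent(gr, v, mode = "out")[-1])) v
          else NULL
        }))))
      for (v in cyc)
        add("error", "cycle", sprintf("gate '%s' lies on a cycle", v), v)
      if (length(cyc) == 0)
        add("error", "cycle", "the gate graph contains a cycle", tree$top)
    } else if (tree$top %in% gids) {
      reach <- names(igraph::subcomponent(gr, tree$top, mode = "out"))
      for (v in sort(setdiff(all_ids, reach)))
        add("warning", "unreachable",
            sprintf("'%s' is not reachable from the top gate", v), v)
    }
  }

  for (e in tree$events) {
    est <- e$estimate
    if (!is.null(est) && length(est$shadowed) > 0)
      add("warning", "shadowed_expert",
          sprintf("event '%s': expert value(s) %s shadowed by literature sources",
                  e$id, paste(format(est$shadowed), collapse = ", ")), e$id)
  }

  out <- if (length(iss) == 0) {
    data.frame(severity = character(), code = character(),
               message = character(), subject_id = character(),
               stringsAsFactors = FALSE)
  } else {
    do.call(rbind, iss)
  }
  out <- out[order(out$subject_id, out$severity, out$code), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("validation_issues", "data.frame")
  out
}

#' Does the tree pass structural validation?
#'
#' @param tree a `fault_tree`.
#' @return `TRUE` iff [validate_tree()] reports no error-severity issues.
#' @export
is_valid_tree <- function(tree) {
  iss <- validate_tree(tree)
  !any(iss$severity == "error")
}

# stop with a readable message when a tree fails validation
assert_valid <- function(tree, context = "analysis") {
  iss <- validate_tree(tree)
  err <- iss[iss$severity == "error", , drop = FALSE]
  if (nrow(err) > 0) {
    stopf("invalid fault tree (%s blocked): %s", context,
          paste(sprintf("[%s] %s", err$code, err$message), collapse = "; "),
          class = "stpra_validation_error")
  }
  invisible(tree)
}
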