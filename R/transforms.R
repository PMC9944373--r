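#' Exclude basic events from a model
#'
#' Removes the named risk factors from the tree, as in a leave-out
#' sensitivity scenario (e.g. re-running the analysis without elderly
#' patients as a risk factor). Each named leaf is deleted from every
#' parent gate's input list; an OR gate left with no inputs is itself
#' deleted from its parents, recursively. Deleting a conjunct changes the
#' meaning of an AND gate, so that case is governed by `and_policy`:
#'
#' * `"forbid"` (default): excluding a direct input of an AND gate — or
#'   cascading an emptied OR into one — is an error naming the gate and
#'   the event.
#' * `"neutralize"`: the leaf is kept with its probability fixed at 1 (a
#'   vacuous, always-true conjunct); an emptied OR feeding an AND is
#'   dropped from the AND's input list on the same always-true reading.
#'
#' @param tree a valid `fault_tree`.
#' @param ids character vector of basic-event identifiers to exclude.
#' @param and_policy `"forbid"` or `"neutralize"`.
#' @return The modified `fault_tree`.
#' @examples
#' tr <- fault_tree("demo", "TOP",
#'   gates = list(gate("TOP", "OR", c("A", "B"))),
#'   events = list(basic_event("A", sources = list(source_estimate(0.1, "literature"))),
#'                 basic_event("B", sources = list(source_estimate(0.1, "literature")))))
#' exclude_events(tr, "B")
#' @export
exclude_events <- function(tree, ids, and_policy = c("forbid", "neutralize")) {
  and_policy <- match.arg(and_policy)
  ids <- unique(as.character(ids))
  missing <- setdiff(ids, names(tree$events))
  if (length(missing) > 0)
    stopf("unknown basic event(s): %s", paste(missing, collapse = ", "),
          class = "stpra_domain_error")

  parents_of <- function(id) {
    keep <- vapply(tree$gates, function(g) id %in% g$inputs, logical(1))
    names(tree$gates)[keep]
  }

  for (id in ids) {
    par <- parents_of(id)
    and_par <- par[vapply(par, function(p) tree$gates[[p]]$kind == "AND",
                          logical(1))]
    if (length(and_par) > 0) {
      if (and_policy == "forbid")
        stopf("cannot exclude '%s': it is an input of AND gate '%s'",
              id, and_par[1], class = "stpra_exclusion_error")
      # neutralize: keep the leaf as an always-true conjunct of its AND
      # parents, but still drop it from any OR parents
      for (p in setdiff(par, and_par))
        tree$gates[[p]]$inputs <- setdiff(tree$gates[[p]]$inputs, id)
      tree <- pin_event(tree, id, 1)
    } else {
      for (p in par)
        tree$gates[[p]]$inputs <- setdiff(tree$gates[[p]]$inputs, id)
      tree$events[[id]] <- NULL
    }
  }

  # cascade: delete emptied OR gates from their parents
  repeat {
    empty <- names(tree$gates)[vapply(tree$gates, function(g)
      length(g$inputs) == 0, logical(1))]
    if (length(empty) == 0) break
    g0 <- empty[1]
    if (identical(g0, tree$top))
      stopf("empty model: exclusions eliminated the top gate '%s'", g0,
            class = "stpra_exclusion_error")
    kind0 <- tree$gates[[g0]]$kind
    par <- parents_of(g0)
    and_par <- par[vapply(par, function(p) tree$gates[[p]]$kind == "AND",
                          logical(1))]
    if (kind0 == "AND")
      stopf("exclusions emptied AND gate '%s'", g0,
            class = "stpra_exclusion_error")
    if (length(and_par) > 0 && and_policy == "forbid")
      stopf("cannot exclude: emptied gate '%s' is an input of AND gate '%s'",
            g0, and_par[1], class = "stpra_exclusion_error")
    for (p in par)
      tree$gates[[p]]$inputs <- setdiff(tree$gates[[p]]$inputs, g0)
    tree$gates[[g0]] <- NULL
  }
  assert_valid(tree, "exclusion result")
  tree
}

#' Remove risk factors without a probability estimate
#'
#' Risk factors to which no probability estimate could be assigned cannot
#' contribute to the quantitative analysis and are removed, using the
#' [exclude_events()] deletion semantics with the `forbid` AND policy
#' (removing a conjunct would silently change the logic, so it errors).
#'
#' @param tree a valid `fault_tree`.
#' @return A list with elements `tree` (the pruned model) and `removed`
#'   (sorted character vector of removed event ids).
#' @export
prune_unestimated <- function(tree) {
  assert_valid(tree, "pruning")
  ids <- unestimated_ids(tree)
  if (length(ids) == 0) return(list(tree = tree, removed = character()))
  list(tree = exclude_events(tree, ids, and_policy = "forbid"),
       removed = sort(ids))
}
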