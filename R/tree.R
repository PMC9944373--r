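#' Create a basic event (risk factor)
#'
#' A leaf of the fault tree: a risk factor with an occurrence probability
#' aggregated from one or more sources. Underdeveloped events are risk
#' factors retained in the model but flagged as insufficiently
#' characterized for further decomposition; they are analyzed like any
#' other leaf when they carry an estimate, and flagged in reports.
#'
#' @param id unique identifier (case-sensitive, exact match).
#' @param label human-readable name; defaults to `id`.
#' @param theme one of [THEMES].
#' @param underdeveloped logical flag.
#' @param sources list of [source_estimate()] objects; low/average/high
#'   point estimates are derived from them by [aggregate_estimates()].
#' @return A list of class `basic_event`.
#' @export
basic_event <- function(id, label = id, theme = "other",
                        underdeveloped = FALSE, sources = list()) {
  stopifnot(is.character(id), length(id) == 1, nzchar(id))
  if (!theme %in% THEMES) {
    stopf("unknown theme '%s' for event '%s'", theme, id,
          class = "stpra_domain_error")
  }
  structure(list(id = id, label = as.character(label), theme = theme,
                 underdeveloped = isTRUE(underdeveloped),
                 sources = sources,
                 estimate = aggregate_estimates(sources),
                 fixed_probability = NULL),
            class = "basic_event")
}

#' Create an AND/OR gate
#'
#' Gates are n-ary: an AND gate fires only when all of its inputs occur,
#' an OR gate when any input occurs. Inputs reference other gates or
#' basic events by identifier; an identifier may not be repeated within a
#' single gate's input list.
#'
#' @param id unique identifier.
#' @param kind `"AND"` or `"OR"`.
#' @param inputs character vector of child identifiers, in declared order.
#' @return A list of class `ft_gate`.
#' @export
gate <- function(id, kind = c("OR", "AND"), inputs = character()) {
  stopifnot(is.character(id), length(id) == 1, nzchar(id))
  kind <- match.arg(toupper(kind), c("OR", "AND"))
  structure(list(id = id, kind = kind, inputs = as.character(inputs)),
            class = "ft_gate")
}

#' Construct a fault tree
#'
#' A fault tree is a directed acyclic graph with a single top gate, AND/OR
#' gates, and basic-event leaves. A basic event may feed more than one
#' gate (a repeated event); the probability engine accounts for the
#' dependence this induces.
#'
#' @param name model name.
#' @param top identifier of the top gate.
#' @param gates list of [gate()] objects.
#' @param events list of [basic_event()] objects.
#' @param metadata free-form named list.
#' @return An object of class `fault_tree`.
#' @examples
#' tr <- fault_tree(
#'   name = "demo", top = "TOP",
#'   gates = list(gate("TOP", "AND", c("G1", "G2")),
#'                gate("G1", "OR", c("A", "B")),
#'                gate("G2", "OR", c("B", "C"))),
#'   events = list(basic_event("A", sources = list(source_estimate(0.1, "literature"))),
#'                 basic_event("B", sources = list(source_estimate(0.1, "literature"))),
#'                 basic_event("C", sources = list(source_estimate(0.1, "literature")))))
#' tr
#' @export
fault_tree <- function(name, top, gates, events, metadata = list()) {
  gates <- stats::setNames(gates, vapply(gates, `[[`, character(1), "id"))
  events <- stats::setNames(events, vapply(events, `[[`, character(1), "id"))
  structure(list(name = as.character(name), top = as.character(top),
                 gates = gates, events = events, metadata = metadata),
            class = "fault_tree")
}

#' @export
print.fault_tree <- function(x, ...) {
  n_and <- sum(vapply(x$gates, function(g) g$kind == "AND", logical(1)))
  n_und <- sum(vapply(x$events, function(e) isTRUE(e$underdeveloped), logical(1)))
  n_unest <- sum(vapply(x$events, function(e) is.null(e$estimate) &&
                          is.null(e$fixed_probability), logical(1)))
  cat(sprintf("fault tree '%s': top gate '%s'\n", x$name, x$top))
  cat(sprintf("  %d gates (%d AND, %d OR), %d basic events (%d underdeveloped, %d unestimated)\n",
              length(x$gates), n_and, length(x$gates) - n_and,
              length(x$events), n_und, n_unest))
  if (isTRUE(x$metadata$illustrative))
    cat("  probabilities flagged illustrative\n")
  invisible(x)
}

event_ids <- function(tree) names(tree$events)
gate_ids <- function(tree) names(tree$gates)
is_gate_id <- function(tree, id) id %in% names(tree$gates)

#' Selected point probability of a basic event
#'
#' Returns the event's probability under the given selector (`low`,
#' `average`, `high`), honouring a fixed override (used when an excluded
#' AND-conjunct is neutralized or an event is pinned for importance
#' calculations). `NA` for unestimated events.
#'
#' @param event a `basic_event`.
#' @param selector `"low"`, `"average"` or `"high"`.
#' @return numeric probability or `NA_real_`.
#' @export
event_probability <- function(event, selector = c("average", "low", "high")) {
  selector <- match.arg(selector)
  if (!is.null(event$fixed_probability)) return(event$fixed_probability)
  if (is.null(event$estimate)) return(NA_real_)
  event$estimate[[selector]]
}

#' Vector of leaf probabilities under a selector
#'
#' @param tree a `fault_tree`.
#' @param selector estimate selector.
#' @return named numeric vector over all basic events (`NA` where
#'   unestimated).
#' @export
leaf_probabilities <- function(tree, selector = c("average", "low", "high")) {
  selector <- match.arg(selector)
  vapply(tree$events, event_probability, numeric(1), selector = selector)
}

# ids of events with neither an aggregated estimate nor a fixed override
unestimated_ids <- function(tree) {
  ids <- names(tree$events)
  ids[vapply(tree$events, function(e)
    is.null(e$estimate) && is.null(e$fixed_probability), logical(1))]
}

#' Pin a basic event to a fixed probability
#'
#' Overrides the event's aggregated estimate with a constant for every
#' selector. Used internally for Birnbaum pinning (0/1) and by
#' [exclude_events()] under the neutralize policy.
#'
#' @param tree a `fault_tree`.
#' @param id basic-event identifier.
#' @param p probability in \[0, 1\], or `NULL` to remove the override.
#' @return The modified tree.
#' @export
pin_event <- function(tree, id, p) {
  if (!id %in% names(tree$events))
    stopf("unknown basic event '%s'", id, class = "stpra_domain_error")
  if (!is.null(p)) assert_probability(p, sprintf("pinned probability for '%s'", id))
  tree$events[[id]]$fixed_probability <- p
  tree
}

#' Stable content hash of a model
#'
#' MD5 of the canonical JSON serialization; identifies exactly which model
#' (structure and estimates) produced a report.
#'
#' @param tree a valid `fault_tree`.
#' @return hex string.
#' @export
model_hash <- function(tree) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  writeLines(serialize_model(tree, "json"), tf)
  unname(tools::md5sum(tf))
}
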