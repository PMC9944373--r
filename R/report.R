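#' Assemble a full analysis report
#'
#' Runs the whole pipeline on a model — top-event probabilities (exact,
#' rare-event sum, MCUB) under all three estimate selectors, the top-k
#' most probable minimal cut sets, the importance ranking, the
#' low/average/high sensitivity table, and the underdeveloped-event
#' listing — and bundles the results with the model's name, content hash
#' and provenance note. Every number is re-derived from a fresh engine
#' run; the report caches nothing. Deterministic given the model and
#' options.
#'
#' @param tree a valid `fault_tree`, every leaf estimated.
#' @param selector selector used for cut sets and importance (the
#'   sensitivity table always covers all three).
#' @param top_k number of minimal cut sets to include (default 10, the
#'   "most critical" sets; `Inf` for all).
#' @param rank_by importance measure used to order the ranking.
#' @param mc_samples if > 0, also run the Monte Carlo oracle with this
#'   many draws.
#' @param seed seed for the Monte Carlo oracle.
#' @return An object of class `analysis_report` (a nested list; see
#'   [report_json()] and the print method).
#' @examples
#' rep <- build_report(worked_example_tree(), top_k = 5)
#' rep
#' @export
build_report <- function(tree, selector = c("average", "low", "high"),
                         top_k = 10, rank_by = "criticality",
                         mc_samples = 0, seed = 1) {
  selector <- match.arg(selector)
  assert_valid(tree, "reporting")
  bad <- unestimated_ids(tree)
  if (length(bad) > 0)
    stopf("unestimated basic event(s): %s (run prune_unestimated first)",
          paste(sort(bad), collapse = ", "), class = "stpra_unestimated_error")

  top <- lapply(stats::setNames(nm = c("low", "average", "high")),
                function(s) {
                  r <- top_probability_exact(tree, s)
                  list(exact = r$exact, rare_event_sum = r$rare_event_sum,
                       rare_event_exceeds_one = r$rare_event_exceeds_one,
                       mcub = r$mcub, method = r$method)
                })
  mcs <- mocus_cut_sets(tree, selector = selector)
  shown <- utils::head(mcs$cut_sets, top_k)
  imp <- rank_events(importance_all(tree, selector), rank_by)
  und <- sort(names(tree$events)[vapply(tree$events, function(e)
    isTRUE(e$underdeveloped), logical(1))])
  prov <- tree$metadata$provenance %||%
    if (isTRUE(tree$metadata$illustrative))
      "reconstruction — illustrative probabilities" else "user-supplied model"

  rep <- list(
    model = list(name = tree$name, hash = model_hash(tree),
                 n_events = length(tree$events), n_gates = length(tree$gates)),
    provenance = prov,
    selector = selector,
    top_event = top,
    cut_sets = list(total = length(mcs$cut_sets), shown = length(shown),
                    sets = lapply(shown, function(cs)
                      list(events = cs$events, probability = cs$probability))),
    importance = list(measure = rank_by,
                      rows = lapply(seq_len(nrow(imp)), function(i)
                        as.list(imp[i, , drop = FALSE]))),
    sensitivity_bounds = as.list(bound_analysis(tree)),
    underdeveloped_events = und)
  if (mc_samples > 0)
    rep$monte_carlo <- monte_carlo_top(tree, selector, n = mc_samples,
                                       seed = seed)
  class(rep) <- "analysis_report"
  rep
}

#' Serialize a report to JSON
#'
#' @param report an `analysis_report`.
#' @return A single JSON string; byte-identical for identical inputs.
#' @export
report_json <- function(report) {
  as.character(jsonlite::toJSON(unclass(report), auto_unbox = TRUE,
                                digits = NA, null = "null", pretty = TRUE))
}

#' Write a report to disk
#'
#' @param report an `analysis_report`.
#' @param path output path; `.json` gets [report_json()], anything else
#'   the human-readable text rendering.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  if (tolower(tools::file_ext(path)) == "json") {
    writeLines(report_json(report), path)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    sink(con); on.exit(sink(), add = TRUE, after = FALSE)
    print(report)
  }
  invisible(path)
}

#' @export
print.analysis_report <- function(x, ...) {
  cat(sprintf("analysis report: model '%s' (hash %s)\n",
              x$model$name, substr(x$model$hash, 1, 12)))
  cat(sprintf("  provenance: %s\n", x$provenance))
  cat(sprintf("  %d basic events, %d gates\n",
              x$model$n_events, x$model$n_gates))
  for (s in c("low", "average", "high")) {
    te <- x$top_event[[s]]
    cat(sprintf("  top event [%s]: exact %.6f | rare-event %.6f%s | MCUB %.6f (%s)\n",
                s, te$exact, te$rare_event_sum,
                if (isTRUE(te$rare_event_exceeds_one)) " (>1)" else "",
                te$mcub, te$method))
  }
  cat(sprintf("  minimal cut sets (%s): %d total, top %d:\n",
              x$selector, x$cut_sets$total, x$cut_sets$shown))
  for (cs in x$cut_sets$sets)
    cat(sprintf("    {%s}  p = %.6f\n",
                paste(cs$events, collapse = ", "), cs$probability))
  cat(sprintf("  importance (by %s), top 10:\n", x$importance$measure))
  for (r in utils::head(x$importance$rows, 10))
    cat(sprintf("    %-28s p=%.4f  birnbaum=%.6f  criticality=%.6f  FV=%.6f%s\n",
                r$id, r$probability, r$birnbaum, r$criticality,
                r$fussell_vesely,
                if (isTRUE(r$underdeveloped)) "  [underdeveloped]" else ""))
  if (length(x$underdeveloped_events) > 0)
    cat(sprintf("  underdeveloped events: %s\n",
                paste(x$underdeveloped_events, collapse = ", ")))
  if (!is.null(x$monte_carlo))
    cat(sprintf("  Monte Carlo (n=%d, seed=%d): %.6f +/- %.6f\n",
                x$monte_carlo$n, x$monte_carlo$seed,
                x$monte_carlo$estimate, x$monte_carlo$half_width_95))
  invisible(x)
}
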