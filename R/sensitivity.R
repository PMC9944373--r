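# Sensitivity analyses: low/average/high estimate bounds and leave-out
# scenarios (re-running the model without selected risk factors).

new_sensitivity_table <- function(rows, baseline) {
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "baseline") <- baseline
  class(out) <- c("sensitivity_table", "data.frame")
  out
}

#' Low/average/high bound analysis
#'
#' Recomputes the exact top-event probability under the three aggregated
#' point estimates. The low estimate of each risk factor is its source
#' average with the largest reported value dropped, the high estimate
#' with the smallest dropped, so on a coherent tree the three top-event
#' probabilities are monotone non-decreasing. The average row is the
#' baseline (delta 0).
#'
#' @param tree a valid `fault_tree`, every leaf estimated.
#' @return A data frame of class `sensitivity_table` with columns
#'   `scenario`, `selector`, `excluded`, `top_probability`, `delta`.
#' @export
bound_analysis <- function(tree) {
  assert_valid(tree, "sensitivity analysis")
  vals <- vapply(c("low", "average", "high"),
                 function(s) exact_prob(tree, leaf_probabilities(tree, s)),
                 numeric(1))
  rows <- lapply(c("low", "average", "high"), function(s)
    data.frame(scenario = paste(s, "estimates"), selector = s, excluded = "",
               top_probability = vals[[s]],
               delta = vals[[s]] - vals[["average"]],
               stringsAsFactors = FALSE))
  new_sensitivity_table(rows, baseline = "average estimates")
}

#' Leave-out sensitivity analysis
#'
#' Re-runs the exact analysis with each named set of risk factors
#' excluded from the model (e.g. with and without elderly patients and
#' history of medical problems as risk factors), reporting the new top
#' probability and its absolute difference from the unmodified baseline.
#' Exclusions use [exclude_events()] with the `forbid` AND policy.
#'
#' @param tree a valid `fault_tree`, every leaf estimated.
#' @param exclusion_sets named list; each element a character vector of
#'   basic-event ids, the name labelling the scenario.
#' @param selector estimate selector.
#' @return A data frame of class `sensitivity_table`; first row is the
#'   baseline (nothing excluded, delta 0).
#' @examples
#' tr <- worked_example_tree()
#' leave_out_analysis(tr, list(`without A` = "A"))
#' @export
leave_out_analysis <- function(tree, exclusion_sets,
                               selector = c("average", "low", "high")) {
  selector <- match.arg(selector)
  assert_valid(tree, "sensitivity analysis")
  base <- exact_prob(tree, leaf_probabilities(tree, selector))
  rows <- list(data.frame(scenario = "baseline", selector = selector,
                          excluded = "", top_probability = base, delta = 0,
                          stringsAsFactors = FALSE))
  labels <- names(exclusion_sets) %||% rep("", length(exclusion_sets))
  for (i in seq_along(exclusion_sets)) {
    ids <- exclusion_sets[[i]]
    lab <- if (nzchar(labels[i])) labels[i] else
      paste("without", paste(ids, collapse = ", "))
    tr2 <- exclude_events(tree, ids, and_policy = "forbid")
    v <- exact_prob(tr2, leaf_probabilities(tr2, selector))
    rows[[length(rows) + 1]] <- data.frame(
      scenario = lab, selector = selector,
      excluded = paste(sort(ids), collapse = ","),
      top_probability = v, delta = v - base, stringsAsFactors = FALSE)
  }
  new_sensitivity_table(rows, baseline = "baseline")
}
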