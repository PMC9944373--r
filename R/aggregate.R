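#' Risk-factor themes
#'
#' The themes into which fall risk factors are classified during model
#' building: patient behavior, the physical condition of the patient,
#' influence of medication, the seclusion environment, fall prevention,
#' and a catch-all.
#'
#' @export
THEMES <- c("patient_behavior", "physical_condition", "medication",
            "environment", "prevention", "other")

#' Create a single probability source
#'
#' One elicited occurrence probability for a risk factor, with its
#' provenance: `"literature"` for values extracted from published studies,
#' `"expert"` for values elicited from practitioner panels.
#'
#' @param value probability in \[0, 1\].
#' @param provenance `"literature"` or `"expert"`.
#' @param citation_label free-text label identifying the source.
#' @return A list of class `source_estimate`.
#' @examples
#' source_estimate(0.12, "literature", "Smith 2019")
#' @export
source_estimate <- function(value, provenance = c("literature", "expert"),
                            citation_label = "") {
  assert_probability(value, "source value")
  provenance <- match.arg(provenance)
  structure(list(value = as.numeric(value), provenance = provenance,
                 citation_label = as.character(citation_label)),
            class = "source_estimate")
}

#' Aggregate per-source probabilities into low/average/high estimates
#'
#' Implements the elicitation rule used to assign risk-factor
#' probabilities. Literature values take priority: if any literature
#' source exists, expert sources are ignored (literature provides the more
#' reliable estimate). From the retained values `V`:
#' `average = mean(V)`; the low estimate is the mean with one instance of
#' the largest value removed; the high estimate is the mean with one
#' instance of the smallest value removed. A single retained value yields
#' `low = average = high`. No sources at all yields `NULL`: the risk
#' factor is unestimated and is a candidate for [prune_unestimated()].
#'
#' @param sources list of [source_estimate()] objects (may be empty).
#' @return `NULL` if no sources, otherwise a list of class
#'   `probability_estimate` with elements `low`, `average`, `high`,
#'   `n_sources` (number of values retained), `basis` (`"literature"` or
#'   `"expert"`), and `shadowed` (expert values ignored because literature
#'   values were present).
#' @examples
#' aggregate_estimates(list(
#'   source_estimate(0.2, "literature"),
#'   source_estimate(0.3, "literature"),
#'   source_estimate(0.7, "literature")
#' ))  # average 0.4, low 0.25, high 0.5
#' @export
aggregate_estimates <- function(sources) {
  if (length(sources) == 0) return(NULL)
  vals <- vapply(sources, function(s) as.numeric(s$value), numeric(1))
  assert_probability(vals, "source value")
  prov <- vapply(sources, function(s) as.character(s$provenance), character(1))
  if (!all(prov %in% c("literature", "expert"))) {
    stopf("unknown provenance: %s",
          paste(setdiff(prov, c("literature", "expert")), collapse = ", "),
          class = "stpra_domain_error")
  }
  lit <- vals[prov == "literature"]
  if (length(lit) > 0) {
    v <- lit
    basis <- "literature"
    shadowed <- vals[prov == "expert"]
  } else {
    v <- vals[prov == "expert"]
    basis <- "expert"
    shadowed <- numeric(0)
  }
  if (length(v) == 1) {
    low <- avg <- high <- v
  } else {
    avg <- mean(v)
    # remove exactly one instance of the extreme value, even under ties
    low <- mean(v[-which.max(v)])
    high <- mean(v[-which.min(v)])
  }
  structure(list(low = low, average = avg, high = high,
                 n_sources = length(v), basis = basis, shadowed = shadowed),
            class = "probability_estimate")
}

#' @export
print.probability_estimate <- function(x, ...) {
  cat(sprintf("probability estimate (%s, n=%d): low %.6f / average %.6f / high %.6f\n",
              x$basis, x$n_sources, x$low, x$average, x$high))
  invisible(x)
}
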