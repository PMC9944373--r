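# The packaged seclusion-falls model.
#
# The reconstruction ships the critical-path architecture of the
# published model — a fall in seclusion requires a psychiatric disorder,
# a mechanism of fall, a reason for the fall (psychological or physical,
# including medication side effects), and the failure of fall prevention,
# itself the conjunction of a risk-assessment failure and a
# prevention-intervention failure. It does NOT claim the full 88-factor /
# 22-OR-gate topology, which is not printed in the paper; the leaf
# probabilities shipped alongside are synthetic, illustrative values and
# are flagged as such in the model metadata and every report.

SECLUSION_DOI <- "doi.10.5281/zenodo.7276312"

#' Load the packaged seclusion-falls fault tree
#'
#' Reads the reconstructed skeleton (structure) from the package's
#' extdata and, optionally, overlays the synthetic illustrative
#' probability sources kept in a separate file so that structure and
#' numbers are independently versioned. The returned model carries
#' `metadata$illustrative = TRUE` and a provenance note; it has exactly
#' two AND gates (the top conjunction and the prevention-failure
#' conjunction), and every minimal cut set has order 5 — one disorder,
#' one mechanism, one reason, one assessment failure, one intervention
#' failure.
#'
#' @param with_probabilities overlay the illustrative probability
#'   sources (default `TRUE`); `FALSE` returns the bare structure with
#'   every leaf unestimated.
#' @return A valid `fault_tree`.
#' @examples
#' skel <- load_seclusion_skeleton()
#' skel
#' @export
load_seclusion_skeleton <- function(with_probabilities = TRUE) {
  struct_path <- system.file("extdata", "seclusion_skeleton.json",
                             package = "stpra", mustWork = TRUE)
  tree <- read_model(struct_path, "json")
  if (with_probabilities) {
    ov_path <- system.file("extdata", "seclusion_probabilities_synthetic.json",
                           package = "stpra", mustWork = TRUE)
    overlay <- jsonlite::fromJSON(ov_path, simplifyVector = FALSE)
    for (id in names(overlay)) {
      if (!id %in% names(tree$events))
        stopf("probability overlay names unknown event '%s'", id,
              class = "stpra_structural_error")
      src <- lapply(overlay[[id]], function(s)
        source_estimate(s$value, s$provenance, s$citation_label %||% ""))
      tree$events[[id]]$sources <- src
      tree$events[[id]]$estimate <- aggregate_estimates(src)
    }
  }
  tree$metadata$illustrative <- TRUE
  tree$metadata$provenance <-
    "reconstruction — illustrative probabilities"
  tree
}

#' Load a deposited fault-tree model from disk
#'
#' Adapter entry point for the study's deposited data (Zenodo record
#' `doi.10.5281/zenodo.7276312`, to be downloaded by the user). Files in
#' the native JSON/YAML or Open-PSA XML formats load directly via
#' [parse_model()]; any other schema raises an "adapter required" error
#' carrying a fingerprint (size, MD5, leading bytes) of the file so an
#' adapter can be written against the actual deposit.
#'
#' @param path path to the downloaded file.
#' @return A `fault_tree` when the file is in a supported format.
#' @export
load_deposited_model <- function(path) {
  if (!file.exists(path))
    stopf(paste0("deposited model not found at '%s'; download the Zenodo ",
                 "record (%s) and pass its local path"), path, SECLUSION_DOI,
          class = "stpra_io_error")
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  for (fmt in c("json", "yaml", "openpsa_xml")) {
    tr <- tryCatch(parse_model(txt, fmt), error = function(e) NULL)
    if (!is.null(tr)) return(tr)
  }
  stopf(paste0("adapter required: '%s' is not in a recognized model format ",
               "(size %d bytes, md5 %s, starts \"%s\")"),
        path, file.info(path)$size, unname(tools::md5sum(path)),
        substr(gsub("\\s+", " ", txt), 1, 40),
        class = "stpra_adapter_error")
}
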