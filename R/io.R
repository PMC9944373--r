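# Model serialization.
#
# Native dialect (JSON, with YAML as a 1:1 alternate surface):
#   { "name": ..., "top": ...,
#     "gates":  [ {"id", "kind", "inputs": [...]}, ... ],
#     "events": [ {"id", "label", "theme", "underdeveloped",
#                  "sources": [{"value", "provenance", "citation_label"}]},
#                 ... ],
#     "metadata": {...} }
# Derived low/average/high estimates are recomputed on load, never trusted
# from the file: the aggregation rule has a single source of truth.

tree_to_plain <- function(tree) {
  list(
    name = tree$name,
    top = tree$top,
    gates = unname(lapply(tree$gates, function(g)
      list(id = g$id, kind = g$kind, inputs = as.list(g$inputs)))),
    events = unname(lapply(tree$events, function(e)
      list(id = e$id, label = e$label, theme = e$theme,
           underdeveloped = e$underdeveloped,
           sources = unname(lapply(e$sources, function(s)
             list(value = s$value, provenance = s$provenance,
                  citation_label = s$citation_label)))))),
    metadata = tree$metadata
  )
}

plain_to_tree <- function(x) {
  for (field in c("top", "gates", "events")) {
    if (is.null(x[[field]]))
      stopf("model is missing required field '%s'", field,
            class = "stpra_parse_error")
  }
  gates <- lapply(x$gates, function(g) {
    if (is.null(g$id) || is.null(g$kind))
      stopf("gate entry missing 'id' or 'kind'", class = "stpra_parse_error")
    gate(g$id, g$kind, unlist(g$inputs, use.names = FALSE) %||% character())
  })
  events <- lapply(x$events, function(e) {
    if (is.null(e$id))
      stopf("event entry missing 'id'", class = "stpra_parse_error")
    src <- lapply(e$sources %||% list(), function(s)
      source_estimate(s$value, s$provenance %||% "literature",
                      s$citation_label %||% ""))
    basic_event(e$id, label = e$label %||% e$id,
                theme = e$theme %||% "other",
                underdeveloped = isTRUE(e$underdeveloped),
                sources = src)
  })
  tr <- fault_tree(x$name %||% "", x$top, gates, events,
                   metadata = x$metadata %||% list())
  iss <- validate_tree(tr)
  dang <- iss[iss$code %in% c("dangling_ref", "missing_top"), , drop = FALSE]
  if (nrow(dang) > 0) {
    stopf("unresolved identifier(s): %s",
          paste(dang$message, collapse = "; "),
          class = "stpra_structural_error")
  }
  tr
}

#' Parse a fault-tree model from text
#'
#' @param text a single string holding the whole document (or a character
#'   vector of lines, which is collapsed).
#' @param format `"json"`, `"yaml"` or `"openpsa_xml"`.
#' @return A `fault_tree`. Derived low/average/high estimates are
#'   recomputed from the serialized sources.
#' @seealso [serialize_model()], [read_model()]
#' @export
parse_model <- function(text, format = c("json", "yaml", "openpsa_xml")) {
  format <- match.arg(format)
  text <- paste(text, collapse = "\n")
  switch(format,
    json = {
      x <- tryCatch(jsonlite::fromJSON(text, simplifyVector = FALSE),
                    error = function(e)
                      stopf("malformed JSON: %s", conditionMessage(e),
                            class = "stpra_parse_error"))
      plain_to_tree(x)
    },
    yaml = {
      x <- tryCatch(yaml::yaml.load(text),
                    error = function(e)
                      stopf("malformed YAML: %s", conditionMessage(e),
                            class = "stpra_parse_error"))
      plain_to_tree(x)
    },
    openpsa_xml = parse_openpsa(text)
  )
}

#' Serialize a fault-tree model to text
#'
#' Refuses trees with validation errors. The native JSON/YAML surfaces
#' round-trip exactly: `parse_model(serialize_model(t))` reproduces the
#' same identifiers, gate kinds, input order and source values to full
#' floating-point precision. The Open-PSA surface is lossy for
#' multi-source estimates (it stores one point probability, the average).
#'
#' @param tree a valid `fault_tree`.
#' @param format `"json"`, `"yaml"` or `"openpsa_xml"`.
#' @return A single string.
#' @export
serialize_model <- function(tree, format = c("json", "yaml", "openpsa_xml")) {
  format <- match.arg(format)
  assert_valid(tree, "serialization")
  switch(format,
    json = as.character(jsonlite::toJSON(tree_to_plain(tree),
                                         auto_unbox = TRUE, digits = NA,
                                         null = "null", pretty = TRUE)),
    yaml = yaml::as.yaml(tree_to_plain(tree), precision = 17L),
    openpsa_xml = serialize_openpsa(tree)
  )
}

#' Read a model from a file
#'
#' Convenience wrapper over [parse_model()] that guesses the format from
#' the file extension (`.json`, `.yaml`/`.yml`, `.xml`).
#'
#' @param path file path.
#' @param format serialization format; default guesses from the extension.
#' @return A `fault_tree`.
#' @export
read_model <- function(path, format = NULL) {
  if (!file.exists(path))
    stopf("model file not found: %s", path, class = "stpra_io_error")
  if (is.null(format)) {
    format <- switch(tolower(tools::file_ext(path)),
                     json = "json", yaml = "yaml", yml = "yaml",
                     xml = "openpsa_xml",
                     stopf("cannot guess model format from '%s'", path,
                           class = "stpra_io_error"))
  }
  parse_model(readLines(path, warn = FALSE), format)
}

#' Write a model to a file
#'
#' @param tree a valid `fault_tree`.
#' @param path output path.
#' @param format serialization format; default guesses from the extension.
#' @return `path`, invisibly.
#' @export
write_model <- function(tree, path, format = NULL) {
  if (is.null(format)) {
    format <- switch(tolower(tools::file_ext(path)),
                     json = "json", yaml = "yaml", yml = "yaml",
                     xml = "openpsa_xml", "json")
  }
  writeLines(serialize_model(tree, format), path)
  invisible(path)
}

# ---- Open-PSA Model Exchange Format (minimal subset) -----------------------
# Maps define-fault-tree / define-gate with <and>/<or> formulas over
# <gate name=.../> and <basic-event name=.../> references, and
# define-basic-event with a single <float value=.../> point probability
# (the average estimate). Theme and the underdeveloped flag travel in an
# <attributes> block; labels in <label>. Multi-source estimates collapse
# to the point value, which reads back as one literature-provenance source.

serialize_openpsa <- function(tree) {
  doc <- xml2::xml_new_root("opsa-mef")
  ft <- xml2::xml_add_child(doc, "define-fault-tree", name = tree$name)
  for (g in tree$gates) {
    gn <- xml2::xml_add_child(ft, "define-gate", name = g$id)
    form <- xml2::xml_add_child(gn, tolower(g$kind))
    for (inp in g$inputs) {
      if (is_gate_id(tree, inp))
        xml2::xml_add_child(form, "gate", name = inp)
      else
        xml2::xml_add_child(form, "basic-event", name = inp)
    }
  }
  md <- xml2::xml_add_child(doc, "model-data")
  for (e in tree$events) {
    be <- xml2::xml_add_child(md, "define-basic-event", name = e$id)
    xml2::xml_add_child(be, "label", e$label)
    at <- xml2::xml_add_child(be, "attributes")
    xml2::xml_add_child(at, "attribute", name = "theme", value = e$theme)
    xml2::xml_add_child(at, "attribute", name = "underdeveloped",
                        value = if (e$underdeveloped) "true" else "false")
    if (!is.null(e$estimate))
      xml2::xml_add_child(be, "float",
                          value = format(e$estimate$average, digits = 17))
  }
  as.character(doc)
}

parse_openpsa <- function(text) {
  doc <- tryCatch(xml2::read_xml(text),
                  error = function(e)
                    stopf("malformed XML: %s", conditionMessage(e),
                          class = "stpra_parse_error"))
  ftn <- xml2::xml_find_first(doc, ".//define-fault-tree")
  if (inherits(ftn, "xml_missing"))
    stopf("no define-fault-tree element found", class = "stpra_parse_error")
  name <- xml2::xml_attr(ftn, "name") %||% ""
  gate_nodes <- xml2::xml_find_all(ftn, "./define-gate")
  gates <- lapply(gate_nodes, function(gn) {
    gid <- xml2::xml_attr(gn, "name")
    form <- xml2::xml_find_first(gn, "./and | ./or")
    if (inherits(form, "xml_missing"))
      stopf("gate '%s' has no and/or formula", gid, class = "stpra_parse_error")
    kind <- toupper(xml2::xml_name(form))
    kids <- xml2::xml_find_all(form, "./gate | ./basic-event")
    gate(gid, kind, xml2::xml_attr(kids, "name"))
  })
  ev_nodes <- xml2::xml_find_all(doc, ".//define-basic-event")
  events <- lapply(ev_nodes, function(en) {
    eid <- xml2::xml_attr(en, "name")
    lab <- xml2::xml_text(xml2::xml_find_first(en, "./label"))
    if (is.na(lab) || !nzchar(lab)) lab <- eid
    theme <- xml2::xml_attr(
      xml2::xml_find_first(en, "./attributes/attribute[@name='theme']"), "value")
    und <- xml2::xml_attr(
      xml2::xml_find_first(en, "./attributes/attribute[@name='underdeveloped']"),
      "value")
    p <- xml2::xml_attr(xml2::xml_find_first(en, "./float"), "value")
    src <- if (is.na(p)) list() else
      list(source_estimate(as.numeric(p), "literature", "openpsa-point-estimate"))
    basic_event(eid, label = lab,
                theme = if (is.na(theme)) "other" else theme,
                underdeveloped = identical(und, "true"),
                sources = src)
  })
  gids <- vapply(gates, `[[`, character(1), "id")
  inputs_all <- unlist(lapply(gates, `[[`, "inputs"))
  top <- setdiff(gids, inputs_all)
  if (length(top) != 1)
    stopf("expected exactly one top gate, found: %s",
          paste(top, collapse = ", "), class = "stpra_structural_error")
  tr <- fault_tree(name, top, gates, events)
  iss <- validate_tree(tr)
  dang <- iss[iss$code == "dangling_ref", , drop = FALSE]
  if (nrow(dang) > 0)
    stopf("unresolved identifier(s): %s", paste(dang$message, collapse = "; "),
          class = "stpra_structural_error")
  tr
}
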