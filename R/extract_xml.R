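## EN/ISO 13606 extract XML dialect: a documented, namespaced subset of
## the extract structure (extract -> entries -> elements carrying typed
## reference-model values as attributes). The XSD shipped under
## inst/extdata/schema/extract.xsd is the normative description of the
## dialect; the norm's full schema is deliberately not reproduced.

EXTRACT_XMLNS <- "urn:ehr2omop:extract:1"

dv_to_attrs <- function(dv) {
  switch(dv$kind,
    CODED_TEXT = c(code = dv$code, code_system = dv$code_system,
                   if (!is.null(dv$display)) c(display = dv$display)),
    QUANTITY = c(magnitude = format(dv$magnitude, scientific = FALSE),
                 units = dv$units),
    IDENTIFIER = c(id = dv$id, scope = dv$scope),
    BOOLEAN = c(value = if (isTRUE(dv$value)) "true" else "false"),
    c(value = dv$value))
}

attrs_to_dv <- function(kind, at) {
  switch(kind,
    CODED_TEXT = dv_coded_text(at[["code"]], at[["code_system"]],
                               if ("display" %in% names(at)) at[["display"]]),
    QUANTITY = dv_quantity(at[["magnitude"]], at[["units"]]),
    IDENTIFIER = dv_identifier(at[["id"]], at[["scope"]]),
    DATE_TIME = dv_date_time(at[["value"]]),
    BOOLEAN = dv_boolean(at[["value"]]),
    SIMPLE_TEXT = dv_simple_text(at[["value"]]),
    abort2(paste0("unknown element kind in XML: ", kind), "ehr2omop_parse_error"))
}

#' Serialize an EHR extract to XML
#'
#' Emits the extract dialect: one `ehr_extract` root with provenance
#' attributes and one `entry` node per built entry; populated elements are
#' written as attribute-typed `element` nodes, absent optional elements
#' are omitted entirely (no empty tags).
#'
#' @param extract an `ehr_extract` from [assemble_extracts()].
#' @param path optional file path; when given the document is written
#'   there.
#' @return An `xml2::xml_document`, invisibly when `path` is given.
#' @export
serialize_extract <- function(extract, path = NULL) {
  stopifnot(inherits(extract, "ehr_extract"))
  doc <- xml2::xml_new_root("ehr_extract", xmlns = EXTRACT_XMLNS,
                            extract_id = extract$extract_id,
                            patient_id = extract$patient_id,
                            archetype_id = extract$archetype_id,
                            source_name = extract$provenance$source_name,
                            extracted_at = extract$provenance$extracted_at)
  for (en in extract$entries) {
    node <- xml2::xml_add_child(doc, "entry")
    for (nid in names(en$values)) {
      at <- dv_to_attrs(en$values[[nid]])
      do.call(xml2::xml_add_child,
              c(list(node, "element", node_id = nid,
                     kind = en$values[[nid]]$kind), as.list(at)))
    }
  }
  if (is.null(path)) return(doc)
  xml2::write_xml(doc, path)
  invisible(doc)
}

#' Parse an extract XML document
#'
#' Inverse of [serialize_extract()]: `parse_extract(serialize_extract(x))`
#' reproduces `x` structurally.
#'
#' @param x a file path or `xml2::xml_document`.
#' @return An `ehr_extract` object.
#' @export
parse_extract <- function(x) {
  doc <- if (inherits(x, "xml_document")) x else xml2::read_xml(x)
  root <- xml2::xml_root(doc)
  ra <- xml2::xml_attrs(root)
  entries <- lapply(xml2::xml_find_all(root, "./*[local-name()='entry']"),
                    function(node) {
    values <- list()
    for (el in xml2::xml_find_all(node, "./*[local-name()='element']")) {
      at <- xml2::xml_attrs(el)
      values[[at[["node_id"]]]] <- attrs_to_dv(at[["kind"]], at)
    }
    list(archetype_id = ra[["archetype_id"]],
         patient_id = ra[["patient_id"]],
         values = values)
  })
  structure(list(extract_id = ra[["extract_id"]],
                 patient_id = ra[["patient_id"]],
                 archetype_id = ra[["archetype_id"]],
                 entries = entries,
                 provenance = list(source_name = ra[["source_name"]],
                                   extracted_at = ra[["extracted_at"]])),
            class = "ehr_extract")
}

#' Validate an extract against the archetype library
#'
#' Checks schema validity (against the packaged XSD) plus archetype
#' conformance of every entry: the named archetype exists, all mandatory
#' elements are populated, data-value kinds match the element
#' specifications, and coded values carry a non-empty code system.
#' Violations are report rows, not errors.
#'
#' @param x extract XML path / document, or an `ehr_extract` object.
#' @param library an [archetype_library()].
#' @return Data frame with columns `entry`, `path`, `violation`; zero rows
#'   when the extract conforms.
#' @export
validate_extract <- function(x, library = archetype_library()) {
  rows <- list()
  add <- function(entry, path, violation)
    rows[[length(rows) + 1L]] <<- data.frame(entry = entry, path = path,
                                             violation = violation)
  if (!inherits(x, "ehr_extract")) {
    ## reparse in-memory documents so namespace declarations take effect
    doc <- if (inherits(x, "xml_document"))
      xml2::read_xml(as.character(x)) else xml2::read_xml(x)
    xsd <- xml2::read_xml(ehr2omop_extdata("schema", "extract.xsd"))
    ok <- xml2::xml_validate(doc, xsd)
    if (!isTRUE(ok))
      for (m in attr(ok, "errors"))
        add(NA_integer_, "<document>", paste0("schema: ", m))
    x <- parse_extract(doc)
  }
  arch <- library[[x$archetype_id]]
  if (is.null(arch)) {
    add(NA_integer_, "archetype_id",
        paste0("unknown archetype: ", x$archetype_id))
  } else {
    for (i in seq_along(x$entries)) {
      en <- x$entries[[i]]
      node_ids <- vapply(arch$entry$elements, `[[`, "", "node_id")
      for (nid in setdiff(names(en$values), node_ids))
        add(i, nid, "element not defined by archetype")
      for (el in arch$entry$elements) {
        dv <- en$values[[el$node_id]]
        if (is.null(dv)) {
          if (el$mandatory)
            add(i, paste0(x$archetype_id, "/", el$node_id),
                "mandatory element missing")
          next
        }
        if (dv$kind != el$kind)
          add(i, paste0(x$archetype_id, "/", el$node_id),
              paste0("kind mismatch: ", dv$kind, " != ", el$kind))
        if (dv$kind == "CODED_TEXT" && !nz_string(dv$code_system))
          add(i, paste0(x$archetype_id, "/", el$node_id),
              "coded value without code system")
      }
    }
  }
  if (!length(rows))
    return(data.frame(entry = integer(0), path = character(0),
                      violation = character(0)))
  do.call(rbind, rows)
}

#' Build and write all extracts for one archetype
#'
#' Convenience wrapper: [build_extracts()], [assemble_extracts()], then
#' one XML file per (patient, archetype) under `out_dir/<concept>/`.
#'
#' @inheritParams build_extracts
#' @inheritParams assemble_extracts
#' @param out_dir output root; a subdirectory per archetype concept is
#'   created.
#' @return Invisibly, a list with `n_entries`, `n_quarantined`, `files`,
#'   `quarantine`, `binding_report`.
#' @export
write_extracts <- function(source, mapping, archetype, out_dir,
                           concept_map = ehr2omop::concept_map(),
                           rules = category_rules(),
                           source_name = "synthetic-his",
                           extracted_at = "2022-02-15T00:00:00+01:00") {
  built <- build_extracts(source, mapping, archetype, concept_map, rules)
  extracts <- assemble_extracts(built$entries, source_name, extracted_at)
  concept <- archetype_concept(archetype)
  dir.create(file.path(out_dir, concept), recursive = TRUE, showWarnings = FALSE)
  files <- vapply(extracts, function(x) {
    p <- file.path(out_dir, concept, paste0(x$extract_id, ".xml"))
    serialize_extract(x, p)
    p
  }, character(1))
  if (nrow(built$quarantine))
    write_csv_rfc(built$quarantine,
                  file.path(out_dir, concept, "quarantine.csv"))
  invisible(list(n_entries = length(built$entries),
                 n_quarantined = nrow(built$quarantine),
                 files = unname(files), quarantine = built$quarantine,
                 binding_report = built$binding_report))
}
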