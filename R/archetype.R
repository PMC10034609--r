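## Entry-level archetypes: formal definitions of clinical concepts
## expressed against the reference model. Only the ENTRY and ELEMENT levels
## are modeled; every packaged archetype is an entry with a flat list of
## typed elements, which is how the concepts in the packaged library were
## authored.

ARCHETYPE_ID_PATTERN <- "^CEN-EN13606-ENTRY\\.[a-z][a-z0-9_]*\\.v[0-9]+$"

#' Parse an archetype definition
#'
#' Archetypes are authored in a small declarative YAML dialect: an
#' `archetype_id` (matching `CEN-EN13606-ENTRY.<concept>.v<N>`), `version`,
#' `language`, `description`, and a single `entry` with a `name` and an
#' ordered list of `elements`. Each element carries `node_id` (unique within
#' the entry), `name`, `kind` (one of `CODED_TEXT`, `SIMPLE_TEXT`,
#' `DATE_TIME`, `QUANTITY`, `IDENTIFIER`, `BOOLEAN`), `mandatory`
#' (default `TRUE`) and, for coded elements, an optional `terminology`
#' binding naming the code system. Unknown fields are rejected.
#'
#' @param definition_text a YAML document as a single string, or a file path.
#' @return An object of class `archetype`.
#' @seealso [archetype_library()], [serialize_archetype()]
#' @examples
#' a <- parse_archetype(ehr2omop_extdata("archetypes", "diagnosis.yaml"))
#' a$entry$name
#' vapply(a$entry$elements, `[[`, "", "node_id")
#' @export
parse_archetype <- function(definition_text) {
  txt <- definition_text
  if (is_string(txt) && !grepl("\n", txt) && file.exists(txt))
    txt <- paste(readLines(txt, warn = FALSE, encoding = "UTF-8"), collapse = "\n")
  doc <- tryCatch(yaml::yaml.load(txt),
                  error = function(e) abort2(
                    paste0("archetype definition is not well-formed YAML: ",
                           conditionMessage(e)), "ehr2omop_parse_error"))
  if (!is.list(doc)) abort2("archetype definition must be a YAML mapping",
                            "ehr2omop_parse_error")
  allowed <- c("archetype_id", "version", "language", "description", "entry")
  unknown <- setdiff(names(doc), allowed)
  if (length(unknown))
    abort2(paste0("unknown archetype field(s): ", paste(unknown, collapse = ", ")),
           "ehr2omop_validation_error")
  for (f in c("archetype_id", "version", "language", "entry"))
    if (is.null(doc[[f]]))
      abort2(paste0("archetype field missing: ", f), "ehr2omop_validation_error")
  if (!grepl(ARCHETYPE_ID_PATTERN, doc$archetype_id))
    abort2(paste0("archetype_id does not match the documented pattern: ",
                  doc$archetype_id), "ehr2omop_validation_error")

  entry <- doc$entry
  unknown <- setdiff(names(entry), c("name", "elements"))
  if (length(unknown))
    abort2(paste0("unknown entry field(s): ", paste(unknown, collapse = ", ")),
           "ehr2omop_validation_error")
  if (!nz_string(entry$name))
    abort2("entry requires a name", "ehr2omop_validation_error")
  if (!length(entry$elements))
    abort2("entry requires at least one element", "ehr2omop_validation_error")

  elements <- lapply(seq_along(entry$elements), function(i) {
    el <- entry$elements[[i]]
    unknown <- setdiff(names(el), c("node_id", "name", "kind", "mandatory",
                                    "terminology"))
    if (length(unknown))
      abort2(paste0("element ", i, ": unknown field(s) ",
                    paste(unknown, collapse = ", ")), "ehr2omop_validation_error")
    if (!nz_string(el$node_id))
      abort2(paste0("element ", i, ": node_id missing"), "ehr2omop_validation_error")
    if (!is_string(el$kind) || !(el$kind %in% DV_KINDS))
      abort2(paste0("element ", el$node_id %||% i, ": unknown data-value kind ",
                    dQuote(el$kind %||% "<missing>")), "ehr2omop_validation_error")
    if (!is.null(el$terminology) && el$kind != "CODED_TEXT")
      abort2(paste0("element ", el$node_id,
                    ": terminology binding requires kind CODED_TEXT"),
             "ehr2omop_validation_error")
    list(node_id = el$node_id,
         name = el$name %||% el$node_id,
         kind = el$kind,
         mandatory = isTRUE(el$mandatory %||% TRUE),
         terminology = el$terminology)
  })
  ids <- vapply(elements, `[[`, "", "node_id")
  if (anyDuplicated(ids))
    abort2(paste0("duplicate element node_id: ",
                  paste(unique(ids[duplicated(ids)]), collapse = ", ")),
           "ehr2omop_validation_error")

  structure(list(archetype_id = doc$archetype_id,
                 version = as.character(doc$version),
                 language = doc$language,
                 description = doc$description %||% "",
                 entry = list(name = entry$name, elements = elements)),
            class = "archetype")
}

#' Serialize an archetype to its canonical YAML form
#'
#' The canonical form orders fields deterministically and spells out
#' defaults, so `parse_archetype(serialize_archetype(x))` is the identity on
#' the parsed structure.
#'
#' @param archetype an `archetype` object.
#' @return A single YAML string.
#' @export
serialize_archetype <- function(archetype) {
  stopifnot(inherits(archetype, "archetype"))
  els <- lapply(archetype$entry$elements, function(el) {
    out <- list(node_id = el$node_id, name = el$name, kind = el$kind,
                mandatory = el$mandatory)
    if (!is.null(el$terminology)) out$terminology <- el$terminology
    out
  })
  doc <- list(archetype_id = archetype$archetype_id,
              version = archetype$version,
              language = archetype$language,
              description = archetype$description,
              entry = list(name = archetype$entry$name, elements = els))
  yaml::as.yaml(doc, indent.mapping.sequence = TRUE)
}

#' @export
print.archetype <- function(x, ...) {
  cat("<archetype> ", x$archetype_id, "\n", sep = "")
  cat("  entry: ", x$entry$name, " (", length(x$entry$elements),
      " elements)\n", sep = "")
  for (el in x$entry$elements)
    cat(sprintf("  - %-22s %-11s%s%s\n", el$node_id, el$kind,
                if (el$mandatory) " mandatory" else " optional",
                if (!is.null(el$terminology)) paste0(" [", el$terminology, "]") else ""))
  invisible(x)
}

archetype_element <- function(archetype, node_id) {
  for (el in archetype$entry$elements) if (el$node_id == node_id) return(el)
  NULL
}

archetype_concept <- function(archetype)
  sub("^CEN-EN13606-ENTRY\\.([a-z0-9_]+)\\.v[0-9]+$", "\\1", archetype$archetype_id)

#' Load an archetype library
#'
#' Reads every `*.yaml` definition in a directory into a named library.
#' With no arguments, loads the packaged library of twelve entry-level
#' concepts: diagnosis, episodes, limitation of life-sustaining treatment,
#' administered medication, cumulative drug dose, prescribed medication,
#' movements between units, clinical observations, laboratory observations,
#' patients, health problems, and procedures.
#'
#' @param dir directory of YAML archetype definitions; defaults to the
#'   packaged fixtures.
#' @return An object of class `archetype_library` (a named list of
#'   `archetype` objects keyed by `archetype_id`).
#' @examples
#' lib <- archetype_library()
#' length(lib)
#' @export
archetype_library <- function(dir = ehr2omop_extdata("archetypes")) {
  files <- sort(list.files(dir, pattern = "\\.yaml$", full.names = TRUE))
  if (!length(files)) abort2(paste0("no archetype definitions in ", dir),
                             "ehr2omop_input_error")
  archetypes <- lapply(files, parse_archetype)
  ids <- vapply(archetypes, `[[`, "", "archetype_id")
  if (anyDuplicated(ids))
    abort2(paste0("duplicate archetype_id in library: ",
                  paste(unique(ids[duplicated(ids)]), collapse = ", ")),
           "ehr2omop_validation_error")
  structure(setNames(archetypes, ids), class = "archetype_library")
}

#' @export
print.archetype_library <- function(x, ...) {
  cat("<archetype_library> ", length(x), " archetypes\n", sep = "")
  for (id in names(x)) cat("  ", id, "\n", sep = "")
  invisible(x)
}

lib_by_concept <- function(library, concept) {
  for (a in library) if (archetype_concept(a) == concept) return(a)
  NULL
}

#' Validate an archetype library
#'
#' Re-checks the structural invariants across a loaded library: identifier
#' pattern and uniqueness, element node_id uniqueness within each entry,
#' known data-value kinds, terminology bindings restricted to coded
#' elements, and round-trip stability of the canonical serialization.
#' Violations are report content, not errors.
#'
#' @param library an `archetype_library`.
#' @return A data frame with columns `archetype_id`, `path`, `violation`;
#'   zero rows when the library is valid.
#' @export
validate_library <- function(library) {
  stopifnot(inherits(library, "archetype_library"))
  rows <- list()
  add <- function(id, path, violation)
    rows[[length(rows) + 1L]] <<- data.frame(archetype_id = id, path = path,
                                             violation = violation)
  seen <- character(0)
  for (a in library) {
    id <- a$archetype_id
    if (id %in% seen) add(id, "archetype_id", "duplicate archetype_id")
    seen <- c(seen, id)
    if (!grepl(ARCHETYPE_ID_PATTERN, id))
      add(id, "archetype_id", "identifier does not match documented pattern")
    if (!length(a$entry$elements))
      add(id, "entry.elements", "entry has no elements")
    node_ids <- vapply(a$entry$elements, `[[`, "", "node_id")
    for (dup in unique(node_ids[duplicated(node_ids)]))
      add(id, paste0("entry.elements.", dup), "duplicate node_id")
    for (el in a$entry$elements) {
      p <- paste0("entry.elements.", el$node_id)
      if (!(el$kind %in% DV_KINDS)) add(id, p, "unknown data-value kind")
      if (!is.null(el$terminology) && el$kind != "CODED_TEXT")
        add(id, p, "terminology binding on non-coded element")
      if (!nz_string(el$name)) add(id, p, "element name missing")
    }
    rt <- tryCatch(parse_archetype(serialize_archetype(a)),
                   error = function(e) NULL)
    if (is.null(rt) || !identical(rt, a))
      add(id, "<document>", "canonical serialization does not round-trip")
  }
  if (!length(rows))
    return(data.frame(archetype_id = character(0), path = character(0),
                      violation = character(0)))
  do.call(rbind, rows)
}
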