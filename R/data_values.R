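## EN/ISO 13606 reference-model data values.
##
## The reference model fixes the vocabulary every communicated record must
## use; at the leaf level that is a small set of typed data values. Six
## variants cover every element of the packaged archetype library; the set
## is closed on purpose so that validation stays decidable.

DV_KINDS <- c("CODED_TEXT", "SIMPLE_TEXT", "DATE_TIME", "QUANTITY",
              "IDENTIFIER", "BOOLEAN")

#' Reference-model data values
#'
#' Constructors for the typed leaf values of the EN/ISO 13606 reference
#' model as used by entry-level archetypes: coded text (a code bound to a
#' terminology), plain text, ISO-8601 timestamps, physical quantities,
#' identifiers scoped to an assigning system, and booleans. Exactly one
#' variant is populated per value.
#'
#' @param code,code_system,display code, its terminology (e.g. `"ICD-10-CM"`)
#'   and an optional human-readable description. `code_system` must be
#'   non-empty.
#' @param value scalar payload for text / datetime / boolean variants.
#' @param magnitude,units numeric magnitude and non-empty unit string.
#' @param id,scope identifier value and the scope assigning it.
#' @return An object of class `ehr_dv`, a tagged list with fields per variant.
#' @examples
#' dv_coded_text("H40.9", "ICD-10-CM", "unspecified glaucoma")
#' dv_quantity(5.5, "mmol/L")
#' @name data_values
NULL

new_dv <- function(kind, fields) {
  structure(c(list(kind = kind), fields), class = "ehr_dv")
}

#' @rdname data_values
#' @export
dv_coded_text <- function(code, code_system, display = NULL) {
  if (!nz_string(code)) abort2("CODED_TEXT requires a non-empty code", "ehr2omop_value_error")
  if (!nz_string(code_system))
    abort2("CODED_TEXT requires a non-empty code_system", "ehr2omop_value_error")
  new_dv("CODED_TEXT", list(code = code, code_system = code_system,
                            display = if (nz_string(display)) display else NULL))
}

#' @rdname data_values
#' @export
dv_simple_text <- function(value) {
  if (!is_string(value)) abort2("SIMPLE_TEXT requires a string", "ehr2omop_value_error")
  new_dv("SIMPLE_TEXT", list(value = value))
}

#' @rdname data_values
#' @export
dv_date_time <- function(value) {
  v <- iso_datetime(value)
  new_dv("DATE_TIME", list(value = v))
}

#' @rdname data_values
#' @export
dv_quantity <- function(magnitude, units) {
  m <- suppressWarnings(as.numeric(magnitude))
  if (length(m) != 1L || is.na(m))
    abort2("QUANTITY requires a numeric magnitude", "ehr2omop_value_error")
  if (!nz_string(units))
    abort2("QUANTITY requires a non-empty units string", "ehr2omop_value_error")
  new_dv("QUANTITY", list(magnitude = m, units = units))
}

#' @rdname data_values
#' @export
dv_identifier <- function(id, scope) {
  if (!nz_string(id)) abort2("IDENTIFIER requires a non-empty id", "ehr2omop_value_error")
  if (!nz_string(scope)) abort2("IDENTIFIER requires an assigning scope", "ehr2omop_value_error")
  new_dv("IDENTIFIER", list(id = id, scope = scope))
}

#' @rdname data_values
#' @export
dv_boolean <- function(value) {
  v <- if (is.logical(value) && length(value) == 1L && !is.na(value)) value
       else if (is_string(value) && tolower(value) %in% c("true", "false"))
         tolower(value) == "true"
       else abort2("BOOLEAN requires TRUE/FALSE", "ehr2omop_value_error")
  new_dv("BOOLEAN", list(value = v))
}

#' @export
print.ehr_dv <- function(x, ...) {
  body <- switch(x$kind,
    CODED_TEXT = paste0(x$code, " [", x$code_system, "]",
                        if (!is.null(x$display)) paste0(" ", dQuote(x$display))),
    QUANTITY = paste(x$magnitude, x$units),
    IDENTIFIER = paste0(x$id, " @", x$scope),
    as.character(x$value))
  cat("<", x$kind, "> ", body, "\n", sep = "")
  invisible(x)
}

dv_is <- function(x) inherits(x, "ehr_dv")

## Scalar rendering used by CSV export and query bindings.
dv_scalar <- function(x, facet = NULL) {
  switch(x$kind,
    CODED_TEXT = switch(facet %||% "code",
                        code = x$code, code_system = x$code_system,
                        display = x$display %||% NA_character_),
    QUANTITY = switch(facet %||% "magnitude",
                      magnitude = format(x$magnitude, scientific = FALSE),
                      units = x$units),
    IDENTIFIER = switch(facet %||% "id", id = x$id, scope = x$scope),
    BOOLEAN = if (isTRUE(x$value)) "true" else "false",
    x$value)
}
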