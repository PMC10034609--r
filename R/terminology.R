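## Terminology binding: attaching standard codes (ICD-10-CM, LOINC,
## SNOMED CT) and readable descriptions to locally coded data, and
## categorizing selected concepts (e.g. hospital units by level of care)
## during normalization. Mapping tables are plain CSVs; no external
## vocabulary service is consulted.

TARGET_SYSTEMS <- c("ICD-10-CM", "LOINC", "SNOMED CT", "local")

#' Load and validate a concept-mapping table
#'
#' The table binds local codes to standard nomenclatures. Columns:
#' `local_code`, `local_system`, `target_code`, `target_system` (one of
#' `ICD-10-CM`, `LOINC`, `SNOMED CT`, `local`), `display`. Matching is
#' case-sensitive and mappings must be one-to-one per
#' `(local_code, local_system)`.
#'
#' @param path CSV path; defaults to the packaged toy dictionary.
#' @return An object of class `concept_map`.
#' @examples
#' cm <- concept_map()
#' bind_code("D003", "HIS-DIAG", cm)
#' @export
concept_map <- function(path = ehr2omop_extdata("terminology", "concept_mappings.csv")) {
  df <- read_csv_chr(path)
  need <- c("local_code", "local_system", "target_code", "target_system", "display")
  if (!all(need %in% names(df)))
    abort2(paste0("mapping table must have columns: ", paste(need, collapse = ", ")),
           "ehr2omop_config_error")
  bad <- setdiff(unique(df$target_system), TARGET_SYSTEMS)
  if (length(bad))
    abort2(paste0("unknown target_system(s): ", paste(bad, collapse = ", ")),
           "ehr2omop_validation_error")
  key <- paste(df$local_code, df$local_system, sep = "\r")
  if (anyDuplicated(key))
    abort2(paste0("mapping table is not one-to-one; duplicate local codes: ",
                  paste(unique(df$local_code[duplicated(key)]), collapse = ", ")),
           "ehr2omop_validation_error")
  structure(list(table = df, index = setNames(seq_len(nrow(df)), key)),
            class = "concept_map")
}

#' @export
print.concept_map <- function(x, ...) {
  cat("<concept_map> ", nrow(x$table), " mappings (",
      paste(sort(unique(x$table$target_system)), collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Bind a local code to a standard terminology
#'
#' Total and deterministic: a mapped code returns the standard coded text
#' (code, system, display); an unmapped code is preserved as coded text in
#' system `"local"` and the miss is registered on the collector when one is
#' supplied. No record is ever dropped at this stage. A code whose
#' `local_system` is already a target system passes through as an identity
#' binding.
#'
#' @param local_code,local_system the source code and its local system.
#' @param map a [concept_map()].
#' @param report optional environment collecting unmapped codes (see
#'   [new_binding_report()]).
#' @return A `CODED_TEXT` data value.
#' @export
bind_code <- function(local_code, local_system, map, report = NULL) {
  if (!nz_string(local_code))
    abort2("bind_code: empty local_code", "ehr2omop_input_error")
  stopifnot(inherits(map, "concept_map"))
  i <- unname(map$index[paste(local_code, local_system, sep = "\r")])
  if (!is.na(i)) {
    row <- map$table[i, ]
    return(dv_coded_text(row$target_code, row$target_system,
                         if (nzchar(row$display)) row$display else NULL))
  }
  if (local_system %in% setdiff(TARGET_SYSTEMS, "local"))
    return(dv_coded_text(local_code, local_system))
  if (!is.null(report))
    report$unmapped[[length(report$unmapped) + 1L]] <-
      c(local_code = local_code, local_system = local_system)
  dv_coded_text(local_code, "local")
}

#' Collector for unmapped codes and uncategorized values
#'
#' @return An environment with fields `unmapped` and `uncategorized`, each a
#'   growing list; summarize with [binding_report_df()].
#' @export
new_binding_report <- function() {
  e <- new.env(parent = emptyenv())
  e$unmapped <- list()
  e$uncategorized <- list()
  e
}

#' @rdname new_binding_report
#' @param report a collector created by [new_binding_report()].
#' @export
binding_report_df <- function(report) {
  to_df <- function(lst, kind) {
    if (!length(lst))
      return(data.frame(kind = character(0), code = character(0),
                        system_or_dimension = character(0)))
    m <- do.call(rbind, lst)
    data.frame(kind = kind, code = m[, 1], system_or_dimension = m[, 2],
               row.names = NULL)
  }
  rbind(to_df(report$unmapped, "unmapped_code"),
        to_df(report$uncategorized, "uncategorized_value"))
}

#' Load a categorization rule set
#'
#' Rules group source values into categories along named dimensions, e.g.
#' hospital units into levels of care. Columns: `source_value`,
#' `dimension`, `category`; `(source_value, dimension)` must be unique.
#'
#' @param path CSV path; defaults to the packaged rules.
#' @return An object of class `category_rules`.
#' @export
category_rules <- function(path = ehr2omop_extdata("terminology", "category_rules.csv")) {
  df <- read_csv_chr(path)
  need <- c("source_value", "dimension", "category")
  if (!all(need %in% names(df)))
    abort2(paste0("category rules must have columns: ", paste(need, collapse = ", ")),
           "ehr2omop_config_error")
  key <- paste(df$source_value, df$dimension, sep = "\r")
  if (anyDuplicated(key))
    abort2("category rules are not unique per (source_value, dimension)",
           "ehr2omop_validation_error")
  structure(list(table = df, index = setNames(seq_len(nrow(df)), key)),
            class = "category_rules")
}

#' Categorize a source value along a dimension
#'
#' @param source_value the value to categorize (e.g. a unit code).
#' @param dimension rule dimension, e.g. `"level_of_care"`; must exist in
#'   the rule set.
#' @param rules a [category_rules()] object.
#' @param report optional [new_binding_report()] collector; unmatched values
#'   are registered there.
#' @return The configured category, or `"uncategorized"` for values with no
#'   rule.
#' @export
categorize <- function(source_value, dimension, rules, report = NULL) {
  stopifnot(inherits(rules, "category_rules"))
  if (!(dimension %in% unique(rules$table$dimension)))
    abort2(paste0("unknown categorization dimension: ", dimension),
           "ehr2omop_config_error")
  i <- unname(rules$index[paste(source_value, dimension, sep = "\r")])
  if (is.na(i)) {
    if (!is.null(report))
      report$uncategorized[[length(report$uncategorized) + 1L]] <-
        c(source_value = source_value, dimension = dimension)
    return("uncategorized")
  }
  rules$table$category[i]
}
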