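## Graph-query export. For each CDM table the generator walks the layer-3
## mapping to find the concept classes feeding the table and the element
## properties feeding each column, then emits a SPARQL SELECT whose
## projection covers *every* schema column — columns with no mapped
## property stay as unbound variables and surface as empty cells, and
## reference-model data-value structure (coded text, quantity, identifier
## component nodes) is navigated explicitly in the patterns. The same
## basic-graph-pattern/OPTIONAL structure is evaluated in-package against
## the instance graph.

## ---- tiny BGP engine -------------------------------------------------

is_var <- function(x) startsWith(x, "?")

match_pattern <- function(df, pat) {
  sel <- rep(TRUE, nrow(df))
  for (pos in c("s", "p", "o")) {
    term <- pat[[pos]]
    col <- c(s = "subject", p = "predicate", o = "object")[[pos]]
    if (!is_var(term)) sel <- sel & (df[[col]] == term)
  }
  hit <- df[sel, , drop = FALSE]
  out <- list()
  for (pos in c("s", "p", "o")) {
    term <- pat[[pos]]
    if (is_var(term))
      out[[substring(term, 2)]] <-
        hit[[c(s = "subject", p = "predicate", o = "object")[[pos]]]]
  }
  res <- as.data.frame(out, optional = TRUE)
  ## same variable twice in one pattern: keep rows where bindings agree
  unique(res)
}

join_bindings <- function(a, b, outer = FALSE) {
  if (is.null(a)) return(b)
  common <- intersect(names(a), names(b))
  if (!length(common)) {
    if (!nrow(a) || !nrow(b))
      return(if (outer) a else a[0, c(names(a), names(b)), drop = FALSE])
    return(merge(a, b, by = NULL))
  }
  merge(a, b, by = common, all.x = outer)
}

eval_bgp <- function(df, patterns, init = NULL) {
  out <- init
  for (pat in patterns) out <- join_bindings(out, match_pattern(df, pat))
  out
}

## ---- query objects ---------------------------------------------------

sparql_prefix_block <- function(ns, used) {
  keep <- names(ns)[names(ns) %in% used]
  paste0("PREFIX ", keep, ": <", unname(ns[keep]), ">")
}

render_pattern_line <- function(pat, ns) {
  term <- function(x) if (is_var(x)) x else compact_iri(x, ns)
  paste0("  ", term(pat$s), " ", term(pat$p), " ", term(pat$o), " .")
}

#' Generate the export query for one OMOP CDM table
#'
#' Reads the layer-3 mapping in the store and produces, per contributing
#' concept class, a SELECT whose projection has one variable per schema
#' column of the table (unmapped columns included, so the emitted table
#' always has the full CDM column set), with one OPTIONAL block per mapped
#' element property navigating the reference-model value structure. Multiple
#' contributing classes (the three drug archetypes feeding `Drug_exposure`)
#' become one query each; their result rows are concatenated on execution.
#'
#' @param table CDM table name.
#' @param store a [triple_store()] with layers built.
#' @param schema schema list from [omop_schema()].
#' @return An `omop_query` object; its `sparql` field is the full query
#'   text, `subqueries` the per-class executable plans.
#' @examples
#' st <- build_ontologies(archetype_library())
#' q <- generate_query("Person", st)
#' cat(substr(q$sparql, 1, 300))
#' @export
generate_query <- function(table, store, schema = omop_schema()) {
  if (!table %in% names(schema))
    abort2(paste0("unknown OMOP table ", dQuote(table), "; supported: ",
                  paste(OMOP_TABLES, collapse = ", ")), "ehr2omop_config_error")
  ns <- store$ns
  tri <- store$triples
  maps_tab <- expand_iri("omop:mapsToTable", ns)
  maps_col <- expand_iri("omop:mapsToColumn", ns)
  tab_cls <- expand_iri(paste0("omop:", table), ns)
  classes <- sort(tri$subject[tri$predicate == maps_tab & tri$object == tab_cls])
  cols <- schema[[table]]$column
  kind_of <- setNames(tri$object[tri$predicate == expand_iri("e2o:valueKind", ns)],
                      tri$subject[tri$predicate == expand_iri("e2o:valueKind", ns)])

  subqueries <- lapply(classes, function(cls) {
    l3 <- tri[tri$predicate == maps_col & startsWith(
      tri$object, paste0(RDF_NS[["omop"]], table, ".")), , drop = FALSE]
    dom <- tri$subject[tri$predicate == expand_iri("rdfs:domain", ns) &
                         tri$object == cls]
    l3 <- l3[l3$subject %in% dom, , drop = FALSE]
    required <- list(list(s = "?entry", p = expand_iri("rdf:type", ns), o = cls))
    optionals <- list()
    for (i in seq_len(nrow(l3))) {
      prop <- l3$subject[i]
      col <- sub(paste0("^", RDF_NS[["omop"]], table, "\\."), "", l3$object[i])
      kind <- kind_of[[prop]] %||% "SIMPLE_TEXT"
      v <- paste0("?", col)
      node <- paste0("?n_", sub("^.*#", "", prop))
      pats <- if (kind %in% RM_STRUCTURED) {
        facet <- value_facet(kind, col)
        list(list(s = "?entry", p = prop, o = node),
             list(s = node, p = paste0(RDF_NS[["iso13606"]], facet), o = v))
      } else {
        list(list(s = "?entry", p = prop, o = v))
      }
      optionals[[length(optionals) + 1L]] <- list(column = col, patterns = pats)
    }
    mapped <- vapply(optionals, `[[`, "", "column")
    lines <- c(paste0("SELECT ", paste0("?", cols, collapse = " "), " WHERE {"),
               vapply(required, render_pattern_line, "", ns = ns),
               unlist(lapply(optionals, function(op) c(
                 "  OPTIONAL {",
                 paste0("  ", vapply(op$patterns, render_pattern_line, "", ns = ns)),
                 "  }"))),
               "}")
    list(class = cls, required = required, optionals = optionals,
         mapped_columns = unique(mapped), sparql = paste(lines, collapse = "\n"))
  })
  used <- c("rdf", "iso13606", "omop", names(ns)[startsWith(names(ns), "arch-")])
  sparql <- paste(c(sparql_prefix_block(ns, used), "",
                    vapply(subqueries, `[[`, "", "sparql")), collapse = "\n")
  structure(list(table = table, columns = cols, subqueries = subqueries,
                 sparql = sparql),
            class = "omop_query")
}

## Which component of a structured reference-model value feeds a column.
value_facet <- function(kind, column) {
  if (kind == "CODED_TEXT") return("code")
  if (kind == "IDENTIFIER") return("idValue")
  if (kind == "QUANTITY") {
    if (grepl("unit", column)) return("units")
    return("magnitude")
  }
  "code"
}

#' @export
print.omop_query <- function(x, ...) {
  cat("<omop_query> ", x$table, ": ", length(x$subqueries),
      " contributing class(es)\n", sep = "")
  cat(x$sparql, "\n")
  invisible(x)
}

#' Execute an export query against the instance graph
#'
#' Evaluates each subquery's basic graph pattern and OPTIONAL blocks over
#' the `"instances"` named graph and returns one data frame with exactly
#' the table's schema columns; unbound variables are `NA`.
#'
#' @param query an `omop_query` from [generate_query()].
#' @param store a [triple_store()].
#' @return Data frame of raw (pre-post-processing) rows; the attribute
#'   `"entry_class"` carries each row's contributing concept class.
#' @export
execute_query <- function(query, store) {
  inst <- ts_graph(store, "instances")
  pieces <- lapply(query$subqueries, function(sq) {
    sol <- eval_bgp(inst, sq$required)
    if (is.null(sol) || !nrow(sol))
      return(cbind(data.frame(entry = character(0)),
                   as.data.frame(setNames(rep(list(character(0)),
                                              length(query$columns)),
                                          query$columns)),
                   data.frame(entry_class = character(0))))
    for (op in sq$optionals) {
      part <- eval_bgp(inst, op$patterns)
      sol <- join_bindings(sol, part, outer = TRUE)
    }
    for (col in setdiff(query$columns, names(sol))) sol[[col]] <- NA_character_
    sol$entry_class <- sq$class
    sol
  })
  out <- do.call(rbind, lapply(pieces, function(p)
    p[, c("entry", intersect(c(query$columns, "entry_class"), names(p))),
      drop = FALSE]))
  cls <- out$entry_class
  ent <- out$entry
  out <- out[, query$columns, drop = FALSE]
  attr(out, "entry_class") <- cls
  attr(out, "entry_iri") <- ent
  out
}
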