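## A minimal in-memory RDF dataset: named graphs of triples held in one
## data frame, with a namespace registry for compact (CURIE) rendering.
## Serialization targets a documented subset of Turtle (one triple per
## line, @prefix header, plain/typed literals) and of N-Quads for whole
## datasets; the package's own output always stays inside that subset, so
## emit -> load preserves triple-set equality.

RDF_NS <- c(
  rdf  = "http://www.w3.org/1999/02/22-rdf-syntax-ns#",
  rdfs = "http://www.w3.org/2000/01/rdf-schema#",
  owl  = "http://www.w3.org/2002/07/owl#",
  xsd  = "http://www.w3.org/2001/XMLSchema#",
  iso13606 = "https://w3id.org/ehr2omop/iso13606#",
  omop = "https://w3id.org/ehr2omop/omop#",
  e2o  = "https://w3id.org/ehr2omop/core#",
  inst = "https://w3id.org/ehr2omop/instance#"
)

arch_ns <- function(concept) {
  setNames(paste0("https://w3id.org/ehr2omop/archetype/", concept, "#"),
           paste0("arch-", gsub("_", "-", concept)))
}

empty_triples <- function() {
  data.frame(graph = character(0), subject = character(0),
              predicate = character(0), object = character(0),
              literal = logical(0), datatype = character(0))
}

#' Create an RDF triple store
#'
#' The store holds any number of named graphs (schema layers, packaged
#' reference ontologies, and the patient-instance graph) as one triple
#' table plus a prefix registry.
#'
#' @param namespaces named character vector of extra prefix -> IRI
#'   namespace bindings (the standard RDF/OWL/XSD prefixes and the
#'   package's own namespaces are always registered).
#' @return An object of class `triple_store` (an environment).
#' @examples
#' ts <- triple_store()
#' ts_add(ts, "g", "inst:x", "rdf:type", "iso13606:Entry")
#' ts_size(ts)
#' @export
triple_store <- function(namespaces = character(0)) {
  e <- new.env(parent = emptyenv())
  e$triples <- empty_triples()
  e$ns <- c(RDF_NS, namespaces)
  class(e) <- "triple_store"
  e
}

#' @export
print.triple_store <- function(x, ...) {
  gs <- unique(x$triples$graph)
  cat("<triple_store> ", nrow(x$triples), " triples in ", length(gs),
      " graph(s)\n", sep = "")
  for (g in sort(gs))
    cat("  ", g, ": ", sum(x$triples$graph == g), "\n", sep = "")
  invisible(x)
}

ts_register_ns <- function(store, namespaces) {
  store$ns <- c(store$ns, namespaces[setdiff(names(namespaces), names(store$ns))])
  invisible(store)
}

expand_iri <- function(x, ns) {
  m <- regexec("^([A-Za-z][A-Za-z0-9-]*):(.*)$", x)
  parts <- regmatches(x, m)
  vapply(seq_along(x), function(i) {
    p <- parts[[i]]
    if (length(p) == 3L && p[2] %in% names(ns)) paste0(ns[[p[2]]], p[3])
    else x[i]
  }, character(1))
}

compact_iri <- function(x, ns) {
  ord <- order(nchar(ns), decreasing = TRUE)
  for (i in ord) {
    hit <- startsWith(x, ns[i])
    local <- substr(x[hit], nchar(ns[i]) + 1L, nchar(x[hit]))
    ok <- grepl("^[A-Za-z0-9_.-]*$", local)
    x[hit][ok] <- paste0(names(ns)[i], ":", local[ok])
  }
  x
}

#' Add triples to a named graph
#'
#' Subjects, predicates and IRI objects may be written as CURIEs against
#' the store's registered prefixes; they are expanded on insertion.
#' Duplicate triples within a graph are collapsed (RDF set semantics).
#'
#' @param store a [triple_store()].
#' @param graph graph name (e.g. `"layer1:diagnosis"`, `"instances"`).
#' @param subject,predicate,object vectors (recycled to a common length).
#' @param literal logical vector: is `object` a literal (default all IRIs)?
#' @param datatype XSD datatype CURIE for typed literals, `NA` for plain.
#' @return The store, invisibly.
#' @export
ts_add <- function(store, graph, subject, predicate, object,
                   literal = FALSE, datatype = NA_character_) {
  n <- max(length(subject), length(predicate), length(object))
  df <- data.frame(graph = graph,
                   subject = expand_iri(rep_len(subject, n), store$ns),
                   predicate = expand_iri(rep_len(predicate, n), store$ns),
                   object = rep_len(object, n),
                   literal = rep_len(literal, n),
                   datatype = rep_len(datatype, n))
  df$object[!df$literal] <- expand_iri(df$object[!df$literal], store$ns)
  df$datatype[!is.na(df$datatype)] <-
    expand_iri(df$datatype[!is.na(df$datatype)], store$ns)
  store$triples <- unique(rbind(store$triples, df))
  invisible(store)
}

ts_graph <- function(store, graph) {
  store$triples[store$triples$graph %in% graph, , drop = FALSE]
}

ts_size <- function(store, graph = NULL) {
  if (is.null(graph)) nrow(store$triples)
  else sum(store$triples$graph %in% graph)
}

ts_graphs <- function(store) sort(unique(store$triples$graph))

ts_drop_graph <- function(store, graph) {
  store$triples <- store$triples[!(store$triples$graph %in% graph), , drop = FALSE]
  invisible(store)
}

## Canonical triple key used for set comparisons.
triple_key <- function(df) {
  paste(df$subject, df$predicate, df$object, df$literal,
        ifelse(is.na(df$datatype), "", df$datatype), sep = "\r")
}

same_triple_set <- function(a, b) {
  setequal(triple_key(a), triple_key(b))
}

escape_lit <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub('"', '\\"', x, fixed = TRUE)
  x <- gsub("\n", "\\n", x, fixed = TRUE)
  x <- gsub("\r", "\\r", x, fixed = TRUE)
  gsub("\t", "\\t", x, fixed = TRUE)
}

unescape_lit <- function(x) {
  out <- character(length(x))
  for (i in seq_along(x)) {
    chars <- strsplit(x[i], "")[[1]]
    buf <- character(0); j <- 1L
    while (j <= length(chars)) {
      if (chars[j] == "\\" && j < length(chars)) {
        nxt <- chars[j + 1L]
        buf <- c(buf, switch(nxt, n = "\n", r = "\r", t = "\t", nxt))
        j <- j + 2L
      } else { buf <- c(buf, chars[j]); j <- j + 1L }
    }
    out[i] <- paste(buf, collapse = "")
  }
  out
}

render_term <- function(value, literal, datatype, ns) {
  literal <- rep_len(literal, length(value))
  datatype <- rep_len(datatype, length(value))
  out <- character(length(value))
  lit <- which(literal)
  iri <- which(!literal)
  if (length(lit)) {
    base <- paste0('"', escape_lit(value[lit]), '"')
    dt <- datatype[lit]
    typed <- !is.na(dt)
    base[typed] <- paste0(base[typed], "^^", compact_iri(dt[typed], ns))
    out[lit] <- base
  }
  if (length(iri)) {
    c_ <- compact_iri(value[iri], ns)
    raw <- !grepl("^[A-Za-z][A-Za-z0-9-]*:[A-Za-z0-9_.-]*$", c_) | c_ == value[iri]
    c_[raw] <- paste0("<", value[iri][raw], ">")
    out[iri] <- c_
  }
  out
}

#' Serialize one graph as Turtle
#'
#' Writes the documented Turtle subset: an `@prefix` header for every
#' namespace used, then one sorted triple per line. [read_turtle()] parses
#' exactly this subset back; together they round-trip triple sets.
#'
#' @param store a [triple_store()].
#' @param graph graph name to serialize.
#' @param path output file; with `NULL` the document is returned as a
#'   character vector of lines.
#' @return The lines, invisibly when written to a file.
#' @export
write_turtle <- function(store, graph, path = NULL) {
  df <- ts_graph(store, graph)
  ns <- store$ns
  lines <- c(paste0("@prefix ", names(ns), ": <", unname(ns), "> ."), "")
  if (nrow(df)) {
    s <- render_term(df$subject, FALSE, NA, ns)
    p <- render_term(df$predicate, FALSE, NA, ns)
    p[df$predicate == expand_iri("rdf:type", ns)] <- "a"
    o <- render_term(df$object, df$literal, df$datatype, ns)
    lines <- c(lines, sort(paste0(s, " ", p, " ", o, " .")))
  }
  if (is.null(path)) return(lines)
  writeLines(lines, path, useBytes = TRUE)
  invisible(lines)
}

parse_term <- function(tok, ns) {
  if (startsWith(tok, '"')) {
    m <- regexec('^"((?:[^"\\\\]|\\\\.)*)"(?:\\^\\^(.+))?$', tok)
    p <- regmatches(tok, m)[[1]]
    if (!length(p)) abort2(paste0("bad literal: ", tok), "ehr2omop_parse_error")
    dt <- if (nzchar(p[3])) expand_iri(p[3], ns) else NA_character_
    list(value = unescape_lit(p[2]), literal = TRUE, datatype = dt)
  } else if (startsWith(tok, "<")) {
    list(value = substr(tok, 2, nchar(tok) - 1L), literal = FALSE,
         datatype = NA_character_)
  } else {
    if (tok == "a") tok <- "rdf:type"
    list(value = expand_iri(tok, ns), literal = FALSE, datatype = NA_character_)
  }
}

## Split a triple/quad line into whitespace-separated terms, honouring
## quoted literals (which may contain escaped spaces/quotes).
tokenize_line <- function(line) {
  pat <- '("(?:[^"\\\\]|\\\\.)*"(?:\\^\\^\\S+)?|<[^>]*>|\\S+)'
  regmatches(line, gregexpr(pat, line, perl = TRUE))[[1]]
}

#' Parse a Turtle document written by [write_turtle()]
#'
#' @param path file path, or a character vector of lines.
#' @param store a [triple_store()] to load into.
#' @param graph graph name the triples are loaded into.
#' @return The store, invisibly.
#' @export
read_turtle <- function(path, store, graph) {
  lines <- if (length(path) == 1L && file.exists(path))
    readLines(path, warn = FALSE, encoding = "UTF-8") else path
  ns <- store$ns
  for (ln in lines) {
    ln <- trimws(ln)
    if (!nzchar(ln) || startsWith(ln, "#")) next
    if (startsWith(ln, "@prefix")) {
      m <- regexec("^@prefix\\s+([A-Za-z][A-Za-z0-9-]*):\\s+<([^>]*)>\\s*\\.$", ln)
      p <- regmatches(ln, m)[[1]]
      if (!length(p)) abort2(paste0("bad @prefix line: ", ln), "ehr2omop_parse_error")
      ns[p[2]] <- p[3]
      next
    }
    toks <- tokenize_line(ln)
    if (length(toks) != 4L || toks[4] != ".")
      abort2(paste0("unsupported Turtle construct: ", ln), "ehr2omop_parse_error")
    s <- parse_term(toks[1], ns); p <- parse_term(toks[2], ns)
    o <- parse_term(toks[3], ns)
    store$triples <- rbind(store$triples, data.frame(
      graph = graph, subject = s$value, predicate = p$value,
      object = o$value, literal = o$literal, datatype = o$datatype))
  }
  ts_register_ns(store, ns)
  store$triples <- unique(store$triples)
  invisible(store)
}

#' Persist / reload a whole dataset as N-Quads
#'
#' Graph names are carried as the fourth term under the store's dataset
#' namespace, so named-graph structure survives the round trip.
#'
#' @param store a [triple_store()].
#' @param path `.nq` file path.
#' @return `write_nquads`: the path; `read_nquads`: a new store.
#' @export
write_nquads <- function(store, path) {
  df <- store$triples
  term <- function(v) paste0("<", v, ">")
  obj <- ifelse(df$literal,
                paste0('"', escape_lit(df$object), '"',
                       ifelse(is.na(df$datatype), "",
                              paste0("^^<", df$datatype, ">"))),
                term(df$object))
  g <- paste0("<urn:ehr2omop:graph:", utils::URLencode(df$graph, reserved = TRUE), ">")
  lines <- sort(paste(term(df$subject), term(df$predicate), obj, g, "."))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_nquads
#' @param namespaces extra prefixes to register on the reloaded store.
#' @export
read_nquads <- function(path, namespaces = character(0)) {
  store <- triple_store(namespaces)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  rows <- lapply(lines[nzchar(trimws(lines))], function(ln) {
    toks <- tokenize_line(trimws(ln))
    if (length(toks) != 5L || toks[5] != ".")
      abort2(paste0("bad N-Quads line: ", ln), "ehr2omop_parse_error")
    s <- parse_term(toks[1], store$ns)
    p <- parse_term(toks[2], store$ns)
    o <- parse_term(toks[3], store$ns)
    g <- parse_term(toks[4], store$ns)$value
    data.frame(graph = utils::URLdecode(sub("^urn:ehr2omop:graph:", "", g)),
               subject = s$value, predicate = p$value, object = o$value,
               literal = o$literal, datatype = o$datatype)
  })
  store$triples <- unique(do.call(rbind, c(list(empty_triples()), rows)))
  store
}
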