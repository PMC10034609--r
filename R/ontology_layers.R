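## The three-layer ontology design. Layer 1 describes the archetyped
## concepts themselves (one class per entry, one property per element) and
## is standard-agnostic. Layer 2 maps each concept onto the EN/ISO 13606
## reference-model ontology (subclass of iso13606:Entry; properties typed
## by the RM data-value classes). Layer 3 maps concepts and properties
## onto an OMOP CDM ontology (table classes, column properties). Layers
## are kept in separate named graphs, each archetype in its own graph, so
## stripping layer 3 leaves a valid EN/ISO 13606-mapped ontology and
## stripping layers 2-3 leaves the bare concept ontology.
##
## Expressivity is deliberately limited to class/property declarations,
## domains/ranges, subclass axioms and annotation-style mapping axioms; the
## transformation pipeline reads the mappings, it does not reason over
## them.

RM_STRUCTURED <- c("CODED_TEXT", "QUANTITY", "IDENTIFIER")

rm_literal_range <- c(SIMPLE_TEXT = "xsd:string", DATE_TIME = "xsd:dateTime",
                      BOOLEAN = "xsd:boolean")

#' Build the packaged EN/ISO 13606 reference-model ontology
#'
#' Declares the entry/element backbone (`iso13606:Entry`,
#' `iso13606:Element`) and one class per reference-model data value
#' (`iso13606:CODED_TEXT`, `iso13606:QUANTITY`, ... all subclasses of
#' `iso13606:DataValue`) together with their component datatype
#' properties (`iso13606:code`, `iso13606:codeSystem`,
#' `iso13606:displayName`, `iso13606:magnitude`, `iso13606:units`,
#' `iso13606:idValue`, `iso13606:assigningScope`).
#'
#' @param store a [triple_store()]; the graph `"rm"` is (re)built in it.
#' @return The store, invisibly.
#' @export
build_rm_ontology <- function(store) {
  ts_drop_graph(store, "rm")
  g <- "rm"
  ts_add(store, g, c("iso13606:Entry", "iso13606:Element", "iso13606:DataValue"),
         "rdf:type", "owl:Class")
  ts_add(store, g, paste0("iso13606:", DV_KINDS), "rdf:type", "owl:Class")
  ts_add(store, g, paste0("iso13606:", DV_KINDS), "rdfs:subClassOf",
         "iso13606:DataValue")
  props <- c(code = "CODED_TEXT", codeSystem = "CODED_TEXT",
             displayName = "CODED_TEXT", magnitude = "QUANTITY",
             units = "QUANTITY", idValue = "IDENTIFIER",
             assigningScope = "IDENTIFIER")
  ts_add(store, g, paste0("iso13606:", names(props)), "rdf:type",
         "owl:DatatypeProperty")
  ts_add(store, g, paste0("iso13606:", names(props)), "rdfs:domain",
         paste0("iso13606:", unname(props)))
  invisible(store)
}

#' Build the packaged OMOP CDM ontology
#'
#' One `owl:Class` per supported CDM table and one `owl:DatatypeProperty`
#' per column (IRIs of the form `omop:<Table>.<column>`), each with its
#' table as `rdfs:domain` and a `omop:columnName` annotation carrying the
#' bare column name.
#'
#' @param store a [triple_store()]; the graph `"omop"` is (re)built.
#' @param schema CDM schema list from [omop_schema()].
#' @return The store, invisibly.
#' @export
build_omop_ontology <- function(store, schema = omop_schema()) {
  ts_drop_graph(store, "omop")
  g <- "omop"
  for (tab in names(schema)) {
    cls <- paste0("omop:", tab)
    ts_add(store, g, cls, "rdf:type", "owl:Class")
    cols <- schema[[tab]]$column
    prop <- paste0("omop:", tab, ".", cols)
    ts_add(store, g, prop, "rdf:type", "owl:DatatypeProperty")
    ts_add(store, g, prop, "rdfs:domain", cls)
    ts_add(store, g, prop, "omop:columnName", cols, literal = TRUE)
  }
  invisible(store)
}

concept_class_iri <- function(concept) {
  ns <- arch_ns(concept)
  cls <- gsub("[^A-Za-z0-9]+", "_", concept)
  cls <- paste0(toupper(substr(cls, 1, 1)), substr(cls, 2, nchar(cls)))
  paste0(unname(ns), cls)
}

element_prop_iri <- function(concept, node_id)
  paste0(unname(arch_ns(concept)), node_id)

#' Build the concept ontology of one archetype (layer 1)
#'
#' One class per entry and one property per element in the archetype's own
#' namespace. Each property carries the element's name as `rdfs:label` and
#' its reference-model value kind as an `e2o:valueKind` annotation; layer 1
#' itself contains no axiom tied to any exchange or analysis standard.
#'
#' @param store a [triple_store()].
#' @param archetype a parsed archetype.
#' @return The store, invisibly; the graph is named `layer1:<concept>`.
#' @export
build_concept_ontology <- function(store, archetype) {
  concept <- archetype_concept(archetype)
  ts_register_ns(store, arch_ns(concept))
  g <- paste0("layer1:", concept)
  ts_drop_graph(store, g)
  cls <- concept_class_iri(concept)
  ts_add(store, g, cls, "rdf:type", "owl:Class")
  ts_add(store, g, cls, "rdfs:label", archetype$entry$name, literal = TRUE)
  for (el in archetype$entry$elements) {
    prop <- element_prop_iri(concept, el$node_id)
    ts_add(store, g, prop, "rdf:type", "rdf:Property")
    ts_add(store, g, prop, "rdfs:domain", cls)
    ts_add(store, g, prop, "rdfs:label", el$name, literal = TRUE)
    ts_add(store, g, prop, "e2o:valueKind", el$kind, literal = TRUE)
    if (!is.null(el$terminology))
      ts_add(store, g, prop, "e2o:terminologyBinding", el$terminology,
             literal = TRUE)
  }
  invisible(store)
}

#' Map a concept ontology onto the reference model (layer 2)
#'
#' Asserts that the concept class is a subclass of `iso13606:Entry` (so it
#' inherits the entry semantics defined in the RM ontology) and types each
#' element property with its RM data-value class via `e2o:rmDataType`;
#' structured kinds additionally receive the RM class as `rdfs:range`,
#' scalar kinds their XSD literal datatype.
#'
#' @param store a [triple_store()] holding `layer1:<concept>` and `"rm"`.
#' @param archetype the archetype whose concept graph is being mapped.
#' @return The store, invisibly; the graph is named `layer2:<concept>`.
#' @export
build_rm_mapping <- function(store, archetype) {
  concept <- archetype_concept(archetype)
  l1 <- ts_graph(store, paste0("layer1:", concept))
  cls <- concept_class_iri(concept)
  if (!any(l1$subject == cls & l1$predicate == expand_iri("rdf:type", store$ns)))
    abort2(paste0("concept class missing from layer 1: ", cls),
           "ehr2omop_config_error")
  if (!ts_size(store, "rm"))
    abort2("reference-model ontology not loaded (run build_rm_ontology)",
           "ehr2omop_config_error")
  g <- paste0("layer2:", concept)
  ts_drop_graph(store, g)
  ts_add(store, g, cls, "rdfs:subClassOf", "iso13606:Entry")
  for (el in archetype$entry$elements) {
    prop <- element_prop_iri(concept, el$node_id)
    ts_add(store, g, prop, "e2o:rmDataType", paste0("iso13606:", el$kind))
    rng <- if (el$kind %in% RM_STRUCTURED) paste0("iso13606:", el$kind)
           else rm_literal_range[[el$kind]]
    ts_add(store, g, prop, "rdfs:range", rng)
  }
  invisible(store)
}

#' Load the archetype-to-OMOP mapping configuration
#'
#' The YAML reproduces the archetype/CDM-table correspondence and the
#' per-element column bindings, plus the derivation rules for the three
#' CDM tables with no archetype of their own (`Observation_period`,
#' `Death`, `Device_exposure`) and the `Procedure_occurrence` toggle.
#'
#' @param path YAML path; defaults to the packaged configuration.
#' @return A list with `concepts` (per-concept `omop_table`, `key_element`,
#'   `columns`, optional `drug_type_concept_id`) and `derived` rules.
#' @export
omop_mapping_config <- function(path = ehr2omop_extdata("mappings", "omop_mapping.yaml")) {
  yaml::read_yaml(path)
}

#' Map a concept ontology onto the OMOP CDM ontology (layer 3)
#'
#' Adds `omop:mapsToTable` from the concept class to its CDM table class
#' and `omop:mapsToColumn` from each mapped element property to the CDM
#' column property (one axiom per target column; an element may feed more
#' than one column, e.g. a quantity's magnitude and units). Every target
#' must exist in the packaged OMOP ontology.
#'
#' @param store a [triple_store()] holding `layer1:<concept>` and `"omop"`.
#' @param archetype the archetype being mapped.
#' @param concept_cfg this concept's entry from [omop_mapping_config()]
#'   (`omop_table` plus `columns`).
#' @return The store, invisibly; the graph is named `layer3:<concept>`.
#' @export
build_omop_mapping <- function(store, archetype, concept_cfg) {
  concept <- archetype_concept(archetype)
  tab <- concept_cfg$omop_table
  if (!ts_size(store, "omop"))
    abort2("OMOP ontology not loaded (run build_omop_ontology)",
           "ehr2omop_config_error")
  omop_props <- ts_graph(store, "omop")
  declared <- omop_props$subject[omop_props$predicate ==
                                   expand_iri("rdf:type", store$ns)]
  cls_target <- expand_iri(paste0("omop:", tab), store$ns)
  if (!cls_target %in% declared)
    abort2(paste0("OMOP ontology has no table class ", tab),
           "ehr2omop_validation_error")
  targets <- unlist(lapply(names(concept_cfg$columns), function(nid)
    setNames(as.list(concept_cfg$columns[[nid]]),
             rep(nid, length(concept_cfg$columns[[nid]])))))
  bad <- character(0)
  for (i in seq_along(targets)) {
    p <- expand_iri(paste0("omop:", tab, ".", targets[[i]]), store$ns)
    if (!p %in% declared) bad <- c(bad, paste0(tab, ".", targets[[i]]))
  }
  if (length(bad))
    abort2(paste0("mapping names column(s) absent from the OMOP ontology: ",
                  paste(unique(bad), collapse = ", ")),
           "ehr2omop_validation_error")
  g <- paste0("layer3:", concept)
  ts_drop_graph(store, g)
  ts_add(store, g, concept_class_iri(concept), "omop:mapsToTable",
         paste0("omop:", tab))
  node_ids <- vapply(archetype$entry$elements, `[[`, "", "node_id")
  for (i in seq_along(targets)) {
    nid <- names(targets)[i]
    if (!nid %in% node_ids)
      abort2(paste0("OMOP mapping binds unknown element ", nid, " of ",
                    concept), "ehr2omop_config_error")
    ts_add(store, g, element_prop_iri(concept, nid), "omop:mapsToColumn",
           paste0("omop:", tab, ".", targets[[i]]))
  }
  invisible(store)
}

#' Build all ontology layers for an archetype library
#'
#' Runs [build_rm_ontology()], [build_omop_ontology()], and for every
#' archetype [build_concept_ontology()], [build_rm_mapping()] and — where
#' the mapping configuration covers the concept — [build_omop_mapping()].
#'
#' @param library an [archetype_library()].
#' @param config an [omop_mapping_config()].
#' @param store optionally, an existing store to build into.
#' @return The populated [triple_store()].
#' @examples
#' st <- build_ontologies(archetype_library())
#' st
#' @export
build_ontologies <- function(library = archetype_library(),
                             config = omop_mapping_config(),
                             store = triple_store()) {
  build_rm_ontology(store)
  build_omop_ontology(store)
  for (a in library) {
    build_concept_ontology(store, a)
    build_rm_mapping(store, a)
    concept <- archetype_concept(a)
    if (!is.null(config$concepts[[concept]]))
      build_omop_mapping(store, a, config$concepts[[concept]])
  }
  store
}

#' Write every schema graph of a store as Turtle files
#'
#' @param store a [triple_store()].
#' @param out_dir output directory; one `.ttl` per graph (layer graphs,
#'   `rm.ttl`, `omop.ttl`), instance graphs excluded.
#' @return Paths written, invisibly.
#' @export
write_ontology_dir <- function(store, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  gs <- setdiff(ts_graphs(store), "instances")
  paths <- vapply(gs, function(g) {
    p <- file.path(out_dir, paste0(gsub(":", "_", g), ".ttl"))
    write_turtle(store, g, p)
    p
  }, character(1))
  invisible(unname(paths))
}
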