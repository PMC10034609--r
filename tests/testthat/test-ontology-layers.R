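lib <- archetype_library()
store <- build_ontologies(lib)
RDF_TYPE <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#type"
ISO <- "https://w3id.org/ehr2omop/iso13606#"
OMOP <- "https://w3id.org/ehr2omop/omop#"

concept_classes <- function(g) {
  g$subject[g$predicate == RDF_TYPE &
              g$object == "http://www.w3.org/2002/07/owl#Class"]
}

test_that("layer 1 has one class per entry and one property per element", {
  for (a in lib) {
    concept <- sub("^CEN-EN13606-ENTRY\\.([a-z0-9_]+)\\.v.*$", "\\1",
                   a$archetype_id)
    g <- ehr2omop:::ts_graph(store, paste0("layer1:", concept))
    expect_length(concept_classes(g), 1L)
    props <- g$subject[g$predicate == RDF_TYPE &
                         g$object == "http://www.w3.org/1999/02/22-rdf-syntax-ns#Property"]
    expect_length(props, length(a$entry$elements))
  }
  g <- ehr2omop:::ts_graph(store, "layer1:diagnosis")
  props <- sub("^.*#", "", g$subject[g$predicate ==
                                       "https://w3id.org/ehr2omop/core#valueKind"])
  expect_setequal(props, c("diagnosis", "diagnosis_id", "episode_id",
                           "diagnosis_datetime", "source", "patient_id"))
})

test_that("layer 2 subclasses every concept under iso13606:Entry, exactly once", {
  subclass <- "http://www.w3.org/2000/01/rdf-schema#subClassOf"
  for (a in lib) {
    concept <- sub("^CEN-EN13606-ENTRY\\.([a-z0-9_]+)\\.v.*$", "\\1",
                   a$archetype_id)
    g2 <- ehr2omop:::ts_graph(store, paste0("layer2:", concept))
    sup <- g2$object[g2$predicate == subclass]
    expect_identical(sup, paste0(ISO, "Entry"))
    # every element property typed by exactly one RM data-value class
    rmdt <- g2[g2$predicate == "https://w3id.org/ehr2omop/core#rmDataType", ]
    expect_identical(nrow(rmdt), length(a$entry$elements))
    expect_identical(anyDuplicated(rmdt$subject), 0L)
    expect_true(all(rmdt$object %in% paste0(ISO, ehr2omop:::DV_KINDS)))
  }
})

test_that("layer 3 maps diagnosis onto Condition_occurrence", {
  g3 <- ehr2omop:::ts_graph(store, "layer3:diagnosis")
  mt <- g3[g3$predicate == paste0(OMOP, "mapsToTable"), ]
  expect_identical(mt$object, paste0(OMOP, "Condition_occurrence"))
  mc <- g3[g3$predicate == paste0(OMOP, "mapsToColumn"), ]
  expect_true(paste0(OMOP, "Condition_occurrence.condition_source_value") %in%
                mc$object[grepl("#diagnosis$", mc$subject)])
})

test_that("every mapped (table, column) pair exists in the packaged OMOP schema", {
  mc <- store$triples[store$triples$predicate == paste0(OMOP, "mapsToColumn"), ]
  expect_gt(nrow(mc), 40L)
  schema <- omop_schema()
  for (target in mc$object) {
    tc <- sub(paste0("^", OMOP), "", target)
    tab <- sub("\\..*$", "", tc)
    col <- sub("^[^.]+\\.", "", tc)
    expect_true(col %in% schema[[tab]]$column, info = target)
  }
})

test_that("no concept class is mapped to more than one OMOP table", {
  mt <- store$triples[store$triples$predicate == paste0(OMOP, "mapsToTable"), ]
  expect_identical(anyDuplicated(mt$subject), 0L)
})

test_that("a mapping naming an unknown column or table is rejected with the offenders listed", {
  a <- lib$`CEN-EN13606-ENTRY.diagnosis.v1`
  bad <- list(omop_table = "Condition_occurrence",
              columns = list(diagnosis = "no_such_column"))
  expect_error(build_omop_mapping(store, a, bad),
               "Condition_occurrence.no_such_column")
  # restore the graph clobbered by the failed call above
  build_omop_mapping(store, a, omop_mapping_config()$concepts$diagnosis)
  expect_error(build_omop_mapping(store, a, list(omop_table = "Nope",
                                                 columns = list())),
               "no table class")
})

test_that("layers separate cleanly: lower layers never reference higher standards", {
  l1 <- store$triples[startsWith(store$triples$graph, "layer1:"), ]
  vals <- c(l1$predicate, l1$object[!l1$literal])
  expect_false(any(startsWith(vals, ISO)))
  expect_false(any(startsWith(vals, OMOP)))
  l2 <- store$triples[startsWith(store$triples$graph, "layer2:"), ]
  expect_false(any(startsWith(c(l2$predicate, l2$object[!l2$literal]), OMOP)))
  # schema graphs carry no instance data
  schema_graphs <- setdiff(ehr2omop:::ts_graphs(store), "instances")
  sg <- store$triples[store$triples$graph %in% schema_graphs, ]
  expect_false(any(startsWith(sg$subject, "https://w3id.org/ehr2omop/instance#")))
})

test_that("every layer graph round-trips through Turtle", {
  for (g in ehr2omop:::ts_graphs(store)) {
    lines <- write_turtle(store, g)
    ts2 <- triple_store(ehr2omop:::arch_ns(sub("^layer[0-9]:", "", g)))
    read_turtle(lines, ts2, g)
    expect_true(ehr2omop:::same_triple_set(ehr2omop:::ts_graph(store, g),
                                           ehr2omop:::ts_graph(ts2, g)),
                info = g)
  }
})
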