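lib <- archetype_library()
ISO <- "https://w3id.org/ehr2omop/iso13606#"
RDF_TYPE <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#type"

fresh_store <- function() build_ontologies(lib)

glaucoma_extract <- function() {
  built <- build_extracts(glaucoma_source(), mapping_specs()$diagnosis,
                          lib$`CEN-EN13606-ENTRY.diagnosis.v1`)
  assemble_extracts(built$entries)[[1]]
}

test_that("a diagnosis extract loads as one typed instance with its coded value", {
  store <- fresh_store()
  batch <- load_extract(glaucoma_extract(), store, lib)
  expect_identical(batch$n_loaded, 1L)
  inst <- ehr2omop:::ts_graph(store, "instances")
  typed <- inst$subject[inst$predicate == RDF_TYPE &
    inst$object == "https://w3id.org/ehr2omop/archetype/diagnosis#Diagnosis"]
  expect_length(typed, 1L)
  codes <- inst$object[inst$predicate == paste0(ISO, "code")]
  expect_identical(codes, "H40.9")
  systems <- inst$object[inst$predicate == paste0(ISO, "codeSystem")]
  expect_true("ICD-10-CM" %in% systems)
})

test_that("loading zero extracts leaves the store untouched and reloads are idempotent", {
  store <- fresh_store()
  n0 <- nrow(store$triples)
  s <- load_extract_dir(file.path(tempdir(), "no-extracts-here"), store, lib)
  expect_identical(nrow(s), 0L)
  expect_identical(nrow(store$triples), n0)

  x <- glaucoma_extract()
  b1 <- load_extract(x, store, lib)
  n1 <- nrow(store$triples)
  b2 <- load_extract(x, store, lib)
  expect_identical(b2$n_loaded, 0L)
  expect_identical(b2$n_skipped, 1L)
  expect_identical(nrow(store$triples), n1)
})

test_that("triple growth equals the per-entry accounting on generated batches", {
  res <- e2e_run("small")
  store <- fresh_store()
  files <- list.files(res$paths$extracts, pattern = "\\.xml$",
                      recursive = TRUE, full.names = TRUE)
  set.seed(5)
  for (f in sample(files, 40)) {
    x <- parse_extract(f)
    expected <- sum(vapply(x$entries, oracle_entry_triples, 0L))
    batch <- load_extract(x, store, lib)
    expect_identical(batch$triples_added, expected, info = basename(f))
    expect_identical(batch$n_loaded, length(x$entries))
  }
})

test_that("invalid extracts are rejected atomically and unknown concepts refuse to load", {
  store <- fresh_store()
  x <- glaucoma_extract()
  x$entries[[1]]$values$diagnosis <- NULL
  n0 <- nrow(store$triples)
  expect_error(load_extract(x, store, lib), "does not validate")
  expect_identical(nrow(store$triples), n0)

  # archetype known to the library but without a built concept ontology
  partial <- triple_store()
  build_rm_ontology(partial); build_omop_ontology(partial)
  expect_error(load_extract(glaucoma_extract(), partial, lib),
               "no concept ontology")
  expect_identical(ehr2omop:::ts_size(partial, "instances"), 0L)
})

test_that("every loaded instance is typed by a subclass of iso13606:Entry and literals match their kinds", {
  res <- e2e_run("small")
  store <- res$store
  inst <- ehr2omop:::ts_graph(store, "instances")
  sub_of_entry <- store$triples$subject[
    store$triples$predicate == "http://www.w3.org/2000/01/rdf-schema#subClassOf" &
      store$triples$object == paste0(ISO, "Entry")]
  types <- inst$object[inst$predicate == RDF_TYPE]
  arch_types <- types[startsWith(types, "https://w3id.org/ehr2omop/archetype/")]
  expect_gt(length(arch_types), 100L)
  expect_true(all(arch_types %in% sub_of_entry))

  # literal datatype must follow the declared element kind
  kind_by_prop <- with(
    store$triples[store$triples$predicate ==
                    "https://w3id.org/ehr2omop/core#valueKind", ],
    setNames(object, subject))
  lits <- inst[inst$literal &
                 startsWith(inst$predicate,
                            "https://w3id.org/ehr2omop/archetype/"), ]
  expected_dt <- c(SIMPLE_TEXT = "http://www.w3.org/2001/XMLSchema#string",
                   DATE_TIME = "http://www.w3.org/2001/XMLSchema#dateTime",
                   BOOLEAN = "http://www.w3.org/2001/XMLSchema#boolean")
  expect_gt(nrow(lits), 100L)
  expect_true(all(lits$datatype == expected_dt[kind_by_prop[lits$predicate]]))
})

test_that("entries in validated extracts equal instances created, per archetype", {
  res <- e2e_run("small")
  for (concept in names(res$extract_counts))
    expect_identical(count_instances(res$store, concept),
                     res$extract_counts[[concept]]$entries, info = concept)
})
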