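test_that("the packaged library holds the twelve entry-level concepts and validates", {
  lib <- archetype_library()
  expect_length(lib, 12L)
  concepts <- sort(sub("^CEN-EN13606-ENTRY\\.([a-z0-9_]+)\\.v[0-9]+$", "\\1",
                       names(lib)))
  expect_identical(concepts, sort(c(
    "diagnosis", "episodes", "limitation_life_sustaining_treatment",
    "administered_medication", "cumulative_drug_dose",
    "prescribed_medication", "movements_between_units",
    "clinical_observations", "laboratory_observations", "patients",
    "health_problems", "procedures")))
  expect_identical(nrow(validate_library(lib)), 0L)
})

test_that("the diagnosis entry carries its six documented elements", {
  a <- archetype_library()[["CEN-EN13606-ENTRY.diagnosis.v1"]]
  node_ids <- vapply(a$entry$elements, `[[`, "", "node_id")
  expect_length(node_ids, 6L)
  expect_setequal(node_ids, c("episode_id", "diagnosis", "diagnosis_datetime",
                              "patient_id", "diagnosis_id", "source"))
  dx <- a$entry$elements[[which(node_ids == "diagnosis")]]
  expect_identical(dx$kind, "CODED_TEXT")
  expect_identical(dx$terminology, "ICD-10-CM")
})

test_that("parse -> serialize -> parse is the identity on every fixture", {
  for (a in archetype_library()) {
    rt <- parse_archetype(serialize_archetype(a))
    expect_identical(rt, a, info = a$archetype_id)
  }
})

test_that("terminology bindings only occur on coded elements", {
  for (a in archetype_library())
    for (el in a$entry$elements)
      if (!is.null(el$terminology))
        expect_identical(el$kind, "CODED_TEXT",
                         info = paste(a$archetype_id, el$node_id))
})

test_that("malformed definitions are rejected with the offending field named", {
  minimal <- function(extra = "", elements = NULL) {
    els <- elements %||% "    - {node_id: x, kind: SIMPLE_TEXT}"
    paste0("archetype_id: CEN-EN13606-ENTRY.test.v1\nversion: '1'\n",
           "language: en\n", extra, "entry:\n  name: Test\n  elements:\n",
           els, "\n")
  }
  `%||%` <- function(a, b) if (is.null(a)) b else a
  a <- parse_archetype(minimal())
  expect_length(a$entry$elements, 1L)
  expect_true(a$entry$elements[[1]]$mandatory)

  expect_error(parse_archetype(minimal(extra = "bogus_field: 1\n")),
               "bogus_field")
  expect_error(parse_archetype(minimal(elements = paste0(
    "    - {node_id: x, kind: SIMPLE_TEXT}\n",
    "    - {node_id: x, kind: SIMPLE_TEXT}"))), "duplicate")
  expect_error(parse_archetype(minimal(elements =
    "    - {node_id: x, kind: NOT_A_KIND}")), "kind")
  expect_error(parse_archetype("archetype_id: [unbalanced"), "YAML")
  expect_error(parse_archetype(sub("CEN-EN13606-ENTRY.test.v1",
                                   "bad id", minimal())), "pattern")
})

test_that("validation pinpoints a corrupted fixture and duplicate ids", {
  lib <- archetype_library()
  # mutate one archetype: drop the kind of one element
  mutant <- lib[["CEN-EN13606-ENTRY.diagnosis.v1"]]
  mutant$entry$elements[[2]]$kind <- "CORRUPTED"
  broken <- structure(c(lib[setdiff(names(lib), mutant$archetype_id)],
                        setNames(list(mutant), mutant$archetype_id)),
                      class = "archetype_library")
  rep <- validate_library(broken)
  expect_true(any(rep$violation == "unknown data-value kind" &
                    rep$path == "entry.elements.diagnosis"))
  expect_true(all(rep$archetype_id == mutant$archetype_id))

  dup <- structure(list(lib[[1]], lib[[1]]),
                   class = "archetype_library")
  rep2 <- validate_library(dup)
  expect_identical(sum(rep2$violation == "duplicate archetype_id"), 1L)
})
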