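test_that("pseudonyms are deterministic, salted, integer-rendered and collision-free at scale", {
  expect_identical(pseudonymize("patient:PAT00001", "s"),
                   pseudonymize("patient:PAT00001", "s"))
  expect_false(pseudonymize("patient:PAT00001", "s1") ==
                 pseudonymize("patient:PAT00001", "s2"))
  expect_error(pseudonymize("x", ""), "salt")
  expect_error(pseudonymize("", "s"), "identifier")
  ids <- sprintf("patient:PAT%05d", 1:10000)
  ps <- pseudonymize(ids, "collision-scan-salt")
  expect_true(all(grepl("^[0-9]+$", ps)))
  expect_identical(anyDuplicated(ps), 0L)
})

test_that("an empty store still emits the ten tables as header-only CSVs", {
  store <- build_ontologies()
  out <- file.path(tempdir(), "empty-export")
  res <- export_all(store, out, salt = "s")
  tables <- sub("\\.csv$", "",
                setdiff(list.files(out, pattern = "\\.csv$"),
                        "integrity_report.csv"))
  expect_setequal(tables, c("Condition_occurrence", "Death", "Device_exposure",
                            "Drug_exposure", "Measurement", "Observation",
                            "Observation_period", "Person", "Visit_detail",
                            "Visit_occurrence"))
  for (tab in tables) {
    df <- read_omop_csv(list(paths = list(omop = out)), tab)
    expect_identical(nrow(df), 0L)
    expect_identical(names(df), omop_schema(tab)$column)
  }
  expect_identical(nrow(res$integrity), 0L)
})

test_that("the Person query projects every column and returns one row per patient instance", {
  res <- e2e_run("small")
  q <- generate_query("Person", res$store)
  expect_identical(q$columns, omop_schema("Person")$column)
  for (col in omop_schema("Person")$column)
    expect_match(q$sparql, paste0("\\?", col, "\\b"))
  expect_match(q$sparql, "iso13606:idValue")
  raw <- execute_query(q, res$store)
  expect_identical(nrow(raw), count_instances(res$store, "patients"))
  expect_error(generate_query("Persona", res$store), "Visit_occurrence")
})

test_that("exported tables conserve instances, respect referential integrity and carry CDM conventions", {
  res <- e2e_run("small")
  m <- res$export$manifest
  cons <- m$conservation
  for (x in cons)
    expect_identical(x$instances, x$exported_rows + x$excluded_rows,
                     info = x$concept)
  tabs <- res$export$tables
  drug_expected <- sum(vapply(cons, function(x)
    if (x$omop_table == "Drug_exposure") x$exported_rows else 0L, 0L))
  expect_identical(nrow(tabs$Drug_exposure), drug_expected)
  meas_expected <- sum(vapply(cons, function(x)
    if (x$omop_table == "Measurement") x$exported_rows else 0L, 0L))
  expect_identical(nrow(tabs$Measurement), meas_expected)
  expect_identical(nrow(res$export$integrity), 0L)
  expect_identical(nrow(tabs$Person), res$source_manifest$counts$patients)
  expect_identical(nrow(tabs$Observation_period),
                   res$source_manifest$counts$patients)
  expect_identical(nrow(tabs$Death), res$source_manifest$deaths)
  expect_true(all(tabs$Visit_occurrence$person_id %in% tabs$Person$person_id))
  expect_true(all(tabs$Visit_detail$visit_occurrence_id %in%
                    tabs$Visit_occurrence$visit_occurrence_id))
  # the three drug archetypes are discriminated by exposure type
  expect_setequal(unique(tabs$Drug_exposure$drug_type_concept_id),
                  c("32818", "32838", "32880"))
  # unresolved standard concepts are 0, never blank
  expect_true(all(tabs$Condition_occurrence$condition_concept_id == "0"))
})

test_that("re-export from the same store and salt is byte-identical", {
  res <- e2e_run("small")
  out2 <- file.path(tempdir(), "re-export")
  export_all(res$store, out2, salt = "unit-salt")
  for (f in list.files(res$paths$omop, pattern = "\\.csv$")) {
    a <- file.path(res$paths$omop, f); b <- file.path(out2, f)
    expect_identical(readBin(a, "raw", file.size(a)),
                     readBin(b, "raw", file.size(b)), info = f)
  }
})

test_that("no source identifier survives into any exported CSV", {
  res <- e2e_run("small")
  src_ids <- grep("^(PAT|EP|DG|RX|AD|MV|CO|LB|PR|LL)[0-9]+$",
                  unlist(lapply(read_source_dir(res$paths$source),
                                function(df) unlist(df, use.names = FALSE))),
                  value = TRUE)
  expect_gt(length(src_ids), 100L)
  for (f in list.files(res$paths$omop, pattern = "\\.csv$", full.names = TRUE)) {
    txt <- paste(readLines(f, warn = FALSE), collapse = "\n")
    hits <- vapply(unique(src_ids), function(id) grepl(id, txt, fixed = TRUE),
                   TRUE)
    expect_false(any(hits), info = basename(f))
  }
})

test_that("device-flagged procedures feed Device_exposure and the rest are logged exclusions", {
  res <- e2e_run("small")
  m <- res$export$manifest
  proc <- Filter(function(x) x$concept == "procedures", m$conservation)[[1]]
  expect_identical(proc$omop_table, "Device_exposure")
  expect_identical(proc$exported_rows, m$derived$Device_exposure)
  if (proc$excluded_rows > 0) {
    excl <- Filter(function(x) x$concept == "procedures", m$exclusions)[[1]]
    expect_identical(excl$rows, proc$excluded_rows)
  }
  dev <- res$export$tables$Device_exposure
  if (nrow(dev))
    expect_true(all(dev$device_source_value %in% c("392230005", "447365002")))
})
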