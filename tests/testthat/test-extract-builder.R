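lib <- archetype_library()
specs <- mapping_specs()

test_that("a source row with the local glaucoma code becomes a normalized diagnosis entry", {
  src <- glaucoma_source()
  built <- build_extracts(src, specs$diagnosis, lib$`CEN-EN13606-ENTRY.diagnosis.v1`)
  expect_length(built$entries, 1L)
  expect_identical(nrow(built$quarantine), 0L)
  en <- built$entries[[1]]
  expect_identical(en$values$diagnosis$code, "H40.9")
  expect_identical(en$values$diagnosis$code_system, "ICD-10-CM")
  expect_identical(en$values$diagnosis_datetime$value, "2021-03-01T10:30:00+01:00")
  expect_identical(en$values$episode_id$id, "EP990001")

  x <- assemble_extracts(built$entries)[[1]]
  doc <- serialize_extract(x)
  el <- xml2::xml_find_first(doc, "//*[local-name()='element'][@node_id='diagnosis']")
  expect_identical(xml2::xml_attr(el, "code"), "H40.9")
  expect_identical(xml2::xml_attr(el, "code_system"), "ICD-10-CM")
  expect_identical(nrow(validate_extract(doc, lib)), 0L)
})

test_that("an empty source table yields zero entries and an empty quarantine", {
  src <- empty_source_tables()
  built <- build_extracts(src, specs$diagnosis, lib$`CEN-EN13606-ENTRY.diagnosis.v1`)
  expect_length(built$entries, 0L)
  expect_identical(nrow(built$quarantine), 0L)
  expect_length(assemble_extracts(built$entries), 0L)
})

test_that("record conservation holds: rows = entries + quarantined, with reasons", {
  src <- glaucoma_source()
  bad1 <- src$diagnoses[1, ]; bad1$diagnosis_code <- ""      # mandatory empty
  bad2 <- src$diagnoses[1, ]; bad2$recorded_at <- "garbage"  # unparseable
  bad1$diagnosis_id <- "DG9900002"; bad2$diagnosis_id <- "DG9900003"
  src$diagnoses <- rbind(src$diagnoses, bad1, bad2)
  built <- build_extracts(src, specs$diagnosis, lib$`CEN-EN13606-ENTRY.diagnosis.v1`)
  expect_identical(length(built$entries) + nrow(built$quarantine),
                   nrow(src$diagnoses))
  expect_setequal(built$quarantine$element, c("diagnosis", "diagnosis_datetime"))

  # and across every archetype pipeline on generated data
  res <- e2e_run("small")
  counts <- res$source_manifest$counts
  for (concept in names(specs)) {
    got <- res$extract_counts[[concept]]
    expect_identical(got$entries + got$quarantined,
                     counts[[specs[[concept]]$source_table]],
                     info = concept)
  }
})

test_that("a mapping referencing a missing column fails before any row is processed", {
  broken <- specs$diagnosis
  broken$elements$diagnosis$column <- "no_such_column"
  expect_error(
    build_extracts(glaucoma_source(), broken,
                   lib$`CEN-EN13606-ENTRY.diagnosis.v1`),
    "no_such_column")
})

test_that("serialize -> parse round-trips every extract of a generated run", {
  res <- e2e_run("small")
  files <- list.files(res$paths$extracts, pattern = "\\.xml$",
                      recursive = TRUE, full.names = TRUE)
  expect_gt(length(files), 50L)
  for (f in files) {
    x <- parse_extract(f)
    doc2 <- serialize_extract(x)
    expect_identical(parse_extract(doc2), x, info = basename(f))
  }
})

test_that("optional elements absent from the source are omitted from the XML", {
  src <- glaucoma_source()
  src$diagnoses$source <- ""
  built <- build_extracts(src, specs$diagnosis, lib$`CEN-EN13606-ENTRY.diagnosis.v1`)
  doc <- serialize_extract(assemble_extracts(built$entries)[[1]])
  expect_length(
    xml2::xml_find_all(doc, "//*[local-name()='element'][@node_id='source']"),
    0L)
  expect_identical(nrow(validate_extract(doc, lib)), 0L)
})

test_that("removing a mandatory element is reported with its node path", {
  src <- glaucoma_source()
  built <- build_extracts(src, specs$diagnosis, lib$`CEN-EN13606-ENTRY.diagnosis.v1`)
  x <- assemble_extracts(built$entries)[[1]]
  x$entries[[1]]$values$diagnosis <- NULL
  rep <- validate_extract(x, lib)
  expect_identical(nrow(rep), 1L)
  expect_identical(rep$violation, "mandatory element missing")
  expect_match(rep$path, "diagnosis\\.v1/diagnosis$")

  x$archetype_id <- "CEN-EN13606-ENTRY.nonexistent.v1"
  rep2 <- validate_extract(x, lib)
  expect_true(any(grepl("unknown archetype", rep2$violation)))
})

test_that("rebuilding from the same source yields byte-identical XML", {
  src_dir <- write_source_dir(glaucoma_source(),
                              file.path(tempdir(), "idem-src"))
  src <- read_source_dir(src_dir)
  out1 <- file.path(tempdir(), "idem1"); out2 <- file.path(tempdir(), "idem2")
  for (out in c(out1, out2))
    write_extracts(src, specs$diagnosis,
                   lib$`CEN-EN13606-ENTRY.diagnosis.v1`, out)
  f1 <- list.files(out1, recursive = TRUE, full.names = TRUE)
  f2 <- list.files(out2, recursive = TRUE, full.names = TRUE)
  expect_identical(basename(f1), basename(f2))
  for (i in seq_along(f1))
    expect_identical(readBin(f1[i], "raw", file.size(f1[i])),
                     readBin(f2[i], "raw", file.size(f2[i])))
})
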