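test_that("the same seed reproduces byte-identical source files", {
  d1 <- file.path(tempdir(), "gen-a"); d2 <- file.path(tempdir(), "gen-b")
  cfg <- synth_config(seed = 123L, n_patients = 6L)
  generate_synthetic_source(cfg, d1)
  generate_synthetic_source(cfg, d2)
  f1 <- sort(list.files(d1, full.names = TRUE))
  f2 <- sort(list.files(d2, full.names = TRUE))
  expect_identical(basename(f1), basename(f2))
  for (i in seq_along(f1))
    expect_identical(readBin(f1[i], "raw", file.size(f1[i])),
                     readBin(f2[i], "raw", file.size(f2[i])))
  # and a different seed does not
  generate_synthetic_source(synth_config(seed = 124L, n_patients = 6L), d2)
  same <- vapply(basename(f1), function(nm) {
    a <- file.path(d1, nm); b <- file.path(d2, nm)
    identical(readBin(a, "raw", file.size(a)), readBin(b, "raw", file.size(b)))
  }, TRUE)
  expect_false(all(same))
})

test_that("manifest counts equal actual CSV row counts for every entity", {
  d <- file.path(tempdir(), "gen-counts")
  gen <- generate_synthetic_source(synth_config(seed = 9L, n_patients = 7L), d)
  for (nm in names(gen$manifest$counts)) {
    df <- read.csv(file.path(d, paste0(nm, ".csv")), colClasses = "character")
    expect_identical(nrow(df), gen$manifest$counts[[nm]], info = nm)
  }
})

test_that("every foreign key resolves and cumulative doses are running sums", {
  gen <- generate_synthetic_source(synth_config(seed = 31L, n_patients = 10L))
  t <- gen$tables
  expect_true(all(t$episodes$patient_id %in% t$patients$patient_id))
  for (nm in c("diagnoses", "drug_prescriptions", "drug_administrations",
               "movements", "clinical_observations",
               "laboratory_observations", "procedures", "llst")) {
    expect_true(all(t[[nm]]$episode_id %in% t$episodes$episode_id), info = nm)
    expect_true(all(t[[nm]]$patient_id %in% t$patients$patient_id), info = nm)
  }
  ad <- t$drug_administrations
  for (key in unique(paste(ad$patient_id, ad$drug_code))) {
    sel <- paste(ad$patient_id, ad$drug_code) == key
    grp <- ad[sel, ][order(ad$administered_at[sel], ad$administration_id[sel]), ]
    expect_equal(as.numeric(grp$cumulative_dose), cumsum(as.numeric(grp$dose)),
                 info = key)
  }
})

test_that("generated entities cover every archetype pipeline in the mapping specs", {
  gen <- generate_synthetic_source(synth_config(seed = 2L, n_patients = 2L))
  needed <- vapply(mapping_specs(), `[[`, "", "source_table")
  expect_true(all(needed %in% names(gen$tables)))
})

test_that("invalid generator configurations are rejected before writing", {
  expect_error(synth_config(n_patients = 0), "non-negative")
  expect_error(synth_config(diagnosis_rate = -1), "non-negative")
  expect_error(synth_config(death_prob = 1.5), "non-negative")
  expect_error(synth_config(window_start = "2022-01-01",
                            window_end = "2021-01-01"), "window")
})
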