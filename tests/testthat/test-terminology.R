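test_that("local diagnosis codes bind to ICD-10-CM with readable displays", {
  cm <- concept_map()
  dv <- bind_code("D003", "HIS-DIAG", cm)
  expect_identical(dv$code, "H40.9")
  expect_identical(dv$code_system, "ICD-10-CM")
  expect_identical(dv$display, "unspecified glaucoma")
  expect_error(bind_code("", "HIS-DIAG", cm), "empty local_code")
})

test_that("codes already in a target system pass through; unmapped codes are preserved and reported", {
  cm <- concept_map()
  idt <- bind_code("H40.9", "ICD-10-CM", cm)
  expect_identical(idt$code, "H40.9")
  expect_identical(idt$code_system, "ICD-10-CM")

  rep <- new_binding_report()
  miss <- bind_code("ZZZ9", "HIS-DIAG", cm, rep)
  expect_identical(miss$code, "ZZZ9")
  expect_identical(miss$code_system, "local")
  df <- binding_report_df(rep)
  expect_identical(nrow(df), 1L)
  expect_identical(df$code, "ZZZ9")
})

test_that("unmapped report size equals the set difference between source and table codes", {
  cm <- concept_map()
  known <- cm$table$local_code[cm$table$local_system == "HIS-DIAG"]
  set.seed(11)
  for (rep_i in 1:5) {
    source_codes <- sample(c(known, paste0("X", 1:40)), 60, replace = TRUE)
    rep <- new_binding_report()
    for (code in source_codes) bind_code(code, "HIS-DIAG", cm, rep)
    expected <- sum(!(source_codes %in% known))  # multiset difference
    expect_identical(nrow(binding_report_df(rep)), as.integer(expected))
  }
})

test_that("mapping tables must be one-to-one and use known target systems", {
  dup <- data.frame(local_code = c("A", "A"), local_system = "S",
                    target_code = c("1", "2"), target_system = "LOINC",
                    display = "x")
  f <- tempfile(fileext = ".csv")
  write.csv(dup, f, row.names = FALSE)
  expect_error(concept_map(f), "one-to-one")
  bad <- dup[1, ]; bad$target_system <- "READ-V2"
  write.csv(bad, f, row.names = FALSE)
  expect_error(concept_map(f), "target_system")
})

test_that("categorization matches a brute-force scan of the rule table and reports misses", {
  rules <- category_rules()
  expect_identical(categorize("U04", "level_of_care", rules), "intensive_care")
  rep <- new_binding_report()
  expect_identical(categorize("U99", "level_of_care", rules, rep),
                   "uncategorized")
  expect_identical(binding_report_df(rep)$code, "U99")
  expect_error(categorize("U04", "no_such_dimension", rules), "dimension")

  set.seed(7)
  for (rep_i in 1:5) {
    tab <- data.frame(source_value = sample(LETTERS, 12),
                      dimension = sample(c("d1", "d2"), 12, replace = TRUE),
                      category = sample(letters, 12, replace = TRUE))
    tab <- tab[!duplicated(tab[c("source_value", "dimension")]), ]
    f <- tempfile(fileext = ".csv")
    write.csv(tab, f, row.names = FALSE)
    rs <- category_rules(f)
    for (q in seq_len(20)) {
      v <- sample(LETTERS, 1)
      d <- sample(unique(tab$dimension), 1)
      hit <- tab$category[tab$source_value == v & tab$dimension == d]
      expect_identical(categorize(v, d, rs),
                       if (length(hit)) hit else "uncategorized")
    }
  }
})
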