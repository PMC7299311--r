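test_that("cohort CSV + metadata round trip preserves values and genotype labels", {
  cohort <- tiny_cohort(n = 5, m = 3)
  tdir <- withr::local_tempdir()
  csv <- file.path(tdir, "cohort.csv")
  meta <- file.path(tdir, "meta.json")
  write_cohort(cohort, csv, meta)
  back <- read_cohort(csv, meta)

  expect_identical(back$patient_ids, cohort$patient_ids)
  expect_identical(back$timepoints, cohort$timepoints)
  expect_identical(dimnames(back$values), dimnames(cohort$values))
  expect_identical(back$values, cohort$values)  # bit-exact, incl. genotype codes
  expect_identical(back$variables$G1$genotype_classes, c("CC", "CT", "TT"))
})

test_that("reader fills missing cells, rejects bad rows and unknown variables", {
  cohort <- tiny_cohort(n = 2, m = 2)
  tdir <- withr::local_tempdir()
  csv <- file.path(tdir, "cohort.csv")
  meta <- file.path(tdir, "meta.json")
  write_cohort(cohort, csv, meta)

  tab <- read.csv(csv, colClasses = "character")
  # dense round trip: 2 patients x 4 variables x 2 timepoints
  expect_equal(nrow(tab), 2 * 4 * 2)

  # omit one row -> that cell is missing
  drop <- which(tab$variable == "sev" & tab$patient_id == "p01" &
                  tab$timepoint == "t1")[1]
  write.csv(tab[-drop, ], csv, row.names = FALSE, quote = FALSE)
  back <- read_cohort(csv, meta)
  expect_true(is.na(back$values["p01", "sev", "t1"]))
  expect_equal(sum(is.na(back$values)), 1L)

  # duplicate row with a conflicting value -> error
  dup <- tab[1, ]; dup$value <- "999"
  write.csv(rbind(tab, dup), csv, row.names = FALSE, quote = FALSE)
  expect_error(read_cohort(csv, meta), "duplicate")

  # unknown variable name -> error
  bad <- tab[1, ]; bad$variable <- "mystery"
  write.csv(rbind(tab[-1, ], bad), csv, row.names = FALSE, quote = FALSE)
  expect_error(read_cohort(csv, meta), "not in metadata")

  # non-numeric value for a continuous variable -> error
  bad2 <- tab; bad2$value[bad2$variable == "sev"][1] <- "abc"
  write.csv(bad2, csv, row.names = FALSE, quote = FALSE)
  expect_error(read_cohort(csv, meta), "non-numeric")

  # genotype label outside the declared classes -> error
  bad3 <- tab; bad3$value[bad3$variable == "G1"][1] <- "AA"
  write.csv(bad3, csv, row.names = FALSE, quote = FALSE)
  expect_error(read_cohort(csv, meta), "not in classes")
})

test_that("variable_spec enforces direction/genotype invariants", {
  expect_error(variable_spec("x", kind = "continuous"), "direction")
  expect_error(variable_spec("x", kind = "binary", direction = 1), "direction")
  expect_error(variable_spec("x", kind = "genotype"), "genotype_classes")
  expect_error(variable_spec("x", kind = "genotype",
                             genotype_classes = "CC"), ">= 2")
  expect_true(variable_spec("x", kind = "genotype",
                            genotype_classes = c("CC", "CT"))$static)
})

test_that("static variables must be constant over time", {
  vals <- array(rnorm(4), c(2, 1, 2))
  vars <- list(variable_spec("age", "Demographic", "continuous",
                             direction = 1, static = TRUE))
  expect_error(longitudinal_cohort(vals, c("a", "b"), c("t0", "t1"), vars),
               "varies over time")
})

test_that("complete-case filter drops exactly the patients with missing cells", {
  cohort <- tiny_cohort(n = 3, m = 2)
  cohort$values[2, 1, 1] <- NA
  expect_message(complete_case_filter(cohort), "1 of 3")
  kept <- suppressMessages(complete_case_filter(cohort))
  expect_equal(kept$patient_ids, cohort$patient_ids[-2])

  clean <- tiny_cohort(n = 3, m = 2)
  expect_identical(complete_case_filter(clean, quiet = TRUE), clean)

  all_na <- tiny_cohort(n = 2, m = 2)
  all_na$values[, 1, 1] <- NA
  expect_error(complete_case_filter(all_na, quiet = TRUE), "every patient")
})

test_that("a 430-enrollee cohort with injected dropout filters to 194 complete cases", {
  sim <- generate_cohort(ppmi_like_spec(N = 430), seed = 7)
  cohort <- sim$cohort
  incomplete <- withr::with_seed(7, sample.int(430, 430 - 194))
  for (i in incomplete) cohort$values[i, 1, 5] <- NA
  kept <- complete_case_filter(cohort, quiet = TRUE)
  expect_equal(length(kept$patient_ids), 194L)
})

test_that("80/20 split of 194 patients gives 39 test and 155 training patients", {
  sim <- generate_cohort(ppmi_like_spec(), seed = 3)
  sp <- split_cohort(sim$cohort, 0.2, seed = 11)
  expect_equal(length(sp$test$patient_ids), 39L)
  expect_equal(length(sp$train$patient_ids), 155L)
})

test_that("splits are seed-reproducible, disjoint, and exhaustive", {
  cohort <- tiny_cohort(n = 10, m = 2)
  s1 <- split_cohort(cohort, 0.5, seed = 99)
  s2 <- split_cohort(cohort, 0.5, seed = 99)
  expect_identical(s1$test_ids, s2$test_ids)

  for (seed in 1:100) {
    sp <- split_cohort(cohort, 0.3, seed = seed)
    expect_length(sp$test$patient_ids, 3L)
    expect_length(intersect(sp$train$patient_ids, sp$test$patient_ids), 0L)
    expect_setequal(c(sp$train$patient_ids, sp$test$patient_ids),
                    cohort$patient_ids)
  }
})

test_that("degenerate splits are rejected", {
  cohort <- tiny_cohort(n = 2, m = 2)
  expect_error(split_cohort(cohort, 0.9, seed = 1), "empty")
  expect_error(split_cohort(cohort, 0.1, seed = 1), "empty")
})
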