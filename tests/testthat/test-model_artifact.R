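# small but realistic fitted model shared across artifact tests
fit_fixture <- function(n = 90, seed = 3, min_size = 5) {
  sim <- generate_cohort(ppmi_like_spec(N = n), seed = seed)
  sp <- split_cohort(sim$cohort, 0.2, seed = seed)
  list(model = fit_tpc(sp$train, seed = seed, min_size = min_size,
                       quiet = TRUE),
       train = sp$train, test = sp$test, labels = sim$labels)
}

test_that("fit -> serialize -> load -> predict equals fit -> predict bit-exactly", {
  fx <- fit_fixture()
  tdir <- withr::local_tempdir()
  path <- file.path(tdir, "model.json")
  write_model_json(fx$model, path)
  model2 <- read_model_json(path)

  expect_identical(model2$thresholds$theta, fx$model$thresholds$theta)
  expect_identical(model2$U, fx$model$U)
  expect_identical(model2$partition$labels, fx$model$partition$labels)
  expect_identical(model2$partition$Q, fx$model$partition$Q)

  r1 <- predict_tpc(fx$model, fx$test)
  r2 <- predict_tpc(model2, fx$test)
  expect_identical(r1$table, r2$table)
  expect_identical(r1$distances$distance, r2$distances$distance)
  expect_identical(r1$accuracy, r2$accuracy)
})

test_that("refitting with the same seed gives an identical model", {
  fx1 <- fit_fixture(seed = 11)
  fx2 <- fit_fixture(seed = 11)
  expect_identical(fx1$model$partition$labels, fx2$model$partition$labels)
  expect_identical(fx1$model$thresholds$theta, fx2$model$thresholds$theta)
  expect_identical(fx1$model$subtype_profiles[[1]]$S,
                   fx2$model$subtype_profiles[[1]]$S)
})

test_that("prediction requires matching variables and a non-empty test set", {
  fx <- fit_fixture()
  expect_error(predict_tpc(fx$model,
                           select_variables(fx$test,
                                            names(fx$test$variables)[1:5])),
               "do not match")
  expect_error(predict_tpc(fx$model, fx$test[integer(0)]), "empty")
})

test_that("reports include a population panel near 0.5 at baseline", {
  fx <- fit_fixture()
  tdir <- withr::local_tempdir()
  res <- report_tpc(fx$model, out_dir = tdir)
  expect_true("population" %in% names(res$panels))
  pop <- res$panels$population
  n_train <- fx$model$thresholds$source_n
  cont <- names(fx$model$thresholds$theta)
  # continuous columns: untied baselines give exactly floor(N/2)/N
  expect_equal(unname(pop[cont, 1]),
               rep(floor(n_train / 2) / n_train, length(cont)))
  expect_true(all(file.exists(res$files)))
  expect_true(any(grepl("subtype_profiles\\.png$", res$files)))

  # a community whose members are all affected renders an all-dark panel
  arr <- array(1, c(4, 2, 2))
  prof <- as_profiles(arr)
  sp <- subtype_profile(prof, baseline_normalizers(prof), members = 1:4)
  expect_true(all(sp$affected_fraction == 1))
})

test_that("distance tables cover every patient, timepoint and subtype", {
  fx <- fit_fixture()
  rep <- predict_tpc(fx$model, fx$test)
  n_test <- length(fx$test$patient_ids)
  k <- length(fx$model$subtype_profiles)
  expect_equal(nrow(rep$distances), n_test * 5 * k)
  expect_setequal(rep$confidence_order, fx$test$patient_ids)
  d0 <- rep$distances[rep$distances$timepoint == "bl", ]
  best <- tapply(d0$distance, d0$patient_id, min)
  expect_equal(as.numeric(best[rep$table$patient_id]),
               rep$table$baseline_distance)
})

test_that("the command-line interface runs the simulate/fit/predict/report cycle", {
  cli <- system.file("cli", "trajpc.R", package = "trajpc")
  expect_true(nzchar(cli))
  tdir <- withr::local_tempdir()
  rscript <- file.path(R.home("bin"), "Rscript")
  libs <- paste0("R_LIBS=", paste(.libPaths(), collapse = .Platform$path.sep))
  run <- function(...) {
    system2(rscript, c(cli, ...), stdout = TRUE, stderr = TRUE, env = libs)
  }

  out <- run("simulate", "--out", file.path(tdir, "sim"), "--n", "80",
             "--seed", "4")
  expect_equal(attr(out, "status") %||% 0L, 0L)
  expect_true(file.exists(file.path(tdir, "sim", "cohort.csv")))

  out <- run("fit", "--cohort", file.path(tdir, "sim", "cohort.csv"),
             "--metadata", file.path(tdir, "sim", "metadata.json"),
             "--out", file.path(tdir, "model.json"), "--seed", "4",
             "--min-size", "5")
  expect_equal(attr(out, "status") %||% 0L, 0L)
  expect_true(file.exists(file.path(tdir, "model.json")))

  out <- run("predict", "--model", file.path(tdir, "model.json"),
             "--cohort", file.path(tdir, "sim", "cohort.csv"),
             "--metadata", file.path(tdir, "sim", "metadata.json"),
             "--out", file.path(tdir, "pred.csv"))
  expect_equal(attr(out, "status") %||% 0L, 0L)
  pred <- read.csv(file.path(tdir, "pred.csv"))
  expect_equal(nrow(pred), 80L)
  expect_true(all(c("predicted_subtype", "final_subtype", "concordant") %in%
                    names(pred)))

  out <- run("stats", "--model", file.path(tdir, "model.json"),
             "--cohort", file.path(tdir, "sim", "cohort.csv"),
             "--metadata", file.path(tdir, "sim", "metadata.json"),
             "--out", file.path(tdir, "stats.csv"))
  expect_equal(attr(out, "status") %||% 0L, 0L)
  expect_true(file.exists(file.path(tdir, "stats.csv")))

  out <- run("report", "--model", file.path(tdir, "model.json"),
             "--out", file.path(tdir, "report"))
  expect_equal(attr(out, "status") %||% 0L, 0L)
  expect_true(file.exists(file.path(tdir, "report", "subtype_profiles.png")))

  # missing required option -> nonzero exit
  out <- suppressWarnings(run("fit"))
  expect_equal(attr(out, "status"), 1L)
})
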