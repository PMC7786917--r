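# Synthetic cohort generators: exactness, determinism, band consistency.

test_that("table-faithful cohorts reproduce every shipped cross-tab for any seed", {
  tables <- fi30_table_counts()
  for (seed in c(1, 99, 20260929)) {
    g <- generate_table_faithful(seed = seed)
    expect_equal(nrow(g), 400)
    for (cv in names(tables)) {
      expect_identical(unname(crosstab(g, cv)$counts), unname(tables[[cv]]),
                       label = sprintf("seed %d, covariate %s", seed, cv))
    }
  }
})

test_that("every generated FI lies in its assigned category band", {
  for (sampler in c("uniform", "grid")) {
    g <- generate_table_faithful(seed = 17, fi_sampler = sampler)
    expect_identical(categorize_fi(g$fi), g$category)
    expect_true(all(g$fi >= 0.05 & g$fi <= 0.71))
  }
})

test_that("same seed gives identical cohorts; different seeds differ in the joint pattern", {
  a <- generate_table_faithful(seed = 5)
  b <- generate_table_faithful(seed = 5)
  expect_identical(a, b)
  c2 <- generate_table_faithful(seed = 6)
  expect_false(identical(a$gender, c2$gender) && identical(a$fi, c2$fi))
  # generation does not disturb the caller's RNG stream
  set.seed(123); before <- runif(1)
  set.seed(123); invisible(generate_table_faithful(seed = 7)); after <- runif(1)
  expect_identical(before, after)
})

test_that("inconsistent spec matrices are rejected by name", {
  tables <- fi30_table_counts()
  tables$gender[1, 1] <- tables$gender[1, 1] + 1L
  expect_error(generate_table_faithful(tables), "gender",
               class = "fi30_spec_error")
})

test_that("deep mode synthesizes item responses that rescore into the assigned band", {
  tables <- lapply(fi30_table_counts()["gender"], function(m) {
    # a scaled-down spec: 40 subjects with the same level structure
    m2 <- matrix(c(3, 7, 8, 5, 1, 5, 6, 5), nrow = 2, byrow = TRUE,
                 dimnames = dimnames(m))
    storage.mode(m2) <- "integer"
    m2
  })
  g <- generate_table_faithful(tables, seed = 31, deep = TRUE)
  expect_true(all(paste0("item_", 1:30) %in% names(g)))
  rescored <- compute_fi(as.matrix(g[paste0("item_", 1:30)]))
  expect_identical(categorize_fi(rescored$fi), g$category)
})

test_that("parametric cohorts follow the declared logistic model", {
  # symmetric null: frail fraction near one half
  g0 <- generate_parametric(4000, beta = list(), intercept = 0, seed = 41)
  expect_lt(abs(mean(g0$status == "FRAIL") - 0.5), 2 * sqrt(0.25 / 4000))
  # intercept alone sets the marginal prevalence by the inverse logit
  g1 <- generate_parametric(10000, beta = list(),
                            intercept = log(0.28 / 0.72), seed = 42)
  expect_equal(mean(g1$status == "FRAIL"), 0.28, tolerance = 0.02)
  # scoring-classification round trip holds
  expect_identical(dichotomize_fi(g1$fi), g1$status)
  expect_identical(categorize_fi(g1$fi), g1$category)
  expect_error(generate_parametric(100, covariates = list(g = c(a = 0.6, b = 0.6))),
               class = "fi30_spec_error")
})

test_that("fit_logistic recovers generator betas within Monte Carlo error", {
  g <- generate_parametric(
    5000, covariates = list(gender = c(Male = 0.5, Female = 0.5)),
    beta = list(gender = c(Female = 0.7)), intercept = -0.5, seed = 77)
  fit <- fit_logistic(g, "gender")
  row <- fit$terms[fit$terms$level %in% "Female", ]
  expect_lt(abs(row$beta - 0.7), 3 * row$se)
})

test_that("calibration_report summarises what the study calibrates against", {
  g <- generate_table_faithful(seed = 55)
  cal <- calibration_report(g)
  expect_equal(as.numeric(cal$category_proportions),
               c(34, 120, 145, 101) / 400)
  expect_equal(cal$frail_prevalence, 246 / 400)
  expect_gte(cal$fi_range[1], 0.05)
  expect_lte(cal$fi_range[2], 0.71)
  # band-uniform expectation bracket for the mean FI
  means <- vapply(1:25, function(s) {
    calibration_report(generate_table_faithful(seed = s))$fi_mean
  }, 1)
  expect_true(all(means > 0.24 & means < 0.32))
  expect_error(calibration_report(data.frame()), class = "fi30_input_error")
})

test_that("add_ages draws ages inside each subject's age band", {
  g <- add_ages(generate_table_faithful(seed = 61), seed = 61)
  expect_true(all(g$age >= 55))
  expect_true(all(g$age[g$age_group == "55-59"] < 60))
  expect_true(all(g$age[g$age_group == "70+"] >= 70))
})
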