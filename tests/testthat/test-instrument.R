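# The FI-30 instrument: registry, deficit coding, score, bands.

test_that("shipped registry has 30 valid items matching the instrument coding", {
  reg <- fi30_registry()
  expect_length(reg, 30)
  expect_identical(validate_registry(reg), character(0))
  ids <- vapply(reg, function(it) it$item_id, 1L)
  expect_setequal(ids, 1:30)
  # graded items carry their instrument weights
  expect_equal(reg[["1"]]$scheme$weights, c(0, 0.5, 1))
  expect_equal(reg[["22"]]$scheme$weights, c(0, 0.33, 0.66, 1))
  expect_equal(reg[["10"]]$scheme$weights, c(0, 0.5, 1))
  # all weights drawn from the admitted grade set
  for (it in reg) {
    expect_true(all(it$scheme$weights %in% c(0, 0.25, 0.33, 0.5, 0.66, 0.75, 1)))
  }
})

test_that("code_item maps labels to weights, robust to case and whitespace", {
  reg <- fi30_registry()
  expect_equal(code_item(reg[["1"]], "Average"), 0.5)
  expect_equal(code_item(reg[["22"]], "Mild"), 0.33)
  expect_equal(code_item(reg[["15"]], "No"), 0)
  expect_equal(code_item(reg[["1"]], "  poor health "), 1)
  expect_equal(code_item(reg[["2"]], c("YES", "no", NA)), c(1, 0, NA))
  # missing passes through; empty string is missing
  expect_true(is.na(code_item(reg[["3"]], "")))
  # pre-coded numeric weights accepted only when legal for the scheme
  expect_equal(code_item(reg[["22"]], c(0.33, NA)), c(0.33, NA))
  expect_error(code_item(reg[["22"]], 0.5), class = "fi30_coding_error")
  expect_error(code_item(reg[["1"]], "excellent"), class = "fi30_coding_error")
  expect_error(code_item(reg[["1"]], "excellent"), "item 1")
})

test_that("registry validation flags duplicate ids and illegal weights", {
  reg <- fi30_registry()
  dup <- reg
  dup[[2]] <- dup[[1]]
  expect_match(validate_registry(dup), "duplicate", all = FALSE)
  expect_error(coding_scheme(c("a", "b"), c(0, 0.4)), class = "fi30_scheme_error")
  expect_error(coding_scheme(c("a", "b", "c"), c(0, 0.75, 0.5)),
               class = "fi30_scheme_error")
  expect_error(coding_scheme(c("a", "b"), c(0.25, 1)), class = "fi30_scheme_error")
  # the generic grade set is admitted even though no default item uses 0.25/0.75
  sch <- coding_scheme(c("none", "mild", "severe", "full"), c(0, 0.25, 0.75, 1))
  expect_s3_class(sch, "fi30_scheme")
})

test_that("compute_fi follows the deficit/denominator formula", {
  expect_equal(compute_fi(rep(0, 30))$fi, 0)
  expect_equal(compute_fi(rep(1, 30))$fi, 1)
  expect_equal(compute_fi(c(rep(1, 15), rep(0, 15)))$fi, 0.5)
  s <- compute_fi(c(rep(1, 7), rep(0, 21), NA, NA))
  expect_equal(s$fi, 0.25)  # 7 / (30 - 2)
  expect_equal(s$deficit_sum, 7)
  expect_equal(s$n_missing, 2)
  # with no missing items the denominator is exactly 30
  w <- c(rep(0.5, 10), rep(0, 20))
  expect_equal(compute_fi(w)$fi, sum(w) / 30)
})

test_that("compute_fi refuses incomplete vectors and bad weights", {
  expect_error(compute_fi(c(rep(1, 20), rep(NA, 10))),
               class = "fi30_incomputable_error")
  # the completeness threshold is configurable
  expect_equal(compute_fi(c(rep(1, 20), rep(NA, 10)), min_items = 20)$fi, 1)
  expect_error(compute_fi(rep(2, 30)), class = "fi30_score_error")
  expect_error(compute_fi(rep(1, 29)), class = "fi30_score_error")
})

test_that("compute_fi agrees with a brute-force oracle on random subjects", {
  reg <- fi30_registry()
  set.seed(42)
  for (i in 1:1000) {
    w <- random_deficit_vector(reg, n_missing = sample(0:5, 1))
    expect_equal(compute_fi(w)$fi, oracle_fi(w))
  }
})

test_that("severity bands are right-closed with boundaries to the milder class", {
  expect_equal(as.character(categorize_fi(c(0, 0.05, 0.12))),
               c("FIT", "FIT", "FIT"))
  expect_equal(as.character(categorize_fi(c(0.24, 0.36, 0.37, 0.71, 1))),
               c("MILD", "MODERATE", "SEVERE", "SEVERE", "SEVERE"))
  expect_equal(as.character(dichotomize_fi(c(0.24, 0.241, 0.71))),
               c("FIT", "FRAIL", "FRAIL"))
  expect_error(categorize_fi(1.2), class = "fi30_domain_error")
  expect_error(dichotomize_fi(-0.1), class = "fi30_domain_error")
})

test_that("binary status and severity category collapse consistently on a dense grid", {
  fi <- seq(0, 1, by = 0.001)
  cat4 <- categorize_fi(fi)
  bin <- dichotomize_fi(fi)
  expect_identical(bin == "FRAIL", cat4 %in% c("MODERATE", "SEVERE"))
})

test_that("raising any single deficit weight never lowers fi or the category", {
  reg <- fi30_registry()
  set.seed(7)
  for (rep in 1:50) {
    w <- random_deficit_vector(reg)
    i <- sample(30, 1)
    ws <- reg[[as.character(i)]]$scheme$weights
    higher <- ws[ws > w[i]]
    if (!length(higher)) next
    w2 <- w
    w2[i] <- min(higher)
    f1 <- compute_fi(w)$fi; f2 <- compute_fi(w2)$fi
    expect_gte(f2, f1)
    expect_gte(as.integer(categorize_fi(f2)), as.integer(categorize_fi(f1)))
  }
})

test_that("score_cohort codes raw labels end-to-end", {
  reg <- fi30_registry()
  # two hand-built subjects: one with zero deficits, one with graded ones
  rec <- blank_record()
  rec2 <- rec
  rec2$item_1 <- "Average"; rec2$item_22 <- "Mild"; rec2$item_2 <- "Yes"
  cohort <- score_cohort(rbind(rec, rec2), registry = reg)
  expect_equal(cohort$fi, c(0, (0.5 + 0.33 + 1) / 30))
  expect_equal(as.character(cohort$category), c("FIT", "FIT"))
})

test_that("score_cohort flags incomputable subjects instead of failing the run", {
  rec <- blank_record()
  rec2 <- rec
  rec2[paste0("item_", 1:10)] <- NA
  cohort <- score_cohort(rbind(rec, rec2))
  expect_equal(attr(cohort, "incomputable"), 2L)
  expect_true(is.na(cohort$fi[2]))
  expect_equal(cohort$fi[1], 0)
})
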