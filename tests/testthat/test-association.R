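# Cross-tabs, chi-square, odds conventions, prevalence, t-test, alpha.

gender_counts <- function() {
  m <- matrix(c(27, 74, 78, 50,
                7, 46, 67, 51), nrow = 2, byrow = TRUE,
              dimnames = list(c("Male", "Female"), NULL))
  as_crosstab(m, "gender")
}

test_that("crosstab counts subjects exactly with dictionary level order", {
  g <- generate_table_faithful(seed = 11)
  ct <- crosstab(g, "gender")
  expect_identical(unname(ct$counts), unname(fi30_table_counts()$gender))
  expect_equal(rownames(ct$counts), c("Male", "Female"))
  # binary collapse columns sum to the 4-column row sums
  expect_equal(unname(rowSums(ct$binary)), unname(rowSums(ct$counts)))
  expect_equal(sum(ct$counts), 400)
  # degenerate cohorts
  one <- data.frame(gender = "Male", category = factor("FIT", levels = levels(g$category)))
  ct1 <- crosstab(one, "gender")
  expect_equal(unname(ct1$counts["Male", ]), c(1L, 0L, 0L, 0L))
  expect_equal(unname(ct1$counts["Female", ]), rep(0L, 4))  # declared, unseen
  expect_error(crosstab(g, "shoe_size"), class = "fi30_input_error")
})

test_that("chi_square reproduces the Pearson statistic and flags degeneracy", {
  res <- chi_square(gender_counts())
  expect_equal(res$df, 3)
  expect_equal(res$statistic, oracle_pearson(gender_counts()$counts))
  expect_equal(round(res$statistic, 2), 10.96)
  expect_equal(round(res$p_value, 3), 0.012)
  # perfect independence
  flat <- chi_square(matrix(10, 2, 2))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p_value, 1)
  # degenerate marginals refuse to test
  expect_error(chi_square(matrix(c(0, 0, 5, 5), 2, 2, byrow = TRUE)),
               class = "fi30_degenerate_table_error")
})

test_that("chi_square matches the O/E oracle and is permutation/scale consistent", {
  set.seed(5)
  for (i in 1:20) {
    m <- matrix(rpois(8, 20) + 1, 2, 4)
    res <- chi_square(m)
    expect_equal(res$statistic, oracle_pearson(m))
    # invariant under row and column permutation
    expect_equal(chi_square(m[2:1, ])$statistic, res$statistic)
    expect_equal(chi_square(m[, sample(4)])$statistic, res$statistic)
    # statistic scales linearly when every count is multiplied
    expect_equal(chi_square(m * 3)$statistic, 3 * res$statistic)
  }
})

test_that("subgroup odds are the within-level frail/fit ratio", {
  ct <- gender_counts()
  o <- subgroup_frailty_odds(ct, "Female")
  expect_equal(o$estimate, 118 / 53)
  expect_equal(round(o$estimate, 3), 2.226)
  se <- sqrt(1 / 118 + 1 / 53)
  expect_equal(o$ci_low, exp(log(118 / 53) - qnorm(0.975) * se))
  # identity: odds = p / (1 - p) with p the level's frail fraction
  set.seed(8)
  for (i in 1:20) {
    m <- matrix(rpois(8, 15) + 1, 2, 4)
    rownames(m) <- c("a", "b")
    ct2 <- as_crosstab(m, "x")
    p <- ct2$binary["a", "frail"] / sum(ct2$binary["a", ])
    expect_equal(subgroup_frailty_odds(ct2, "a")$estimate, p / (1 - p))
  }
  # undefined when the level has no fit subjects
  zf <- as_crosstab(matrix(c(0, 0, 3, 4, 1, 1, 1, 1), 2, 4, byrow = TRUE,
                           dimnames = list(c("a", "b"), NULL)))
  expect_error(subgroup_frailty_odds(zf, "a"), class = "fi30_infinite_odds_error")
})

test_that("odds_ratio is the 2x2 cross-product with a Woolf interval", {
  ct <- gender_counts()
  o <- odds_ratio(ct, "Female", "Male")
  expect_equal(o$estimate, (118 * 101) / (53 * 128))
  expect_equal(round(o$estimate, 3), 1.757)
  se <- sqrt(1 / 118 + 1 / 101 + 1 / 53 + 1 / 128)
  expect_equal(o$ci_high, exp(log(o$estimate) + qnorm(0.975) * se))
  # self-comparison is 1
  expect_equal(odds_ratio(ct, "Male", "Male")$estimate, 1)
  # zero cells error unless the Haldane correction is asked for
  zc <- as_crosstab(matrix(c(2, 3, 0, 0, 1, 1, 1, 1), 2, 4, byrow = TRUE,
                           dimnames = list(c("a", "b"), NULL)))
  expect_error(odds_ratio(zc, "a", "b"), class = "fi30_zero_cell_error")
  oh <- odds_ratio(zc, "a", "b", haldane = TRUE)
  expect_equal(oh$estimate, (0.5 * 2.5) / (5.5 * 2.5))
})

test_that("prevalence_ci gives Wilson (default) and Wald intervals", {
  w <- prevalence_ci(34, 400)
  expect_equal(w$estimate, 0.085)
  expect_equal(c(w$ci_low, w$ci_high), oracle_wilson(34, 400), tolerance = 1e-8)
  # k = 0: estimate 0 and lower bound 0
  z <- prevalence_ci(0, 50)
  expect_equal(z$estimate, 0)
  expect_equal(z$ci_low, 0)
  # symmetric at one half
  h <- prevalence_ci(200, 400)
  expect_equal(h$estimate - h$ci_low, h$ci_high - h$estimate, tolerance = 1e-10)
  wd <- prevalence_ci(34, 400, method = "wald")
  expect_equal(wd$ci_high - wd$ci_low,
               2 * qnorm(0.975) * sqrt(0.085 * 0.915 / 400), tolerance = 1e-10)
  expect_error(prevalence_ci(5, 0), class = "fi30_domain_error")
})

test_that("fi_t_test pools variances and accepts raw or summary input", {
  # the study's gender comparison from its printed summaries
  r <- fi_t_test(c(229, 0.271, 0.118), c(171, 0.303, 0.114))
  o <- oracle_pooled_t(229, 0.271, 0.118, 171, 0.303, 0.114)
  expect_equal(r$t, o$t)
  expect_equal(r$df, 398)
  expect_equal(r$p_value, o$p)
  expect_equal(round(r$t, 2), -2.72)
  expect_equal(round(r$p_value, 3), 0.007)
  # raw vectors agree with their own summaries, and with stats::t.test
  set.seed(3)
  x <- runif(40, 0.1, 0.5); y <- runif(35, 0.2, 0.6)
  raw <- fi_t_test(x, y)
  summ <- fi_t_test(c(length(x), mean(x), sd(x)), c(length(y), mean(y), sd(y)))
  expect_equal(raw$t, summ$t)
  ref <- t.test(x, y, var.equal = TRUE)
  expect_equal(raw$t, unname(ref$statistic))
  expect_equal(raw$p_value, ref$p.value)
  # identical groups: t = 0, p = 1
  same <- fi_t_test(x, x)
  expect_equal(same$t, 0)
  expect_equal(same$p_value, 1)
  expect_error(fi_t_test(c(10, 0.3, 0), c(10, 0.3, 0.1)),
               class = "fi30_domain_error")
})

test_that("cronbach_alpha matches its closed forms and behavioural limits", {
  set.seed(21)
  base <- runif(50)
  # perfectly duplicated columns: alpha = 1
  dup <- matrix(rep(base, 30), ncol = 30)
  expect_equal(cronbach_alpha(dup)$alpha, 1)
  # two items: the 2-item closed form
  x1 <- runif(40); x2 <- 0.6 * x1 + 0.4 * runif(40)
  expect_equal(cronbach_alpha(cbind(x1, x2))$alpha, oracle_alpha2(x1, x2))
  # independent items: alpha near zero
  ind <- matrix(runif(2000 * 10), ncol = 10)
  expect_lt(abs(cronbach_alpha(ind)$alpha), 0.1)
  expect_error(cronbach_alpha(matrix(1, 5, 3)), class = "fi30_undefined_alpha_error")
  expect_error(cronbach_alpha(cbind(x1)), class = "fi30_domain_error")
})
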