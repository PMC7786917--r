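# The association layer: severity cross-tabs, Pearson chi-square,
# within-level frailty odds and conventional odds ratios, prevalence
# intervals, pooled t-test and Cronbach's alpha.

Z95 <- stats::qnorm(0.975)  # 1.959964

#' Cross-tabulate a covariate against the severity categories
#'
#' Builds the level x category count table (FIT, MILD, MODERATE, SEVERE
#' columns) for one covariate, together with its binary collapse
#' (fit = FIT + MILD, frail = MODERATE + SEVERE). Level order follows the
#' data dictionary when the covariate is declared there, otherwise the
#' factor levels / sorted unique values of the column. Declared levels
#' absent from the data appear with zero counts.
#'
#' @param records scored subject data.frame (needs a `category` column,
#'   e.g. from [score_cohort()] or a generator).
#' @param covariate name of the covariate column.
#' @param dictionary covariate dictionary (default [fi30_covariates()]).
#' @return Object of class `fi30_crosstab`: list with `covariate`,
#'   `counts` (levels x 4 integer matrix), `binary` (levels x 2 matrix
#'   with columns fit, frail).
#' @export
crosstab <- function(records, covariate, dictionary = fi30_covariates()) {
  if (!is.data.frame(records)) {
    fi30_stop("fi30_input_error", "records must be a data.frame")
  }
  if (!covariate %in% names(records)) {
    fi30_stop("fi30_input_error",
              sprintf("unknown covariate: %s", covariate))
  }
  if (!"category" %in% names(records)) {
    fi30_stop("fi30_input_error", "records carry no 'category' column; score them first")
  }
  x <- records[[covariate]]
  lv <- if (covariate %in% names(dictionary)) {
    dictionary[[covariate]]$levels
  } else if (is.factor(x)) levels(x) else sort(unique(as.character(x)))
  x <- as.character(x)
  undeclared <- setdiff(unique(x), lv)
  if (length(undeclared)) {
    fi30_stop("fi30_input_error",
              sprintf("covariate %s has undeclared level(s): %s", covariate,
                      paste(undeclared, collapse = ", ")))
  }
  counts <- table(factor(x, levels = lv),
                  factor(as.character(records$category), levels = FI_CATEGORIES))
  counts <- matrix(as.integer(counts), nrow = length(lv),
                   dimnames = list(lv, FI_CATEGORIES))
  new_crosstab(covariate, counts)
}

new_crosstab <- function(covariate, counts) {
  binary <- cbind(fit = counts[, "FIT"] + counts[, "MILD"],
                  frail = counts[, "MODERATE"] + counts[, "SEVERE"])
  structure(list(covariate = covariate, counts = counts, binary = binary),
            class = "fi30_crosstab")
}

#' Build a cross-tab object from a printed count matrix
#'
#' For re-analysing published level x severity tables without
#' individual-level data.
#'
#' @param counts levels x 4 matrix (columns FIT, MILD, MODERATE, SEVERE,
#'   rownames = level labels).
#' @param covariate covariate name to attach.
#' @return An `fi30_crosstab`.
#' @export
as_crosstab <- function(counts, covariate = "covariate") {
  counts <- as.matrix(counts)
  if (ncol(counts) != 4) {
    fi30_stop("fi30_input_error", "counts must have 4 severity columns")
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    fi30_stop("fi30_input_error", "counts must be non-negative integers")
  }
  colnames(counts) <- FI_CATEGORIES
  if (is.null(rownames(counts))) {
    rownames(counts) <- paste0("level_", seq_len(nrow(counts)))
  }
  new_crosstab(covariate, counts)
}

#' @export
print.fi30_crosstab <- function(x, ...) {
  cat(sprintf("Severity cross-tab for '%s' (n = %d)\n",
              x$covariate, sum(x$counts)))
  print(cbind(x$counts, x$binary))
  invisible(x)
}

#' Pearson chi-square test on a severity cross-tab
#'
#' Pearson statistic sum((O - E)^2 / E) on the full 4-category table (not
#' the binary collapse), no continuity correction, with
#' df = (rows - 1)(cols - 1). A `low_expected` flag is set when any
#' expected count falls below 5.
#'
#' @param x an `fi30_crosstab` or a count matrix.
#' @return List of class `fi30_chisq` with `statistic`, `df`, `p_value`,
#'   `low_expected`.
#' @export
chi_square <- function(x) {
  m <- if (inherits(x, "fi30_crosstab")) x$counts else as.matrix(x)
  if (nrow(m) < 2 || ncol(m) < 2) {
    fi30_stop("fi30_degenerate_table_error", "need at least a 2 x 2 table")
  }
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    fi30_stop("fi30_degenerate_table_error",
              "zero marginal row/column makes the test degenerate")
  }
  res <- suppressWarnings(chisq.test(m, correct = FALSE))
  structure(list(statistic = unname(res$statistic),
                 df = unname(res$parameter),
                 p_value = unname(res$p.value),
                 low_expected = any(res$expected < 5)),
            class = "fi30_chisq")
}

#' @export
print.fi30_chisq <- function(x, ...) {
  cat(sprintf("Pearson chi-square = %.3f, df = %d, p = %.4g%s\n",
              x$statistic, x$df, x$p_value,
              if (x$low_expected) "  (some expected counts < 5)" else ""))
  invisible(x)
}

odds_result <- function(kind, estimate, ci_low, ci_high, reference = NA_character_) {
  structure(list(kind = kind, estimate = estimate,
                 ci_low = ci_low, ci_high = ci_high,
                 reference_level = reference),
            class = "fi30_odds")
}

#' @export
print.fi30_odds <- function(x, ...) {
  cat(sprintf("%s = %.3f (95%% CI %.2f-%.2f)%s\n", x$kind, x$estimate,
              x$ci_low, x$ci_high,
              if (!is.na(x$reference_level)) paste0(" vs ", x$reference_level) else ""))
  invisible(x)
}

#' Within-level frailty odds
#'
#' The frail/fit odds inside one covariate level, computed on the binary
#' collapse of the severity table: `frail_count / fit_count`. This is the
#' convention behind the "unadjusted OR" column of the published
#' risk-factor tables this package reproduces; for the textbook
#' reference-contrast estimator see [odds_ratio()]. The 95% interval uses
#' the log-odds normal approximation
#' exp(ln(odds) +/- 1.96 sqrt(1/frail + 1/fit)).
#'
#' @param x an `fi30_crosstab`.
#' @param level level label within the covariate.
#' @return An `fi30_odds` with `kind = "subgroup_odds"`.
#' @export
subgroup_frailty_odds <- function(x, level) {
  b <- binary_row(x, level)
  if (b["fit"] == 0) {
    fi30_stop("fi30_infinite_odds_error",
              sprintf("level %s has no fit subjects (frail = %d, fit = 0): odds undefined",
                      level, b["frail"]),
              counts = b)
  }
  est <- b["frail"] / b["fit"]
  se <- sqrt(1 / b["frail"] + 1 / b["fit"])
  odds_result("subgroup_odds", unname(est),
              unname(exp(log(est) - Z95 * se)),
              unname(exp(log(est) + Z95 * se)))
}

binary_row <- function(x, level) {
  if (!inherits(x, "fi30_crosstab")) {
    fi30_stop("fi30_input_error", "x must be an fi30_crosstab")
  }
  if (!level %in% rownames(x$binary)) {
    fi30_stop("fi30_input_error",
              sprintf("level %s not found in covariate %s", level, x$covariate))
  }
  x$binary[level, ]
}

#' Conventional odds ratio between two covariate levels
#'
#' The 2 x 2 cross-product estimator on the binary collapse:
#' OR = (frail_l * fit_ref) / (fit_l * frail_ref), with a Woolf interval
#' exp(ln OR +/- 1.96 sqrt(sum of reciprocal cells)). With
#' `haldane = TRUE` a 0.5 continuity correction is added to every cell
#' when any cell is zero.
#'
#' @param x an `fi30_crosstab`.
#' @param level comparison level.
#' @param reference reference level.
#' @param haldane apply the Haldane-Anscombe 0.5 correction on zero cells.
#' @return An `fi30_odds` with `kind = "odds_ratio"`.
#' @export
odds_ratio <- function(x, level, reference, haldane = FALSE) {
  b_l <- binary_row(x, level)
  b_r <- binary_row(x, reference)
  cells <- c(b_l["frail"], b_l["fit"], b_r["frail"], b_r["fit"])
  if (any(cells == 0)) {
    if (!haldane) {
      fi30_stop("fi30_zero_cell_error",
                "zero cell in the 2 x 2 table; enable haldane = TRUE to correct")
    }
    cells <- cells + 0.5
  }
  est <- (cells[1] * cells[4]) / (cells[2] * cells[3])
  se <- sqrt(sum(1 / cells))
  odds_result("odds_ratio", unname(est),
              unname(exp(log(est) - Z95 * se)),
              unname(exp(log(est) + Z95 * se)),
              reference)
}

#' Binomial prevalence with a 95% confidence interval
#'
#' Point estimate k/n with either the Wilson score interval (default; no
#' continuity correction) or the Wald normal-approximation interval.
#'
#' @param k number of cases.
#' @param n denominator, positive.
#' @param method `"wilson"` (default) or `"wald"`.
#' @param conf_level confidence level (default 0.95).
#' @return List with `estimate`, `ci_low`, `ci_high`, `method`, `k`, `n`.
#' @examples
#' prevalence_ci(34, 400)
#' @export
prevalence_ci <- function(k, n, method = c("wilson", "wald"),
                          conf_level = 0.95) {
  method <- match.arg(method)
  if (n <= 0 || k < 0 || k > n) {
    fi30_stop("fi30_domain_error", "need 0 <= k <= n with n > 0")
  }
  p <- k / n
  if (method == "wilson") {
    ci <- stats::prop.test(k, n, correct = FALSE, conf.level = conf_level)$conf.int
  } else {
    z <- stats::qnorm(1 - (1 - conf_level) / 2)
    half <- z * sqrt(p * (1 - p) / n)
    ci <- c(max(0, p - half), min(1, p + half))
  }
  list(estimate = p, ci_low = ci[1], ci_high = ci[2],
       method = method, k = k, n = n)
}

#' Pooled-variance Student t-test for a frailty-index mean difference
#'
#' Two-sided pooled t-test with df = n_a + n_b - 2. Each group is either a
#' raw numeric vector or a summary triplet `c(n, mean, sd)` — the form
#' published tables provide. Both input paths give identical results on
#' the same data.
#'
#' @param group_a,group_b numeric vector of FI values, or `c(n, mean, sd)`.
#' @return List of class `fi30_ttest`: `t`, `df`, `p_value`, `mean_diff`
#'   (a minus b).
#' @examples
#' fi_t_test(c(229, 0.271, 0.118), c(171, 0.303, 0.114))
#' @export
fi_t_test <- function(group_a, group_b) {
  summ <- function(g) {
    if (length(g) == 3 && g[1] >= 2 && g[1] == round(g[1])) {
      list(n = g[1], mean = g[2], sd = g[3])
    } else {
      if (length(g) < 2) fi30_stop("fi30_domain_error", "each group needs n >= 2")
      list(n = length(g), mean = mean(g), sd = stats::sd(g))
    }
  }
  a <- summ(group_a); b <- summ(group_b)
  if (a$sd <= 0 || b$sd <= 0) {
    fi30_stop("fi30_domain_error", "degenerate group: sd must be positive")
  }
  df <- a$n + b$n - 2
  sp2 <- ((a$n - 1) * a$sd^2 + (b$n - 1) * b$sd^2) / df
  t <- (a$mean - b$mean) / sqrt(sp2 * (1 / a$n + 1 / b$n))
  structure(list(t = t, df = df,
                 p_value = 2 * stats::pt(-abs(t), df),
                 mean_diff = a$mean - b$mean),
            class = "fi30_ttest")
}

#' @export
print.fi30_ttest <- function(x, ...) {
  cat(sprintf("pooled t = %.3f, df = %d, p = %.4g (mean difference %.4f)\n",
              x$t, x$df, x$p_value, x$mean_diff))
  invisible(x)
}

#' Cronbach's alpha for the deficit-item matrix
#'
#' Internal-consistency coefficient over the coded deficit weights:
#' alpha = (k / (k - 1)) (1 - sum of item variances / variance of the
#' total score), with sample variances.
#'
#' @param item_matrix subjects x items numeric matrix of deficit weights,
#'   no missing entries, at least 2 items and 2 subjects.
#' @return List of class `fi30_alpha`: `alpha`, `n_items`, `n_subjects`.
#' @export
cronbach_alpha <- function(item_matrix) {
  m <- as.matrix(item_matrix)
  if (ncol(m) < 2 || nrow(m) < 2) {
    fi30_stop("fi30_domain_error", "need >= 2 items and >= 2 subjects")
  }
  if (anyNA(m)) {
    fi30_stop("fi30_domain_error", "item matrix must have no missing entries")
  }
  total_var <- stats::var(rowSums(m))
  if (total_var == 0) {
    fi30_stop("fi30_undefined_alpha_error",
              "total-score variance is zero; alpha undefined")
  }
  k <- ncol(m)
  item_var <- apply(m, 2, stats::var)
  structure(list(alpha = k / (k - 1) * (1 - sum(item_var) / total_var),
                 n_items = k, n_subjects = nrow(m)),
            class = "fi30_alpha")
}

#' @export
print.fi30_alpha <- function(x, ...) {
  cat(sprintf("Cronbach's alpha = %.3f (%d items, %d subjects)\n",
              x$alpha, x$n_items, x$n_subjects))
  invisible(x)
}
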