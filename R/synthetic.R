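# Seeded synthetic cohort generators.
#
# Two modes: table-faithful (every covariate x severity cross-tab equals a
# shipped set of published marginal tables exactly, with FI drawn inside
# the assigned band) and parametric (covariates and a known-ground-truth
# logistic model, for parameter-recovery studies). Neither mode claims to
# reproduce the real joint covariate distribution: within a severity
# category, covariates are assigned conditionally independently.

#' Shipped covariate x severity count matrices
#'
#' The default calibration of the table-faithful generator: for each of
#' the nine socio-demographic covariates, the level x severity count
#' matrix of the 400-subject study cohort the package emulates. Column
#' sums are 34 (FIT), 120 (MILD), 145 (MODERATE), 101 (SEVERE) for every
#' covariate.
#'
#' @return Named list of integer matrices (levels x 4).
#' @export
fi30_table_counts <- function() {
  mk <- function(levels, ...) {
    m <- matrix(c(...), nrow = length(levels), byrow = TRUE,
                dimnames = list(levels, FI_CATEGORIES))
    storage.mode(m) <- "integer"
    m
  }
  dict <- fi30_covariates()
  list(
    age_group = mk(dict$age_group$levels,
                   22, 51, 53, 19,
                   4, 21, 40, 25,
                   4, 30, 19, 13,
                   4, 18, 33, 44),
    gender = mk(dict$gender$levels,
                27, 74, 78, 50,
                7, 46, 67, 51),
    education = mk(dict$education$levels,
                   15, 62, 80, 70,
                   19, 58, 65, 31),
    occupation = mk(dict$occupation$levels,
                    17, 41, 45, 13,
                    17, 79, 100, 88),
    marital_status = mk(dict$marital_status$levels,
                        30, 102, 121, 67,
                        4, 18, 24, 34),
    smoking = mk(dict$smoking$levels,
                 21, 83, 115, 75,
                 13, 37, 30, 26),
    income = mk(dict$income$levels,
                3, 32, 44, 39,
                16, 41, 51, 31,
                11, 20, 32, 22,
                3, 12, 11, 5,
                1, 15, 7, 4),
    family_type = mk(dict$family_type$levels,
                     14, 58, 57, 43,
                     20, 62, 88, 58),
    religion = mk(dict$religion$levels,
                  27, 110, 132, 87,
                  7, 10, 13, 14)
  )
}

# FI band limits used by the samplers, clipped to the observed global
# range [0.05, 0.71]
band_limits <- function() {
  rbind(FIT      = c(0.05, 0.12),
        MILD     = c(0.12, 0.24),
        MODERATE = c(0.24, 0.36),
        SEVERE   = c(0.36, 0.71))
}

validate_table_spec <- function(tables) {
  totals <- NULL
  for (cv in names(tables)) {
    m <- tables[[cv]]
    if (any(m < 0)) {
      fi30_stop("fi30_spec_error", sprintf("negative counts in covariate %s", cv))
    }
    cs <- colSums(m)
    if (is.null(totals)) totals <- cs
    if (!all(cs == totals)) {
      fi30_stop("fi30_spec_error",
                sprintf("covariate %s: category column sums %s do not match %s",
                        cv, paste(cs, collapse = "/"),
                        paste(totals, collapse = "/")))
    }
  }
  totals
}

#' Generate a table-faithful synthetic cohort
#'
#' Produces one record per subject such that every covariate x severity
#' cross-tab equals the supplied count matrices exactly, for any seed.
#' Each subject is assigned a severity category per the category totals;
#' within each category block every covariate's levels are dealt out by a
#' seeded permutation (covariates conditionally independent given
#' category). The FI of each subject is drawn from `fi_sampler` inside
#' the assigned band.
#'
#' @param tables named list of level x 4 count matrices with equal column
#'   sums (default [fi30_table_counts()], a 400-subject cohort).
#' @param seed integer seed; the same seed reproduces the cohort exactly.
#' @param fi_sampler `"uniform"` draws FI uniformly within the band
#'   (clipped globally to \[0.05, 0.71\]); `"grid"` draws uniformly from
#'   the FI values attainable as sums of 0/0.5/1-type weights over 30
#'   items (multiples of 1/60) that fall in the band.
#' @param deep also synthesize 30 item-level responses per subject whose
#'   recomputed FI lands in the assigned band (exercises the full coding
#'   path; slower).
#' @param registry item registry used when `deep = TRUE`.
#' @return data.frame with `id`, the covariate columns, `fi`, `category`,
#'   `status` (and `item_1..item_30` when `deep = TRUE`); attribute
#'   `seed` records the seed.
#' @export
generate_table_faithful <- function(tables = fi30_table_counts(), seed = 1L,
                                    fi_sampler = c("uniform", "grid"),
                                    deep = FALSE, registry = NULL) {
  fi_sampler <- match.arg(fi_sampler)
  totals <- validate_table_spec(tables)
  n <- sum(totals)
  with_seed(seed, {
    category <- factor(rep(FI_CATEGORIES, totals), levels = FI_CATEGORIES)
    out <- data.frame(id = seq_len(n), stringsAsFactors = FALSE)
    for (cv in names(tables)) {
      m <- tables[[cv]]
      col <- character(n)
      for (k in seq_along(FI_CATEGORIES)) {
        idx <- which(category == FI_CATEGORIES[k])
        labels <- rep(rownames(m), m[, k])
        col[idx] <- sample(labels)  # seeded deal within the category block
      }
      out[[cv]] <- col
    }
    lim <- band_limits()
    fi <- numeric(n)
    for (k in seq_along(FI_CATEGORIES)) {
      idx <- which(category == FI_CATEGORIES[k])
      lo <- lim[k, 1]; hi <- lim[k, 2]
      if (fi_sampler == "uniform") {
        fi[idx] <- runif(length(idx), lo, hi)
      } else {
        grid <- (0:60) / 60  # sums of half-weights over 30 items
        grid <- grid[grid > lo & grid <= hi & grid >= 0.05 & grid <= 0.71]
        fi[idx] <- sample(grid, length(idx), replace = TRUE)
      }
    }
    out$fi <- fi
    out$category <- category
    out$status <- dichotomize_fi(fi)
    if (deep) {
      registry <- registry %||% fi30_registry()
      items <- t(vapply(fi, function(f) synth_item_responses(f, registry),
                        numeric(N_ITEMS)))
      colnames(items) <- paste0("item_", seq_len(N_ITEMS))
      out <- cbind(out, as.data.frame(items))
    }
    attr(out, "seed") <- seed
    out
  })
}

# draw 30 item weights whose FI-30 score falls in the same band as the
# target fi: seeded rejection sampling around the target deficit load,
# with a deterministic fallback
synth_item_responses <- function(target_fi, registry) {
  band <- as.character(categorize_fi(target_fi))
  schemes <- lapply(registry, function(it) it$scheme$weights)
  for (try in 1:200) {
    w <- vapply(schemes, function(ws) {
      # severity-graded draw: expected weight tracks the target load
      probs <- stats::dbinom(seq_along(ws) - 1, length(ws) - 1, target_fi)
      sample(ws, 1, prob = probs)
    }, 1)
    if (as.character(categorize_fi(compute_fi(w)$fi)) == band) return(w)
  }
  # fallback: set the closest attainable number of binary deficits
  w <- rep(0, N_ITEMS)
  w[seq_len(min(N_ITEMS, round(target_fi * N_ITEMS)))] <- 1
  w
}

#' Generate a parametric synthetic cohort
#'
#' Covariates are drawn independently from declared level probabilities;
#' the binary frail outcome is Bernoulli with
#' P(frail) = plogis(intercept + sum of indicator effects); FI is then
#' drawn from a class-conditional distribution (default uniform (0.24,
#' 0.71\] when frail, uniform \[0.05, 0.24\] when fit), so scoring and
#' classification round-trip. Ground-truth coefficients are returned for
#' recovery studies.
#'
#' @param n cohort size.
#' @param covariates named list; each element is a named numeric vector
#'   of level probabilities summing to 1 (first name = reference level).
#' @param beta named list of per-level log-odds effects, e.g.
#'   `list(gender = c(Female = 0.8))`; levels not named carry effect 0.
#' @param intercept intercept on the log-odds scale.
#' @param seed integer seed.
#' @return data.frame with `id`, covariate columns, `p_frail`, `status`,
#'   `fi`, `category`; attributes `beta`, `intercept`, `seed`.
#' @examples
#' g <- generate_parametric(500, covariates = list(gender = c(Male = 0.6, Female = 0.4)),
#'                          beta = list(gender = c(Female = 0.8)), intercept = -0.5,
#'                          seed = 7)
#' mean(g$status == "FRAIL")
#' @export
generate_parametric <- function(n,
                                covariates = list(gender = c(Male = 0.573, Female = 0.427)),
                                beta = list(), intercept = 0, seed = 1L) {
  if (n <= 0) fi30_stop("fi30_spec_error", "n must be positive")
  for (cv in names(covariates)) {
    p <- covariates[[cv]]
    if (is.null(names(p)) || abs(sum(p) - 1) > 1e-8 || any(p < 0)) {
      fi30_stop("fi30_spec_error",
                sprintf("covariate %s: level probabilities must be named, non-negative and sum to 1", cv))
    }
  }
  with_seed(seed, {
    out <- data.frame(id = seq_len(n))
    eta <- rep(intercept, n)
    for (cv in names(covariates)) {
      p <- covariates[[cv]]
      x <- sample(names(p), n, replace = TRUE, prob = p)
      out[[cv]] <- x
      eff <- beta[[cv]]
      if (!is.null(eff)) {
        hit <- match(x, names(eff))
        eta <- eta + ifelse(is.na(hit), 0, eff[hit])
      }
    }
    p_frail <- plogis(eta)
    frail <- rbinom(n, 1, p_frail) == 1
    fi <- ifelse(frail, runif(n, 0.24, 0.71), runif(n, 0.05, 0.24))
    # the frail band is open at 0.24: nudge any exact boundary draw up
    fi[frail & fi <= 0.24] <- 0.2400001
    out$p_frail <- p_frail
    out$fi <- fi
    out$category <- categorize_fi(fi)
    out$status <- dichotomize_fi(fi)
    attr(out, "beta") <- beta
    attr(out, "intercept") <- intercept
    attr(out, "seed") <- seed
    out
  })
}

#' Calibration summary of a generated (or real) cohort
#'
#' Means and dispersions to eyeball against a study's printed calibration
#' values: mean/SD of FI and its range, severity-category proportions,
#' binary frailty prevalence, and mean/SD age when an `age` column exists.
#'
#' @param cohort scored data.frame with `fi` (and optionally `category`,
#'   `status`, `age`).
#' @return List of class `fi30_calibration`.
#' @export
calibration_report <- function(cohort) {
  if (!is.data.frame(cohort) || nrow(cohort) == 0) {
    fi30_stop("fi30_input_error", "cohort must be a non-empty data.frame")
  }
  if (!"fi" %in% names(cohort)) {
    fi30_stop("fi30_input_error", "cohort carries no fi column")
  }
  category <- if ("category" %in% names(cohort)) cohort$category else categorize_fi(cohort$fi)
  status <- if ("status" %in% names(cohort)) cohort$status else dichotomize_fi(cohort$fi)
  out <- list(
    n = nrow(cohort),
    fi_mean = mean(cohort$fi), fi_sd = stats::sd(cohort$fi),
    fi_range = range(cohort$fi),
    category_proportions = prop.table(table(factor(category, levels = FI_CATEGORIES))),
    frail_prevalence = mean(status == "FRAIL")
  )
  if ("age" %in% names(cohort)) {
    out$age_mean <- mean(cohort$age)
    out$age_sd <- stats::sd(cohort$age)
  }
  structure(out, class = "fi30_calibration")
}

#' @export
print.fi30_calibration <- function(x, ...) {
  cat(sprintf("Cohort calibration (n = %d)\n", x$n))
  cat(sprintf("  FI: mean %.3f (SD %.3f), range %.3f-%.3f\n",
              x$fi_mean, x$fi_sd, x$fi_range[1], x$fi_range[2]))
  cat("  Severity proportions:",
      paste(sprintf("%s %.3f", names(x$category_proportions),
                    as.numeric(x$category_proportions)), collapse = ", "), "\n")
  cat(sprintf("  Frail prevalence: %.3f\n", x$frail_prevalence))
  if (!is.null(x$age_mean)) {
    cat(sprintf("  Age: mean %.2f (SD %.2f)\n", x$age_mean, x$age_sd))
  }
  invisible(x)
}

#' Draw continuous ages for a cohort
#'
#' Truncated-normal ages (mean 63.61, SD 8.73, range 55-100 by default)
#' for calibration displays; when the cohort has an `age_group` column
#' the draw is rejected into the subject's age band.
#'
#' @param cohort data.frame (optionally with `age_group`).
#' @param mean,sd,lo,hi truncated-normal parameters.
#' @param seed integer seed.
#' @return `cohort` with an `age` column appended.
#' @export
add_ages <- function(cohort, mean = 63.61, sd = 8.73, lo = 55, hi = 100,
                     seed = 1L) {
  bands <- list("55-59" = c(55, 60), "60-64" = c(60, 65),
                "65-69" = c(65, 70), "70+" = c(70, hi + 1))
  with_seed(seed, {
    draw <- function(a, b, k) {
      out <- numeric(0)
      while (length(out) < k) {
        x <- stats::rnorm(2 * k, mean, sd)
        out <- c(out, x[x >= a & x < b])
      }
      out[seq_len(k)]
    }
    if ("age_group" %in% names(cohort)) {
      age <- numeric(nrow(cohort))
      for (g in unique(cohort$age_group)) {
        idx <- which(cohort$age_group == g)
        b <- bands[[g]] %||% c(lo, hi)
        age[idx] <- draw(b[1], min(b[2], hi + 1), length(idx))
      }
      cohort$age <- age
    } else {
      cohort$age <- draw(lo, hi + 1, nrow(cohort))
    }
    cohort
  })
}
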