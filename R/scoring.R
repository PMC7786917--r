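# FI computation, severity classification and binary dichotomization.

FI_CATEGORIES <- c("FIT", "MILD", "MODERATE", "SEVERE")
FI_CUTS <- c(FIT = 0.12, MILD = 0.24, MODERATE = 0.36)
FRAIL_CUT <- 0.24

#' Compute the frailty index from a deficit vector
#'
#' The frailty index is the accumulated deficit load divided by the number
#' of deficits actually measured:
#' \deqn{FI = \sum \mathrm{deficits} / (30 - \sum \mathrm{missing})}
#' Missing items shrink the denominator rather than being imputed. A score
#' is refused when fewer than `min_items` of the 30 items are non-missing,
#' to avoid degenerate indices from tiny denominators.
#'
#' @param deficits numeric vector of length 30 of deficit weights in
#'   \[0, 1\], `NA` for missing items; or a matrix/data.frame with 30
#'   columns (one row per subject).
#' @param min_items minimum number of non-missing items required
#'   (default 24, i.e. 80% completeness).
#' @return For a single vector, a list of class `fi30_score` with elements
#'   `fi`, `deficit_sum`, `n_missing`. For a matrix, a data.frame with one
#'   row per subject and those three columns.
#' @examples
#' compute_fi(rep(0, 30))$fi                      # 0
#' compute_fi(c(rep(1, 15), rep(0, 15)))$fi       # 0.5
#' compute_fi(c(rep(1, 7), rep(0, 21), NA, NA))$fi  # 7/28 = 0.25
#' @export
compute_fi <- function(deficits, min_items = 24L) {
  if (is.matrix(deficits) || is.data.frame(deficits)) {
    m <- as.matrix(deficits)
    res <- t(apply(m, 1L, function(r) {
      s <- compute_fi(as.numeric(r), min_items = min_items)
      c(fi = s$fi, deficit_sum = s$deficit_sum, n_missing = s$n_missing)
    }))
    return(as.data.frame(res))
  }
  deficits <- as.numeric(deficits)
  if (length(deficits) != N_ITEMS) {
    fi30_stop("fi30_score_error",
              sprintf("deficit vector must have length %d, got %d",
                      N_ITEMS, length(deficits)))
  }
  ok <- !is.na(deficits)
  if (any(deficits[ok] < 0 | deficits[ok] > 1)) {
    fi30_stop("fi30_score_error", "deficit weights must lie in [0, 1]")
  }
  n_nonmiss <- sum(ok)
  if (n_nonmiss < min_items) {
    fi30_stop("fi30_incomputable_error",
              sprintf("only %d of %d items non-missing; %d required",
                      n_nonmiss, N_ITEMS, min_items))
  }
  deficit_sum <- sum(deficits[ok])
  n_missing <- N_ITEMS - n_nonmiss
  structure(list(fi = deficit_sum / (N_ITEMS - n_missing),
                 deficit_sum = deficit_sum,
                 n_missing = n_missing),
            class = "fi30_score")
}

check_fi_domain <- function(fi) {
  fi <- as.numeric(fi)
  if (any(is.na(fi)) || any(fi < 0 | fi > 1)) {
    fi30_stop("fi30_domain_error", "fi must lie in [0, 1] and be non-missing")
  }
  fi
}

#' Classify a frailty index into a severity category
#'
#' Four right-closed bands: FIT (fi <= 0.12, good health), MILD
#' (0.12 < fi <= 0.24, slightly poor health), MODERATE (0.24 < fi <= 0.36,
#' poor health), SEVERE (fi > 0.36, very poor health). Boundary values
#' belong to the less severe band; fi = 0 is FIT.
#'
#' @param fi numeric vector of frailty indices in \[0, 1\].
#' @return Factor with levels FIT, MILD, MODERATE, SEVERE.
#' @examples
#' categorize_fi(c(0.12, 0.24, 0.36, 0.37))
#' @export
categorize_fi <- function(fi) {
  fi <- check_fi_domain(fi)
  # bands are right-closed: a boundary value belongs to the less severe band
  idx <- 1L + (fi > FI_CUTS["FIT"]) + (fi > FI_CUTS["MILD"]) +
    (fi > FI_CUTS["MODERATE"])
  factor(FI_CATEGORIES[idx], levels = FI_CATEGORIES)
}

#' Dichotomize a frailty index into fit/frail
#'
#' Binary collapse of the severity bands at fi = 0.24: FIT (fairly
#' healthy, fi <= 0.24) versus FRAIL (medical conditions, fi > 0.24). This
#' is the outcome of the logistic risk-factor model.
#'
#' @param fi numeric vector of frailty indices in \[0, 1\].
#' @return Factor with levels FIT, FRAIL.
#' @examples
#' dichotomize_fi(c(0.24, 0.241, 0.71))
#' @export
dichotomize_fi <- function(fi) {
  fi <- check_fi_domain(fi)
  factor(ifelse(fi > FRAIL_CUT, "FRAIL", "FIT"), levels = c("FIT", "FRAIL"))
}

#' @export
print.fi30_score <- function(x, ...) {
  cat(sprintf("FI-30 score: fi = %.4f (deficit sum %.2f over %d items, %d missing)\n",
              x$fi, x$deficit_sum, N_ITEMS - x$n_missing, x$n_missing))
  invisible(x)
}

#' Score a cohort of subject records
#'
#' Takes a data.frame with one row per subject and adds `fi`, `category`
#' and `status` columns. Three input layouts are recognised, in order of
#' precedence:
#' \enumerate{
#'   \item raw item responses in columns `item_1` .. `item_30` (labels or
#'     pre-coded weights), coded through `registry` and scored by
#'     [compute_fi()]; raw measurement columns (`height_m`, `weight_kg`,
#'     `sbp_mmhg`, `dbp_mmhg`, `rbs_mmol_l`, `gds_total` or
#'     `gds_q1`..`gds_q15`), when present, are graded by the `measurements`
#'     functions and override the corresponding item columns;
#'   \item a precomputed `fi` column, which is classified directly.
#' }
#' Missing cells (empty string or NA) count toward the denominator
#' adjustment. Subjects whose score is incomputable (fewer than `min_items`
#' answered) get `NA` scores and are listed in the `incomputable` attribute.
#'
#' @param records data.frame of subject records.
#' @param registry item registry (default the shipped FI-30 registry).
#' @param min_items completeness threshold passed to [compute_fi()].
#' @param graders optional overrides for the measurement graders, a list
#'   with any of `bmi`, `bp`, `rbs`, `gds` (functions).
#' @return `records` with columns `fi`, `category`, `status` appended
#'   (and `deficit_sum`, `n_missing` when scored from items).
#' @export
score_cohort <- function(records, registry = fi30_registry(),
                         min_items = 24L, graders = list()) {
  if (!is.data.frame(records) || nrow(records) == 0) {
    fi30_stop("fi30_input_error", "records must be a non-empty data.frame")
  }
  item_cols <- paste0("item_", seq_len(N_ITEMS))
  if (all(item_cols %in% names(records)) || any(measurement_cols() %in% names(records))) {
    wmat <- coded_item_matrix(records, registry, graders)
    scores <- vector("list", nrow(wmat))
    bad <- integer(0)
    for (i in seq_len(nrow(wmat))) {
      s <- tryCatch(compute_fi(wmat[i, ], min_items = min_items),
                    fi30_incomputable_error = function(e) e)
      if (inherits(s, "fi30_incomputable_error")) {
        bad <- c(bad, i)
        scores[[i]] <- list(fi = NA_real_, deficit_sum = NA_real_,
                            n_missing = sum(is.na(wmat[i, ])))
      } else scores[[i]] <- s
    }
    records$fi <- vapply(scores, function(s) s$fi, 1)
    records$deficit_sum <- vapply(scores, function(s) s$deficit_sum, 1)
    records$n_missing <- vapply(scores, function(s) as.numeric(s$n_missing), 1)
    attr(records, "incomputable") <- bad
  } else if (!"fi" %in% names(records)) {
    fi30_stop("fi30_input_error",
              "records need either item_1..item_30 columns, raw measurement columns, or an fi column")
  }
  ok <- !is.na(records$fi)
  records$category <- factor(NA_character_, levels = FI_CATEGORIES)
  records$status <- factor(NA_character_, levels = c("FIT", "FRAIL"))
  records$category[ok] <- categorize_fi(records$fi[ok])
  records$status[ok] <- dichotomize_fi(records$fi[ok])
  records
}

measurement_cols <- function() {
  c("height_m", "weight_kg", "sbp_mmhg", "dbp_mmhg", "rbs_mmol_l",
    "gds_total", paste0("gds_q", 1:15))
}

# build the n x 30 coded weight matrix from raw item labels and/or raw
# measurement columns
coded_item_matrix <- function(records, registry, graders = list()) {
  n <- nrow(records)
  wmat <- matrix(NA_real_, n, N_ITEMS)
  for (j in seq_len(N_ITEMS)) {
    col <- paste0("item_", j)
    if (col %in% names(records)) {
      wmat[, j] <- code_item(registry[[as.character(j)]], records[[col]])
    }
  }
  g <- function(name, default) graders[[name]] %||% default
  if (all(c("height_m", "weight_kg") %in% names(records))) {
    bmi <- compute_bmi(records$height_m, records$weight_kg)
    wmat[, 10L] <- g("bmi", grade_bmi)(bmi)$weight
  }
  if ("rbs_mmol_l" %in% names(records)) {
    wmat[, 17L] <- g("rbs", grade_rbs)(records$rbs_mmol_l)$weight
  }
  gds_q <- paste0("gds_q", 1:15)
  if ("gds_total" %in% names(records)) {
    wmat[, 20L] <- g("gds", grade_gds)(records$gds_total)$weight
  } else if (all(gds_q %in% names(records))) {
    total <- rowSums(records[gds_q])
    wmat[, 20L] <- g("gds", grade_gds)(total)$weight
  }
  if (all(c("sbp_mmhg", "dbp_mmhg") %in% names(records))) {
    wmat[, 22L] <- g("bp", grade_bp)(records$sbp_mmhg, records$dbp_mmhg)$weight
  }
  wmat
}
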