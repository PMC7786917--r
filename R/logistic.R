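# Binary logistic regression for frailty risk factors, with Wald
# intervals, in univariable (one covariate at a time) and multivariable
# (all covariates jointly) modes.

#' Fit the binary logistic frailty model
#'
#' Maximum-likelihood logistic regression of the binary fit/frail status
#' on socio-demographic covariates, fitted by iteratively reweighted least
#' squares (up to 100 iterations, tight convergence tolerance). Covariates
#' are expanded to indicator terms against the reference levels declared
#' in the data dictionary. Standard errors are Wald (inverse observed
#' information); odds ratios are exp(beta) with 95% intervals
#' exp(beta +/- 1.96 se) and two-sided normal p-values.
#'
#' In `"univariable"` mode each covariate is fitted in its own
#' one-covariate model (the "unadjusted OR" of a risk-factor table);
#' `"multivariable"` fits all covariates jointly (the "adjusted OR").
#'
#' @param records scored subject data.frame with a `status` column
#'   (levels FIT/FRAIL) and the covariate columns.
#' @param covariates character vector of covariate column names; empty
#'   fits the intercept-only model (multivariable mode only).
#' @param mode `"multivariable"` (default) or `"univariable"`.
#' @param outcome name of the binary outcome column (default `"status"`;
#'   the second factor level is the event).
#' @param dictionary covariate dictionary supplying level order and
#'   reference levels (default [fi30_covariates()]).
#' @return Object of class `fi30_logistic`: list with `terms` (data.frame:
#'   covariate, level, beta, se, adjusted_or, ci_low, ci_high, p_value;
#'   reference levels carry NA estimates), `mode`, `converged`,
#'   `n_iterations`, `log_likelihood`, `n`, and `fits` (the underlying
#'   glm objects).
#' @export
fit_logistic <- function(records, covariates,
                         mode = c("multivariable", "univariable"),
                         outcome = "status", dictionary = fi30_covariates()) {
  mode <- match.arg(mode)
  covariates <- as.character(covariates)
  if (mode == "univariable" && length(covariates) == 0) {
    fi30_stop("fi30_input_error", "univariable mode needs at least one covariate")
  }
  if (!outcome %in% names(records)) {
    fi30_stop("fi30_input_error", sprintf("no outcome column '%s'", outcome))
  }
  missing_cov <- setdiff(covariates, names(records))
  if (length(missing_cov)) {
    fi30_stop("fi30_input_error",
              sprintf("unknown covariate(s): %s", paste(missing_cov, collapse = ", ")))
  }
  y <- records[[outcome]]
  if (!is.factor(y)) y <- factor(y)
  if (nlevels(droplevels(y)) != 2) {
    fi30_stop("fi30_input_error", "outcome must have exactly two observed classes")
  }
  dat <- records[covariates]
  for (cv in covariates) {
    x <- as.character(dat[[cv]])
    lv <- if (cv %in% names(dictionary)) dictionary[[cv]]$levels else unique(x)
    ref <- if (cv %in% names(dictionary)) dictionary[[cv]]$reference else lv[1]
    f <- factor(x, levels = lv)
    if (anyNA(f)) {
      fi30_stop("fi30_input_error",
                sprintf("covariate %s has values outside its declared levels", cv))
    }
    dat[[cv]] <- stats::relevel(droplevels(f), ref = ref)
  }
  dat[[".y"]] <- as.integer(y == levels(y)[2])

  fit_one <- function(rhs) {
    fml <- stats::as.formula(
      paste(".y ~", if (length(rhs)) paste(rhs, collapse = " + ") else "1"))
    warned_sep <- FALSE
    fit <- withCallingHandlers(
      stats::glm(fml, family = stats::binomial(),
                 data = dat,
                 control = stats::glm.control(epsilon = 1e-10, maxit = 100)),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
          warned_sep <<- TRUE
        }
        invokeRestart("muffleWarning")
      })
    beta <- stats::coef(fit)
    if (anyNA(beta)) {
      fi30_stop("fi30_rank_deficiency_error",
                sprintf("singular design: no estimate for %s",
                        paste(names(beta)[is.na(beta)], collapse = ", ")))
    }
    if (warned_sep && any(abs(beta[-1]) > 10)) {
      fi30_stop("fi30_separation_error",
                sprintf("complete or quasi-complete separation on term(s): %s",
                        paste(names(beta)[-1][abs(beta[-1]) > 10], collapse = ", ")))
    }
    fit
  }

  term_rows <- function(fit, covs) {
    beta <- stats::coef(fit)
    se <- sqrt(diag(stats::vcov(fit)))
    rows <- list()
    rows[["(Intercept)"]] <- data.frame(
      covariate = "(Intercept)", level = NA_character_,
      beta = beta[["(Intercept)"]], se = se[["(Intercept)"]],
      stringsAsFactors = FALSE)
    for (cv in covs) {
      lvs <- levels(dat[[cv]])
      for (lv in lvs) {
        nm <- paste0(cv, lv)
        if (lv == lvs[1]) {  # reference level: no estimate
          rows[[paste(cv, lv)]] <- data.frame(
            covariate = cv, level = lv, beta = NA_real_, se = NA_real_,
            stringsAsFactors = FALSE)
        } else {
          rows[[paste(cv, lv)]] <- data.frame(
            covariate = cv, level = lv, beta = beta[[nm]], se = se[[nm]],
            stringsAsFactors = FALSE)
        }
      }
    }
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  }

  if (mode == "multivariable") {
    fit <- fit_one(covariates)
    terms <- term_rows(fit, covariates)
    fits <- list(fit)
    converged <- fit$converged
    n_iter <- fit$iter
    ll <- as.numeric(stats::logLik(fit))
  } else {
    fits <- lapply(covariates, function(cv) fit_one(cv))
    names(fits) <- covariates
    terms <- do.call(rbind, c(lapply(seq_along(covariates), function(i) {
      tr <- term_rows(fits[[i]], covariates[i])
      tr[tr$covariate != "(Intercept)", , drop = FALSE]
    }), list(make.row.names = FALSE)))
    converged <- all(vapply(fits, function(f) f$converged, TRUE))
    n_iter <- max(vapply(fits, function(f) f$iter, 1L))
    ll <- sum(vapply(fits, function(f) as.numeric(stats::logLik(f)), 1))
  }
  terms$adjusted_or <- exp(terms$beta)
  terms$ci_low <- exp(terms$beta - Z95 * terms$se)
  terms$ci_high <- exp(terms$beta + Z95 * terms$se)
  terms$p_value <- 2 * stats::pnorm(-abs(terms$beta / terms$se))
  structure(list(terms = terms, mode = mode, converged = converged,
                 n_iterations = n_iter, log_likelihood = ll,
                 n = nrow(dat), fits = fits),
            class = "fi30_logistic")
}

#' @export
print.fi30_logistic <- function(x, digits = 3, ...) {
  cat(sprintf("%s logistic model (n = %d, %s in %d iterations, logLik %.2f)\n",
              x$mode, x$n,
              if (x$converged) "converged" else "NOT converged",
              x$n_iterations, x$log_likelihood))
  tr <- x$terms
  num <- vapply(tr, is.numeric, TRUE)
  tr[num] <- lapply(tr[num], round, digits)
  print(tr, row.names = FALSE)
  invisible(x)
}

#' @importFrom stats logLik as.formula relevel sd
NULL
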