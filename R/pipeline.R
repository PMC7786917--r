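# End-to-end pipeline: read -> measure -> score -> classify -> associate
# -> report. Pure orchestration; every number in a report is produced by
# an operation from the other modules.

#' Read a subject table
#'
#' Comma-separated UTF-8 text with a header row. Empty cells and "NA" are
#' read as missing.
#'
#' @param path path to the CSV file.
#' @return data.frame of subject records.
#' @export
read_subjects <- function(path) {
  if (!file.exists(path)) {
    fi30_stop("fi30_input_error", sprintf("input file not found: %s", path))
  }
  df <- tryCatch(
    read.csv(path, stringsAsFactors = FALSE, na.strings = c("", "NA")),
    error = function(e) fi30_stop("fi30_input_error",
                                  sprintf("cannot parse %s: %s", path,
                                          conditionMessage(e))))
  if (nrow(df) == 0 || ncol(df) == 0) {
    fi30_stop("fi30_input_error",
              sprintf("input %s is empty; expected a header row plus one row per subject", path))
  }
  df
}

#' Build a pipeline configuration
#'
#' @param input path to the subject CSV (ignored when `simulate` is set).
#' @param output_dir directory the report bundle is written into.
#' @param simulate `NULL`, or `"table_faithful"` / `"parametric"` to
#'   generate the cohort instead of reading one.
#' @param registry_path optional path to a replacement item registry CSV.
#' @param covariates covariate columns to analyse (default: all dictionary
#'   covariates present in the data).
#' @param min_items completeness threshold for [compute_fi()].
#' @param ci_method prevalence interval method, `"wilson"` or `"wald"`.
#' @param odds_convention `"subgroup"` (within-level frail/fit odds, the
#'   published-table convention) or `"ratio"` (reference-contrast OR).
#' @param max_incomputable_frac maximum tolerated fraction of subjects
#'   whose score is incomputable before the run fails.
#' @param digits decimals for printed floats in the report tables.
#' @param seed integer seed used by simulation.
#' @param n cohort size for parametric simulation.
#' @return List of class `fi30_config`.
#' @export
pipeline_config <- function(input = NULL, output_dir = "fi30_report",
                            simulate = NULL, registry_path = NULL,
                            covariates = NULL, min_items = 24L,
                            ci_method = "wilson",
                            odds_convention = "subgroup",
                            max_incomputable_frac = 0.05,
                            digits = 3L, seed = 1L, n = 400L) {
  if (!ci_method %in% c("wilson", "wald")) {
    fi30_stop("fi30_config_error", "ci_method must be 'wilson' or 'wald'")
  }
  if (!odds_convention %in% c("subgroup", "ratio")) {
    fi30_stop("fi30_config_error", "odds_convention must be 'subgroup' or 'ratio'")
  }
  if (!is.null(simulate) && !simulate %in% c("table_faithful", "parametric")) {
    fi30_stop("fi30_config_error",
              "simulate must be NULL, 'table_faithful' or 'parametric'")
  }
  if (is.null(simulate) && is.null(input)) {
    fi30_stop("fi30_config_error", "either input or simulate must be given")
  }
  structure(list(input = input, output_dir = output_dir, simulate = simulate,
                 registry_path = registry_path, covariates = covariates,
                 min_items = as.integer(min_items), ci_method = ci_method,
                 odds_convention = odds_convention,
                 max_incomputable_frac = max_incomputable_frac,
                 digits = as.integer(digits), seed = as.integer(seed),
                 n = as.integer(n)),
            class = "fi30_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file whose keys are the arguments of
#'   [pipeline_config()].
#' @return List of class `fi30_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) {
    fi30_stop("fi30_config_error", sprintf("config file not found: %s", path))
  }
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals)
}

fmt <- function(x, digits) {
  ifelse(is.na(x), "", formatC(x, digits = digits, format = "f"))
}

#' Run the full analysis pipeline
#'
#' Reads (or simulates) a cohort, scores it, classifies severity, runs
#' the association layer, and writes a report bundle into
#' `config$output_dir`:
#' \describe{
#'   \item{scored_subjects.csv}{one row per subject with fi, category, status}
#'   \item{crosstabs.csv}{level x severity counts with binary collapse and
#'     the Pearson chi-square per covariate}
#'   \item{odds_table.csv}{per-level unadjusted (univariable) and adjusted
#'     (multivariable) odds with 95% Wald intervals}
#'   \item{prevalence.csv}{per-category and binary prevalence with CIs}
#'   \item{summary.json}{machine-readable summary of every table}
#'   \item{manifest.json}{seed, config, package version, resolved cut points}
#'   \item{errors.csv}{subjects with incomputable scores, when any}
#' }
#'
#' @param config an `fi30_config` from [pipeline_config()] or
#'   [read_config()].
#' @return Invisibly, a list with the in-memory results (`cohort`,
#'   `crosstabs`, `chi_square`, `odds`, `logistic_univariable`,
#'   `logistic_multivariable`, `prevalence`, `calibration`, `manifest`).
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "fi30_config")) {
    fi30_stop("fi30_config_error", "config must come from pipeline_config()")
  }
  registry <- if (!is.null(config$registry_path)) {
    read_registry(config$registry_path)
  } else fi30_registry()

  cohort <- if (is.null(config$simulate)) {
    read_subjects(config$input)
  } else if (config$simulate == "table_faithful") {
    generate_table_faithful(seed = config$seed)
  } else {
    generate_parametric(n = config$n, seed = config$seed)
  }

  needs_scoring <- !all(c("fi", "category", "status") %in% names(cohort))
  if (needs_scoring) {
    cohort <- score_cohort(cohort, registry = registry,
                           min_items = config$min_items)
    bad <- attr(cohort, "incomputable") %||% integer(0)
    if (length(bad) / nrow(cohort) > config$max_incomputable_frac) {
      fi30_stop("fi30_pipeline_error",
                sprintf("%d of %d subjects (%.1f%%) have incomputable scores; tolerance is %.1f%%",
                        length(bad), nrow(cohort),
                        100 * length(bad) / nrow(cohort),
                        100 * config$max_incomputable_frac))
    }
  } else bad <- integer(0)

  dict <- fi30_covariates()
  covs <- config$covariates %||% intersect(names(dict), names(cohort))
  scored <- cohort[!is.na(cohort$fi), , drop = FALSE]

  crosstabs <- lapply(covs, function(cv) crosstab(scored, cv, dict))
  names(crosstabs) <- covs
  chis <- lapply(crosstabs, chi_square)

  odds <- do.call(rbind, c(lapply(covs, function(cv) {
    ct <- crosstabs[[cv]]
    ref <- dict[[cv]]$reference %||% rownames(ct$counts)[1]
    do.call(rbind, lapply(rownames(ct$counts), function(lv) {
      o <- if (config$odds_convention == "subgroup") {
        tryCatch(subgroup_frailty_odds(ct, lv), fi30_error = function(e) NULL)
      } else if (lv != ref) {
        tryCatch(odds_ratio(ct, lv, ref), fi30_error = function(e) NULL)
      }
      data.frame(covariate = cv, level = lv,
                 estimate = if (is.null(o)) NA_real_ else o$estimate,
                 ci_low = if (is.null(o)) NA_real_ else o$ci_low,
                 ci_high = if (is.null(o)) NA_real_ else o$ci_high,
                 stringsAsFactors = FALSE)
    }))
  }), list(make.row.names = FALSE)))

  log_uni <- fit_logistic(scored, covs, mode = "univariable", dictionary = dict)
  log_multi <- fit_logistic(scored, covs, mode = "multivariable", dictionary = dict)

  prev <- do.call(rbind, lapply(FI_CATEGORIES, function(cat) {
    ci <- prevalence_ci(sum(scored$category == cat), nrow(scored),
                        method = config$ci_method)
    data.frame(outcome = cat, k = ci$k, n = ci$n, estimate = ci$estimate,
               ci_low = ci$ci_low, ci_high = ci$ci_high,
               stringsAsFactors = FALSE)
  }))
  frail_ci <- prevalence_ci(sum(scored$status == "FRAIL"), nrow(scored),
                            method = config$ci_method)
  prev <- rbind(prev, data.frame(outcome = "FRAIL", k = frail_ci$k,
                                 n = frail_ci$n, estimate = frail_ci$estimate,
                                 ci_low = frail_ci$ci_low,
                                 ci_high = frail_ci$ci_high,
                                 stringsAsFactors = FALSE))

  calib <- calibration_report(scored)

  manifest <- list(
    package = "fi30",
    version = as.character(utils::packageVersion("fi30")),
    seed = config$seed,
    # paths are machine-specific and excluded so the manifest (and hence the
    # whole bundle) is byte-identical across reruns of one configuration
    config = {
      cf <- unclass(config)[!vapply(unclass(config), is.null, TRUE)]
      cf[setdiff(names(cf), c("input", "output_dir", "registry_path"))]
    },
    resolved_cut_points = list(
      severity_bands = as.list(FI_CUTS), frail_cut = FRAIL_CUT,
      bmi = list(normal_lo = 18.5, normal_hi = 25, severe_lo = 30),
      bp = list(sbp = c(140, 160, 180), dbp = c(90, 100, 110)),
      gds = list(moderate_lo = 5, severe_lo = 10),
      rbs = list(elevated_lo = 7.9, high_lo = 15)),
    n_subjects = nrow(cohort),
    n_incomputable = length(bad))

  # ---- write the bundle ------------------------------------------------
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$output_dir, f)
  d <- config$digits

  sc <- cohort
  sc$fi <- round(sc$fi, d)
  write.csv(sc, out("scored_subjects.csv"), row.names = FALSE)

  ct_rows <- do.call(rbind, c(lapply(covs, function(cv) {
    ct <- crosstabs[[cv]]; ch <- chis[[cv]]
    cbind(data.frame(covariate = cv, level = rownames(ct$counts),
                     stringsAsFactors = FALSE),
          as.data.frame(ct$counts), as.data.frame(ct$binary),
          data.frame(chisq = round(ch$statistic, d), df = ch$df,
                     p_value = round(ch$p_value, 4)))
  }), list(make.row.names = FALSE)))
  write.csv(ct_rows, out("crosstabs.csv"), row.names = FALSE)

  fmt_terms <- function(fit) {
    tr <- fit$terms[fit$terms$covariate != "(Intercept)",
                    c("covariate", "level", "adjusted_or", "ci_low",
                      "ci_high", "p_value")]
    names(tr)[3] <- "or"
    tr
  }
  ut <- fmt_terms(log_uni); mt <- fmt_terms(log_multi)
  names(ut)[3:6] <- paste0("unadj_", names(ut)[3:6])
  names(mt)[3:6] <- paste0("adj_", names(mt)[3:6])
  odds_tab <- merge(merge(odds, ut, by = c("covariate", "level"), all = TRUE),
                    mt, by = c("covariate", "level"), all = TRUE)
  odds_tab <- odds_tab[order(match(odds_tab$covariate, covs),
                             match(odds_tab$level,
                                   unlist(lapply(dict, `[[`, "levels")))), ]
  num <- vapply(odds_tab, is.numeric, TRUE)
  odds_tab[num] <- lapply(odds_tab[num], round, d)
  write.csv(odds_tab, out("odds_table.csv"), row.names = FALSE)

  prev_out <- prev
  prev_out[c("estimate", "ci_low", "ci_high")] <-
    lapply(prev_out[c("estimate", "ci_low", "ci_high")], round, d)
  write.csv(prev_out, out("prevalence.csv"), row.names = FALSE)

  summary_doc <- list(
    calibration = list(n = calib$n, fi_mean = calib$fi_mean,
                       fi_sd = calib$fi_sd, fi_range = calib$fi_range,
                       frail_prevalence = calib$frail_prevalence),
    chi_square = lapply(chis, unclass),
    prevalence = prev,
    odds = odds_tab)
  jsonlite::write_json(summary_doc, out("summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  if (length(bad)) {
    write.csv(data.frame(row = bad), out("errors.csv"), row.names = FALSE)
  }

  invisible(list(cohort = cohort, crosstabs = crosstabs, chi_square = chis,
                 odds = odds, logistic_univariable = log_uni,
                 logistic_multivariable = log_multi, prevalence = prev,
                 calibration = calib, manifest = manifest))
}
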