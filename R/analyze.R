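#' Cohort outcome analysis
#'
#' Reproduces the standard matched-therapy outcome pipeline on a scored
#' cohort: for each binary covariate, Kaplan-Meier medians, log-rank p and
#' univariate Cox hazard ratio for PFS and OS, and a Fisher/odds-ratio
#' contingency analysis of clinical benefit; covariates passing the
#' univariate screen (p < `alpha_enter`) enter multivariate Cox /
#' logistic models when at least two are selected.
#'
#' The covariates, each compared as level-vs-rest, are built from whichever
#' of these columns are present in `data`: `age` (dichotomized at the cohort
#' median), `sex` (female vs male), `histology` (adenocarcinoma vs not),
#' `line` (first line vs later), `n_drugs` (>= 2 drugs vs single),
#' `score_percent` (both "matched", score > 0, and "ms_high", score >
#' `cutoff`), and `immunotherapy` (logical). Patients with `not_evaluable`
#' best response (or SD of unknown duration) are excluded from the benefit
#' analysis only.
#'
#' @param data Data frame with one row per treated patient; required columns
#'   `score_percent`, `pfs_months`, `pfs_event`, `os_months`, `os_event`,
#'   `best_response`, `sd_duration_months`; optional covariate columns as
#'   above.
#' @param cutoff Matching Score cutoff percent for the high/low grouping.
#' @param alpha_enter Univariate entry threshold for the multivariate step.
#' @param ties Tie handling for Cox fits.
#' @return Object of class `cohort_analysis`: data frames `pfs`, `os`,
#'   `benefit`, plus `multivariate` (a list with `pfs`, `os`, `benefit`
#'   entries, `NULL` where the step was skipped) and `cutoff`.
#' @export
analyze_cohort <- function(data, cutoff = 50, alpha_enter = 0.1,
                           ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  if (is.null(data) || nrow(data) == 0) stop("empty cohort")
  req <- c("score_percent", "pfs_months", "pfs_event", "os_months", "os_event",
           "best_response")
  miss <- setdiff(req, names(data))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (!"sd_duration_months" %in% names(data)) data$sd_duration_months <- NA_real_

  covs <- list()
  if ("age" %in% names(data)) {
    covs[["age_ge_median"]] <- data$age >= stats::median(data$age, na.rm = TRUE)
  }
  if ("sex" %in% names(data)) covs[["female"]] <- tolower(data$sex) == "female"
  if ("histology" %in% names(data)) {
    covs[["adenocarcinoma"]] <- tolower(data$histology) == "adenocarcinoma"
  }
  if ("line" %in% names(data)) covs[["first_line"]] <- data$line == 1
  if ("n_drugs" %in% names(data)) covs[["multi_drug"]] <- data$n_drugs >= 2
  covs[["matched"]] <- data$score_percent > 0
  covs[["ms_high"]] <- dichotomize_score(data$score_percent, cutoff) == "high"
  if ("immunotherapy" %in% names(data)) {
    covs[["immunotherapy"]] <- as.logical(data$immunotherapy)
  }

  usable <- vapply(covs, function(v) {
    sum(v, na.rm = TRUE) >= 2 && sum(!v, na.rm = TRUE) >= 2
  }, logical(1))
  for (nm in names(covs)[!usable]) {
    warning("covariate '", nm, "' skipped: fewer than 2 patients per level")
  }
  covs <- covs[usable]
  if (length(covs) == 0) stop("no usable covariates")

  surv_row <- function(nm, v, time, event) {
    km1 <- km_curve(time[v], event[v])
    km0 <- km_curve(time[!v], event[!v])
    lr <- suppressWarnings(logrank_test(time, event, v))
    cx <- cox_fit(time, event, as.numeric(v), ties = ties)
    data.frame(covariate = nm, n_yes = sum(v), n_no = sum(!v),
               median_yes = km1$median_months, median_no = km0$median_months,
               hazard_ratio = cx$hazard_ratio, ci_low = cx$ci_low,
               ci_high = cx$ci_high, logrank_p = lr$p_value,
               stringsAsFactors = FALSE)
  }
  surv_table <- function(time, event) {
    do.call(rbind, lapply(names(covs), function(nm) {
      surv_row(nm, covs[[nm]], time, event)
    }))
  }
  pfs <- surv_table(data$pfs_months, data$pfs_event)
  os <- surv_table(data$os_months, data$os_event)

  evaluable <- data$best_response != "not_evaluable" &
    !(data$best_response == "SD" & is.na(data$sd_duration_months))
  ben <- clinical_benefit(data$best_response[evaluable],
                          data$sd_duration_months[evaluable])
  benefit <- do.call(rbind, lapply(names(covs), function(nm) {
    v <- covs[[nm]][evaluable]
    if (sum(v) == 0 || sum(!v) == 0) return(NULL)
    ct <- contingency_2x2(sum(ben[v]), sum(v), sum(ben[!v]), sum(!v))
    data.frame(covariate = nm, n_yes = sum(v), n_no = sum(!v),
               rate_yes = ct$rate_high, rate_low = ct$rate_low,
               odds_ratio = ct$odds_ratio, ci_low = ct$or_ci_low,
               ci_high = ct$or_ci_high, fisher_p = ct$fisher_p,
               stringsAsFactors = FALSE)
  }))

  multiv <- list(pfs = NULL, os = NULL, benefit = NULL)
  mk_matrix <- function(sel, rows = rep(TRUE, nrow(data))) {
    m <- vapply(sel, function(nm) as.numeric(covs[[nm]][rows]),
                numeric(sum(rows)))
    colnames(m) <- sel
    m
  }
  sel <- screen_univariate(pfs$covariate, pfs$logrank_p, alpha_enter)
  if (attr(sel, "run_multivariate")) {
    multiv$pfs <- cox_fit(data$pfs_months, data$pfs_event, mk_matrix(sel),
                          ties = ties)
  }
  sel <- screen_univariate(os$covariate, os$logrank_p, alpha_enter)
  if (attr(sel, "run_multivariate")) {
    multiv$os <- cox_fit(data$os_months, data$os_event, mk_matrix(sel),
                         ties = ties)
  }
  sel <- screen_univariate(benefit$covariate, benefit$fisher_p, alpha_enter)
  if (attr(sel, "run_multivariate")) {
    multiv$benefit <- logistic_fit(ben, mk_matrix(sel, evaluable))
  }

  structure(list(pfs = pfs, os = os, benefit = benefit,
                 multivariate = multiv, cutoff = cutoff,
                 n = nrow(data), n_evaluable = sum(evaluable)),
            class = "cohort_analysis")
}

#' @export
print.cohort_analysis <- function(x, ...) {
  cat(sprintf("<cohort_analysis> %d patients (%d response-evaluable), cutoff %s%%\n",
              x$n, x$n_evaluable, format(x$cutoff)))
  fmt_med <- function(m) ifelse(is.na(m), "NR", format(round(m, 1)))
  cat("Progression-free survival:\n")
  for (i in seq_len(nrow(x$pfs))) {
    r <- x$pfs[i, ]
    cat(sprintf("  %-16s %s vs %s mo; HR %.2f (%.2f-%.2f); log-rank p = %.3g\n",
                r$covariate, fmt_med(r$median_yes), fmt_med(r$median_no),
                r$hazard_ratio, r$ci_low, r$ci_high, r$logrank_p))
  }
  cat("Clinical benefit (SD >= 6 months / PR / CR):\n")
  for (i in seq_len(nrow(x$benefit))) {
    r <- x$benefit[i, ]
    cat(sprintf("  %-16s %d%% (%d/%d) vs %d%% (%d/%d); OR %.2f; Fisher p = %.3g\n",
                r$covariate,
                round_half_up(100 * r$rate_yes), round(r$rate_yes * r$n_yes), r$n_yes,
                round_half_up(100 * r$rate_low), round(r$rate_low * r$n_no), r$n_no,
                r$odds_ratio, r$fisher_p))
  }
  invisible(x)
}
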