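#' Kaplan-Meier curve
#'
#' Product-limit estimate of the survival function, with the median defined
#' as the smallest observed time at which the estimate drops to 0.5 or below
#' (undefined, `NA`, when the curve never reaches 0.5).
#'
#' @param time_months Positive follow-up times.
#' @param event Logical; `TRUE` = event observed, `FALSE` = censored.
#' @return Object of class `km_curve`: `event_times`, `survival_probs`
#'   (after each event time), `median_months`, `n`, and the underlying
#'   [survival::survfit] object as `fit`.
#' @export
km_curve <- function(time_months, event) {
  if (length(time_months) == 0) stop("no survival records")
  stopifnot(length(time_months) == length(event), all(time_months > 0))
  fit <- survival::survfit(survival::Surv(time_months, event) ~ 1)
  keep <- fit$n.event > 0
  surv <- fit$surv[keep]
  times <- fit$time[keep]
  med <- if (any(surv <= 0.5)) times[which(surv <= 0.5)[1]] else NA_real_
  structure(list(event_times = times, survival_probs = surv,
                 median_months = med, n = length(time_months), fit = fit),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("<km_curve> n = %d, %d event times, median = %s months\n",
              x$n, length(x$event_times),
              if (is.na(x$median_months)) "not reached" else
                format(x$median_months)))
  invisible(x)
}

#' Two-group log-rank test
#'
#' @param time_months Positive follow-up times.
#' @param event Logical event indicators.
#' @param group Two-level factor/character/logical group labels.
#' @return List with `chi_square`, `p_value` (1 df, two-sided) and `df`.
#' @export
logrank_test <- function(time_months, event, group) {
  group <- as.factor(group)
  if (nlevels(droplevels(group)) != 2) stop("log-rank test needs exactly two groups")
  group <- droplevels(group)
  for (lev in levels(group)) {
    if (sum(event[group == lev]) == 0) {
      warning("group '", lev, "' has zero events; log-rank statistic may be degenerate")
    }
  }
  sd <- survival::survdiff(survival::Surv(time_months, event) ~ group)
  chi <- unname(sd$chisq)
  list(chi_square = chi, p_value = stats::pchisq(chi, df = 1, lower.tail = FALSE),
       df = 1L)
}

#' Cox proportional-hazards fit
#'
#' Maximum partial-likelihood estimation with Wald confidence intervals.
#' Monotone likelihood (perfect separation of risk sets) is flagged and the
#' confidence interval reported as unbounded.
#'
#' @param time_months Positive follow-up times.
#' @param event Logical event indicators.
#' @param covariates Numeric vector, matrix or data frame of covariates.
#' @param ties `"efron"` (default) or `"breslow"` tie handling.
#' @return Data frame with one row per covariate: `term`, `hazard_ratio`,
#'   `ci_low`, `ci_high`, `p_value`, `flagged`.
#' @export
cox_fit <- function(time_months, event, covariates, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  x <- as.matrix(covariates)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  stopifnot(nrow(x) == length(time_months), all(is.finite(x)))
  if (sum(event) == 0) stop("Cox fit needs at least one event")
  constant <- apply(x, 2, function(col) length(unique(col)) == 1)
  out <- data.frame(term = colnames(x), hazard_ratio = NA_real_,
                    ci_low = NA_real_, ci_high = NA_real_, p_value = NA_real_,
                    flagged = FALSE, stringsAsFactors = FALSE)
  if (all(constant)) {
    # no information: HR 1 by convention
    out$hazard_ratio <- 1
    out$ci_low <- 0
    out$ci_high <- Inf
    out$p_value <- 1
    return(out)
  }
  keep <- !constant
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(time_months, event) ~ x[, keep, drop = FALSE],
                    ties = ties),
    warning = function(w) {
      if (grepl("infinite|did not converge|Loglik converged before",
                conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  s <- summary(fit)
  coefs <- s$coefficients
  separated <- abs(coefs[, "coef"]) > 10 | coefs[, "se(coef)"] > 100
  out$hazard_ratio[keep] <- exp(coefs[, "coef"])
  out$ci_low[keep] <- exp(coefs[, "coef"] - 1.96 * coefs[, "se(coef)"])
  out$ci_high[keep] <- exp(coefs[, "coef"] + 1.96 * coefs[, "se(coef)"])
  out$p_value[keep] <- coefs[, "Pr(>|z|)"]
  out$flagged[keep] <- separated
  out$ci_low[keep][separated] <- 0
  out$ci_high[keep][separated] <- Inf
  if (any(constant)) {
    out$hazard_ratio[constant] <- 1
    out$ci_low[constant] <- 0
    out$ci_high[constant] <- Inf
    out$p_value[constant] <- 1
  }
  out
}

#' 2x2 contingency analysis of clinical benefit
#'
#' Benefit rates per group, the sample odds ratio with a Woolf (log) 95%
#' confidence interval (Haldane-Anscombe 0.5 correction when any cell is
#' zero), and the two-sided Fisher exact p-value.
#'
#' @param benefit_high,n_high Benefit count and total in the high group.
#' @param benefit_low,n_low Benefit count and total in the low group.
#' @return List of class `contingency_result`: `rate_high`, `rate_low`,
#'   `odds_ratio`, `or_ci_low`, `or_ci_high`, `fisher_p`, `table`.
#' @export
contingency_2x2 <- function(benefit_high, n_high, benefit_low, n_low) {
  stopifnot(benefit_high >= 0, benefit_low >= 0,
            benefit_high <= n_high, benefit_low <= n_low)
  if (n_high == 0 || n_low == 0) stop("each group must contain at least one patient")
  a <- benefit_high; b <- n_high - benefit_high
  c_ <- benefit_low; d <- n_low - benefit_low
  tab <- matrix(c(a, b, c_, d), nrow = 2, byrow = TRUE,
                dimnames = list(c("high", "low"), c("benefit", "no_benefit")))
  cells <- c(a, b, c_, d)
  if (any(cells == 0)) cells <- cells + 0.5
  or <- (cells[1] * cells[4]) / (cells[2] * cells[3])
  se <- sqrt(sum(1 / cells))
  fisher_p <- stats::fisher.test(tab)$p.value
  structure(list(rate_high = a / n_high, rate_low = c_ / n_low,
                 odds_ratio = or,
                 or_ci_low = exp(log(or) - 1.96 * se),
                 or_ci_high = exp(log(or) + 1.96 * se),
                 fisher_p = fisher_p, table = tab),
            class = "contingency_result")
}

#' @export
print.contingency_result <- function(x, ...) {
  cat(sprintf("<contingency_result> %s%% (%d/%d) vs %s%% (%d/%d); OR %.2f (%.2f-%.2f); Fisher p = %.3g\n",
              round_half_up(100 * x$rate_high), x$table[1, 1], sum(x$table[1, ]),
              round_half_up(100 * x$rate_low), x$table[2, 1], sum(x$table[2, ]),
              x$odds_ratio, x$or_ci_low, x$or_ci_high, x$fisher_p))
  invisible(x)
}

#' Logistic regression fit
#'
#' Maximum-likelihood logistic coefficients reported as odds ratios with Wald
#' 95% confidence intervals. Complete or quasi-complete separation is
#' detected (fitted probabilities degenerate or implausibly large
#' coefficients) and flagged, with the interval reported as unbounded.
#'
#' @param outcome Logical/binary outcome vector.
#' @param covariates Numeric vector, matrix or data frame of covariates.
#' @return Data frame with one row per covariate: `term`, `odds_ratio`,
#'   `ci_low`, `ci_high`, `p_value`, `flagged`.
#' @export
logistic_fit <- function(outcome, covariates) {
  y <- as.integer(outcome)
  if (length(unique(y)) < 2) stop("outcome must contain both classes")
  x <- as.matrix(covariates)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  stopifnot(nrow(x) == length(y), all(is.finite(x)))
  fit <- suppressWarnings(stats::glm(y ~ x, family = stats::binomial()))
  s <- summary(fit)
  coefs <- s$coefficients[-1, , drop = FALSE]
  eps <- 1e-8
  separated <- !fit$converged |
    abs(coefs[, "Estimate"]) > 10 | coefs[, "Std. Error"] > 100 |
    all(fit$fitted.values < eps | fit$fitted.values > 1 - eps)
  out <- data.frame(term = colnames(x),
                    odds_ratio = exp(coefs[, "Estimate"]),
                    ci_low = exp(coefs[, "Estimate"] - 1.96 * coefs[, "Std. Error"]),
                    ci_high = exp(coefs[, "Estimate"] + 1.96 * coefs[, "Std. Error"]),
                    p_value = coefs[, "Pr(>|z|)"],
                    flagged = separated, stringsAsFactors = FALSE)
  out$ci_low[separated] <- 0
  out$ci_high[separated] <- Inf
  rownames(out) <- NULL
  out
}

#' Univariate screen for multivariate entry
#'
#' Selects covariates whose univariate p-value is strictly below
#' `alpha_enter` (default 0.1), preserving input order. When fewer than two
#' covariates are selected the multivariate step is skipped (a single
#' selected covariate has nothing to be adjusted for).
#'
#' @param labels Covariate labels.
#' @param p_values Univariate p-values, same length as `labels`.
#' @param alpha_enter Entry threshold (strict `<`).
#' @return Character vector of selected labels, with attribute
#'   `run_multivariate` (`TRUE` when at least two were selected).
#' @export
screen_univariate <- function(labels, p_values, alpha_enter = 0.1) {
  stopifnot(length(labels) == length(p_values))
  sel <- labels[!is.na(p_values) & p_values < alpha_enter]
  structure(sel, run_multivariate = length(sel) >= 2)
}

#' ROC-based cutoff selection
#'
#' Evaluates candidate cutoffs (default: the unique observed scores) for
#' dichotomizing a score against a binary benefit label, classifying
#' "positive" as score strictly greater than the cutoff. The default
#' criterion is the Youden index (sensitivity + specificity - 1); ties are
#' broken toward the larger cutoff. `method = "rate_diff"` instead maximizes
#' the benefit-rate difference between the two groups.
#'
#' @param scores Numeric scores.
#' @param benefit_labels Logical labels (needs both classes present).
#' @param candidate_cutoffs Optional candidate cutoffs.
#' @param method `"youden"` or `"rate_diff"`.
#' @return The selected cutoff, with attribute `criterion` (its achieved
#'   criterion value).
#' @export
roc_cutoff <- function(scores, benefit_labels, candidate_cutoffs = NULL,
                       method = c("youden", "rate_diff")) {
  method <- match.arg(method)
  stopifnot(length(scores) == length(benefit_labels))
  benefit_labels <- as.logical(benefit_labels)
  if (!any(benefit_labels) || all(benefit_labels)) {
    stop("benefit labels must contain both classes")
  }
  cands <- sort(unique(candidate_cutoffs %||% scores))
  crit <- vapply(cands, function(ct) {
    pos <- scores > ct
    if (method == "youden") {
      sens <- mean(pos[benefit_labels])
      spec <- mean(!pos[!benefit_labels])
      sens + spec - 1
    } else {
      if (!any(pos) || all(pos)) return(-Inf)
      mean(benefit_labels[pos]) - mean(benefit_labels[!pos])
    }
  }, numeric(1))
  best <- max(crit)
  pick <- max(cands[crit == best])  # tie toward the larger cutoff
  structure(pick, criterion = best)
}

round_half_up <- function(x, digits = 0) {
  # report percentages the way clinical tables print them (0.5 rounds up)
  p <- 10^digits
  floor(x * p + 0.5) / p
}
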