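test_that("KM median equals the sample median under no censoring", {
  km <- km_curve(1:5, rep(TRUE, 5))
  expect_equal(km$median_months, 3)
  expect_equal(km$survival_probs, c(0.8, 0.6, 0.4, 0.2, 0))
  # with zero censoring the curve is the empirical survival function
  set.seed(3)
  t <- round(rexp(40, 0.2), 3)
  km <- km_curve(t, rep(TRUE, 40))
  emp <- vapply(km$event_times, function(x) mean(t > x), 1)
  expect_equal(km$survival_probs, emp)
})

test_that("KM handles censoring per the product-limit definition", {
  # times 1 (censored), 2, 3: steps 1.0 -> 0.5 at t=2 -> 0 at t=3; median 2
  km <- km_curve(c(1, 2, 3), c(FALSE, TRUE, TRUE))
  expect_equal(km$event_times, c(2, 3))
  expect_equal(km$survival_probs, c(0.5, 0))
  expect_equal(km$median_months, 2)
})

test_that("KM median is undefined when the curve never reaches 0.5", {
  expect_true(is.na(km_curve(c(5, 6, 7), c(FALSE, FALSE, FALSE))$median_months))
  expect_true(is.na(km_curve(c(1, 5, 6, 7), c(TRUE, FALSE, FALSE, FALSE))$median_months))
  expect_error(km_curve(numeric(), logical()), "no survival records")
  expect_true(all(diff(km_curve(rexp(30, 1) + 0.01, rep(TRUE, 30))$survival_probs) <= 0))
})

test_that("log-rank test is null for identical groups and matches the O-E oracle", {
  t <- c(1, 2, 3, 4, 5)
  lr <- suppressWarnings(logrank_test(c(t, t), rep(TRUE, 10),
                                      rep(c("a", "b"), each = 5)))
  expect_equal(lr$chi_square, 0, tolerance = 1e-10)
  expect_equal(lr$p_value, 1, tolerance = 1e-10)

  # 6-patient example against direct observed-minus-expected tabulation
  time <- c(1, 2.5, 4, 1.5, 3, 6)
  event <- c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE)
  grp <- rep(c("x", "y"), each = 3)
  lr <- logrank_test(time, event, grp)
  expect_equal(lr$chi_square, oracle_logrank_chisq(time, event, grp),
               tolerance = 1e-9)

  expect_warning(logrank_test(c(1, 2, 3, 4), c(TRUE, TRUE, FALSE, FALSE),
                              c("a", "a", "b", "b")), "zero events")
  expect_error(logrank_test(1:3, rep(TRUE, 3), c("a", "a", "a")),
               "two groups")
})

test_that("Cox fit maximizes the partial likelihood (grid-search oracle)", {
  set.seed(21)
  for (i in 1:5) {
    n <- 16
    x <- rbinom(n, 1, 0.5)
    t <- rexp(n, exp(0.8 * x))
    ev <- runif(n) > 0.2
    if (sum(ev) < 3 || length(unique(x)) < 2) next
    fit <- cox_fit(t, ev, x)
    if (fit$flagged || abs(log(fit$hazard_ratio)) > 4.5) next
    want <- oracle_cox_grid(t, ev, x)
    expect_equal(log(fit$hazard_ratio), want, tolerance = 2e-3,
                 info = paste("rep", i))
  }
})

test_that("Cox fit on a constant covariate reports no information", {
  fit <- cox_fit(rexp(10) + 0.1, rep(TRUE, 10), rep(1, 10))
  expect_equal(fit$hazard_ratio, 1)
  expect_equal(fit$p_value, 1)
})

test_that("Cox fit recovers a generating hazard ratio of 0.27", {
  set.seed(22)
  n <- 500
  arm <- rep(c(1, 0), each = n)  # 1 = high Matching Score arm
  med <- ifelse(arm == 1, 10.4, 2.8)
  # geometric mean over replicate cohorts: isolates estimator accuracy from
  # single-draw Monte-Carlo noise at the fixed cohort size
  hrs <- replicate(8, {
    t <- rexp(2 * n, log(2) / med)
    cox_fit(t, rep(TRUE, 2 * n), arm)$hazard_ratio
  })
  hr <- exp(mean(log(hrs)))
  expect_lt(abs(hr - 0.27) / 0.27, 0.15)
  fit <- cox_fit(rexp(2 * n, log(2) / med), rep(TRUE, 2 * n), arm)
  expect_true(fit$ci_low < fit$hazard_ratio & fit$hazard_ratio < fit$ci_high)
})

test_that("Cox flags monotone likelihood", {
  # covariate perfectly orders the event times
  t <- c(1, 2, 3, 10, 11, 12)
  x <- c(1, 1, 1, 0, 0, 0)
  fit <- cox_fit(t, rep(TRUE, 6), x)
  expect_true(fit$flagged)
  expect_equal(fit$ci_high, Inf)
})

test_that("Efron and Breslow tie handling are both available and differ on ties", {
  set.seed(23)
  t <- rep(1:5, each = 4)
  x <- rbinom(20, 1, 0.5)
  ev <- rep(TRUE, 20)
  hr_e <- cox_fit(t, ev, x, ties = "efron")$hazard_ratio
  hr_b <- cox_fit(t, ev, x, ties = "breslow")$hazard_ratio
  expect_false(isTRUE(all.equal(hr_e, hr_b, tolerance = 1e-12)))
})

test_that("contingency analysis reproduces printed benefit rates", {
  ms <- contingency_2x2(10, 14, 10, 41)
  expect_equal(round(100 * ms$rate_high), 71)
  expect_equal(round(100 * ms$rate_low), 24)
  io <- contingency_2x2(10, 18, 10, 37)
  expect_equal(round(100 * io$rate_high), 56)
  expect_equal(round(100 * io$rate_low), 27)
  expect_error(contingency_2x2(0, 0, 1, 5), "at least one patient")
})

test_that("odds ratio is symmetric and Fisher p matches enumeration", {
  sym <- contingency_2x2(1, 2, 1, 2)
  expect_equal(sym$odds_ratio, 1)
  expect_equal(sym$fisher_p, 1)
  set.seed(24)
  for (i in 1:25) {
    a <- sample(0:8, 1); b <- sample(0:8, 1)
    c_ <- sample(0:8, 1); d <- sample(0:8, 1)
    if ((a + b) == 0 || (c_ + d) == 0) next
    res <- contingency_2x2(a, a + b, c_, c_ + d)
    expect_equal(res$fisher_p, oracle_fisher_p(a, b, c_, d),
                 tolerance = 1e-9, info = paste(a, b, c_, d))
  }
  # transposing rows inverts the odds ratio
  r1 <- contingency_2x2(10, 14, 10, 41)
  r2 <- contingency_2x2(10, 41, 10, 14)
  expect_equal(r1$odds_ratio, 1 / r2$odds_ratio, tolerance = 1e-12)
})

test_that("Woolf CI uses the Haldane-Anscombe correction on zero cells", {
  res <- contingency_2x2(5, 5, 0, 5)
  expect_true(is.finite(res$odds_ratio))
  expect_true(res$or_ci_high > res$odds_ratio)
})

test_that("logistic fit equals the 2x2 cross-product odds ratio", {
  x <- rep(c(1, 1, 0, 0), c(10, 4, 10, 31))
  y <- rep(c(1, 0, 1, 0), c(10, 4, 10, 31))
  fit <- logistic_fit(y, x)
  expect_equal(fit$odds_ratio, (10 * 31) / (4 * 10), tolerance = 1e-4)
  expect_error(logistic_fit(rep(1, 10), rnorm(10)), "both classes")
})

test_that("logistic fit flags complete separation", {
  y <- rep(c(0, 1), each = 10)
  fit <- logistic_fit(y, y)
  expect_true(fit$flagged)
  expect_equal(fit$ci_high, Inf)
})

test_that("logistic fit recovers known odds ratios on orthogonal covariates", {
  set.seed(25)
  n <- 2000
  x1 <- rbinom(n, 1, 0.5)
  x2 <- rbinom(n, 1, 0.5)
  eta <- -0.3 + log(2) * x1 + log(0.5) * x2
  y <- rbinom(n, 1, plogis(eta))
  fit <- logistic_fit(y, cbind(a = x1, b = x2))
  expect_lt(abs(fit$odds_ratio[1] - 2) / 2, 0.2)
  expect_lt(abs(fit$odds_ratio[2] - 0.5) / 0.5, 0.2)
})

test_that("univariate screen selects p < 0.1 strictly, in order", {
  sel <- screen_univariate(c("MS", "IO", "matched"), c(0.002, 0.063, 0.41))
  expect_equal(as.character(sel), c("MS", "IO"))
  expect_true(attr(sel, "run_multivariate"))
  none <- screen_univariate(c("a", "b"), c(0.2, 0.5))
  expect_length(none, 0)
  boundary <- screen_univariate(c("a", "b"), c(0.1, 0.05))
  expect_equal(as.character(boundary), "b")
  expect_false(attr(boundary, "run_multivariate"))
})

test_that("ROC cutoff maximizes Youden with ties toward the larger cutoff", {
  expect_equal(as.numeric(roc_cutoff(c(10, 30, 50, 60, 80),
                                     c(FALSE, FALSE, FALSE, TRUE, TRUE))), 50)
  ct <- roc_cutoff(c(10, 20, 60, 80), c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(as.numeric(ct), 20)
  expect_equal(attr(ct, "criterion"), 1)
  # exhaustive-candidate check on a random case
  set.seed(26)
  scores <- sample(0:100, 30, replace = TRUE)
  labels <- runif(30) < plogis((scores - 40) / 15)
  if (any(labels) && !all(labels)) {
    ct <- roc_cutoff(scores, labels)
    js <- vapply(sort(unique(scores)), function(c0) {
      mean(scores[labels] > c0) + mean(scores[!labels] <= c0) - 1
    }, 1)
    expect_equal(attr(ct, "criterion"), max(js))
  }
  expect_error(roc_cutoff(1:4, rep(TRUE, 4)), "both classes")
})

test_that("ROC cutoff criterion is near zero for labels independent of scores", {
  set.seed(27)
  scores <- runif(400, 0, 100)
  labels <- runif(400) < 0.4
  ct <- roc_cutoff(scores, labels)
  expect_lt(attr(ct, "criterion"), 0.25)
})

test_that("log-rank p and Cox p point the same way on a clear two-group difference", {
  set.seed(28)
  t <- c(rexp(60, 1), rexp(60, 3))
  g <- rep(c(0, 1), each = 60)
  lr <- logrank_test(t, rep(TRUE, 120), g)
  cx <- cox_fit(t, rep(TRUE, 120), g)
  expect_lt(lr$p_value, 0.01)
  expect_lt(cx$p_value, 0.01)
  expect_gt(cx$hazard_ratio, 1)
  # score test of Cox equals the log-rank statistic on no-ties data
  sc <- survival::coxph(survival::Surv(t, rep(TRUE, 120)) ~ g)
  expect_equal(unname(summary(sc)$sctest["test"]), lr$chi_square,
               tolerance = 1e-6)
})

test_that("analyze_cohort reproduces the univariate/multivariate pipeline", {
  d <- make_scored_cohort(n = 120)
  rep <- suppressWarnings(analyze_cohort(d))
  expect_s3_class(rep, "cohort_analysis")
  expect_true("ms_high" %in% rep$pfs$covariate)
  ms_row <- rep$pfs[rep$pfs$covariate == "ms_high", ]
  expect_lt(ms_row$hazard_ratio, 1)
  expect_lt(ms_row$logrank_p, 0.05)
  ben <- rep$benefit[rep$benefit$covariate == "ms_high", ]
  expect_gt(ben$rate_yes, ben$rate_low)
  expect_error(analyze_cohort(d[0, ]), "empty cohort")
})

test_that("multivariate step is skipped when fewer than two covariates pass", {
  set.seed(29)
  n <- 60
  d <- data.frame(
    score_percent = runif(n, 0, 100),
    pfs_months = rexp(n, 0.2), pfs_event = TRUE,
    os_months = rexp(n, 0.1) + 1, os_event = TRUE,
    best_response = sample(c("PR", "PD"), n, TRUE),
    sd_duration_months = NA_real_)
  d$pfs_months <- ifelse(d$score_percent > 50, d$pfs_months * 8,
                         d$pfs_months)  # only the score moves PFS
  rep <- suppressWarnings(analyze_cohort(d))
  expect_null(rep$multivariate$os)
  # undersized covariate levels are skipped with a warning
  d$immunotherapy <- c(TRUE, rep(FALSE, n - 1))
  w <- capture_warnings(analyze_cohort(d))
  expect_true(any(grepl("fewer than 2", w)))
})
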