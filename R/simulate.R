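# Gene pool used for the unnamed ("filler") alterations beyond the explicitly
# calibrated genes; recurrently altered genes in carcinoma of unknown primary.
FILLER_GENES <- c(
  "ARID1A", "MYC", "CCND1", "PTEN", "SMAD4", "BRAF", "EGFR", "ERBB2", "CDK4",
  "CDK6", "MDM2", "KIT", "NF1", "RB1", "STK11", "BRCA2", "BRCA1", "ATM",
  "NRAS", "FGFR1", "FGFR2", "MCL1", "GNAS", "APC", "CTNNB1", "NOTCH1",
  "KEAP1", "SMARCA4", "MTOR", "PDGFRA")

#' Simulation configuration for synthetic CUP cohorts
#'
#' Defaults emulate the molecular structure of a carcinoma-of-unknown-primary
#' cohort: per-assay alteration counts with tissue median 4 (range 0-25) and
#' cfDNA median 2 (range 0-9); named-gene marginal frequencies (tissue TP53
#' 55.4%, CDKN2A 24.3%, KRAS 20.3%; cfDNA TP53 61.1%, KRAS 20.8%, PIK3CA
#' 16.7%); TMB category shares 62.5 / 28.1 / 9.4% (low / intermediate /
#' high); MSI-high 3.6%; PD-L1 positivity 30.9%. The outcome model links the
#' Matching Score group to exponential PFS/OS and Bernoulli clinical benefit
#' (defaults: PFS medians 10.4 / 2.8 months, OS 15.8 / 6.9, benefit 0.71 /
#' 0.24 for high / low).
#'
#' Count model: each named gene is present independently with its marginal
#' frequency, and a negative-binomial count of additional filler genes
#' (tissue size 2, mean 3.4; cfDNA size 1.5, mean 1.0 - calibrated so the
#' truncated totals hit the target medians) is added, truncated to the
#' configured maximum.
#'
#' @param n_patients Number of patients.
#' @param tissue_count,cfdna_count Lists with `size`, `mu`, `max` for the
#'   filler-count negative binomial and the per-assay truncation cap.
#' @param tissue_gene_freq,cfdna_gene_freq Named numeric vectors of per-assay
#'   marginal alteration probabilities.
#' @param assay_probs Probabilities that a patient has a tissue / cfDNA assay
#'   (a patient with neither is given a tissue assay).
#' @param tmb_category_probs Probabilities of TMB low / intermediate / high.
#' @param msi_high_prob,pdl1_positive_prob Marginal biomarker probabilities.
#' @param er_positive_prob,ar_positive_prob Hormone-receptor IHC positivity.
#' @param regimen_policy `"matched_rich"` (drugs chosen to target sampled
#'   genes, checkpoint added for qualifying biomarkers), `"unmatched"`
#'   (non-targeting cytotoxics) or `"random"`.
#' @param pfs_median,os_median,benefit_prob Named (`high`, `low`) outcome
#'   model parameters; medians in months.
#' @param censor_frac Fraction of patients censored (independently for PFS
#'   and OS).
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_patients = 200,
                       tissue_count = list(size = 2, mu = 3.4, max = 25),
                       cfdna_count = list(size = 1.5, mu = 1.0, max = 9),
                       tissue_gene_freq = c(TP53 = 0.554, CDKN2A = 0.243, KRAS = 0.203),
                       cfdna_gene_freq = c(TP53 = 0.611, KRAS = 0.208, PIK3CA = 0.167),
                       assay_probs = c(tissue = 0.76, cfdna = 0.74),
                       tmb_category_probs = c(low = 0.625, intermediate = 0.281, high = 0.094),
                       msi_high_prob = 0.036,
                       pdl1_positive_prob = 0.309,
                       er_positive_prob = 0.10,
                       ar_positive_prob = 0.05,
                       regimen_policy = c("matched_rich", "unmatched", "random"),
                       pfs_median = c(high = 10.4, low = 2.8),
                       os_median = c(high = 15.8, low = 6.9),
                       benefit_prob = c(high = 0.71, low = 0.24),
                       censor_frac = 0.2) {
  regimen_policy <- match.arg(regimen_policy)
  probs <- c(tissue_gene_freq, cfdna_gene_freq, assay_probs, tmb_category_probs,
             msi_high_prob, pdl1_positive_prob, er_positive_prob,
             ar_positive_prob, benefit_prob, censor_frac)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (abs(sum(tmb_category_probs) - 1) > 1e-8) {
    stop("tmb_category_probs must sum to 1")
  }
  if (any(pfs_median <= 0) || any(os_median <= 0)) stop("medians must be positive")
  if (any(os_median <= pfs_median)) {
    stop("os_median must exceed pfs_median in each group")
  }
  structure(list(n_patients = n_patients, tissue_count = tissue_count,
                 cfdna_count = cfdna_count, tissue_gene_freq = tissue_gene_freq,
                 cfdna_gene_freq = cfdna_gene_freq, assay_probs = assay_probs,
                 tmb_category_probs = tmb_category_probs,
                 msi_high_prob = msi_high_prob,
                 pdl1_positive_prob = pdl1_positive_prob,
                 er_positive_prob = er_positive_prob,
                 ar_positive_prob = ar_positive_prob,
                 regimen_policy = regimen_policy,
                 pfs_median = pfs_median, os_median = os_median,
                 benefit_prob = benefit_prob, censor_frac = censor_frac),
            class = "sim_config")
}

sample_assay <- function(patient_id, assay_id, assay_type, gene_freq, count_cfg) {
  present <- names(gene_freq)[stats::runif(length(gene_freq)) < gene_freq]
  n_filler <- stats::rnbinom(1, size = count_cfg$size, mu = count_cfg$mu)
  n_filler <- min(n_filler, count_cfg$max - length(present),
                  length(FILLER_GENES))
  filler <- if (n_filler > 0) {
    sample(setdiff(FILLER_GENES, present), n_filler)
  } else character()
  genes <- c(present, filler)
  if (length(genes) == 0) return(NULL)
  classes <- sample(ALTERATION_CLASSES, length(genes), replace = TRUE,
                    prob = c(0.70, 0.15, 0.08, 0.04, 0.03))
  data.frame(patient_id = patient_id, assay_id = assay_id,
             assay_type = assay_type, gene = genes,
             alteration_class = classes, descriptor = NA_character_,
             stringsAsFactors = FALSE)
}

draw_regimen <- function(genes, biomarkers, policy, kb) {
  cytotoxics <- names(kb$drugs)[vapply(kb$drugs, `[[`, "", "class") == "cytotoxic_other"]
  cpis <- names(kb$drugs)[vapply(kb$drugs, `[[`, "", "class") == "checkpoint_inhibitor"]
  if (policy == "unmatched") {
    return(sample(cytotoxics, sample(1:2, 1)))
  }
  if (policy == "random") {
    return(sample(names(kb$drugs), sample(1:3, 1)))
  }
  # matched_rich: greedily pick drugs covering the patient's genes
  regimen <- character()
  covered <- character()
  candidates <- setdiff(names(kb$drugs), c(cytotoxics, cpis))
  for (d in sample(candidates)) {
    if (length(regimen) >= 3) break
    eff <- effective_target_genes(d, kb)
    gain <- setdiff(intersect(genes, eff), covered)
    if (length(gain) > 0) {
      regimen <- c(regimen, d)
      covered <- c(covered, gain)
    }
  }
  qualifies <- biomarkers$msi_status == "msi_high" ||
    (!is.na(biomarkers$tmb_mut_per_mb) && biomarkers$tmb_mut_per_mb >= 6) ||
    (!is.na(biomarkers$pdl1_percent) && biomarkers$pdl1_percent >= 1)
  if (qualifies && stats::runif(1) < 0.5) {
    regimen <- c(regimen, sample(cpis, 1))
  }
  if (length(regimen) == 0) regimen <- sample(cytotoxics, 1)
  regimen
}

# Median of the sum of two independent exponentials (rates a and b): used to
# solve for the post-progression rate that puts the OS median on target.
hypoexp_median <- function(a, b) {
  surv <- function(t) {
    if (abs(a - b) < 1e-8 * a) (1 + a * t) * exp(-a * t)
    else (b * exp(-a * t) - a * exp(-b * t)) / (b - a)
  }
  upper <- 20 * (log(2) / a + log(2) / b)
  stats::uniroot(function(t) surv(t) - 0.5, c(1e-9, upper))$root
}

solve_pp_rate <- function(pfs_median, os_median) {
  a <- log(2) / pfs_median
  stats::uniroot(function(b) hypoexp_median(a, b) - os_median,
                 c(1e-6, 1e3))$root
}

#' Simulate outcomes for scored patients
#'
#' PFS is exponential with the group's configured median; OS is PFS plus an
#' independent exponential post-progression time whose rate is solved so the
#' OS median hits the group's target (hence OS >= PFS always). Best response
#' is drawn so the probability of clinical benefit equals the group's
#' configured value, consistently with PFS (a benefit via stable disease
#' requires PFS >= 6 months; otherwise the benefit is realised as PR/CR).
#' Censoring is by an independent exponential censoring time per endpoint,
#' with rate chosen so the expected censored fraction equals `censor_frac`.
#'
#' @param group_labels Character vector of `"high"` / `"low"` labels.
#' @param config A [sim_config()] (only the outcome model fields are used).
#' @param seed Optional integer seed; `NULL` leaves the RNG stream alone (so
#'   callers that already seeded can draw through).
#' @return Data frame with columns `pfs_months`, `pfs_event`, `os_months`,
#'   `os_event`, `best_response`, `sd_duration_months`.
#' @export
simulate_outcomes <- function(group_labels, config = sim_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(all(group_labels %in% c("high", "low")))
  n <- length(group_labels)
  pfs_med <- config$pfs_median[group_labels]
  pfs_true <- stats::rexp(n, rate = log(2) / pfs_med)
  pp_rate <- c(high = solve_pp_rate(config$pfs_median[["high"]], config$os_median[["high"]]),
               low = solve_pp_rate(config$pfs_median[["low"]], config$os_median[["low"]]))
  os_true <- pfs_true + stats::rexp(n, rate = pp_rate[group_labels])

  benefit <- stats::runif(n) < config$benefit_prob[group_labels]
  response <- character(n)
  sd_dur <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (benefit[i]) {
      r <- sample(c("PR", "CR", "SD"), 1, prob = c(0.5, 0.1, 0.4))
      if (r == "SD" && pfs_true[i] < 6) r <- "PR"  # keep endpoints consistent
      if (r == "SD") sd_dur[i] <- pfs_true[i]
    } else {
      r <- sample(c("PD", "SD"), 1, prob = c(0.7, 0.3))
      if (r == "SD") sd_dur[i] <- min(pfs_true[i], stats::runif(1, 0, 6))
    }
    response[i] <- r
  }
  # independent exponential censoring with rate chosen so the expected
  # censored fraction equals censor_frac (c = a * f / (1 - f) for event rate a)
  frac <- config$censor_frac
  if (frac > 0) {
    c_pfs <- (log(2) / pfs_med) * frac / (1 - frac)
    c_os <- (log(2) / config$os_median[group_labels]) * frac / (1 - frac)
    cens_t_pfs <- stats::rexp(n, c_pfs)
    cens_t_os <- stats::rexp(n, c_os)
  } else {
    cens_t_pfs <- cens_t_os <- rep(Inf, n)
  }
  pfs_obs <- pmin(pfs_true, cens_t_pfs)
  os_obs <- pmin(os_true, cens_t_os)
  data.frame(pfs_months = pfs_obs, pfs_event = pfs_true <= cens_t_pfs,
             os_months = os_obs, os_event = os_true <= cens_t_os,
             best_response = response, sd_duration_months = sd_dur,
             stringsAsFactors = FALSE)
}

#' Simulate a synthetic CUP cohort
#'
#' Generates per-patient molecular profiles (tissue and/or cfDNA alteration
#' tables), immune biomarkers, treatment regimens drawn per the configured
#' policy, Matching Scores computed by the scoring engine, and outcomes drawn
#' from the group-linked outcome model. Deterministic given `seed`.
#'
#' @param config A [sim_config()].
#' @param kb A `matching_kb` used both to draw matched regimens and to score.
#' @param seed Integer seed (required for reproducibility).
#' @param cutoff Matching Score cutoff for the high/low grouping.
#' @return Object of class `ms_cohort`: data frames `patients`, `assays`
#'   (assay presence, including assays that found no alteration),
#'   `alterations`, `biomarkers`, `treatments`, `outcomes`, `scores`.
#' @examples
#' coh <- simulate_cohort(sim_config(n_patients = 20), seed = 1)
#' head(coh$scores)
#' @export
simulate_cohort <- function(config = sim_config(), kb = default_kb(), seed,
                            cutoff = 50) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  n <- config$n_patients
  ids <- sprintf("P%04d", seq_len(n))

  patients <- data.frame(
    patient_id = ids,
    age = round(stats::rnorm(n, 63, 12)),
    sex = sample(c("female", "male"), n, replace = TRUE, prob = c(0.61, 0.39)),
    histology = sample(c("adenocarcinoma", "neuroendocrine", "squamous",
                         "poorly_differentiated", "other"),
                       n, replace = TRUE, prob = c(0.54, 0.19, 0.10, 0.14, 0.03)),
    stringsAsFactors = FALSE)

  alt_list <- list()
  bio_list <- list()
  trt_list <- list()
  assay_list <- list()
  profiles <- vector("list", n)
  for (i in seq_len(n)) {
    has_tissue <- stats::runif(1) < config$assay_probs[["tissue"]]
    has_cfdna <- stats::runif(1) < config$assay_probs[["cfdna"]]
    if (!has_tissue && !has_cfdna) has_tissue <- TRUE
    alts <- list()
    if (has_tissue) {
      alts$t <- sample_assay(ids[i], paste0(ids[i], "-T"), "tissue_ngs",
                             config$tissue_gene_freq, config$tissue_count)
    }
    if (has_cfdna) {
      alts$c <- sample_assay(ids[i], paste0(ids[i], "-B"), "cfdna",
                             config$cfdna_gene_freq, config$cfdna_count)
    }
    assay_list[[i]] <- data.frame(
      patient_id = ids[i],
      assay_id = c(if (has_tissue) paste0(ids[i], "-T"),
                   if (has_cfdna) paste0(ids[i], "-B")),
      assay_type = c(if (has_tissue) "tissue_ngs", if (has_cfdna) "cfdna"),
      stringsAsFactors = FALSE)
    alts <- do.call(rbind, alts)

    tmb_cat <- sample(names(config$tmb_category_probs), 1,
                      prob = config$tmb_category_probs)
    tmb <- switch(tmb_cat,
                  low = stats::runif(1, 0, 5.4),
                  intermediate = stats::runif(1, 6, 19.4),
                  high = stats::runif(1, 20, 45))
    pdl1 <- if (stats::runif(1) < config$pdl1_positive_prob) {
      stats::runif(1, 1, 100)
    } else stats::runif(1, 0, 0.9)
    bio <- immune_biomarkers(
      tmb_mut_per_mb = tmb,
      msi_status = if (stats::runif(1) < config$msi_high_prob) "msi_high" else "stable",
      pdl1_percent = pdl1,
      er_ihc = if (stats::runif(1) < config$er_positive_prob) "positive" else "negative",
      ar_ihc = if (stats::runif(1) < config$ar_positive_prob) "positive" else "negative")

    genes <- unique(alts$gene)
    regimen <- draw_regimen(genes %||% character(), bio,
                            config$regimen_policy, kb)

    alt_list[[i]] <- alts
    bio_list[[i]] <- data.frame(patient_id = ids[i],
                                tmb_mut_per_mb = bio$tmb_mut_per_mb,
                                msi_status = bio$msi_status,
                                pdl1_percent = bio$pdl1_percent,
                                er_ihc = bio$er_ihc, ar_ihc = bio$ar_ihc,
                                stringsAsFactors = FALSE)
    trt_list[[i]] <- data.frame(patient_id = ids[i], line = sample(1:3, 1, prob = c(0.66, 0.24, 0.1)),
                                drugs = paste(regimen, collapse = ";"),
                                stringsAsFactors = FALSE)
    prof_alts <- if (is.null(alts)) {
      alteration_table(character(), character(), character(), character())
    } else alts[, c("assay_id", "assay_type", "gene", "alteration_class",
                    "descriptor")]
    profiles[[i]] <- patient_profile(ids[i], prof_alts, bio)
  }
  alterations <- do.call(rbind, alt_list[!vapply(alt_list, is.null, TRUE)])
  rownames(alterations) <- NULL
  assays <- do.call(rbind, assay_list)
  biomarkers <- do.call(rbind, bio_list)
  treatments <- do.call(rbind, trt_list)

  scores <- do.call(rbind, lapply(seq_len(n), function(i) {
    regimen <- strsplit(treatments$drugs[i], ";", fixed = TRUE)[[1]]
    ms <- compute_matching_score(profiles[[i]], regimen, kb)
    data.frame(patient_id = ids[i], numerator = ms$numerator,
               denominator = ms$denominator,
               checkpoint_component = ms$checkpoint_component,
               score_percent = ms$score_percent, matched = ms$matched,
               group = dichotomize_score(ms$score_percent, cutoff),
               stringsAsFactors = FALSE)
  }))

  outcomes <- cbind(patient_id = ids,
                    simulate_outcomes(scores$group, config, seed = NULL))

  structure(list(patients = patients, assays = assays,
                 alterations = alterations, biomarkers = biomarkers,
                 treatments = treatments, outcomes = outcomes,
                 scores = scores),
            class = "ms_cohort")
}

#' @export
print.ms_cohort <- function(x, ...) {
  cat(sprintf("<ms_cohort> %d patients, %d alterations, %d high / %d low Matching Score\n",
              nrow(x$patients), if (is.null(x$alterations)) 0L else nrow(x$alterations),
              sum(x$scores$group == "high"), sum(x$scores$group == "low")))
  invisible(x)
}
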