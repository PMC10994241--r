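# Independent oracles. These re-derive expected values from first principles
# (literal rule transcription, brute-force enumeration, grid search) and never
# call the code paths they check.

# Literal transcription of the Matching Score rules, computed directly from
# the raw alteration table, biomarkers, regimen and KB list structure.
oracle_matching_score <- function(alterations, bio, regimen, kb) {
  key <- vapply(tolower(trimws(regimen)), function(nm) {
    if (nm %in% names(kb$aliases)) kb$aliases[[nm]] else nm
  }, "")
  entries <- kb$drugs[key]
  stopifnot(!vapply(entries, is.null, TRUE))
  cls <- vapply(entries, `[[`, "", "class")

  tmb <- bio$tmb_mut_per_mb
  pdl1 <- bio$pdl1_percent
  tier <- "absent"
  if (any(cls == "checkpoint_inhibitor")) {
    full <- identical(bio$msi_status, "msi_high") ||
      (!is.na(tmb) && tmb >= 20) || (!is.na(pdl1) && pdl1 >= 50)
    half <- (!is.na(tmb) && tmb >= 6 && tmb < 20) ||
      (!is.na(pdl1) && pdl1 >= 1 && pdl1 < 50)
    tier <- if (full) "full" else if (half) "half" else "zero"
  }

  eff <- function(e) {
    g <- e$targets
    if (isTRUE(e$anti_vegf) && isTRUE(kb$tp53_vegf_rule_enabled)) g <- c(g, "TP53")
    if (e$class %in% c("parp_inhibitor", "platinum")) g <- c(g, kb$brca_related_genes)
    unique(g)
  }
  noncpi <- entries[cls != "checkpoint_inhibitor"]
  target_union <- unique(unlist(lapply(noncpi, eff)))

  syn_genes <- character()
  for (e in entries) {
    sp <- e$synergy_partner
    if (!is.null(sp) && sp$drug %in% names(entries)) {
      syn_genes <- c(syn_genes, sp$gene)
    }
  }

  # units: one per distinct (assay, gene, class)
  units <- if (nrow(alterations)) {
    unique(alterations[, c("assay_id", "gene", "alteration_class")])
  } else alterations
  n <- 0; d <- 0
  if (nrow(units)) {
    for (i in seq_len(nrow(units))) {
      g <- units$gene[i]
      matched <- g %in% target_union
      w <- if (matched && g %in% syn_genes) 2 else 1
      d <- d + w
      if (matched) n <- n + w
    }
  }
  hormone_hit <- function(status, tag) {
    identical(status, "positive") &&
      any(vapply(noncpi, function(e) {
        e$class == "hormone_modulator" && tag %in% e$targets
      }, TRUE))
  }
  if (hormone_hit(bio$er_ihc, "ER")) { n <- n + 1; d <- d + 1 }
  if (hormone_hit(bio$ar_ihc, "AR")) { n <- n + 1; d <- d + 1 }

  frac <- if (d > 0) n / d else 0
  score <- if (tier == "full") 100
  else if (tier == "half") 50 + 100 * frac / 2
  else 100 * frac
  min(100, score)
}

# Random small profile + regimen for the oracle-equivalence fuzz.
random_score_case <- function(kb) {
  pool <- c("TP53", "KRAS", "BRAF", "ERBB2", "KIT", "EGFR", "PIK3CA",
            "CDKN2A", "BRCA1", "ATM", "MYC", "APC", "SMAD4", "ER", "AR")
  n_alt <- sample(0:6, 1)
  alts <- if (n_alt > 0) {
    alteration_table(
      assay_id = sample(c("T1", "T1", "B1"), n_alt, replace = TRUE),
      assay_type = "tissue_ngs",
      gene = sample(pool, n_alt, replace = TRUE),
      alteration_class = sample(c("mutation", "amplification", "deletion"),
                                n_alt, replace = TRUE))
  } else alteration_table(character(), character(), character(), character())
  alts$assay_type[alts$assay_id == "B1"] <- "cfdna"
  bio <- immune_biomarkers(
    tmb_mut_per_mb = sample(c(NA, 3, 12, 25), 1),
    msi_status = sample(c("stable", "stable", "msi_high", "unknown"), 1),
    pdl1_percent = sample(c(NA, 0, 5, 80), 1),
    er_ihc = sample(c("negative", "positive", "unknown"), 1),
    ar_ihc = sample(c("negative", "positive", "unknown"), 1))
  regimen <- sample(names(kb$drugs), sample(1:3, 1))
  list(profile = patient_profile("fz", alts, bio), regimen = regimen)
}

# Cox partial log-likelihood for a single covariate with no tied event times,
# evaluated directly from its definition; maximized by two-stage grid search.
oracle_cox_grid <- function(time, event, x, lower = -5, upper = 5) {
  stopifnot(!anyDuplicated(time[event]))
  ord <- order(time)
  time <- time[ord]; event <- event[ord]; x <- x[ord]
  logpl <- function(betas) {
    sapply(betas, function(b) {
      s <- 0
      for (i in which(event)) {
        risk <- time >= time[i]
        s <- s + b * x[i] - log(sum(exp(b * x[risk])))
      }
      s
    })
  }
  coarse <- seq(lower, upper, by = 0.01)
  b0 <- coarse[which.max(logpl(coarse))]
  fine <- seq(b0 - 0.02, b0 + 0.02, by = 1e-4)
  fine[which.max(logpl(fine))]
}

# Two-sided Fisher exact p by direct hypergeometric enumeration.
oracle_fisher_p <- function(a, b, c_, d) {
  m <- a + b; n <- c_ + d; k <- a + c_
  support <- max(0, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Log-rank statistic by direct observed-minus-expected tabulation.
oracle_logrank_chisq <- function(time, event, group) {
  group <- as.integer(as.factor(group)) - 1L
  oe <- 0; v <- 0
  for (t in sort(unique(time[event]))) {
    at_risk <- time >= t
    n1 <- sum(at_risk & group == 1); n0 <- sum(at_risk & group == 0)
    d1 <- sum(event & time == t & group == 1)
    d0 <- sum(event & time == t & group == 0)
    dt <- d1 + d0; nt <- n1 + n0
    oe <- oe + d1 - dt * n1 / nt
    if (nt > 1) v <- v + dt * (n1 / nt) * (n0 / nt) * (nt - dt) / (nt - 1)
  }
  oe^2 / v
}

# Per-assay alteration counts including assays that found nothing.
assay_counts <- function(coh, type) {
  ids <- coh$assays$assay_id[coh$assays$assay_type == type]
  tab <- table(factor(coh$alterations$assay_id[
    coh$alterations$assay_type == type], levels = ids))
  as.integer(tab)
}

# Small deterministic cohort builder used across analysis tests.
make_scored_cohort <- function(n = 80, seed = 7) {
  set.seed(seed)
  high <- rep(c(TRUE, FALSE), length.out = n)
  pfs <- rexp(n, log(2) / ifelse(high, 10, 3))
  os <- pfs + rexp(n, log(2) / 6)
  benefit <- runif(n) < ifelse(high, 0.7, 0.25)
  resp <- ifelse(benefit, "PR", "PD")
  data.frame(
    patient_id = sprintf("p%02d", seq_len(n)),
    score_percent = ifelse(high, runif(n, 60, 100), runif(n, 0, 45)),
    pfs_months = pfs, pfs_event = TRUE,
    os_months = os, os_event = runif(n) > 0.3,
    best_response = resp, sd_duration_months = NA_real_,
    age = round(runif(n, 30, 90)),
    sex = sample(c("female", "male"), n, TRUE),
    histology = sample(c("adenocarcinoma", "squamous"), n, TRUE),
    immunotherapy = runif(n) < 0.3,
    stringsAsFactors = FALSE)
}
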