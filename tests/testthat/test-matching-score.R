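kb <- default_kb()

profile_with_genes <- function(genes, bio = immune_biomarkers(),
                               class = "mutation") {
  alts <- if (length(genes)) {
    alteration_table("T1", "tissue_ngs", genes, class)
  } else alteration_table(character(), character(), character(), character())
  patient_profile("pt", alts, bio)
}

ten_genes <- c("KIT", "EGFR", "BRAF", "MYC", "APC", "SMAD4", "GNAS", "RB1",
               "PTEN", "NF1")

test_that("checkpoint component follows the biomarker tiers", {
  msi <- immune_biomarkers(msi_status = "msi_high")
  expect_equal(checkpoint_component(msi, "pembrolizumab", kb), "full")
  expect_equal(checkpoint_component(immune_biomarkers(tmb_mut_per_mb = 25),
                                    "nivolumab", kb), "full")
  expect_equal(checkpoint_component(immune_biomarkers(pdl1_percent = 80),
                                    "pembrolizumab", kb), "full")
  expect_equal(checkpoint_component(immune_biomarkers(tmb_mut_per_mb = 12),
                                    "pembrolizumab", kb), "half")
  expect_equal(checkpoint_component(immune_biomarkers(pdl1_percent = 5),
                                    "pembrolizumab", kb), "half")
  expect_equal(checkpoint_component(immune_biomarkers(tmb_mut_per_mb = 3),
                                    "pembrolizumab", kb), "zero")
  expect_equal(checkpoint_component(msi, c("imatinib", "gemcitabine"), kb),
               "absent")
  expect_error(checkpoint_component(msi, "madeupdrug", kb), "madeupdrug")
  # two half-tier biomarkers do not stack to full
  both_half <- immune_biomarkers(tmb_mut_per_mb = 12, pdl1_percent = 10)
  expect_equal(checkpoint_component(both_half, "pembrolizumab", kb), "half")
})

test_that("3 of 10 targeted alterations give a 30% score", {
  # imatinib covers KIT; erlotinib EGFR; dabrafenib BRAF; 7 others untargeted
  ms <- compute_matching_score(profile_with_genes(ten_genes),
                               c("imatinib", "erlotinib", "dabrafenib"), kb)
  expect_equal(ms$numerator, 3)
  expect_equal(ms$denominator, 10)
  expect_equal(ms$score_percent, 30)
  expect_equal(ms$checkpoint_component, "absent")
  expect_true(ms$matched)
})

test_that("TMB-intermediate checkpoint plus a KIT-matched drug scores 75%", {
  prof <- profile_with_genes(c("KIT", "EGFR"),
                             immune_biomarkers(tmb_mut_per_mb = 12))
  ms <- compute_matching_score(prof, c("pembrolizumab", "imatinib"), kb)
  expect_equal(ms$checkpoint_component, "half")
  expect_equal(ms$numerator, 1)
  expect_equal(ms$denominator, 2)
  expect_equal(ms$score_percent, 75)  # 50 + 100 * 1 / (2 * 2)
})

test_that("MSI-high plus checkpoint blockade scores 100% regardless of units", {
  prof <- profile_with_genes(c("KRAS", "APC", "SMAD4", "MYC"),
                             immune_biomarkers(msi_status = "msi_high"))
  ms <- compute_matching_score(prof, "pembrolizumab", kb)
  expect_equal(ms$score_percent, 100)
  ms2 <- compute_matching_score(profile_with_genes(character(),
                                  immune_biomarkers(msi_status = "msi_high")),
                                "pembrolizumab", kb)
  expect_equal(ms2$score_percent, 100)
})

test_that("a fully unmatched regimen scores 0 and is flagged unmatched", {
  ms <- compute_matching_score(profile_with_genes(c("KRAS", "APC", "MYC",
                                                    "RB1", "GNAS")),
                               "gemcitabine", kb)
  expect_equal(ms$score_percent, 0)
  expect_equal(ms$denominator, 5)
  expect_false(ms$matched)
})

test_that("synergy pairs double the matched unit in numerator and denominator", {
  prof <- profile_with_genes(c("BRAF", "APC", "MYC", "RB1"))
  ms <- compute_matching_score(prof, c("dabrafenib", "trametinib"), kb)
  expect_equal(ms$numerator, 2)
  expect_equal(ms$denominator, 5)
  expect_equal(ms$score_percent, 40)
  # a single partner scores once
  ms1 <- compute_matching_score(prof, "dabrafenib", kb)
  expect_equal(ms1$numerator, 1)
  expect_equal(ms1$denominator, 4)
})

test_that("hormone-receptor positivity targeted by a modulator adds one to both sides", {
  prof <- profile_with_genes(c("APC", "MYC", "RB1", "GNAS"),
                             immune_biomarkers(er_ihc = "positive"))
  ms <- compute_matching_score(prof, "letrozole", kb)
  expect_equal(ms$numerator, 1)
  expect_equal(ms$denominator, 5)
  # ER+ with no genomic units: add-on-only fraction
  ms2 <- compute_matching_score(
    profile_with_genes(character(), immune_biomarkers(er_ihc = "positive")),
    "letrozole", kb)
  expect_equal(ms2$score_percent, 100)
  # ER+ without a hormone modulator adds nothing
  ms3 <- compute_matching_score(
    profile_with_genes("KIT", immune_biomarkers(er_ihc = "positive")),
    "imatinib", kb)
  expect_equal(ms3$denominator, 1)
})

test_that("degenerate inputs: no units and no matches give score 0", {
  ms <- compute_matching_score(profile_with_genes(character()),
                               "gemcitabine", kb)
  expect_equal(ms$denominator, 0)
  expect_equal(ms$score_percent, 0)
  expect_false(ms$matched)
  expect_error(compute_matching_score(profile_with_genes("KIT"),
                                      character(), kb), "at least one drug")
})

test_that("TP53 counts as matched to anti-VEGF drugs, toggleable", {
  prof <- profile_with_genes(c("TP53", "APC"))
  ms <- compute_matching_score(prof, "bevacizumab", kb)
  expect_equal(ms$numerator, 1)
  kb_off <- kb
  kb_off$tp53_vegf_rule_enabled <- FALSE
  ms_off <- compute_matching_score(prof, "bevacizumab", kb_off)
  expect_equal(ms_off$numerator, 0)
})

test_that("BRCA-related alterations are matched to PARP inhibitors and platinums", {
  prof <- profile_with_genes(c("BRCA1", "APC"))
  expect_equal(compute_matching_score(prof, "olaparib", kb)$numerator, 1)
  expect_equal(compute_matching_score(prof, "carboplatin", kb)$numerator, 1)
  expect_equal(compute_matching_score(prof, "gemcitabine", kb)$numerator, 0)
})

test_that("scores are capped at 100 and ledger sums reconcile", {
  set.seed(11)
  for (i in 1:60) {
    case <- random_score_case(kb)
    ms <- compute_matching_score(case$profile, case$regimen, kb)
    expect_gte(ms$score_percent, 0)
    expect_lte(ms$score_percent, 100)
    expect_lte(ms$numerator, ms$denominator)
    expect_equal(ms$matched, ms$score_percent > 0)
    expect_equal(ms$denominator, sum(ms$ledger$weight))
    expect_equal(ms$numerator, sum(ms$ledger$weight[ms$ledger$matched]))
  }
})

test_that("adding drugs never decreases the score; inert drugs leave it unchanged", {
  set.seed(12)
  for (i in 1:30) {
    case <- random_score_case(kb)
    base <- compute_matching_score(case$profile, case$regimen, kb)
    extra <- sample(setdiff(names(kb$drugs), tolower(case$regimen)), 1)
    more <- compute_matching_score(case$profile, c(case$regimen, extra), kb)
    expect_gte(more$score_percent, base$score_percent - 1e-12)
    inert <- compute_matching_score(case$profile,
                                    c(case$regimen, "gemcitabine"), kb)
    expect_equal(inert$score_percent, base$score_percent)
  }
})

test_that("duplicating every unit k-fold leaves the targeted fraction unchanged", {
  genes <- c("KIT", "EGFR", "APC")
  for (k in 2:3) {
    one <- compute_matching_score(profile_with_genes(genes), "imatinib", kb)
    alts <- do.call(rbind, lapply(seq_len(k), function(j) {
      alteration_table(paste0("T", j), "tissue_ngs", genes, "mutation")
    }))
    many <- compute_matching_score(patient_profile("pt", alts,
                                                   immune_biomarkers()),
                                   "imatinib", kb)
    expect_equal(many$score_percent, one$score_percent)
    expect_equal(many$denominator, k * one$denominator)
  }
})

test_that("scoring engine agrees exactly with the brute-force rule oracle", {
  set.seed(13)
  for (i in 1:150) {
    case <- random_score_case(kb)
    got <- compute_matching_score(case$profile, case$regimen, kb)$score_percent
    want <- oracle_matching_score(case$profile$alterations,
                                  case$profile$biomarkers, case$regimen, kb)
    expect_equal(got, want, info = paste("case", i))
  }
})

test_that("score dichotomization puts the boundary in the low group", {
  expect_equal(dichotomize_score(c(0, 50, 50.1, 51, 100)),
               c("low", "low", "high", "high", "high"))
  expect_equal(dichotomize_score(31, cutoff = 30), "high")
  expect_error(dichotomize_score(120), "\\[0, 100\\]")
})
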