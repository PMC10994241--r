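#' Checkpoint-inhibitor scoring component
#'
#' When the regimen contains an immune checkpoint inhibitor, the immune
#' biomarkers set a fixed score tier: 100% (`"full"`) for MSI-high, TMB-high
#' (>= 20 mutations/Mb) or high PD-L1 expression; 50% (`"half"`) for
#' TMB-intermediate (6-19) or low-positive PD-L1. A checkpoint drug given
#' with none of these qualifying biomarkers contributes `"zero"` (it is
#' treated as an unmatched drug), and a regimen without a checkpoint drug
#' has no component (`"absent"`). Two half-tier biomarkers do not stack.
#'
#' @param biomarkers An [immune_biomarkers()] record.
#' @param regimen Character vector of drug names.
#' @param kb A `matching_kb`.
#' @param pdl1_low,pdl1_high PD-L1 band edges passed to [classify_pdl1()].
#' @return `"absent"`, `"zero"`, `"half"` or `"full"`.
#' @export
checkpoint_component <- function(biomarkers, regimen, kb,
                                 pdl1_low = 1, pdl1_high = 50) {
  entries <- lapply(regimen, resolve_drug, kb = kb)
  has_cpi <- any(vapply(entries, `[[`, "", "class") == "checkpoint_inhibitor")
  if (!has_cpi) return("absent")
  tmb_cat <- if (is.na(biomarkers$tmb_mut_per_mb)) NA_character_ else
    classify_tmb(biomarkers$tmb_mut_per_mb)
  pdl1_cat <- if (is.na(biomarkers$pdl1_percent)) NA_character_ else
    classify_pdl1(biomarkers$pdl1_percent, pdl1_low, pdl1_high)
  if (biomarkers$msi_status == "msi_high" ||
      identical(tmb_cat, "high") || identical(pdl1_cat, "high")) {
    return("full")
  }
  if (identical(tmb_cat, "intermediate") || identical(pdl1_cat, "low_positive")) {
    return("half")
  }
  "zero"
}

#' Targeted fraction of countable units
#'
#' Computes the numerator and denominator of the genomic part of the Matching
#' Score. A unit is matched when any regimen drug's effective target set
#' contains its gene. A matched unit whose gene is covered by a complete
#' synergy pair in the regimen (e.g. dabrafenib + trametinib for BRAF) is
#' counted twice in both numerator and denominator. Hormone-receptor IHC
#' positivity targeted by a hormone modulator in the regimen adds one to both
#' sides. Checkpoint inhibitors contribute nothing here (see
#' [checkpoint_component()]); unmatched biomarkers add nothing to either side.
#'
#' @param units Data frame from [pool_countable_alterations()].
#' @param biomarkers An [immune_biomarkers()] record.
#' @param regimen Character vector of drug names.
#' @param kb A `matching_kb`.
#' @return List with `numerator`, `denominator`, and `ledger` (a data frame
#'   with one row per counted unit: `label`, `matched`, `weight`, `rule`).
#' @export
targeted_fraction <- function(units, biomarkers, regimen, kb) {
  entries <- lapply(regimen, resolve_drug, kb = kb)
  noncpi <- entries[vapply(entries, `[[`, "", "class") != "checkpoint_inhibitor"]
  target_union <- unique(unlist(lapply(noncpi, effective_target_genes, kb = kb)))
  synergy <- active_synergy_pairs(regimen, kb)

  ledger <- data.frame(label = character(), matched = logical(),
                       weight = integer(), rule = character(),
                       stringsAsFactors = FALSE)
  num <- 0L
  den <- 0L
  if (!is.null(units) && nrow(units) > 0) {
    for (i in seq_len(nrow(units))) {
      gene <- units$label[i]
      matched <- gene %in% target_union
      weight <- 1L
      rule <- if (matched) "targeted by regimen" else "untargeted"
      if (matched && gene %in% synergy$gene) {
        weight <- 2L
        pair <- synergy[synergy$gene == gene, , drop = FALSE][1, ]
        rule <- paste0("synergy pair ", pair$drug_a, "+", pair$drug_b,
                       " (counted twice in numerator and denominator)")
      }
      den <- den + weight
      if (matched) num <- num + weight
      ledger <- rbind(ledger, data.frame(
        label = paste0(gene, " [", units$alteration_class[i], ", ",
                       units$assay_id[i], "]"),
        matched = matched, weight = weight, rule = rule,
        stringsAsFactors = FALSE))
    }
  }
  hormone <- function(status, receptor) {
    if (!identical(status, "positive")) return(NULL)
    mods <- Filter(function(e) e$class == "hormone_modulator" &&
                     receptor %in% e$targets, noncpi)
    if (length(mods) == 0) return(NULL)
    data.frame(label = paste0(receptor, " IHC positive"),
               matched = TRUE, weight = 1L,
               rule = paste0("hormone receptor targeted by ",
                             mods[[1]]$name,
                             " (one in numerator and denominator)"),
               stringsAsFactors = FALSE)
  }
  for (add in list(hormone(biomarkers$er_ihc, "ER"),
                   hormone(biomarkers$ar_ihc, "AR"))) {
    if (is.null(add)) next
    num <- num + 1L
    den <- den + 1L
    ledger <- rbind(ledger, add)
  }
  list(numerator = num, denominator = den, ledger = ledger)
}

#' Compute the Matching Score for a patient and regimen
#'
#' The Matching Score (0-100%) quantifies how completely a regimen targets a
#' tumour's deleterious alterations and immune biomarkers. Writing n/d for
#' the targeted fraction of countable units (see [targeted_fraction()]) and
#' cc for the checkpoint component:
#'
#' * cc = full: score = 100, regardless of n/d;
#' * cc = half: score = 50 + 100 * n / (2 d) (the half tier plus half of the
#'   targeted fraction), 50 when d = 0;
#' * otherwise: score = 100 * n / d (0 when d = 0).
#'
#' The score is capped at 100 and a patient is "matched" when it is positive.
#'
#' @param profile A [patient_profile()].
#' @param regimen Character vector of drug names (non-empty).
#' @param kb A `matching_kb` (default [default_kb()]).
#' @param dedup_across_assays,pathway_map Passed to
#'   [pool_countable_alterations()].
#' @param pdl1_low,pdl1_high Passed to [checkpoint_component()].
#' @return An object of class `matching_score` with fields `numerator`,
#'   `denominator`, `checkpoint_component`, `score_percent`, `matched` and
#'   `ledger`.
#' @examples
#' kb <- default_kb()
#' p <- patient_profile("pt1",
#'   alteration_table("T1", "tissue_ngs", c("KIT", "EGFR"), "mutation"),
#'   immune_biomarkers(tmb_mut_per_mb = 12))
#' compute_matching_score(p, c("pembrolizumab", "imatinib"), kb)
#' @export
compute_matching_score <- function(profile, regimen, kb = default_kb(),
                                   dedup_across_assays = FALSE,
                                   pathway_map = NULL,
                                   pdl1_low = 1, pdl1_high = 50) {
  if (length(regimen) == 0) stop("regimen must contain at least one drug")
  if (!inherits(profile, "patient_profile")) stop("profile must be a patient_profile")
  units <- pool_countable_alterations(profile$alterations,
                                      dedup_across_assays = dedup_across_assays,
                                      pathway_map = pathway_map)
  cc <- checkpoint_component(profile$biomarkers, regimen, kb,
                             pdl1_low = pdl1_low, pdl1_high = pdl1_high)
  tf <- targeted_fraction(units, profile$biomarkers, regimen, kb)
  n <- tf$numerator
  d <- tf$denominator
  frac <- if (d > 0) n / d else 0
  score <- if (cc == "full") 100 else if (cc == "half") 50 + 100 * frac / 2 else 100 * frac
  score <- min(100, score)
  structure(list(patient_id = profile$patient_id,
                 numerator = n, denominator = d,
                 checkpoint_component = cc,
                 score_percent = score,
                 matched = score > 0,
                 ledger = tf$ledger),
            class = "matching_score")
}

#' Dichotomize a Matching Score
#'
#' High means strictly above the cutoff: with the default cutoff of 50 the
#' groups are score > 50% vs 0-50%, and unmatched patients (score 0) fall in
#' the low group.
#'
#' @param score_percent Numeric vector of scores in `[0, 100]`.
#' @param cutoff Cutoff percent (default 50, the ROC-derived convention).
#' @return Character vector: `"high"` or `"low"`.
#' @export
dichotomize_score <- function(score_percent, cutoff = 50) {
  if (any(score_percent < 0 | score_percent > 100, na.rm = TRUE)) {
    stop("score_percent must lie in [0, 100]")
  }
  ifelse(score_percent > cutoff, "high", "low")
}

#' @export
print.matching_score <- function(x, ...) {
  cat(sprintf("<matching_score> %s: %.1f%% (%s)\n", x$patient_id,
              x$score_percent, if (x$matched) "matched" else "unmatched"))
  cat(sprintf("  targeted fraction: %d / %d; checkpoint component: %s\n",
              x$numerator, x$denominator, x$checkpoint_component))
  if (nrow(x$ledger)) {
    for (i in seq_len(nrow(x$ledger))) {
      cat(sprintf("  %s %-34s w=%d  %s\n",
                  if (x$ledger$matched[i]) "*" else " ",
                  x$ledger$label[i], x$ledger$weight[i], x$ledger$rule[i]))
    }
  }
  invisible(x)
}
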