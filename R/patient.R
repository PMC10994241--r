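ALTERATION_CLASSES <- c("mutation", "amplification", "deletion", "fusion",
                        "rearrangement")
ASSAY_TYPES <- c("tissue_ngs", "cfdna")
RESPONSES <- c("CR", "PR", "SD", "PD", "not_evaluable")

#' Build a validated alteration table
#'
#' One row per deleterious (pathogenic) alteration call. Variants of unknown
#' significance must be excluded upstream: this model stores deleterious calls
#' only, and no driver/passenger distinction is made.
#'
#' @param assay_id Assay identifier (recycled).
#' @param assay_type `"tissue_ngs"` or `"cfdna"` (recycled).
#' @param gene Gene symbol(s); uppercased.
#' @param alteration_class One of `r paste(ALTERATION_CLASSES, collapse=", ")`.
#' @param descriptor Optional free-text descriptor (e.g. protein change).
#' @return Data frame with columns `assay_id`, `assay_type`, `gene`,
#'   `alteration_class`, `descriptor`.
#' @export
alteration_table <- function(assay_id, assay_type, gene, alteration_class,
                             descriptor = NA_character_) {
  gene <- toupper(trimws(as.character(gene)))
  if (length(gene) == 0) {
    return(data.frame(assay_id = character(), assay_type = character(),
                      gene = character(), alteration_class = character(),
                      descriptor = character(), stringsAsFactors = FALSE))
  }
  if (any(!nzchar(gene) | is.na(gene))) stop("empty gene symbol in alteration table")
  alteration_class <- as.character(alteration_class)
  bad <- setdiff(unique(alteration_class), ALTERATION_CLASSES)
  if (length(bad)) stop("unknown alteration class: ", paste(bad, collapse = ", "))
  bad <- setdiff(unique(as.character(assay_type)), ASSAY_TYPES)
  if (length(bad)) stop("unknown assay type: ", paste(bad, collapse = ", "))
  data.frame(assay_id = as.character(assay_id),
             assay_type = as.character(assay_type),
             gene = gene, alteration_class = alteration_class,
             descriptor = as.character(descriptor), stringsAsFactors = FALSE)
}

#' Immune biomarker record
#'
#' @param tmb_mut_per_mb Tumor mutational burden in mutations/Mb, or `NA`.
#' @param msi_status `"msi_high"`, `"stable"` or `"unknown"`.
#' @param pdl1_percent PD-L1 IHC staining percentage in `[0, 100]`, or `NA`.
#' @param er_ihc,ar_ihc Hormone-receptor IHC: `"positive"`, `"negative"` or
#'   `"unknown"`.
#' @param rna_immune_levels Optional named character vector of RNA immune
#'   marker levels (`"low"`, `"intermediate"`, `"high"`, `"very_high"`);
#'   stored for reporting only, never scored.
#' @return A list of class `immune_biomarkers`.
#' @export
immune_biomarkers <- function(tmb_mut_per_mb = NA_real_,
                              msi_status = c("unknown", "msi_high", "stable"),
                              pdl1_percent = NA_real_,
                              er_ihc = c("unknown", "positive", "negative"),
                              ar_ihc = c("unknown", "positive", "negative"),
                              rna_immune_levels = NULL) {
  msi_status <- match.arg(msi_status)
  er_ihc <- match.arg(er_ihc)
  ar_ihc <- match.arg(ar_ihc)
  if (!is.na(tmb_mut_per_mb) && tmb_mut_per_mb < 0) stop("TMB must be non-negative")
  if (!is.na(pdl1_percent) && (pdl1_percent < 0 || pdl1_percent > 100)) {
    stop("PD-L1 percent must lie in [0, 100]")
  }
  structure(list(tmb_mut_per_mb = tmb_mut_per_mb, msi_status = msi_status,
                 pdl1_percent = pdl1_percent, er_ihc = er_ihc, ar_ihc = ar_ihc,
                 rna_immune_levels = rna_immune_levels),
            class = "immune_biomarkers")
}

#' Patient profile: alterations plus immune biomarkers
#'
#' @param patient_id Patient identifier.
#' @param alterations Data frame from [alteration_table()].
#' @param biomarkers An [immune_biomarkers()] record.
#' @return A list of class `patient_profile`.
#' @export
patient_profile <- function(patient_id, alterations = alteration_table(character(), character(), character(), character()),
                            biomarkers = immune_biomarkers()) {
  stopifnot(is.character(patient_id), length(patient_id) == 1, nzchar(patient_id))
  if (!inherits(biomarkers, "immune_biomarkers")) stop("biomarkers must be an immune_biomarkers record")
  structure(list(patient_id = patient_id, alterations = alterations,
                 biomarkers = biomarkers), class = "patient_profile")
}

#' Pool raw alterations into countable units
#'
#' Applies the counting rules that define the denominator of the Matching
#' Score: within one assay result, alterations sharing gene and alteration
#' class (or, with `pathway_map`, mapping to the same pathway with the same
#' class) collapse to a single unit; the same gene altered in structurally
#' distinct ways (e.g. amplification and mutation) yields separate units;
#' and alterations from different assay results are counted separately,
#' reflecting tumour heterogeneity between samples.
#'
#' @param alterations Data frame from [alteration_table()] (or the
#'   `alterations` element of a [patient_profile()]).
#' @param dedup_across_assays If `TRUE`, identical gene/class units seen in
#'   several assays collapse to one (alternative reading of the per-test
#'   counting rule); default `FALSE` counts each test result separately.
#' @param pathway_map Optional named character vector mapping gene symbol to
#'   pathway label; genes mapping to the same pathway (same class, same assay)
#'   collapse to one unit labelled by the pathway.
#' @return Data frame of countable units with columns `assay_id`, `label`,
#'   `alteration_class`, `multiplicity`, `rationale`, sorted by
#'   (`assay_id`, `label`, `alteration_class`).
#' @export
pool_countable_alterations <- function(alterations,
                                       dedup_across_assays = FALSE,
                                       pathway_map = NULL) {
  if (is.null(alterations) || nrow(alterations) == 0) {
    return(data.frame(assay_id = character(), label = character(),
                      alteration_class = character(), multiplicity = integer(),
                      rationale = character(), stringsAsFactors = FALSE))
  }
  if (any(!nzchar(alterations$gene) | is.na(alterations$gene))) {
    stop("empty gene symbol among alterations")
  }
  a <- alterations
  a$label <- a$gene
  if (!is.null(pathway_map)) {
    names(pathway_map) <- toupper(names(pathway_map))
    hit <- a$gene %in% names(pathway_map)
    a$label[hit] <- as.character(pathway_map[a$gene[hit]])
  }
  key_assay <- if (dedup_across_assays) "" else a$assay_id
  key <- paste(key_assay, a$label, a$alteration_class, sep = "\r")
  grp <- split(seq_len(nrow(a)), key)
  units <- do.call(rbind, lapply(grp, function(idx) {
    rows <- a[idx, , drop = FALSE]
    n_collapsed <- length(idx)
    data.frame(
      assay_id = if (dedup_across_assays) paste(sort(unique(rows$assay_id)), collapse = "+") else rows$assay_id[1],
      label = rows$label[1],
      alteration_class = rows$alteration_class[1],
      multiplicity = 1L,
      rationale = if (n_collapsed > 1) {
        paste0("collapsed ", n_collapsed, " same-", rows$alteration_class[1],
               " calls (", paste(sort(unique(rows$gene)), collapse = ","), ")")
      } else "single call",
      stringsAsFactors = FALSE)
  }))
  units <- units[order(units$assay_id, units$label, units$alteration_class), ,
                 drop = FALSE]
  rownames(units) <- NULL
  units
}

#' Classify tumour mutational burden
#'
#' Bins: low (< 6 mutations/Mb, i.e. the printed "<= 5" band), intermediate
#' (6-19), high (>= 20). The open interval (5, 6) is assigned to low.
#'
#' @param tmb_mut_per_mb Numeric vector of TMB values (mutations/Mb).
#' @return Character vector: `"low"`, `"intermediate"` or `"high"`.
#' @export
classify_tmb <- function(tmb_mut_per_mb) {
  if (any(tmb_mut_per_mb < 0, na.rm = TRUE)) stop("TMB must be non-negative")
  out <- ifelse(tmb_mut_per_mb >= 20, "high",
                ifelse(tmb_mut_per_mb >= 6, "intermediate", "low"))
  out[is.na(tmb_mut_per_mb)] <- NA_character_
  out
}

#' Classify PD-L1 IHC expression
#'
#' Positive at `low_threshold` (default 1%, the assay-positivity convention);
#' high at `high_threshold` (default 50%, the standard tumour proportion
#' score convention for strong expression).
#'
#' @param pdl1_percent Numeric vector of staining percentages in `[0, 100]`.
#' @param low_threshold,high_threshold Band edges, `0 < low <= high`.
#' @return Character vector: `"negative"`, `"low_positive"` or `"high"`.
#' @export
classify_pdl1 <- function(pdl1_percent, low_threshold = 1, high_threshold = 50) {
  stopifnot(low_threshold > 0, low_threshold <= high_threshold)
  if (any(pdl1_percent < 0 | pdl1_percent > 100, na.rm = TRUE)) {
    stop("PD-L1 percent must lie in [0, 100]")
  }
  out <- ifelse(pdl1_percent >= high_threshold, "high",
                ifelse(pdl1_percent >= low_threshold, "low_positive", "negative"))
  out[is.na(pdl1_percent)] <- NA_character_
  out
}

#' Outcome record for one treatment line
#'
#' @param pfs_months,os_months Non-negative times from treatment initiation.
#' @param pfs_event,os_event Logical; `TRUE` = progression/death observed,
#'   `FALSE` = censored at that time.
#' @param best_response `"CR"`, `"PR"`, `"SD"`, `"PD"` or `"not_evaluable"`.
#' @param sd_duration_months Duration of stable disease; required when
#'   `best_response == "SD"`.
#' @return A list of class `outcome_record`.
#' @export
outcome_record <- function(pfs_months, pfs_event, os_months, os_event,
                           best_response, sd_duration_months = NA_real_) {
  best_response <- match.arg(best_response, RESPONSES)
  stopifnot(pfs_months >= 0, os_months >= 0)
  if (isTRUE(pfs_event) && isTRUE(os_event) && pfs_months > os_months) {
    stop("observed PFS cannot exceed observed OS on the same clock")
  }
  if (best_response == "SD" && is.na(sd_duration_months)) {
    stop("stable disease requires sd_duration_months")
  }
  structure(list(pfs_months = pfs_months, pfs_event = isTRUE(pfs_event),
                 os_months = os_months, os_event = isTRUE(os_event),
                 best_response = best_response,
                 sd_duration_months = sd_duration_months),
            class = "outcome_record")
}

#' Clinical benefit indicator
#'
#' Clinical benefit is a best response of CR or PR, or stable disease lasting
#' at least six months (inclusive). Non-evaluable responses raise an error;
#' callers exclude those patients from benefit analyses.
#'
#' @param best_response Character vector of best responses, or an
#'   [outcome_record()].
#' @param sd_duration_months Stable-disease durations (recycled with
#'   `best_response`); required where the response is `"SD"`.
#' @return Logical vector.
#' @export
clinical_benefit <- function(best_response, sd_duration_months = NA_real_) {
  if (inherits(best_response, "outcome_record")) {
    sd_duration_months <- best_response$sd_duration_months
    best_response <- best_response$best_response
  }
  bad <- setdiff(unique(best_response), RESPONSES)
  if (length(bad)) stop("unknown best response: ", paste(bad, collapse = ", "))
  if (any(best_response == "not_evaluable")) {
    stop("clinical benefit is undefined for not_evaluable responses; exclude them")
  }
  if (any(best_response == "SD" & is.na(sd_duration_months))) {
    stop("stable disease requires sd_duration_months")
  }
  best_response %in% c("CR", "PR") |
    (best_response == "SD" & !is.na(sd_duration_months) & sd_duration_months >= 6)
}

#' Cohort-level biomarker summary
#'
#' Descriptive proportions among tested patients: MSI-high rate, TMB category
#' shares, the TMB >= 10 mutations/Mb share (the tissue-agnostic checkpoint
#' approval threshold), and PD-L1 positivity (>= 1%).
#'
#' @param biomarkers Data frame with columns `tmb_mut_per_mb`, `msi_status`,
#'   `pdl1_percent` (`NA` = not tested; `msi_status == "unknown"` = not
#'   tested).
#' @return Data frame with columns `measure`, `numerator`, `denominator`,
#'   `percent` (one decimal).
#' @export
summarize_biomarkers <- function(biomarkers) {
  msi_tested <- biomarkers$msi_status %in% c("msi_high", "stable")
  tmb_tested <- !is.na(biomarkers$tmb_mut_per_mb)
  pdl1_tested <- !is.na(biomarkers$pdl1_percent)
  tmb_cat <- classify_tmb(biomarkers$tmb_mut_per_mb[tmb_tested])
  row <- function(measure, num, den) {
    data.frame(measure = measure, numerator = num, denominator = den,
               percent = if (den > 0) round(100 * num / den, 1) else NA_real_,
               stringsAsFactors = FALSE)
  }
  rbind(
    row("msi_high", sum(biomarkers$msi_status == "msi_high"), sum(msi_tested)),
    row("tmb_low", sum(tmb_cat == "low"), sum(tmb_tested)),
    row("tmb_intermediate", sum(tmb_cat == "intermediate"), sum(tmb_tested)),
    row("tmb_high", sum(tmb_cat == "high"), sum(tmb_tested)),
    row("tmb_ge_10", sum(biomarkers$tmb_mut_per_mb[tmb_tested] >= 10), sum(tmb_tested)),
    row("pdl1_positive", sum(biomarkers$pdl1_percent[pdl1_tested] >= 1), sum(pdl1_tested))
  )
}
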