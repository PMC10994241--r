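COHORT_FILES <- list(
  patients = c("patient_id", "age", "sex", "histology"),
  assays = c("patient_id", "assay_id", "assay_type"),
  alterations = c("patient_id", "assay_id", "assay_type", "gene",
                  "alteration_class", "descriptor"),
  biomarkers = c("patient_id", "tmb_mut_per_mb", "msi_status", "pdl1_percent",
                 "er_ihc", "ar_ihc"),
  treatments = c("patient_id", "line", "drugs"),
  outcomes = c("patient_id", "pfs_months", "pfs_event", "os_months",
               "os_event", "best_response", "sd_duration_months"))

#' Write a cohort to a directory of CSV files
#'
#' One UTF-8, comma-delimited file per table (`patients.csv`,
#' `alterations.csv`, `biomarkers.csv`, `treatments.csv`, `outcomes.csv`),
#' missing values as empty fields.
#'
#' @param cohort An `ms_cohort` (e.g. from [simulate_cohort()] or
#'   [read_cohort()]).
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(COHORT_FILES)) {
    tab <- cohort[[nm]]
    if (is.null(tab)) next
    utils::write.csv(tab, file.path(dir, paste0(nm, ".csv")),
                     row.names = FALSE, na = "")
  }
  invisible(dir)
}

read_table_checked <- function(dir, name, required = TRUE) {
  path <- file.path(dir, paste0(name, ".csv"))
  if (!file.exists(path)) {
    if (required) stop("required cohort file missing: ", path)
    return(NULL)
  }
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(COHORT_FILES[[name]], names(tab))
  if (length(missing_cols)) {
    stop(path, ": missing column(s) ", paste(missing_cols, collapse = ", "))
  }
  tab
}

#' Read a cohort from a directory of CSV files
#'
#' Validates headers, enum fields and identifiers; row-level problems are
#' reported with file and line numbers. `outcomes.csv` is optional: scoring
#' is possible without it, but [analyze_cohort()] input cannot be assembled,
#' and patients missing an outcome row are flagged non-evaluable.
#'
#' @param dir Directory containing the cohort CSV files (see
#'   [write_cohort()] for the schema).
#' @return An `ms_cohort` list of data frames; `outcomes` is `NULL` when the
#'   file is absent.
#' @export
read_cohort <- function(dir) {
  if (!dir.exists(dir)) stop("cohort directory not found: ", dir)
  patients <- read_table_checked(dir, "patients")
  if (anyDuplicated(patients$patient_id)) {
    stop("patients.csv: duplicate patient_id: ",
         paste(unique(patients$patient_id[duplicated(patients$patient_id)]),
               collapse = ", "))
  }
  assays <- read_table_checked(dir, "assays", required = FALSE)
  alterations <- read_table_checked(dir, "alterations")
  problems <- character()
  bad <- which(is.na(alterations$gene) | !nzchar(trimws(alterations$gene)))
  if (length(bad)) {
    problems <- c(problems, paste0("alterations.csv line ", bad + 1,
                                   ": empty gene symbol"))
  }
  bad <- which(!alterations$alteration_class %in% ALTERATION_CLASSES)
  if (length(bad)) {
    problems <- c(problems, paste0("alterations.csv line ", bad + 1,
                                   ": unknown alteration_class '",
                                   alterations$alteration_class[bad], "'"))
  }
  bad <- which(!alterations$assay_type %in% ASSAY_TYPES)
  if (length(bad)) {
    problems <- c(problems, paste0("alterations.csv line ", bad + 1,
                                   ": unknown assay_type '",
                                   alterations$assay_type[bad], "'"))
  }
  biomarkers <- read_table_checked(dir, "biomarkers")
  bad <- which(!biomarkers$msi_status %in% c("msi_high", "stable", "unknown") &
                 !is.na(biomarkers$msi_status))
  if (length(bad)) {
    problems <- c(problems, paste0("biomarkers.csv line ", bad + 1,
                                   ": unknown msi_status '",
                                   biomarkers$msi_status[bad], "'"))
  }
  treatments <- read_table_checked(dir, "treatments")
  outcomes <- read_table_checked(dir, "outcomes", required = FALSE)
  if (!is.null(outcomes)) {
    bad <- which(!outcomes$best_response %in% RESPONSES)
    if (length(bad)) {
      problems <- c(problems, paste0("outcomes.csv line ", bad + 1,
                                     ": unknown best_response '",
                                     outcomes$best_response[bad], "'"))
    }
  }
  if (length(problems)) {
    stop("cohort validation failed:\n  ", paste(problems, collapse = "\n  "))
  }
  no_outcome <- if (is.null(outcomes)) patients$patient_id else
    setdiff(patients$patient_id, outcomes$patient_id)
  structure(list(patients = patients, assays = assays,
                 alterations = alterations, biomarkers = biomarkers,
                 treatments = treatments, outcomes = outcomes,
                 non_evaluable = no_outcome),
            class = "ms_cohort")
}

biomarkers_from_row <- function(row) {
  msi <- row$msi_status
  if (is.na(msi) || !nzchar(msi)) msi <- "unknown"
  er <- row$er_ihc; ar <- row$ar_ihc
  immune_biomarkers(
    tmb_mut_per_mb = if (is.na(row$tmb_mut_per_mb)) NA_real_ else row$tmb_mut_per_mb,
    msi_status = msi,
    pdl1_percent = if (is.na(row$pdl1_percent)) NA_real_ else row$pdl1_percent,
    er_ihc = if (is.na(er) || !nzchar(er)) "unknown" else er,
    ar_ihc = if (is.na(ar) || !nzchar(ar)) "unknown" else ar)
}

#' Score every patient in a cohort
#'
#' @param cohort An `ms_cohort`.
#' @param kb A `matching_kb`.
#' @param cutoff Matching Score cutoff for the high/low grouping.
#' @param dedup_across_assays,pathway_map Passed to
#'   [pool_countable_alterations()].
#' @return Data frame with one row per treated patient: `patient_id`,
#'   `numerator`, `denominator`, `checkpoint_component`, `score_percent`,
#'   `matched`, `group`; per-patient audit ledgers in the `ledgers`
#'   attribute (a named list).
#' @export
score_cohort <- function(cohort, kb = default_kb(), cutoff = 50,
                         dedup_across_assays = FALSE, pathway_map = NULL) {
  ids <- cohort$treatments$patient_id
  ledgers <- list()
  rows <- lapply(seq_along(ids), function(i) {
    pid <- ids[i]
    alts <- cohort$alterations[cohort$alterations$patient_id == pid, , drop = FALSE]
    brow <- cohort$biomarkers[cohort$biomarkers$patient_id == pid, , drop = FALSE]
    bio <- if (nrow(brow)) biomarkers_from_row(brow[1, ]) else immune_biomarkers()
    regimen <- strsplit(cohort$treatments$drugs[i], ";", fixed = TRUE)[[1]]
    prof <- patient_profile(pid, alts[, COHORT_FILES$alterations[-1]], bio)
    ms <- compute_matching_score(prof, trimws(regimen), kb,
                                 dedup_across_assays = dedup_across_assays,
                                 pathway_map = pathway_map)
    ledgers[[pid]] <<- ms$ledger
    data.frame(patient_id = pid, numerator = ms$numerator,
               denominator = ms$denominator,
               checkpoint_component = ms$checkpoint_component,
               score_percent = ms$score_percent, matched = ms$matched,
               group = dichotomize_score(ms$score_percent, cutoff),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "ledgers") <- ledgers
  out
}

assemble_analysis_data <- function(cohort, scores) {
  if (is.null(cohort$outcomes)) {
    stop("cohort has no outcomes.csv; scoring is possible but outcome ",
         "analysis requires outcome records")
  }
  d <- merge(scores, cohort$outcomes, by = "patient_id")
  d <- merge(d, cohort$patients, by = "patient_id", all.x = TRUE)
  trt <- cohort$treatments
  trt$n_drugs <- vapply(strsplit(trt$drugs, ";", fixed = TRUE), length, 1L)
  d <- merge(d, trt[, c("patient_id", "line", "n_drugs", "drugs")],
             by = "patient_id", all.x = TRUE)
  d
}

#' Run the full scoring and analysis pipeline
#'
#' Reads (or simulates) a cohort, scores every treated patient, analyses
#' outcomes, and writes `scores.csv`, `ledger.json`, `report.json` and
#' `report.md` to the output directory. Deterministic given the same inputs,
#' config and seed; on error, partial artifacts are removed.
#'
#' @param config Either a list or a YAML file path with fields: `input_dir`
#'   (cohort CSV directory) or `simulate` (a list of [sim_config()]
#'   arguments), optional `kb` (KB file path; default KB when absent),
#'   `cutoff` (default 50), `dedup_across_assays` (default `FALSE`), `seed`
#'   (required when simulating), and `out_dir`.
#' @return The analysis report (list), invisibly; also serialized as JSON.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  out_dir <- config$out_dir %||% stop("config must give out_dir")
  cutoff <- config$cutoff %||% 50
  kb <- if (is.null(config$kb)) default_kb() else load_kb(config$kb)
  artifacts <- file.path(out_dir, c("scores.csv", "ledger.json",
                                    "report.json", "report.md"))
  ok <- FALSE
  on.exit(if (!ok) unlink(artifacts), add = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  cohort <- if (!is.null(config$input_dir)) {
    read_cohort(config$input_dir)
  } else if (!is.null(config$simulate)) {
    if (is.null(config$seed)) stop("simulation requires a seed")
    simulate_cohort(do.call(sim_config, config$simulate), kb = kb,
                    seed = config$seed, cutoff = cutoff)
  } else stop("config must give input_dir or simulate")

  scores <- score_cohort(cohort, kb, cutoff = cutoff,
                         dedup_across_assays = isTRUE(config$dedup_across_assays))
  utils::write.csv(scores, artifacts[1], row.names = FALSE, na = "")
  jsonlite::write_json(attr(scores, "ledgers"), artifacts[2],
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  data <- assemble_analysis_data(cohort, scores)
  data$immunotherapy <- scores$checkpoint_component[
    match(data$patient_id, scores$patient_id)] != "absent"
  report <- suppressWarnings(analyze_cohort(data, cutoff = cutoff))
  jsonlite::write_json(unclass(report), artifacts[3], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
  writeLines(report_markdown(report), artifacts[4])
  ok <- TRUE
  invisible(report)
}

#' Render a cohort analysis as a Markdown table pair
#'
#' @param report A `cohort_analysis` from [analyze_cohort()].
#' @return Character vector of Markdown lines.
#' @export
report_markdown <- function(report) {
  fmt_med <- function(m) ifelse(is.na(m), "NR", formatC(m, digits = 1, format = "f"))
  lines <- c("# Cohort outcome analysis", "",
             sprintf("%d patients; %d response-evaluable; Matching Score cutoff %s%%.",
                     report$n, report$n_evaluable, format(report$cutoff)), "",
             "## Survival (univariate)", "",
             "| Covariate | PFS median (yes vs no), months | PFS HR (95% CI) | PFS log-rank P | OS median (yes vs no), months | OS HR (95% CI) | OS log-rank P |",
             "|---|---|---|---|---|---|---|")
  for (i in seq_len(nrow(report$pfs))) {
    p <- report$pfs[i, ]; o <- report$os[i, ]
    lines <- c(lines, sprintf(
      "| %s | %s vs %s | %.2f (%.2f-%.2f) | %.3g | %s vs %s | %.2f (%.2f-%.2f) | %.3g |",
      p$covariate, fmt_med(p$median_yes), fmt_med(p$median_no),
      p$hazard_ratio, p$ci_low, p$ci_high, p$logrank_p,
      fmt_med(o$median_yes), fmt_med(o$median_no),
      o$hazard_ratio, o$ci_low, o$ci_high, o$logrank_p))
  }
  lines <- c(lines, "", "## Clinical benefit (SD >= 6 months / PR / CR)", "",
             "| Covariate | Rate (yes) | Rate (no) | OR (95% CI) | Fisher P |",
             "|---|---|---|---|---|")
  for (i in seq_len(nrow(report$benefit))) {
    b <- report$benefit[i, ]
    lines <- c(lines, sprintf(
      "| %s | %d%% (%d/%d) | %d%% (%d/%d) | %.2f (%.2f-%.2f) | %.3g |",
      b$covariate,
      round_half_up(100 * b$rate_yes), round(b$rate_yes * b$n_yes), b$n_yes,
      round_half_up(100 * b$rate_low), round(b$rate_low * b$n_no), b$n_no,
      b$odds_ratio, b$ci_low, b$ci_high, b$fisher_p))
  }
  mv <- report$multivariate
  lines <- c(lines, "", "## Multivariate models", "")
  if (is.null(mv$pfs) && is.null(mv$os) && is.null(mv$benefit)) {
    lines <- c(lines, "Multivariate analysis not performed: fewer than two covariates passed the univariate screen.")
  } else {
    for (nm in c("pfs", "os", "benefit")) {
      if (is.null(mv[[nm]])) next
      est <- if (nm == "benefit") "OR" else "HR"
      col <- if (nm == "benefit") "odds_ratio" else "hazard_ratio"
      lines <- c(lines, sprintf("### %s", toupper(nm)), "",
                 sprintf("| Covariate | %s (95%% CI) | P |", est),
                 "|---|---|---|")
      for (i in seq_len(nrow(mv[[nm]]))) {
        r <- mv[[nm]][i, ]
        lines <- c(lines, sprintf("| %s | %.2f (%.2f-%.2f) | %.3g |",
                                  r$term, r[[col]], r$ci_low, r$ci_high,
                                  r$p_value))
      }
      lines <- c(lines, "")
    }
  }
  lines
}
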