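#' @keywords internal
"_PACKAGE"

DRUG_CLASSES <- c("small_molecule", "monoclonal_antibody", "checkpoint_inhibitor",
                  "parp_inhibitor", "platinum", "hormone_modulator", "cytotoxic_other")

#' Drug-target knowledge base
#'
#' A `matching_kb` object maps drug names (case-insensitive, with trade-name
#' aliases) to the molecular targets they are considered matched to, and
#' carries the matching conventions used by the scoring engine:
#'
#' * `brca_related_genes`: genes whose alteration makes PARP inhibitors and
#'   platinum cytotoxics matched;
#' * `tp53_vegf_rule_enabled`: whether TP53 alterations count as matched to
#'   drugs with anti-VEGF/VEGFR activity;
#' * synergy pairs (e.g. dabrafenib + trametinib via BRAF): when both partners
#'   appear in a regimen, their shared alteration is counted twice in both the
#'   numerator and denominator of the score.
#'
#' Checkpoint inhibitors carry no target genes: they are scored against immune
#' biomarkers (MSI, TMB, PD-L1), not genomic alterations. Hormone modulators
#' use the receptor tags `"ER"` / `"AR"`, matched against IHC positivity.
#'
#' @param path Path to a KB file.
#' @param format `"auto"` (by extension), `"json"` or `"yaml"`.
#' @return A validated `matching_kb` object.
#' @examples
#' kb <- default_kb()
#' effective_target_genes("bevacizumab", kb)
#' @export
load_kb <- function(path, format = c("auto", "json", "yaml")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("KB file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) "yaml" else "json"
  }
  raw <- if (format == "yaml") {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyDataFrame = FALSE, simplifyVector = TRUE)
  }
  kb_from_list(raw)
}

#' Build a knowledge base from an R list
#'
#' @param raw List with elements `drugs` (list of entries with `name`, `class`,
#'   `targets`, optional `synergy_partner` (`list(drug, gene)`) and
#'   `anti_vegf`), optional `brca_related_genes`, `aliases`,
#'   `tp53_vegf_rule_enabled`.
#' @return A `matching_kb` object.
#' @export
kb_from_list <- function(raw) {
  if (is.null(raw$drugs) || length(raw$drugs) == 0) stop("KB has no drugs")
  entries <- lapply(raw$drugs, function(d) {
    name <- tolower(trimws(as.character(d$name %||% "")))
    if (!nzchar(name)) stop("KB load error: drug with empty name")
    cls <- as.character(d$class %||% "")
    if (!cls %in% DRUG_CLASSES) {
      stop("KB load error: unknown drug class '", cls, "' for drug '", name, "'")
    }
    targets <- toupper(as.character(unlist(d$targets)))
    targets <- unique(targets[nzchar(targets)])
    if (cls == "checkpoint_inhibitor" && length(targets) > 0) {
      stop("KB load error: checkpoint inhibitor '", name,
           "' must not list target genes")
    }
    sp <- d$synergy_partner
    if (!is.null(sp)) {
      sp <- list(drug = tolower(as.character(sp$drug)),
                 gene = toupper(as.character(sp$gene)))
      if (!nzchar(sp$drug) || !nzchar(sp$gene)) {
        stop("KB load error: malformed synergy_partner for drug '", name, "'")
      }
    }
    list(name = name, class = cls, targets = targets,
         synergy_partner = sp, anti_vegf = isTRUE(d$anti_vegf))
  })
  nms <- vapply(entries, `[[`, "", "name")
  if (anyDuplicated(nms)) {
    stop("KB load error: duplicate drug name(s): ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "))
  }
  names(entries) <- nms

  aliases <- raw$aliases %||% list()
  aliases <- stats::setNames(tolower(as.character(unlist(aliases))),
                             tolower(names(aliases)))

  kb <- structure(list(
    drugs = entries,
    brca_related_genes = toupper(as.character(
      unlist(raw$brca_related_genes %||%
               c("BRCA1", "BRCA2", "PALB2", "ATM", "BARD1", "BRIP1",
                 "RAD51C", "RAD51D")))),
    tp53_vegf_rule_enabled = raw$tp53_vegf_rule_enabled %||% TRUE,
    aliases = aliases
  ), class = "matching_kb")

  problems <- validate_kb(kb)
  if (length(problems)) stop("KB load error: ", paste(problems, collapse = "; "))
  kb
}

#' Validate a knowledge base
#'
#' Checks alias targets, synergy-partner existence and reciprocity, and that
#' every synergy gene lies in both partners' effective target sets.
#'
#' @param kb A `matching_kb`.
#' @return Character vector of problems (empty when valid).
#' @export
validate_kb <- function(kb) {
  problems <- character()
  for (al in names(kb$aliases)) {
    if (!kb$aliases[[al]] %in% names(kb$drugs)) {
      problems <- c(problems, paste0("alias '", al, "' points to unknown drug '",
                                     kb$aliases[[al]], "'"))
    }
  }
  for (e in kb$drugs) {
    sp <- e$synergy_partner
    if (is.null(sp)) next
    partner <- kb$drugs[[sp$drug]]
    if (is.null(partner)) {
      problems <- c(problems, paste0("synergy partner '", sp$drug,
                                     "' of '", e$name, "' is not in the KB"))
      next
    }
    if (!sp$gene %in% effective_target_genes(e, kb) ||
        !sp$gene %in% effective_target_genes(partner, kb)) {
      problems <- c(problems, paste0("synergy gene ", sp$gene, " of pair ",
                                     e$name, "/", sp$drug,
                                     " is not in both effective target sets"))
    }
  }
  problems
}

#' @rdname load_kb
#' @export
default_kb <- function() {
  load_kb(system.file("extdata", "default_kb.json", package = "matchscore"),
          format = "json")
}

#' Write a knowledge base to file
#'
#' @param kb A `matching_kb`.
#' @param path Output path.
#' @param format `"json"` or `"yaml"`.
#' @return `path`, invisibly.
#' @export
write_kb <- function(kb, path, format = c("json", "yaml")) {
  format <- match.arg(format)
  raw <- list(
    drugs = lapply(unname(kb$drugs), function(e) {
      out <- list(name = e$name, class = e$class, targets = as.list(e$targets))
      if (!is.null(e$synergy_partner)) out$synergy_partner <- e$synergy_partner
      if (isTRUE(e$anti_vegf)) out$anti_vegf <- TRUE
      out
    }),
    brca_related_genes = as.list(kb$brca_related_genes),
    tp53_vegf_rule_enabled = kb$tp53_vegf_rule_enabled,
    aliases = as.list(kb$aliases)
  )
  if (format == "yaml") {
    yaml::write_yaml(raw, path)
  } else {
    jsonlite::write_json(raw, path, auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(path)
}

#' Resolve a drug name against the knowledge base
#'
#' Case-insensitive, with trade-name aliases.
#'
#' @param name Drug name.
#' @param kb A `matching_kb`.
#' @return The drug entry (a list).
#' @export
resolve_drug <- function(name, kb) {
  key <- tolower(trimws(name))
  if (key %in% names(kb$aliases)) key <- kb$aliases[[key]]
  entry <- kb$drugs[[key]]
  if (is.null(entry)) stop("unknown drug name: '", name, "'")
  entry
}

#' Effective target genes of a drug
#'
#' The drug's curated target set augmented by the matching conventions:
#' TP53 is added for drugs with anti-VEGF/VEGFR activity (when the rule is
#' enabled), and the KB's BRCA-related gene list is added for PARP inhibitors
#' and platinum cytotoxics.
#'
#' @param drug Drug name or entry.
#' @param kb A `matching_kb`.
#' @return Character vector of gene symbols (possibly empty).
#' @export
effective_target_genes <- function(drug, kb) {
  entry <- if (is.character(drug)) resolve_drug(drug, kb) else drug
  genes <- entry$targets
  if (isTRUE(entry$anti_vegf) && isTRUE(kb$tp53_vegf_rule_enabled)) {
    genes <- c(genes, "TP53")
  }
  if (entry$class %in% c("parp_inhibitor", "platinum")) {
    genes <- c(genes, kb$brca_related_genes)
  }
  unique(genes)
}

#' Synergy pairs completed by a regimen
#'
#' @param regimen Character vector of drug names.
#' @param kb A `matching_kb`.
#' @return Data frame with columns `drug_a`, `drug_b`, `gene`, one row per
#'   synergy pair whose two partners are both present in `regimen`.
#' @export
active_synergy_pairs <- function(regimen, kb) {
  entries <- lapply(regimen, resolve_drug, kb = kb)
  present <- vapply(entries, `[[`, "", "name")
  out <- data.frame(drug_a = character(), drug_b = character(),
                    gene = character(), stringsAsFactors = FALSE)
  for (e in entries) {
    sp <- e$synergy_partner
    if (is.null(sp) || !sp$drug %in% present) next
    pair <- sort(c(e$name, sp$drug))
    key <- paste(pair, collapse = "/")
    if (key %in% paste(out$drug_a, out$drug_b, sep = "/")) next
    out <- rbind(out, data.frame(drug_a = pair[1], drug_b = pair[2],
                                 gene = sp$gene, stringsAsFactors = FALSE))
  }
  out
}

#' @export
print.matching_kb <- function(x, ...) {
  cat("<matching_kb>", length(x$drugs), "drugs\n")
  cls <- vapply(x$drugs, `[[`, "", "class")
  for (cl in unique(cls)) {
    cat("  ", cl, ": ", paste(names(x$drugs)[cls == cl], collapse = ", "),
        "\n", sep = "")
  }
  cat("  BRCA-related genes:", paste(x$brca_related_genes, collapse = ", "), "\n")
  cat("  TP53/anti-VEGF rule:", if (isTRUE(x$tp53_vegf_rule_enabled)) "on" else "off", "\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
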