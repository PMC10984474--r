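#' Default tumor-microenvironment marker panel
#'
#' The ten marker axes evaluated by the full pipeline: fibroblasts (SPARC),
#' endothelia (PECAM1), cytotoxic T cells (CD8A), myeloid cells (CD14),
#' CD3 T-cell infiltrates (CD3G), functional and immature myeloid-derived
#' suppressor cells (ARG1, CD33), regulatory T cells (FOXP3), B-cell
#' infiltrates (MS4A1) and neutrophils (S100A9).
#'
#' @return data.frame with columns `signature`, `anchor_symbol`
#' @export
default_marker_panel <- function() {
  data.frame(
    signature = c("CAFG", "TAEG", "CTLG", "TAMCG", "CD3TILG",
                  "ARG1G", "iMDSCG", "TregG", "BTILG", "TANG"),
    anchor_symbol = c("SPARC", "PECAM1", "CD8A", "CD14", "CD3G",
                      "ARG1", "CD33", "FOXP3", "MS4A1", "S100A9"),
    stringsAsFactors = FALSE)
}

#' Run the full signature-to-prognosis workflow
#'
#' Orchestrates the study workflow on a paired compartment dataset and a
#' linked survival cohort: housekeeping normalization, per-probe cS/E
#' profiles, one co-expression signature per marker anchor, per-marker
#' associated-gene counts (R-index filter alone, ignoring specificity and
#' abundance), anchor specificity classes, signature overlap with fibrosis
#' subclassing, per-gene prognostic evaluation of the lead signature's top
#' symbols in the cohort, an AUC ranking, and optional two-gene combined
#' stratifications. Signatures derive from the compartment dataset;
#' prognosis runs on the cohort; gene identity is bridged by symbol, with
#' the cohort row for a symbol chosen as its most abundant probe when the
#' cohort is probe-level.
#'
#' @param compartment an `ExpressionMatrix` of paired stroma/epithelium
#'   samples (raw signals)
#' @param cohort a `SurvivalCohort` (expression rows indexed by symbol)
#' @param hk_probe housekeeping probe id of the compartment dataset
#' @param marker_panel data.frame with columns `signature`,
#'   `anchor_symbol`; anchors absent from the annotation are reported as
#'   skipped. An empty panel yields a valid report with zero signatures.
#' @param r_min,cse_min,amount_min signature thresholds, see
#'   [derive_signature()]
#' @param top_n number of lead-signature symbols carried into prognostic
#'   analysis (default 76)
#' @param alpha significance level for direction calls
#' @param cse_mode see [compute_cse()]
#' @param cutoff_mode see [evaluate_gene()]
#' @param combos optional list of `c(gene_a, gene_b)` symbol pairs for
#'   [combined_stratification()]
#' @param lead_signature name of the signature whose symbols enter
#'   prognosis (default the first panel row, conventionally the CAF
#'   signature)
#' @param out_dir optional directory: per-stage TSVs plus a `report.json`
#'   manifest (config + seed + package version) are written there
#' @param seed recorded in the manifest; the pipeline itself is
#'   deterministic given its inputs
#' @return a report list (class `stromascape_report`) with elements
#'   `profiles`, `signatures`, `signature_summary`, `overlap`, `prognosis`,
#'   `auc_ranking`, `combos`, `manifest`
#' @export
run_full_pipeline <- function(compartment, cohort, hk_probe,
                              marker_panel = default_marker_panel(),
                              r_min = 0.9, cse_min = 10, amount_min = 40,
                              top_n = 76, alpha = 0.05,
                              cse_mode = "ratio-of-means",
                              cutoff_mode = "youden",
                              combos = NULL,
                              lead_signature = NULL,
                              out_dir = NULL, seed = NULL) {
  stopifnot(inherits(compartment, "ExpressionMatrix"),
            inherits(cohort, "SurvivalCohort"))
  nm <- normalize_by_housekeeping(compartment, hk_probe)
  profiles <- compute_cse(nm, mode = cse_mode)

  signatures <- list()
  summary_rows <- list()
  for (i in seq_len(nrow(marker_panel))) {
    sig_name <- marker_panel$signature[i]
    anchor <- marker_panel$anchor_symbol[i]
    if (!anchor %in% nm$probe_anno$symbol) {
      summary_rows[[sig_name]] <- data.frame(
        signature = sig_name, anchor_symbol = anchor, anchor_probe = NA,
        anchor_cse = NA_real_, anchor_cse_class = NA_character_,
        n_member_probes = NA_integer_, n_member_symbols = NA_integer_,
        n_associated = NA_integer_, skipped = TRUE,
        stringsAsFactors = FALSE)
      next
    }
    sig <- withCallingHandlers(
      derive_signature(nm, profiles, anchor, r_min = r_min,
                       cse_min = cse_min, amount_min = amount_min,
                       name = sig_name),
      warning = function(w) invokeRestart("muffleWarning"))
    signatures[[sig_name]] <- sig
    arow <- profiles[profiles$probe_id == sig$anchor_probe, ]
    summary_rows[[sig_name]] <- data.frame(
      signature = sig_name, anchor_symbol = anchor,
      anchor_probe = sig$anchor_probe,
      anchor_cse = arow$cse_ratio,
      anchor_cse_class = as.character(arow$cse_class),
      n_member_probes = nrow(sig$members),
      n_member_symbols = length(unique(stats::na.omit(sig$members$symbol))),
      n_associated = sig$n_associated, skipped = FALSE,
      stringsAsFactors = FALSE)
  }
  signature_summary <- if (length(summary_rows))
    do.call(rbind, summary_rows) else
    data.frame(signature = character(0))
  rownames(signature_summary) <- NULL

  overlap <- NULL
  if (length(signatures) >= 2L) {
    cafg <- if (!is.null(lead_signature)) lead_signature
      else if ("CAFG" %in% names(signatures)) "CAFG"
      else names(signatures)[1L]
    overlap <- intersect_signatures(unname(signatures), cafg_name = cafg)
  }

  # prognosis on the lead signature's top symbols
  prognosis <- NULL
  auc_ranking <- NULL
  lead <- if (!is.null(lead_signature)) lead_signature
    else if (length(signatures)) names(signatures)[1L] else NULL
  n_skipped_cohort <- 0L
  if (!is.null(lead) && lead %in% names(signatures)) {
    syms <- select_top_by_amount(
      suppressMessages(collapse_to_symbols(signatures[[lead]])), top_n)
    present <- intersect(syms, rownames(cohort$expression))
    n_skipped_cohort <- length(syms) - length(present)
    if (length(present)) {
      res <- lapply(present, function(g)
        evaluate_gene(cohort$expression[g, ], cohort$clinical$time,
                      cohort$clinical$event, alpha = alpha,
                      cutoff_mode = cutoff_mode, id = g))
      prognosis <- do.call(rbind, res)
      auc_ranking <- rank_by_auc(prognosis)
    }
  }

  combo_results <- NULL
  if (!is.null(combos)) {
    combo_results <- lapply(combos, function(pair) {
      if (!all(pair %in% rownames(cohort$expression)))
        return(list(gene_a = pair[1L], gene_b = pair[2L],
                    evaluable = FALSE))
      c(list(gene_a = pair[1L], gene_b = pair[2L], evaluable = TRUE),
        combined_stratification(cohort$expression[pair[1L], ],
                                cohort$expression[pair[2L], ],
                                cohort$clinical$time,
                                cohort$clinical$event))
    })
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("stromascape")),
    seed = seed,
    hk_probe = hk_probe,
    thresholds = list(r_min = r_min, cse_min = cse_min,
                      amount_min = amount_min),
    top_n = top_n, alpha = alpha,
    cse_mode = cse_mode, cutoff_mode = cutoff_mode,
    marker_panel = marker_panel,
    n_probes = nrow(compartment$signals),
    n_compartment_samples = ncol(compartment$signals),
    n_patients = nrow(cohort$clinical),
    n_lead_symbols_absent_from_cohort = n_skipped_cohort)

  report <- structure(list(profiles = profiles,
                           signatures = signatures,
                           signature_summary = signature_summary,
                           overlap = overlap,
                           prognosis = prognosis,
                           auc_ranking = auc_ranking,
                           combos = combo_results,
                           manifest = manifest),
                      class = "stromascape_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.stromascape_report <- function(x, ...) {
  cat("<stromascape_report>\n")
  cat("  signatures:\n")
  print(x$signature_summary)
  if (!is.null(x$auc_ranking)) {
    cat("  top prognostic genes by AUC:\n")
    print(utils::head(x$auc_ranking, 5L))
  }
  invisible(x)
}

#' Write a pipeline report to disk
#'
#' Per-stage TSVs (profiles, per-signature member tables, overlap
#' membership, prognostic results) plus `report.json` carrying the summary
#' tables and the manifest that suffices to reproduce the run (config and
#' seed; no timestamps).
#'
#' @param report a `stromascape_report`
#' @param out_dir output directory (created if needed)
#' @return `out_dir`, invisibly
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_cse_table(report$profiles, file.path(out_dir, "cse_profiles.tsv"))
  for (sig in report$signatures)
    utils::write.table(sig$members,
                       file.path(out_dir, paste0("signature_", sig$name, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(report$overlap))
    utils::write.table(report$overlap$membership,
                       file.path(out_dir, "overlap.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(report$prognosis))
    utils::write.table(report$prognosis,
                       file.path(out_dir, "prognosis.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  json <- list(manifest = report$manifest,
               signature_summary = report$signature_summary,
               auc_ranking = report$auc_ranking)
  jsonlite::write_json(json, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
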