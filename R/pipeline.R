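#' Run the full biomarker analysis pipeline
#'
#' End-to-end workflow on a Cq table and patient table: NTC detection rule,
#' sample QC (spike-ins, hemolysis) with logged exclusions, 80% detection
#' filter, global-mean normalization with a NormFinder-style normalizer
#' ranking, limit-of-detection imputation, univariable screen with BH
#' adjustment, patient-characteristics table, elastic-net stability
#' selection for the miRs-only and miRs + risk-factor predictor sets, and
#' cross-validated ROC for the top-ranked miR against the traditional
#' lipid-panel model. Deterministic given `config$seed` and the inputs.
#'
#' @param cq A [cq_table()].
#' @param patients Patient tibble (see [read_patient_table()]); sample ids
#'   must cover the Cq table's samples.
#' @param config A [run_config()].
#' @param include_risk_factors Also fit the extended predictor set?
#' @return A list of class `plq_report`; see the elements documented in the
#'   package vignette. Aborts when fewer than 2 samples per outcome class
#'   survive QC.
#' @export
run_pipeline <- function(cq, patients, config = run_config(),
                         include_risk_factors = TRUE) {
  if (!all(rownames(cq$values) %in% patients$sample_id)) {
    abort("sample ids in the Cq table are missing from the patient table")
  }
  log <- list()
  note <- function(stage, message, n = NA_real_) {
    log[[length(log) + 1]] <<- tibble(stage = stage, message = message, n = n)
  }

  cq2 <- apply_ntc_rule(cq, margin = config$ntc_margin_cq)
  note("ntc", "cells censored by NTC margin rule",
       attr(cq2, "n_censored"))

  qc <- qc_report(cq2, config)
  keep <- qc$samples$sample_id[qc$samples$pass]
  excluded <- setdiff(rownames(cq2$values), keep)
  note("qc", paste0("samples excluded: ",
                    if (length(excluded)) paste(excluded, collapse = ", ")
                    else "none"),
       length(excluded))
  cq3 <- cq_table(cq2$values[keep, , drop = FALSE], roles = cq2$roles,
                  max_cycles = cq2$max_cycles, ntc = cq2$ntc)
  patients <- patients[match(keep, patients$sample_id), ]
  if (sum(patients$lipid_rich) < 2 || sum(!patients$lipid_rich) < 2) {
    abort("fewer than 2 samples per outcome class after QC")
  }

  det <- detection_filter(cq3, min_frac = config$detection_min_frac)
  note("detection", "target assays retained by detection filter",
       length(det$retained))

  norm <- global_mean_normalize(cq3, assays = det$retained)
  note("normalize", "normalizer assays (detected in all samples)",
       length(norm$normalizer_assays))
  normfinder <- normfinder_stability(
    cq3$values[, norm$normalizer_assays, drop = FALSE],
    groups = patients$lipid_rich,
    global_mean = norm$global_mean
  )
  norm <- impute_lod(norm)
  note("impute", "cells imputed at assay minimum", sum(norm$imputed_mask))

  screen <- screen_mirs(norm, patients$lipid_rich, config)
  characteristics <- characteristics_table(patients, config)

  design_mir <- build_design(norm, patients, include_risk_factors = FALSE)
  stab_mir <- bootstrap_stability(design_mir, config)
  stab_full <- NULL
  if (include_risk_factors) {
    design_full <- build_design(norm, patients, include_risk_factors = TRUE)
    stab_full <- bootstrap_stability(design_full, config)
  }

  top_mir <- stab_mir$variable[1]
  roc_mir <- cv_roc(design_mir, variables = top_mir, config = config,
                    model = paste0("single-miR: ", top_mir),
                    seed_stream = "roc-mir")
  lipid_design <- lipid_panel_model(patients)
  roc_lipid <- cv_roc(lipid_design, config = config,
                      model = "traditional lipid panel",
                      seed_stream = "roc-lipid")
  spearman <- spearman_matrix(norm, assays = utils::head(stab_mir$variable, 10))

  structure(
    list(qc = qc, detection = det$detection_rate, retained = det$retained,
         normalizer_ranking = normfinder, norm = norm,
         screen = screen, characteristics = characteristics,
         stability_mirs = stab_mir, stability_full = stab_full,
         selected_mir = top_mir, roc_mir = roc_mir, roc_lipid = roc_lipid,
         spearman_top = spearman,
         config = config, log = dplyr::bind_rows(log)),
    class = "plq_report"
  )
}

#' @export
print.plq_report <- function(x, ...) {
  cat("<plq_report>\n")
  cat(sprintf("  retained assays: %d | screen smallest adjusted p: %.3f\n",
              length(x$retained), min(x$screen$p_adjusted)))
  cat(sprintf("  top miR: %s (%.1f%% bootstrap presence, OR %.2f)\n",
              x$selected_mir, x$stability_mirs$percent_presence[1],
              x$stability_mirs$odds_ratio[1]))
  cat(sprintf("  AUC %s: %.2f (%.2f-%.2f) | lipid panel: %.2f (%.2f-%.2f)\n",
              x$selected_mir, x$roc_mir$auc, x$roc_mir$ci[1], x$roc_mir$ci[2],
              x$roc_lipid$auc, x$roc_lipid$ci[1], x$roc_lipid$ci[2]))
  invisible(x)
}

#' Write the report bundle as delimited tables
#'
#' One TSV per result table (QC samples, detection rates, normalizer
#' ranking, screen, characteristics, stability rankings, ROC points and
#' summaries, run log) plus a small run manifest with the configuration.
#'
#' @param report A `plq_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name) {
    utils::write.table(as.data.frame(df), file.path(dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  w(report$qc$samples, "qc_samples.tsv")
  w(report$detection, "detection_rates.tsv")
  w(report$normalizer_ranking, "normalizer_ranking.tsv")
  w(report$screen, "screen.tsv")
  w(report$characteristics, "characteristics.tsv")
  w(report$stability_mirs, "stability_mirs.tsv")
  if (!is.null(report$stability_full)) {
    w(report$stability_full, "stability_mirs_riskfactors.tsv")
  }
  w(glance(report$roc_mir), "roc_summary_mir.tsv")
  w(glance(report$roc_lipid), "roc_summary_lipid.tsv")
  w(report$roc_mir$points, "roc_points_mir.tsv")
  w(report$roc_lipid$points, "roc_points_lipid.tsv")
  w(report$log, "run_log.tsv")
  cfg <- report$config
  w(tibble(key = names(unclass(cfg)),
           value = vapply(unclass(cfg), function(v) paste(format(v), collapse = ","),
                          character(1))),
    "run_manifest.tsv")
  invisible(dir)
}
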