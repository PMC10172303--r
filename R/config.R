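#' Analysis run configuration
#'
#' Collects every tunable of the pipeline in one validated object: the
#' elastic-net mixing parameter, the regularization path, the repeated
#' cross-validation scheme, the bootstrap size, the qPCR detection rules and
#' the lipid-rich plaque cut-point.
#'
#' @param seed Integer root seed. Every random stage (fold assignment,
#'   bootstrap resampling, simulation) derives its own child seed from this
#'   root via named streams, so a run is reproducible end to end.
#' @param alpha Elastic-net mixing parameter in `[0, 1]`; 1 is the lasso,
#'   0 is ridge. Default 0.9 (a model closer to lasso than ridge).
#' @param n_lambda Number of penalty values on the log-spaced path.
#' @param lambda_min_ratio Smallest penalty as a fraction of the data-derived
#'   maximum, suitable for the p > n regime.
#' @param cv_folds Number of stratified cross-validation folds.
#' @param cv_repeats Number of times the fold assignment is redrawn; the
#'   penalty minimizes the across-repeat average of the per-repeat mean
#'   held-out binomial deviance.
#' @param n_bootstrap Number of bootstrap resamples for stability selection.
#' @param bootstrap_cv_repeats Cross-validation repeats used *within each
#'   bootstrap resample*. Defaults to `cv_repeats` (the faithful mode, where
#'   the entire fitting procedure is repeated per resample); a smaller value
#'   gives a fast mode for desk-scale runs.
#' @param detection_min_frac Minimum fraction of samples in which an assay
#'   must be detected to enter the analysis (default 0.8).
#' @param ntc_margin_cq A target Cq must undercut the no-template control by
#'   at least this many cycles to count as detected (default 5).
#' @param lipid_rich_threshold maxLCBI4mm cut-point defining a lipid-rich
#'   plaque; the boundary value itself is classified lipid-rich (default
#'   324.7).
#' @param fdr_level Benjamini-Hochberg false discovery rate (default 0.05).
#' @param welch_t Use the Welch (unequal-variance) t statistic for the
#'   univariable comparisons routed to a t test. Default `TRUE`.
#' @param sw_alpha Per-group Shapiro-Wilk level below which a variable is
#'   routed to the Mann-Whitney U test.
#' @param hemolysis_warn,hemolysis_fail Warn/fail thresholds (Cq) for the
#'   hemolysis indicator Cq(miR-23a-3p) - Cq(miR-451a).
#' @param spike_in_max_dev Maximum tolerated deviation (Cq) of a sample's
#'   spike-in from the cohort median for that spike-in.
#'
#' @return A validated list of class `plq_config`.
#' @examples
#' cfg <- run_config(seed = 7, n_bootstrap = 50)
#' cfg$alpha
#' @export
run_config <- function(seed = 1L,
                       alpha = 0.9,
                       n_lambda = 100L,
                       lambda_min_ratio = 0.01,
                       cv_folds = 10L,
                       cv_repeats = 10L,
                       n_bootstrap = 1000L,
                       bootstrap_cv_repeats = cv_repeats,
                       detection_min_frac = 0.8,
                       ntc_margin_cq = 5,
                       lipid_rich_threshold = 324.7,
                       fdr_level = 0.05,
                       welch_t = TRUE,
                       sw_alpha = 0.05,
                       hemolysis_warn = 5,
                       hemolysis_fail = 7,
                       spike_in_max_dev = 2) {
  cfg <- list(
    seed = as.integer(seed), alpha = alpha, n_lambda = as.integer(n_lambda),
    lambda_min_ratio = lambda_min_ratio, cv_folds = as.integer(cv_folds),
    cv_repeats = as.integer(cv_repeats), n_bootstrap = as.integer(n_bootstrap),
    bootstrap_cv_repeats = as.integer(bootstrap_cv_repeats),
    detection_min_frac = detection_min_frac, ntc_margin_cq = ntc_margin_cq,
    lipid_rich_threshold = lipid_rich_threshold, fdr_level = fdr_level,
    welch_t = isTRUE(welch_t), sw_alpha = sw_alpha,
    hemolysis_warn = hemolysis_warn, hemolysis_fail = hemolysis_fail,
    spike_in_max_dev = spike_in_max_dev
  )
  stopifnot(
    length(cfg$seed) == 1L, is.finite(cfg$seed),
    cfg$alpha >= 0, cfg$alpha <= 1,
    cfg$n_lambda >= 1L, cfg$lambda_min_ratio > 0, cfg$lambda_min_ratio <= 1,
    cfg$cv_folds >= 2L, cfg$cv_repeats >= 1L, cfg$n_bootstrap >= 1L,
    cfg$bootstrap_cv_repeats >= 1L,
    cfg$detection_min_frac > 0, cfg$detection_min_frac <= 1,
    cfg$ntc_margin_cq > 0, cfg$lipid_rich_threshold > 0,
    cfg$fdr_level > 0, cfg$fdr_level < 1,
    cfg$sw_alpha > 0, cfg$sw_alpha < 1,
    cfg$hemolysis_fail >= cfg$hemolysis_warn, cfg$spike_in_max_dev > 0
  )
  structure(cfg, class = "plq_config")
}

#' @export
print.plq_config <- function(x, ...) {
  cat("<plq_config>\n")
  cat(sprintf("  seed %d | alpha %.2f | path %d lambdas (min ratio %.3g)\n",
              x$seed, x$alpha, x$n_lambda, x$lambda_min_ratio))
  cat(sprintf("  CV %d-fold x %d repeats | bootstrap B = %d (CV repeats per resample %d)\n",
              x$cv_folds, x$cv_repeats, x$n_bootstrap, x$bootstrap_cv_repeats))
  cat(sprintf("  detection >= %.0f%% | NTC margin %.1f Cq | lipid-rich >= %.1f | FDR %.2f\n",
              100 * x$detection_min_frac, x$ntc_margin_cq,
              x$lipid_rich_threshold, x$fdr_level))
  invisible(x)
}

# Deterministic child seed for a named random stream. Keeps every stage's
# randomness reproducible from one root seed; result is always in [1, 2^31-2].
derive_seed <- function(seed, stream) {
  h <- as.double(seed) %% 2147483647
  for (ch in utf8ToInt(as.character(stream))) {
    h <- (h * 31 + ch) %% 2147483629
  }
  as.integer(h + 1)
}

with_stream_seed <- function(seed, stream, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(derive_seed(seed, stream))
  force(code)
}
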