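#' Cross-validated out-of-fold scores for a small logistic model
#'
#' Stratified k-fold cross-validation repeated several times: in every
#' repeat each sample receives the predicted probability from an unpenalized
#' maximum-likelihood logistic fit on the training folds; the final score is
#' the per-sample mean over repeats. Training splits with separation (or any
#' glm failure) fall back to a lightly ridge-stabilized fit, which is
#' counted in the `fallbacks` attribute.
#'
#' @param design A [build_design()] result with one or a few columns.
#' @param config A [run_config()] (folds, repeats, seed).
#' @param seed_stream Name of the randomness stream.
#' @return Numeric vector of per-sample scores (named by sample id), with
#'   attribute `fallbacks`.
#' @export
cv_scores <- function(design, config = run_config(), seed_stream = "roc") {
  y <- design$y
  n <- length(y)
  scores <- matrix(NA_real_, n, config$cv_repeats)
  fallbacks <- 0L
  for (r in seq_len(config$cv_repeats)) {
    folds <- with_stream_seed(config$seed, paste0(seed_stream, ":", r),
                              stratified_folds(y, config$cv_folds))
    for (f in seq_len(max(folds))) {
      hold <- folds == f
      xtr <- design$x[!hold, , drop = FALSE]
      xho <- design$x[hold, , drop = FALSE]
      df_tr <- data.frame(y = y[!hold], xtr, check.names = FALSE)
      fit <- tryCatch({
        g <- suppressWarnings(glm(y ~ ., data = df_tr, family = binomial()))
        if (!g$converged || any(abs(coef(g)) > 50, na.rm = TRUE)) NULL else g
      }, error = function(e) NULL)
      if (is.null(fit)) {
        fallbacks <- fallbacks + 1L
        tr <- structure(list(x = xtr, y = y[!hold],
                             variables = design$variables,
                             sample_id = design$sample_id[!hold]),
                        class = "plq_design")
        rfit <- enet_logistic(tr, lambda = 1e-3, alpha = 0)
        scores[hold, r] <- predict(rfit, xho)
      } else {
        nd <- data.frame(xho, check.names = FALSE)
        scores[hold, r] <- predict(fit, newdata = nd, type = "response")
      }
    }
  }
  out <- rowMeans(scores)
  names(out) <- design$sample_id
  attr(out, "fallbacks") <- fallbacks
  out
}

#' ROC curve and AUC with a DeLong confidence interval
#'
#' Operating points come from a threshold sweep over the pooled scores; the
#' AUC is the tie-corrected rank statistic `U / (n1 * n0)` (ties count one
#' half), and the 95% confidence interval uses the DeLong nonparametric
#' variance of the placement values.
#'
#' @param scores Numeric score vector (higher = more case-like).
#' @param labels 0/1 or logical outcome vector.
#' @param model Optional model descriptor carried into the result.
#' @param conf_level Confidence level (default 0.95).
#' @return An object of class `plq_roc`: `points` (tibble `threshold`,
#'   `fpr`, `tpr`), `auc`, `ci` (length 2), `n_case`, `n_control`, `model`.
#' @export
roc_auc <- function(scores, labels, model = "model", conf_level = 0.95) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels)) abort("scores and labels differ in length")
  if (all(labels) || !any(labels)) abort("both classes required")
  cs <- scores[labels]
  ct <- scores[!labels]
  n1 <- length(cs); n0 <- length(ct)

  # placement values: psi(case, control) averaged each way (DeLong)
  psi_case <- vapply(cs, function(s) {
    (sum(s > ct) + 0.5 * sum(s == ct)) / n0
  }, numeric(1))
  psi_ctrl <- vapply(ct, function(s) {
    (sum(cs > s) + 0.5 * sum(cs == s)) / n1
  }, numeric(1))
  auc <- mean(psi_case)
  v <- if (n1 > 1 && n0 > 1) var(psi_case) / n1 + var(psi_ctrl) / n0 else NA_real_
  z <- qnorm(1 - (1 - conf_level) / 2)
  ci <- if (is.na(v)) c(NA_real_, NA_real_) else {
    pmin(pmax(auc + c(-1, 1) * z * sqrt(v), 0), 1)
  }

  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  points <- tibble(
    threshold = thr,
    tpr = vapply(thr, function(t) mean(cs >= t), numeric(1)),
    fpr = vapply(thr, function(t) mean(ct >= t), numeric(1))
  )
  structure(
    list(points = points, auc = auc, ci = ci, n_case = n1, n_control = n0,
         model = model, conf_level = conf_level),
    class = "plq_roc"
  )
}

#' @export
print.plq_roc <- function(x, ...) {
  cat(sprintf("<plq_roc> %s: AUC %.3f (%d%% CI %.3f-%.3f), %d cases / %d controls\n",
              x$model, x$auc, round(100 * x$conf_level), x$ci[1], x$ci[2],
              x$n_case, x$n_control))
  invisible(x)
}

#' @export
#' @param x A `plq_roc`.
#' @param ... Unused.
#' @rdname roc_auc
glance.plq_roc <- function(x, ...) {
  tibble(model = x$model, auc = x$auc, ci_low = x$ci[1], ci_high = x$ci[2],
         n_case = x$n_case, n_control = x$n_control)
}

#' @export
#' @rdname roc_auc
tidy.plq_roc <- function(x, ...) x$points

#' @export
#' @rdname roc_auc
#' @param object A `plq_roc`.
autoplot.plq_roc <- function(object, ...) {
  ggplot2::ggplot(object$points, ggplot2::aes(.data$fpr, .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  title = sprintf("%s: AUC %.2f (%.2f-%.2f)", object$model,
                                  object$auc, object$ci[1], object$ci[2]))
}

#' Traditional lipid-panel comparison model
#'
#' Builds the five-column design of the traditional lipid measurements:
#' LDL-C, HDL-C, triglycerides, LDL/HDL ratio and lipoprotein(a). Samples
#' with any missing lipid value are excluded listwise (logged via the
#' `n_excluded` attribute); non-positive HDL is an error.
#'
#' @param patients Patient tibble with `lipid_rich` and the lipid columns.
#' @return A `plq_design` with 5 predictor columns.
#' @export
lipid_panel_model <- function(patients) {
  cols <- c("ldl_c", "hdl_c", "triglycerides", "lipoprotein_a")
  if (!all(cols %in% names(patients))) {
    abort(paste0("missing lipid columns: ",
                 paste(setdiff(cols, names(patients)), collapse = ", ")))
  }
  ok <- complete.cases(patients[cols])
  pt <- patients[ok, ]
  if (any(pt$hdl_c <= 0)) abort("non-positive HDL-C: LDL/HDL ratio undefined")
  x <- cbind(as.matrix(pt[cols]), ldl_hdl_ratio = pt$ldl_c / pt$hdl_c)
  x <- x[, c("ldl_c", "hdl_c", "triglycerides", "ldl_hdl_ratio",
             "lipoprotein_a"), drop = FALSE]
  rownames(x) <- pt$sample_id
  out <- structure(list(x = x, y = as.integer(pt$lipid_rich),
                        variables = colnames(x), sample_id = pt$sample_id),
                   class = "plq_design")
  attr(out, "n_excluded") <- sum(!ok)
  out
}

#' Cross-validated ROC for a single-predictor logistic model
#'
#' Convenience wrapper chaining [cv_scores()] and [roc_auc()] for a design
#' restricted to the named variables.
#'
#' @param design A `plq_design`.
#' @param variables Variables to keep (default: all).
#' @param config A [run_config()].
#' @param model Descriptor for the result.
#' @param seed_stream Randomness stream name.
#' @return A `plq_roc`.
#' @export
cv_roc <- function(design, variables = design$variables,
                   config = run_config(), model = "model",
                   seed_stream = "roc") {
  sub <- structure(list(x = design$x[, variables, drop = FALSE],
                        y = design$y, variables = variables,
                        sample_id = design$sample_id),
                   class = "plq_design")
  sc <- cv_scores(sub, config, seed_stream = seed_stream)
  roc_auc(sc, design$y, model = model)
}
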