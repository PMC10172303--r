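#' Bootstrap stability selection for the elastic net
#'
#' Repeats the *entire* fitting procedure — path grid, repeated
#' cross-validation, fit at the selected penalty — on bootstrap resamples of
#' the cohort, and reports for every variable the percentage of resamples in
#' which its coefficient stayed nonzero, alongside the full-data odds ratio.
#' Resamples that draw a single outcome class are redrawn (bounded, logged).
#'
#' Ranking is by percent presence, ties broken by larger absolute full-data
#' coefficient, then variable name.
#'
#' @param design A [build_design()] result.
#' @param config A [run_config()]. `n_bootstrap` gives B;
#'   `bootstrap_cv_repeats` the CV repeats per resample (equal to
#'   `cv_repeats` by default — the faithful mode; smaller values give a fast
#'   desk-scale mode).
#' @param B Override for the number of bootstrap resamples.
#' @return A tibble of class `plq_stability` (`variable`, `selection_count`,
#'   `percent_presence`, `odds_ratio`, `rank`), with the full-data fit, the
#'   selected penalty, B and the redraw count in attributes.
#' @export
bootstrap_stability <- function(design, config = run_config(),
                                B = config$n_bootstrap) {
  full <- enet_cv_fit(design, config, seed_stream = "cv-full")
  n <- length(design$y)
  p <- ncol(design$x)
  counts <- integer(p)
  redraws <- 0L
  model_sizes <- integer(B)
  for (b in seq_len(B)) {
    fit_b <- NULL
    for (t in 0:25) {
      idx <- with_stream_seed(config$seed, paste0("boot:", b, ":", t),
                              sample.int(n, n, replace = TRUE))
      if (length(unique(design$y[idx])) < 2L ||
          min(table(design$y[idx])) < 2L) {
        redraws <- redraws + 1L
        next
      }
      bs <- structure(list(x = design$x[idx, , drop = FALSE],
                           y = design$y[idx],
                           variables = design$variables,
                           sample_id = design$sample_id[idx]),
                      class = "plq_design")
      fit_b <- tryCatch(
        enet_cv_fit(bs, config, cv_repeats = config$bootstrap_cv_repeats,
                    seed_stream = paste0("boot-cv:", b, ":", t))$fit,
        error = function(e) NULL
      )
      if (!is.null(fit_b)) break
      redraws <- redraws + 1L   # e.g. a constant predictor in the resample
    }
    if (is.null(fit_b)) abort("bootstrap resampling degenerate after 25 redraws")
    nz <- fit_b$coefficients != 0
    counts <- counts + nz
    model_sizes[b] <- sum(nz)
  }
  out <- tibble(
    variable = design$variables,
    selection_count = counts,
    percent_presence = 100 * counts / B,
    odds_ratio = unname(full$fit$odds_ratio)
  ) |>
    dplyr::arrange(dplyr::desc(.data$percent_presence),
                   dplyr::desc(abs(log(.data$odds_ratio))),
                   .data$variable) |>
    dplyr::mutate(rank = dplyr::row_number())
  class(out) <- c("plq_stability", class(out))
  attr(out, "B") <- B
  attr(out, "lambda_star") <- full$cv$lambda_star
  attr(out, "full_fit") <- full$fit
  attr(out, "cv") <- full$cv
  attr(out, "redraws") <- redraws
  attr(out, "model_sizes") <- model_sizes
  attr(out, "config") <- config
  out
}

#' Full-data odds ratios at the cross-validated penalty
#'
#' Fits the elastic net on the complete data at the penalty selected by
#' [repeated_cv()] and returns per-variable odds ratios on the original
#' predictor scale (`exp(0) = 1` exactly for unselected variables).
#'
#' @inheritParams bootstrap_stability
#' @return Tibble `variable`, `estimate` (log-odds), `odds_ratio`.
#' @export
full_data_or <- function(design, config = run_config()) {
  fit <- enet_cv_fit(design, config, seed_stream = "cv-full")$fit
  tibble(variable = fit$variables,
         estimate = unname(fit$coefficients),
         odds_ratio = unname(fit$odds_ratio))
}

#' Top of the stability ranking
#'
#' The top `k` variables by bootstrap percent presence, in the layout of a
#' published ranking table: variable, estimated odds ratio (1 for variables
#' not selected in the full-data fit), percent presence.
#'
#' @param report A `plq_stability`.
#' @param k Number of rows (default 10).
#' @return Tibble with `k` rows.
#' @export
top_table <- function(report, k = 10L) {
  stopifnot(k >= 1L, k <= nrow(report))
  out <- report |>
    dplyr::slice_head(n = k) |>
    dplyr::select("variable", "odds_ratio", "percent_presence")
  class(out) <- setdiff(class(out), "plq_stability")
  out
}

#' @export
print.plq_stability <- function(x, ...) {
  cat(sprintf("<plq_stability> B = %d resamples, %d variables, lambda* = %.4g\n",
              attr(x, "B"), nrow(x), attr(x, "lambda_star")))
  print(top_table(x, min(10L, nrow(x))))
  invisible(x)
}

#' @export
#' @param x A `plq_stability`.
#' @param ... Unused.
#' @rdname bootstrap_stability
glance.plq_stability <- function(x, ...) {
  tibble(B = attr(x, "B"), lambda_star = attr(x, "lambda_star"),
         n_variables = nrow(x),
         n_selected_full = sum(x$odds_ratio != 1),
         mean_model_size = mean(attr(x, "model_sizes")),
         redraws = attr(x, "redraws"))
}

#' @export
#' @rdname bootstrap_stability
#' @param object A `plq_stability`.
#' @param top_n Number of variables shown.
autoplot.plq_stability <- function(object, top_n = 10L, ...) {
  df <- top_table(object, min(top_n, nrow(object)))
  df$variable <- factor(df$variable, levels = rev(df$variable))
  ggplot2::ggplot(df, ggplot2::aes(.data$percent_presence, .data$variable)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = sprintf("presence in %d bootstrap resamples (%%)",
                              attr(object, "B")),
                  y = NULL, title = "Bootstrap selection stability")
}
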