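# Stratified fold assignment: within each class, a random permutation is
# dealt round-robin, so fold class counts differ by at most one. If the
# rarer class has fewer members than folds, the fold count is reduced
# (recorded by the caller via max(folds)).
stratified_folds <- function(y, k) {
  n_min <- min(table(y))
  if (n_min < k) k <- n_min
  folds <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

#' Penalty selection by repeated stratified cross-validation
#'
#' For each repeat the cohort is split into stratified folds; for every
#' penalty on the path the held-out binomial deviance (`-2 x` mean held-out
#' log-likelihood) is averaged over folds, giving one deviance curve per
#' repeat. The selected penalty minimizes the across-repeat average curve
#' (ties resolve to the more penalized end). The path grid is computed once
#' from the full design so curves are comparable across folds and repeats.
#'
#' @param design A [build_design()] result.
#' @param config A [run_config()]; `alpha`, the grid and the CV scheme are
#'   taken from it.
#' @param cv_repeats Override for the number of repeats (the bootstrap fast
#'   mode passes a reduced value).
#' @param lambdas Optional pre-computed grid.
#' @param seed_stream Name distinguishing independent CV randomness streams.
#' @param tol Coordinate-update tolerance for the fold fits.
#' @return An object of class `plq_cv`: `lambda` (grid), `deviance`
#'   (grid x repeats matrix), `mean_deviance`, `lambda_star`, `index_star`.
#' @export
repeated_cv <- function(design, config = run_config(),
                        cv_repeats = config$cv_repeats,
                        lambdas = NULL, seed_stream = "cv",
                        tol = 1e-8) {
  if (is.null(lambdas)) {
    lambdas <- lambda_grid(design, alpha = config$alpha,
                           n_lambda = config$n_lambda,
                           min_ratio = config$lambda_min_ratio)
  }
  y <- design$y
  if (sum(y) < 2 || sum(1 - y) < 2) abort("need at least 2 samples per class")
  dev <- matrix(NA_real_, length(lambdas), cv_repeats)
  folds_used <- integer(cv_repeats)
  for (r in seq_len(cv_repeats)) {
    folds <- with_stream_seed(config$seed, paste0(seed_stream, ":", r),
                              stratified_folds(y, config$cv_folds))
    k <- max(folds)
    folds_used[r] <- k
    fold_dev <- matrix(NA_real_, length(lambdas), k)
    for (f in seq_len(k)) {
      hold <- folds == f
      tr <- structure(list(x = design$x[!hold, , drop = FALSE],
                           y = y[!hold],
                           variables = design$variables,
                           sample_id = design$sample_id[!hold]),
                      class = "plq_design")
      path <- enet_path_fit(tr, config$alpha, lambdas, tol = tol)
      xh <- design$x[hold, , drop = FALSE]
      eta <- matrix(path$intercept, nrow = sum(hold), ncol = length(lambdas),
                    byrow = TRUE) + xh %*% path$beta
      prob <- plogis(eta)
      fold_dev[, f] <- vapply(seq_along(lambdas), function(l) {
        binomial_deviance(y[hold], prob[, l])
      }, numeric(1))
    }
    dev[, r] <- rowMeans(fold_dev)
  }
  mean_dev <- rowMeans(dev)
  idx <- which.min(mean_dev)
  structure(
    list(lambda = lambdas, deviance = dev, mean_deviance = mean_dev,
         lambda_star = lambdas[idx], index_star = idx,
         cv_repeats = cv_repeats, cv_folds = config$cv_folds,
         folds_used = folds_used),
    class = "plq_cv"
  )
}

#' @export
print.plq_cv <- function(x, ...) {
  cat(sprintf("<plq_cv> %d-fold x %d repeats over %d penalties\n",
              x$cv_folds, x$cv_repeats, length(x$lambda)))
  cat(sprintf("  lambda* = %.4g (index %d), mean deviance %.4f\n",
              x$lambda_star, x$index_star, x$mean_deviance[x$index_star]))
  invisible(x)
}

#' @export
#' @param x A `plq_cv`.
#' @param ... Unused.
#' @rdname repeated_cv
tidy.plq_cv <- function(x, ...) {
  tibble(
    lambda = rep(x$lambda, times = ncol(x$deviance)),
    cv_repeat = rep(seq_len(ncol(x$deviance)), each = length(x$lambda)),
    deviance = as.vector(x$deviance)
  )
}

#' @export
#' @rdname repeated_cv
glance.plq_cv <- function(x, ...) {
  tibble(lambda_star = x$lambda_star, index_star = x$index_star,
         min_mean_deviance = x$mean_deviance[x$index_star],
         cv_folds = x$cv_folds, cv_repeats = x$cv_repeats)
}

#' @export
#' @rdname repeated_cv
#' @param object A `plq_cv`.
autoplot.plq_cv <- function(object, ...) {
  df <- tidy(object)
  avg <- tibble(lambda = object$lambda, deviance = object$mean_deviance)
  ggplot2::ggplot(df, ggplot2::aes(log(.data$lambda), .data$deviance,
                                   group = .data$cv_repeat)) +
    ggplot2::geom_line(alpha = 0.3) +
    ggplot2::geom_line(data = avg, ggplot2::aes(group = NULL),
                       linewidth = 1) +
    ggplot2::geom_vline(xintercept = log(object$lambda_star),
                        linetype = "dashed") +
    ggplot2::labs(x = "log(lambda)", y = "mean held-out binomial deviance",
                  title = "Repeated cross-validation deviance")
}

#' Fit the full model at the cross-validated penalty
#'
#' Convenience wrapper: computes the path grid, runs [repeated_cv()], and
#' refits on the complete data at the selected penalty.
#'
#' @inheritParams repeated_cv
#' @return A list with elements `cv` (`plq_cv`) and `fit` (`plq_enet`).
#' @export
enet_cv_fit <- function(design, config = run_config(),
                        cv_repeats = config$cv_repeats,
                        seed_stream = "cv") {
  lambdas <- lambda_grid(design, alpha = config$alpha,
                         n_lambda = config$n_lambda,
                         min_ratio = config$lambda_min_ratio)
  cv <- repeated_cv(design, config, cv_repeats = cv_repeats,
                    lambdas = lambdas, seed_stream = seed_stream)
  path <- enet_path_fit(design, config$alpha,
                        lambdas[seq_len(cv$index_star)])
  list(cv = cv, fit = new_enet(path, cv$index_star, design, config$alpha))
}
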