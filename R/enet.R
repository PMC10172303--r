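#' Build a design matrix for the multivariable models
#'
#' Assembles the predictor matrix and 0/1 outcome from the normalized miRNA
#' matrix and the patient table. The miRs-only set uses the retained assays;
#' the extended set appends the 14 cardiovascular risk factors, including
#' the derived LDL/HDL ratio (an error if HDL is not positive). Binary
#' factors are 0/1 coded. Rows with missing predictors are an error: QC
#' exclusions are logged upstream, never silently imputed here.
#'
#' @param norm A `plq_norm` after [impute_lod()], restricted to retained
#'   assays.
#' @param patients Patient tibble with `lipid_rich` (and covariates when
#'   `include_risk_factors = TRUE`), rows matching `norm` samples by
#'   `sample_id`.
#' @param include_risk_factors Append the CVD risk factors?
#' @return A list of class `plq_design`: `x` (samples x variables), `y`
#'   (0/1), `variables`, `sample_id`.
#' @export
build_design <- function(norm, patients, include_risk_factors = FALSE) {
  vals <- if (inherits(norm, "plq_norm")) norm$values else as.matrix(norm)
  ids <- rownames(vals)
  if (!all(ids %in% patients$sample_id)) {
    abort("samples in the normalized matrix are missing from the patient table")
  }
  pt <- patients[match(ids, patients$sample_id), ]
  x <- vals
  if (include_risk_factors) {
    rf <- setdiff(cvd_risk_factors(), "ldl_hdl_ratio")
    missing_cols <- setdiff(rf, names(pt))
    if (length(missing_cols)) {
      abort(paste0("missing covariate columns: ",
                   paste(missing_cols, collapse = ", ")))
    }
    if (any(is.na(pt[rf]))) abort("missing covariate values; exclude or complete upstream")
    if (any(pt$hdl_c <= 0)) abort("non-positive HDL-C: LDL/HDL ratio undefined")
    rfm <- as.matrix(pt[rf])
    rfm <- cbind(rfm, ldl_hdl_ratio = pt$ldl_c / pt$hdl_c)
    rfm <- rfm[, cvd_risk_factors(), drop = FALSE]
    x <- cbind(x, rfm)
  }
  if (anyNA(x)) abort("design matrix contains missing values")
  y <- as.integer(pt$lipid_rich)
  if (length(unique(y)) < 2L) abort("outcome must have both classes")
  if (anyDuplicated(colnames(x))) abort("duplicate variable names")
  structure(list(x = x, y = y, variables = colnames(x), sample_id = ids),
            class = "plq_design")
}

#' @export
print.plq_design <- function(x, ...) {
  cat(sprintf("<plq_design> %d samples x %d variables; outcome %d / %d positive\n",
              nrow(x$x), ncol(x$x), sum(x$y), length(x$y)))
  invisible(x)
}

# Per-variable mean and population (1/n) standard deviation. Constant
# columns (possible in CV training splits or bootstrap resamples of
# near-degenerate binary covariates) are intercept aliases: they are carried
# with unit scale and coefficient pinned to zero by the caller.
standardize_info <- function(x) {
  m <- colMeans(x)
  s <- sqrt(pmax(colMeans(x^2) - m^2, 0))
  constant <- s <= 0 | !is.finite(s)
  s[constant] <- 1
  list(center = m, scale = s, constant = constant)
}

#' Regularization path grid
#'
#' Log-spaced descending grid of `n_lambda` penalties from the data-derived
#' maximum `lambda_max = max_j |(1/n) sum_i x_ij (y_i - ybar)| / alpha`
#' (standardized predictors) down to `lambda_max * min_ratio`. At
#' `lambda_max` the fitted coefficient vector is exactly zero.
#'
#' @param design A [build_design()] result.
#' @param alpha Elastic-net mixing parameter; for `alpha = 0` (pure ridge)
#'   the L1 ceiling is undefined and a small floor of 0.001 is substituted.
#' @param n_lambda Grid length.
#' @param min_ratio Smallest penalty as a fraction of `lambda_max`.
#' @return Numeric vector, strictly descending.
#' @export
lambda_grid <- function(design, alpha = 0.9, n_lambda = 100L,
                        min_ratio = 0.01) {
  std <- standardize_info(design$x)
  xs <- scale(design$x, center = std$center, scale = std$scale)
  y <- design$y
  n <- length(y)
  g <- abs(crossprod(xs, y - mean(y))) / n
  a <- if (alpha > 0) alpha else 0.001
  # tiny relative guard so the path head stays above the data-derived
  # ceiling after the exp/log round trip and the alpha product: the fitted
  # coefficient vector at the first grid point is then exactly zero
  lambda_max <- max(g) / a * (1 + 1e-10)
  lam <- exp(seq(log(lambda_max), log(lambda_max * min_ratio),
                 length.out = n_lambda))
  lam[1] <- lambda_max
  lam
}

# Fit the whole path; returns original-scale coefficients plus the
# standardized-scale solution used internally.
enet_path_fit <- function(design, alpha, lambdas, tol = 1e-9,
                          max_sweeps = 1e5L, warm = NULL) {
  std <- standardize_info(design$x)
  xs <- scale(design$x, center = std$center, scale = std$scale)
  use_init <- !is.null(warm)
  init_beta <- if (use_init) warm$beta_std else numeric(ncol(xs))
  init_b0 <- if (use_init) warm$intercept_std else 0
  fit <- cpp_enet_path(xs, as.numeric(design$y), alpha,
                       as.numeric(lambdas), tol, as.integer(max_sweeps),
                       as.numeric(init_beta), init_b0, use_init)
  beta_std <- fit$beta
  rownames(beta_std) <- colnames(design$x)
  beta <- beta_std / std$scale
  b0 <- fit$b0 - colSums(beta_std * (std$center / std$scale))
  list(lambdas = lambdas, intercept = b0, beta = beta,
       intercept_std = fit$b0, beta_std = beta_std,
       sweeps = fit$sweeps, converged = fit$converged, std = std)
}

#' Elastic-net penalized logistic regression at a single penalty
#'
#' Minimizes the penalized average negative log-likelihood
#' `(1/n) sum_i [log(1 + exp(eta_i)) - y_i eta_i] +
#'  lambda (alpha ||beta||_1 + (1 - alpha)/2 ||beta||_2^2)` with
#' `eta = beta_0 + X beta` on standardized predictors and an unpenalized
#' intercept, by an outer quadratic approximation and inner cyclic
#' coordinate descent with soft-thresholding. Coefficients are reported on
#' the original predictor scale, so `exp(beta_j)` is the odds ratio per unit
#' increase of the variable.
#'
#' @param design A [build_design()] result.
#' @param lambda Penalty (>= 0).
#' @param alpha Mixing parameter in `[0, 1]`.
#' @param warm Optional previous `plq_enet` fit used as a warm start.
#' @param tol Coordinate-update convergence tolerance (standardized scale).
#' @param max_sweeps Sweep budget before a non-convergence error.
#' @return An object of class `plq_enet` with `intercept`, `coefficients`
#'   (original scale), `odds_ratio`, `lambda`, `alpha`, standardized-scale
#'   solution and convergence diagnostics.
#' @export
enet_logistic <- function(design, lambda, alpha = 0.9, warm = NULL,
                          tol = 1e-9, max_sweeps = 1e5L) {
  stopifnot(lambda >= 0, alpha >= 0, alpha <= 1)
  fit <- enet_path_fit(design, alpha, lambda, tol = tol,
                       max_sweeps = max_sweeps, warm = warm)
  if (!fit$converged[1]) {
    abort(sprintf("elastic-net fit did not converge in %d sweeps (lambda=%g)",
                  max_sweeps, lambda))
  }
  new_enet(fit, 1L, design, alpha)
}

new_enet <- function(path, l, design, alpha) {
  beta <- path$beta[, l]
  structure(
    list(intercept = unname(path$intercept[l]),
         coefficients = beta,
         odds_ratio = exp(beta),
         lambda = path$lambdas[l],
         alpha = alpha,
         intercept_std = unname(path$intercept_std[l]),
         beta_std = path$beta_std[, l],
         standardization = path$std,
         sweeps = path$sweeps[l],
         converged = path$converged[l],
         variables = design$variables),
    class = "plq_enet"
  )
}

#' @export
print.plq_enet <- function(x, ...) {
  nz <- sum(x$coefficients != 0)
  cat(sprintf("<plq_enet> lambda = %.4g, alpha = %.2f: %d of %d nonzero coefficients\n",
              x$lambda, x$alpha, nz, length(x$coefficients)))
  invisible(x)
}

#' @export
#' @param object,x A `plq_enet` fit.
#' @param ... Unused.
#' @rdname enet_logistic
tidy.plq_enet <- function(x, ...) {
  tibble(term = x$variables,
         estimate = unname(x$coefficients),
         odds_ratio = unname(x$odds_ratio)) |>
    dplyr::arrange(dplyr::desc(abs(.data$estimate)))
}

#' @export
#' @rdname enet_logistic
glance.plq_enet <- function(x, ...) {
  tibble(lambda = x$lambda, alpha = x$alpha,
         df = sum(x$coefficients != 0),
         sweeps = x$sweeps, converged = x$converged)
}

#' @export
#' @param newdata Numeric matrix with the fit's variables as columns.
#' @param type `"link"` or `"response"`.
#' @rdname enet_logistic
predict.plq_enet <- function(object, newdata, type = c("response", "link"),
                             ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)[, object$variables, drop = FALSE]
  eta <- object$intercept + drop(newdata %*% object$coefficients)
  if (type == "link") eta else plogis(eta)
}

# Penalized objective on the standardized scale (used by oracles and tests).
enet_objective <- function(design, intercept_std, beta_std, lambda, alpha) {
  std <- standardize_info(design$x)
  xs <- scale(design$x, center = std$center, scale = std$scale)
  eta <- intercept_std + drop(xs %*% beta_std)
  nll <- mean(log1p(exp(-abs(eta))) + pmax(eta, 0) - design$y * eta)
  nll + lambda * (alpha * sum(abs(beta_std)) +
                    (1 - alpha) / 2 * sum(beta_std^2))
}

#' Karush-Kuhn-Tucker certificate of an elastic-net fit
#'
#' Verifies the stationarity conditions on the standardized scale: for
#' nonzero coefficients the penalized gradient must vanish; for zero
#' coefficients the unpenalized gradient must not exceed the L1 threshold.
#'
#' @param fit A `plq_enet`.
#' @param design The design the fit came from.
#' @param tol Certificate tolerance (default 1e-6).
#' @return Logical; attributes carry the worst violations.
#' @export
enet_kkt <- function(fit, design, tol = 1e-6) {
  std <- fit$standardization
  xs <- scale(design$x, center = std$center, scale = std$scale)
  eta <- fit$intercept_std + drop(xs %*% fit$beta_std)
  p <- plogis(eta)
  g <- drop(crossprod(xs, design$y - p)) / length(design$y)
  b <- fit$beta_std
  lam <- fit$lambda; a <- fit$alpha
  active <- b != 0
  v_active <- if (any(active)) {
    max(abs(g[active] - lam * (a * sign(b[active]) + (1 - a) * b[active])))
  } else 0
  v_zero <- if (any(!active)) max(abs(g[!active]) - lam * a, 0) else 0
  v_int <- abs(mean(design$y - p))
  ok <- v_active <= tol && v_zero <= tol && v_int <= tol
  structure(ok, active = v_active, zero = v_zero, intercept = v_int)
}

# Held-out binomial deviance: -2 x mean log-likelihood.
binomial_deviance <- function(y, prob, eps = 1e-12) {
  prob <- pmin(pmax(prob, eps), 1 - eps)
  -2 * mean(y * log(prob) + (1 - y) * log(1 - prob))
}
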