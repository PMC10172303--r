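test_that("at and above lambda_max the fit is exactly the null model", {
  d <- make_design(40, 5, beta = c(1, rep(0, 4)), seed = 2)
  lg <- lambda_grid(d, alpha = 0.9, n_lambda = 100, min_ratio = 0.01)
  expect_length(lg, 100)
  expect_true(all(diff(lg) < 0))
  fit <- enet_logistic(d, lambda = lg[1], alpha = 0.9)
  expect_identical(unname(fit$coefficients), rep(0, 5))
  expect_equal(fit$intercept, qlogis(mean(d$y)), tolerance = 1e-12)
  expect_true(all(fit$odds_ratio == 1))
  fit2 <- enet_logistic(d, lambda = 2 * lg[1], alpha = 0.9)
  expect_identical(unname(fit2$coefficients), rep(0, 5))
})

test_that("duplicating the strongest predictor leaves lambda_max unchanged", {
  d <- make_design(60, 4, beta = c(2, 0, 0, 0), seed = 3)
  lg1 <- lambda_grid(d, alpha = 0.9)
  strongest <- which.max(abs(crossprod(scale(d$x), d$y - mean(d$y))))
  x2 <- cbind(d$x, dup = d$x[, strongest])
  d2 <- structure(list(x = x2, y = d$y, variables = colnames(x2),
                       sample_id = d$sample_id), class = "plq_design")
  lg2 <- lambda_grid(d2, alpha = 0.9)
  expect_equal(lg2[1], lg1[1], tolerance = 1e-12)
})

test_that("unpenalized fit matches an independent Newton (glm) solver", {
  d <- make_design(40, 3, beta = c(1, -0.5, 0), seed = 4)
  fit <- enet_logistic(d, lambda = 0, alpha = 0.9)
  ref <- glm(d$y ~ d$x, family = binomial())
  expect_equal(c(fit$intercept, unname(fit$coefficients)),
               unname(coef(ref)), tolerance = 1e-6)
})

test_that("penalized objective is at least as low as a generic minimizer's", {
  d <- make_design(40, 5, beta = c(1.2, -0.8, 0, 0, 0), seed = 5)
  lambda <- 0.05; alpha <- 0.9
  fit <- enet_logistic(d, lambda = lambda, alpha = alpha)
  obj <- plaqmir:::enet_objective
  ours <- obj(d, fit$intercept_std, fit$beta_std, lambda, alpha)
  nm <- optim(rep(0, 6), function(par) {
    obj(d, par[1], par[-1], lambda, alpha)
  }, method = "Nelder-Mead",
  control = list(maxit = 50000, reltol = 1e-14))
  expect_lte(ours, nm$value + 1e-8)
})

test_that("KKT certificates hold at every fit along random paths", {
  for (s in 1:3) {
    d <- make_design(50, 12, beta = c(1, -1, rep(0, 10)), seed = 10 + s)
    lg <- lambda_grid(d, alpha = 0.9, n_lambda = 20, min_ratio = 0.02)
    for (l in lg[c(1, 5, 10, 15, 20)]) {
      fit <- enet_logistic(d, lambda = l, alpha = 0.9)
      expect_true(enet_kkt(fit, d, tol = 1e-6))
    }
  }
})

test_that("coefficients agree with glmnet across alpha values", {
  skip_if_not_installed("glmnet")
  d <- make_design(80, 10, beta = c(1.5, -1, 0.5, rep(0, 7)), seed = 6)
  for (a in c(1, 0.9, 0.5)) {
    for (l in c(0.02, 0.08)) {
      fit <- enet_logistic(d, lambda = l, alpha = a)
      g <- glmnet::glmnet(d$x, d$y, family = "binomial", alpha = a,
                          lambda = l, standardize = TRUE, thresh = 1e-14,
                          maxit = 1e6)
      expect_equal(unname(fit$coefficients), as.numeric(g$beta),
                   tolerance = 1e-5)
      expect_equal(fit$intercept, as.numeric(g$a0), tolerance = 1e-5)
    }
  }
})

test_that("ridge at a tiny penalty approaches the maximum-likelihood fit", {
  d <- make_design(100, 3, beta = c(0.8, -0.4, 0), seed = 7)
  fit <- enet_logistic(d, lambda = 1e-6, alpha = 0)
  ref <- glm(d$y ~ d$x, family = binomial())
  expect_equal(c(fit$intercept, unname(fit$coefficients)),
               unname(coef(ref)), tolerance = 1e-3)
})

test_that("predictions are identical from standardized and original parameterizations", {
  d <- make_design(40, 4, beta = c(1, 0, -1, 0), seed = 8)
  fit <- enet_logistic(d, lambda = 0.03, alpha = 0.9)
  std <- fit$standardization
  xs <- scale(d$x, center = std$center, scale = std$scale)
  p_std <- plogis(fit$intercept_std + drop(xs %*% fit$beta_std))
  p_orig <- predict(fit, d$x)
  expect_equal(unname(p_orig), unname(p_std), tolerance = 1e-12)
})

test_that("odds ratios are affine-invariant in the predictors", {
  d <- make_design(60, 4, beta = c(1.5, 0, 0, 0), seed = 9)
  fit <- enet_logistic(d, lambda = 0.02, alpha = 0.9)
  d2 <- d; d2$x[, 1] <- d2$x[, 1] + 10
  fit2 <- enet_logistic(d2, lambda = 0.02, alpha = 0.9)
  expect_equal(fit2$odds_ratio, fit$odds_ratio, tolerance = 1e-6)
})

test_that("design matrix assembly matches the predictor-set contracts", {
  coh <- simulate_cohort(sim_config(seed = 25))
  cq <- apply_ntc_rule(coh$cq)
  det <- detection_filter(cq)
  norm <- impute_lod(global_mean_normalize(cq, assays = det$retained))
  d_mir <- build_design(norm, coh$patients, include_risk_factors = FALSE)
  expect_identical(ncol(d_mir$x), length(det$retained))
  d_full <- build_design(norm, coh$patients, include_risk_factors = TRUE)
  expect_identical(ncol(d_full$x), length(det$retained) + 14L)
  expect_true(all(cvd_risk_factors() %in% colnames(d_full$x)))
  # derived ratio column
  expect_equal(unname(d_full$x[, "ldl_hdl_ratio"]),
               coh$patients$ldl_c / coh$patients$hdl_c)
  # guard: non-positive HDL
  bad <- coh$patients; bad$hdl_c[1] <- 0
  expect_error(build_design(norm, bad, include_risk_factors = TRUE), "HDL")
})

test_that("tidy and glance expose the fit in broom style", {
  d <- make_design(40, 4, beta = c(1, 0, 0, 0), seed = 12)
  fit <- enet_logistic(d, lambda = 0.05, alpha = 0.9)
  td <- tidy(fit)
  expect_identical(names(td), c("term", "estimate", "odds_ratio"))
  expect_setequal(td$term, d$variables)
  expect_equal(td$odds_ratio, exp(td$estimate))
  gl <- glance(fit)
  expect_identical(gl$df, sum(fit$coefficients != 0))
  expect_true(gl$converged)
})
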