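# Shared fixtures and independent oracles used across test files.

# Small logistic design with named columns; beta on the latent scale.
make_design <- function(n, p, beta = rep(0, p), intercept = 0, seed = 1) {
  withr::with_seed(seed, {
    x <- matrix(rnorm(n * p), n, p,
                dimnames = list(sprintf("s%03d", seq_len(n)),
                                sprintf("v%02d", seq_len(p))))
    y <- rbinom(n, 1, plogis(intercept + drop(x %*% beta)))
    # ensure both classes
    if (sum(y) < 2) y[sample.int(n, 2)] <- 1L
    if (sum(1 - y) < 2) y[sample.int(n, 2)] <- 0L
    structure(list(x = x, y = y, variables = colnames(x),
                   sample_id = rownames(x)),
              class = "plq_design")
  })
}

# Hand-built 3-sample x 4-assay Cq table with one spike-in and an NTC record.
tiny_cq <- function() {
  m <- matrix(c(28, 29, 27,
                30, 31, 29,
                32, 33, 31,
                20, 20.1, 19.9),
              nrow = 3,
              dimnames = list(c("A", "B", "C"),
                              c("miR-1", "miR-2", "miR-3", "UniSp6")))
  cq_table(m,
           roles = c("miR-1" = "target", "miR-2" = "target",
                     "miR-3" = "target", "UniSp6" = "spike_in"),
           max_cycles = 45,
           ntc = c("miR-1" = 45, "miR-2" = 45, "miR-3" = 45, "UniSp6" = 45))
}

# Brute-force Benjamini-Hochberg step-up from the definition.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    adj[i] <- min(1, min(m * ps[i:m] / (i:m)))
  }
  out <- numeric(m)
  out[o] <- adj
  out
}

# Exhaustive two-sided Mann-Whitney p by explicit pairwise counting over all
# group assignments (independent of the rank-based implementation).
mwu_oracle <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  nn <- length(pooled)
  u_of <- function(xs, ys) {
    sum(vapply(xs, function(a) sum(a > ys) + 0.5 * sum(a == ys), numeric(1)))
  }
  u_obs <- u_of(x, y)
  mu <- n1 * (nn - n1) / 2
  splits <- utils::combn(nn, n1)
  u_all <- apply(splits, 2, function(ii) u_of(pooled[ii], pooled[-ii]))
  p <- mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-12)
  list(u = u_obs, p = p)
}

# Scalar re-implementation of the grouped stability-value formulas
# (sample-centering, corrected intragroup variances, shrunken intergroup
# difference), written loop-wise and independently of the package code.
normfinder_oracle <- function(x, groups) {
  k <- ncol(x)
  g <- as.factor(groups)
  lev <- levels(g)
  r <- x
  for (i in seq_len(nrow(x))) r[i, ] <- x[i, ] - mean(x[i, ])
  v <- matrix(0, 2, k); m <- matrix(0, 2, k); ng <- numeric(2)
  for (gi in 1:2) {
    rows <- which(g == lev[gi])
    ng[gi] <- length(rows)
    for (j in seq_len(k)) {
      vals <- r[rows, j]
      v[gi, j] <- var(vals)
      m[gi, j] <- mean(vals)
    }
  }
  s2 <- matrix(0, 2, k)
  for (gi in 1:2) {
    tot <- sum(v[gi, ])
    for (j in seq_len(k)) {
      s2[gi, j] <- max(0, (v[gi, j] - tot / (k * (k - 1))) / (1 - 2 / k))
    }
  }
  d <- m[1, ] - m[2, ]
  se2 <- s2[1, ] / ng[1] + s2[2, ] / ng[2]
  gamma2 <- max(0, var(d) - mean(se2))
  ds <- if (gamma2 > 0) d * gamma2 / (gamma2 + se2) else rep(0, k)
  abs(ds) + sqrt(se2)
}

# Normalized matrix + design straight from a simulated cohort.
cohort_design <- function(cohort, include_risk_factors = FALSE,
                          config = run_config()) {
  cq <- apply_ntc_rule(cohort$cq, margin = config$ntc_margin_cq)
  det <- detection_filter(cq, min_frac = config$detection_min_frac)
  norm <- impute_lod(global_mean_normalize(cq, assays = det$retained))
  build_design(norm, cohort$patients,
               include_risk_factors = include_risk_factors)
}
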