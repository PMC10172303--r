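test_that("NTC margin rule censors with an inclusive boundary", {
  m <- matrix(c(30, 35, 36), 3, 1, dimnames = list(c("A", "B", "C"), "miR-1"))
  cq <- cq_table(m, roles = c("miR-1" = "target"), max_cycles = 45,
                 ntc = c("miR-1" = 40))
  out <- apply_ntc_rule(cq, margin = 5)
  expect_identical(is.na(out$values[, "miR-1"]),
                   c(A = FALSE, B = FALSE, C = TRUE))
  expect_identical(attr(out, "n_censored"), 1L)

  # assay with no NTC amplification keeps all detected cells
  cq2 <- cq_table(m, roles = c("miR-1" = "target"), max_cycles = 45,
                  ntc = c("miR-1" = NA_real_))
  expect_identical(sum(is.na(apply_ntc_rule(cq2, 5)$values)), 0L)
  # absent NTC record is a warning, not an error
  cq3 <- cq_table(m, roles = c("miR-1" = "target"), max_cycles = 45)
  expect_warning(apply_ntc_rule(cq3, 5), "no NTC")
})

test_that("hemolysis indicator applies the warn/fail thresholds", {
  m <- matrix(c(25, 30, 28, 25, 22, 22.5), 3, 2,
              dimnames = list(c("A", "B", "C"),
                              c("hsa-miR-23a-3p", "hsa-miR-451a")))
  cq <- cq_table(m, roles = c("hsa-miR-23a-3p" = "target",
                              "hsa-miR-451a" = "target"))
  h <- hemolysis_score(cq)
  expect_equal(h$score, c(0, 8, 5.5))
  expect_identical(h$status, c("pass", "fail", "warn"))

  m[1, 2] <- NA
  cq2 <- cq_table(m, roles = cq$roles)
  h2 <- hemolysis_score(cq2)
  expect_true(is.na(h2$score[1]) && is.na(h2$status[1]))
})

test_that("spike-in QC flags deviated samples", {
  coh <- simulate_cohort(sim_config(n_samples = 12, n_assays = 6, seed = 2))
  cq <- coh$cq
  cq$values[2, "UniSp3"] <- cq$values[2, "UniSp3"] + 3   # inject a deviation
  qc <- qc_report(cq, run_config())
  expect_false(qc$samples$pass[2])
  expect_match(qc$samples$reasons[2], "spike-in")
  expect_true(all(qc$samples$pass[-2]))
  expect_true(all(nchar(qc$samples$reasons[!qc$samples$pass]) > 0))
})

test_that("detection filter applies the inclusive 80% rule and is monotone", {
  n <- 47
  m <- matrix(25, n, 2, dimnames = list(sprintf("s%02d", 1:n),
                                        c("pass80", "fail80")))
  m[1:9, "pass80"] <- NA    # 38/47 = 0.808
  m[1:10, "fail80"] <- NA   # 37/47 = 0.787
  cq <- cq_table(m, roles = c(pass80 = "target", fail80 = "target"))
  det <- detection_filter(cq, 0.8)
  expect_identical(det$retained, "pass80")
  expect_identical(det$dropped, "fail80")

  # raising the threshold never adds assays
  coh <- simulate_cohort(sim_config(seed = 9))
  fracs <- c(0.5, 0.7, 0.8, 0.9, 1)
  sets <- lapply(fracs, function(f) detection_filter(coh$cq, f)$retained)
  for (i in seq_along(sets)[-1]) {
    expect_true(all(sets[[i]] %in% sets[[i - 1]]))
  }
  # at min_frac = 1 the retained set is exactly the global-mean normalizer set
  norm <- global_mean_normalize(coh$cq)
  expect_setequal(sets[[length(sets)]], norm$normalizer_assays)
})

test_that("global-mean normalization matches the printed formula and is shift-invariant", {
  m <- matrix(c(28, 25, 30, 25, 32, 25), 2, 3,
              dimnames = list(c("A", "B"), c("m1", "m2", "m3")))
  cq <- cq_table(m, roles = c(m1 = "target", m2 = "target", m3 = "target"))
  norm <- global_mean_normalize(cq)
  expect_equal(unname(norm$values["A", ]), c(2, 0, -2))
  expect_equal(unname(norm$values["B", ]), c(0, 0, 0))   # all equal -> all zero

  # adding a constant to one sample's Cq leaves its normalized values unchanged
  m2 <- m; m2["A", ] <- m2["A", ] + 3.7
  norm2 <- global_mean_normalize(cq_table(m2, roles = cq$roles))
  expect_equal(norm2$values, norm$values, tolerance = 1e-12)

  # no fully detected assay -> instructive error
  m3 <- m; m3[1, 1] <- NA; m3[2, 2] <- NA; m3[1, 3] <- NA
  expect_error(global_mean_normalize(cq_table(m3, roles = cq$roles)),
               "NormFinder")
})

test_that("LOD imputation fills with the assay minimum and is idempotent", {
  m <- matrix(c(26.8, 29.5, NA, 28, 29, 30), 3, 2,
              dimnames = list(c("A", "B", "C"), c("m1", "m2")))
  cq <- cq_table(m, roles = c(m1 = "target", m2 = "target"))
  norm <- global_mean_normalize(cq)
  imp <- impute_lod(norm)
  # assay m1 values (1.2, -0.5, missing) on the normalized scale -> -0.5
  expect_equal(unname(norm$values[c("A", "B"), "m1"]), c(1.2, -0.5))
  expect_equal(unname(imp$values["C", "m1"]), min(norm$values[c("A", "B"), "m1"]))
  expect_true(imp$imputed_mask["C", "m1"])
  expect_identical(sum(imp$imputed_mask), 1L)
  # assay without missing cells unchanged; per-assay minimum unchanged
  expect_identical(imp$values[, "m2"], norm$values[, "m2"])
  expect_equal(min(imp$values[, "m1"]), min(norm$values[, "m1"], na.rm = TRUE))
  # idempotent
  expect_identical(impute_lod(imp)$values, imp$values)
})

test_that("stability ranking favors constant candidates and penalizes group shifts", {
  withr::with_seed(41, {
    n <- 20
    g <- rep(c(0, 1), each = n / 2)
    base <- sapply(1:6, function(j) rnorm(n, sd = 0.4))
    colnames(base) <- paste0("c", 1:6)
    base[, "c1"] <- 5                       # constant candidate
    base[, "c2"] <- rnorm(n, sd = 0.4) + g * 1.0   # group-shifted candidate
    base[, "c3"] <- rnorm(n, sd = 0.4)             # same variance, no shift
    rnk <- normfinder_stability(base, groups = g)
    expect_identical(rnk$candidate[1], "c1")
    s <- setNames(rnk$stability, rnk$candidate)
    expect_gt(s["c2"], s["c3"])
    # ranking is a permutation and stability values are finite
    expect_setequal(rnk$candidate, colnames(base))
    expect_true(all(is.finite(rnk$stability)))
  })
})

test_that("stability values match an independent formula re-implementation", {
  withr::with_seed(73, {
    x <- matrix(rnorm(10 * 5, mean = 25), 10, 5,
                dimnames = list(NULL, paste0("g", 1:5)))
    x[, 2] <- x[, 2] + rep(c(0, 0.8), each = 5)
    g <- rep(c("a", "b"), each = 5)
    rnk <- normfinder_stability(x, groups = g)
    oracle <- normfinder_oracle(x, g)
    got <- setNames(rnk$stability, rnk$candidate)[colnames(x)]
    expect_equal(unname(got), unname(oracle), tolerance = 1e-6)
  })
  # preconditions
  expect_error(normfinder_stability(matrix(rnorm(12), 6, 2),
                                    groups = rep(c("a", "b"), 3)),
               "3 candidates")
  expect_error(normfinder_stability(matrix(rnorm(15), 5, 3),
                                    groups = c("a", "a", "a", "b", "b")),
               "3 samples")
})
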