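test_that("test routing follows per-group normality screening", {
  withr::with_seed(5, {
    expect_identical(choose_test(rnorm(50), rnorm(50)), "t")
    expect_identical(choose_test(rexp(50), rnorm(50)), "mwu")
    expect_identical(choose_test(rep(1, 10), rnorm(10)), "mwu")
  })
})

test_that("Mann-Whitney U matches exhaustive enumeration on small samples", {
  res <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1 / 3)
  expect_identical(res$method, "exact")

  # identical multisets -> p = 1
  expect_equal(mann_whitney_u(c(1, 2, 3), c(1, 2, 3))$p_value, 1)

  # tied data: exact path vs independent pairwise-counting oracle
  withr::with_seed(12, {
    for (rep in 1:5) {
      x <- sample(1:4, 7, replace = TRUE)
      y <- sample(1:4, 6, replace = TRUE)
      got <- mann_whitney_u(x, y)
      want <- mwu_oracle(x, y)
      expect_equal(got$statistic, want$u)
      expect_equal(got$p_value, want$p, tolerance = 1e-9)
    }
  })
})

test_that("Mann-Whitney large-sample path uses the tie-corrected normal approximation", {
  withr::with_seed(8, {
    x <- sample(seq(0, 5, by = 0.5), 30, replace = TRUE)
    y <- sample(seq(1, 6, by = 0.5), 28, replace = TRUE)
  })
  got <- mann_whitney_u(x, y)
  expect_identical(got$method, "normal")
  ref <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                             correct = FALSE))
  expect_equal(got$statistic, unname(ref$statistic))
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-10)
})

test_that("Mann-Whitney p is invariant under strictly monotone transforms", {
  withr::with_seed(3, {
    x <- rnorm(12); y <- rnorm(15, 0.5)
    p0 <- mann_whitney_u(x, y)$p_value
    for (f in list(function(v) exp(v), function(v) v^3,
                   function(v) 10 + 2 * v)) {
      expect_equal(mann_whitney_u(f(x), f(y))$p_value, p0)
    }
  })
})

test_that("BH adjustment matches the brute-force step-up definition", {
  expect_equal(bh_adjust(0.01), 0.01)
  expect_error(bh_adjust(c(0.2, 1.2)), "\\[0, 1\\]")

  withr::with_seed(21, {
    for (m in c(2, 4, 7, 8)) {
      p <- runif(m)
      expect_equal(bh_adjust(p), bh_oracle(p))
    }
  })

  # five small p-values among 160 tests: smallest adjusted value is 0.48
  p5 <- c(0.003, 0.008, 0.030, 0.042, 0.047)
  p <- c(p5, seq(0.06, 1, length.out = 155))
  adj <- bh_adjust(p)
  expect_equal(min(adj), 0.48)
  expect_true(all(adj >= 0.05))

  # permutation invariance
  withr::with_seed(6, {
    p <- runif(20)
    perm <- sample(20)
    expect_equal(bh_adjust(p)[perm], bh_adjust(p[perm]))
  })
  # adjusted >= raw, <= 1
  expect_true(all(bh_adjust(p) >= p & bh_adjust(p) <= 1))
})

test_that("chi-square without continuity correction reproduces published 2x2 p-values", {
  expect_equal(round(chi_square_2x2(matrix(c(15, 10, 9, 13), 2))$p_value, 2),
               0.19)
  expect_equal(round(chi_square_2x2(matrix(c(21, 23, 3, 0), 2))$p_value, 2),
               0.08)
  bal <- chi_square_2x2(matrix(c(10, 10, 10, 10), 2))
  expect_equal(bal$statistic, 0)
  expect_equal(bal$p_value, 1)
  expect_error(chi_square_2x2(matrix(c(5, 5, 0, 0), 2)), "zero margin")

  # invariance under transposition and row/column swaps
  tab <- matrix(c(15, 10, 9, 13), 2)
  p0 <- chi_square_2x2(tab)$p_value
  expect_equal(chi_square_2x2(t(tab))$p_value, p0)
  expect_equal(chi_square_2x2(tab[2:1, ])$p_value, p0)
  expect_equal(chi_square_2x2(tab[, 2:1])$p_value, p0)
})

test_that("Spearman matrix equals rank-then-Pearson and handles edge columns", {
  x <- cbind(a = c(3, 1, 4, 1.5, 9), b = c(2, 7, 1, 8, 2.8),
             c = c(1, 1, 2, 2, 3))
  rho <- spearman_matrix(x)
  oracle <- cor(apply(x, 2, rank))
  expect_equal(rho, oracle, tolerance = 1e-12)
  expect_equal(diag(rho), c(a = 1, b = 1, c = 1))
  expect_equal(spearman_matrix(cbind(a = x[, 1], neg = -x[, 1]))["a", "neg"],
               -1)
  rho2 <- spearman_matrix(cbind(a = x[, 1], k = rep(2, 5)))
  expect_true(is.na(rho2["a", "k"]))
  expect_equal(rho2["k", "k"], 1)
})

test_that("screen table has one row per assay with valid BH ordering", {
  coh <- simulate_cohort(sim_config(seed = 14))
  cq <- apply_ntc_rule(coh$cq)
  det <- detection_filter(cq)
  norm <- impute_lod(global_mean_normalize(cq, assays = det$retained))
  scr <- screen_mirs(norm, coh$patients$lipid_rich)
  expect_identical(nrow(scr), length(det$retained))
  expect_true(all(scr$p_adjusted >= scr$p_value))
  expect_true(all(scr$p_adjusted <= 1))
  expect_true(!is.unsorted(scr$p_value))
  expect_true(!is.unsorted(scr$p_adjusted))   # monotone in the raw-p order
  expect_true(all(scr$test %in% c("t", "mwu")))
})

test_that("a strongly planted assay attains the smallest univariable p", {
  hits <- vapply(1:100, function(s) {
    sim <- sim_config(n_samples = 100, n_assays = 20, n_planted = 1,
                      planted_shift_cq = 1.5 * 0.8, frac_low_detection = 0,
                      seed = 1000 + s)
    coh <- simulate_cohort(sim)
    norm <- impute_lod(global_mean_normalize(coh$cq))
    scr <- screen_mirs(norm, coh$patients$lipid_rich)
    scr$assay[1] == coh$truth$planted$assay
  }, logical(1))
  expect_gte(sum(hits), 95)
})

test_that("characteristics table summarizes and tests by variable type", {
  coh <- simulate_cohort(sim_config(seed = 19))
  tab <- characteristics_table(coh$patients)
  expect_true(all(c("age", "smoker", "ldl_c") %in% tab$variable))
  expect_identical(tab$test[tab$variable == "smoker"], "chisq")
  expect_true(tab$test[tab$variable == "age"] %in% c("t", "mwu"))
  expect_true(all(tab$p_value >= 0 & tab$p_value <= 1, na.rm = TRUE))
  expect_true(all(tab$n_missing == 0))
})
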