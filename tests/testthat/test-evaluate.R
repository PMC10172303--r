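test_that("AUC equals the tie-corrected rank statistic", {
  r <- roc_auc(c(0.9, 0.8, 0.3, 0.2), c(1, 1, 0, 0))
  expect_equal(r$auc, 1)
  expect_equal(roc_auc(rep(0.4, 10), rep(c(0, 1), 5))$auc, 0.5)

  withr::with_seed(11, {
    scores <- round(rnorm(30), 1)   # induce ties
    labels <- rbinom(30, 1, 0.5)
    labels[1:2] <- c(0, 1)
    r <- roc_auc(scores, labels)
    w <- suppressWarnings(stats::wilcox.test(scores[labels == 1],
                                             scores[labels == 0]))
    n1 <- sum(labels); n0 <- sum(1 - labels)
    expect_equal(r$auc, unname(w$statistic) / (n1 * n0), tolerance = 1e-12)
  })
})

test_that("ROC curve is monotone with fixed endpoints and AUC inside the CI", {
  withr::with_seed(4, {
    scores <- rnorm(40) + rep(c(0, 1), 20)
    labels <- rep(c(0, 1), 20)
  })
  r <- roc_auc(scores, labels)
  expect_equal(r$points$fpr[1], 0)
  expect_equal(r$points$tpr[1], 0)
  expect_equal(r$points$fpr[nrow(r$points)], 1)
  expect_equal(r$points$tpr[nrow(r$points)], 1)
  expect_true(all(diff(r$points$fpr) >= 0))
  expect_true(all(diff(r$points$tpr) >= 0))
  expect_true(r$ci[1] <= r$auc && r$auc <= r$ci[2])
})

test_that("DeLong interval matches pROC and shrinks with sample size", {
  skip_if_not_installed("pROC")
  withr::with_seed(9, {
    scores <- rnorm(60) + rep(c(0, 0.8), 30)
    labels <- rep(c(0, 1), 30)
  })
  r <- roc_auc(scores, labels)
  ref <- pROC::ci.auc(pROC::roc(labels, scores, quiet = TRUE),
                      method = "delong")
  expect_equal(r$auc, as.numeric(ref[2]), tolerance = 1e-10)
  expect_equal(r$ci[1], as.numeric(ref[1]), tolerance = 1e-8)
  expect_equal(r$ci[2], as.numeric(ref[3]), tolerance = 1e-8)

  widths <- vapply(c(50, 200, 800), function(n) {
    withr::with_seed(n, {
      s <- rnorm(n) + rep(c(0, 0.8), n / 2)
      l <- rep(c(0, 1), n / 2)
    })
    ci <- roc_auc(s, l)$ci
    ci[2] - ci[1]
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
})

test_that("AUC is invariant to monotone score transforms and flips with labels", {
  withr::with_seed(2, {
    scores <- rnorm(50)
    labels <- rbinom(50, 1, plogis(scores))
    labels[1:2] <- c(0, 1)
  })
  a0 <- roc_auc(scores, labels)$auc
  expect_equal(roc_auc(exp(scores), labels)$auc, a0)
  expect_equal(roc_auc(scores^3, labels)$auc, a0)
  expect_equal(roc_auc(scores, 1 - labels)$auc, 1 - a0)
})

test_that("cross-validated scores behave at the uninformative and separating extremes", {
  # constant predictor: scores hover at the training prevalence, AUC ~ 0.5
  n <- 60
  x <- matrix(rnorm(n) * 0 + 1e-8 * seq_len(n), n, 1,
              dimnames = list(sprintf("s%02d", 1:n), "flat"))
  y <- rep(c(0L, 1L), n / 2)
  d <- structure(list(x = x, y = y, variables = "flat",
                      sample_id = rownames(x)), class = "plq_design")
  cfg <- run_config(seed = 6, cv_repeats = 2)
  sc <- cv_scores(d, cfg)
  expect_true(all(abs(sc - mean(y)) < 0.2))
  expect_lt(abs(roc_auc(sc, y)$auc - 0.5), 0.2)

  # perfectly separating predictor: AUC 1 via the ridge-stabilized fallback
  x2 <- matrix(c(rnorm(30, -3), rnorm(30, 3)), n, 1,
               dimnames = list(rownames(x), "sep"))
  y2 <- rep(c(0L, 1L), each = 30)
  d2 <- structure(list(x = x2, y = y2, variables = "sep",
                       sample_id = rownames(x)), class = "plq_design")
  sc2 <- cv_scores(d2, cfg)
  expect_equal(roc_auc(sc2, y2)$auc, 1)

  # deterministic under a fixed seed
  expect_identical(cv_scores(d2, cfg), cv_scores(d2, cfg))
})

test_that("lipid-panel model has five columns and guards its inputs", {
  coh <- simulate_cohort(sim_config(n_samples = 30, n_assays = 6, seed = 15))
  d <- lipid_panel_model(coh$patients)
  expect_identical(d$variables,
                   c("ldl_c", "hdl_c", "triglycerides", "ldl_hdl_ratio",
                     "lipoprotein_a"))
  expect_identical(attr(d, "n_excluded"), 0L)

  pt <- coh$patients
  pt$triglycerides[3] <- NA
  d2 <- lipid_panel_model(pt)
  expect_identical(attr(d2, "n_excluded"), 1L)
  expect_identical(nrow(d2$x), 29L)

  pt2 <- coh$patients; pt2$hdl_c[1] <- 0
  expect_error(lipid_panel_model(pt2), "HDL")
})

test_that("lipid panel is uninformative when lipids are independent of outcome", {
  aucs <- vapply(1:20, function(s) {
    coh <- simulate_cohort(sim_config(n_samples = 200, n_assays = 6,
                                      n_planted = 0, seed = 600 + s))
    cfg <- run_config(seed = 600 + s, cv_repeats = 2)
    cv_roc(lipid_panel_model(coh$patients), config = cfg,
           model = "lipids")$auc
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.08)
})
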