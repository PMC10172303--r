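#' Route a two-group comparison to t or Mann-Whitney U
#'
#' Mirrors the normality-screening convention: Shapiro-Wilk per group at
#' level `sw_alpha`; if either group rejects normality (or is constant,
#' where the test is undefined) the variable is routed to the Mann-Whitney U
#' test, otherwise to the t test.
#'
#' @param x,y Numeric vectors for the two groups (each n >= 3).
#' @param sw_alpha Shapiro-Wilk level (default 0.05).
#' @return `"t"` or `"mwu"`.
#' @export
choose_test <- function(x, y, sw_alpha = 0.05) {
  stopifnot(length(x) >= 3, length(y) >= 3)
  sw_p <- function(v) {
    if (length(unique(v)) == 1L) return(0)   # constant: SW undefined -> MWU
    shapiro.test(v)$p.value
  }
  if (sw_p(x) < sw_alpha || sw_p(y) < sw_alpha) "mwu" else "t"
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum test. For `min(n) <= exact_max` the null distribution
#' of U is enumerated exhaustively over all group assignments of the pooled
#' (possibly tied) data; otherwise the normal approximation with tie
#' correction (no continuity correction) is used. U is the number of
#' `(x, y)` pairs with `x > y`, ties counting one half.
#'
#' @param x,y Non-empty numeric vectors.
#' @param exact_max Largest `min(n)` for which exact enumeration is used.
#' @return A list with `statistic` (U for `x`), `p_value` and `method`
#'   (`"exact"` or `"normal"`).
#' @examples
#' mann_whitney_u(c(1, 2), c(3, 4)) # U = 0, exact p = 1/3
#' @export
mann_whitney_u <- function(x, y, exact_max = 8L) {
  if (!length(x) || !length(y)) abort("empty vector")
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  rk <- rank(pooled)
  u <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2

  if (min(n1, n2) <= exact_max) {
    idx <- utils::combn(n1 + n2, n1)
    u_all <- colSums(matrix(rk[idx], nrow = n1)) - n1 * (n1 + 1) / 2
    dev <- abs(u - mu)
    p <- mean(abs(u_all - mu) >= dev - 1e-12)
    return(list(statistic = u, p_value = p, method = "exact"))
  }
  nn <- n1 + n2
  ties <- table(pooled)
  tie_term <- sum(ties^3 - ties) / (nn * (nn - 1))
  v <- n1 * n2 / 12 * ((nn + 1) - tie_term)
  if (v <= 0) return(list(statistic = u, p_value = 1, method = "normal"))
  z <- (u - mu) / sqrt(v)
  list(statistic = u, p_value = min(1, 2 * pnorm(-abs(z))), method = "normal")
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment; a thin validated wrapper around
#' [stats::p.adjust()] so the screening table and the report pipeline share
#' one entry point.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values in the input order.
#' @export
bh_adjust <- function(p) {
  if (anyNA(p) || any(p < 0) || any(p > 1)) abort("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Pearson chi-square test for a 2x2 table
#'
#' Pearson chi-square without continuity correction (df = 1), the variant
#' whose p-values match published two-group frequency comparisons of
#' baseline characteristics. Degenerate tables (a zero row or column margin)
#' are an error.
#'
#' @param tab 2x2 matrix of nonnegative integer counts.
#' @return List with `statistic` (chi-square) and `p_value`.
#' @examples
#' chi_square_2x2(matrix(c(15, 10, 9, 13), 2))$p_value # ~0.19
#' @export
chi_square_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L))) abort("need a 2x2 table")
  if (any(tab < 0) || any(tab != round(tab))) {
    abort("counts must be nonnegative integers")
  }
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    abort("degenerate table: zero margin")
  }
  res <- suppressWarnings(chisq.test(tab, correct = FALSE))
  list(statistic = unname(res$statistic), p_value = res$p.value)
}

#' Univariable miRNA screen
#'
#' One two-group comparison per assay on the normalized (imputed) scale,
#' routed per assay by [choose_test()] — Welch t (configurable to pooled) or
#' Mann-Whitney U — with Benjamini-Hochberg adjustment across all assays.
#'
#' @param norm A `plq_norm` after [impute_lod()] (no missing cells), already
#'   restricted to retained assays.
#' @param labels Logical/0-1 outcome vector aligned with the rows of
#'   `norm$values` (TRUE/1 = lipid-rich).
#' @param config A [run_config()].
#' @return A tibble of class `plq_screen`, sorted ascending by raw p:
#'   `assay`, `test`, `statistic`, `p_value`, `p_adjusted`, group means.
#' @export
screen_mirs <- function(norm, labels, config = run_config()) {
  vals <- norm$values
  if (anyNA(vals)) abort("normalized matrix must be imputed before screening")
  labels <- as.logical(labels)
  if (length(labels) != nrow(vals)) abort("labels must match samples")
  if (sum(labels) < 2 || sum(!labels) < 2) {
    abort("need at least 2 samples per outcome class")
  }
  rows <- purrr::map_dfr(colnames(vals), function(a) {
    x1 <- vals[labels, a]    # lipid-rich
    x0 <- vals[!labels, a]
    test <- choose_test(x1, x0, sw_alpha = config$sw_alpha)
    if (test == "t") {
      tt <- t.test(x1, x0, var.equal = !config$welch_t)
      stat <- unname(tt$statistic); p <- tt$p.value
    } else {
      mw <- mann_whitney_u(x1, x0)
      stat <- mw$statistic; p <- mw$p_value
    }
    tibble(assay = a, test = test, statistic = stat, p_value = p,
           mean_lipid_rich = mean(x1), mean_other = mean(x0))
  })
  rows$p_adjusted <- bh_adjust(rows$p_value)
  out <- dplyr::arrange(rows, .data$p_value, .data$assay)
  class(out) <- c("plq_screen", class(out))
  out
}

#' Patient-characteristics comparison table
#'
#' Per-variable two-group summaries and tests: continuous variables are
#' summarized as mean (SD) and routed by [choose_test()] to Welch t or
#' Mann-Whitney U; binary variables as n (%) with the Pearson chi-square
#' test (no continuity correction). Missing values are dropped per variable
#' and counted.
#'
#' @param patients Patient tibble with a `lipid_rich` column (see
#'   [label_lipid_rich()]).
#' @param config A [run_config()].
#' @param variables Columns to compare; defaults to every column except
#'   identifiers, the outcome and bookkeeping columns.
#' @return Tibble: `variable`, `type`, per-group summaries, `test`, `p_value`,
#'   `n_missing`.
#' @export
characteristics_table <- function(patients, config = run_config(),
                                  variables = NULL) {
  if (is.null(variables)) {
    variables <- setdiff(names(patients),
                         c("sample_id", "max_lcbi_4mm", "lipid_rich",
                           "n_missing_covariates"))
  }
  g <- patients$lipid_rich
  purrr::map_dfr(variables, function(v) {
    x <- patients[[v]]
    ok <- !is.na(x)
    xv <- x[ok]; gv <- g[ok]
    binary <- length(unique(xv)) <= 2
    if (binary) {
      tab <- rbind(c(sum(xv[!gv] == 1), sum(xv[!gv] == 0)),
                   c(sum(xv[gv] == 1), sum(xv[gv] == 0)))
      res <- tryCatch(chi_square_2x2(tab),
                      error = function(e) list(p_value = NA_real_))
      tibble(
        variable = v, type = "binary",
        summary_other = sprintf("%d (%.1f%%)", sum(xv[!gv] == 1),
                                100 * mean(xv[!gv] == 1)),
        summary_lipid_rich = sprintf("%d (%.1f%%)", sum(xv[gv] == 1),
                                     100 * mean(xv[gv] == 1)),
        test = "chisq", p_value = res$p_value, n_missing = sum(!ok)
      )
    } else {
      test <- choose_test(xv[gv], xv[!gv], sw_alpha = config$sw_alpha)
      p <- if (test == "t") {
        t.test(xv[gv], xv[!gv], var.equal = !config$welch_t)$p.value
      } else {
        mann_whitney_u(xv[gv], xv[!gv])$p_value
      }
      tibble(
        variable = v, type = "continuous",
        summary_other = sprintf("%.1f (%.1f)", mean(xv[!gv]), sd(xv[!gv])),
        summary_lipid_rich = sprintf("%.1f (%.1f)", mean(xv[gv]), sd(xv[gv])),
        test = test, p_value = p, n_missing = sum(!ok)
      )
    }
  })
}

#' Spearman correlation matrix between assays
#'
#' Tie-aware rank correlation between the columns of the normalized matrix.
#' Constant columns have undefined correlations and are returned as `NA`.
#'
#' @param norm A `plq_norm` (imputed) or a plain numeric matrix.
#' @param assays Optional subset of assay columns.
#' @return Symmetric matrix with unit diagonal.
#' @export
spearman_matrix <- function(norm, assays = NULL) {
  vals <- if (inherits(norm, "plq_norm")) norm$values else as.matrix(norm)
  if (!is.null(assays)) vals <- vals[, assays, drop = FALSE]
  if (nrow(vals) < 3) abort("need at least 3 samples")
  const <- apply(vals, 2, function(v) length(unique(v)) == 1L)
  rho <- suppressWarnings(cor(vals, method = "spearman"))
  rho[const, ] <- NA_real_
  rho[, const] <- NA_real_
  diag(rho) <- 1
  rho
}
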