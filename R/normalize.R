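#' Detection filter
#'
#' Keeps target assays detected in at least `min_frac` of samples (boundary
#' inclusive). Spike-ins never enter the candidate set.
#'
#' @param cq A [cq_table()].
#' @param min_frac Minimum detected-sample fraction in `(0, 1]`.
#' @return A list: `retained`, `dropped` (assay id vectors) and
#'   `detection_rate` (tibble `assay`, `rate`, `retained`).
#' @examples
#' # 38/47 detected = 0.808 >= 0.8 -> retained; 37/47 = 0.787 -> dropped
#' @export
detection_filter <- function(cq, min_frac = 0.8) {
  stopifnot(min_frac > 0, min_frac <= 1)
  tgt <- target_assays(cq)
  rate <- colMeans(!is.na(cq$values[, tgt, drop = FALSE]))
  keep <- rate >= min_frac
  list(
    retained = tgt[keep],
    dropped = tgt[!keep],
    detection_rate = tibble(assay = tgt, rate = unname(rate),
                            retained = unname(keep))
  )
}

#' Global-mean normalization of a Cq table
#'
#' The per-sample reference is the mean Cq over the normalizer set: all
#' target assays detected in 100% of samples (the "global mean"). The
#' normalized value is `global mean Cq(sample) - assay Cq(sample)`, so
#' higher values mean higher abundance relative to the sample's global mean,
#' and any per-sample technical offset cancels exactly. Undetected cells
#' stay missing; imputation is a separate step ([impute_lod()]).
#'
#' @param cq A [cq_table()].
#' @param assays Target assays to carry into the normalized matrix
#'   (default: all target assays). The normalizer set is always computed
#'   from all target assays, regardless of this subset.
#' @return A list of class `plq_norm`: `values` (samples x assays, delta-Cq),
#'   `detection_mask`, `imputed_mask`, `normalizer_assays`,
#'   `detection_rate`, `global_mean` (per sample).
#' @examples
#' # sample Cqs (28, 30, 32) with all three assays in the normalizer set:
#' # global mean 30 -> normalized (2, 0, -2)
#' @export
global_mean_normalize <- function(cq, assays = NULL) {
  tgt <- target_assays(cq)
  tv <- cq$values[, tgt, drop = FALSE]
  normalizers <- tgt[colMeans(!is.na(tv)) == 1]
  if (!length(normalizers)) {
    abort(paste0("no target assay is detected in all samples; a NormFinder-",
                 "ranked reference set is required instead (see ",
                 "normfinder_stability())"))
  }
  if (is.null(assays)) assays <- tgt
  stopifnot(all(assays %in% tgt))
  g <- rowMeans(tv[, normalizers, drop = FALSE])
  vals <- g - cq$values[, assays, drop = FALSE]
  detection <- !is.na(vals)
  structure(
    list(values = vals,
         detection_mask = detection,
         imputed_mask = matrix(FALSE, nrow(vals), ncol(vals),
                               dimnames = dimnames(vals)),
         normalizer_assays = normalizers,
         detection_rate = colMeans(detection),
         global_mean = g),
    class = "plq_norm"
  )
}

#' @export
print.plq_norm <- function(x, ...) {
  cat(sprintf("<plq_norm> %d samples x %d assays; %d normalizer assays\n",
              nrow(x$values), ncol(x$values), length(x$normalizer_assays)))
  cat(sprintf("  missing cells: %d; imputed cells: %d\n",
              sum(!x$detection_mask), sum(x$imputed_mask)))
  invisible(x)
}

#' @export
as_tibble.plq_norm <- function(x, ...) {
  tibble(
    sample_id = rep(rownames(x$values), times = ncol(x$values)),
    assay = rep(colnames(x$values), each = nrow(x$values)),
    dcq = as.vector(x$values),
    detected = as.vector(x$detection_mask),
    imputed = as.vector(x$imputed_mask)
  )
}

#' Limit-of-detection imputation
#'
#' Each undetected cell of an assay receives the assay's lowest measured
#' concentration, i.e. the minimum observed normalized value (on the
#' delta-Cq scale, the minimum — lower delta-Cq means less abundant).
#' Imputation happens on the normalized scale so that per-sample technical
#' offsets do not leak into imputed cells.
#'
#' @param norm A `plq_norm` from [global_mean_normalize()].
#' @return The `plq_norm` with missing cells filled and `imputed_mask`
#'   updated. An assay with no detected value at all must have been dropped
#'   by [detection_filter()] earlier; encountering one is an error.
#' @export
impute_lod <- function(norm) {
  vals <- norm$values
  for (j in seq_len(ncol(vals))) {
    miss <- is.na(vals[, j])
    if (!any(miss)) next
    if (all(miss)) {
      abort(sprintf("assay '%s' has no detected values; it should have been dropped by the detection filter", colnames(vals)[j]))
    }
    vals[miss, j] <- min(vals[!miss, j])
    norm$imputed_mask[miss, j] <- TRUE
  }
  norm$values <- vals
  norm
}

#' Model-based reference stability ranking (NormFinder-style)
#'
#' Ranks candidate references (including the global-mean pseudo-assay) by a
#' model-based stability value combining intragroup variance and intergroup
#' bias, in the spirit of the NormFinder variance-decomposition model.
#'
#' With expression values centered per sample across the `k` candidates
#' (removing the common sample effect), the method estimates for each
#' candidate and group the intragroup variance with the correction
#' `sigma2 = (v - sum(v_l)/(k (k-1))) / (1 - 2/k)` (floored at zero), where
#' `v` is the within-group sample variance of the centered values, and the
#' intergroup difference of group means `d`. The difference is shrunken
#' towards zero by its estimated signal-to-noise ratio, and the stability
#' value is `|d_shrunk| + sqrt(sigma2_1/n_1 + sigma2_2/n_2)` — lower is more
#' stable. The ungrouped variant ranks by `sqrt(sigma2)` pooled over all
#' samples.
#'
#' @param x Numeric matrix (samples x candidate assays), typically raw Cq of
#'   fully detected assays or normalized values; no missing cells allowed.
#' @param groups Two-level factor/vector of per-sample group labels, each
#'   level with at least 3 samples.
#' @param global_mean Optional per-sample numeric vector; when supplied it is
#'   evaluated like any candidate under the name `"global_mean"`.
#' @return A tibble of class `plq_normfinder`, ranked ascending by the
#'   grouped stability value, with columns `candidate`, `stability`
#'   (grouped), `stability_ungrouped`, `intergroup_difference` and `rank`.
#' @export
normfinder_stability <- function(x, groups, global_mean = NULL) {
  if (anyNA(x)) abort("candidates must be fully detected (no missing cells)")
  if (!is.null(global_mean)) {
    x <- cbind(x, global_mean = global_mean)
  }
  k <- ncol(x)
  if (k < 3) abort("need at least 3 candidates for the variance decomposition")
  groups <- as.factor(groups)
  if (nlevels(groups) != 2L) abort("exactly two groups required")
  if (any(table(groups) < 3L)) abort("each group needs at least 3 samples")

  r <- x - rowMeans(x)                       # remove common sample effect
  lev <- levels(groups)
  n_g <- table(groups)

  sigma2 <- matrix(0, 2, k)
  m <- matrix(0, 2, k)
  for (gi in 1:2) {
    rg <- r[groups == lev[gi], , drop = FALSE]
    v <- apply(rg, 2, var)
    sigma2[gi, ] <- pmax(0, (v - sum(v) / (k * (k - 1))) / (1 - 2 / k))
    m[gi, ] <- colMeans(rg)
  }
  d <- m[1, ] - m[2, ]
  se2 <- sigma2[1, ] / n_g[[1]] + sigma2[2, ] / n_g[[2]]
  gamma2 <- max(0, var(d) - mean(se2))
  d_shrunk <- if (gamma2 > 0) d * gamma2 / (gamma2 + se2) else rep(0, k)
  stability <- abs(d_shrunk) + sqrt(se2)

  # ungrouped variant: pooled variance of centered values with correction
  v_all <- apply(r, 2, var)
  s2_all <- pmax(0, (v_all - sum(v_all) / (k * (k - 1))) / (1 - 2 / k))

  out <- tibble(
    candidate = colnames(x),
    stability = unname(stability),
    stability_ungrouped = sqrt(unname(s2_all)),
    intergroup_difference = unname(d)
  ) |>
    dplyr::arrange(.data$stability, .data$candidate) |>
    dplyr::mutate(rank = dplyr::row_number())
  class(out) <- c("plq_normfinder", class(out))
  out
}
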