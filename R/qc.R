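#' Apply the no-template-control detection rule
#'
#' A reaction counts as detected only if its Cq undercuts the assay's
#' negative-control (NTC) background by at least `margin` cycles:
#' `Cq(i, j) <= NTC(j) - margin` (boundary inclusive). Assays without NTC
#' amplification (`NA` background) keep all their detected cells; an absent
#' NTC record is flagged but not fatal.
#'
#' @param cq A [cq_table()].
#' @param margin Required margin in Cq (default 5).
#' @return A `plq_cq` with failing cells set undetected; the number of
#'   censored cells is attached as attribute `n_censored`.
#' @examples
#' # Cq 30 vs NTC 40 with margin 5: detected (30 <= 35); Cq 36: undetected
#' @export
apply_ntc_rule <- function(cq, margin = 5) {
  stopifnot(margin > 0)
  if (is.null(cq$ntc)) {
    warn("no NTC record in Cq table; detection left unchanged")
    attr(cq, "n_censored") <- 0L
    return(cq)
  }
  vals <- cq$values
  n_censored <- 0L
  for (a in colnames(vals)) {
    bg <- cq$ntc[[a]]
    if (is.na(bg)) next
    fail <- !is.na(vals[, a]) & vals[, a] > bg - margin
    n_censored <- n_censored + sum(fail)
    vals[fail, a] <- NA_real_
  }
  out <- cq_table(vals, roles = cq$roles, max_cycles = cq$max_cycles,
                  ntc = cq$ntc)
  attr(out, "n_censored") <- n_censored
  out
}

#' Per-sample hemolysis indicator
#'
#' Red-blood-cell contamination of plasma is screened with the standard
#' miRNA indicator `Cq(miR-23a-3p) - Cq(miR-451a)`: miR-451a is highly
#' enriched in erythrocytes, so a large difference flags hemolysis.
#' Scores above `warn` warrant caution; above `fail` the sample is flagged.
#'
#' @param cq A [cq_table()].
#' @param reporter Assay whose Cq rises with hemolysis-free plasma
#'   (default `"hsa-miR-23a-3p"`).
#' @param reference Erythrocyte-enriched assay (default `"hsa-miR-451a"`).
#' @param warn,fail Thresholds in Cq (defaults 5 and 7).
#' @return Tibble `sample_id`, `score`, `status` (`pass`/`warn`/`fail`;
#'   `NA` score when either assay is undetected in the sample).
#' @export
hemolysis_score <- function(cq, reporter = "hsa-miR-23a-3p",
                            reference = "hsa-miR-451a",
                            warn = 5, fail = 7) {
  if (!all(c(reporter, reference) %in% colnames(cq$values))) {
    abort("hemolysis assays not present in Cq table")
  }
  score <- cq$values[, reporter] - cq$values[, reference]
  tibble(
    sample_id = rownames(cq$values),
    score = unname(score),
    status = dplyr::case_when(
      is.na(score) ~ NA_character_,
      score > fail ~ "fail",
      score > warn ~ "warn",
      TRUE ~ "pass"
    )
  )
}

#' Spike-in deviation QC
#'
#' Spike-ins (UniSp2/4/5 for extraction, UniSp3 for qPCR, UniSp6 for reverse
#' transcription) are added at fixed amounts, so their Cq should be
#' near-constant across the cohort. A sample is flagged when any of its
#' spike-in Cq values deviates from the cohort median for that spike-in by
#' more than `max_dev` cycles.
#'
#' @param cq A [cq_table()].
#' @param max_dev Maximum tolerated absolute deviation in Cq (default 2).
#' @return Tibble `sample_id`, `assay`, `cq`, `deviation`, `flagged`.
#' @export
spike_in_qc <- function(cq, max_dev = 2) {
  sp <- spike_in_assays(cq)
  if (!length(sp)) {
    return(tibble(sample_id = character(), assay = character(),
                  cq = numeric(), deviation = numeric(), flagged = logical()))
  }
  purrr::map_dfr(sp, function(a) {
    v <- cq$values[, a]
    med <- median(v, na.rm = TRUE)
    tibble(sample_id = rownames(cq$values), assay = a, cq = unname(v),
           deviation = unname(v - med),
           flagged = is.na(v) | abs(v - med) > max_dev)
  })
}

#' Full sample-level quality-control report
#'
#' Combines the spike-in deviation check and the hemolysis indicator into a
#' per-sample pass/fail table; failing samples carry their reasons. The
#' per-assay NTC background is reported alongside. Samples failing QC are
#' excluded from analysis (exclusion is logged, never imputed).
#'
#' @param cq A [cq_table()].
#' @param config A [run_config()] supplying the thresholds.
#' @return A list of class `plq_qc`: `samples` (tibble with `pass` and
#'   `reasons`), `spike_ins`, `hemolysis`, `ntc` tibbles.
#' @export
qc_report <- function(cq, config = run_config()) {
  sp <- spike_in_qc(cq, max_dev = config$spike_in_max_dev)
  hem <- hemolysis_score(cq, warn = config$hemolysis_warn,
                         fail = config$hemolysis_fail)
  ids <- rownames(cq$values)
  sp_bad <- if (nrow(sp)) {
    sp |> dplyr::group_by(.data$sample_id) |>
      dplyr::summarise(spike_flag = any(.data$flagged), .groups = "drop")
  } else {
    tibble(sample_id = ids, spike_flag = FALSE)
  }
  samples <- tibble(sample_id = ids) |>
    dplyr::left_join(sp_bad, by = "sample_id") |>
    dplyr::left_join(hem, by = "sample_id") |>
    dplyr::mutate(
      spike_flag = dplyr::coalesce(.data$spike_flag, FALSE),
      hemolysis_fail = !is.na(.data$status) & .data$status == "fail",
      pass = !.data$spike_flag & !.data$hemolysis_fail,
      reasons = dplyr::case_when(
        .data$spike_flag & .data$hemolysis_fail ~ "spike-in deviation; hemolysis",
        .data$spike_flag ~ "spike-in deviation",
        .data$hemolysis_fail ~ "hemolysis",
        TRUE ~ ""
      )
    ) |>
    dplyr::select("sample_id", hemolysis_score = "score",
                  hemolysis_status = "status", "spike_flag", "pass", "reasons")
  ntc <- tibble(
    assay = colnames(cq$values),
    ntc_cq = if (is.null(cq$ntc)) NA_real_ else unname(cq$ntc)
  )
  structure(list(samples = samples, spike_ins = sp, hemolysis = hem,
                 ntc = ntc),
            class = "plq_qc")
}

#' @export
print.plq_qc <- function(x, ...) {
  cat(sprintf("<plq_qc> %d samples, %d pass / %d fail\n",
              nrow(x$samples), sum(x$samples$pass), sum(!x$samples$pass)))
  bad <- x$samples[!x$samples$pass, ]
  if (nrow(bad)) {
    for (i in seq_len(nrow(bad))) {
      cat(sprintf("  %s: %s\n", bad$sample_id[i], bad$reasons[i]))
    }
  }
  invisible(x)
}
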