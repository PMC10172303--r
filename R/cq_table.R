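#' Raw quantification-cycle (Cq) table
#'
#' Container for a samples-by-assays matrix of raw Cq values from a qPCR
#' panel. Undetected reactions are `NA`. Each assay carries a role (`target`
#' miRNA or `spike_in` control) and the panel may carry a no-template control
#' (NTC) record: one background Cq per assay, against which sample signals
#' are compared by [apply_ntc_rule()].
#'
#' @param values Numeric matrix, rows = samples, columns = assays, with
#'   unique row and column names. `NA` marks an undetected reaction.
#' @param roles Named character vector mapping every assay to `"target"` or
#'   `"spike_in"`.
#' @param max_cycles Number of PCR cycles run; detected Cq must lie in
#'   `(0, max_cycles]`.
#' @param ntc Optional named numeric vector of per-assay negative-control Cq
#'   (`NA` = no NTC amplification for that assay). `NULL` means no NTC record
#'   is available, which is flagged but not fatal.
#'
#' @return An object of class `plq_cq`.
#' @examples
#' m <- matrix(c(25, 30, 26, NA), 2, 2,
#'             dimnames = list(c("S1", "S2"), c("miR-a", "miR-b")))
#' cq_table(m, roles = c("miR-a" = "target", "miR-b" = "target"))
#' @export
cq_table <- function(values, roles, max_cycles = 45L, ntc = NULL) {
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("`values` must be a numeric matrix (samples x assays).")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    abort("`values` needs sample rownames and assay colnames.")
  }
  if (anyDuplicated(rownames(values))) abort("duplicated sample identifiers")
  if (anyDuplicated(colnames(values))) abort("duplicated assay identifiers")
  roles <- roles[colnames(values)]
  if (anyNA(names(roles)) || !all(colnames(values) %in% names(roles))) {
    abort("every assay needs a role")
  }
  bad_role <- setdiff(unique(roles), c("target", "spike_in"))
  if (length(bad_role)) {
    abort(paste0("unknown assay role: ", paste(bad_role, collapse = ", ")))
  }
  det <- values[!is.na(values)]
  if (length(det) && (any(det <= 0) || any(det > max_cycles))) {
    abort(sprintf("detected Cq values must lie in (0, %d]", max_cycles))
  }
  if (!is.null(ntc)) {
    ntc <- ntc[colnames(values)]
    names(ntc) <- colnames(values)
  }
  structure(
    list(values = values, roles = roles,
         max_cycles = as.integer(max_cycles), ntc = ntc),
    class = "plq_cq"
  )
}

#' @export
print.plq_cq <- function(x, ...) {
  n_t <- sum(x$roles == "target")
  n_s <- sum(x$roles == "spike_in")
  cat(sprintf("<plq_cq> %d samples x %d assays (%d target, %d spike-in), %d cycles\n",
              nrow(x$values), ncol(x$values), n_t, n_s, x$max_cycles))
  cat(sprintf("  undetected cells: %d (%.1f%%); NTC record: %s\n",
              sum(is.na(x$values)),
              100 * mean(is.na(x$values)),
              if (is.null(x$ntc)) "absent" else "present"))
  invisible(x)
}

#' @export
as_tibble.plq_cq <- function(x, ...) {
  tibble(
    sample_id = rep(rownames(x$values), times = ncol(x$values)),
    assay = rep(colnames(x$values), each = nrow(x$values)),
    role = rep(unname(x$roles), each = nrow(x$values)),
    cq = as.vector(x$values)
  )
}

target_assays <- function(cq) names(cq$roles)[cq$roles == "target"]
spike_in_assays <- function(cq) names(cq$roles)[cq$roles == "spike_in"]

#' Read and write Cq tables
#'
#' Tab-separated dialect matching instrument exports: samples as rows with a
#' leading `sample_id` column, assays as columns, empty cells for undetected
#' reactions. A row with the reserved id `NTC` holds the per-assay
#' no-template-control Cq. Assay metadata (`assay`, `role`, `max_cycles`)
#' travels in a sidecar table.
#'
#' @param path Path of the Cq value table (TSV).
#' @param assay_meta_path Path of the assay metadata table (TSV) with columns
#'   `assay`, `role` (`target` or `spike-in`) and `max_cycles`.
#' @return [read_cq_table()] returns a [cq_table()]; `write_cq_table()`
#'   returns `path` invisibly.
#' @export
read_cq_table <- function(path, assay_meta_path) {
  meta <- utils::read.delim(assay_meta_path, sep = "\t", stringsAsFactors = FALSE,
                            check.names = FALSE)
  need <- c("assay", "role", "max_cycles")
  if (!all(need %in% names(meta))) {
    abort("assay metadata must have columns assay, role, max_cycles")
  }
  role <- gsub("-", "_", meta$role)
  bad <- setdiff(unique(role), c("target", "spike_in"))
  if (length(bad)) abort(paste0("unknown assay role: ", paste(bad, collapse = ", ")))

  raw <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                           check.names = FALSE, colClasses = "character")
  if (names(raw)[1] != "sample_id") abort("first column must be sample_id")
  ids <- raw$sample_id
  if (anyDuplicated(ids)) {
    abort(paste0("duplicated sample id: ", ids[duplicated(ids)][1]))
  }
  assays <- setdiff(names(raw), "sample_id")
  if (anyDuplicated(assays)) abort("duplicated assay identifiers")
  if (!setequal(assays, meta$assay)) {
    abort("assay columns and assay metadata disagree")
  }
  vals <- matrix(NA_real_, length(ids), length(assays),
                 dimnames = list(ids, assays))
  for (a in assays) {
    cell <- trimws(raw[[a]])
    empty <- cell == "" | is.na(cell) | toupper(cell) == "NA"
    num <- suppressWarnings(as.numeric(cell))
    bad <- !empty & is.na(num)
    if (any(bad)) {
      i <- which(bad)[1]
      abort(sprintf("malformed numeric cell at sample '%s', assay '%s': '%s'",
                    ids[i], a, cell[i]))
    }
    vals[, a] <- ifelse(empty, NA_real_, num)
  }
  ntc <- NULL
  if ("NTC" %in% ids) {
    ntc <- vals["NTC", ]
    vals <- vals[setdiff(ids, "NTC"), , drop = FALSE]
  }
  cq_table(vals, roles = setNames(role, meta$assay),
           max_cycles = meta$max_cycles[1], ntc = ntc)
}

#' @rdname read_cq_table
#' @param cq A [cq_table()].
#' @export
write_cq_table <- function(cq, path, assay_meta_path) {
  vals <- cq$values
  if (!is.null(cq$ntc)) vals <- rbind(vals, NTC = cq$ntc)
  df <- data.frame(sample_id = rownames(vals), vals, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  meta <- data.frame(assay = colnames(cq$values),
                     role = gsub("_", "-", unname(cq$roles)),
                     max_cycles = cq$max_cycles)
  utils::write.table(meta, assay_meta_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a patient phenotype table and derive the lipid-rich label
#'
#' Expects a TSV with `sample_id`, `max_lcbi_4mm` and the cardiovascular
#' covariate columns (see [cvd_risk_factors()]). The binary outcome
#' `lipid_rich` is derived as `max_lcbi_4mm >= config$lipid_rich_threshold`
#' (boundary inclusive).
#'
#' @param path TSV path.
#' @param config A [run_config()]; only the threshold is used.
#' @return A tibble with a `lipid_rich` logical column; samples with missing
#'   covariates are flagged in the `n_missing_covariates` column.
#' @export
read_patient_table <- function(path, config = run_config()) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  label_lipid_rich(df, threshold = config$lipid_rich_threshold)
}

#' @rdname read_patient_table
#' @param patients Data frame with `sample_id` and `max_lcbi_4mm` columns.
#' @param threshold Lipid-rich cut-point on maxLCBI4mm.
#' @export
label_lipid_rich <- function(patients, threshold = 324.7) {
  if (!all(c("sample_id", "max_lcbi_4mm") %in% names(patients))) {
    abort("patient table needs sample_id and max_lcbi_4mm columns")
  }
  if (anyDuplicated(patients$sample_id)) abort("duplicated sample id")
  if (any(patients$max_lcbi_4mm < 0, na.rm = TRUE)) {
    abort("max_lcbi_4mm must be nonnegative")
  }
  covars <- intersect(cvd_risk_factors(), names(patients))
  out <- as_tibble(patients)
  out$lipid_rich <- out$max_lcbi_4mm >= threshold
  if (length(covars)) {
    out$n_missing_covariates <-
      rowSums(is.na(out[, covars, drop = FALSE]))
  }
  out
}

#' @export
#' @rdname read_patient_table
write_patient_table <- function(patients, path) {
  utils::write.table(as.data.frame(patients), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Names of the cardiovascular risk-factor covariates
#'
#' The 14 established CVD risk factors entering the extended predictor set:
#' age, body mass index, smoking, medically treated hypertension, diabetes
#' mellitus, hyperlipidemia, heredity of CVD, previous CVD, total
#' cholesterol, LDL-C, HDL-C, triglycerides, the LDL/HDL ratio (derived) and
#' lipoprotein(a).
#'
#' @return Character vector of column names; the ratio column is derived by
#'   [build_design()] and is not expected in input tables.
#' @export
cvd_risk_factors <- function() {
  c("age", "bmi", "smoker", "hypertension", "diabetes", "hyperlipidemia",
    "heredity_cvd", "previous_cvd", "total_cholesterol", "ldl_c", "hdl_c",
    "triglycerides", "ldl_hdl_ratio", "lipoprotein_a")
}
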