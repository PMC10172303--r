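#' Synthetic-cohort configuration
#'
#' Parameters of the generator that emulates the data structure of a
#' dichotomized maxLCBI4mm case-control miRNA panel study: a small cohort,
#' a fixed-content qPCR panel in which a minority of assays sit near the
#' limit of detection, per-sample technical Cq offsets, spike-in and
#' no-template controls, and a small number of planted miR-outcome effects.
#'
#' Defaults reproduce the study conditions of the emulated design: 47
#' patients with lipid-rich prevalence 23/47; group maxLCBI4mm moments
#' 153.0 (91.0) and 427.0 (85.8); 177 target assays of which about 17 sit
#' near the limit of detection and fail an 80% detection filter, leaving
#' about 160.
#'
#' @param n_samples Cohort size.
#' @param n_assays Number of target miRNA assays on the panel.
#' @param n_planted Number of assays given a true group effect.
#' @param planted_shift_cq Cq shift of planted assays in the lipid-rich
#'   group; positive values mean *lower* Cq (higher abundance) in cases.
#' @param group_prevalence Probability a sample is drawn from the lipid-rich
#'   component.
#' @param lcbi_means,lcbi_sds Length-2 numerics: maxLCBI4mm mean/SD for the
#'   (non-lipid-rich, lipid-rich) components; draws are truncated at zero and
#'   the final label is re-derived from the threshold so label and value
#'   always agree.
#' @param lipid_rich_threshold Cut-point used for the re-derived label.
#' @param assay_baseline_range Range (Cq) of per-assay baseline abundances.
#' @param sample_offset_sd SD (Cq) of the per-sample technical offset shared
#'   by all assays of a sample (what global-mean normalization removes).
#' @param noise_sd SD (Cq) of independent per-reaction noise.
#' @param lod_cq Limit of detection: reactions with Cq above this are
#'   reported undetected.
#' @param frac_low_detection Fraction of target assays whose baseline is
#'   placed just above the limit of detection so they fail the detection
#'   filter.
#' @param seed Integer seed for the generator.
#' @return A validated list of class `plq_sim_config`.
#' @export
sim_config <- function(n_samples = 47L,
                       n_assays = 177L,
                       n_planted = 1L,
                       planted_shift_cq = 0.9,
                       group_prevalence = 23 / 47,
                       lcbi_means = c(153.0, 427.0),
                       lcbi_sds = c(91.0, 85.8),
                       lipid_rich_threshold = 324.7,
                       assay_baseline_range = c(22, 35),
                       sample_offset_sd = 0.5,
                       noise_sd = 0.8,
                       lod_cq = 40,
                       frac_low_detection = 17 / 177,
                       seed = 1L) {
  sim <- list(
    n_samples = as.integer(n_samples), n_assays = as.integer(n_assays),
    n_planted = as.integer(n_planted), planted_shift_cq = planted_shift_cq,
    group_prevalence = group_prevalence, lcbi_means = lcbi_means,
    lcbi_sds = lcbi_sds, lipid_rich_threshold = lipid_rich_threshold,
    assay_baseline_range = assay_baseline_range,
    sample_offset_sd = sample_offset_sd, noise_sd = noise_sd,
    lod_cq = lod_cq, frac_low_detection = frac_low_detection,
    seed = as.integer(seed)
  )
  stopifnot(
    sim$n_samples >= 4L, sim$n_assays >= 3L,
    sim$n_planted >= 0L, sim$n_planted <= sim$n_assays,
    sim$group_prevalence > 0, sim$group_prevalence < 1,
    length(sim$lcbi_means) == 2L, length(sim$lcbi_sds) == 2L,
    all(sim$lcbi_sds > 0), sim$lipid_rich_threshold > 0,
    length(sim$assay_baseline_range) == 2L,
    diff(sim$assay_baseline_range) > 0,
    sim$sample_offset_sd >= 0, sim$noise_sd > 0,
    sim$lod_cq > sim$assay_baseline_range[2],
    sim$frac_low_detection >= 0, sim$frac_low_detection < 1
  )
  structure(sim, class = "plq_sim_config")
}

# Pooled Table-1-style marginals used for independently drawn covariates:
# binary as prevalence, continuous as mean/sd (truncated at a floor where a
# positive value is structurally required, e.g. HDL for the LDL/HDL ratio).
covariate_marginals <- function() {
  list(
    binary = c(smoker = 30 / 47, hypertension = 25 / 47, diabetes = 5 / 47,
               hyperlipidemia = 15 / 47, heredity_cvd = 40 / 46,
               previous_cvd = 23 / 47),
    continuous = tibble(
      variable = c("age", "bmi", "total_cholesterol", "ldl_c", "hdl_c",
                   "triglycerides", "lipoprotein_a"),
      mean = c(58, 28.8, 3.8, 2.2, 1.0, 1.5, 450),
      sd = c(7.4, 3.7, 0.85, 0.75, 0.25, 0.75, 500),
      floor = c(30, 16, 1, 0.3, 0.3, 0.2, 0)
    )
  )
}

rnorm_trunc <- function(n, mean, sd, lower) {
  x <- rnorm(n, mean, sd)
  while (any(bad <- x < lower)) {
    x[bad] <- rnorm(sum(bad), mean, sd)
  }
  x
}

#' Simulate a Cq table and patient table with known ground truth
#'
#' Draws group membership, maxLCBI4mm from per-group zero-truncated normals
#' (re-labelled by the threshold so labels and values are always consistent),
#' covariates from marginal distributions, and a Cq matrix
#' `Cq(i,j) = a_j + b_i + delta_j * g_i + eps` with assay baselines `a_j`,
#' sample offsets `b_i`, planted case shifts `delta_j = -planted_shift_cq`
#' and reaction noise. Cells above the limit of detection are undetected; a
#' configured fraction of assays is placed near the limit so they fail the
#' detection filter. Five spike-in assays are near-constant and the NTC
#' record sits at the maximum cycle count.
#'
#' @param sim A [sim_config()].
#' @return A list of class `plq_cohort` with elements `cq` ([cq_table()]),
#'   `patients` (tibble), and `truth` (planted assays with their Cq shifts,
#'   per-sample offsets, and the redraw count).
#' @examples
#' coh <- simulate_cohort(sim_config(seed = 42))
#' coh$truth$planted
#' @export
simulate_cohort <- function(sim = sim_config()) {
  with_stream_seed(sim$seed, "cohort", {
    n <- sim$n_samples
    p <- sim$n_assays
    ids <- sprintf("S%03d", seq_len(n))

    # group draw with redraw-on-degeneracy (both classes required downstream)
    redraws <- 0L
    repeat {
      g0 <- rbinom(n, 1, sim$group_prevalence)
      lcbi <- numeric(n)
      for (k in 0:1) {
        idx <- which(g0 == k)
        if (length(idx)) {
          lcbi[idx] <- rnorm_trunc(length(idx), sim$lcbi_means[k + 1],
                                   sim$lcbi_sds[k + 1], lower = 0)
        }
      }
      g <- as.integer(lcbi >= sim$lipid_rich_threshold)
      if (length(unique(g)) == 2L) break
      redraws <- redraws + 1L
      if (redraws > 100L) abort("degenerate simulation: one outcome class")
    }

    hemo_pair <- c("hsa-miR-23a-3p", "hsa-miR-451a")
    n_generic <- p - length(hemo_pair)
    assays <- c(hemo_pair, sprintf("hsa-miR-sim-%03d", seq_len(n_generic)))
    generic <- setdiff(assays, hemo_pair)

    baselines <- setNames(runif(p, sim$assay_baseline_range[1],
                                sim$assay_baseline_range[2]), assays)
    baselines[hemo_pair] <- c(24, 23)

    n_low <- round(sim$frac_low_detection * p)
    planted <- if (sim$n_planted > 0) {
      sample(generic, sim$n_planted)
    } else character(0)
    low_pool <- setdiff(generic, planted)
    low_det <- if (n_low > 0) sample(low_pool, min(n_low, length(low_pool))) else character(0)
    baselines[low_det] <- runif(length(low_det), sim$lod_cq + 0.5, sim$lod_cq + 2)

    delta <- setNames(rep(0, p), assays)
    delta[planted] <- -sim$planted_shift_cq

    b <- rnorm(n, 0, sim$sample_offset_sd)
    eps <- matrix(rnorm(n * p, 0, sim$noise_sd), n, p)
    cqv <- outer(b, baselines, `+`) + outer(g, delta) + eps
    dimnames(cqv) <- list(ids, assays)
    cqv[cqv > sim$lod_cq] <- NA_real_

    # spike-ins: near-constant controls, far below the limit of detection
    spikes <- c(UniSp2 = 19, UniSp4 = 24, UniSp5 = 28, UniSp3 = 20, UniSp6 = 21)
    spv <- sapply(spikes, function(m) m + rnorm(n, 0, 0.15))
    dimnames(spv) <- list(ids, names(spikes))
    vals <- cbind(cqv, spv)
    roles <- setNames(c(rep("target", p), rep("spike_in", length(spikes))),
                      colnames(vals))
    max_cycles <- 45L
    ntc <- setNames(rep(max_cycles, ncol(vals)), colnames(vals))
    cq <- cq_table(vals, roles = roles, max_cycles = max_cycles, ntc = ntc)

    marg <- covariate_marginals()
    patients <- tibble(sample_id = ids, max_lcbi_4mm = lcbi)
    for (v in names(marg$binary)) {
      patients[[v]] <- rbinom(n, 1, marg$binary[[v]])
    }
    for (i in seq_len(nrow(marg$continuous))) {
      row <- marg$continuous[i, ]
      patients[[row$variable]] <- rnorm_trunc(n, row$mean, row$sd, row$floor)
    }
    patients <- label_lipid_rich(patients,
                                 threshold = sim$lipid_rich_threshold)

    truth <- list(
      planted = tibble(assay = planted,
                       delta_cq = unname(delta[planted])),
      sample_offset = tibble(sample_id = ids, offset = b),
      low_detection_assays = low_det,
      group = setNames(g, ids),
      redraws = redraws
    )
    structure(list(cq = cq, patients = patients, truth = truth, sim = sim),
              class = "plq_cohort")
  })
}

#' @export
print.plq_cohort <- function(x, ...) {
  cat(sprintf("<plq_cohort> %d samples, %d target assays, %d planted effect(s)\n",
              nrow(x$cq$values), sum(x$cq$roles == "target"),
              nrow(x$truth$planted)))
  cat(sprintf("  lipid-rich: %d / %d\n", sum(x$patients$lipid_rich),
              nrow(x$patients)))
  invisible(x)
}

#' Calibrate the planted Cq shift to a target odds ratio
#'
#' Under the equal-variance two-class Gaussian model the logistic
#' coefficient of a single predictor is `beta = delta / sigma^2`, where
#' `delta` is the between-group mean shift and `sigma^2` the within-group
#' variance on the normalized scale (here `noise_sd^2`, since sample offsets
#' cancel under global-mean normalization). The planted shift achieving a
#' per-unit odds ratio `target_or` is therefore `log(target_or) * sigma^2`.
#'
#' @param sim A [sim_config()].
#' @param target_or Target per-unit odds ratio (> 0) of the planted assay on
#'   the normalized scale.
#' @return The updated `sim_config` with `planted_shift_cq` set.
#' @examples
#' plant_effect_or(sim_config(noise_sd = 1), 1.18)$planted_shift_cq # ~0.1655
#' @export
plant_effect_or <- function(sim, target_or) {
  if (!is.numeric(target_or) || length(target_or) != 1L || target_or <= 0) {
    abort("`target_or` must be a single positive number")
  }
  sim$planted_shift_cq <- log(target_or) * sim$noise_sd^2
  sim
}

#' Write a simulated cohort to delimited files
#'
#' Emits the same dialects the readers consume: `cq.tsv` + `assay_meta.tsv`
#' ([read_cq_table()]), `patients.tsv` ([read_patient_table()]) and the
#' ground truth as `ground_truth.tsv`.
#'
#' @param cohort A `plq_cohort` from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_cq_table(cohort$cq, file.path(dir, "cq.tsv"),
                 file.path(dir, "assay_meta.tsv"))
  write_patient_table(cohort$patients, file.path(dir, "patients.tsv"))
  utils::write.table(as.data.frame(cohort$truth$planted),
                     file.path(dir, "ground_truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
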