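# Synthetic IC-level EEG: spectrally shaped 1/f background plus alpha and
# beta carriers whose amplitude is suppressed around the button press.

# One epoch of 1/f background noise, shaped in the frequency domain so the
# one-sided PSD density equals 10^b * f^(-chi) (log10 power b at 1 Hz).
shaped_noise <- function(n, fs, b, chi) {
  half <- n %/% 2L
  f <- (1:(half - 1L)) * fs / n
  s <- 10^b * f^(-chi)
  amp <- sqrt(s * fs * n / 2)
  z <- complex(real = stats::rnorm(half - 1L), imaginary = stats::rnorm(half - 1L)) /
    sqrt(2)
  X <- complex(length.out = n)
  X[2:half] <- amp * z
  X[n:(n - half + 2L)] <- Conj(X[2:half])
  Re(stats::fft(X, inverse = TRUE)) / n
}

# Gaussian-in-time multiplicative suppression envelope:
# 1 - d * exp(-(t - t0)^2 / (2 sigma^2)); power ratio (1-d)^2 at trough.
erd_envelope <- function(t_ms, depth, center_ms, width_ms) {
  1 - depth * exp(-(t_ms - center_ms)^2 / (2 * width_ms^2))
}

#' Simulate IC activation epochs for one participant and condition
#'
#' Each trial is spectrally shaped 1/f noise with the participant's
#' aperiodic offset and exponent, plus alpha (~10 Hz) and beta (~21 Hz)
#' sinusoids with random phase. Each oscillation is amplitude-modulated by
#' a Gaussian-in-time suppression of fractional depth `erd_depth` centered
#' at `response_time + erd_center_ms`, so the planted power ratio at the
#' trough is `(1 - depth)^2`. Response times are drawn from a normal
#' distribution truncated to [100, 1000] ms. Identical `(spec, seed)`
#' yield bit-identical output.
#'
#' @param spec A [participant_spec()].
#' @param design A [make_design()] design.
#' @param condition Condition label present in `spec$cond`.
#' @param seed Integer seed.
#' @param n_trials Trial count; defaults to the design's per-condition
#'   count.
#' @param scale_amp Multiplier applied to both band amplitudes (used for
#'   non-motor "scatter" ICs).
#' @param zero_erd If `TRUE`, suppression depths are forced to zero.
#' @return An object of class `ic_epochs`: `data` (trials x samples),
#'   `times_ms`, `rt_ms`, `srate_hz`.
#' @export
simulate_ic_epochs <- function(spec, design, condition, seed,
                               n_trials = NULL, scale_amp = 1,
                               zero_erd = FALSE) {
  stopifnot(inherits(spec, "participant_spec"), inherits(design, "study_design"))
  if (!condition %in% names(spec$cond))
    stop("unknown condition: ", condition)
  if (design$srate_hz < 250) stop("srate must be >= 250 Hz")
  p <- spec$cond[[condition]]
  da <- if (zero_erd) 0 else p$alpha_erd_depth
  db <- if (zero_erd) 0 else p$beta_erd_depth
  if (da < 0 || da >= 1 || db < 0 || db >= 1)
    stop("erd_depth must lie in [0, 1)")
  span <- design$epoch_span_ms
  fs <- design$srate_hz
  t_ms <- seq(span[1], span[2] - 1000 / fs, by = 1000 / fs)
  n <- length(t_ms)
  n_trials <- n_trials %||% trials_per_condition(design)
  # the ERD trough must fall inside the epoch even for late responses
  if (1000 + max(p$alpha_center_ms, p$beta_center_ms) > span[2])
    stop("epoch too short for the ERD time course")

  with_seed(seed, {
    rt <- rtruncnorm(n_trials, spec$rt_mean_ms, spec$rt_sd_ms, 100, 1000)
    dat <- matrix(0, n_trials, n)
    for (i in seq_len(n_trials)) {
      x <- shaped_noise(n, fs, p$aperiodic_offset, p$aperiodic_exponent)
      pha <- stats::runif(2, 0, 2 * pi)
      env_a <- erd_envelope(t_ms, da, rt[i] + p$alpha_center_ms, p$alpha_width_ms)
      env_b <- erd_envelope(t_ms, db, rt[i] + p$beta_center_ms, p$beta_width_ms)
      x <- x +
        scale_amp * p$alpha_amp * env_a *
          cos(2 * pi * spec$alpha_freq_hz * t_ms / 1000 + pha[1]) +
        scale_amp * p$beta_amp * env_b *
          cos(2 * pi * spec$beta_freq_hz * t_ms / 1000 + pha[2])
      dat[i, ] <- x
    }
    structure(
      list(data = dat, times_ms = t_ms, rt_ms = rt, srate_hz = fs,
           participant = spec$id, condition = condition),
      class = "ic_epochs"
    )
  })
}

#' @export
print.ic_epochs <- function(x, ...) {
  cat(sprintf("IC epochs: %d trials x %d samples @ %g Hz (%s, %s)\n",
              nrow(x$data), ncol(x$data), x$srate_hz,
              x$participant %||% "?", x$condition %||% "?"))
  cat(sprintf("  time %g..%g ms; RT %.0f +- %.0f ms\n",
              min(x$times_ms), max(x$times_ms), mean(x$rt_ms),
              stats::sd(x$rt_ms)))
  invisible(x)
}

# Dipole scattered uniformly in a whole-head Talairach box, rejected while
# closer than `min_dist` mm to either ROI.
scatter_dipole <- function(roi_left, roi_right, min_dist = 30) {
  repeat {
    xyz <- c(stats::runif(1, -70, 70), stats::runif(1, -100, 70),
             stats::runif(1, -45, 80))
    if (sqrt(sum((xyz - roi_left)^2)) >= min_dist &&
        sqrt(sum((xyz - roi_right)^2)) >= min_dist)
      return(xyz)
  }
}

#' Simulate a full synthetic cohort
#'
#' Draws participant specifications for two age groups, places one
#' equivalent dipole per hemisphere in a spherical cloud around the left
#' (-33, -10, 49) and right (38, -7, 48) Talairach motor ROIs plus a
#' configurable number of far-off non-motor ("scatter") ICs, simulates
#' IC-level epochs per condition, and generates the behavioral table with
#' walking-speed dual-task costs negatively coupled to each participant's
#' planted desynchronization dual-task cost.
#'
#' @param n_per_group Participants per age group (>= 2).
#' @param config An [effect_config()].
#' @param design A [make_design()] design.
#' @param seed Integer master seed.
#' @param spread_mm SD of the ROI dipole cloud, mm.
#' @param n_scatter_ics Scatter ICs per participant (no planted ERD).
#' @param outlier_frac Fraction of ROI ICs displaced 40-80 mm from their
#'   ROI ("designated outliers"; flagged in the output).
#' @param simulate_epochs If `FALSE`, only geometry, specs and behavioral
#'   tables are generated (fast path for clustering and statistics tests).
#' @param n_trials Per-condition trial count override.
#' @return A list of class `cohort`: `ics` (list of IC records), `specs`,
#'   `behavior` (one row per participant), `truth` (one row per
#'   participant x condition), `design`, `config`, `roi_left`, `roi_right`.
#' @export
simulate_cohort <- function(n_per_group = 15L,
                            config = effect_config(),
                            design = make_design(n_per_group = n_per_group),
                            seed = 1L,
                            spread_mm = 6,
                            n_scatter_ics = 1L,
                            outlier_frac = 0,
                            simulate_epochs = TRUE,
                            n_trials = NULL) {
  if (n_per_group < 2) stop("n_per_group must be >= 2")
  roi_left <- c(-33, -10, 49)
  roi_right <- c(38, -7, 48)
  with_seed(seed, {
    groups <- rep(c("young", "old"), each = n_per_group)
    ids <- sprintf("P%02d", seq_along(groups))
    specs <- lapply(seq_along(ids), function(i)
      participant_spec(ids[i], groups[i], design, config))
    names(specs) <- ids

    # nominal planted desynchronization dual-task cost implied by the
    # configured cell means, used to center the speed-cost coupling
    nominal_cost <- function(db_sit, db_walk) (db_sit - db_walk) / db_sit * 100
    center_cost <- mean(c(
      nominal_cost(config$ersp_alpha_db[["sitting"]],
                   config$ersp_alpha_db[["walking"]]),
      nominal_cost(config$ersp_beta_db[["sitting"]] + config$beta_age_shift_db,
                   config$ersp_beta_db[["walking"]] + config$beta_age_shift_db)))

    ics <- list()
    behavior <- NULL
    truth <- NULL
    ic_seq <- 0L
    for (i in seq_along(ids)) {
      sp <- specs[[i]]
      # planted desynchronization dual-task cost (mean of both bands)
      has_sw <- all(c("sitting", "walking") %in% design$conditions)
      desync_cost <- if (has_sw) {
        mean(c(nominal_cost(sp$cond$sitting$alpha_db_planted,
                            sp$cond$walking$alpha_db_planted),
               nominal_cost(sp$cond$sitting$beta_db_planted,
                            sp$cond$walking$beta_db_planted)))
      } else NA_real_
      speed_cost <- config$speed_cost_group[[sp$age_group]] +
        (if (has_sw) config$coupling_slope * (desync_cost - center_cost) else 0) +
        stats::rnorm(1, 0, config$coupling_noise_sd)
      dual_speed <- max(0.2, sp$baseline_walk_speed * (1 - speed_cost / 100))
      behavior <- rbind(behavior, data.frame(
        participant = sp$id, age_group = sp$age_group,
        rt_mean_ms = sp$rt_mean_ms,
        baseline_walk_speed = sp$baseline_walk_speed,
        dualtask_walk_speed = dual_speed,
        speed_cost_pct = speed_cost,
        planted_desync_cost_pct = desync_cost,
        stringsAsFactors = FALSE))
      for (cn in design$conditions) {
        p <- sp$cond[[cn]]
        truth <- rbind(truth, data.frame(
          participant = sp$id, age_group = sp$age_group, condition = cn,
          alpha_db = p$alpha_db_planted, beta_db = p$beta_db_planted,
          alpha_depth = p$alpha_erd_depth, beta_depth = p$beta_erd_depth,
          offset = p$aperiodic_offset, exponent = p$aperiodic_exponent,
          alpha_amp = p$alpha_amp, beta_amp = p$beta_amp,
          alpha_freq_hz = sp$alpha_freq_hz, beta_freq_hz = sp$beta_freq_hz,
          stringsAsFactors = FALSE))
      }

      rois <- list(left = roi_left, right = roi_right)
      for (side in names(rois)) {
        ic_seq <- ic_seq + 1L
        is_out <- stats::runif(1) < outlier_frac
        xyz <- if (is_out) {
          u <- stats::rnorm(3)
          rois[[side]] + u / sqrt(sum(u^2)) * stats::runif(1, 40, 80)
        } else {
          rois[[side]] + stats::rnorm(3, 0, spread_mm)
        }
        ics[[ic_seq]] <- list(
          ic_id = sprintf("IC%03d", ic_seq), participant = sp$id,
          age_group = sp$age_group,
          hemisphere = if (xyz[1] < 0) "left" else "right",
          dipole_xyz = xyz, residual_variance = stats::runif(1, 0.02, 0.10),
          roi = side, designated_outlier = is_out,
          epochs = NULL)
      }
      for (k in seq_len(n_scatter_ics)) {
        ic_seq <- ic_seq + 1L
        xyz <- scatter_dipole(roi_left, roi_right)
        ics[[ic_seq]] <- list(
          ic_id = sprintf("IC%03d", ic_seq), participant = sp$id,
          age_group = sp$age_group,
          hemisphere = if (xyz[1] < 0) "left" else "right",
          dipole_xyz = xyz, residual_variance = stats::runif(1, 0.05, 0.25),
          roi = "none", designated_outlier = FALSE,
          epochs = NULL)
      }
    }

    if (simulate_epochs) {
      for (j in seq_along(ics)) {
        sp <- specs[[ics[[j]]$participant]]
        eps <- lapply(design$conditions, function(cn)
          simulate_ic_epochs(
            sp, design, cn,
            seed = derive_seed(seed, j * 131L + match(cn, design$conditions)),
            n_trials = n_trials,
            scale_amp = if (ics[[j]]$roi == "none") 0.4 else 1,
            zero_erd = ics[[j]]$roi == "none"))
        names(eps) <- design$conditions
        ics[[j]]$epochs <- eps
      }
    }

    structure(
      list(ics = ics, specs = specs, behavior = behavior, truth = truth,
           design = design, config = config,
           roi_left = roi_left, roi_right = roi_right, seed = seed),
      class = "cohort"
    )
  })
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d participants (%d ICs), conditions: %s\n",
              nrow(x$behavior), length(x$ics),
              paste(x$design$conditions, collapse = ", ")))
  cat(sprintf("  epochs simulated: %s\n",
              if (is.null(x$ics[[1]]$epochs)) "no" else "yes"))
  invisible(x)
}

#' Write a cohort to a directory container
#'
#' Plain directory layout: `behavior.tsv` and `truth.tsv` (tab-separated,
#' header row), `design.json`, and one serialized record per IC under
#' `ics/` holding epochs per condition with sampling rate and event
#' latencies.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort"))
  dir.create(file.path(dir, "ics"), recursive = TRUE, showWarnings = FALSE)
  utils::write.table(cohort$behavior, file.path(dir, "behavior.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(cohort$truth, file.path(dir, "truth.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(unclass(cohort$design), file.path(dir, "design.json"),
                       auto_unbox = TRUE, digits = NA)
  for (ic in cohort$ics)
    saveRDS(ic, file.path(dir, "ics", paste0(ic$ic_id, ".rds")))
  saveRDS(cohort[c("specs", "config", "roi_left", "roi_right", "seed")],
          file.path(dir, "meta.rds"))
  invisible(dir)
}

#' Read a cohort container written by [write_cohort()]
#'
#' @param dir Container directory.
#' @return A `cohort` object.
#' @export
read_cohort <- function(dir) {
  meta <- readRDS(file.path(dir, "meta.rds"))
  dj <- jsonlite::read_json(file.path(dir, "design.json"), simplifyVector = TRUE)
  design <- make_design(dj$n_per_group, dj$conditions, dj$angles_deg,
                        dj$hemifields, dj$trials_per_cell, dj$epoch_span_ms,
                        dj$srate_hz)
  files <- sort(list.files(file.path(dir, "ics"), full.names = TRUE))
  structure(
    list(ics = lapply(files, readRDS), specs = meta$specs,
         behavior = utils::read.delim(file.path(dir, "behavior.tsv")),
         truth = utils::read.delim(file.path(dir, "truth.tsv")),
         design = design, config = meta$config,
         roi_left = meta$roi_left, roi_right = meta$roi_right,
         seed = meta$seed),
    class = "cohort"
  )
}
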