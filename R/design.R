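#' Define the factorial study design
#'
#' Encodes the experimental layout the pipeline assumes: visual stimuli at
#' three eccentricities in two hemifields, repeated under each motor
#' condition, with fixed-length epochs around stimulus onset. The default
#' values reproduce the study layout: 100 stimuli per eccentricity and
#' hemifield in each of sitting, standing and walking (1800 events in
#' total), 2.5 s epochs starting 1000 ms before stimulus onset.
#'
#' @param n_per_group Participants per age group (young, old).
#' @param conditions Ordered motor-condition labels.
#' @param angles_deg Stimulus eccentricities in degrees.
#' @param hemifields Stimulus hemifields.
#' @param trials_per_cell Stimuli per angle x hemifield x condition cell.
#' @param epoch_span_ms Epoch limits in ms relative to stimulus onset.
#' @param srate_hz Sampling rate of the IC activations, Hz.
#' @return An object of class `study_design`.
#' @examples
#' d <- make_design()
#' total_events(d) # 1800
#' @export
make_design <- function(n_per_group = 15L,
                        conditions = c("sitting", "standing", "walking"),
                        angles_deg = c(20, 40, 60),
                        hemifields = c("left", "right"),
                        trials_per_cell = 100L,
                        epoch_span_ms = c(-1000, 1500),
                        srate_hz = 250) {
  if (length(conditions) < 1L) stop("condition list must be non-empty")
  if (!is.numeric(trials_per_cell) || trials_per_cell < 1)
    stop("invalid design: trials_per_cell must be >= 1")
  if (n_per_group < 1) stop("invalid design: n_per_group must be >= 1")
  if (length(epoch_span_ms) != 2L || diff(epoch_span_ms) <= 0)
    stop("invalid design: epoch_span_ms must be increasing length-2")
  # epoch must contain the pre-response baseline and the warp target RT
  if (epoch_span_ms[1] > -300 || epoch_span_ms[2] < 356)
    stop("invalid design: epoch must cover the -300:-100 ms baseline and 356 ms RT")
  if (srate_hz < 250) stop("invalid design: srate_hz must be >= 250")
  structure(
    list(
      n_per_group = as.integer(n_per_group),
      conditions = conditions,
      angles_deg = angles_deg,
      hemifields = hemifields,
      trials_per_cell = as.integer(trials_per_cell),
      epoch_span_ms = as.numeric(epoch_span_ms),
      srate_hz = srate_hz
    ),
    class = "study_design"
  )
}

#' Total number of stimulus events in a design
#'
#' Product of trials per cell, eccentricities, hemifields and motor
#' conditions.
#'
#' @param design A `study_design`.
#' @return Integer event count.
#' @export
total_events <- function(design) {
  stopifnot(inherits(design, "study_design"))
  design$trials_per_cell * length(design$angles_deg) *
    length(design$hemifields) * length(design$conditions)
}

# Trials per motor condition (all angles x hemifields pooled).
trials_per_condition <- function(design) {
  design$trials_per_cell * length(design$angles_deg) * length(design$hemifields)
}

#' @export
print.study_design <- function(x, ...) {
  cat("Study design:", x$n_per_group, "participants/group;",
      paste(x$conditions, collapse = ", "), "\n")
  cat("  ", x$trials_per_cell, "trials x", length(x$angles_deg), "angles x",
      length(x$hemifields), "hemifields x", length(x$conditions),
      "conditions =", total_events(x), "events\n")
  cat("  epoch", x$epoch_span_ms[1], "..", x$epoch_span_ms[2], "ms @",
      x$srate_hz, "Hz\n")
  invisible(x)
}

#' Planted effect configuration for the synthetic cohort
#'
#' Ground-truth group/condition structure the generator plants, expressed
#' as cell means of the quantities the pipeline later recovers. Defaults
#' are anchored to the study's printed group and condition means and point
#' in the reported effect directions: deeper beta desynchronization and a
#' higher beta power baseline in the older group, deeper desynchronization
#' in both bands while sitting than walking, a higher aperiodic offset
#' while walking, no exponent effects, and a negative coupling between
#' desynchronization dual-task costs and walking-speed dual-task costs.
#'
#' Suppression cell means are in dB of trough power relative to baseline
#' (negative = desynchronization); amplitudes are oscillation amplitudes in
#' arbitrary units; offsets are log10 power at 1 Hz.
#'
#' @param ersp_alpha_db Named condition means of planted alpha trough dB.
#' @param ersp_beta_db Named condition means of planted beta trough dB.
#' @param beta_age_shift_db Additive old/young shifts applied to
#'   `ersp_beta_db` (deeper for old by default).
#' @param alpha_amp Named condition means of baseline alpha amplitude.
#' @param beta_amp_group Named old/young means of baseline beta amplitude.
#' @param offset Named condition means of the aperiodic offset.
#' @param exponent Mean aperiodic exponent (no planted effects).
#' @param sd Dispersion parameters (participant intercepts and
#'   per-condition idiosyncratic noise); see the methods vignette.
#' @param coupling_slope Slope of walking-speed cost on desynchronization
#'   cost (% per %, negative).
#' @param coupling_noise_sd SD of the speed-cost residual, percent points.
#' @param speed_cost_group Mean walking-speed dual-task cost per group, %.
#' @param alpha_center_ms,beta_center_ms ERD trough center relative to the
#'   button press, ms (356 + 22 = 378 ms and 356 + 206 = 562 ms after
#'   stimulus onset).
#' @param alpha_width_ms,beta_width_ms Gaussian SD of the ERD envelope, ms.
#' @param alpha_freq_hz,beta_freq_hz Population mean carrier frequencies.
#' @param alpha_freq_sd,beta_freq_sd Per-participant carrier jitter SD, Hz.
#' @return A list of class `effect_config`.
#' @seealso [zero_effects()] for a null configuration.
#' @export
effect_config <- function(
    ersp_alpha_db = c(sitting = -2.85, standing = -2.10, walking = -1.40),
    ersp_beta_db = c(sitting = -4.80, standing = -3.85, walking = -2.90),
    beta_age_shift_db = c(young = 1.20, old = -1.20),
    alpha_amp = c(sitting = 1.20, standing = 1.05, walking = 0.90),
    beta_amp_group = c(young = 0.55, old = 0.95),
    offset = c(sitting = -0.98, standing = -0.92, walking = -0.86),
    exponent = 1.0,
    sd = list(erd_subject_db = 0.50, erd_cond_db = 0.60,
              amp_subject_log10 = 0.08, amp_cond_log10 = 0.04,
              offset_subject = 0.30, offset_cond = 0.04,
              exponent_subject = 0.12, exponent_cond = 0.03,
              rt_subject_ms = 25, rt_trial_ms = 80,
              speed_subject = 0.12),
    coupling_slope = -0.5,
    coupling_noise_sd = 5,
    speed_cost_group = c(young = 2, old = 9),
    alpha_center_ms = 22, beta_center_ms = 206,
    alpha_width_ms = 150, beta_width_ms = 200,
    alpha_freq_hz = 10.5, beta_freq_hz = 21.0,
    alpha_freq_sd = 1, beta_freq_sd = 2) {
  cfg <- as.list(environment())
  class(cfg) <- "effect_config"
  cfg
}

#' Null effect configuration
#'
#' All condition and group differences removed (cell means collapsed to
#' their grand means, coupling slope zero). Per-participant dispersion is
#' retained, so measures are exchangeable across groups and conditions:
#' under this configuration every test in the statistics layer operates at
#' its nominal type-I level.
#'
#' @param ... Overrides forwarded to [effect_config()].
#' @return An `effect_config`.
#' @export
zero_effects <- function(...) {
  cfg <- effect_config(...)
  flat <- function(x) {
    x[] <- mean(x)
    x
  }
  cfg$ersp_alpha_db <- flat(cfg$ersp_alpha_db)
  cfg$ersp_beta_db <- flat(cfg$ersp_beta_db)
  cfg$beta_age_shift_db <- flat(cfg$beta_age_shift_db) * 0
  cfg$alpha_amp <- flat(cfg$alpha_amp)
  cfg$beta_amp_group <- flat(cfg$beta_amp_group)
  cfg$offset <- flat(cfg$offset)
  cfg$speed_cost_group <- flat(cfg$speed_cost_group)
  cfg$coupling_slope <- 0
  cfg
}

# dB of trough power relative to baseline -> fractional amplitude depth d,
# using the envelope power law (1 - d)^2 at the trough.
db_to_depth <- function(db) {
  d <- 1 - 10^(db / 20)
  pmin(pmax(d, 0), 0.95)
}

#' Draw a participant specification
#'
#' Samples one participant's ground-truth parameters (per condition:
#' aperiodic offset/exponent, band amplitudes, ERD depths and time course,
#' response-time distribution, walking speeds) from an effect
#' configuration. Uses the caller's RNG stream.
#'
#' @param id Participant identifier.
#' @param age_group `"young"` or `"old"`.
#' @param design A `study_design`.
#' @param config An [effect_config()].
#' @return A list of class `participant_spec` with one `$cond[[condition]]`
#'   entry per condition.
#' @export
participant_spec <- function(id, age_group, design, config = effect_config()) {
  stopifnot(age_group %in% c("young", "old"))
  sd <- config$sd
  # participant-level intercepts, shared across conditions
  erd_a_int <- stats::rnorm(1, 0, sd$erd_subject_db)
  erd_b_int <- stats::rnorm(1, 0, sd$erd_subject_db)
  amp_a_int <- stats::rnorm(1, 0, sd$amp_subject_log10)
  amp_b_int <- stats::rnorm(1, 0, sd$amp_subject_log10)
  off_int <- stats::rnorm(1, 0, sd$offset_subject)
  chi_int <- stats::rnorm(1, 0, sd$exponent_subject)
  f_alpha <- stats::rnorm(1, config$alpha_freq_hz, config$alpha_freq_sd)
  f_beta <- stats::rnorm(1, config$beta_freq_hz, config$beta_freq_sd)
  rt_mean <- stats::rnorm(1, 356, sd$rt_subject_ms)
  base_speed <- max(0.4, stats::rnorm(
    1, if (age_group == "young") 1.35 else 1.20, sd$speed_subject))

  cond <- lapply(design$conditions, function(cn) {
    a_db <- config$ersp_alpha_db[[cn]] + erd_a_int +
      stats::rnorm(1, 0, sd$erd_cond_db)
    b_db <- config$ersp_beta_db[[cn]] + config$beta_age_shift_db[[age_group]] +
      erd_b_int + stats::rnorm(1, 0, sd$erd_cond_db)
    a_db <- min(a_db, -0.3)
    b_db <- min(b_db, -0.3)
    list(
      aperiodic_offset = config$offset[[cn]] + off_int +
        stats::rnorm(1, 0, sd$offset_cond),
      aperiodic_exponent = max(0, config$exponent + chi_int +
                                 stats::rnorm(1, 0, sd$exponent_cond)),
      alpha_amp = config$alpha_amp[[cn]] *
        10^(amp_a_int + stats::rnorm(1, 0, sd$amp_cond_log10)),
      beta_amp = config$beta_amp_group[[age_group]] *
        10^(amp_b_int + stats::rnorm(1, 0, sd$amp_cond_log10)),
      alpha_erd_depth = db_to_depth(a_db),
      beta_erd_depth = db_to_depth(b_db),
      alpha_db_planted = a_db,
      beta_db_planted = b_db,
      alpha_center_ms = config$alpha_center_ms,
      beta_center_ms = config$beta_center_ms,
      alpha_width_ms = config$alpha_width_ms,
      beta_width_ms = config$beta_width_ms
    )
  })
  names(cond) <- design$conditions
  structure(
    list(id = id, age_group = age_group,
         alpha_freq_hz = f_alpha, beta_freq_hz = f_beta,
         rt_mean_ms = rt_mean, rt_sd_ms = sd$rt_trial_ms,
         baseline_walk_speed = base_speed,
         cond = cond),
    class = "participant_spec"
  )
}

#' @export
print.participant_spec <- function(x, ...) {
  cat("Participant", x$id, sprintf("(%s): alpha %.1f Hz, beta %.1f Hz, RT %.0f ms\n",
                                   x$age_group, x$alpha_freq_hz, x$beta_freq_hz,
                                   x$rt_mean_ms))
  for (cn in names(x$cond)) {
    p <- x$cond[[cn]]
    cat(sprintf("  %-9s offset %+.2f chi %.2f  alpha %.2f dB  beta %.2f dB\n",
                cn, p$aperiodic_offset, p$aperiodic_exponent,
                p$alpha_db_planted, p$beta_db_planted))
  }
  invisible(x)
}
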