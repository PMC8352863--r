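# Shared fixtures: tiny designs, deterministic participant specs, and
# hand-built TF/ERSP objects for oracle tests.

quick_design <- function(trials_per_cell = 2L,
                         conditions = c("sitting", "walking"), ...) {
  make_design(trials_per_cell = trials_per_cell, conditions = conditions, ...)
}

quick_spec <- function(seed = 1L, age_group = "old",
                       config = effect_config()) {
  set.seed(seed)
  participant_spec("Pfix", age_group, make_design(), config)
}

# participant spec with a strong, deterministic beta carrier and a known
# planted suppression depth: the ERD-calibration fixture
calibration_spec <- function(beta_db = 10 * log10(0.5)) {
  sp <- quick_spec(seed = 3)
  sp$beta_freq_hz <- 21
  sp$alpha_freq_hz <- 10.5
  sp$rt_sd_ms <- 80
  sp$cond$sitting <- modifyList(sp$cond$sitting, list(
    beta_amp = 2.0, alpha_amp = 1.0,
    beta_erd_depth = 1 - 10^(beta_db / 20),
    alpha_erd_depth = 0.3,
    beta_center_ms = 206, beta_width_ms = 275,
    alpha_center_ms = 22, alpha_width_ms = 150,
    aperiodic_offset = -1, aperiodic_exponent = 1))
  sp
}

# minimal tf_map built by hand: power (trials x freqs x times), all valid
make_tf <- function(power, times_ms, grid = NULL, rt_ms = NULL) {
  if (is.null(grid)) {
    nf <- dim(power)[2]
    grid <- make_freq_grid(n = max(nf, 2L))
    grid$freqs_hz <- grid$freqs_hz[seq_len(nf)]
    grid$cycles <- grid$cycles[seq_len(nf)]
  }
  structure(
    list(power = power, valid = array(TRUE, dim(power)),
         times_ms = times_ms,
         rt_ms = rt_ms %||% rep(356, dim(power)[1]), grid = grid),
    class = "tf_map")
}

# minimal ersp built by hand on an arbitrary grid
make_test_ersp <- function(db, times_ms, freqs_hz = NULL) {
  grid <- make_freq_grid()
  if (!is.null(freqs_hz)) {
    grid$freqs_hz <- freqs_hz
    grid$cycles <- rep(7, length(freqs_hz))
  }
  stopifnot(nrow(db) == length(grid$freqs_hz))
  structure(
    list(db = db, times_ms = times_ms, grid = grid,
         baseline_ms = c(-300, -100), n_trials = 1L,
         warp_target_rt_ms = 356),
    class = "ersp")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# direct time-domain Morlet convolution: the independent oracle for
# wavelet_power (explicit sums, no FFT)
oracle_wavelet_power <- function(x, fs, f, cycles) {
  sigma_t <- cycles / (2 * pi * f)
  half <- as.integer(ceiling(3.5 * sigma_t * fs))
  tt <- (-half:half) / fs
  env <- exp(-tt^2 / (2 * sigma_t^2))
  psi <- env * exp(2i * pi * f * tt) * (2 / sum(env))
  n <- length(x)
  out <- rep(NA_real_, n)
  for (tau in (half + 1L):(n - half)) {
    acc <- 0i
    for (u in seq_along(psi)) acc <- acc + psi[u] * x[tau + half + 1L - u]
    out[tau] <- Mod(acc)^2
  }
  out
}

# from-scratch sums-of-squares oracle for the 2 (between) x 2 (within)
# mixed ANOVA, via the subject-mean / subject-difference decomposition
oracle_mixed_anova <- function(y, group, cond, subject) {
  lv <- sort(unique(as.character(cond)))
  s1 <- subject[cond == lv[1]]
  o1 <- order(s1)
  o2 <- order(subject[cond == lv[2]])
  y1 <- y[cond == lv[1]][o1]
  y2 <- y[cond == lv[2]][o2]
  g <- factor(group[cond == lv[1]][o1])
  n <- length(y1)
  sm <- (y1 + y2) / 2          # subject means (between stratum)
  df_ <- y2 - y1               # within differences
  grand <- mean(c(y1, y2))
  # between stratum (x2: two observations per subject)
  ss_a <- 2 * sum(tapply(sm, g, function(v) length(v) * (mean(v) - mean(sm))^2))
  ss_s <- 2 * sum((sm - ave(sm, g))^2)
  # within stratum from differences: SS_B = N dbar^2 / 2 etc.
  ss_b <- n * mean(df_)^2 / 2
  gm <- ave(df_, g)
  ss_ab <- sum((gm - mean(df_))^2) / 2
  ss_e <- sum((df_ - gm)^2) / 2
  f_and_p <- function(ss_eff, df1, ss_err, df2) {
    f <- (ss_eff / df1) / (ss_err / df2)
    c(F = f, p = pf(f, df1, df2, lower.tail = FALSE))
  }
  ges <- function(ss_eff) ss_eff / (ss_eff + ss_s + ss_e)
  list(
    between = c(f_and_p(ss_a, 1, ss_s, n - 2), ges = ges(ss_a)),
    within = c(f_and_p(ss_b, 1, ss_e, n - 2), ges = ges(ss_b)),
    interaction = c(f_and_p(ss_ab, 1, ss_e, n - 2), ges = ges(ss_ab)))
}
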