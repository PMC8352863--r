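# Morlet time-frequency decomposition, linear trial time-warping,
# full-epoch single-trial normalization, and baseline-referenced ERSPs.

#' Logarithmic frequency grid with linearly expanding cycles
#'
#' `n` log-spaced frequencies from `fmin` to `fmax`,
#' `freqs[k] = fmin * (fmax/fmin)^(k/(n-1))`, with the Morlet cycle count
#' expanding linearly in grid index from 3 at the lowest frequency to 15
#' at the highest. Defaults give the 37-bin 4-40 Hz grid used throughout
#' the pipeline.
#'
#' @param fmin,fmax Frequency range, Hz.
#' @param n Number of bins (>= 2).
#' @param cycles_min,cycles_max Cycle counts at the grid endpoints.
#' @return An object of class `freq_grid` with `freqs_hz` and `cycles`.
#' @examples
#' g <- make_freq_grid()
#' g$freqs_hz[c(1, 19, 37)] # 4, 12.649, 40
#' @export
make_freq_grid <- function(fmin = 4, fmax = 40, n = 37L,
                           cycles_min = 3, cycles_max = 15) {
  if (n < 2) stop("n must be >= 2")
  if (fmin >= fmax) stop("fmin must be < fmax")
  k <- seq_len(n) - 1L
  structure(
    list(freqs_hz = fmin * (fmax / fmin)^(k / (n - 1L)),
         cycles = cycles_min + (cycles_max - cycles_min) * k / (n - 1L)),
    class = "freq_grid"
  )
}

#' @export
print.freq_grid <- function(x, ...) {
  cat(sprintf("Frequency grid: %d bins, %.3g-%.3g Hz, %g-%g cycles\n",
              length(x$freqs_hz), min(x$freqs_hz), max(x$freqs_hz),
              min(x$cycles), max(x$cycles)))
  invisible(x)
}

# Complex Morlet kernel at frequency f (Hz) with n cycles, sampled at fs.
# Truncated at +-3.5 sigma_t; normalized so a sinusoid of amplitude A at
# the carrier yields |convolution| ~ A, i.e. power ~ A^2.
morlet_kernel <- function(f, cycles, fs) {
  sigma_t <- cycles / (2 * pi * f)
  half <- as.integer(ceiling(3.5 * sigma_t * fs))
  t <- (-half:half) / fs
  env <- exp(-t^2 / (2 * sigma_t^2))
  psi <- env * exp(2i * pi * f * t)
  list(psi = psi * (2 / sum(env)), half = half)
}

#' Single-trial Morlet wavelet power
#'
#' Convolves every trial with a complex Morlet wavelet per grid frequency
#' (FFT-based linear convolution) and returns squared magnitude. Samples
#' closer to an epoch edge than the wavelet half-length are marked invalid
#' and are excluded from all downstream averages.
#'
#' @param epochs An [simulate_ic_epochs()] `ic_epochs` object (or any list
#'   with `data`, `times_ms`, `srate_hz`, `rt_ms`).
#' @param grid A [make_freq_grid()] grid.
#' @param hop Output time stride in samples. Power envelopes are smooth
#'   at the wavelet time constants, so a coarse hop loses no structure;
#'   the final ERSP is interpolated to a 1 ms grid downstream.
#' @return An object of class `tf_map`: `power` (trials x freqs x times,
#'   linear power, a.u.^2), `valid` (same shape), `times_ms`, `rt_ms`,
#'   `grid`.
#' @export
wavelet_power <- function(epochs, grid = make_freq_grid(), hop = 1L) {
  x <- epochs$data
  stopifnot(is.matrix(x))
  fs <- epochs$srate_hz
  nt <- nrow(x)
  n <- ncol(x)
  kernels <- lapply(seq_along(grid$freqs_hz), function(k)
    morlet_kernel(grid$freqs_hz[k], grid$cycles[k], fs))
  halves <- vapply(kernels, `[[`, integer(1), "half")
  if (2L * max(halves) + 1L > n)
    stop("epoch shorter than the widest (lowest-frequency) wavelet")
  # circular convolution with the kernel center wrapped to index 1: equal
  # to linear convolution everywhere outside the edge margin, which is
  # masked invalid anyway
  wf <- lapply(kernels, function(kr) {
    h <- kr$half
    kern <- complex(length.out = n)
    kern[1:(h + 1L)] <- kr$psi[(h + 1L):(2L * h + 1L)]
    kern[(n - h + 1L):n] <- kr$psi[1:h]
    stats::fft(kern)
  })
  nf <- length(grid$freqs_hz)
  keep_t <- seq(1L, n, by = as.integer(hop))
  nk <- length(keep_t)
  pow <- array(NA_real_, c(nt, nf, nk))
  valid <- array(FALSE, c(nt, nf, nk))
  # batch all trials per frequency through column-wise FFTs
  X <- stats::mvfft(t(x) * (1 + 0i))
  for (k in seq_len(nf)) {
    y <- stats::mvfft(X * wf[[k]], inverse = TRUE) / n
    pow[, k, ] <- t(Mod(y[keep_t, , drop = FALSE])^2)
    valid[, k, keep_t >= halves[k] + 1L & keep_t <= n - halves[k]] <- TRUE
  }
  structure(
    list(power = pow, valid = valid, times_ms = epochs$times_ms[keep_t],
         rt_ms = epochs$rt_ms, grid = grid),
    class = "tf_map"
  )
}

#' @export
print.tf_map <- function(x, ...) {
  d <- dim(x$power)
  cat(sprintf("TF map: %d trials x %d freqs x %d time points (%g..%g ms)\n",
              d[1], d[2], d[3], min(x$times_ms), max(x$times_ms)))
  invisible(x)
}

#' Time-warp trials to a common stimulus-response interval
#'
#' Piecewise-linearly remaps each trial's time axis with anchors
#' epoch start -> epoch start, stimulus onset (0) -> 0, response time ->
#' `target_rt_ms`, epoch end -> epoch end, and linearly interpolates power
#' onto the common output grid. Trials with a response time outside
#' (0, epoch end) are rejected with a warning. Edge-invalid samples stay
#' invalid through the warp (validity follows the source time point).
#'
#' @param tfmap A [wavelet_power()] `tf_map`.
#' @param rt_ms Per-trial response times; defaults to `tfmap$rt_ms`.
#' @param target_rt_ms Common response latency after warping, ms.
#' @return A warped `tf_map` with `rt_ms` set to the target.
#' @export
timewarp <- function(tfmap, rt_ms = NULL, target_rt_ms = 356) {
  stopifnot(inherits(tfmap, "tf_map"))
  rt <- rt_ms %||% tfmap$rt_ms
  tt <- tfmap$times_ms
  t0 <- tt[1]
  t1 <- tt[length(tt)]
  if (target_rt_ms <= 0 || target_rt_ms >= t1)
    stop("target_rt_ms must lie inside (0, epoch end)")
  keep <- is.finite(rt) & rt > 0 & rt < t1
  if (!all(keep))
    warning(sum(!keep), " trial(s) rejected: response time outside the epoch")
  idx <- which(keep)
  nf <- dim(tfmap$power)[2]
  np <- length(tt)
  pow <- array(NA_real_, c(length(idx), nf, np))
  valid <- array(FALSE, c(length(idx), nf, np))
  # per-frequency valid source-time range (uniform across trials pre-warp)
  vlo <- vhi <- numeric(nf)
  for (k in seq_len(nf)) {
    vk <- tt[tfmap$valid[1, k, ]]
    vlo[k] <- min(vk)
    vhi[k] <- max(vk)
  }
  for (j in seq_along(idx)) {
    i <- idx[j]
    src_t <- stats::approx(x = c(t0, 0, target_rt_ms, t1),
                           y = c(t0, 0, rt[i], t1), xout = tt)$y
    pow[j, , ] <- interp_rows(tfmap$power[i, , ], tt, src_t)
    for (k in seq_len(nf)) {
      valid[j, k, ] <- src_t >= vlo[k] & src_t <= vhi[k]
    }
  }
  out <- tfmap
  out$power <- pow
  out$valid <- valid
  out$rt_ms <- rep(target_rt_ms, length(idx))
  out$warp_target_rt_ms <- target_rt_ms
  out
}

#' Full-epoch single-trial normalization
#'
#' Divides each trial's power, per frequency, by that trial's mean over
#' all valid time points of the full epoch, so the time-mean of every
#' normalized trial is 1 at every frequency. Degenerate trials
#' (non-positive full-epoch mean) are rejected with a warning.
#'
#' @param tfmap A `tf_map`.
#' @return A normalized `tf_map`.
#' @export
normalize_trial <- function(tfmap) {
  stopifnot(inherits(tfmap, "tf_map"))
  pow <- tfmap$power
  pw0 <- pow
  pw0[!tfmap$valid] <- 0
  m <- rowSums(pw0, dims = 2) / rowSums(tfmap$valid, dims = 2)
  keep <- apply(is.finite(m) & m > 0, 1, all)
  # recycling c(m) over the time dimension (dims 1:2 vary fastest)
  pow <- pow / c(m)
  if (!all(keep))
    warning(sum(!keep), " trial(s) rejected: non-positive full-epoch mean")
  out <- tfmap
  out$power <- pow[keep, , , drop = FALSE]
  out$valid <- tfmap$valid[keep, , , drop = FALSE]
  out$rt_ms <- tfmap$rt_ms[keep]
  out
}

#' Trial-average and decibel-transform into an ERSP
#'
#' Averages power over trials (valid samples only), converts to decibels,
#' and references each frequency to its mean dB over the baseline window,
#' so desynchronization appears as negative dB.
#'
#' @param tfmap A `tf_map` (typically warped and normalized).
#' @param baseline_ms Baseline window in ms relative to stimulus onset.
#' @return An object of class `ersp`: `db` (freqs x times, `NA` where no
#'   valid data), `times_ms`, `grid`, `baseline_ms`, `n_trials`.
#' @export
average_and_db <- function(tfmap, baseline_ms = c(-300, -100)) {
  stopifnot(inherits(tfmap, "tf_map"))
  if (dim(tfmap$power)[1] < 1) stop("no valid trials")
  bl <- tfmap$times_ms >= baseline_ms[1] & tfmap$times_ms <= baseline_ms[2]
  if (!any(bl)) stop("empty baseline window")
  pw <- tfmap$power
  pw[!tfmap$valid] <- 0
  ps <- colSums(pw, dims = 1)
  nn <- colSums(tfmap$valid, dims = 1)
  meanpow <- ps / nn
  # a (freq, time) cell enters the map only where every trial is valid;
  # partially covered cells (post-warp edges) would otherwise mix
  # different trial subsets
  meanpow[nn < dim(pw)[1]] <- NA_real_
  db <- 10 * log10(meanpow)
  base <- rowMeans(db[, bl, drop = FALSE], na.rm = TRUE)
  if (any(!is.finite(base)))
    stop("baseline window has no valid data at some frequency")
  db <- db - base
  structure(
    list(db = db, times_ms = tfmap$times_ms, grid = tfmap$grid,
         baseline_ms = baseline_ms, n_trials = dim(tfmap$power)[1],
         warp_target_rt_ms = tfmap$warp_target_rt_ms %||% NA_real_),
    class = "ersp"
  )
}

#' Resample an ERSP onto a 1 ms grid
#'
#' Linear interpolation of the dB map onto a 1 ms time axis, so the
#' +-20 ms suppression-extraction window spans exactly 41 samples.
#'
#' @param ersp An `ersp`.
#' @param dt_ms Output resolution, ms.
#' @return An `ersp` on the resampled axis.
#' @export
resample_ersp <- function(ersp, dt_ms = 1) {
  stopifnot(inherits(ersp, "ersp"))
  tt <- ersp$times_ms
  xout <- seq(ceiling(tt[1]), floor(tt[length(tt)]), by = dt_ms)
  out <- ersp
  out$db <- interp_rows(ersp$db, tt, xout)
  out$times_ms <- xout
  out
}

#' Compute a condition ERSP from IC epochs
#'
#' Convenience chain: wavelet power, time-warp to the target response
#' latency, full-epoch single-trial normalization, trial averaging with dB
#' baseline correction, and resampling to a 1 ms grid.
#'
#' @param epochs An `ic_epochs` object.
#' @param grid A [make_freq_grid()] grid.
#' @param target_rt_ms Warp target latency, ms.
#' @param baseline_ms Baseline window, ms.
#' @param normalize Apply single-trial normalization (default `TRUE`).
#' @param resample Resample to 1 ms (default `TRUE`).
#' @param hop Internal TF time stride in samples (see [wavelet_power()]).
#' @return An `ersp`.
#' @export
compute_ersp <- function(epochs, grid = make_freq_grid(),
                         target_rt_ms = 356, baseline_ms = c(-300, -100),
                         normalize = TRUE, resample = TRUE, hop = 4L) {
  tf <- wavelet_power(epochs, grid, hop = hop)
  tf <- timewarp(tf, target_rt_ms = target_rt_ms)
  if (normalize) tf <- normalize_trial(tf)
  e <- average_and_db(tf, baseline_ms)
  if (resample) e <- resample_ersp(e) else e
}

#' Average several ERSPs sharing one grid
#'
#' Element-wise mean of the dB maps, e.g. over the ICs of one participant
#' or over participants for a grand average. A cell is retained only
#' where at least `min_coverage` of the input maps have valid data
#' (default: all of them), so edge cells never rest on a small subset of
#' maps.
#'
#' @param ersps List of `ersp` objects with identical axes.
#' @param min_coverage Minimum fraction of maps required per cell.
#' @return An `ersp`.
#' @export
average_ersps <- function(ersps, min_coverage = 1) {
  stopifnot(length(ersps) >= 1)
  db <- Reduce(`+`, lapply(ersps, function(e) {
    z <- e$db
    z[is.na(z)] <- 0
    z
  }))
  nn <- Reduce(`+`, lapply(ersps, function(e) !is.na(e$db)))
  db <- db / nn
  db[nn < max(1, ceiling(min_coverage * length(ersps)))] <- NA_real_
  out <- ersps[[1]]
  out$db <- db
  out$n_trials <- sum(vapply(ersps, function(e) e$n_trials, numeric(1)))
  out
}

#' @export
print.ersp <- function(x, ...) {
  cat(sprintf("ERSP: %d freqs x %d time points, baseline %g..%g ms, %d trials\n",
              nrow(x$db), ncol(x$db), x$baseline_ms[1], x$baseline_ms[2],
              x$n_trials))
  cat(sprintf("  range %.2f .. %.2f dB\n", min(x$db, na.rm = TRUE),
              max(x$db, na.rm = TRUE)))
  invisible(x)
}

#' @export
plot.ersp <- function(x, main = "ERSP (dB)", ...) {
  pal <- grDevices::hcl.colors(64, "Blue-Red 3")
  lim <- max(abs(x$db), na.rm = TRUE)
  graphics::image(x$times_ms, seq_along(x$grid$freqs_hz), t(x$db),
                  col = pal, zlim = c(-lim, lim), xlab = "time (ms)",
                  ylab = "frequency (Hz)", yaxt = "n", main = main, ...)
  at <- pretty(seq_along(x$grid$freqs_hz))
  at <- at[at >= 1 & at <= length(x$grid$freqs_hz)]
  graphics::axis(2, at = at, labels = round(x$grid$freqs_hz[at], 1))
  graphics::abline(v = c(0, x$warp_target_rt_ms), lty = c(1, 2))
  invisible(x)
}

#' Export an ERSP dB matrix as TSV
#'
#' Rows are grid frequencies (Hz), columns are time points (ms).
#'
#' @param ersp An `ersp`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
export_ersp_tsv <- function(ersp, path) {
  m <- ersp$db
  rownames(m) <- sprintf("%.4f", ersp$grid$freqs_hz)
  colnames(m) <- sprintf("%g", ersp$times_ms)
  utils::write.table(m, path, sep = "\t", quote = FALSE, col.names = NA)
  invisible(path)
}
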