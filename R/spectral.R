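# PSD estimation and FOOOF-style aperiodic (1/f) parameterization.

#' Welch power spectral density of IC epochs
#'
#' Per-epoch Welch estimate (demeaned Hann-tapered segments, 50% overlap,
#' one-sided density scaling), averaged over all epochs and returned as
#' log10 power.
#'
#' @param epochs An `ic_epochs` object.
#' @param window_s Segment length in seconds (default 2).
#' @param overlap Fractional segment overlap (default 0.5).
#' @param participant,condition Optional labels carried in the record.
#' @return An object of class `psd_record`: `freqs_hz`, `log_power`
#'   (log10 density), `power` (linear density).
#' @export
compute_psd <- function(epochs, window_s = 2, overlap = 0.5,
                        participant = NULL, condition = NULL) {
  x <- epochs$data
  stopifnot(is.matrix(x), nrow(x) >= 1)
  fs <- epochs$srate_hz
  n <- ncol(x)
  len <- min(round(window_s * fs), n)
  if (len < 8) stop("epoch shorter than one PSD window")
  step <- max(1L, round(len * (1 - overlap)))
  starts <- seq(1L, n - len + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, len - 1) / (len - 1))
  scale <- 2 / (fs * sum(w^2))
  half <- len %/% 2L
  acc <- numeric(half)
  nseg <- 0L
  for (i in seq_len(nrow(x))) {
    for (s in starts) {
      seg <- x[i, s:(s + len - 1L)]
      seg <- (seg - mean(seg)) * w
      sp <- Mod(stats::fft(seg)[2:(half + 1L)])^2 * scale
      acc <- acc + sp
      nseg <- nseg + 1L
    }
  }
  p <- acc / nseg
  structure(
    list(freqs_hz = (1:half) * fs / len, power = p, log_power = log10(p),
         participant = participant %||% epochs$participant,
         condition = condition %||% epochs$condition),
    class = "psd_record"
  )
}

#' @export
print.psd_record <- function(x, ...) {
  cat(sprintf("PSD: %d bins, %.2f-%.1f Hz (%s, %s)\n", length(x$freqs_hz),
              min(x$freqs_hz), max(x$freqs_hz), x$participant %||% "?",
              x$condition %||% "?"))
  invisible(x)
}

#' Average several PSD records on the linear power scale
#'
#' @param psds List of `psd_record`s sharing one frequency axis.
#' @return A `psd_record`.
#' @export
average_psds <- function(psds) {
  stopifnot(length(psds) >= 1)
  p <- Reduce(`+`, lapply(psds, `[[`, "power")) / length(psds)
  out <- psds[[1]]
  out$power <- p
  out$log_power <- log10(p)
  out
}

# Gaussian in frequency: height (log10 units) at center, SD sd_hz.
gauss_peak <- function(f, center, height, sd_hz) {
  height * exp(-(f - center)^2 / (2 * sd_hz^2))
}

#' Fit the aperiodic (1/f) component of a power spectrum
#'
#' Iterative no-knee parameterization: (1) robust straight-line fit of
#' log10 power against log10 frequency, down-weighting bins far above the
#' line; (2) peak detection in the flattened spectrum (threshold
#' `peak_threshold_sd` SD of the flattened residuals, with an absolute
#' floor) and Gaussian fitting/removal, at most `max_peaks` peaks with
#' bandwidth inside `bw_bounds`; (3) aperiodic re-fit on the peak-removed
#' spectrum. The offset is the log10-power intercept at 1 Hz; the exponent
#' is the negated log-log slope.
#'
#' @param psd A [compute_psd()] record.
#' @param range Fit range in Hz (default 2-40).
#' @param peak_threshold_sd Relative peak threshold, in SD of the
#'   flattened spectrum.
#' @param min_peak_height Absolute peak floor, log10 units.
#' @param max_peaks Maximum number of Gaussians.
#' @param bw_bounds Gaussian full bandwidth (2 SD) bounds, Hz.
#' @return An object of class `aperiodic_fit` with elements `offset`,
#'   `exponent`, `peaks` (data frame: center_hz, height, bandwidth_hz),
#'   `fit_error` (mean absolute residual), and the fitted spectrum.
#' @examples
#' # exact power law P(f) = 10^1.5 * f^-1 recovers b = 1.5, chi = 1
#' @export
fit_aperiodic <- function(psd, range = c(2, 40), peak_threshold_sd = 2,
                          min_peak_height = 0.05, max_peaks = 6,
                          bw_bounds = c(1, 12)) {
  sel <- psd$freqs_hz >= range[1] & psd$freqs_hz <= range[2]
  if (sum(sel) < 10) stop("need at least 10 frequency bins in the fit range")
  f <- psd$freqs_hz[sel]
  lp <- psd$log_power[sel]
  if (any(!is.finite(lp))) stop("non-finite spectrum values in fit range")
  lf <- log10(f)

  line_fit <- function(y, keep = TRUE) {
    ft <- stats::lm.fit(cbind(1, lf[keep]), y[keep])
    ft$coefficients
  }
  # robust initial line: refit ignoring bins well above the first fit
  cf <- line_fit(lp)
  res <- lp - (cf[1] + cf[2] * lf)
  s <- stats::sd(res)
  if (is.finite(s) && s > 0) cf <- line_fit(lp, keep = res <= s)

  flat <- lp - (cf[1] + cf[2] * lf)
  peaks <- NULL
  work <- flat
  for (it in seq_len(max_peaks)) {
    thr <- max(peak_threshold_sd * stats::sd(work), min_peak_height)
    i0 <- which.max(work)
    h0 <- work[i0]
    if (!is.finite(h0) || h0 <= thr) break
    c0 <- f[i0]
    wlo <- bw_bounds[1] / 2
    whi <- bw_bounds[2] / 2
    df_ <- data.frame(f = f, y = work)
    fit <- tryCatch(suppressWarnings(
      stats::nls(y ~ h * exp(-(f - c) ^ 2 / (2 * w ^ 2)), data = df_,
                 start = list(h = h0, c = c0, w = max(wlo, min(1.5, whi))),
                 lower = c(h = 0, c = max(range[1], c0 - 3), w = wlo),
                 upper = c(h = 2 * h0, c = min(range[2], c0 + 3), w = whi),
                 algorithm = "port",
                 control = stats::nls.control(warnOnly = TRUE))),
      error = function(e) NULL)
    pk <- if (is.null(fit)) c(h = h0, c = c0, w = 1.5) else stats::coef(fit)
    peaks <- rbind(peaks, data.frame(center_hz = pk[["c"]],
                                     height = pk[["h"]],
                                     bandwidth_hz = 2 * pk[["w"]]))
    work <- work - gauss_peak(f, pk[["c"]], pk[["h"]], pk[["w"]])
  }

  peak_sum <- numeric(length(f))
  if (!is.null(peaks))
    for (j in seq_len(nrow(peaks)))
      peak_sum <- peak_sum + gauss_peak(f, peaks$center_hz[j],
                                        peaks$height[j],
                                        peaks$bandwidth_hz[j] / 2)
  cf <- line_fit(lp - peak_sum)
  offset <- unname(cf[1])
  exponent <- unname(-cf[2])
  if (exponent < 0)
    warning("fitted aperiodic exponent is negative")
  model <- offset - exponent * lf + peak_sum
  structure(
    list(offset = offset, exponent = exponent,
         peaks = peaks %||% data.frame(center_hz = numeric(0),
                                       height = numeric(0),
                                       bandwidth_hz = numeric(0)),
         fit_error = mean(abs(lp - model)),
         freqs_hz = f, log_power = lp, fitted_log_power = model,
         range = range),
    class = "aperiodic_fit"
  )
}

#' @export
print.aperiodic_fit <- function(x, ...) {
  cat(sprintf("Aperiodic fit (%g-%g Hz, no knee): offset %.3f, exponent %.3f\n",
              x$range[1], x$range[2], x$offset, x$exponent))
  if (nrow(x$peaks)) {
    cat(sprintf("  %d peak(s):\n", nrow(x$peaks)))
    for (j in seq_len(nrow(x$peaks)))
      cat(sprintf("    %.1f Hz, height %.2f, bw %.1f Hz\n",
                  x$peaks$center_hz[j], x$peaks$height[j],
                  x$peaks$bandwidth_hz[j]))
  }
  cat(sprintf("  mean abs residual %.4f\n", x$fit_error))
  invisible(x)
}

#' @export
coef.aperiodic_fit <- function(object, ...) {
  c(offset = object$offset, exponent = object$exponent)
}

#' Predict log10 power from an aperiodic fit
#'
#' @param object An `aperiodic_fit`.
#' @param freqs_hz Frequencies at which to evaluate (default: fit grid).
#' @param component `"full"` (aperiodic + peaks) or `"aperiodic"`.
#' @param ... Unused.
#' @return Numeric vector of log10 power.
#' @export
predict.aperiodic_fit <- function(object, freqs_hz = object$freqs_hz,
                                  component = c("full", "aperiodic"), ...) {
  component <- match.arg(component)
  out <- object$offset - object$exponent * log10(freqs_hz)
  if (component == "full" && nrow(object$peaks))
    for (j in seq_len(nrow(object$peaks)))
      out <- out + gauss_peak(freqs_hz, object$peaks$center_hz[j],
                              object$peaks$height[j],
                              object$peaks$bandwidth_hz[j] / 2)
  out
}

#' @export
fitted.aperiodic_fit <- function(object, ...) object$fitted_log_power

#' @export
residuals.aperiodic_fit <- function(object, ...) {
  object$log_power - object$fitted_log_power
}

#' @export
plot.aperiodic_fit <- function(x, ...) {
  graphics::plot(x$freqs_hz, x$log_power, type = "l", log = "x",
                 xlab = "frequency (Hz)", ylab = "log10 power",
                 main = "Spectral parameterization", ...)
  graphics::lines(x$freqs_hz, predict(x, component = "aperiodic"),
                  lty = 2, col = "grey40")
  graphics::lines(x$freqs_hz, x$fitted_log_power, col = "red3")
  invisible(x)
}

#' Band peak power of a PSD
#'
#' Power (log10) at the local maximum of the 1/f-corrected spectrum inside
#' a frequency band. Maxima must rise at least `min_height` log10 units
#' above the aperiodic fit; if no such local maximum exists in the band,
#' the band mean of the raw log10 power is returned with `no_peak = TRUE`.
#'
#' @param psd A `psd_record`.
#' @param band Two-element band limits, Hz.
#' @param fit Optional precomputed [fit_aperiodic()] result.
#' @param min_height Minimum corrected height of an acceptable peak.
#' @return List with `power` (log10), `freq_hz`, `no_peak`.
#' @export
band_peak_power <- function(psd, band, fit = NULL, min_height = 0.05) {
  if (length(band) != 2 || band[1] >= band[2]) stop("empty band")
  fit <- fit %||% fit_aperiodic(psd)
  sel <- which(psd$freqs_hz >= band[1] & psd$freqs_hz <= band[2])
  if (!length(sel)) stop("band outside PSD range")
  corrected <- psd$log_power -
    (fit$offset - fit$exponent * log10(psd$freqs_hz))
  in_spec <- sel[sel > 1 & sel < length(psd$freqs_hz)]
  is_max <- vapply(in_spec, function(i)
    corrected[i] > corrected[i - 1] && corrected[i] >= corrected[i + 1] &&
      corrected[i] >= min_height,
    logical(1))
  cand <- in_spec[is_max]
  if (!length(cand)) {
    return(list(power = mean(psd$log_power[sel]), freq_hz = NA_real_,
                no_peak = TRUE))
  }
  best <- cand[which.max(corrected[cand])]
  list(power = psd$log_power[best], freq_hz = psd$freqs_hz[best],
       no_peak = FALSE)
}
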