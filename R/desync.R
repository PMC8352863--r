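# Data-driven extraction of alpha/beta desynchronization maxima and
# proportional dual-task costs.

#' Band definition for desynchronization extraction
#'
#' The alpha band (8-12 Hz) averages over +-1 neighboring log-spaced
#' frequency bins around the individual peak; the broader beta band
#' (16-30 Hz) averages over +-2 bins.
#'
#' @param name `"alpha"` or `"beta"`.
#' @return List with `name`, `range` (Hz) and `n_neighbor` (grid bins).
#' @export
band_def <- function(name = c("alpha", "beta")) {
  name <- match.arg(name)
  if (name == "alpha") list(name = "alpha", range = c(8, 12), n_neighbor = 1L)
  else list(name = "beta", range = c(16, 30), n_neighbor = 2L)
}

band_bins <- function(grid, band) {
  which(grid$freqs_hz >= band[1] & grid$freqs_hz <= band[2])
}

# argmin over a dB submatrix with the shared tie rule: earliest time,
# then lowest frequency.
argmin_db <- function(db, bins, tsel, times, grid) {
  sub <- db[bins, tsel, drop = FALSE]
  if (all(is.na(sub))) stop("no valid ERSP data in the search region")
  m <- min(sub, na.rm = TRUE)
  hit <- which(sub == m, arr.ind = TRUE)
  hit <- hit[order(hit[, 2], hit[, 1]), , drop = FALSE]
  fb <- bins[hit[1, 1]]
  tb <- which(tsel)[hit[1, 2]]
  list(time_ms = times[tb], freq_hz = grid$freqs_hz[fb], freq_bin = fb,
       db = m)
}

#' Grand-average desynchronization maximum
#'
#' Minimum dB of the grand-average ERSP over the band's frequencies and
#' post-stimulus time points; ties resolve to the earliest time, then the
#' lowest frequency. If the map is all-positive a warning is raised and
#' the minimum is returned anyway.
#'
#' @param ersps List of `ersp` objects (all participants x conditions).
#' @param band A [band_def()] or two-element Hz range.
#' @return List with `time_ms`, `freq_hz`, `freq_bin`, `db`.
#' @export
grand_peak <- function(ersps, band) {
  if (!length(ersps)) stop("need at least one ERSP")
  if (is.list(band) && !is.null(band$range)) band <- band$range
  g <- average_ersps(ersps)
  bins <- band_bins(g$grid, band)
  if (!length(bins)) stop("band is empty on this grid")
  tsel <- g$times_ms > 0
  res <- argmin_db(g$db, bins, tsel, g$times_ms, g$grid)
  if (res$db >= 0)
    warning("no desynchronization: grand-average minimum is non-negative")
  res
}

#' Individual desynchronization maximum near the grand-average latency
#'
#' Argmin of the dB map within the band and a +-`half_window_ms` window
#' around the grand-average peak time. A window clipped by the epoch edge
#' is truncated with a warning.
#'
#' @param ersp A single participant/condition `ersp`.
#' @param band A [band_def()] or Hz range.
#' @param t_star Grand-average peak time, ms.
#' @param half_window_ms Half search window, ms (default 100).
#' @return List with `time_ms`, `freq_hz`, `freq_bin`, `db`.
#' @export
individual_peak <- function(ersp, band, t_star, half_window_ms = 100) {
  if (is.list(band) && !is.null(band$range)) band <- band$range
  tt <- ersp$times_ms
  lo <- t_star - half_window_ms
  hi <- t_star + half_window_ms
  if (lo < tt[1] || hi > tt[length(tt)]) {
    warning("search window clipped by the epoch edge")
    lo <- max(lo, tt[1])
    hi <- min(hi, tt[length(tt)])
  }
  bins <- band_bins(ersp$grid, band)
  argmin_db(ersp$db, bins, tt >= lo & tt <= hi, tt, ersp$grid)
}

#' Mean suppression around an individual peak
#'
#' Mean dB over +-`half_window_ms` around the peak time (41 samples on
#' the 1 ms grid) and +-`n_neighbor` log-spaced frequency bins around the
#' peak bin. Neighbor bins outside the grid are truncated with a warning.
#'
#' @param ersp An `ersp` on the 1 ms grid.
#' @param t_i Individual peak time, ms.
#' @param f_bin Individual peak frequency bin index.
#' @param half_window_ms Half time window, ms (default 20).
#' @param n_neighbor Frequency neighbors per side (1 alpha, 2 beta).
#' @return List with `mean_db`, `n_time`, `n_freq`.
#' @export
mean_suppression <- function(ersp, t_i, f_bin, half_window_ms = 20,
                             n_neighbor = 1L) {
  tt <- ersp$times_ms
  tsel <- tt >= t_i - half_window_ms & tt <= t_i + half_window_ms
  if (!any(tsel)) stop("time window outside the ERSP time axis")
  bins <- (f_bin - n_neighbor):(f_bin + n_neighbor)
  if (any(bins < 1 | bins > nrow(ersp$db))) {
    warning("neighbor bins truncated at the grid edge")
    bins <- bins[bins >= 1 & bins <= nrow(ersp$db)]
  }
  vals <- ersp$db[bins, tsel, drop = FALSE]
  list(mean_db = mean(vals, na.rm = TRUE), n_time = sum(tsel),
       n_freq = length(bins))
}

#' Proportional dual-task cost
#'
#' Lindenberger-style cost: `(single - dual) / single * 100`.
#'
#' @param single Single-task score(s); must be non-zero and finite.
#' @param dual Dual-task score(s).
#' @return Cost in percent.
#' @examples
#' dual_task_cost(2, 1) # 50
#' dual_task_cost(-2.20, -1.07) # 51.36..., the worked alpha example
#' @export
dual_task_cost <- function(single, dual) {
  if (any(!is.finite(single)) || any(!is.finite(dual)))
    stop("non-finite inputs")
  if (any(single == 0)) stop("undefined cost: single-task score is zero")
  (single - dual) / single * 100
}

#' Extract desynchronization measures for a set of participant ERSPs
#'
#' Applies the data-driven chain: grand-average peak per band over all
#' ERSPs, individual peak per participant x condition within +-100 ms of
#' the grand latency, then mean suppression over +-20 ms and the band's
#' neighbor bins.
#'
#' @param ersps List of `ersp` objects on the 1 ms grid.
#' @param meta Data frame aligned with `ersps` (columns `participant`,
#'   `condition`, and optionally `age_group`).
#' @param bands List of [band_def()]s.
#' @return List with `measures` (data frame: participant, condition, band,
#'   peak_time_ms, center_freq_hz, mean_db) and `grand` (per-band grand
#'   peaks).
#' @export
extract_desync <- function(ersps, meta,
                           bands = list(band_def("alpha"), band_def("beta"))) {
  stopifnot(length(ersps) == nrow(meta))
  grand <- lapply(bands, function(b) grand_peak(ersps, b))
  names(grand) <- vapply(bands, `[[`, character(1), "name")
  ag <- meta$age_group %||% rep(NA_character_, nrow(meta))
  rows <- NULL
  for (bi in seq_along(bands)) {
    b <- bands[[bi]]
    for (i in seq_along(ersps)) {
      pk <- individual_peak(ersps[[i]], b, grand[[bi]]$time_ms)
      ms <- mean_suppression(ersps[[i]], pk$time_ms, pk$freq_bin,
                             n_neighbor = b$n_neighbor)
      rows <- rbind(rows, data.frame(
        participant = meta$participant[i],
        age_group = ag[i],
        condition = meta$condition[i],
        band = b$name, peak_time_ms = pk$time_ms,
        center_freq_hz = pk$freq_hz, peak_db = pk$db,
        mean_db = ms$mean_db, stringsAsFactors = FALSE))
    }
  }
  list(measures = rows, grand = grand)
}

#' Dual-task cost table from desynchronization measures
#'
#' Computes per participant x band the proportional cost of the dual
#' (walking) relative to the single (sitting) condition on the mean
#' suppression values, plus the ordered-quantile-normalized cost.
#'
#' @param measures Measure data frame from [extract_desync()].
#' @param single,dual Condition labels for single and dual task.
#' @return Data frame: participant, age_group, band, single_value,
#'   dual_value, cost_pct, cost_normalized.
#' @export
cost_table <- function(measures, single = "sitting", dual = "walking") {
  out <- NULL
  for (b in unique(measures$band)) {
    mb <- measures[measures$band == b, ]
    s <- mb[mb$condition == single, ]
    d <- mb[mb$condition == dual, ]
    ids <- intersect(s$participant, d$participant)
    s <- s[match(ids, s$participant), ]
    d <- d[match(ids, d$participant), ]
    cost <- dual_task_cost(s$mean_db, d$mean_db)
    out <- rbind(out, data.frame(
      participant = ids, age_group = s$age_group, band = b,
      single_value = s$mean_db, dual_value = d$mean_db,
      cost_pct = cost, cost_normalized = orq_normalize(cost),
      stringsAsFactors = FALSE))
  }
  out
}
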