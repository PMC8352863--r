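# Desynchronization peak extraction, suppression averaging, dual-task
# costs.

flat_ersp <- function(value = 0, times = seq(-1000, 1496, 1)) {
  make_test_ersp(matrix(value, 37, length(times)), times)
}

test_that("grand peak finds planted troughs with the tie rule", {
  tt <- seq(-1000, 1496, 1)
  g <- make_freq_grid()
  bins <- which(g$freqs_hz >= 8 & g$freqs_hz <= 12)

  e <- flat_ersp(0, tt)
  i10 <- which.min(abs(g$freqs_hz - 10))
  e$db[i10, ] <- e$db[i10, ] - 3 * exp(-(tt - 400)^2 / (2 * 50^2))
  pk <- grand_peak(list(e), band_def("alpha"))
  expect_equal(pk$time_ms, 400)
  expect_equal(pk$freq_bin, i10)

  # deeper of two troughs wins
  e2 <- flat_ersp(0, tt)
  e2$db[i10, which(tt == 300)] <- -3
  e2$db[i10, which(tt == 500)] <- -5
  expect_equal(grand_peak(list(e2), c(8, 12))$time_ms, 500)

  # exact ties resolve to earliest time, then lowest frequency
  e3 <- flat_ersp(0, tt)
  e3$db[bins[2], which(tt == 600)] <- -2
  e3$db[bins[1], which(tt == 600)] <- -2
  e3$db[bins[3], which(tt == 800)] <- -2
  pk3 <- grand_peak(list(e3), c(8, 12))
  expect_equal(pk3$time_ms, 600)
  expect_equal(pk3$freq_bin, bins[1])

  # all-positive map warns but still returns the minimum
  e4 <- flat_ersp(1, tt)
  expect_warning(pk4 <- grand_peak(list(e4), c(8, 12)), "no desynchronization")
  expect_equal(pk4$db, 1)

  # random map agrees with an exhaustive argmin scan
  set.seed(12)
  e5 <- flat_ersp(0, tt)
  e5$db[] <- rnorm(length(e5$db))
  pk5 <- grand_peak(list(e5), c(8, 12))
  sub <- e5$db[bins, tt > 0]
  expect_equal(pk5$db, min(sub))
})

test_that("individual peak is confined to the +-100 ms window", {
  tt <- seq(-1000, 1496, 1)
  g <- make_freq_grid()
  i10 <- which.min(abs(g$freqs_hz - 10))

  e <- flat_ersp(0, tt)
  e$db[i10, ] <- -2 * exp(-(tt - 460)^2 / (2 * 40^2)) # trough at t*+60
  pk <- individual_peak(e, c(8, 12), t_star = 400)
  expect_equal(pk$time_ms, 460)

  # trough outside the window: the window-edge minimum is returned
  e2 <- flat_ersp(0, tt)
  e2$db[i10, ] <- -2 * exp(-(tt - 550)^2 / (2 * 40^2)) # at t*+150
  pk2 <- individual_peak(e2, c(8, 12), t_star = 400)
  expect_equal(pk2$time_ms, 500)

  # clipped window warns
  expect_warning(individual_peak(e, c(8, 12), t_star = -950), "clipped")

  # random map matches a brute-force scan within the window
  set.seed(3)
  e3 <- flat_ersp(0, tt)
  e3$db[] <- rnorm(length(e3$db))
  pk3 <- individual_peak(e3, c(16, 30), t_star = 500)
  bins <- which(g$freqs_hz >= 16 & g$freqs_hz <= 30)
  sub <- e3$db[bins, tt >= 400 & tt <= 600]
  expect_equal(pk3$db, min(sub))
})

test_that("mean suppression averages the exact index set", {
  tt <- seq(-1000, 1496, 1)
  e <- flat_ersp(-2, tt)
  ms <- mean_suppression(e, t_i = 400, f_bin = 10, n_neighbor = 1)
  expect_equal(ms$mean_db, -2)
  expect_equal(ms$n_time, 41L)
  expect_equal(ms$n_freq, 3L)

  set.seed(9)
  e2 <- flat_ersp(0, tt)
  e2$db[] <- rnorm(length(e2$db))
  ms2 <- mean_suppression(e2, t_i = 600, f_bin = 20, n_neighbor = 2)
  expect_equal(ms2$mean_db,
               mean(e2$db[18:22, which(tt == 580):which(tt == 620)]))

  # uniform deepening shifts the output by exactly c
  e3 <- e2
  e3$db <- e3$db - 1.7
  expect_equal(mean_suppression(e3, 600, 20, n_neighbor = 2)$mean_db,
               ms2$mean_db - 1.7, tolerance = 1e-12)

  # neighbor truncation at the grid edge warns
  expect_warning(mse <- mean_suppression(e2, 600, 1, n_neighbor = 2),
                 "truncated")
  expect_equal(mse$n_freq, 3L)
})

test_that("dual-task cost follows the proportional formula", {
  expect_equal(dual_task_cost(2, 1), 50)
  expect_equal(dual_task_cost(-3.2, -3.2), 0)
  expect_equal(dual_task_cost(0.7, 0.7), 0)
  # the worked example from the printed alpha condition means
  expect_equal(dual_task_cost(-2.20, -1.07), 51.3636, tolerance = 1e-4)
  expect_error(dual_task_cost(0, 1), "zero")
  expect_error(dual_task_cost(NA, 1), "non-finite")
  expect_error(dual_task_cost(1, Inf), "non-finite")
})

test_that("cost table pairs conditions within participant and band", {
  measures <- expand.grid(participant = c("P1", "P2", "P3"),
                          condition = c("sitting", "walking"),
                          band = c("alpha", "beta"),
                          stringsAsFactors = FALSE)
  measures$age_group <- "young"
  set.seed(4)
  measures$mean_db <- -runif(nrow(measures), 0.5, 3)
  ct <- cost_table(measures)
  expect_equal(nrow(ct), 6L)
  r1 <- ct[ct$participant == "P2" & ct$band == "beta", ]
  s <- measures$mean_db[measures$participant == "P2" &
                          measures$condition == "sitting" &
                          measures$band == "beta"]
  d <- measures$mean_db[measures$participant == "P2" &
                          measures$condition == "walking" &
                          measures$band == "beta"]
  expect_equal(r1$cost_pct, (s - d) / s * 100)
})

test_that("full-chain extraction recovers a planted trough", {
  g <- make_freq_grid()
  sp <- calibration_spec(beta_db = -4)
  d <- make_design(trials_per_cell = 10L, conditions = "sitting")
  ep <- simulate_ic_epochs(sp, d, "sitting", seed = 77)
  e <- compute_ersp(ep, g)
  pk <- grand_peak(list(e), band_def("beta"))
  # planted trough at 356 + 206 = 562 ms; wavelet smoothing shallows the
  # planted -4 dB trough (analysis in the methods vignette)
  expect_lt(abs(pk$time_ms - 562), 100)
  expect_lt(pk$db, -2.5)
  expect_gt(pk$db, -5)
  # center frequency near the 21 Hz carrier
  expect_lt(abs(pk$freq_hz - 21), 2.5)
})
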