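# Time-frequency layer: grid closed forms, wavelet oracle equivalence,
# warp anchor algebra, normalization and baseline properties.

test_that("frequency grid follows the log-spacing and cycle closed forms", {
  g <- make_freq_grid()
  expect_equal(g$freqs_hz[1], 4)
  expect_equal(g$cycles[1], 3)
  expect_equal(g$freqs_hz[37], 40)
  expect_equal(g$cycles[37], 15)
  expect_equal(g$freqs_hz[19], 4 * 10^0.5, tolerance = 1e-12)
  expect_equal(g$cycles[19], 9)
  expect_true(all(diff(g$freqs_hz) > 0))
  expect_true(all(diff(g$cycles) >= 0))
  expect_error(make_freq_grid(n = 1), "n must be")
})

test_that("wavelet power localizes and scales with amplitude", {
  g <- make_freq_grid()
  fs <- 250
  tt <- seq(-1000, 1496, by = 4)
  f0 <- g$freqs_hz[20] # an exact grid frequency
  mk <- function(a) list(data = matrix(a * cos(2 * pi * f0 * tt / 1000), 1),
                         times_ms = tt, rt_ms = 500, srate_hz = fs)
  tf1 <- wavelet_power(mk(1), g)
  mid <- which.min(abs(tt - 250))
  expect_equal(which.max(tf1$power[1, , mid]), 20L)
  tf2 <- wavelet_power(mk(2), g)
  ratio <- tf2$power[1, 20, mid] / tf1$power[1, 20, mid]
  expect_equal(10 * log10(ratio), 6.02, tolerance = 0.01)
})

test_that("FFT wavelet power matches the direct-convolution oracle", {
  g <- make_freq_grid()
  fs <- 250
  set.seed(42)
  for (rep in 1:3) {
    x <- rnorm(fs) # 1 s signal
    ep <- list(data = matrix(x, 1), times_ms = seq_len(fs) * 4,
               rt_ms = 500, srate_hz = fs)
    tf <- wavelet_power(ep, g)
    for (k in c(1L, 14L, 37L)) {
      ora <- oracle_wavelet_power(x, fs, g$freqs_hz[k], g$cycles[k])
      v <- tf$valid[1, k, ]
      rel <- abs(tf$power[1, k, v] - ora[v]) / pmax(ora[v], 1e-300)
      expect_lt(max(rel), 1e-6)
    }
  }
})

test_that("epoch too short for the widest wavelet errors", {
  g <- make_freq_grid()
  ep <- list(data = matrix(rnorm(100), 1), times_ms = seq_len(100) * 4,
             rt_ms = 200, srate_hz = 250)
  expect_error(wavelet_power(ep, g), "shorter")
})

test_that("time-warp anchor algebra holds", {
  tt <- seq(-1000, 1496, by = 4)
  ramp <- matrix(rep(tt + 2000, each = 2), nrow = 1) # linear in time
  pow <- array(0, c(1, 2, length(tt)))
  pow[1, 1, ] <- tt + 2000
  pow[1, 2, ] <- 2 * tt + 5000
  tf <- make_tf(pow, tt)

  # rt equal to the target: identity warp
  w1 <- timewarp(tf, rt_ms = 356)
  expect_equal(w1$power[1, , ], tf$power[1, , ], tolerance = 1e-12)

  # rt = 712: the value originally at 712 ms appears at 356 ms
  w2 <- timewarp(tf, rt_ms = 712)
  i356 <- which.min(abs(tt - 356))
  expect_equal(w2$power[1, 1, i356], 712 + 2000, tolerance = 1e-9)

  # rt = 200, query at 178 ms -> input linearly interpolated at 100 ms
  w3 <- timewarp(tf, rt_ms = 200)
  i178 <- which(tt == 180) # closest representable query on this grid
  src <- 180 * 200 / 356
  expect_equal(w3$power[1, 2, i178], 2 * src + 5000, tolerance = 1e-9)

  # stimulus-onset anchor is preserved for any rt
  i0 <- which(tt == 0)
  for (rt in c(150, 356, 600, 900))
    expect_equal(timewarp(tf, rt_ms = rt)$power[1, 1, i0],
                 tf$power[1, 1, i0], tolerance = 1e-9)

  expect_warning(timewarp(tf, rt_ms = -5), "rejected")
  expect_error(timewarp(tf, rt_ms = 356, target_rt_ms = 2000), "target")
})

test_that("single-trial normalization has unit time-mean and scale invariance", {
  tt <- seq(-1000, 1496, by = 4)
  set.seed(7)
  pow <- array(rexp(2 * 3 * length(tt)) + 0.1, c(2, 3, length(tt)))
  tf <- make_tf(pow, tt)
  nn <- normalize_trial(tf)
  for (i in 1:2) for (k in 1:3)
    expect_equal(mean(nn$power[i, k, ]), 1, tolerance = 1e-12)

  tf7 <- tf
  tf7$power[1, , ] <- tf7$power[1, , ] * 7
  nn7 <- normalize_trial(tf7)
  expect_equal(nn7$power[1, , ], nn$power[1, , ], tolerance = 1e-12)

  const <- make_tf(array(3, c(1, 2, length(tt))), tt)
  expect_equal(unname(normalize_trial(const)$power[1, 1, 1]), 1)

  degen <- make_tf(array(0, c(1, 2, length(tt))), tt)
  expect_warning(normalize_trial(degen), "rejected")
})

test_that("ERSP averaging, dB transform and baseline referencing", {
  tt <- seq(-1000, 1496, by = 4)
  np <- length(tt)

  # constant input -> 0 dB everywhere
  e0 <- average_and_db(make_tf(array(5, c(3, 2, np)), tt))
  expect_equal(max(abs(e0$db)), 0, tolerance = 1e-12)

  # halved post-stimulus power at one frequency -> -3.0103 dB there
  pow <- array(1, c(2, 2, np))
  pow[, 2, tt > 0] <- 0.5
  e1 <- average_and_db(make_tf(pow, tt))
  expect_equal(e1$db[2, which(tt == 400)], 10 * log10(0.5),
               tolerance = 1e-9)
  expect_equal(e1$db[1, which(tt == 400)], 0, tolerance = 1e-12)

  # uniform power rescaling (+c dB) cancels against the baseline
  c_db <- 7
  e2 <- average_and_db(make_tf(pow * 10^(c_db / 10), tt))
  expect_equal(e2$db, e1$db, tolerance = 1e-9)

  # baseline dB mean is zero per frequency
  set.seed(1)
  er <- average_and_db(make_tf(array(rexp(5 * 3 * np) + 0.05,
                                     c(5, 3, np)), tt))
  bl <- tt >= -300 & tt <= -100
  expect_equal(max(abs(rowMeans(er$db[, bl]))), 0, tolerance = 1e-9)

  expect_error(average_and_db(make_tf(pow, tt), baseline_ms = c(-3000, -2500)),
               "baseline")
})

test_that("ERSP of common-scale trials is unchanged by normalization", {
  g <- make_freq_grid()
  sp <- quick_spec(seed = 8)
  ep <- simulate_ic_epochs(sp, quick_design(trials_per_cell = 3L), "sitting",
                           seed = 14)
  raw <- compute_ersp(ep, g, normalize = FALSE, resample = FALSE)
  nrm <- compute_ersp(ep, g, normalize = TRUE, resample = FALSE)
  # same trials, same scale: normalization only reweights trials, so the
  # two maps agree closely
  expect_lt(median(abs(raw$db - nrm$db), na.rm = TRUE), 0.35)
})

test_that("1 ms resampling makes the 41-sample suppression window exact", {
  g <- make_freq_grid()
  sp <- quick_spec(seed = 9)
  ep <- simulate_ic_epochs(sp, quick_design(trials_per_cell = 2L), "sitting",
                           seed = 15)
  e <- compute_ersp(ep, g)
  expect_equal(median(diff(e$times_ms)), 1)
  ms <- mean_suppression(e, t_i = 400, f_bin = 10, n_neighbor = 1)
  expect_equal(ms$n_time, 41L)
  expect_equal(ms$n_freq, 3L)
})
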