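# Weighted feature construction and repetitive ROI-targeted clustering.

fake_ic <- function(id, part, xyz, rv = 0.05) {
  list(ic_id = id, participant = part, dipole_xyz = xyz,
       residual_variance = rv)
}

# a cohort of ICs with two compact planted blobs and uniform scatter
blob_ics <- function(n_blob = 20, n_scatter = 40, seed = 1,
                     left = c(-33, -10, 49), right = c(38, -7, 48)) {
  set.seed(seed)
  ics <- list()
  lab <- character(0)
  add <- function(xyz, tag) {
    i <- length(ics) + 1L
    ics[[i]] <<- fake_ic(sprintf("IC%03d", i), sprintf("P%02d", i %% 30L),
                         xyz, runif(1, 0.02, 0.2))
    lab[i] <<- tag
  }
  for (i in seq_len(n_blob)) add(left + rnorm(3, 0, 5), "left")
  for (i in seq_len(n_blob)) add(right + rnorm(3, 0, 5), "right")
  for (i in seq_len(n_scatter))
    add(c(runif(1, -70, 70), runif(1, -100, 70), runif(1, -45, 80)),
        "scatter")
  list(ics = ics, labels = lab)
}

test_that("identical ICs map to identical feature vectors", {
  ics <- c(lapply(1:2, function(i)
    fake_ic(paste0("A", i), "P1", c(-33, -10, 49), 0.05)),
    list(fake_ic("B", "P2", c(20, 30, 10), 0.1)))
  fx <- build_features(ics, matrix(c(1, 1, 5), 3, 1))
  expect_equal(fx$x[1, ], fx$x[2, ], tolerance = 1e-12)
  expect_false(isTRUE(all.equal(fx$x[1, ], fx$x[3, ])))
})

test_that("dipole/ERSP weighting gives the (10/3)^2 variance ratio", {
  set.seed(2)
  n <- 60
  dip <- matrix(rnorm(3 * n), n)
  ers <- matrix(rnorm(2 * n), n, 2)
  ics <- lapply(seq_len(n), function(i)
    fake_ic(paste0("IC", i), paste0("P", i), dip[i, ]))
  fx <- build_features(ics, ers)
  v <- apply(fx$weighted, 2, var)
  # standardized columns have unit variance, so weighted variances are
  # exactly w^2 and the ratio is (10/3)^2
  expect_equal(unname(v[1] / v[4]), (10 / 3)^2, tolerance = 1e-9)
})

test_that("feature dimension is capped by the available rank", {
  ics <- lapply(1:8, function(i)
    fake_ic(paste0("IC", i), paste0("P", i), rnorm(3)))
  expect_message(fx <- build_features(ics, matrix(rnorm(8), 8, 1)),
                 "reduced")
  expect_equal(ncol(fx$x), 4L)
})

test_that("missing dipoles are excluded with a warning", {
  ics <- list(fake_ic("a", "P1", c(1, 2, 3)),
              fake_ic("b", "P2", c(NA, 2, 3)),
              fake_ic("c", "P3", c(4, 5, 6)))
  expect_warning(fx <- build_features(ics, matrix(rnorm(3), 3, 1)),
                 "missing dipole")
  expect_equal(nrow(fx$x), 2L)
})

test_that("k-means recovers two well-separated planted blobs", {
  bb <- blob_ics(n_blob = 15, n_scatter = 0, seed = 3)
  fx <- build_features(bb$ics, matrix(rnorm(30, 0, 0.01), 30, 1))
  sol <- cluster_once(fx, k = 2, seed = 5)
  a <- sol$assignments
  expect_false(any(is.na(a[1:15]) | is.na(a[16:30])))
  expect_equal(length(unique(a[1:15])), 1L)
  expect_equal(length(unique(a[16:30])), 1L)
  expect_false(a[1] == a[16])
})

test_that("degenerate and outlier geometries behave as specified", {
  ics <- lapply(1:6, function(i) fake_ic(paste0("IC", i), "P1", c(1, 2, 3)))
  fx <- build_features(ics, matrix(0, 6, 1))
  sol <- cluster_once(fx, k = 1, seed = 2)
  expect_equal(sol$clusters$spread, 0)
  expect_equal(sum(is.na(sol$assignments)), 0L)

  set.seed(8)
  pts <- rbind(matrix(rnorm(60 * 3, 0, 1), 60), c(60, 60, 60))
  ics2 <- lapply(seq_len(61), function(i)
    fake_ic(paste0("IC", i), paste0("P", i %% 20), pts[i, ]))
  fx2 <- build_features(ics2, matrix(0, 61, 1))
  expect_warning(sol2 <- cluster_once(fx2, k = 1, seed = 2), NA)
  expect_true(is.na(sol2$assignments[61]))

  expect_error(cluster_once(fx2, k = 100), "exceeds")
})

test_that("repetitive clustering is deterministic and honors weights", {
  bb <- blob_ics(n_blob = 12, n_scatter = 25, seed = 4)
  fx <- build_features(bb$ics, matrix(rnorm(49, 0, 0.01), 49, 1))

  r1 <- repetitive_cluster(fx, c(-33, -10, 49), n_reps = 20, k = 5,
                           seed = 99)
  r2 <- repetitive_cluster(fx, c(-33, -10, 49), n_reps = 20, k = 5,
                           seed = 99)
  expect_identical(r1$members, r2$members)
  expect_identical(r1$rep, r2$rep)

  # n_reps = 1 returns that repetition's candidate (all z contributions 0)
  expect_warning(
    r3 <- repetitive_cluster(fx, c(-33, -10, 49), n_reps = 1, k = 5,
                             seed = 7),
    "zero-variance")
  expect_equal(r3$rep, 1)

  # a dominating weight on n_subjects selects the max-subject candidate
  rw <- repetitive_cluster(fx, c(-33, -10, 49), n_reps = 30, k = 5,
                           seed = 13,
                           selection_weights = c(
                             n_subjects = 1000, ics_per_subject = -2,
                             spread = -1, mean_rv = -1, dist_to_roi = -1,
                             mahalanobis = -1))
  win <- rw$candidates[rw$candidates$rep == rw$rep, ]
  expect_equal(win$n_subjects, max(rw$candidates$n_subjects))
})

test_that("bilateral runs recover disjoint planted lateral clusters", {
  bb <- blob_ics(n_blob = 14, n_scatter = 30, seed = 6)
  fx <- build_features(bb$ics, matrix(rnorm(58, 0, 0.01), 58, 1))
  bi <- run_bilateral(fx, n_reps = 25, k = 6, seed = 21)
  expect_length(bi$overlap, 0L)
  left_ids <- fx$meta$ic_id[bb$labels == "left"]
  right_ids <- fx$meta$ic_id[bb$labels == "right"]
  expect_gte(mean(left_ids %in% bi$left$members), 0.9)
  expect_gte(mean(right_ids %in% bi$right$members), 0.9)
  expect_error(run_bilateral(list()), "no ICs")
})
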