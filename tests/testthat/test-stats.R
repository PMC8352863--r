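# Statistics layer: normalization, mixed ANOVA against a from-scratch SS
# oracle, Welch t, partial Spearman, FDR.

test_that("ordered quantile normalization maps ranks to normal scores", {
  expect_equal(orq_normalize(c(3, 1, 2)),
               qnorm(c(5 / 6, 1 / 6, 3 / 6)), tolerance = 1e-12)
  expect_equal(orq_normalize(c(3, 1, 2))[2], -0.9674216, tolerance = 1e-6)

  # invariance under strictly monotone transforms
  set.seed(10)
  x <- rexp(50)
  expect_equal(orq_normalize(x), orq_normalize(log(x)), tolerance = 1e-12)
  expect_equal(orq_normalize(x), orq_normalize(x^3), tolerance = 1e-12)
  expect_equal(rank(orq_normalize(x)), rank(x))

  # large-sample output is symmetric (skewness near 0)
  set.seed(11)
  y <- orq_normalize(rlnorm(1001))
  sk <- mean((y - mean(y))^3) / sd(y)^3
  expect_lt(abs(sk), 0.1)

  expect_error(orq_normalize(c(1, 2)), "at least 3")
  expect_error(orq_normalize(rep(2, 5)), "all values equal")
  expect_error(orq_normalize(c(1, NA, 3)), "non-finite")
})

test_that("mixed 2x2 ANOVA matches the sums-of-squares oracle", {
  toy_sets <- list(
    data.frame( # hand-constructed 4-participant set
      participant = rep(c("s1", "s2", "s3", "s4"), each = 2),
      age_group = rep(c("young", "young", "old", "old"), each = 2),
      condition = rep(c("sitting", "walking"), 4),
      value = c(1.0, 2.0, 1.5, 2.5, 3.0, 3.5, 2.0, 4.0)),
    { set.seed(20)
      expand.grid(condition = c("sitting", "walking"),
                  participant = sprintf("s%d", 1:10)) |>
        transform(age_group = rep(c("young", "old"), each = 2,
                                  length.out = 20),
                  value = rnorm(20)) },
    { set.seed(21)
      expand.grid(condition = c("a", "b"),
                  participant = sprintf("s%d", 1:8)) |>
        transform(age_group = rep(c("g1", "g2"), each = 8),
                  value = rnorm(16, sd = 3) + rep(c(0, 1), 8)) })
  for (d in toy_sets) {
    got <- mixed_anova_2x2(d, "value")
    ora <- oracle_mixed_anova(d$value, d$age_group, d$condition,
                              d$participant)
    for (eff in c("between", "within", "interaction")) {
      row <- got[got$effect == eff, ]
      expect_equal(row$F, unname(ora[[eff]]["F"]), tolerance = 1e-8)
      expect_equal(row$p, unname(ora[[eff]]["p"]), tolerance = 1e-8)
      expect_equal(row$ges, unname(ora[[eff]]["ges"]), tolerance = 1e-8)
    }
  }
})

test_that("mixed ANOVA degenerate and invariance cases", {
  d <- expand.grid(condition = c("sitting", "walking"),
                   participant = sprintf("s%d", 1:6))
  d$age_group <- rep(c("young", "old"), each = 6)
  d$value <- 3.3
  flat <- mixed_anova_2x2(d, "value")
  expect_equal(flat$F, c(0, 0, 0))
  expect_equal(flat$p, c(1, 1, 1))

  set.seed(30)
  d$value <- rnorm(12)
  a1 <- mixed_anova_2x2(d, "value")
  d2 <- d
  d2$value <- d$value + 100
  expect_equal(mixed_anova_2x2(d2, "value")$F, a1$F, tolerance = 1e-9)

  # a participant missing one within level is dropped with a warning
  d3 <- d[-1, ]
  expect_warning(a3 <- mixed_anova_2x2(d3, "value"), "dropped")
  expect_equal(a3$df2[1], 3) # 5 complete participants minus 2 groups
})

test_that("Welch t-test matches the closed-form statistic", {
  a <- c(1, 2, 3)
  b <- c(1, 2, 3, 4, 5)
  wt <- welch_t(a, b)
  se <- sqrt(var(a) / 3 + var(b) / 5)
  t_hand <- (mean(a) - mean(b)) / se
  df_hand <- se^4 / ((var(a) / 3)^2 / 2 + (var(b) / 5)^2 / 4)
  expect_equal(wt$t, t_hand, tolerance = 1e-12)
  expect_equal(wt$df, df_hand, tolerance = 1e-12)
  expect_equal(wt$p, 2 * pt(-abs(t_hand), df_hand), tolerance = 1e-12)

  expect_equal(welch_t(a, a)$t, 0)
  ws <- welch_t(b, a)
  expect_equal(ws$t, -wt$t, tolerance = 1e-12)
  expect_equal(ws$p, wt$p, tolerance = 1e-12)
  expect_error(welch_t(c(1, 1), c(2, 2)), "zero variance")
  expect_error(welch_t(1, c(1, 2)), "n >= 2")
})

test_that("partial Spearman matches the rank-residual oracle", {
  set.seed(40)
  x <- rnorm(30)
  y <- 0.5 * x + rnorm(30)
  z <- 0.3 * x + rnorm(30)
  ps <- partial_spearman(x, y, z)
  # oracle: correlate residuals of rank regressions
  rx <- rank(x); ry <- rank(y); rz <- rank(z)
  ex <- residuals(lm(rx ~ rz))
  ey <- residuals(lm(ry ~ rz))
  expect_equal(ps$r, cor(ex, ey), tolerance = 1e-10)
  expect_equal(ps$df, 27)

  # x = y gives r = 1
  expect_equal(partial_spearman(x, x, z)$r, 1, tolerance = 1e-12)

  # an orthogonal control reduces to the plain Spearman correlation
  xo <- c(1, 2, 3, 4, 5, 6, 7, 8)
  yo <- c(2, 1, 4, 3, 6, 5, 8, 7)
  zo <- c(1, 1, 2, 2, 2, 2, 1, 1) + c(0.1, 0.2, 0.3, 0.4, 0.4, 0.3, 0.2, 0.1)
  rxz <- cor(rank(xo), rank(zo))
  ryz <- cor(rank(yo), rank(zo))
  if (abs(rxz) < 1e-12 && abs(ryz) < 1e-12)
    expect_equal(partial_spearman(xo, yo, zo)$r,
                 cor(xo, yo, method = "spearman"), tolerance = 1e-12)

  # group controls are accepted as factors
  g <- factor(rep(c("old", "young"), 15))
  expect_type(partial_spearman(x, y, g)$r, "double")

  expect_error(partial_spearman(x, y, x), "collinear")
  expect_error(partial_spearman(1:4, 1:4, 1:3), "unequal")
  expect_error(partial_spearman(1:4, c(2, 1, 4, 3), c(1, 2, 1, 2)), "n >= 5")
})

test_that("BH adjustment matches the step-up oracle", {
  expect_equal(fdr_bh(0.03), 0.03)
  expect_equal(fdr_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))

  # brute-force step-up oracle
  set.seed(50)
  p <- runif(25)
  o <- order(p)
  m <- length(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  expected <- numeric(m)
  expected[o] <- adj
  expect_equal(fdr_bh(p), expected, tolerance = 1e-12)

  expect_true(all(fdr_bh(p) >= p))
  expect_equal(order(fdr_bh(p)[o]), seq_len(m)) # order-preserving
  expect_error(fdr_bh(c(0.5, 1.2)), "0, 1")
  expect_error(fdr_bh(c(0.5, NA)), "0, 1")
})

test_that("planted null cohorts keep the ANOVA at its nominal level", {
  # statistics-layer type-I check on the generator's planted participant
  # measures (no TF chain): pooled rejection rate over replicates ~ 5%
  cfg <- zero_effects()
  n_rep <- 60
  rej <- 0
  tot <- 0
  for (r in seq_len(n_rep)) {
    co <- simulate_cohort(6, cfg, design = quick_design(), seed = 3000 + r,
                          simulate_epochs = FALSE)
    tr <- co$truth[co$truth$condition %in% c("sitting", "walking"), ]
    for (m in c("alpha_db", "beta_db", "offset")) {
      a <- mixed_anova_2x2(data.frame(
        participant = tr$participant, age_group = tr$age_group,
        condition = tr$condition, value = tr[[m]]), "value")
      rej <- rej + sum(a$p < 0.05)
      tot <- tot + 3
    }
  }
  expect_gt(rej / tot, 0.01)
  expect_lt(rej / tot, 0.10)
})
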