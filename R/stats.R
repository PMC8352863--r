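# Group-level inference: ordered quantile normalization, mixed 2x2 ANOVA
# with generalized eta squared, Welch t-tests, partial Spearman rank
# correlations, and Benjamini-Hochberg FDR adjustment.

#' Ordered quantile normalization
#'
#' Rank-based mapping onto normal quantiles,
#' `y_i = qnorm((rank(x_i) - 0.5) / n)`, with average ranks for ties. The
#' transform is rank-preserving and invariant to strictly monotone
#' transformations of the input.
#'
#' @param x Numeric vector, `n >= 3`, finite, not all equal.
#' @return Normalized vector.
#' @examples
#' orq_normalize(c(3, 1, 2)) # +0.967, -0.967, 0
#' @export
orq_normalize <- function(x) {
  if (length(x) < 3) stop("need at least 3 values")
  if (any(!is.finite(x))) stop("non-finite values")
  if (length(unique(x)) == 1) stop("all values equal: no ordering information")
  stats::qnorm((rank(x, ties.method = "average") - 0.5) / length(x))
}

#' Mixed 2x2 ANOVA with generalized eta squared
#'
#' Between-subject factor (age group) by within-subject factor (motor
#' task) ANOVA on participant-level measures, fitted via `aov` with a
#' subject error stratum. Generalized eta squared follows Olejnik-Algina:
#' effect SS over effect SS plus all error SS (between-subject and
#' within-subject residuals). Participants missing a within level are
#' dropped with a warning.
#'
#' @param data Long-format data frame.
#' @param dv Name of the dependent-variable column.
#' @param between Name of the two-level between factor column.
#' @param within Name of the two-level within factor column.
#' @param subject Name of the subject identifier column.
#' @return Data frame with one row per effect (`between`, `within`,
#'   `interaction`): `df1`, `df2`, `F`, `p`, `ges`.
#' @export
mixed_anova_2x2 <- function(data, dv, between = "age_group",
                            within = "condition", subject = "participant") {
  d <- data.frame(y = data[[dv]],
                  A = factor(data[[between]]),
                  B = factor(data[[within]]),
                  S = factor(data[[subject]]))
  if (nlevels(d$B) != 2) stop("within factor must have exactly 2 levels")
  if (nlevels(d$A) != 2) stop("between factor must have exactly 2 levels")
  counts <- table(d$S)
  incomplete <- names(counts)[counts < 2]
  if (length(incomplete)) {
    warning(length(incomplete),
            " participant(s) dropped: missing a within-factor level")
    d <- d[!d$S %in% incomplete, ]
    d$S <- droplevels(d$S)
  }
  if (min(table(unique(d[, c("A", "S")])$A)) < 2)
    stop("need at least 2 participants per group")
  fit <- stats::aov(y ~ A * B + Error(S), data = d)
  sm <- summary(fit)
  s_between <- sm[["Error: S"]][[1]]
  s_within <- sm[["Error: Within"]][[1]]
  pick <- function(tab, term) {
    i <- match(term, trimws(rownames(tab)))
    c(ss = tab[i, "Sum Sq"], df = tab[i, "Df"])
  }
  ss_a <- pick(s_between, "A")
  ss_s <- pick(s_between, "Residuals")
  ss_b <- pick(s_within, "B")
  ss_ab <- pick(s_within, "A:B")
  ss_e <- pick(s_within, "Residuals")
  err_all <- ss_s[["ss"]] + ss_e[["ss"]]
  row <- function(effect, eff, err) {
    ms_eff <- eff[["ss"]] / eff[["df"]]
    ms_err <- err[["ss"]] / err[["df"]]
    if (eff[["ss"]] < 1e-12) {
      f <- 0
      p <- 1
    } else {
      f <- ms_eff / ms_err
      p <- stats::pf(f, eff[["df"]], err[["df"]], lower.tail = FALSE)
    }
    ges <- if (eff[["ss"]] < 1e-12 && err_all < 1e-12) 0
           else eff[["ss"]] / (eff[["ss"]] + err_all)
    data.frame(effect = effect, df1 = eff[["df"]], df2 = err[["df"]],
               F = f, p = p, ges = ges, stringsAsFactors = FALSE)
  }
  rbind(row("between", ss_a, ss_s),
        row("within", ss_b, ss_e),
        row("interaction", ss_ab, ss_e))
}

#' Welch two-sample t-test
#'
#' Unequal-variance t statistic with Satterthwaite degrees of freedom.
#'
#' @param a,b Numeric samples, each `n >= 2`.
#' @return List with `t`, `df`, `p`.
#' @export
welch_t <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) stop("each sample needs n >= 2")
  if (stats::var(a) == 0 && stats::var(b) == 0)
    stop("zero variance in both samples")
  ht <- stats::t.test(a, b, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}

#' Partial Spearman rank correlation
#'
#' Rank-transforms all three variables, computes Pearson correlations on
#' the ranks, and partials out the control:
#' `r_xy.z = (r_xy - r_xz r_yz) / sqrt((1 - r_xz^2)(1 - r_yz^2))`, with
#' `df = n - 3` and a t-approximation p-value.
#'
#' @param x,y Numeric vectors.
#' @param control Control variable (numeric or factor, e.g. age group).
#' @return List with `r`, `df`, `p`.
#' @export
partial_spearman <- function(x, y, control) {
  if (is.factor(control) || is.character(control))
    control <- as.numeric(factor(control))
  n <- length(x)
  if (length(y) != n || length(control) != n) stop("unequal lengths")
  if (n < 5) stop("need n >= 5")
  rx <- rank(x)
  ry <- rank(y)
  rz <- rank(control)
  rxy <- stats::cor(rx, ry)
  rxz <- stats::cor(rx, rz)
  ryz <- stats::cor(ry, rz)
  den <- (1 - rxz^2) * (1 - ryz^2)
  if (den < 1e-12) stop("control is collinear with x or y")
  r <- (rxy - rxz * ryz) / sqrt(den)
  r <- max(-1, min(1, r))
  df <- n - 3
  t <- r * sqrt(df / max(1 - r^2, 1e-12))
  list(r = r, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values, monotone and capped at 1.
#'
#' @param pvals Numeric p-values in `[0, 1]`.
#' @return Adjusted p-values.
#' @export
fdr_bh <- function(pvals) {
  if (any(!is.finite(pvals)) || any(pvals < 0 | pvals > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}
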