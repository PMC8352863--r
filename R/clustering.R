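# Repetitive ROI-targeted clustering of ICs on weighted dipole + ERSP
# features, with six-metric weighted selection of the winning solution.

#' Build weighted, PCA-compressed IC feature vectors
#'
#' Standardizes each measure across ICs, applies the dipole (10) and ERSP
#' (3) weights, concatenates, and compresses jointly to the first
#' `ndim` principal components. ICs with a missing dipole are excluded
#' with a warning.
#'
#' @param ics List of IC records (each with `dipole_xyz`, `participant`,
#'   `residual_variance`, `ic_id`).
#' @param ersp_summaries Numeric matrix, one row per IC (aligned with
#'   `ics`), holding a coarse ERSP representation.
#' @param w_dipole,w_ersp Feature weights.
#' @param ndim Target dimensionality (reduced to the available rank if
#'   fewer input dimensions exist, with a message).
#' @return Object of class `ic_features`: `x` (scores), `weighted`
#'   (pre-PCA weighted matrix), `meta` (per-IC data frame).
#' @export
build_features <- function(ics, ersp_summaries, w_dipole = 10, w_ersp = 3,
                           ndim = 10L) {
  stopifnot(length(ics) >= 1)
  if (is.null(dim(ersp_summaries)))
    ersp_summaries <- matrix(ersp_summaries, nrow = length(ics))
  stopifnot(nrow(ersp_summaries) == length(ics))
  has_dip <- vapply(ics, function(ic)
    !is.null(ic$dipole_xyz) && all(is.finite(ic$dipole_xyz)), logical(1))
  if (!all(has_dip)) {
    warning(sum(!has_dip), " IC(s) excluded: missing dipole")
    ics <- ics[has_dip]
    ersp_summaries <- ersp_summaries[has_dip, , drop = FALSE]
  }
  dip <- t(vapply(ics, `[[`, numeric(3), "dipole_xyz"))
  std <- function(m) {
    apply(m, 2, function(col) {
      s <- stats::sd(col)
      if (!is.finite(s) || s == 0) rep(0, length(col)) else (col - mean(col)) / s
    })
  }
  weighted <- cbind(std(dip) * w_dipole, std(ersp_summaries) * w_ersp)
  pc <- stats::prcomp(weighted, center = TRUE, scale. = FALSE)
  keep <- max(1L, min(ndim, ncol(pc$x), sum(pc$sdev > 1e-10)))
  if (keep < ndim)
    message("feature dimension reduced to ", keep, " (available rank)")
  meta <- data.frame(
    ic_id = vapply(ics, `[[`, character(1), "ic_id"),
    participant = vapply(ics, `[[`, character(1), "participant"),
    x = dip[, 1], y = dip[, 2], z = dip[, 3],
    rv = vapply(ics, `[[`, numeric(1), "residual_variance"),
    stringsAsFactors = FALSE)
  structure(list(x = pc$x[, seq_len(keep), drop = FALSE],
                 weighted = weighted, meta = meta),
            class = "ic_features")
}

#' @export
print.ic_features <- function(x, ...) {
  cat(sprintf("IC features: %d ICs x %d dims (weighted dipole + ERSP)\n",
              nrow(x$x), ncol(x$x)))
  invisible(x)
}

#' One k-means clustering of IC features with 3-SD outlier removal
#'
#' Partitions the feature vectors with k-means, then relabels ICs whose
#' distance to their centroid exceeds `outlier_sd` SD of all member
#' distances as outliers, and computes per-cluster quality metrics
#' (participants, ICs per participating subject, dipole spread in mm,
#' mean residual variance, distance of the dipole centroid to an optional
#' ROI).
#'
#' @param features An [build_features()] `ic_features` object.
#' @param k Number of clusters.
#' @param outlier_sd Outlier threshold in SD of member distances.
#' @param seed Integer seed for the k-means starts.
#' @param nstart k-means restarts.
#' @param roi_xyz Optional ROI (Talairach mm) for the distance metric.
#' @param max_outlier_frac Warn when a larger fraction is removed.
#' @return Object of class `cluster_solution`: `assignments` (cluster id
#'   per IC, `NA` = outlier), `clusters` (metric data frame), `k`, `seed`.
#' @export
cluster_once <- function(features, k = 14L, outlier_sd = 3, seed = 1L,
                         nstart = 3L, roi_xyz = NULL,
                         max_outlier_frac = 0.2) {
  stopifnot(inherits(features, "ic_features"))
  fm <- features$x
  if (k > nrow(fm)) stop("k exceeds the number of ICs")
  km <- with_seed(seed,
                  stats::kmeans(fm, centers = k, nstart = nstart,
                                iter.max = 100))
  dists <- sqrt(rowSums((fm - km$centers[km$cluster, , drop = FALSE])^2))
  # outliers: centroid-distance z-score above outlier_sd within the
  # member distance distribution of each cluster
  out <- rep(FALSE, length(dists))
  for (cl in seq_len(k)) {
    mem <- km$cluster == cl
    sdd <- stats::sd(dists[mem])
    if (is.finite(sdd) && sdd > 0)
      out[mem] <- (dists[mem] - mean(dists[mem])) / sdd > outlier_sd
  }
  if (mean(out) > max_outlier_frac)
    warning(sprintf("outlier rule removed %.0f%% of ICs", 100 * mean(out)))
  assign <- ifelse(out, NA_integer_, km$cluster)
  meta <- features$meta
  rows <- lapply(seq_len(k), function(cl) {
    mem <- which(!is.na(assign) & assign == cl)
    if (!length(mem)) {
      return(data.frame(cluster = cl, n_ics = 0L, n_subjects = 0L,
                        ics_per_subject = NA_real_, spread = NA_real_,
                        mean_rv = NA_real_, dist_to_roi = NA_real_,
                        cx = NA_real_, cy = NA_real_, cz = NA_real_))
    }
    dxyz <- as.matrix(meta[mem, c("x", "y", "z")])
    ctr <- colMeans(dxyz)
    data.frame(
      cluster = cl, n_ics = length(mem),
      n_subjects = length(unique(meta$participant[mem])),
      ics_per_subject = length(mem) /
        length(unique(meta$participant[mem])),
      spread = mean(sqrt(rowSums((dxyz - rep(ctr, each = nrow(dxyz)))^2))),
      mean_rv = mean(meta$rv[mem]),
      dist_to_roi = if (is.null(roi_xyz)) NA_real_
                    else sqrt(sum((ctr - roi_xyz)^2)),
      cx = ctr[1], cy = ctr[2], cz = ctr[3])
  })
  structure(
    list(assignments = assign, clusters = do.call(rbind, rows),
         k = k, seed = seed, outlier = out),
    class = "cluster_solution"
  )
}

#' @export
print.cluster_solution <- function(x, ...) {
  cat(sprintf("Cluster solution: k = %d, %d ICs (%d outliers)\n", x$k,
              length(x$assignments), sum(is.na(x$assignments))))
  print(x$clusters[, c("cluster", "n_ics", "n_subjects", "spread",
                       "mean_rv", "dist_to_roi")], row.names = FALSE)
  invisible(x)
}

#' Repetitive ROI-targeted clustering with weighted solution scoring
#'
#' Repeats [cluster_once()] `n_reps` times with derived seeds. In each
#' repetition the candidate cluster is the one whose dipole centroid lies
#' nearest the ROI. Across repetitions the six candidate metrics are
#' z-scored and combined into the selection score
#' `3 z(n_subjects) - 2 z(ics_per_subject) - z(spread) - z(mean_rv) -
#' z(dist_to_roi) - z(mahalanobis)`, where the Mahalanobis term is the
#' distance of a candidate's base metrics from the median candidate. The
#' highest-scoring repetition wins; ties break to the lowest ROI distance,
#' then the lowest repetition index. Zero-variance metrics contribute 0
#' with a warning.
#'
#' @param features An `ic_features` object.
#' @param roi_xyz Region of interest, Talairach mm.
#' @param n_reps Number of repetitions (>= 1).
#' @param k,outlier_sd,nstart Passed to [cluster_once()].
#' @param selection_weights Named weights for the six metrics.
#' @param seed Master seed.
#' @return Object of class `repetitive_solution`: winning `solution`,
#'   `winner_cluster` id, `members` (IC ids), `candidates` (per-rep metric
#'   and score table), `rep` (winning repetition).
#' @export
repetitive_cluster <- function(features, roi_xyz, n_reps = 10000L,
                               k = 14L, outlier_sd = 3, nstart = 3L,
                               selection_weights = c(
                                 n_subjects = 3, ics_per_subject = -2,
                                 spread = -1, mean_rv = -1,
                                 dist_to_roi = -1, mahalanobis = -1),
                               seed = 1L) {
  if (n_reps < 1) stop("n_reps must be >= 1")
  base_metrics <- c("n_subjects", "ics_per_subject", "spread", "mean_rv",
                    "dist_to_roi")
  cand <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    sol <- cluster_once(features, k = k, outlier_sd = outlier_sd,
                        seed = derive_seed(seed, r), nstart = nstart,
                        roi_xyz = roi_xyz)
    cl <- sol$clusters
    cl <- cl[cl$n_ics > 0, , drop = FALSE]
    if (!nrow(cl)) stop("all clusters empty after outlier removal")
    best <- cl[which.min(cl$dist_to_roi), , drop = FALSE]
    cand[[r]] <- cbind(rep = r, best)
  }
  cand <- do.call(rbind, cand)
  M <- as.matrix(cand[, base_metrics])
  med <- apply(M, 2, stats::median)
  S <- stats::cov(M)
  mah <- if (n_reps > 1 && all(is.finite(S))) {
    Sr <- S + diag(1e-8 * pmax(diag(S), 1e-12))
    tryCatch(stats::mahalanobis(M, med, Sr),
             error = function(e) rep(0, nrow(M)))
  } else rep(0, nrow(M))
  cand$mahalanobis <- mah
  zs <- function(v) {
    s <- stats::sd(v)
    if (!is.finite(s) || s == 0) {
      warning("zero-variance selection metric; z contribution set to 0")
      return(rep(0, length(v)))
    }
    (v - mean(v)) / s
  }
  Z <- vapply(names(selection_weights), function(m) zs(cand[[m]]),
              numeric(nrow(cand)))
  Z <- matrix(Z, nrow = nrow(cand),
              dimnames = list(NULL, names(selection_weights)))
  score <- as.numeric(Z %*% selection_weights)
  cand$score <- score
  ord <- order(-cand$score, cand$dist_to_roi, cand$rep)
  win <- cand[ord[1], ]
  solution <- cluster_once(features, k = k, outlier_sd = outlier_sd,
                           seed = derive_seed(seed, win$rep),
                           nstart = nstart, roi_xyz = roi_xyz)
  members <- features$meta$ic_id[
    !is.na(solution$assignments) & solution$assignments == win$cluster]
  structure(
    list(solution = solution, winner_cluster = win$cluster,
         members = members, candidates = cand, rep = win$rep,
         roi_xyz = roi_xyz, selection_weights = selection_weights,
         n_reps = n_reps, seed = seed),
    class = "repetitive_solution"
  )
}

#' @export
print.repetitive_solution <- function(x, ...) {
  win <- x$candidates[x$candidates$rep == x$rep &
                        x$candidates$cluster == x$winner_cluster, ]
  cat(sprintf(
    "Repetitive clustering: %d reps, winner rep %d (score %.2f)\n",
    x$n_reps, x$rep, win$score))
  cat(sprintf(
    "  winning cluster: %d ICs from %d participants; centroid (%.0f, %.0f, %.0f), %.1f mm from ROI\n",
    win$n_ics, win$n_subjects, win$cx, win$cy, win$cz, win$dist_to_roi))
  invisible(x)
}

#' Bilateral repetitive clustering around the two motor ROIs
#'
#' Runs [repetitive_cluster()] independently for the left (-33, -10, 49)
#' and right (38, -7, 48) centrolateral ROIs and reports the membership
#' overlap between the two winners (expected empty; a warning is raised
#' otherwise). Negative x is the left hemisphere.
#'
#' @param features An `ic_features` object.
#' @param left_roi,right_roi ROI coordinates, Talairach mm.
#' @param ... Passed to [repetitive_cluster()].
#' @param seed Master seed (left and right runs derive distinct streams).
#' @return Object of class `bilateral_solution`: `left`, `right`,
#'   `overlap` (IC ids in both winners).
#' @export
run_bilateral <- function(features, left_roi = c(-33, -10, 49),
                          right_roi = c(38, -7, 48), ..., seed = 1L) {
  if (!inherits(features, "ic_features") || nrow(features$x) == 0)
    stop("no ICs to cluster")
  left <- repetitive_cluster(features, left_roi, ...,
                             seed = derive_seed(seed, 1001L))
  right <- repetitive_cluster(features, right_roi, ...,
                              seed = derive_seed(seed, 2002L))
  overlap <- intersect(left$members, right$members)
  if (length(overlap))
    warning(length(overlap), " IC(s) shared between the left and right ",
            "cluster solutions")
  structure(list(left = left, right = right, overlap = overlap),
            class = "bilateral_solution")
}

#' @export
print.bilateral_solution <- function(x, ...) {
  cat("Bilateral repetitive clustering\n")
  cat("-- left ROI --\n")
  print(x$left)
  cat("-- right ROI --\n")
  print(x$right)
  cat(sprintf("Overlap: %d IC(s)\n", length(x$overlap)))
  invisible(x)
}

#' Export a winning cluster solution as TSV
#'
#' One row per IC with participant, cluster label (winning cluster,
#' other, or outlier) and dipole coordinates.
#'
#' @param rsol A `repetitive_solution`.
#' @param features The `ic_features` used for clustering.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
export_cluster_tsv <- function(rsol, features, path) {
  a <- rsol$solution$assignments
  lab <- ifelse(is.na(a), "outlier",
                ifelse(a == rsol$winner_cluster, "winner", "other"))
  df <- cbind(features$meta, cluster = a, label = lab)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
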