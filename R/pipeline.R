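# End-to-end orchestration: synthetic cohort -> ERSP -> clustering ->
# spectral parameterization -> desynchronization measures -> statistics.

#' Pipeline run configuration
#'
#' Collects every tunable parameter of the analysis chain. Defaults follow
#' the study configuration: 15 participants per group, 100 stimuli per
#' eccentricity and hemifield per condition, 37 log-spaced frequencies
#' 4-40 Hz, warp target 356 ms, baseline -300:-100 ms, k = 14 clusters
#' with 10,000 repetitions, ROIs (-33, -10, 49) and (38, -7, 48), alpha
#' 8-12 Hz and beta 16-30 Hz, aperiodic fit 2-40 Hz, statistical contrast
#' sitting vs walking.
#'
#' @param seed Master seed for the whole run.
#' @param n_per_group Participants per age group.
#' @param conditions Simulated motor conditions.
#' @param contrast The two conditions entering the statistics.
#' @param trials_per_cell Stimuli per angle x hemifield x condition.
#' @param srate_hz Sampling rate.
#' @param n_scatter_ics Non-motor ICs per participant.
#' @param spread_mm ROI dipole cloud SD.
#' @param effects An [effect_config()].
#' @param target_rt_ms Warp target.
#' @param baseline_ms Baseline window.
#' @param k,n_reps,nstart,outlier_sd Clustering parameters.
#' @param psd_window_s,psd_fit_range PSD parameters.
#' @param summary_nf,summary_nt Coarse ERSP summary grid for clustering
#'   features.
#' @return A list of class `run_config`.
#' @export
run_config <- function(seed = 1L,
                       n_per_group = 15L,
                       conditions = c("sitting", "standing", "walking"),
                       contrast = c("sitting", "walking"),
                       trials_per_cell = 100L,
                       srate_hz = 250,
                       n_scatter_ics = 1L,
                       spread_mm = 6,
                       effects = effect_config(),
                       target_rt_ms = 356,
                       baseline_ms = c(-300, -100),
                       k = 14L,
                       n_reps = 10000L,
                       nstart = 3L,
                       outlier_sd = 3,
                       psd_window_s = 2,
                       psd_fit_range = c(2, 40),
                       summary_nf = 2L,
                       summary_nt = 3L) {
  if (!all(contrast %in% conditions))
    stop("contrast conditions must be simulated conditions")
  if (length(contrast) != 2) stop("contrast must name exactly 2 conditions")
  cfg <- as.list(environment())
  class(cfg) <- "run_config"
  cfg
}

#' Reduced-size configuration for examples and replicate studies
#'
#' Same chain and defaults-by-structure as [run_config()], scaled so one
#' full run completes in seconds: 8 participants per group, sitting and
#' walking only, 48 trials per condition, 3 ICs per participant, k = 6
#' clusters, 30 clustering repetitions.
#'
#' @param seed Master seed.
#' @param ... Overrides forwarded to [run_config()] (take precedence over
#'   the scaled defaults).
#' @return A `run_config`.
#' @export
demo_run_config <- function(seed = 1L, ...) {
  args <- list(seed = seed, n_per_group = 8L,
               conditions = c("sitting", "walking"),
               trials_per_cell = 8L, k = 6L, n_reps = 30L)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(run_config, args)
}

#' @export
print.run_config <- function(x, ...) {
  cat(sprintf(
    "Run config: seed %d, %d/group, conditions %s, %d trials/cell\n",
    x$seed, x$n_per_group, paste(x$conditions, collapse = "+"),
    x$trials_per_cell))
  cat(sprintf("  clustering k=%d x %d reps; contrast %s vs %s\n", x$k,
              x$n_reps, x$contrast[1], x$contrast[2]))
  invisible(x)
}

#' Write / read a run configuration as JSON
#'
#' The JSON round trip is lossless: `read_config(write_config(cfg, f))`
#' reproduces `cfg`.
#'
#' @param config A `run_config`.
#' @param path JSON file path.
#' @return `path` / the `run_config`.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  raw <- unclass(config)
  # named numeric vectors must become JSON objects to keep their names
  raw$effects <- lapply(unclass(raw$effects), function(x)
    if (is.numeric(x) && !is.null(names(x))) as.list(x) else x)
  jsonlite::write_json(raw, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  eff <- raw$effects
  eff[names(eff) != "sd"] <- lapply(eff[names(eff) != "sd"], function(x)
    if (is.list(x)) unlist(x) else x)
  raw$effects <- do.call(effect_config, eff)
  do.call(run_config, raw)
}

# Block-average an ERSP dB map onto a coarse (nf x nt) grid for the
# clustering feature vector.
coarse_ersp_summary <- function(ersp, nf = 8L, nt = 10L) {
  db <- ersp$db
  fi <- cut(seq_len(nrow(db)), nf, labels = FALSE)
  ti <- cut(seq_len(ncol(db)), nt, labels = FALSE)
  out <- matrix(NA_real_, nf, nt)
  for (i in seq_len(nf))
    for (j in seq_len(nt))
      out[i, j] <- mean(db[fi == i, ti == j], na.rm = TRUE)
  out[!is.finite(out)] <- 0
  as.numeric(out)
}

#' Run the full analysis pipeline
#'
#' Executes synthetic cohort generation, per-IC ERSP computation,
#' bilateral repetitive clustering, participant-level desynchronization
#' extraction, spectral parameterization, dual-task costs, and the
#' statistics layer. Deterministic given `config$seed`. With `out_dir`
#' set, writes all result tables as TSV plus a JSON run manifest and a
#' plain-text log.
#'
#' @param config A [run_config()].
#' @param out_dir Optional artifact directory.
#' @param verbose Print stage progress.
#' @return An object of class `pipeline_result`.
#' @export
run_all <- function(config = run_config(), out_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  log_lines <- character(0)
  say <- function(...) {
    msg <- sprintf(...)
    log_lines <<- c(log_lines, paste0(format(Sys.time(), "%H:%M:%S "), msg))
    if (verbose) message(msg)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE))
  }

  say("synth: simulating cohort (seed %d)", config$seed)
  design <- make_design(n_per_group = config$n_per_group,
                        conditions = config$conditions,
                        trials_per_cell = config$trials_per_cell,
                        srate_hz = config$srate_hz)
  cohort <- stage("synth", simulate_cohort(
    n_per_group = config$n_per_group, config = config$effects,
    design = design, seed = config$seed, spread_mm = config$spread_mm,
    n_scatter_ics = config$n_scatter_ics))

  say("timefreq: ERSPs for %d ICs x %d conditions", length(cohort$ics),
      length(design$conditions))
  grid <- make_freq_grid()
  ic_ersps <- stage("timefreq", lapply(cohort$ics, function(ic) {
    es <- lapply(design$conditions, function(cn)
      compute_ersp(ic$epochs[[cn]], grid,
                   target_rt_ms = config$target_rt_ms,
                   baseline_ms = config$baseline_ms))
    names(es) <- design$conditions
    es
  }))

  say("clustering: bilateral repetitive clustering (k=%d, %d reps)",
      config$k, config$n_reps)
  summaries <- t(vapply(ic_ersps, function(es)
    coarse_ersp_summary(average_ersps(es), config$summary_nf,
                        config$summary_nt),
    numeric(config$summary_nf * config$summary_nt)))
  features <- stage("clustering",
                    build_features(cohort$ics, summaries))
  bilateral <- stage("clustering", run_bilateral(
    features, k = config$k, n_reps = config$n_reps,
    nstart = config$nstart, outlier_sd = config$outlier_sd,
    seed = derive_seed(config$seed, 777L)))
  members <- union(bilateral$left$members, bilateral$right$members)
  say("clustering: %d member ICs (%d left, %d right, overlap %d)",
      length(members), length(bilateral$left$members),
      length(bilateral$right$members), length(bilateral$overlap))

  ids <- vapply(cohort$ics, `[[`, character(1), "ic_id")
  member_idx <- match(members, ids)
  part_of <- vapply(cohort$ics, `[[`, character(1), "participant")[member_idx]
  participants <- unique(cohort$behavior$participant)
  have <- participants[participants %in% part_of]
  if (length(have) < length(participants))
    warning(length(participants) - length(have),
            " participant(s) without a motor-cluster IC excluded")

  say("desync: participant ERSPs and suppression measures")
  ersps <- list()
  meta <- NULL
  for (pid in have) {
    idx <- member_idx[part_of == pid]
    for (cn in config$contrast) {
      ersps[[length(ersps) + 1L]] <-
        average_ersps(lapply(idx, function(j) ic_ersps[[j]][[cn]]))
      meta <- rbind(meta, data.frame(
        participant = pid,
        age_group = cohort$behavior$age_group[
          cohort$behavior$participant == pid],
        condition = cn, stringsAsFactors = FALSE))
    }
  }
  desync <- stage("desync", extract_desync(ersps, meta))

  say("spectral: PSD and aperiodic parameterization")
  spectral <- stage("spectral", {
    rows <- NULL
    for (i in seq_len(nrow(meta))) {
      pid <- meta$participant[i]
      cn <- meta$condition[i]
      idx <- member_idx[part_of == pid]
      psd <- average_psds(lapply(idx, function(j)
        compute_psd(cohort$ics[[j]]$epochs[[cn]],
                    window_s = config$psd_window_s)))
      fit <- fit_aperiodic(psd, range = config$psd_fit_range)
      pa <- band_peak_power(psd, band_def("alpha")$range, fit)
      pb <- band_peak_power(psd, band_def("beta")$range, fit)
      rows <- rbind(rows, data.frame(
        participant = pid, age_group = meta$age_group[i], condition = cn,
        alpha_power = pa$power, alpha_no_peak = pa$no_peak,
        beta_power = pb$power, beta_no_peak = pb$no_peak,
        offset = fit$offset, exponent = fit$exponent,
        fit_error = fit$fit_error, stringsAsFactors = FALSE))
    }
    rows
  })

  say("stats: costs, ANOVAs, t-tests, partial correlations")
  costs <- stage("stats", cost_table(desync$measures,
                                     single = config$contrast[1],
                                     dual = config$contrast[2]))
  beh <- cohort$behavior[cohort$behavior$participant %in% have, ]
  speed_cost <- dual_task_cost(beh$baseline_walk_speed,
                               beh$dualtask_walk_speed)

  long <- function(df, col) data.frame(
    participant = df$participant, age_group = df$age_group,
    condition = df$condition, value = df[[col]])
  measures_long <- list(
    psd_alpha = long(spectral, "alpha_power"),
    psd_beta = long(spectral, "beta_power"),
    aperiodic_offset = long(spectral, "offset"),
    aperiodic_exponent = long(spectral, "exponent"),
    ersp_alpha = long(desync$measures[desync$measures$band == "alpha", ],
                      "mean_db"),
    ersp_beta = long(desync$measures[desync$measures$band == "beta", ],
                     "mean_db"))
  anova_tbl <- stage("stats", {
    rows <- NULL
    for (m in names(measures_long)) {
      d <- measures_long[[m]]
      a <- mixed_anova_2x2(d, "value")
      cm <- function(g) mean(d$value[d$age_group == g])
      cc <- function(cn) mean(d$value[d$condition == cn])
      a <- cbind(measure = m, a,
                 mean_old = cm("old"), mean_young = cm("young"),
                 mean_single = cc(config$contrast[1]),
                 mean_dual = cc(config$contrast[2]))
      rows <- rbind(rows, a)
    }
    rows
  })

  ttests <- stage("stats", {
    rows <- NULL
    for (b in unique(costs$band)) {
      cb <- costs[costs$band == b, ]
      wt <- welch_t(cb$cost_normalized[cb$age_group == "old"],
                    cb$cost_normalized[cb$age_group == "young"])
      rows <- rbind(rows, data.frame(
        band = b, t = wt$t, df = wt$df, p = wt$p,
        mean_cost_old = mean(cb$cost_pct[cb$age_group == "old"]),
        mean_cost_young = mean(cb$cost_pct[cb$age_group == "young"])))
    }
    rows$p_fdr <- fdr_bh(rows$p)
    rows
  })

  correlations <- stage("stats", {
    rows <- NULL
    for (b in unique(costs$band)) {
      cb <- costs[costs$band == b, ]
      ord <- match(cb$participant, beh$participant)
      ps <- partial_spearman(cb$cost_pct, speed_cost[ord], cb$age_group)
      rows <- rbind(rows, data.frame(
        measure = paste0(b, "_cost"), against = "speed_cost",
        controlled = "age_group", r = ps$r, df = ps$df, p = ps$p))
    }
    # combined sensorimotor cost (mean of both bands): the direct
    # counterpart of the planted desynchronization cost
    comb <- stats::aggregate(cost_pct ~ participant + age_group,
                             data = costs, FUN = mean)
    ord <- match(comb$participant, beh$participant)
    ps <- partial_spearman(comb$cost_pct, speed_cost[ord], comb$age_group)
    rows <- rbind(rows, data.frame(
      measure = "combined_cost", against = "speed_cost",
      controlled = "age_group", r = ps$r, df = ps$df, p = ps$p))
    rows$p_fdr <- fdr_bh(rows$p)
    rows
  })

  signs <- sign_table(anova_tbl)

  result <- structure(
    list(config = config, design = design,
         behavior = cohort$behavior, truth = cohort$truth,
         bilateral = bilateral, members = members,
         desync = desync$measures, grand_peaks = desync$grand,
         spectral = spectral, costs = costs,
         speed_cost = data.frame(participant = beh$participant,
                                 age_group = beh$age_group,
                                 speed_cost_pct = speed_cost),
         anova = anova_tbl, ttests = ttests,
         correlations = correlations, sign_table = signs,
         log = log_lines),
    class = "pipeline_result")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    wt <- function(df, name) utils::write.table(
      df, file.path(out_dir, name), sep = "\t", row.names = FALSE,
      quote = FALSE)
    wt(cohort$behavior, "behavior.tsv")
    wt(desync$measures, "desync_measures.tsv")
    wt(spectral, "spectral.tsv")
    wt(costs, "cost_table.tsv")
    wt(anova_tbl, "anova.tsv")
    wt(ttests, "ttests.tsv")
    wt(correlations, "correlations.tsv")
    wt(signs, "sign_table.tsv")
    export_cluster_tsv(bilateral$left, features,
                       file.path(out_dir, "cluster_left.tsv"))
    export_cluster_tsv(bilateral$right, features,
                       file.path(out_dir, "cluster_right.tsv"))
    raw_cfg <- unclass(config)
    raw_cfg$effects <- unclass(raw_cfg$effects)
    manifest <- list(
      config = raw_cfg,
      package_version = as.character(utils::packageVersion("mobersp")),
      r_version = R.version.string,
      grand_peaks = desync$grand,
      n_member_ics = length(members))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    writeLines(log_lines, file.path(out_dir, "run.log"))
  }
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Pipeline result\n")
  cat(sprintf("  %d participants, %d motor-cluster ICs\n",
              length(unique(x$desync$participant)), length(x$members)))
  cat(sprintf("  grand peaks: alpha %.0f ms @ %.1f Hz, beta %.0f ms @ %.1f Hz\n",
              x$grand_peaks$alpha$time_ms, x$grand_peaks$alpha$freq_hz,
              x$grand_peaks$beta$time_ms, x$grand_peaks$beta$freq_hz))
  cat("  ANOVA effects (p < 0.05):\n")
  sig <- x$anova[x$anova$p < 0.05, ]
  for (i in seq_len(nrow(sig)))
    cat(sprintf("    %-18s %-11s F(%d,%d)=%.2f, p=%.4g, ges=%.2f\n",
                sig$measure[i], sig$effect[i], sig$df1[i], sig$df2[i],
                sig$F[i], sig$p[i], sig$ges[i]))
  cat("  dual-task cost correlations with walking-speed cost:\n")
  for (i in seq_len(nrow(x$correlations)))
    cat(sprintf("    %-10s r(%d)=%.2f, p=%.4g\n",
                x$correlations$measure[i], x$correlations$df[i],
                x$correlations$r[i], x$correlations$p[i]))
  invisible(x)
}

#' Effect-direction sign table
#'
#' Condenses the ANOVA table into one row per measure with the direction
#' of significant (p < 0.05) age and motor-task main effects, mirroring a
#' compact effect-overview table.
#'
#' @param anova_tbl ANOVA table from [run_all()].
#' @param alpha Significance level.
#' @return Data frame: measure, age, motor (direction strings or "-").
#' @export
sign_table <- function(anova_tbl, alpha = 0.05) {
  out <- NULL
  for (m in unique(anova_tbl$measure)) {
    am <- anova_tbl[anova_tbl$measure == m, ]
    btw <- am[am$effect == "between", ]
    wit <- am[am$effect == "within", ]
    itx <- am[am$effect == "interaction", ]
    age <- if (btw$p < alpha)
      (if (btw$mean_old > btw$mean_young) "old>young" else "old<young")
      else "-"
    motor <- if (wit$p < alpha)
      (if (wit$mean_single > wit$mean_dual) "sit>walk" else "sit<walk")
      else "-"
    out <- rbind(out, data.frame(
      measure = m, age = age, motor = motor,
      interaction = if (itx$p < alpha) "sig" else "-",
      stringsAsFactors = FALSE))
  }
  out
}

#' Reference effect-direction pattern of the default generator
#'
#' The six planted effects the default [effect_config()] encodes: higher
#' alpha PSD sitting than walking; higher beta PSD in the older group;
#' higher aperiodic offset walking than sitting; deeper (more negative)
#' alpha suppression sitting than walking; deeper beta suppression in the
#' older group and while sitting; no exponent effects.
#'
#' @return Data frame of expected significant cells.
#' @export
reference_effect_pattern <- function() {
  data.frame(
    measure = c("psd_alpha", "psd_beta", "aperiodic_offset",
                "ersp_alpha", "ersp_beta", "ersp_beta"),
    effect = c("motor", "age", "motor", "motor", "age", "motor"),
    direction = c("sit>walk", "old>young", "sit<walk",
                  "sit<walk", "old<young", "sit<walk"),
    stringsAsFactors = FALSE)
}

#' Does a sign table reproduce the reference pattern?
#'
#' Checks that every expected significant effect in
#' [reference_effect_pattern()] is significant with the expected
#' direction. Cells outside the reference pattern are not checked (their
#' rejection behaves at the nominal type-I rate under the null).
#'
#' @param signs A [sign_table()] data frame.
#' @return Logical.
#' @export
matches_reference_pattern <- function(signs) {
  ref <- reference_effect_pattern()
  all(vapply(seq_len(nrow(ref)), function(i) {
    row <- signs[signs$measure == ref$measure[i], ]
    if (!nrow(row)) return(FALSE)
    got <- if (ref$effect[i] == "age") row$age else row$motor
    identical(got, ref$direction[i])
  }, logical(1)))
}
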