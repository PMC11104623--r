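#' Pipeline configuration
#'
#' Bundles every knob of the simulate -> detect -> metrics -> stats pipeline
#' into one serialisable list. A single master seed fans out deterministically
#' to named sub-seeds (`simulate`, `stats`, `mc`) so stages can be re-run
#' independently; the configuration round-trips through YAML unchanged.
#'
#' @param seed master integer seed.
#' @param n_participants cohort size.
#' @param savings,mode,eta,delay_range learner settings
#'   (see [simulate_experiment()]).
#' @param scene_args,kinematic_args,layout_args argument lists forwarded to
#'   [build_scene()], [kinematic_params()], [session_layout()].
#' @param fidelity `"endpoint"` or `"stream"`.
#' @param n_perm permutations for the statistical tests.
#' @param n_mc Monte-Carlo samples for the dip test (the pipeline default is
#'   smaller than [dip_test()]'s own default because the null reference is
#'   recomputed per analysis run).
#' @param dip_max_n cap on the sample size entering the dip test; larger
#'   pooled angle distributions are subsampled (seeded) to this size, which
#'   keeps the exact dip computation fast while leaving its power against
#'   well-separated bimodality essentially unchanged.
#' @param alpha familywise alpha for Holm-corrected decisions.
#' @return Object of class `pipeline_config` (a named list).
#' @export
pipeline_config <- function(seed = 1L, n_participants = 22,
                            savings = 0.8, mode = "error_based", eta = 0.15,
                            delay_range = c(10, 80),
                            scene_args = list(), kinematic_args = list(),
                            layout_args = list(),
                            fidelity = "endpoint",
                            n_perm = 10000, n_mc = 999, dip_max_n = 500,
                            alpha = 0.05) {
  cfg <- list(seed = as.integer(seed),
              sub_seeds = derive_seeds(seed),
              n_participants = n_participants,
              savings = savings, mode = mode, eta = eta,
              delay_range = delay_range,
              scene_args = scene_args, kinematic_args = kinematic_args,
              layout_args = layout_args, fidelity = fidelity,
              n_perm = n_perm, n_mc = n_mc, dip_max_n = dip_max_n,
              alpha = alpha)
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

# deterministic fan-out of the master seed into per-stage seeds
derive_seeds <- function(seed) {
  base <- (as.integer(seed) * 2654435L) %% 2147480000L
  list(simulate = (base + 101L) %% 2147480000L,
       stats = (base + 202L) %% 2147480000L,
       mc = (base + 303L) %% 2147480000L)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("Pipeline configuration (master seed", x$seed, ")\n")
  cat(sprintf("  cohort: n = %d, mode = %s, eta = %.3g, savings = %.2g, %s fidelity\n",
              x$n_participants, x$mode, x$eta, x$savings, x$fidelity))
  cat(sprintf("  stats: %d permutations, %d dip MC samples, alpha = %.3g\n",
              x$n_perm, x$n_mc, x$alpha))
  invisible(x)
}

#' Write/read a pipeline configuration as YAML
#' @param config a [pipeline_config()].
#' @param path file path.
#' @return `read_pipeline_config()` returns the `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

#' Run the simulation stage and write the dataset to disk
#'
#' Simulates the cohort described by the configuration and writes
#' `trials.csv` (the trial table, one row per trial; see
#' [simulate_experiment()] for columns) and `config.yaml` (the provenance
#' snapshot) into `out_dir`. Re-running with the same configuration
#' reproduces the files byte for byte.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if missing).
#' @return The simulated `gaze_cohort`, invisibly.
#' @export
run_simulate <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cohort <- simulate_experiment(
    n_participants = config$n_participants, savings = config$savings,
    mode = config$mode, eta = config$eta,
    delay_range = config$delay_range,
    layout_args = config$layout_args,
    params = do.call(kinematic_params, config$kinematic_args),
    scene = do.call(build_scene, config$scene_args),
    fidelity = config$fidelity,
    seed = config$sub_seeds$simulate)
  write.csv(cohort$trials, file.path(out_dir, "trials.csv"),
            row.names = FALSE)
  write_pipeline_config(config, file.path(out_dir, "config.yaml"))
  invisible(cohort)
}

#' Analyse a simulated (or imported) dataset
#'
#' Computes the per-trial derived metrics (signed angles to the intended
#' object and the optimal point, post-secondary angles), applies the
#' validity filters with logged exclusion counts, builds the per-trial
#' decoding-outcome table and the per-phase condition summaries, and runs
#' the statistical battery: the participant-level learning-trend test, the
#' session-2 pre-learning baseline test, the paired early-vs-late
#' comparison of the angle to the optimal point, a permutation mixed ANOVA
#' (order x feedback x phase) on the angle to the optimal point, and dip
#' tests of the session-wise angle distributions.
#'
#' @param dataset a `gaze_cohort`, a trial-table data frame, or a directory
#'   containing `trials.csv`.
#' @param config a [pipeline_config()] (controls permutation counts etc.).
#' @param scene the scene geometry the dataset was generated under.
#' @return Object of class `gaze_report`.
#' @export
run_analyze <- function(dataset, config = pipeline_config(),
                        scene = do.call(build_scene, config$scene_args)) {
  trials <- if (inherits(dataset, "gaze_cohort")) dataset$trials
    else if (is.character(dataset)) read.csv(file.path(dataset, "trials.csv"))
    else dataset
  need <- c("participant", "session", "order", "feedback", "trial",
            "trial_type", "phase", "intended", "end_x", "end_y",
            "latency", "amplitude", "duration", "valid_primary", "decoded")
  miss <- setdiff(need, names(trials))
  if (length(miss)) {
    stop("dataset schema mismatch; missing columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  trials <- add_angle_metrics(trials, scene)
  n_all <- nrow(trials)
  keep <- !is.na(trials$valid_primary) & trials$valid_primary
  exclusions <- data.frame(
    reason = c("no primary saccade detected", "invalid primary saccade"),
    n = c(sum(is.na(trials$valid_primary)),
          sum(!trials$valid_primary, na.rm = TRUE))
  )
  valid <- trials[keep, , drop = FALSE]
  stopifnot(n_all == nrow(valid) + sum(exclusions$n))

  summaries <- phase_summaries(valid)
  outcome_tab <- decoding_outcome_table(trials[keep, , drop = FALSE])

  nperm <- config$n_perm
  sseed <- config$sub_seeds$stats
  stats <- list()
  stats$learning_trend <- try(
    learning_trend_test(outcome_tab, n_perm = nperm, seed = sseed),
    silent = TRUE)
  # session-2 pre-learning baseline: mean angle to intended vs 0
  pre2 <- valid[valid$session == 2 & valid$phase == "pre", ]
  if (nrow(pre2) > 3) {
    m <- tapply(pre2$angle_to_intended, pre2$participant, mean)
    stats$baseline_pre_s2 <- try(
      perm_ttest(as.numeric(m), 0, alternative = "two.sided",
                 n_perm = nperm, seed = sseed + 1L), silent = TRUE)
  }
  # early vs late angle to optimal (paired across participants)
  el <- valid[valid$trial_type == "feedback" & valid$phase %in%
                c("early", "late"), ]
  me <- tapply(el$angle_to_optimal[el$phase == "early"],
               el$participant[el$phase == "early"], mean)
  ml <- tapply(el$angle_to_optimal[el$phase == "late"],
               el$participant[el$phase == "late"], mean)
  common <- intersect(names(me), names(ml))
  if (length(common) > 2) {
    stats$early_vs_late <- try(
      perm_ttest(as.numeric(me[common]), as.numeric(ml[common]),
                 paired = TRUE, alternative = "greater",
                 n_perm = nperm, seed = sseed + 2L), silent = TRUE)
  }
  # mixed ANOVA on angle to optimal: order (between) x feedback x phase
  cell <- stats::aggregate(angle_to_optimal ~ participant + order +
                             feedback + phase, data = el, FUN = mean)
  stats$anova_angle_optimal <- try(
    perm_mixed_anova(cell, dv = "angle_to_optimal",
                     participant = "participant", between = "order",
                     within = c("feedback", "phase"),
                     n_perm = min(nperm, 2000), seed = sseed + 3L),
    silent = TRUE)
  # dip tests of the angle-to-optimal distribution per session (subsampled
  # to config$dip_max_n for tractability of the exact dip computation)
  fbt <- valid[valid$trial_type == "feedback", ]
  cap <- if (is.null(config$dip_max_n)) 500 else config$dip_max_n
  dip_sub <- function(v, sd_offset) {
    v <- v[!is.na(v)]
    if (length(v) > cap) {
      v <- with_seed(config$sub_seeds$mc + sd_offset,
                     sample(v, cap))
    }
    dip_test(v, n_mc = config$n_mc, seed = config$sub_seeds$mc)
  }
  stats$dip_session1 <- try(
    dip_sub(fbt$angle_to_optimal[fbt$session == 1], 1L), silent = TRUE)
  stats$dip_session2 <- try(
    dip_sub(fbt$angle_to_optimal[fbt$session == 2], 2L), silent = TRUE)
  stats <- lapply(stats, function(s) if (inherits(s, "try-error")) NULL else s)

  report <- list(
    summaries = summaries,
    outcome_table = outcome_tab,
    stats = stats,
    exclusions = exclusions,
    trials = valid,
    provenance = list(
      package = as.character(utils::packageVersion("gazedecode")),
      config = unclass(config))
  )
  class(report) <- "gaze_report"
  report
}

# per-phase x feedback x order cell summaries (mean and SD), in the layout
# of the condition tables the analysis is usually reported in
phase_summaries <- function(valid) {
  agg <- function(v) c(mean = mean(v, na.rm = TRUE),
                       sd = sd(v, na.rm = TRUE))
  out <- list()
  for (metric in c("angle_to_optimal", "angle_to_intended", "latency",
                   "curvature", "sec_angle_to_intended")) {
    if (all(is.na(valid[[metric]]))) next
    a <- stats::aggregate(valid[[metric]],
                          by = list(order = valid$order,
                                    feedback = valid$feedback,
                                    phase = valid$phase),
                          FUN = agg)
    df <- data.frame(a[1:3], mean = a$x[, "mean"], sd = a$x[, "sd"])
    df <- df[order(df$order, df$feedback,
                   match(df$phase, c("pre", "early", "mid", "late",
                                     "post"))), ]
    rownames(df) <- NULL
    out[[metric]] <- df
  }
  out
}

#' Add signed-angle metrics to a trial table
#'
#' Computes `angle_to_intended` (signed angle of the primary endpoint
#' relative to the intended object, clockwise positive),
#' `angle_to_optimal` (relative to the optimal point, i.e. shifted by the
#' scene distortion) and `sec_angle_to_intended` (same angle for the eye
#' position after the secondary saccade).
#'
#' @param trials trial-table data frame.
#' @param scene the [build_scene()] geometry.
#' @return The trial table with the three columns added.
#' @export
add_angle_metrics <- function(trials, scene = build_scene()) {
  ic <- scene$object_clock_angle[trials$intended]
  ok <- !is.na(trials$end_x)
  trials$angle_to_intended <- NA_real_
  trials$angle_to_intended[ok] <-
    signed_angle(trials$end_x[ok], trials$end_y[ok], ic[ok])
  trials$angle_to_optimal <- wrap_angle(trials$angle_to_intended +
                                          scene$distortion)
  oks <- !is.na(trials$sec_end_x) &
    !(trials$sec_end_x == 0 & trials$sec_end_y == 0)
  trials$sec_angle_to_intended <- NA_real_
  trials$sec_angle_to_intended[oks] <-
    signed_angle(trials$sec_end_x[oks], trials$sec_end_y[oks], ic[oks])
  trials
}

#' @export
print.gaze_report <- function(x, ...) {
  cat("Analysis report\n")
  cat("  exclusions:\n")
  print(x$exclusions, row.names = FALSE)
  if (!is.null(x$summaries$angle_to_optimal)) {
    cat("  angle to optimal point by condition cell (arc deg):\n")
    df <- x$summaries$angle_to_optimal
    df <- df[df$phase %in% c("early", "late"), ]
    df$mean <- round(df$mean, 2); df$sd <- round(df$sd, 2)
    print(df, row.names = FALSE)
  }
  for (nm in names(x$stats)) {
    if (is.null(x$stats[[nm]])) next
    cat("\n[", nm, "]\n", sep = "")
    print(x$stats[[nm]])
  }
  invisible(x)
}

#' Write a human-readable report and figures
#'
#' Renders the analysis report as markdown (`report.md`), writes the
#' condition summaries, the per-trial outcome table and the
#' per-participant learning-trend slopes as CSV, a machine-readable
#' per-test stats block as JSON (`stats.json`), and draws
#' PNG figures: the learning curve (valid-decoding rate over feedback
#' trials by session), the angle-to-optimal by phase, and (when available)
#' curvature by phase. Statistics that were not computed render as
#' "not computed". Regenerating from the same report reproduces the same
#' numbers.
#'
#' @param report a `gaze_report` from [run_analyze()].
#' @param out_dir output directory (created if missing).
#' @return Character vector of the files written, invisibly.
#' @export
run_report <- function(report, out_dir) {
  stopifnot(inherits(report, "gaze_report"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)

  f <- file.path(out_dir, "outcome_table.csv")
  write.csv(report$outcome_table, f, row.names = FALSE)
  files <- c(files, f)
  for (nm in names(report$summaries)) {
    f <- file.path(out_dir, paste0("summary_", nm, ".csv"))
    write.csv(report$summaries[[nm]], f, row.names = FALSE)
    files <- c(files, f)
  }

  md <- c("# Gaze-decoding analysis report", "",
          paste0("Package version: ", report$provenance$package),
          paste0("Master seed: ", report$provenance$config$seed), "",
          "## Exclusions", "",
          paste0("- ", report$exclusions$reason, ": ",
                 report$exclusions$n))
  md <- c(md, "", "## Statistics", "")
  fmt_stat <- function(s, nm) {
    if (is.null(s)) return(paste0("- ", nm, ": not computed"))
    if (inherits(s, "perm_htest")) {
      sprintf("- %s: t = %.3f, p_perm = %.4g (%s, %d permutations)",
              nm, s$statistic, s$p.value, s$alternative, s$n_perm)
    } else if (inherits(s, "dip_htest")) {
      sprintf("- %s: D = %.4f, p = %.4g (n = %d)", nm, s$statistic,
              s$p.value, s$n)
    } else if (inherits(s, "perm_anova")) {
      paste(c(sprintf("- %s:", nm),
              sprintf("    - %s: F(%d, %d) = %.2f, p_perm = %.4g",
                      s$table$effect, s$table$df1, s$table$df2, s$table$F,
                      s$table$p_perm)), collapse = "\n")
    } else paste0("- ", nm, ": not computed")
  }
  for (nm in c("learning_trend", "baseline_pre_s2", "early_vs_late",
               "anova_angle_optimal", "dip_session1", "dip_session2")) {
    md <- c(md, fmt_stat(report$stats[[nm]], nm))
  }
  f <- file.path(out_dir, "report.md")
  writeLines(md, f)
  files <- c(files, f)

  # machine-readable stats block: one entry per test
  stats_json <- lapply(report$stats, function(s) {
    if (inherits(s, "perm_htest")) {
      list(statistic = s$statistic, p = s$p.value, n_perm = s$n_perm,
           alternative = s$alternative, scheme = s$scheme, seed = s$seed)
    } else if (inherits(s, "dip_htest")) {
      list(statistic = s$statistic, p = s$p.value, n = s$n, n_mc = s$n_mc)
    } else if (inherits(s, "perm_anova")) {
      list(effects = s$table, n_perm = s$n_perm, seed = s$seed)
    } else NULL
  })
  f <- file.path(out_dir, "stats.json")
  jsonlite::write_json(stats_json, f, auto_unbox = TRUE, digits = NA,
                       null = "null")
  files <- c(files, f)
  if (!is.null(report$stats$learning_trend$slopes)) {
    f <- file.path(out_dir, "participant_slopes.csv")
    write.csv(report$stats$learning_trend$slopes, f, row.names = FALSE)
    files <- c(files, f)
  }

  files <- c(files, report_figures(report, out_dir))
  invisible(files)
}

report_figures <- function(report, out_dir) {
  files <- character(0)
  ot <- report$outcome_table
  f <- file.path(out_dir, "fig_learning_curve.png")
  png(f, width = 900, height = 500)
  par(mar = c(4, 4, 2, 1))
  bins <- pmin(ceiling(ot$trial / 10), 20) * 10
  rate <- tapply(ot$outcome, list(bins, ot$session), mean)
  matplot(as.numeric(rownames(rate)), rate, type = "b", pch = 16,
          lty = 1, xlab = "feedback trial", ylab = "valid decoding rate",
          main = "Learning curve (10-trial bins)", ylim = c(0, 1))
  legend("bottomright", legend = paste("session", colnames(rate)),
         col = seq_len(ncol(rate)), lty = 1, pch = 16, bty = "n")
  dev.off()
  files <- c(files, f)

  sm <- report$summaries$angle_to_optimal
  if (!is.null(sm)) {
    f <- file.path(out_dir, "fig_angle_by_phase.png")
    png(f, width = 900, height = 500)
    par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
    for (ordl in unique(sm$order)) {
      s <- sm[sm$order == ordl, ]
      ph <- c("pre", "early", "mid", "late", "post")
      plot(NA, xlim = c(1, 5), ylim = range(sm$mean, na.rm = TRUE) + c(-5, 5),
           xaxt = "n", xlab = "phase", ylab = "angle to optimal (arc deg)",
           main = ordl)
      axis(1, at = 1:5, labels = ph)
      for (fbl in unique(s$feedback)) {
        ss <- s[s$feedback == fbl, ]
        lines(match(ss$phase, ph), ss$mean, type = "b", pch = 16,
              col = if (fbl == "motor") 2 else 4)
      }
      abline(h = 0, lty = 3)
      legend("topright", legend = unique(s$feedback),
             col = ifelse(unique(s$feedback) == "motor", 2, 4),
             lty = 1, pch = 16, bty = "n")
    }
    dev.off()
    files <- c(files, f)
  }
  sc <- report$summaries$curvature
  if (!is.null(sc)) {
    f <- file.path(out_dir, "fig_curvature_by_phase.png")
    png(f, width = 700, height = 500)
    par(mar = c(4, 4, 2, 1))
    ph <- c("pre", "early", "mid", "late", "post")
    plot(NA, xlim = c(1, 5), ylim = range(sc$mean, na.rm = TRUE),
         xaxt = "n", xlab = "phase", ylab = "curvature index",
         main = "Saccade curvature by phase")
    axis(1, at = 1:5, labels = ph)
    for (i in seq_len(nrow(unique(sc[c("order", "feedback")])))) {
      key <- unique(sc[c("order", "feedback")])[i, ]
      ss <- sc[sc$order == key$order & sc$feedback == key$feedback, ]
      lines(match(ss$phase, ph), ss$mean, type = "b", pch = 16, col = i)
    }
    abline(h = 0, lty = 3)
    dev.off()
    files <- c(files, f)
  }
  files
}

#' Run the full pipeline: simulate, analyse, report
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory.
#' @return The `gaze_report`, invisibly.
#' @export
run_pipeline <- function(config, out_dir) {
  cohort <- run_simulate(config, out_dir)
  report <- run_analyze(cohort, config)
  run_report(report, out_dir)
  invisible(report)
}

#' Read/write gaze streams in the package CSV dialect
#'
#' Long-format CSV with columns `trial_id`, `t_ms`, `x_deg`, `y_deg`; trial
#' events (fixation-cross offset) travel in a companion column
#' `fixation_off_ms` (constant within a trial).
#'
#' @param streams named list of [gaze_stream()] objects.
#' @param path CSV file path.
#' @return `read_gaze_streams()` returns a named list of `gaze_stream`s.
#' @export
write_gaze_streams <- function(streams, path) {
  dfs <- lapply(names(streams), function(id) {
    s <- streams[[id]]
    data.frame(trial_id = id, t_ms = s$t, x_deg = s$x, y_deg = s$y,
               fixation_off_ms = s$fixation_off_t)
  })
  write.csv(do.call(rbind, dfs), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_gaze_streams
#' @export
read_gaze_streams <- function(path) {
  df <- read.csv(path)
  need <- c("trial_id", "t_ms", "x_deg", "y_deg", "fixation_off_ms")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("gaze-stream CSV lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  out <- lapply(split(df, df$trial_id), function(d) {
    gaze_stream(d$t_ms, d$x_deg, d$y_deg,
                fixation_off_t = d$fixation_off_ms[1])
  })
  out
}
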