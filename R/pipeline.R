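# I/O formats, configuration and end-to-end orchestration:
# simulate -> segment -> metrics -> outlier removal -> scoring -> statistics
# -> report. All files are UTF-8 CSV/TSV with dot decimals; units are
# encoded in column names; coordinates are metres, times seconds.

#' Pipeline configuration
#'
#' @param experiment `"exp1"` or `"exp2"`.
#' @param n_subjects number of simulated subjects.
#' @param effect_config named list of [condition_effect_model()]s.
#' @param seed master seed for every stochastic stage.
#' @param fs resampling rate, Hz.
#' @param cutoff speed-filter cutoff, Hz.
#' @param v_threshold movement-onset speed threshold, m/s (0.2 by default).
#' @param min_separation velocity-peak minimum separation, s.
#' @param outlier_grouping `"pooled"` (fences per participant, pooled across
#'   conditions) or `"per_condition"`.
#' @param alpha significance level (0.05).
#' @param aggregate `"mean"` or `"median"` cell aggregation.
#' @param d_method Cohen's d convention for post-hoc tests.
#' @param out_dir output directory (`NULL`: nothing written).
#' @param write_samples also write the (large) trajectory CSV.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(experiment = "exp2", n_subjects = 5,
                            effect_config = default_effect_config(),
                            seed = 1, fs = 500, cutoff = 10,
                            v_threshold = 0.2, min_separation = 0.05,
                            outlier_grouping = c("pooled", "per_condition"),
                            alpha = 0.05, aggregate = c("mean", "median"),
                            d_method = c("dz", "dav"),
                            out_dir = NULL, write_samples = FALSE) {
  .assert(v_threshold > 0 && v_threshold < 5, "`v_threshold` out of bounds")
  .assert(alpha > 0 && alpha < 1, "`alpha` must be in (0, 1)")
  .assert(!is.null(seed), "a seed is mandatory for stochastic stages")
  structure(list(
    experiment = match.arg(experiment, c("exp1", "exp2")),
    n_subjects = n_subjects, effect_config = effect_config, seed = seed,
    fs = fs, cutoff = cutoff, v_threshold = v_threshold,
    min_separation = min_separation,
    outlier_grouping = match.arg(outlier_grouping),
    alpha = alpha, aggregate = match.arg(aggregate),
    d_method = match.arg(d_method),
    out_dir = out_dir, write_samples = write_samples
  ), class = "pipeline_config")
}

#' Write a simulated dataset's trajectory and event CSV files
#'
#' @param dataset a [simulate_dataset()] result.
#' @param dir output directory (created if needed).
#' @return Named character vector of written paths, invisibly.
#' @export
write_dataset_csv <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  traj_path <- file.path(dir, "trajectories.csv")
  ev_path <- file.path(dir, "events.csv")
  traj <- dataset$samples
  names(traj)[names(traj) == "t"] <- "time_s"
  names(traj)[names(traj) == "x"] <- "x_m"
  names(traj)[names(traj) == "y"] <- "y_m"
  names(traj)[names(traj) == "z"] <- "z_m"
  write.csv(traj, traj_path, row.names = FALSE, quote = FALSE)

  ev <- dataset$events
  long <- rbind(
    data.frame(trial_id = ev$trial_id, participant = ev$participant,
               condition = ev$condition, event = "fruit_appear",
               t_s = ev$fruit_appear_t, block_index = ev$block_index,
               fruit = ev$fruit_kind, location_id = ev$location_id,
               depth_class = ev$depth_class),
    data.frame(trial_id = ev$trial_id, participant = ev$participant,
               condition = ev$condition, event = "collision",
               t_s = ev$collision_t, block_index = ev$block_index,
               fruit = ev$fruit_kind, location_id = ev$location_id,
               depth_class = ev$depth_class)
  )
  long <- long[order(long$trial_id, long$t_s), ]
  write.csv(long, ev_path, row.names = FALSE, quote = FALSE)
  invisible(c(trajectories = traj_path, events = ev_path))
}

#' Read a long-format trajectory CSV (with its events CSV)
#'
#' Validates the headers, numeric content and per-trial time monotonicity
#' (rows are sorted by time within trial; duplicated timestamps are
#' rejected naming the trial).
#'
#' @param path trajectory CSV with header
#'   `trial_id,participant,condition,time_s,x_m,y_m,z_m` (extra columns are
#'   allowed and preserved).
#' @param events_path events CSV with header
#'   `trial_id,event,t_s` plus metadata columns.
#' @return List with `samples` (tibble `trial_id`, `participant`,
#'   `condition`, `t`, `x`, `y`, `z`, ...) and `events` (wide tibble with
#'   `fruit_appear_t`, `collision_t` and metadata).
#' @export
read_trajectory_file <- function(path, events_path) {
  traj <- read.csv(path, stringsAsFactors = FALSE)
  required <- c("trial_id", "participant", "condition", "time_s", "x_m", "y_m", "z_m")
  missing_cols <- setdiff(required, names(traj))
  .assert(length(missing_cols) == 0, "malformed trajectory header; missing: %s",
          paste(missing_cols, collapse = ", "))
  for (col in c("time_s", "x_m", "y_m", "z_m")) {
    v <- traj[[col]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))) & !is.na(v))
      stop(sprintf("non-numeric values in column '%s' at rows: %s", col,
                   paste(head(bad, 10), collapse = ", ")), call. = FALSE)
    }
  }
  traj <- traj[order(traj$trial_id, traj$time_s), ]
  dup <- unlist(lapply(split(traj$time_s, traj$trial_id),
                       function(tt) any(duplicated(tt))))
  .assert(!any(dup), "duplicated timestamps within trial(s): %s",
          paste(names(dup)[dup], collapse = ", "))
  names(traj)[match(c("time_s", "x_m", "y_m", "z_m"), names(traj))] <-
    c("t", "x", "y", "z")

  ev <- read.csv(events_path, stringsAsFactors = FALSE)
  .assert(all(c("trial_id", "event", "t_s") %in% names(ev)),
          "malformed events header (need trial_id, event, t_s)")
  meta_cols <- setdiff(names(ev), c("event", "t_s"))
  appear <- ev[ev$event == "fruit_appear", ]
  coll <- ev[ev$event == "collision", c("trial_id", "t_s")]
  wide <- merge(appear[, meta_cols, drop = FALSE],
                stats::setNames(appear[, c("trial_id", "t_s")], c("trial_id", "fruit_appear_t")),
                by = "trial_id")
  wide <- merge(wide, stats::setNames(coll, c("trial_id", "collision_t")),
                by = "trial_id", all.x = TRUE)
  wide <- wide[order(wide$trial_id), ]
  list(samples = tibble::as_tibble(traj), events = tibble::as_tibble(wide))
}

.write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
  path
}

METRIC_COLS <- c(
  normalized_duration = "normalized_duration_s_per_m",
  straightness = "straightness",
  peak_velocity = "peak_velocity_m_s",
  n_velocity_peaks = "n_velocity_peaks",
  onset = "onset_s"
)

#' Run the full analysis pipeline
#'
#' Orchestrates simulation, segmentation, metric computation, per-participant
#' extreme-outlier removal, dual-task and questionnaire scoring, and the
#' repeated-measures statistics; optionally writes all tables, a
#' human-readable report and a machine-readable run manifest.
#'
#' @param config a [pipeline_config()].
#' @return List of class `pipeline_result` with elements `protocol`,
#'   `dataset`, `segments`, `metrics`, `outlier_reports`, `cell_means`,
#'   `condition_means`, `scores` (counting + questionnaires), `stats`
#'   (per-metric RM-ANOVAs, SUS RM-ANOVA, IMI/RTLX RM-MANOVAs, counting
#'   Friedman, post-hoc tables), `report` (character lines) and `manifest`.
#' @export
run_full_pipeline <- function(config) {
  .assert(inherits(config, "pipeline_config"), "`config` must be a pipeline_config")
  warnings_log <- character(0)
  log_warning <- function(w) {
    warnings_log <<- c(warnings_log, conditionMessage(w))
    invokeRestart("muffleWarning")
  }
  seeds <- .spawn_seeds(config$seed, 4)

  protocol <- build_protocol(config$experiment)
  dataset <- simulate_dataset(protocol, config$effect_config,
                              n_subjects = config$n_subjects,
                              seed = seeds[1], fs = config$fs)

  segments <- withCallingHandlers(
    segment_movements(dataset$samples, dataset$events), warning = log_warning)
  metrics <- compute_metrics(segments, fs = config$fs, cutoff = config$cutoff,
                             v_threshold = config$v_threshold,
                             min_separation = config$min_separation)

  group_cols <- if (config$outlier_grouping == "pooled") "participant"
                else c("participant", "condition")
  outlier_reports <- list()
  kept_list <- list()
  for (mname in names(METRIC_COLS)) {
    col <- METRIC_COLS[[mname]]
    dat <- metrics[!is.na(metrics[[col]]),
                   c("participant", "condition", "depth_class", col)]
    rep_m <- withCallingHandlers(
      remove_extreme_outliers(dat, col, group_cols), warning = log_warning)
    outlier_reports[[mname]] <- rep_m
    kept <- rep_m$kept
    kept$metric <- mname
    names(kept)[names(kept) == col] <- "value"
    kept_list[[mname]] <- kept
  }
  long_metrics <- dplyr::bind_rows(kept_list)

  agg_fun <- if (config$aggregate == "mean") mean else stats::median
  cell_means <- dplyr::summarise(
    dplyr::group_by(long_metrics, .data$metric, .data$participant,
                    .data$condition, .data$depth_class),
    value = agg_fun(.data$value), n_segments = dplyr::n(), .groups = "drop")
  condition_means <- dplyr::summarise(
    dplyr::group_by(long_metrics, .data$metric, .data$participant, .data$condition),
    value = agg_fun(.data$value), .groups = "drop")

  # ---- statistics on the movement metrics -------------------------------
  anovas <- list(); posthocs <- list()
  for (mname in names(METRIC_COLS)) {
    tab <- cell_means[cell_means$metric == mname, ]
    res <- tryCatch(
      rm_anova_2way(tab, "value", "participant", c("condition", "depth_class"),
                    alpha = config$alpha),
      error = function(e) e)
    if (inherits(res, "error")) {
      warnings_log <- c(warnings_log,
                        sprintf("RM-ANOVA for %s failed: %s", mname, conditionMessage(res)))
      next
    }
    anovas[[mname]] <- res
    if (res$p_reported[res$effect == "condition"] < config$alpha) {
      ctab <- condition_means[condition_means$metric == mname, ]
      ph <- posthoc_paired(ctab, "value", "participant", "condition",
                           d_method = config$d_method)
      ph$metric <- mname
      posthocs[[mname]] <- ph
    }
  }

  # ---- scoring ----------------------------------------------------------
  quest <- simulate_questionnaires(config$n_subjects, seed = seeds[2],
                                   sus_scale_max = if (config$experiment == "exp2") 5 else 7)
  sus_max <- if (config$experiment == "exp2") 5 else 7
  sus_tab <- dplyr::summarise(
    dplyr::group_by(quest[quest$instrument == "SUS", ],
                    .data$participant, .data$condition),
    value = score_sus(.data$value, scale_max = sus_max), .groups = "drop")
  imi_tab <- dplyr::summarise(
    dplyr::group_by(quest[quest$instrument == "IMI", ],
                    .data$participant, .data$condition, .data$subscale),
    value = mean(.data$value), .groups = "drop")
  rtlx_tab <- quest[quest$instrument == "RTLX",
                    c("participant", "condition", "subscale", "value")]

  counting_seeds <- .spawn_seeds(seeds[3], config$n_subjects * 3)
  counting <- list(); ci <- 1L
  for (s in seq_len(config$n_subjects)) {
    for (cond in CONDITIONS) {
      blocks <- split(dataset$plan, dataset$plan$block_index)
      block_seeds <- .spawn_seeds(counting_seeds[ci], length(blocks))
      scores <- vapply(seq_along(blocks), function(b) {
        truth <- tibble::tibble(category = blocks[[b]]$fruit_kind)
        resp <- simulate_counting(truth, dataset$subjects$counting_error_rate[s],
                                  seed = block_seeds[b])
        score_counting_block(data.frame(category = resp$category,
                                        said_category = resp$said_category,
                                        said_count = resp$said_count))
      }, numeric(1))
      counting[[ci]] <- tibble::tibble(
        participant = dataset$subjects$subject_id[s], condition = cond,
        counting_score = aggregate_counting(scores))
      ci <- ci + 1L
    }
  }
  counting <- dplyr::bind_rows(counting)

  # ---- questionnaire / counting statistics ------------------------------
  stats_out <- list(anova = anovas, posthoc = posthocs)
  stats_out$sus_anova <- tryCatch(
    rm_anova_oneway(sus_tab, "value", "participant", "condition",
                    alpha = config$alpha),
    error = function(e) NULL)
  imi_wide <- tidyr::pivot_wider(imi_tab, names_from = "subscale",
                                 values_from = "value")
  stats_out$imi_manova <- tryCatch(
    rm_manova_oneway(imi_wide, setdiff(names(imi_wide), c("participant", "condition")),
                     "participant", "condition"),
    error = function(e) NULL)
  rtlx_wide <- tidyr::pivot_wider(rtlx_tab, names_from = "subscale",
                                  values_from = "value")
  stats_out$rtlx_manova <- tryCatch(
    rm_manova_oneway(rtlx_wide, setdiff(names(rtlx_wide), c("participant", "condition")),
                     "participant", "condition"),
    error = function(e) NULL)
  stats_out$counting_friedman <- friedman_kendall(
    counting, dv = "counting_score", subject = "participant", within = "condition")

  # ---- outlier accounting (mirrors per-condition reporting) -------------
  removed_counts <- dplyr::bind_rows(lapply(names(outlier_reports), function(mname) {
    rem <- outlier_reports[[mname]]$removed
    tibble::tibble(metric = mname,
                   condition = CONDITIONS,
                   n_removed = vapply(CONDITIONS, function(cc)
                     sum(rem$condition == cc), integer(1)))
  }))

  scores <- list(counting = counting, sus = sus_tab, imi = imi_tab, rtlx = rtlx_tab)
  report_lines <- build_report(cell_means, condition_means, stats_out,
                               removed_counts, nrow(segments))

  result <- list(protocol = protocol, dataset = dataset, segments = segments,
                 metrics = metrics, outlier_reports = outlier_reports,
                 cell_means = cell_means, condition_means = condition_means,
                 scores = scores, stats = stats_out, report = report_lines)

  manifest <- list(
    tool = "reachkin",
    version = as.character(utils::packageVersion("reachkin")),
    config = config[setdiff(names(config), "effect_config")],
    effect_config = lapply(config$effect_config, unclass),
    counts = list(
      n_trials_planned = nrow(dataset$plan) * config$n_subjects * 3,
      n_segments = nrow(segments),
      n_metric_values = nrow(long_metrics),
      removed_per_metric_condition = removed_counts
    ),
    warnings = warnings_log,
    files = list()
  )

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    paths <- c(
      metrics = .write_tsv(metrics[, setdiff(names(metrics), "data")],
                           file.path(config$out_dir, "metrics.tsv")),
      cell_means = .write_tsv(cell_means, file.path(config$out_dir, "cell_means.tsv")),
      outliers = .write_tsv(removed_counts, file.path(config$out_dir, "outlier_counts.tsv")),
      counting = .write_tsv(counting, file.path(config$out_dir, "counting_scores.tsv")),
      sus = .write_tsv(sus_tab, file.path(config$out_dir, "sus_scores.tsv")),
      imi = .write_tsv(imi_tab, file.path(config$out_dir, "imi_scores.tsv")),
      rtlx = .write_tsv(rtlx_tab, file.path(config$out_dir, "rtlx_scores.tsv")),
      anova = .write_tsv(anova_table(stats_out),
                         file.path(config$out_dir, "stats_tests.tsv"))
    )
    if (length(posthocs)) {
      paths["posthoc"] <- .write_tsv(dplyr::bind_rows(posthocs),
                                     file.path(config$out_dir, "posthoc.tsv"))
    }
    if (config$write_samples) {
      paths <- c(paths, write_dataset_csv(dataset, config$out_dir))
    }
    proto_path <- file.path(config$out_dir, "protocol.yaml")
    write_protocol_yaml(protocol, proto_path)
    paths["protocol"] <- proto_path
    report_path <- file.path(config$out_dir, "report.txt")
    writeLines(report_lines, report_path)
    paths["report"] <- report_path
    manifest$files <- as.list(tools::md5sum(unname(paths)))
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         force = TRUE)
  }
  result$manifest <- manifest
  class(result) <- "pipeline_result"
  result
}

# Flatten every test result into one tidy table (effect, df, statistic,
# effect size, p), mirroring the layout of a results table.
anova_table <- function(stats_out) {
  rows <- list()
  for (mname in names(stats_out$anova)) {
    av <- stats_out$anova[[mname]]
    rows[[length(rows) + 1]] <- tibble::tibble(
      analysis = paste0("RM-ANOVA-", mname), effect = av$effect,
      df1 = av$df1, df2 = av$df2, statistic = av$F,
      effect_size = av$partial_eta_sq, p = av$p_reported)
  }
  if (!is.null(stats_out$sus_anova)) {
    av <- stats_out$sus_anova
    rows[[length(rows) + 1]] <- tibble::tibble(
      analysis = "RM-ANOVA-SUS", effect = "condition",
      df1 = av$df1, df2 = av$df2, statistic = av$F,
      effect_size = av$partial_eta_sq, p = av$p_reported)
  }
  for (nm in c("imi_manova", "rtlx_manova")) {
    mv <- stats_out[[nm]]
    if (is.null(mv)) next
    rows[[length(rows) + 1]] <- tibble::tibble(
      analysis = paste0("RM-MANOVA-", toupper(sub("_manova", "", nm))),
      effect = "condition", df1 = mv$df1, df2 = mv$df2, statistic = mv$F,
      effect_size = mv$partial_eta_sq, p = mv$p)
  }
  fr <- stats_out$counting_friedman
  rows[[length(rows) + 1]] <- tibble::tibble(
    analysis = "Friedman-counting", effect = "condition",
    df1 = fr$df, df2 = NA_real_, statistic = fr$chi_sq,
    effect_size = fr$kendalls_W, p = fr$p)
  dplyr::bind_rows(rows)
}

# Human-readable summary: descriptive tables (mean +/- SD per condition and
# per condition x depth class) followed by the test table.
build_report <- function(cell_means, condition_means, stats_out,
                         removed_counts, n_segments) {
  fmt <- function(x) formatC(x, digits = 3, format = "fg", flag = "#")
  lines <- c("Movement quality and cognitive load analysis", "",
             sprintf("Segments analysed (before outlier removal): %d", n_segments), "",
             "Descriptive statistics per condition (mean +/- SD of participant cell values)")
  for (mname in unique(condition_means$metric)) {
    sub <- condition_means[condition_means$metric == mname, ]
    if (all(is.na(sub$value))) {
      lines <- c(lines, sprintf("  %-22s absent", mname))
      next
    }
    per_cond <- vapply(CONDITIONS, function(cc) {
      v <- sub$value[sub$condition == cc]
      sprintf("%s: %s +/- %s", cc, fmt(mean(v)), fmt(sd(v)))
    }, character(1))
    lines <- c(lines, sprintf("  %-22s %s", mname, paste(per_cond, collapse = " | ")))
  }
  lines <- c(lines, "", "Condition x depth-usage cells (mean of participant cell values)")
  for (mname in unique(cell_means$metric)) {
    sub <- cell_means[cell_means$metric == mname, ]
    lines <- c(lines, sprintf("  %s:", mname))
    for (dc in DEPTH_CLASSES) {
      vals <- vapply(CONDITIONS, function(cc) {
        v <- sub$value[sub$condition == cc & sub$depth_class == dc]
        if (!length(v) || all(is.na(v))) "absent" else fmt(mean(v, na.rm = TRUE))
      }, character(1))
      lines <- c(lines, sprintf("    %-15s %s", dc,
                                paste(sprintf("%s=%s", CONDITIONS, vals), collapse = "  ")))
    }
  }
  tab <- anova_table(stats_out)
  lines <- c(lines, "", "Statistical tests (effect, df, statistic, effect size, p)")
  lines <- c(lines, sprintf("  %-28s %-24s df=(%s, %s)  stat=%s  es=%s  p=%s",
                            tab$analysis, tab$effect,
                            fmt(tab$df1), ifelse(is.na(tab$df2), "-", fmt(tab$df2)),
                            fmt(tab$statistic), fmt(tab$effect_size),
                            format.pval(tab$p, digits = 3)))
  lines <- c(lines, "", "Extreme outliers removed per metric and condition")
  for (mname in unique(removed_counts$metric)) {
    sub <- removed_counts[removed_counts$metric == mname, ]
    lines <- c(lines, sprintf("  %-22s %s", mname,
                              paste(sprintf("%s: %d", sub$condition, sub$n_removed),
                                    collapse = ", ")))
  }
  lines
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(paste(x$report, collapse = "\n"), "\n")
  invisible(x)
}
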