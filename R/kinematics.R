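# Segmentation of recordings into individual fruit-reaching movements and
# computation of the movement-quality metrics: normalized movement duration
# (s/m), trajectory straightness ratio, peak velocity (m/s), number of
# velocity peaks, and movement onset relative to target appearance.

#' Resample a trajectory onto a uniform time grid
#'
#' Linear interpolation of each coordinate onto a uniform `1/fs` grid
#' spanning the recorded interval. Recordings are sampled at only an
#' approximate 500 Hz, so downstream filtering and differentiation always
#' operate on resampled data.
#'
#' @param samples tibble with columns `t`, `x`, `y`, `z` (>= 2 rows).
#' @param fs target sampling rate, Hz.
#' @return Tibble `t`, `x`, `y`, `z` on the uniform grid.
#' @export
resample_uniform <- function(samples, fs = 500) {
  .assert(nrow(samples) >= 2, "need at least 2 samples")
  .assert_scalar_num(fs, "fs", positive = TRUE)
  .assert(all(diff(samples$t) > 0), "timestamps must be strictly increasing")
  grid <- seq(samples$t[1], samples$t[nrow(samples)], by = 1 / fs)
  tibble::tibble(
    t = grid,
    x = approx(samples$t, samples$x, grid)$y,
    y = approx(samples$t, samples$y, grid)$y,
    z = approx(samples$t, samples$z, grid)$y
  )
}

# Zero-phase Butterworth low-pass (order-2 filter run forward and backward,
# 4th-order effective response). The signal is extended by odd reflection at
# both ends before filtering to suppress edge transients, then trimmed.
.zero_phase_lowpass <- function(x, fs, cutoff) {
  n <- length(x)
  if (cutoff >= fs / 2) return(x)
  bf <- signal::butter(2, cutoff / (fs / 2), type = "low")
  n_pad <- min(n - 1, max(12L, ceiling(3 * fs / cutoff)))
  left <- 2 * x[1] - x[seq(n_pad + 1, 2)]
  right <- 2 * x[n] - x[seq(n - 1, n - n_pad)]
  padded <- c(left, x, right)
  filtered <- signal::filtfilt(bf, padded)
  filtered[(n_pad + 1):(n_pad + n)]
}

# Resample + low-pass filter the three coordinates of a segment.
.filter_positions <- function(samples, fs = 500, cutoff = 10) {
  rs <- resample_uniform(samples, fs)
  if (nrow(rs) >= 7) {
    rs$x <- .zero_phase_lowpass(rs$x, fs, cutoff)
    rs$y <- .zero_phase_lowpass(rs$y, fs, cutoff)
    rs$z <- .zero_phase_lowpass(rs$z, fs, cutoff)
  }
  rs
}

#' Compute the filtered speed profile of a segment
#'
#' Resamples the segment to a uniform grid, low-pass filters the positions
#' with a zero-phase Butterworth filter, differentiates with central
#' differences (one-sided at the edges) and takes the Euclidean magnitude.
#'
#' @param samples tibble `t`, `x`, `y`, `z` (>= 5 samples after resampling).
#' @param fs uniform resampling rate, Hz.
#' @param cutoff low-pass cutoff, Hz.
#' @return An object of class `speed_profile`: tibble `t`, `speed` with the
#'   filtered positions attached as attribute `"positions"` and the sampling
#'   rate as `"fs"`.
#' @export
compute_speed <- function(samples, fs = 500, cutoff = 10) {
  pos <- .filter_positions(samples, fs, cutoff)
  n <- nrow(pos)
  .assert(n >= 5, "segment too short after resampling (need >= 5 samples)")
  dt <- 1 / fs
  dvec <- function(p) {
    v <- numeric(n)
    v[2:(n - 1)] <- (p[3:n] - p[1:(n - 2)]) / (2 * dt)
    v[1] <- (p[2] - p[1]) / dt
    v[n] <- (p[n] - p[n - 1]) / dt
    v
  }
  vx <- dvec(pos$x); vy <- dvec(pos$y); vz <- dvec(pos$z)
  out <- tibble::tibble(t = pos$t, speed = sqrt(vx^2 + vy^2 + vz^2))
  attr(out, "positions") <- pos
  attr(out, "fs") <- fs
  class(out) <- c("speed_profile", class(out))
  out
}

#' Cut a recording stream into individual fruit-reaching movements
#'
#' One segment per fruit: from the instant the fruit appears (the home
#' sphere disappears) to the collision of the cursor with the fruit.
#' Return-to-home samples are excluded. Events with a missing collision are
#' dropped with a warning. Segment time is re-zeroed at fruit appearance.
#'
#' @param samples long tibble of recorded samples with columns `trial_id`,
#'   `t`, `x`, `y`, `z` (additional columns are ignored).
#' @param events tibble with one row per fruit: `trial_id`,
#'   `fruit_appear_t`, `collision_t` plus any metadata columns (carried
#'   through to the output).
#' @return Nested tibble: one row per segment with the event metadata and a
#'   list-column `data` holding the segment samples (`t`, `x`, `y`, `z`).
#' @export
segment_movements <- function(samples, events) {
  .assert(all(c("trial_id", "t", "x", "y", "z") %in% names(samples)),
          "`samples` must have columns trial_id, t, x, y, z")
  .assert(all(c("trial_id", "fruit_appear_t", "collision_t") %in% names(events)),
          "`events` must have columns trial_id, fruit_appear_t, collision_t")

  incomplete <- is.na(events$collision_t)
  if (any(incomplete)) {
    warning(sprintf("dropping %d segment(s) with no collision event: %s",
                    sum(incomplete),
                    paste(events$trial_id[incomplete], collapse = ", ")))
    events <- events[!incomplete, , drop = FALSE]
  }

  by_trial <- split(samples[, c("trial_id", "t", "x", "y", "z")], samples$trial_id)
  segs <- lapply(seq_len(nrow(events)), function(i) {
    tr <- by_trial[[events$trial_id[i]]]
    if (is.null(tr)) return(NULL)
    win <- tr$t >= events$fruit_appear_t[i] & tr$t <= events$collision_t[i]
    seg <- tr[win, c("t", "x", "y", "z")]
    seg$t <- seg$t - events$fruit_appear_t[i]
    seg
  })
  keep <- !vapply(segs, is.null, logical(1))
  if (!all(keep)) {
    warning(sprintf("dropping %d event(s) with no matching samples", sum(!keep)))
  }
  out <- events[keep, , drop = FALSE]
  out$data <- segs[keep]
  tibble::as_tibble(out)
}

#' Sphere/capsule collision test between cursor and fruit
#'
#' The cursor is a sphere; fruits carry either a spherical collider (orange,
#' apple) or a sphere-plus-capsule collider (pear: lower sphere at the fruit
#' location, capsule extending vertically above it). Contact holds when the
#' cursor sphere overlaps any collider part: for spheres, centre distance at
#' most the sum of radii; for the capsule, distance from the cursor centre
#' to the capsule axis segment at most capsule radius plus cursor radius.
#'
#' @param cursor_center cursor-sphere centre, numeric 3-vector, m.
#' @param cursor_radius cursor-sphere radius, m.
#' @param fruit_center fruit location (centre of the spherical collider), m.
#' @param collider a [collider_spec()].
#' @return `TRUE` if in contact.
#' @export
detect_collision <- function(cursor_center, cursor_radius, fruit_center, collider) {
  cursor_center <- .vec3(cursor_center, "cursor_center")
  fruit_center <- .vec3(fruit_center, "fruit_center")
  .assert(inherits(collider, "collider_spec"), "`collider` must be a collider_spec")
  r_sphere <- collider$sphere_diameter / 2
  if (.norm3(cursor_center - fruit_center) <= r_sphere + cursor_radius) return(TRUE)
  if (collider$shape == "sphere_plus_capsule") {
    a <- fruit_center
    b <- fruit_center + c(0, collider$capsule_height, 0)
    d <- .point_segment_distance(cursor_center, a, b)
    if (d <= collider$capsule_diameter / 2 + cursor_radius) return(TRUE)
  }
  FALSE
}

.chord_length <- function(pos) {
  .norm3(as.numeric(pos[nrow(pos), c("x", "y", "z")]) -
           as.numeric(pos[1, c("x", "y", "z")]))
}

.path_length <- function(pos) {
  dx <- diff(pos$x); dy <- diff(pos$y); dz <- diff(pos$z)
  sum(sqrt(dx^2 + dy^2 + dz^2))
}

#' Normalized movement duration (s/m)
#'
#' Duration of the reaching movement divided by the straight-line distance
#' between its last and first positions. Absent (`NA`) when the chord is
#' shorter than `eps`.
#'
#' @param segment tibble `t`, `x`, `y`, `z` (raw or filtered positions).
#' @param eps degenerate-chord guard, m. Default 1 mm.
#' @return Seconds per metre, or `NA_real_` for a degenerate segment.
#' @export
normalized_duration <- function(segment, eps = 0.001) {
  chord <- .chord_length(segment)
  if (chord <= eps) return(NA_real_)
  (segment$t[nrow(segment)] - segment$t[1]) / chord
}

#' Trajectory straightness ratio
#'
#' Length of the path followed divided by the straight-line distance between
#' the last and first positions; 1 for a perfectly straight reach.
#'
#' @inheritParams normalized_duration
#' @return Dimensionless ratio >= 1 up to noise, or `NA_real_`.
#' @export
straightness_ratio <- function(segment, eps = 0.001) {
  chord <- .chord_length(segment)
  if (chord <= eps) return(NA_real_)
  .path_length(segment) / chord
}

#' Peak velocity of a segment (m/s)
#'
#' @param profile a [compute_speed()] result.
#' @return Highest filtered speed during the movement.
#' @export
peak_velocity <- function(profile) {
  max(profile$speed)
}

#' Count velocity peaks (movement smoothness)
#'
#' Number of local maxima of the filtered speed profile with topographic
#' prominence at least `min_prominence` and pairwise separation at least
#' `min_separation`. More peaks indicate more corrective submovements, i.e.
#' less smooth movement.
#'
#' @param profile a [compute_speed()] result (or tibble `t`, `speed`).
#' @param min_prominence minimum peak prominence, m/s. `NULL` (default) uses
#'   `max(0.02, 5%` of the peak speed`)`.
#' @param min_separation minimum time between retained peaks, s.
#' @return Integer count (0 for a flat profile).
#' @export
count_velocity_peaks <- function(profile, min_prominence = NULL,
                                 min_separation = 0.05) {
  s <- profile$speed
  t <- profile$t
  n <- length(s)
  if (n < 3 || max(s) <= 0) return(0L)
  if (is.null(min_prominence)) min_prominence <- max(0.02, 0.05 * max(s))

  cand <- which(s[2:(n - 1)] > s[1:(n - 2)] & s[2:(n - 1)] >= s[3:n]) + 1L
  if (!length(cand)) return(0L)

  prominence <- vapply(cand, function(i) {
    jj <- which(s[seq_len(i - 1)] > s[i])          # nearest higher point left
    left_min <- if (length(jj)) min(s[max(jj):i]) else min(s[1:i])
    j <- if (i < n) which(s[(i + 1):n] > s[i]) else integer(0)
    right_min <- if (length(j)) min(s[i:(i + j[1])]) else min(s[i:n])
    s[i] - max(left_min, right_min)
  }, numeric(1))

  keep <- cand[prominence >= min_prominence]
  if (!length(keep)) return(0L)
  keep <- keep[order(s[keep], decreasing = TRUE)]
  retained <- numeric(0)
  for (i in keep) {
    if (!length(retained) || all(abs(t[i] - retained) >= min_separation)) {
      retained <- c(retained, t[i])
    }
  }
  length(retained)
}

#' Movement onset (s)
#'
#' Time elapsed between target appearance (segment start) and the first
#' sample whose filtered speed reaches `v_threshold`. Segments that never
#' reach the threshold have no onset (`NA`) and are excluded from onset
#' statistics downstream.
#'
#' @param profile a [compute_speed()] result.
#' @param v_threshold speed threshold, m/s. Default 0.2.
#' @return Onset in seconds, or `NA_real_` if the threshold is never reached.
#' @export
movement_onset <- function(profile, v_threshold = 0.2) {
  idx <- which(profile$speed >= v_threshold)
  if (!length(idx)) return(NA_real_)
  profile$t[idx[1]] - profile$t[1]
}

#' Compute all movement-quality metrics for segmented recordings
#'
#' For each segment: resample, low-pass filter, then compute normalized
#' duration, straightness ratio, peak velocity, velocity-peak count and
#' movement onset. Path and chord lengths use the filtered positions;
#' durations use the recorded segment times.
#'
#' @param segments output of [segment_movements()].
#' @param fs resampling rate, Hz.
#' @param cutoff low-pass cutoff, Hz.
#' @param v_threshold onset threshold, m/s.
#' @param min_prominence,min_separation see [count_velocity_peaks()].
#' @return Tibble with one row per segment: metadata columns plus
#'   `normalized_duration_s_per_m`, `straightness`, `peak_velocity_m_s`,
#'   `n_velocity_peaks`, `onset_s` and a `flags` column (`"ok"`,
#'   `"degenerate_chord"`, `"below_onset_threshold"`).
#' @export
compute_metrics <- function(segments, fs = 500, cutoff = 10, v_threshold = 0.2,
                            min_prominence = NULL, min_separation = 0.05) {
  meta_cols <- setdiff(names(segments), "data")
  rows <- lapply(seq_len(nrow(segments)), function(i) {
    seg <- segments$data[[i]]
    profile <- compute_speed(seg, fs = fs, cutoff = cutoff)
    pos <- attr(profile, "positions")
    nd <- normalized_duration(pos)
    onset <- movement_onset(profile, v_threshold)
    flags <- if (is.na(nd)) "degenerate_chord"
             else if (is.na(onset)) "below_onset_threshold" else "ok"
    tibble::tibble(
      normalized_duration_s_per_m = nd,
      straightness = straightness_ratio(pos),
      peak_velocity_m_s = peak_velocity(profile),
      n_velocity_peaks = count_velocity_peaks(profile, min_prominence, min_separation),
      onset_s = onset,
      flags = flags
    )
  })
  dplyr::bind_cols(segments[, meta_cols], dplyr::bind_rows(rows))
}

#' Remove extreme outliers with Tukey 3xIQR fences
#'
#' Flags values strictly outside `[Q1 - 3*IQR, Q3 + 3*IQR]`, computed per
#' group (typically per participant) with the linear-interpolation quantile
#' convention (R type 7). Values exactly on a fence are kept. A single pass
#' is made: fences are not recomputed after removal. Groups with fewer than
#' 4 values are passed through untouched with a warning.
#'
#' @param data data frame of values.
#' @param value_col name of the numeric column to screen.
#' @param group_cols character vector of grouping columns (e.g.
#'   `"participant"` for pooled fences, `c("participant", "condition")` for
#'   per-condition fences). `NULL` treats all rows as one group.
#' @return List of class `outlier_report`: `kept` and `removed` (row subsets
#'   of `data`), and `fences` (one row per group with `q1`, `q3`, `lower`,
#'   `upper`, `n`, `n_removed`). `NA` values are always kept (they are
#'   absent, not extreme).
#' @export
remove_extreme_outliers <- function(data, value_col, group_cols = NULL) {
  .assert(value_col %in% names(data), "`%s` is not a column of `data`", value_col)
  if (is.null(group_cols)) {
    data$.group <- "all"
    group_cols_eff <- ".group"
  } else {
    group_cols_eff <- group_cols
  }
  grp_key <- interaction(data[group_cols_eff], drop = TRUE, lex.order = TRUE)
  remove_flag <- logical(nrow(data))
  fence_rows <- list()
  for (g in levels(grp_key)) {
    idx <- which(grp_key == g)
    x <- data[[value_col]][idx]
    xx <- x[!is.na(x)]
    if (length(xx) < 4) {
      warning(sprintf("group '%s' has fewer than 4 values; passed through untouched", g))
      fence_rows[[g]] <- data.frame(group = g, q1 = NA_real_, q3 = NA_real_,
                                    lower = -Inf, upper = Inf,
                                    n = length(xx), n_removed = 0L)
      next
    }
    q <- quantile(xx, c(0.25, 0.75), type = 7, names = FALSE)
    iqr <- q[2] - q[1]
    lower <- q[1] - 3 * iqr
    upper <- q[2] + 3 * iqr
    bad <- !is.na(x) & (x < lower | x > upper)
    remove_flag[idx[bad]] <- TRUE
    fence_rows[[g]] <- data.frame(group = g, q1 = q[1], q3 = q[2],
                                  lower = lower, upper = upper,
                                  n = length(xx), n_removed = sum(bad))
  }
  data$.group <- NULL
  structure(list(
    kept = data[!remove_flag, setdiff(names(data), ".group"), drop = FALSE],
    removed = data[remove_flag, setdiff(names(data), ".group"), drop = FALSE],
    fences = tibble::as_tibble(do.call(rbind, fence_rows)),
    value_col = value_col,
    group_cols = group_cols
  ), class = "outlier_report")
}
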