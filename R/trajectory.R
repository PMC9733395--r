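# Minimum-jerk kinematics and trajectory perturbations used by the
# synthetic-data generator. The minimum-jerk polynomial is the standard
# model of smooth point-to-point reaching: a straight path with a single
# symmetric speed peak of 1.875 * distance / duration.

#' Minimum-jerk position polynomial
#'
#' @param tau normalized time in `[0, 1]`.
#' @return Normalized displacement `10*tau^3 - 15*tau^4 + 6*tau^5`.
#' @export
min_jerk_profile <- function(tau) 10 * tau^3 - 15 * tau^4 + 6 * tau^5

#' Closed-form minimum-jerk speed
#'
#' @param t time in seconds from movement start.
#' @param distance straight-line reach distance, m.
#' @param duration movement duration, s.
#' @return Speed in m/s: `30 * (D/T) * tau^2 (1-tau)^2`, zero outside `[0, T]`.
#' @export
min_jerk_speed <- function(t, distance, duration) {
  tau <- t / duration
  ifelse(tau >= 0 & tau <= 1,
         30 * (distance / duration) * tau^2 * (1 - tau)^2, 0)
}

#' Sample a minimum-jerk reach
#'
#' Generates a straight minimum-jerk trajectory from `p0` to `p1` sampled on
#' a uniform grid. The final time point `duration` is always included so the
#' endpoints are exact.
#'
#' @param p0,p1 start and end positions, numeric 3-vectors, m.
#' @param duration movement duration, s (> 0).
#' @param fs sampling frequency, Hz (> 0). Default 500.
#' @return A tibble with columns `t`, `x`, `y`, `z`.
#' @examples
#' tr <- min_jerk_trajectory(c(0, 0, 0), c(0.3, 0, 0), duration = 1)
#' @export
min_jerk_trajectory <- function(p0, p1, duration, fs = 500) {
  p0 <- .vec3(p0, "p0"); p1 <- .vec3(p1, "p1")
  .assert_scalar_num(duration, "duration", positive = TRUE)
  .assert_scalar_num(fs, "fs", positive = TRUE)
  .assert(any(p0 != p1), "`p0` and `p1` must differ")
  t <- seq(0, duration, by = 1 / fs)
  # land exactly on `duration` without creating a sub-sample final interval
  if (t[length(t)] < duration - 1e-12) t[length(t)] <- duration
  s <- min_jerk_profile(t / duration)
  tibble::tibble(
    t = t,
    x = p0[1] + (p1[1] - p0[1]) * s,
    y = p0[2] + (p1[2] - p0[2]) * s,
    z = p0[3] + (p1[3] - p0[3]) * s
  )
}

.traj_endpoints <- function(traj) {
  list(p0 = as.numeric(traj[1, c("x", "y", "z")]),
       p1 = as.numeric(traj[nrow(traj), c("x", "y", "z")]))
}

#' Add a curved lateral deviation to a trajectory
#'
#' Bends a reach by adding a half-sine bump (peak excursion = `amplitude`)
#' in a direction perpendicular to the start-to-end chord. The bump is zero
#' at both endpoints, so the chord is unchanged while the path length (and
#' hence the straightness ratio) strictly increases for positive amplitudes.
#'
#' @param traj trajectory tibble (`t`, `x`, `y`, `z`), at least 3 samples.
#' @param amplitude peak lateral excursion, m (>= 0).
#' @param seed integer seed choosing the bump direction within the
#'   perpendicular plane; `NULL` uses the current RNG state.
#' @return The perturbed trajectory tibble.
#' @export
add_curved_deviation <- function(traj, amplitude, seed = NULL) {
  .assert(nrow(traj) >= 3, "need at least 3 samples")
  .assert_scalar_num(amplitude, "amplitude")
  .assert(amplitude >= 0, "`amplitude` must be non-negative")
  if (amplitude == 0) return(traj)
  ep <- .traj_endpoints(traj)
  chord <- ep$p1 - ep$p0
  u <- chord / .norm3(chord)
  basis <- .perp_basis(u)
  phi <- .with_seed(seed, runif(1, 0, 2 * pi))
  n <- cos(phi) * basis$n1 + sin(phi) * basis$n2
  tau <- (traj$t - traj$t[1]) / (traj$t[nrow(traj)] - traj$t[1])
  bump <- amplitude * sin(pi * tau)
  traj$x <- traj$x + bump * n[1]
  traj$y <- traj$y + bump * n[2]
  traj$z <- traj$z + bump * n[3]
  traj
}

#' Append corrective submovements to a reach
#'
#' Decomposes the reach into a main movement plus `k` temporally separated
#' corrective minimum-jerk submovements, the classical model of corrected
#' reaching: the input trajectory is rescaled to stop `k * scale` metres
#' short of the target, and each correction then covers `scale` metres along
#' the chord as its own minimum-jerk step (after a brief near-stationary
#' gap, as when a reach undershoots and is corrected). The spatial endpoints
#' are preserved exactly while the movement time grows by
#' `k * (width + gap)`. Each correction contributes one isolated bell to the
#' speed profile, so a reach with `k` submovements shows `1 + k` velocity
#' peaks.
#'
#' @param traj trajectory tibble (`t`, `x`, `y`, `z`).
#' @param k number of corrective submovements (>= 0).
#' @param scale distance covered by each correction, m; reduced if `k *
#'   scale` would exceed 80% of the chord.
#' @param seed unused (kept for a uniform generator interface); corrections
#'   are deterministic given the trajectory.
#' @param width duration of each correction, s. Default 0.3.
#' @param gap near-stationary pause before each correction, s. Default 0.08.
#' @return The extended trajectory tibble.
#' @export
add_submovements <- function(traj, k, scale, seed = NULL, width = 0.3,
                             gap = 0.08) {
  .assert(is.numeric(k) && length(k) == 1L && k >= 0 && k == round(k),
          "`k` must be a non-negative integer")
  if (k == 0) return(traj)
  .assert_scalar_num(scale, "scale", positive = TRUE)
  ep <- .traj_endpoints(traj)
  chord <- ep$p1 - ep$p0
  D <- .norm3(chord)
  u <- chord / D
  scale <- min(scale, 0.8 * D / k)
  f <- 1 - k * scale / D

  n <- nrow(traj)
  dt <- (traj$t[n] - traj$t[1]) / (n - 1)
  main <- tibble::tibble(
    t = traj$t,
    x = ep$p0[1] + (traj$x - ep$p0[1]) * f,
    y = ep$p0[2] + (traj$y - ep$p0[2]) * f,
    z = ep$p0[3] + (traj$z - ep$p0[3]) * f
  )

  pieces <- list(main)
  t_cur <- main$t[n]
  p_cur <- as.numeric(main[n, c("x", "y", "z")])
  for (i in seq_len(k)) {
    tt <- seq(dt, gap + width, by = dt)
    s <- scale * min_jerk_profile(pmax(0, pmin(1, (tt - gap) / width)))
    pieces[[i + 1]] <- tibble::tibble(
      t = t_cur + tt,
      x = p_cur[1] + s * u[1],
      y = p_cur[2] + s * u[2],
      z = p_cur[3] + s * u[3]
    )
    t_cur <- t_cur + tt[length(tt)]
    p_cur <- p_cur + scale * u
  }
  dplyr::bind_rows(pieces)
}
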