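# Seeded synthetic-data generator. Emulates the statistical structure the
# analysis assumes: ~500 Hz 3D reach-and-return recordings under three
# visualization conditions with condition-dependent duration, curvature,
# smoothness and onset effects; counting responses with occasional +1
# errors; and Likert / slider questionnaire responses.

#' Per-condition effect model
#'
#' Bundles the parameters through which a visualization condition shapes the
#' simulated movements. The defaults in [default_effect_config()] encode the
#' expected ordering (head-mounted displays yield straighter, shorter and
#' smoother movements than a 2D screen); the magnitudes are simulation
#' configuration, not empirical claims.
#'
#' @param condition condition label (`"IVR"`, `"AR"` or `"Screen"`).
#' @param duration_scale dimensionless multiplier on movement duration (> 0).
#' @param curvature_amplitude lateral bump amplitude, m (>= 0).
#' @param submovement_rate Poisson mean of corrective submovements per reach.
#' @param onset_latency_mean,onset_latency_sd truncated-normal latency between
#'   target appearance and movement start, s.
#' @param noise_sd isotropic additive position-noise SD, m.
#' @return A list of class `condition_effect_model`.
#' @export
condition_effect_model <- function(condition, duration_scale = 1,
                                   curvature_amplitude = 0.01,
                                   submovement_rate = 0.5,
                                   onset_latency_mean = 0.3,
                                   onset_latency_sd = 0.06,
                                   noise_sd = 0.001) {
  .assert_scalar_num(duration_scale, "duration_scale", positive = TRUE)
  .assert(curvature_amplitude >= 0, "`curvature_amplitude` must be >= 0")
  .assert(submovement_rate >= 0, "`submovement_rate` must be >= 0")
  .assert(onset_latency_mean >= 0 && onset_latency_sd >= 0,
          "onset latency parameters must be >= 0")
  .assert(noise_sd >= 0, "`noise_sd` must be >= 0")
  structure(list(condition = condition, duration_scale = duration_scale,
                 curvature_amplitude = curvature_amplitude,
                 submovement_rate = submovement_rate,
                 onset_latency_mean = onset_latency_mean,
                 onset_latency_sd = onset_latency_sd,
                 noise_sd = noise_sd),
            class = "condition_effect_model")
}

#' Default condition effects (Screen > AR > IVR on duration etc.)
#'
#' @return Named list of [condition_effect_model()]s for IVR, AR and Screen.
#' @export
default_effect_config <- function() {
  list(
    IVR    = condition_effect_model("IVR", duration_scale = 1.00,
                                    curvature_amplitude = 0.010,
                                    submovement_rate = 0.4,
                                    onset_latency_mean = 0.30),
    AR     = condition_effect_model("AR", duration_scale = 1.08,
                                    curvature_amplitude = 0.016,
                                    submovement_rate = 0.7,
                                    onset_latency_mean = 0.34),
    Screen = condition_effect_model("Screen", duration_scale = 1.18,
                                    curvature_amplitude = 0.024,
                                    submovement_rate = 1.1,
                                    onset_latency_mean = 0.40,
                                    onset_latency_sd = 0.07)
  )
}

#' Null condition effects (all conditions exchangeable)
#'
#' @return Named list of identical [condition_effect_model()]s, for type-I
#'   error calibration.
#' @export
null_effect_config <- function() {
  setNames(lapply(CONDITIONS, function(cc)
    condition_effect_model(cc, duration_scale = 1.05,
                           curvature_amplitude = 0.015,
                           submovement_rate = 0.6,
                           onset_latency_mean = 0.33)), CONDITIONS)
}

#' Sample subject-level models
#'
#' @param n_subjects number of subjects (>= 1).
#' @param seed integer seed.
#' @param baseline_duration_per_m population-mean normalized duration, s/m.
#' @param subject_sd log-scale SD of the subject random multiplier.
#' @param counting_error_rate per-fruit counting error probability.
#' @return Tibble with `subject_id`, `baseline_duration_per_m`,
#'   `subject_random_effect`, `counting_error_rate`.
#' @export
sample_subjects <- function(n_subjects, seed = NULL,
                            baseline_duration_per_m = 3.0,
                            subject_sd = 0.15,
                            counting_error_rate = 0.05) {
  .assert(n_subjects >= 1, "need at least one subject")
  .with_seed(seed, tibble::tibble(
    subject_id = sprintf("P%02d", seq_len(n_subjects)),
    baseline_duration_per_m = baseline_duration_per_m,
    subject_random_effect = exp(rnorm(n_subjects, 0, subject_sd)),
    counting_error_rate = counting_error_rate
  ))
}

# Radius at which the cursor first contacts a fruit collider (lower sphere).
.contact_radius <- function(protocol, fruit_kind) {
  protocol$colliders[[fruit_kind]]$sphere_diameter / 2 +
    protocol$cursor_sphere_diameter / 2
}

#' Simulate one fruit-reach trial
#'
#' Generates a single recording: a latency phase at the home position, a
#' minimum-jerk reach (with per-condition curvature and Poisson-many
#' corrective submovements) ending just inside the fruit's contact boundary,
#' and a flagged return-to-home movement. Timestamps sit on a nominal 2 ms
#' grid with small Gaussian jitter; isotropic position noise is added
#' throughout.
#'
#' @param subject one row of [sample_subjects()] (list or 1-row tibble).
#' @param effects a [condition_effect_model()].
#' @param plan_row one row of [plan_trial_sequence()].
#' @param protocol the [build_protocol()] result.
#' @param seed integer seed; same seed, same recording.
#' @param cond_mult subject-by-condition duration multiplier (default 1).
#' @param trial_sd log-scale SD of trial-to-trial duration noise.
#' @param submovement_scale perpendicular excursion of corrective bumps, m.
#' @param fs nominal sampling rate, Hz.
#' @param include_return generate the flagged return movement (default TRUE).
#' @return List of class `trial_recording` with `samples` (tibble `t`, `x`,
#'   `y`, `z`, `phase`), `events` (`fruit_appear_t`, `collision_t`), `meta`
#'   and `truth` (the injected parameters).
#' @export
simulate_trial <- function(subject, effects, plan_row, protocol, seed = NULL,
                           cond_mult = 1, trial_sd = 0.08,
                           submovement_scale = 0.015, fs = 500,
                           include_return = TRUE) {
  .with_seed(seed, {
    target <- c(plan_row$x, plan_row$y, plan_row$z)
    d_target <- .norm3(target)
    r_contact <- .contact_radius(protocol, plan_row$fruit_kind)
    margin <- max(0.002, 5 * effects$noise_sd)
    d_reach <- d_target - r_contact + margin
    .assert(d_reach > 0.01, "target too close to the home position")
    aim <- target * (d_reach / d_target)

    trial_mult <- exp(rnorm(1, 0, trial_sd))
    duration <- subject$baseline_duration_per_m * subject$subject_random_effect *
      effects$duration_scale * cond_mult * trial_mult * d_reach
    latency <- max(0.05, rnorm(1, effects$onset_latency_mean,
                               effects$onset_latency_sd))
    k_sub <- rpois(1, effects$submovement_rate)
    curve_amp <- effects$curvature_amplitude * exp(rnorm(1, 0, 0.2))

    reach <- min_jerk_trajectory(c(0, 0, 0), aim, duration, fs)
    if (curve_amp > 0) reach <- add_curved_deviation(reach, curve_amp)
    if (k_sub > 0) reach <- add_submovements(reach, k_sub, submovement_scale)

    n_lat <- max(1L, floor(latency * fs))
    lat_t <- seq(0, by = 1 / fs, length.out = n_lat)
    samples <- tibble::tibble(
      t = c(lat_t, reach$t + latency),
      x = c(rep(0, n_lat), reach$x),
      y = c(rep(0, n_lat), reach$y),
      z = c(rep(0, n_lat), reach$z),
      phase = c(rep("latency", n_lat), rep("reach", nrow(reach)))
    )
    collision_idx <- nrow(samples)

    if (include_return) {
      ret <- min_jerk_trajectory(aim, c(0, 0, 0), 0.9 * duration, fs)
      t_coll <- samples$t[collision_idx]
      samples <- dplyr::bind_rows(
        samples,
        tibble::tibble(t = ret$t[-1] + t_coll, x = ret$x[-1], y = ret$y[-1],
                       z = ret$z[-1], phase = "return")
      )
    }

    n <- nrow(samples)
    jitter <- pmax(pmin(rnorm(n, 0, 1e-4), 9e-4), -9e-4)
    samples$t <- samples$t + jitter - jitter[1]
    if (effects$noise_sd > 0) {
      samples$x <- samples$x + rnorm(n, 0, effects$noise_sd)
      samples$y <- samples$y + rnorm(n, 0, effects$noise_sd)
      samples$z <- samples$z + rnorm(n, 0, effects$noise_sd)
    }

    structure(list(
      samples = samples,
      events = list(fruit_appear_t = 0, collision_t = samples$t[collision_idx]),
      meta = list(subject_id = subject$subject_id, condition = effects$condition,
                  trial_index = plan_row$trial_index,
                  block_index = plan_row$block_index,
                  fruit_kind = plan_row$fruit_kind,
                  location_id = plan_row$location_id,
                  depth_class = plan_row$depth_class),
      truth = list(duration = duration, latency = latency, distance = d_reach,
                   k_submovements = k_sub, curvature_amplitude = curve_amp,
                   trial_mult = trial_mult)
    ), class = "trial_recording")
  })
}

#' Simulate a full crossed dataset
#'
#' Generates every subject x condition x trial recording of the crossed
#' within-subject design (e.g. 5 subjects under the experiment-2 protocol
#' give 5 x 3 x 48 = 720 recordings), alongside the ground-truth table of
#' injected parameters.
#'
#' @param protocol a [build_protocol()] result.
#' @param effect_config named list of [condition_effect_model()]s (one per
#'   condition); default [default_effect_config()].
#' @param n_subjects number of subjects (>= 2).
#' @param seed master integer seed; every stage derives its randomness from it.
#' @param cond_sd log-scale SD of the subject-by-condition duration
#'   multiplier (the within-subject error term of the RM design).
#' @param fs nominal sampling rate, Hz.
#' @param include_return include return-to-home movements (flagged).
#' @return A list of class `reach_dataset` with `samples` (one long tibble:
#'   `trial_id`, `participant`, `condition`, `t`, `x`, `y`, `z`, `phase`),
#'   `events` (one row per trial with appearance/collision times and
#'   metadata), `plan`, `subjects`, `truth` and `effect_config`.
#' @export
simulate_dataset <- function(protocol, effect_config = default_effect_config(),
                             n_subjects = 5, seed = 1, cond_sd = 0.05,
                             fs = 500, include_return = TRUE) {
  validate_protocol(protocol)
  .assert(n_subjects >= 2, "need at least 2 subjects")
  .assert(all(CONDITIONS %in% names(effect_config)),
          "`effect_config` must name all of IVR, AR, Screen")

  seeds <- .spawn_seeds(seed, 3)
  subjects <- sample_subjects(n_subjects, seed = seeds[1])
  plan <- plan_trial_sequence(protocol, seed = seeds[2])
  n_trials <- nrow(plan)

  grid <- expand.grid(s = seq_len(n_subjects), cond = CONDITIONS, i = seq_len(n_trials),
                      stringsAsFactors = FALSE)
  # cond_mult drawn first so the distribution-level fast path shares the
  # subject-by-condition effects for the same master seed
  aux <- .with_seed(seeds[3], list(
    cond_mult = matrix(exp(rnorm(n_subjects * 3, 0, cond_sd)), n_subjects, 3,
                       dimnames = list(NULL, CONDITIONS)),
    trial_seeds = sample.int(.Machine$integer.max, nrow(grid))
  ))

  sample_list <- vector("list", nrow(grid))
  event_list <- vector("list", nrow(grid))
  truth_list <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    s <- grid$s[g]; cond <- grid$cond[g]; i <- grid$i[g]
    rec <- simulate_trial(
      subject = as.list(subjects[s, ]),
      effects = effect_config[[cond]],
      plan_row = as.list(plan[i, ]),
      protocol = protocol,
      seed = aux$trial_seeds[g],
      cond_mult = aux$cond_mult[s, cond],
      fs = fs, include_return = include_return
    )
    trial_id <- sprintf("%s_%s_%03d", subjects$subject_id[s], cond, i)
    sm <- rec$samples
    sm$trial_id <- trial_id
    sm$participant <- subjects$subject_id[s]
    sm$condition <- cond
    sample_list[[g]] <- sm
    event_list[[g]] <- tibble::tibble(
      trial_id = trial_id, participant = subjects$subject_id[s],
      condition = cond, trial_index = i,
      block_index = rec$meta$block_index, fruit_kind = rec$meta$fruit_kind,
      location_id = rec$meta$location_id, depth_class = rec$meta$depth_class,
      fruit_appear_t = rec$events$fruit_appear_t,
      collision_t = rec$events$collision_t
    )
    truth_list[[g]] <- tibble::as_tibble(c(list(trial_id = trial_id), rec$truth))
  }

  structure(list(
    samples = dplyr::bind_rows(sample_list)[, c("trial_id", "participant",
                                                "condition", "t", "x", "y", "z",
                                                "phase")],
    events = dplyr::bind_rows(event_list),
    plan = plan,
    subjects = subjects,
    truth = dplyr::bind_rows(truth_list),
    effect_config = effect_config,
    protocol = protocol
  ), class = "reach_dataset")
}

#' Fast distribution-level simulation of per-trial metrics
#'
#' Draws per-trial movement-quality metrics directly from the same generative
#' parameters as [simulate_dataset()], skipping trajectory synthesis. The
#' mapping uses the minimum-jerk closed forms: normalized duration equals the
#' injected duration multipliers; peak velocity is `1.875 / normalized
#' duration`; straightness follows the half-sine arc-length expansion;
#' velocity peaks are `1 + Poisson(rate)`; onset is the injected latency plus
#' the closed-form 0.2 m/s threshold-crossing time of the minimum-jerk ramp.
#' Intended for calibration and power studies of the statistical harness,
#' where thousands of replicate datasets are needed.
#'
#' @inheritParams simulate_dataset
#' @param v_threshold onset speed threshold, m/s.
#' @return Tibble with one row per trial: `participant`, `condition`,
#'   `depth_class`, `trial_index`, `normalized_duration`, `straightness`,
#'   `peak_velocity`, `n_velocity_peaks`, `onset`.
#' @export
simulate_metric_table <- function(protocol, effect_config = default_effect_config(),
                                  n_subjects = 17, seed = 1, cond_sd = 0.05,
                                  v_threshold = 0.2) {
  validate_protocol(protocol)
  seeds <- .spawn_seeds(seed, 3)
  subjects <- sample_subjects(n_subjects, seed = seeds[1])
  plan <- plan_trial_sequence(protocol, seed = seeds[2])
  n_trials <- nrow(plan)

  .with_seed(seeds[3], {
    rows <- expand.grid(s = seq_len(n_subjects), condition = CONDITIONS,
                        i = seq_len(n_trials), stringsAsFactors = FALSE)
    n <- nrow(rows)
    cond_mult <- matrix(exp(rnorm(n_subjects * 3, 0, cond_sd)), n_subjects, 3,
                        dimnames = list(NULL, CONDITIONS))
    eff <- function(field) vapply(rows$condition,
                                  function(cc) effect_config[[cc]][[field]],
                                  numeric(1))

    r_contact <- vapply(plan$fruit_kind[rows$i],
                        function(k) .contact_radius(protocol, k), numeric(1))
    d_target <- sqrt(plan$x[rows$i]^2 + plan$y[rows$i]^2 + plan$z[rows$i]^2)
    noise_sd <- eff("noise_sd")
    d_reach <- d_target - r_contact + pmax(0.002, 5 * noise_sd)

    trial_mult <- exp(rnorm(n, 0, 0.08))
    norm_dur <- subjects$baseline_duration_per_m[rows$s] *
      subjects$subject_random_effect[rows$s] * eff("duration_scale") *
      cond_mult[cbind(rows$s, match(rows$condition, CONDITIONS))] * trial_mult
    duration <- norm_dur * d_reach

    curve_amp <- eff("curvature_amplitude") * exp(rnorm(n, 0, 0.2))
    k_sub <- rpois(n, eff("submovement_rate"))
    latency <- pmax(0.05, rnorm(n, eff("onset_latency_mean"), eff("onset_latency_sd")))
    # corrective submovements extend the movement by 0.38 s each; the peak
    # velocity belongs to the main (pre-correction) movement; the analysed
    # segment spans target appearance to touch, so its duration includes
    # the reaction latency
    peak_vel <- 1.875 * (1 - 0.015 * k_sub / d_reach) / norm_dur
    norm_dur <- norm_dur + (k_sub * 0.38 + latency) / d_reach
    straightness <- 1 + (pi * curve_amp)^2 / (4 * d_reach^2)
    # first tau with 30 (D/T) tau^2 (1-tau)^2 = v_threshold:
    # tau (1 - tau) = sqrt(v_threshold T / (30 D)), smaller root of the quadratic
    s_term <- sqrt(v_threshold * duration / (30 * d_reach))
    onset <- ifelse(s_term <= 0.25,
                    latency + duration * (1 - sqrt(pmax(0, 1 - 4 * s_term))) / 2,
                    NA_real_)

    tibble::tibble(
      participant = subjects$subject_id[rows$s],
      condition = rows$condition,
      depth_class = plan$depth_class[rows$i],
      trial_index = rows$i,
      normalized_duration = norm_dur,
      straightness = straightness,
      peak_velocity = peak_vel,
      n_velocity_peaks = 1 + k_sub,
      onset = onset
    )
  })
}

#' Simulate counting-task responses
#'
#' Walks through a block's fruit sequence keeping an internal per-category
#' counter. With probability `error_rate` the spoken value exceeds the
#' intended next value by one (a "+1" error); with probability `carry_prob`
#' the participant then continues counting from the erroneous value
#' (carry-forward), otherwise they recover to the true count.
#'
#' @param truth tibble with a `category` column giving the fruit sequence of
#'   one block (a `true_count` column is recomputed if absent).
#' @param error_rate per-fruit error probability in `[0, 1]`.
#' @param seed integer seed.
#' @param carry_prob probability of continuing from an erroneous value.
#' @return `truth` with columns `true_count`, `said_category`, `said_count`.
#' @export
simulate_counting <- function(truth, error_rate, seed = NULL, carry_prob = 1) {
  .assert(error_rate >= 0 && error_rate <= 1, "`error_rate` must be in [0, 1]")
  .assert(nrow(truth) >= 1, "empty fruit sequence")
  .with_seed(seed, {
    cats <- as.character(truth$category)
    true_count <- integer(length(cats))
    said <- integer(length(cats))
    counter_true <- counter_internal <- setNames(integer(length(unique(cats))),
                                                 unique(cats))
    for (i in seq_along(cats)) {
      cc <- cats[i]
      counter_true[cc] <- counter_true[cc] + 1L
      true_count[i] <- counter_true[cc]
      intended <- counter_internal[cc] + 1L
      said[i] <- if (runif(1) < error_rate) intended + 1L else intended
      counter_internal[cc] <- if (said[i] != true_count[i] && runif(1) >= carry_prob) {
        counter_true[cc]
      } else {
        said[i]
      }
    }
    out <- truth
    out$true_count <- true_count
    out$said_category <- cats
    out$said_count <- said
    out
  })
}

#' Simulate questionnaire response tables
#'
#' Generates SUS (10 Likert items), IMI (four subscales of 5--7 Likert items:
#' interest/enjoyment, perceived competence, effort/importance,
#' pressure/tension) and NASA-RTLX (six 0--100 sliders) responses for each
#' subject under each condition. Optional per-condition location shifts move
#' an instrument's latent mean; shifts that would push items beyond the
#' instrument's range are clipped with a warning.
#'
#' @param n_subjects number of subjects.
#' @param condition_shifts named list (`SUS`, `IMI`, `RTLX`) of named numeric
#'   vectors of per-condition shifts (instrument units); default no shift.
#' @param seed integer seed.
#' @param sus_scale_max top of the SUS/IMI Likert scale (7 in experiment 1,
#'   5 in experiment 2 for the SUS).
#' @return Long tibble: `participant`, `condition`, `instrument`, `subscale`,
#'   `item`, `value`.
#' @export
simulate_questionnaires <- function(n_subjects, condition_shifts = NULL,
                                    seed = 1, sus_scale_max = 7) {
  shifts <- function(instr) {
    sh <- condition_shifts[[instr]] %||% setNames(rep(0, 3), CONDITIONS)
    sh[CONDITIONS]
  }
  items <- rbind(
    data.frame(instrument = "SUS", subscale = "usability",
               item = sprintf("sus_%02d", 1:10), base = 4.8),
    data.frame(instrument = "IMI",
               subscale = rep(c("interest_enjoyment", "perceived_competence",
                                "effort_importance", "pressure_tension"),
                              c(7, 5, 5, 5)),
               item = sprintf("imi_%02d", 1:22),
               base = rep(c(5.0, 4.5, 5.0, 3.0), c(7, 5, 5, 5))),
    data.frame(instrument = "RTLX",
               subscale = c("mental_demand", "physical_demand", "temporal_demand",
                            "performance", "effort", "frustration"),
               item = c("mental_demand", "physical_demand", "temporal_demand",
                        "performance", "effort", "frustration"),
               base = 40)
  )

  .with_seed(seed, {
    out <- vector("list", n_subjects * 3)
    idx <- 1L
    subj_eff <- rnorm(n_subjects, 0, 0.5)
    subj_eff_rtlx <- rnorm(n_subjects, 0, 8)
    clipped_by_shift <- FALSE
    for (s in seq_len(n_subjects)) {
      for (cond in CONDITIONS) {
        tab <- items
        likert <- tab$instrument != "RTLX"
        sh <- ifelse(tab$instrument == "SUS", shifts("SUS")[cond],
                     ifelse(tab$instrument == "IMI", shifts("IMI")[cond],
                            shifts("RTLX")[cond]))
        latent <- tab$base + sh +
          ifelse(likert, subj_eff[s], subj_eff_rtlx[s]) +
          rnorm(nrow(tab), 0, ifelse(likert, 0.8, 10))
        value <- ifelse(likert,
                        pmin(pmax(round(latent), 1), sus_scale_max),
                        pmin(pmax(round(latent), 0), 100))
        if (any(sh != 0 & likert & (tab$base + sh > sus_scale_max | tab$base + sh < 1)) ||
            any(sh != 0 & !likert & (tab$base + sh > 100 | tab$base + sh < 0))) {
          clipped_by_shift <- TRUE
        }
        out[[idx]] <- tibble::tibble(
          participant = sprintf("P%02d", s), condition = cond,
          instrument = tab$instrument, subscale = tab$subscale,
          item = tab$item, value = value
        )
        idx <- idx + 1L
      }
    }
    if (clipped_by_shift) {
      warning("condition shift pushes items beyond the instrument range; values clipped")
    }
    dplyr::bind_rows(out)
  })
}
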