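#' Minimum-jerk position profile
#'
#' Classic fifth-order polynomial reach profile: zero velocity and
#' acceleration at both ends.  Times outside `[t0, t1]` are clamped to the
#' endpoints.
#'
#' @param t Time(s) at which to evaluate (s).
#' @param t0,t1 Segment start / end times (s).
#' @param x0,x1 Segment start / end positions.
#' @return Positions at `t`.
#' @export
min_jerk <- function(t, t0, t1, x0, x1) {
  tau <- pmin(pmax((t - t0) / (t1 - t0), 0), 1)
  x0 + (x1 - x0) * (10 * tau^3 - 15 * tau^4 + 6 * tau^5)
}

#' True corrective delay as a function of trial index
#'
#' On unpredictable (random-schedule) trials the correction begins
#' `true_rtp_initial` after perturbation onset.  On predictable
#' (repeat-schedule) trials the delay decays exponentially with the
#' within-condition trial index `k`:
#' `rtp_floor + (true_rtp_initial - rtp_floor) * exp(-k / rtp_decay_constant)`.
#' A negative floor lets late corrections begin before the perturbation
#' itself (full anticipation).
#'
#' @param k Within-condition trial index (>= 1); ignored for non-repeat
#'   schedules.
#' @param behavior A [behavior_params()] object.
#' @param schedule `"random"`, `"repeat"` or `"fixed"`.
#' @return Corrective delay in seconds.
#' @export
true_rtp <- function(k, behavior = behavior_params(), schedule = "random") {
  if (identical(schedule, "repeat")) {
    if (any(is.na(k)) || any(k < 1))
      stop("repeat-schedule trials need a trial index k >= 1")
    behavior$rtp_floor + (behavior$true_rtp_initial - behavior$rtp_floor) *
      exp(-k / behavior$rtp_decay_constant)
  } else {
    rep(behavior$true_rtp_initial, length(k))
  }
}

# Deterministic (noise-free) hand-orientation angle for one trial.
# Perturbed trials: primary movement toward the initial orientation, then a
# two-segment minimum-jerk correction from the correction onset to the final
# orientation with a transient over-rotation of amplitude A past it.
.trajectory_angle_one <- function(t, trial, behavior, k = trial$repeat_index) {
  start <- behavior$start_orientation
  rel <- trial$t_center_release
  hit <- trial$t_target_hit
  if (trial$perturbation == "none") {
    ang <- min_jerk(t, rel, hit, start, trial$final_orientation)
    return(ang)
  }
  t_corr <- trial$t_perturbation + true_rtp(k, behavior, trial$schedule)
  amp <- behavior$overrotation_initial
  if (identical(trial$schedule, "repeat"))
    amp <- amp * exp(-(k - 1) / behavior$overrotation_decay)
  s <- sign(trial$final_orientation - trial$initial_orientation)
  over <- trial$final_orientation + s * amp
  t_mid <- t_corr + behavior$overrotation_peak_frac * (hit - t_corr)
  base_at_corr <- min_jerk(t_corr, rel, hit, start, trial$initial_orientation)
  ang <- min_jerk(t, rel, hit, start, trial$initial_orientation)
  seg1 <- t >= t_corr & t < t_mid
  seg2 <- t >= t_mid & t < hit
  ang[seg1] <- min_jerk(t[seg1], t_corr, t_mid, base_at_corr, over)
  ang[seg2] <- min_jerk(t[seg2], t_mid, hit, over, trial$final_orientation)
  ang[t >= hit] <- trial$final_orientation
  ang
}

#' Noise-free hand-orientation angle of a trial
#'
#' Evaluates the generator's deterministic orientation path, used by tests to
#' check endpoint and over-rotation properties independently of sampling.
#'
#' @param t Times (s from pad hit).
#' @param trial One-row trial data.frame (see [generate_block()]).
#' @param behavior A [behavior_params()] object.
#' @param repeat_trial_index Within-condition index for repeat trials.
#' @return Angles in degrees.
#' @export
trajectory_angle <- function(t, trial, behavior = behavior_params(),
                             repeat_trial_index = trial$repeat_index) {
  stopifnot(nrow(trial) == 1L)
  .trajectory_angle_one(t, trial, behavior, repeat_trial_index)
}

# smooth Gaussian noise with marginal sd `sd`; correlation time smooth_sd (s)
.smooth_noise <- function(n, sd, dt, smooth_sd) {
  if (sd <= 0) return(numeric(n))
  m <- max(1L, ceiling(3 * smooth_sd / dt))
  kern <- stats::dnorm(seq(-m, m), sd = max(smooth_sd / dt, 1e-6))
  w <- stats::rnorm(n + 2L * m)
  sm <- stats::convolve(w, kern, type = "filter") # length n
  sm / sqrt(sum(kern^2)) * sd
}

#' Simulate the sampled hand-orientation trajectory of one trial
#'
#' Samples the deterministic path at 100 Hz (10 ms steps from pad hit to
#' target release) and adds smooth measurement noise.  Uses the current RNG
#' state; seed the session for reproducibility.
#'
#' @inheritParams trajectory_angle
#' @return A data.frame with `trial_id`, `t` (s) and `angle_deg`.
#' @export
simulate_trajectory <- function(trial, behavior = behavior_params(),
                                repeat_trial_index = trial$repeat_index) {
  stopifnot(nrow(trial) == 1L)
  tt <- seq(0, trial$t_target_release, by = 0.010)
  ang <- .trajectory_angle_one(tt, trial, behavior, repeat_trial_index) +
    .smooth_noise(length(tt), behavior$trajectory_noise_sd, 0.010,
                  behavior$noise_smooth_sd)
  data.frame(trial_id = trial$trial_id, t = tt, angle_deg = ang)
}

#' Simulate trajectories for a whole trial table
#'
#' @param trials Trial data.frame from [generate_block()] or [make_trials()].
#' @param behavior A [behavior_params()] object.
#' @return Long data.frame (`trial_id`, `t`, `angle_deg`) over all trials.
#' @export
simulate_block_trajectories <- function(trials,
                                        behavior = behavior_params()) {
  out <- lapply(seq_len(nrow(trials)), function(i)
    simulate_trajectory(trials[i, ], behavior))
  do.call(rbind, out)
}
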