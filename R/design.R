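#' Block design parameters
#'
#' Describes one testing block of the orientation-perturbation reaching task:
#' four sets of trials run back to back.  Set 1 holds unperturbed reaches to
#' targets fixed at 45, 90 or 135 degrees; set 2 perturbs a 90-degree target
#' randomly (45 degrees clockwise, counterclockwise, or not at all, in equal
#' proportion); sets 3 and 4 repeat a single perturbation direction (CW and
#' CCW respectively) on every trial so the perturbation becomes predictable.
#' The defaults give the standard 90/90/30/30 block of 240 trials.
#'
#' @param n_set1 Number of unperturbed trials in set 1.  Must be a positive
#'   multiple of 6 so that consecutive groups of six trials can carry three
#'   reaches per target side.
#' @param n_set2 Number of random-perturbation trials in set 2.  Must be a
#'   positive multiple of 6 (two sides times three perturbation conditions).
#' @param n_repeat Number of trials in each of sets 3 and 4; must be a
#'   positive even number.
#' @param orientations Fixed target orientations (degrees) used in set 1.
#' @param random_probs Named probabilities for the set-2 perturbation draw,
#'   in order CW45, CCW45, none.  Must sum to 1 and yield integer per-side
#'   counts; trials are allocated exactly and shuffled (pseudo-random order
#'   with the stated marginal probabilities).
#'
#' @return An object of class `design_params`.
#' @export
design_params <- function(n_set1 = 90L, n_set2 = 90L, n_repeat = 30L,
                          orientations = c(45, 90, 135),
                          random_probs = c(CW45 = 1/3, CCW45 = 1/3, none = 1/3)) {
  n_set1 <- as.integer(n_set1)
  n_set2 <- as.integer(n_set2)
  n_repeat <- as.integer(n_repeat)
  if (n_set1 < 6L || n_set1 %% 6L != 0L)
    stop("configuration error: n_set1 must be a positive multiple of 6")
  if (n_set2 < 6L || n_set2 %% 2L != 0L)
    stop("configuration error: n_set2 must be a positive even number")
  if (n_repeat < 2L || n_repeat %% 2L != 0L)
    stop("configuration error: n_repeat must be a positive even number")
  if (length(orientations) < 1L || any(!is.finite(orientations)))
    stop("configuration error: invalid orientations")
  if (n_set1 %% (2L * length(orientations)) != 0L)
    stop("configuration error: n_set1 must balance sides x orientations")
  if (length(random_probs) != 3L || any(random_probs < 0) ||
      abs(sum(random_probs) - 1) > 1e-8)
    stop("configuration error: random_probs must be 3 non-negative values summing to 1")
  cnt <- random_probs * (n_set2 / 2L)
  if (max(abs(cnt - round(cnt))) > 1e-8)
    stop("configuration error: random_probs do not yield integer per-side counts")
  structure(list(n_set1 = n_set1, n_set2 = n_set2, n_repeat = n_repeat,
                 orientations = orientations, random_probs = random_probs),
            class = "design_params")
}

#' Behavioural generator parameters
#'
#' All durations are seconds from central-pad hit (the trial clock zero);
#' angles are degrees.  Defaults encode the task timing: a >= 300 ms holding
#' phase before the cue light, a ~250 ms cue reaction time, movement times of
#' about 270 ms (unperturbed) and 400 ms (perturbed), the 70 ms
#' release-to-perturbation latency, and a corrective reaction that starts
#' about 100 ms after perturbation onset on unpredictable trials.  Under
#' repeated (predictable) perturbations the true corrective delay decays
#' exponentially with the trial index towards `rtp_floor`, which may be
#' negative: a correction that starts before the perturbation itself, i.e.
#' full anticipation.  Over-rotation past the new target decays likewise.
#'
#' `trajectory_noise_sd` is measurement noise of the optical tracker on the
#' reconstructed orientation angle (smooth on a ~20 ms timescale), not
#' biological path variability.
#'
#' @param rtc_mean,rtc_sd Cue reaction time lognormal mean / sd (s).
#' @param mt_unperturbed_mean,mt_perturbed_mean,mt_sd Movement time mean for
#'   unperturbed and perturbed trials and common sd (s).
#' @param hold_min,hold_jitter Holding phase: minimum duration plus a uniform
#'   jitter (s).
#' @param tht_mean,tht_sd Target holding time mean / sd (s).
#' @param perturbation_latency Central-pad release to perturbation onset (s).
#' @param true_rtp_initial Corrective delay after perturbation onset on
#'   unpredictable trials and on the first predictable trial (s).
#' @param rtp_decay_constant Trials over which the predictable-trial
#'   corrective delay decays (e-folding, trials; > 0).
#' @param rtp_floor Asymptotic corrective delay on predictable trials (s, may
#'   be negative).
#' @param overrotation_initial Initial over-rotation amplitude past the new
#'   target orientation (degrees).
#' @param overrotation_decay Trials over which over-rotation decays on
#'   predictable trials (> 0).
#' @param overrotation_peak_frac Fraction of the corrective interval at which
#'   the over-rotation peak is reached.
#' @param trajectory_noise_sd Marginal sd of additive smooth angle noise
#'   (degrees).
#' @param noise_smooth_sd Gaussian smoothing timescale of the noise (s).
#' @param start_orientation Hand orientation at the holding pad (degrees).
#' @param fail_prob Probability that a trial is marked unsuccessful.
#'
#' @return An object of class `behavior_params`.
#' @export
behavior_params <- function(rtc_mean = 0.250, rtc_sd = 0.050,
                            mt_unperturbed_mean = 0.270,
                            mt_perturbed_mean = 0.400,
                            mt_sd = 0.030,
                            hold_min = 0.300, hold_jitter = 0.150,
                            tht_mean = 0.300, tht_sd = 0.050,
                            perturbation_latency = 0.070,
                            true_rtp_initial = 0.100,
                            rtp_decay_constant = 3,
                            rtp_floor = -0.020,
                            overrotation_initial = 10,
                            overrotation_decay = 5,
                            overrotation_peak_frac = 0.6,
                            trajectory_noise_sd = 0.15,
                            noise_smooth_sd = 0.020,
                            start_orientation = 90,
                            fail_prob = 0) {
  p <- list(rtc_mean = rtc_mean, rtc_sd = rtc_sd,
            mt_unperturbed_mean = mt_unperturbed_mean,
            mt_perturbed_mean = mt_perturbed_mean, mt_sd = mt_sd,
            hold_min = hold_min, hold_jitter = hold_jitter,
            tht_mean = tht_mean, tht_sd = tht_sd,
            perturbation_latency = perturbation_latency,
            true_rtp_initial = true_rtp_initial,
            rtp_decay_constant = rtp_decay_constant,
            rtp_floor = rtp_floor,
            overrotation_initial = overrotation_initial,
            overrotation_decay = overrotation_decay,
            overrotation_peak_frac = overrotation_peak_frac,
            trajectory_noise_sd = trajectory_noise_sd,
            noise_smooth_sd = noise_smooth_sd,
            start_orientation = start_orientation,
            fail_prob = fail_prob)
  if (p$mt_perturbed_mean <= p$mt_unperturbed_mean)
    stop("configuration error: mt_perturbed_mean must exceed mt_unperturbed_mean")
  if (p$rtp_decay_constant <= 0 || p$overrotation_decay <= 0)
    stop("configuration error: decay constants must be > 0")
  if (p$hold_min < 0.300)
    stop("configuration error: holding phase must be at least 300 ms")
  if (p$trajectory_noise_sd < 0 || p$fail_prob < 0 || p$fail_prob > 1)
    stop("configuration error: invalid noise sd or failure probability")
  if (p$overrotation_peak_frac <= 0 || p$overrotation_peak_frac >= 1)
    stop("configuration error: overrotation_peak_frac must lie in (0, 1)")
  structure(p, class = "behavior_params")
}

# lognormal draws parameterised by natural-scale mean and sd
.rlnorm_msd <- function(n, m, s) {
  sdlog <- sqrt(log(1 + (s / m)^2))
  meanlog <- log(m) - sdlog^2 / 2
  stats::rlnorm(n, meanlog, sdlog)
}

#' Generate one block of trials
#'
#' Produces the trial table for a complete 240-trial block (or a resized one,
#' see [design_params()]): condition labels, event timestamps and the
#' within-condition trial index for predictable-perturbation trials.  Trial
#' order is pseudo-random: in set 1 every consecutive (non-overlapping) group
#' of six trials carries three reaches per target side; set 2 shuffles a
#' balanced allocation of CW / CCW / unperturbed trials; whether the all-CW
#' or the all-CCW repeat set comes first is random.
#'
#' Event times satisfy `t_pad_hit < t_light_on < t_center_release <
#' t_target_hit < t_target_release`, with the light at least 300 ms after pad
#' hit and, on perturbed trials, `t_perturbation` exactly
#' `perturbation_latency` (70 ms) after central-pad release.
#'
#' @param seed Integer seed; if `NULL` the current RNG state is used.
#' @param design A [design_params()] object.
#' @param behavior A [behavior_params()] object.
#'
#' @return A data.frame with one row per trial: `trial_id`, `set_index`,
#'   `target_side`, `initial_orientation`, `final_orientation`,
#'   `perturbation` (`none`/`CW45`/`CCW45`), `schedule`
#'   (`fixed`/`random`/`repeat`), `condition`, `repeat_index` (1-based index
#'   within set and side for repeat trials, `NA` otherwise), the six event
#'   times in seconds, and `success`.
#' @export
#' @examples
#' tr <- generate_block(seed = 1)
#' table(tr$set_index)
generate_block <- function(seed = NULL, design = design_params(),
                           behavior = behavior_params()) {
  stopifnot(inherits(design, "design_params"),
            inherits(behavior, "behavior_params"))
  if (!is.null(seed)) set.seed(as.integer(seed))

  # --- set 1: fixed targets, balanced sides in every group of six ---
  n1 <- design$n_set1
  sides1 <- unlist(lapply(seq_len(n1 / 6L), function(i)
    sample(rep(c("left", "right"), 3L))))
  ors1 <- numeric(n1)
  for (sd_ in c("left", "right")) {
    sel <- which(sides1 == sd_)
    ors1[sel] <- sample(rep(design$orientations,
                            length.out = length(sel)))
  }
  set1 <- data.frame(set_index = 1L, target_side = sides1,
                     initial_orientation = ors1, perturbation = "none",
                     schedule = "fixed", stringsAsFactors = FALSE)

  # --- set 2: random perturbation of a 90-degree target ---
  per_side <- design$n_set2 / 2L
  cnt <- round(design$random_probs * per_side)
  conds <- rep(c("CW45", "CCW45", "none"), times = cnt)
  d2 <- data.frame(target_side = rep(c("left", "right"), each = per_side),
                   perturbation = c(conds, conds), stringsAsFactors = FALSE)
  d2 <- d2[sample.int(nrow(d2)), ]
  set2 <- data.frame(set_index = 2L, target_side = d2$target_side,
                     initial_orientation = 90, perturbation = d2$perturbation,
                     schedule = "random", stringsAsFactors = FALSE)

  # --- sets 3 and 4: repeated CW / CCW perturbation, order randomised ---
  mk_rep <- function(idx, pert) {
    data.frame(set_index = idx,
               target_side = sample(rep(c("left", "right"),
                                        design$n_repeat / 2L)),
               initial_orientation = 90, perturbation = pert,
               schedule = "repeat", stringsAsFactors = FALSE)
  }
  s3 <- mk_rep(3L, "CW45")
  s4 <- mk_rep(4L, "CCW45")
  reps <- if (sample.int(2L, 1L) == 1L) rbind(s3, s4) else rbind(s4, s3)

  tr <- rbind(set1, set2, reps)
  tr$trial_id <- seq_len(nrow(tr))
  tr$final_orientation <- tr$initial_orientation +
    ifelse(tr$perturbation == "CW45", 45,
           ifelse(tr$perturbation == "CCW45", -45, 0))
  tr$condition <- ifelse(tr$set_index == 1L, "unperturbed",
    ifelse(tr$set_index == 2L,
           paste0("random_", c(CW45 = "CW", CCW45 = "CCW",
                               none = "none")[tr$perturbation]),
           paste0("repeat_", c(CW45 = "CW", CCW45 = "CCW")[tr$perturbation])))

  # within-condition trial index for repeat trials (1..n per set and side)
  tr$repeat_index <- NA_integer_
  for (si in c(3L, 4L)) for (sd_ in c("left", "right")) {
    sel <- which(tr$set_index == si & tr$target_side == sd_)
    tr$repeat_index[sel] <- seq_along(sel)
  }

  n <- nrow(tr)
  perturbed <- tr$perturbation != "none"
  hold <- behavior$hold_min + stats::runif(n, 0, behavior$hold_jitter)
  rtc <- .rlnorm_msd(n, behavior$rtc_mean, behavior$rtc_sd)
  mt_mean <- ifelse(perturbed, behavior$mt_perturbed_mean,
                    behavior$mt_unperturbed_mean)
  mt_min <- ifelse(perturbed, behavior$perturbation_latency + 0.150, 0.120)
  mt <- pmax(stats::rnorm(n, mt_mean, behavior$mt_sd), mt_min)
  tht <- pmax(stats::rnorm(n, behavior$tht_mean, behavior$tht_sd), 0.100)

  tr$t_pad_hit <- 0
  tr$t_light_on <- hold
  tr$t_center_release <- hold + rtc
  tr$t_perturbation <- ifelse(perturbed,
                              tr$t_center_release +
                                behavior$perturbation_latency,
                              NA_real_)
  tr$t_target_hit <- tr$t_center_release + mt
  tr$t_target_release <- tr$t_target_hit + tht
  tr$success <- stats::runif(n) >= behavior$fail_prob

  rownames(tr) <- NULL
  tr[, c("trial_id", "set_index", "target_side", "initial_orientation",
         "final_orientation", "perturbation", "schedule", "condition",
         "repeat_index", "t_pad_hit", "t_light_on", "t_center_release",
         "t_perturbation", "t_target_hit", "t_target_release", "success")]
}

#' Construct ad-hoc trial tables for focused experiments
#'
#' Convenience constructor used by tests and recovery harnesses: `n` trials
#' of a single condition with event times drawn from the same behavioural
#' model as [generate_block()].  `condition` is one of `unperturbed`,
#' `random_CW`, `random_CCW`, `random_none`, `repeat_CW`, `repeat_CCW`.
#' For repeat conditions `repeat_index` runs 1..`n`.
#'
#' @param n Number of trials.
#' @param condition Condition label (see above).
#' @param target_side Target side for all trials.
#' @param orientation Initial target orientation in degrees.
#' @param behavior A [behavior_params()] object.
#' @return A trial data.frame with the same columns as [generate_block()].
#' @export
make_trials <- function(n, condition = "unperturbed", target_side = "right",
                        orientation = 90, behavior = behavior_params()) {
  pert <- switch(condition,
                 unperturbed = , random_none = "none",
                 random_CW = , repeat_CW = "CW45",
                 random_CCW = , repeat_CCW = "CCW45",
                 stop("unknown condition: ", condition))
  schedule <- switch(condition,
                     unperturbed = "fixed",
                     random_CW = , random_CCW = , random_none = "random",
                     repeat_CW = , repeat_CCW = "repeat")
  tr <- data.frame(trial_id = seq_len(n), set_index = NA_integer_,
                   target_side = target_side,
                   initial_orientation = orientation,
                   perturbation = pert, schedule = schedule,
                   condition = condition, stringsAsFactors = FALSE)
  tr$set_index <- switch(condition, unperturbed = 1L, repeat_CW = 3L,
                         repeat_CCW = 4L, 2L)
  tr$final_orientation <- tr$initial_orientation +
    ifelse(pert == "CW45", 45, ifelse(pert == "CCW45", -45, 0))
  tr$repeat_index <- if (schedule == "repeat") seq_len(n) else NA_integer_
  perturbed <- pert != "none"
  hold <- behavior$hold_min + stats::runif(n, 0, behavior$hold_jitter)
  rtc <- .rlnorm_msd(n, behavior$rtc_mean, behavior$rtc_sd)
  mt_mean <- if (perturbed) behavior$mt_perturbed_mean else
    behavior$mt_unperturbed_mean
  mt_min <- if (perturbed) behavior$perturbation_latency + 0.150 else 0.120
  mt <- pmax(stats::rnorm(n, mt_mean, behavior$mt_sd), mt_min)
  tht <- pmax(stats::rnorm(n, behavior$tht_mean, behavior$tht_sd), 0.100)
  tr$t_pad_hit <- 0
  tr$t_light_on <- hold
  tr$t_center_release <- hold + rtc
  tr$t_perturbation <- if (perturbed)
    tr$t_center_release + behavior$perturbation_latency else NA_real_
  tr$t_target_hit <- tr$t_center_release + mt
  tr$t_target_release <- tr$t_target_hit + tht
  tr$success <- TRUE
  tr[, c("trial_id", "set_index", "target_side", "initial_orientation",
         "final_orientation", "perturbation", "schedule", "condition",
         "repeat_index", "t_pad_hit", "t_light_on", "t_center_release",
         "t_perturbation", "t_target_hit", "t_target_release", "success")]
}
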