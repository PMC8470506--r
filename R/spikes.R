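#' Ground-truth firing parameters of a simulated neuron
#'
#' The conditional intensity of a unit is a sum of non-negative components,
#' clipped at zero:
#' \itemize{
#'   \item a constant baseline (`baseline_rate`, Hz);
#'   \item a movement transient: Gaussian bump of height `movement_gain`
#'     centred `movement_center` s after central-pad release with width
#'     `movement_sd` (identical across conditions);
#'   \item a corrective burst on perturbed trials: Gaussian bump of width
#'     `corrective_width` centred `corrective_peak_latency` after release.
#'     Its height is `corrective_gain_random` on random-schedule trials and
#'     `corrective_gain_repeat * exp(-(k - 1) / corrective_decay_constant)`
#'     on repeat-schedule trials (the burst fades as the perturbation is
#'     learned);
#'   \item an anticipatory ramp on repeat trials only, rising linearly from
#'     the cue light to perturbation onset and relaxing over 100 ms after
#'     it, with height `anticipatory_gain * (1 - exp(-k *
#'     anticipatory_learning_rate))` scaled by cosine tuning of the
#'     anticipated final orientation around `preferred_orientation`;
#'   \item cosine orientation tuning (`orientation_gain`) and a target-side
#'     term (`direction_gain` when the target is on `preferred_side`), both
#'     tonic from the cue light until target release.
#' }
#'
#' @param neuron_id Integer identifier.
#' @param class Free-text class label (see [class_mixture_preset()]).
#' @param baseline_rate Baseline rate, Hz.
#' @param movement_gain,movement_center,movement_sd Movement transient
#'   height (Hz), centre and width (s after release).
#' @param corrective_gain_random,corrective_gain_repeat Corrective burst
#'   heights (Hz) under random / repeat schedules.
#' @param corrective_peak_latency,corrective_width Burst centre and width
#'   (s after release).
#' @param corrective_decay_constant Trials over which the repeat burst fades.
#' @param anticipatory_gain Peak anticipatory rate (Hz).
#' @param anticipatory_learning_rate Per-trial learning rate of the ramp.
#' @param anticipatory_tuning_power Sharpness exponent of the anticipatory
#'   ramp's tuning to the anticipated final orientation (default: the
#'   unit's `tuning_power`).
#' @param preferred_orientation Preferred target orientation (degrees).
#' @param orientation_gain Orientation-tuning depth (Hz).
#' @param tuning_power Sharpness exponent of the orientation tuning curve:
#'   the half-cosine `0.5 * (1 + cos)` raised to this power.  1 (default)
#'   is classic broad cosine tuning; larger values narrow the curve, as
#'   observed in sharply tuned units.
#' @param direction_gain Additive rate when the target is on the preferred
#'   side (Hz).
#' @param preferred_side `"left"` or `"right"`.
#' @return An object of class `neuron_params`.
#' @export
neuron_params <- function(neuron_id = 1L, class = "custom",
                          baseline_rate = 8,
                          movement_gain = 20, movement_center = 0.135,
                          movement_sd = 0.090,
                          corrective_gain_random = 0,
                          corrective_gain_repeat = 0,
                          corrective_peak_latency = 0.250,
                          corrective_width = 0.060,
                          corrective_decay_constant = 5,
                          anticipatory_gain = 0,
                          anticipatory_learning_rate = 0.35,
                          anticipatory_tuning_power = NULL,
                          preferred_orientation = 90,
                          orientation_gain = 0,
                          tuning_power = 1,
                          direction_gain = 0,
                          preferred_side = "right") {
  p <- list(neuron_id = as.integer(neuron_id), class = class,
            baseline_rate = baseline_rate, movement_gain = movement_gain,
            movement_center = movement_center, movement_sd = movement_sd,
            corrective_gain_random = corrective_gain_random,
            corrective_gain_repeat = corrective_gain_repeat,
            corrective_peak_latency = corrective_peak_latency,
            corrective_width = corrective_width,
            corrective_decay_constant = corrective_decay_constant,
            anticipatory_gain = anticipatory_gain,
            anticipatory_learning_rate = anticipatory_learning_rate,
            anticipatory_tuning_power =
              if (is.null(anticipatory_tuning_power)) tuning_power
              else anticipatory_tuning_power,
            preferred_orientation = preferred_orientation,
            orientation_gain = orientation_gain,
            tuning_power = tuning_power,
            direction_gain = direction_gain,
            preferred_side = preferred_side)
  rates <- c(p$baseline_rate, p$movement_gain, p$corrective_gain_random,
             p$corrective_gain_repeat, p$anticipatory_gain,
             p$orientation_gain, p$direction_gain)
  if (any(rates < 0)) stop("rate parameters must be non-negative")
  if (p$corrective_decay_constant <= 0 || p$movement_sd <= 0 ||
      p$corrective_width <= 0)
    stop("widths and decay constants must be positive")
  if (p$tuning_power < 1)
    stop("tuning_power must be >= 1")
  structure(p, class = c("neuron_params", "list"))
}

#' Named single-neuron presets
#'
#' `"strong"` is the exemplar unit of the decoding analyses: a fully adapted
#' unit from the top of the performance distribution, with an enormous
#' corrective burst after unpredictable perturbations, a repeat-schedule
#' burst that fades within the first few trials, a marked anticipatory ramp
#' that saturates after one or two predictable trials, and sharp orientation
#' tuning preferring 135 degrees (so the three task orientations map onto
#' well-separated rate levels).  `"anticipatory_only"` modulates exclusively
#' through the repeat-trial anticipatory ramp (no corrective burst and no
#' orientation sensitivity), the unit used for the cross-test of
#' random-perturbation trials.  `"corrective_only"` bursts after random
#' perturbations only, and `"non_responsive"` fires at baseline throughout.
#'
#' @param name Preset name.
#' @param neuron_id Identifier to stamp on the returned parameters.
#' @return A [neuron_params()] object.
#' @export
neuron_preset <- function(name = c("strong", "anticipatory_only",
                                   "corrective_only", "non_responsive"),
                          neuron_id = 1L) {
  switch(match.arg(name),
    strong = neuron_params(neuron_id, class = "corrective_anticipatory",
                           baseline_rate = 5,
                           corrective_gain_random = 250,
                           corrective_gain_repeat = 30,
                           corrective_decay_constant = 1,
                           anticipatory_gain = 80,
                           anticipatory_learning_rate = 3,
                           orientation_gain = 120,
                           preferred_orientation = 135,
                           tuning_power = 4),
    anticipatory_only = neuron_params(neuron_id, class = "anticipatory_only",
                                      anticipatory_gain = 80,
                                      anticipatory_learning_rate = 3,
                                      preferred_orientation = 45,
                                      anticipatory_tuning_power = 1),
    corrective_only = neuron_params(neuron_id, class = "corrective_only",
                                    corrective_gain_random = 60),
    non_responsive = neuron_params(neuron_id, class = "non_responsive",
                                   movement_gain = 0))
}

# per-trial context vectors used by the vectorised intensity
.trial_context <- function(trials) {
  list(rel = trials$t_center_release, light = trials$t_light_on,
       pert = trials$t_perturbation, hit = trials$t_target_hit,
       initial = trials$initial_orientation,
       trel = trials$t_target_release,
       final = trials$final_orientation, side = trials$target_side,
       schedule = trials$schedule,
       perturbed = trials$perturbation != "none",
       k = ifelse(is.na(trials$repeat_index), 1, trials$repeat_index))
}

.cos_tuning <- function(theta, preferred, power = 1) {
  (0.5 * (1 + cospi((theta - preferred) / 180)))^power
}

# intensity for candidate times `t`; all ctx entries are vectors of length(t)
.intensity_vec <- function(t, ctx, p) {
  lam <- rep(p$baseline_rate, length(t))
  if (p$movement_gain > 0)
    lam <- lam + p$movement_gain *
      exp(-((t - (ctx$rel + p$movement_center))^2) / (2 * p$movement_sd^2))
  gc <- ifelse(ctx$perturbed & ctx$schedule == "random",
               p$corrective_gain_random,
               ifelse(ctx$perturbed & ctx$schedule == "repeat",
                      p$corrective_gain_repeat *
                        exp(-(ctx$k - 1) / p$corrective_decay_constant), 0))
  if (any(gc > 0))
    lam <- lam + gc *
      exp(-((t - (ctx$rel + p$corrective_peak_latency))^2) /
            (2 * p$corrective_width^2))
  if (p$anticipatory_gain > 0) {
    amp <- ifelse(ctx$schedule == "repeat" & ctx$perturbed,
                  p$anticipatory_gain *
                    (1 - exp(-ctx$k * p$anticipatory_learning_rate)) *
                    .cos_tuning(ctx$final, p$preferred_orientation,
                                p$anticipatory_tuning_power), 0)
    pert <- ifelse(is.na(ctx$pert), Inf, ctx$pert)
    ramp <- ifelse(t <= pert,
                   pmin(pmax((t - ctx$light) / (pert - ctx$light), 0), 1),
                   pmax(1 - (t - pert) / 0.100, 0))
    lam <- lam + amp * ramp
  }
  # tonic task components stay on through the grasp hold: a unit whose
  # activity merely tracked movement duration would otherwise read as
  # perturbation-responsive on duration-matched windows
  active <- t >= ctx$light & t < ctx$trel
  if (p$orientation_gain > 0) {
    # tuning follows the target orientation the unit is working towards: the
    # displayed (initial) one before perturbation onset and the final one
    # after it -- except that on predictable (repeat) trials the
    # pre-perturbation tuning shifts towards the *anticipated* final
    # orientation in proportion to learning (planning to a target
    # orientation not yet shown)
    tune_i <- .cos_tuning(ctx$initial, p$preferred_orientation,
                          p$tuning_power)
    tune_f <- .cos_tuning(ctx$final, p$preferred_orientation,
                          p$tuning_power)
    learn <- ifelse(ctx$schedule == "repeat" & ctx$perturbed,
                    1 - exp(-ctx$k * p$anticipatory_learning_rate), 0)
    tune_pre <- (1 - learn) * tune_i + learn * tune_f
    post <- ctx$perturbed & !is.na(ctx$pert) & t >= ctx$pert
    lam <- lam + p$orientation_gain *
      ifelse(post, tune_f, tune_pre) * active
  }
  if (p$direction_gain > 0)
    lam <- lam + p$direction_gain * (ctx$side == p$preferred_side) * active
  pmax(lam, 0)
}

# conservative per-trial upper bound on the intensity (sum of term maxima)
.lambda_max <- function(trials, p) {
  ctx <- .trial_context(trials)
  gc <- ifelse(ctx$perturbed & ctx$schedule == "random",
               p$corrective_gain_random,
               ifelse(ctx$perturbed & ctx$schedule == "repeat",
                      p$corrective_gain_repeat *
                        exp(-(ctx$k - 1) / p$corrective_decay_constant), 0))
  amp <- ifelse(ctx$schedule == "repeat" & ctx$perturbed,
                p$anticipatory_gain *
                  (1 - exp(-ctx$k * p$anticipatory_learning_rate)) *
                  .cos_tuning(ctx$final, p$preferred_orientation), 0)
  p$baseline_rate + p$movement_gain + gc + amp +
    p$orientation_gain *
      pmax(.cos_tuning(ctx$final, p$preferred_orientation),
           .cos_tuning(ctx$initial, p$preferred_orientation)) +
    p$direction_gain * (ctx$side == p$preferred_side)
}

#' Conditional firing intensity of a neuron on one trial
#'
#' Evaluates the ground-truth rate function lambda(t); exposed so tests can
#' locate rate peaks analytically instead of through simulated spikes.
#'
#' @param t Times (s from pad hit).
#' @param trial One-row trial data.frame.
#' @param neuron A [neuron_params()] object.
#' @param repeat_trial_index Within-condition index for repeat trials.
#' @return Intensity in Hz at each `t`.
#' @export
firing_intensity <- function(t, trial, neuron,
                             repeat_trial_index = trial$repeat_index) {
  stopifnot(nrow(trial) == 1L)
  trial$repeat_index <- repeat_trial_index
  ctx <- .trial_context(trial)
  ctx <- lapply(ctx, function(v) rep(v, length(t)))
  .intensity_vec(t, ctx, neuron)
}

#' Simulate a spike train for one trial
#'
#' Draws spike times on `[0, t_target_release]` from an inhomogeneous Poisson
#' process with the neuron's intensity, by thinning (rejection from a
#' homogeneous process at an upper bound of the rate).  Uses the current RNG
#' state.
#'
#' @inheritParams firing_intensity
#' @return Sorted numeric vector of spike times (s from pad hit).
#' @export
simulate_spikes <- function(neuron, trial,
                            repeat_trial_index = trial$repeat_index) {
  stopifnot(nrow(trial) == 1L)
  trial$repeat_index <- repeat_trial_index
  df <- simulate_neuron_session(neuron, trial)
  df$t_spike
}

#' Simulate spike trains for a neuron over a whole trial table
#'
#' Vectorised thinning across all trials at once; the workhorse behind the
#' population pipeline.
#'
#' @param neuron A [neuron_params()] object.
#' @param trials Trial data.frame.
#' @return A data.frame (`neuron_id`, `trial_id`, `t_spike`) sorted by trial
#'   and time.  Trials without spikes contribute no rows.
#' @export
simulate_neuron_session <- function(neuron, trials) {
  Tend <- trials$t_target_release
  lmax <- .lambda_max(trials, neuron)
  ncand <- stats::rpois(nrow(trials), lmax * Tend)
  idx <- rep(seq_len(nrow(trials)), ncand)
  if (length(idx) == 0L)
    return(data.frame(neuron_id = integer(), trial_id = integer(),
                      t_spike = numeric()))
  tt <- stats::runif(length(idx), 0, Tend[idx])
  ctx <- .trial_context(trials)
  ctx_e <- lapply(ctx, function(v) v[idx])
  lam <- .intensity_vec(tt, ctx_e, neuron)
  keep <- stats::runif(length(idx)) < lam / lmax[idx]
  idx <- idx[keep]; tt <- tt[keep]
  o <- order(idx, tt)
  data.frame(neuron_id = neuron$neuron_id,
             trial_id = trials$trial_id[idx[o]],
             t_spike = tt[o])
}

#' Class-mixture presets for population generation
#'
#' `"paper_mixture"` allocates a population of task-related units into four
#' response classes in the proportions 293 : 315 : 235 : 42 (out of 885):
#' units bursting only after unpredictable perturbations
#' (`corrective_only`), units bursting under both schedules (`mixed`), units
#' with a fading repeat burst plus an anticipatory ramp
#' (`corrective_anticipatory`), and direction-tuned movement units with no
#' perturbation sensitivity (`direction_tuned` -- a unit tuned to the
#' displayed target orientation would necessarily respond when the
#' orientation jumps, so it could not sit in the unperturbed-only group).
#'
#' @param name Preset name (currently only `"paper_mixture"`).
#' @return Named numeric vector of proportions summing to 1.
#' @export
class_mixture_preset <- function(name = "paper_mixture") {
  switch(name,
    paper_mixture = c(corrective_only = 293, mixed = 315,
                      corrective_anticipatory = 235,
                      direction_tuned = 42) / 885,
    stop("unknown mixture preset: ", name))
}

# gains by class; baselines vary across units for realism
.neuron_from_class <- function(id, class, baseline) {
  switch(class,
    non_responsive = neuron_params(id, class, baseline_rate = baseline,
                                   movement_gain = 0),
    corrective_only = neuron_params(id, class, baseline_rate = baseline,
                                    corrective_gain_random = 60),
    mixed = neuron_params(id, class, baseline_rate = baseline,
                          corrective_gain_random = 60,
                          corrective_gain_repeat = 40),
    corrective_anticipatory = neuron_params(
      id, class, baseline_rate = baseline,
      corrective_gain_repeat = 40, anticipatory_gain = 25),
    orientation_tuned = neuron_params(id, class, baseline_rate = baseline,
                                      orientation_gain = 20),
    direction_tuned = neuron_params(id, class, baseline_rate = baseline,
                                    direction_gain = 20),
    stop("unknown neuron class: ", class))
}

#' Generate a ground-truth population (optionally with spikes)
#'
#' Allocates `n_neurons` across response classes by largest-remainder
#' rounding of `class_mixture` (deterministic), draws per-unit nuisance
#' parameters (baseline rate uniform on 5--12 Hz, preferred orientation from
#' {45, 90, 135}, preferred side at random), and, when a trial table is
#' supplied, simulates every unit's spikes.
#'
#' @param n_neurons Population size.
#' @param class_mixture Named proportions over the classes understood by the
#'   generator (see [class_mixture_preset()]); must sum to 1.
#' @param seed Integer seed (`NULL` to use the current RNG state).
#' @param trials Optional trial table; if given, spikes are returned too.
#' @return A list with `neurons` (ground-truth data.frame, one row per unit)
#'   and `spikes` (long data.frame, or `NULL` when `trials` is missing).
#' @export
generate_population <- function(n_neurons,
                                class_mixture =
                                  class_mixture_preset("paper_mixture"),
                                seed = NULL, trials = NULL) {
  if (abs(sum(class_mixture) - 1) > 1e-8 || any(class_mixture < 0))
    stop("configuration error: class_mixture proportions must sum to 1")
  if (!is.null(seed)) set.seed(as.integer(seed))
  raw <- class_mixture * n_neurons
  cnt <- floor(raw)
  rem <- n_neurons - sum(cnt)
  if (rem > 0) {
    o <- order(raw - cnt, decreasing = TRUE)
    cnt[o[seq_len(rem)]] <- cnt[o[seq_len(rem)]] + 1
  }
  classes <- rep(names(class_mixture), times = cnt)
  n <- length(classes)
  baseline <- stats::runif(n, 5, 12)
  pref_or <- sample(c(45, 90, 135), n, replace = TRUE)
  pref_side <- sample(c("left", "right"), n, replace = TRUE)
  units <- lapply(seq_len(n), function(i) {
    p <- .neuron_from_class(i, classes[i], baseline[i])
    p$preferred_orientation <- pref_or[i]
    p$preferred_side <- pref_side[i]
    p
  })
  neurons <- do.call(rbind, lapply(units, function(p)
    as.data.frame(unclass(p), stringsAsFactors = FALSE)))
  spikes <- NULL
  if (!is.null(trials))
    spikes <- do.call(rbind, lapply(units, simulate_neuron_session,
                                    trials = trials))
  list(neurons = neurons, spikes = spikes)
}

#' Rebuild a [neuron_params()] object from a ground-truth table row
#'
#' @param row One row of the `neurons` data.frame returned by
#'   [generate_population()].
#' @return A [neuron_params()] object.
#' @export
neuron_from_row <- function(row) {
  stopifnot(nrow(row) == 1L)
  do.call(neuron_params, as.list(row))
}
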