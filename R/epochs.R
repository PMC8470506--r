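#' Trial epoch windows
#'
#' Builds the per-trial analysis windows, in seconds from pad hit:
#' \describe{
#'   \item{CHT}{pre-cue baseline, `[t_pad_hit, t_light_on)` (the holding
#'     phase; see the methods vignette for why the baseline window must
#'     precede the cue).}
#'   \item{RTc}{cue reaction, `[t_light_on, t_center_release)`.}
#'   \item{MT}{movement, `[t_center_release, t_target_hit)`.}
#'   \item{PD}{perturbation delay, `[t_center_release, t_perturbation)`
#'     (perturbed trials only).}
#'   \item{PR}{perturbation response, `[t_perturbation, t_target_hit)`
#'     (perturbed trials only).}
#'   \item{THT}{target holding, `[t_target_hit, t_target_release)`.}
#' }
#' On perturbed trials PD and PR partition MT exactly.
#'
#' @param trials Trial data.frame (see [generate_block()]).
#' @return A data.frame keyed by `trial_id` with `<epoch>_on` / `<epoch>_off`
#'   columns; PD/PR columns are `NA` on unperturbed trials.
#' @export
compute_epochs <- function(trials) {
  perturbed <- trials$perturbation != "none"
  if (any(perturbed & is.na(trials$t_perturbation)))
    stop("data error: perturbed trial lacks t_perturbation")
  ord_ok <- trials$t_pad_hit < trials$t_light_on &
    trials$t_light_on < trials$t_center_release &
    trials$t_center_release < trials$t_target_hit &
    trials$t_target_hit < trials$t_target_release
  if (!all(ord_ok))
    stop("data error: event times out of order or zero-length window (trials ",
         paste(trials$trial_id[!ord_ok], collapse = ", "), ")")
  if (any(perturbed &
          (trials$t_perturbation <= trials$t_center_release |
             trials$t_perturbation >= trials$t_target_hit)))
    stop("data error: perturbation time outside the movement window")
  data.frame(trial_id = trials$trial_id,
             cht_on = trials$t_pad_hit, cht_off = trials$t_light_on,
             rtc_on = trials$t_light_on, rtc_off = trials$t_center_release,
             mt_on = trials$t_center_release, mt_off = trials$t_target_hit,
             pd_on = ifelse(perturbed, trials$t_center_release, NA_real_),
             pd_off = ifelse(perturbed, trials$t_perturbation, NA_real_),
             pr_on = ifelse(perturbed, trials$t_perturbation, NA_real_),
             pr_off = ifelse(perturbed, trials$t_target_hit, NA_real_),
             tht_on = trials$t_target_hit,
             tht_off = trials$t_target_release)
}

#' Per-trial epoch firing rates
#'
#' Spike counts over each epoch window divided by window length, with the
#' half-open convention `[start, end)`.  All trials appear in the output even
#' when no spike fell inside (rate 0); PD/PR rates are `NA` on unperturbed
#' trials.
#'
#' @param spikes Data.frame with `trial_id`, `t_spike` and optionally
#'   `neuron_id` (assumed a single unit when absent).
#' @param epochs Epoch table from [compute_epochs()].
#' @return Data.frame with `neuron_id`, `trial_id` and rate columns `cht`,
#'   `rtc`, `mt`, `pd`, `pr`, `tht` (Hz).
#' @export
epoch_firing_rates <- function(spikes, epochs) {
  if (is.null(spikes$neuron_id)) spikes$neuron_id <- 1L
  neurons <- sort(unique(spikes$neuron_id))
  if (length(neurons) == 0L) neurons <- 1L
  grid <- expand.grid(trial_id = epochs$trial_id, neuron_id = neurons,
                      KEEP.OUT.ATTRS = FALSE)
  key_grid <- paste(grid$neuron_id, grid$trial_id)
  out <- data.frame(neuron_id = grid$neuron_id, trial_id = grid$trial_id)
  m <- match(spikes$trial_id, epochs$trial_id)
  key_sp <- paste(spikes$neuron_id, spikes$trial_id)
  pos <- match(key_sp, key_grid)
  for (e in c("cht", "rtc", "mt", "pd", "pr", "tht")) {
    on <- epochs[[paste0(e, "_on")]][m]
    off <- epochs[[paste0(e, "_off")]][m]
    inside <- !is.na(on) & spikes$t_spike >= on & spikes$t_spike < off
    cnt <- numeric(nrow(grid))
    if (length(pos)) {
      agg <- rowsum(as.numeric(inside), pos, reorder = FALSE)
      cnt[as.integer(rownames(agg))] <- agg[, 1]
    }
    dur <- epochs[[paste0(e, "_off")]] - epochs[[paste0(e, "_on")]]
    dur_g <- dur[match(grid$trial_id, epochs$trial_id)]
    out[[e]] <- cnt / dur_g
  }
  out
}

#' Task-related unit detection (2-SD rule)
#'
#' A unit is task-related when the across-trial mean rate of the cue-reaction
#' (RTc), movement (MT) or target-holding (THT) epoch exceeds the baseline
#' (CHT) mean by more than two across-trial standard deviations of the CHT
#' rate.  Returns the per-epoch z-scores alongside the flag.  A degenerate
#' zero baseline SD is floored at `sd_floor` and flagged.
#'
#' @param rates Output of [epoch_firing_rates()] (one or more units).
#' @param min_trials Minimum trials with a valid CHT rate.
#' @param sd_floor Floor applied to a zero baseline SD.
#' @return Data.frame with `neuron_id`, `task_related`, `z_rtc`, `z_mt`,
#'   `z_tht`, `cht_mean`, `cht_sd`, `degenerate_baseline`.
#' @export
detect_task_related <- function(rates, min_trials = 10, sd_floor = 1e-8) {
  res <- lapply(split(rates, rates$neuron_id), function(r) {
    ok <- !is.na(r$cht)
    if (sum(ok) < min_trials)
      stop("need at least ", min_trials, " trials with valid baseline rates")
    m <- mean(r$cht[ok]); s <- stats::sd(r$cht[ok])
    degen <- !is.finite(s) || s <= 0
    s <- max(s, sd_floor, na.rm = TRUE)
    z <- vapply(c("rtc", "mt", "tht"),
                function(e) (mean(r[[e]], na.rm = TRUE) - m) / s, 0)
    data.frame(neuron_id = r$neuron_id[1],
               task_related = any(z > 2), z_rtc = z[["rtc"]],
               z_mt = z[["mt"]], z_tht = z[["tht"]],
               cht_mean = m, cht_sd = s, degenerate_baseline = degen)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

# pooled / Welch two-sample t-test with a guard for two degenerate samples
.rate_t_test <- function(x, y, alternative = "two.sided", var_equal = TRUE) {
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    p <- if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0
    return(list(p.value = p, statistic = NA_real_))
  }
  ht <- stats::t.test(x, y, alternative = alternative, var.equal = var_equal)
  list(p.value = ht$p.value, statistic = unname(ht$statistic))
}

#' Baseline stability filter
#'
#' Units whose baseline (CHT) firing rate differs between any two sets of the
#' block -- every pairwise two-sample t-test, uncorrected -- are excluded
#' from analysis.  Units with fewer than two sets of `min_trials` trials are
#' retained but flagged untestable.
#'
#' @param rates Output of [epoch_firing_rates()].
#' @param trials Trial table carrying `set_index`.
#' @param alpha Significance level of each pairwise test.
#' @param min_trials Minimum trials per set for a testable pair.
#' @param var_equal Pooled-variance t-test when `TRUE` (default).
#' @return Data.frame with `neuron_id`, `excluded_unstable_baseline`,
#'   `min_p_baseline`, `untestable`.
#' @export
baseline_stability_filter <- function(rates, trials, alpha = 0.05,
                                      min_trials = 5, var_equal = TRUE) {
  set_of <- trials$set_index[match(rates$trial_id, trials$trial_id)]
  rates$.set <- set_of
  res <- lapply(split(rates, rates$neuron_id), function(r) {
    grp <- split(r$cht[!is.na(r$cht)], r$.set[!is.na(r$cht)])
    grp <- grp[vapply(grp, length, 0L) >= min_trials]
    if (length(grp) < 2L)
      return(data.frame(neuron_id = r$neuron_id[1],
                        excluded_unstable_baseline = FALSE,
                        min_p_baseline = NA_real_, untestable = TRUE))
    pairs <- utils::combn(length(grp), 2)
    ps <- apply(pairs, 2, function(ij)
      .rate_t_test(grp[[ij[1]]], grp[[ij[2]]],
                   var_equal = var_equal)$p.value)
    data.frame(neuron_id = r$neuron_id[1],
               excluded_unstable_baseline = any(ps < alpha),
               min_p_baseline = min(ps), untestable = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

# spike rate over [release + offset, release + offset + duration) per trial
.window_rates <- function(spikes, trials, offset, duration) {
  on <- trials$t_center_release + offset
  off <- on + duration
  m <- match(spikes$trial_id, trials$trial_id)
  inside <- !is.na(m) & spikes$t_spike >= on[m] & spikes$t_spike < off[m]
  cnt <- numeric(nrow(trials))
  if (any(inside)) {
    agg <- rowsum(rep(1, sum(inside)), m[inside], reorder = FALSE)
    cnt[as.integer(rownames(agg))] <- agg[, 1]
  }
  cnt / duration
}

# unperturbed trials sharing the 90-degree start orientation
.control_trials <- function(trials) {
  trials[trials$perturbation == "none" & trials$initial_orientation == 90, ]
}

#' Perturbation-response test of one unit
#'
#' Two-sided two-sample t-test comparing firing rates during the
#' perturbation-response (PR) epoch of perturbed trials of one schedule with
#' rates of unperturbed 90-degree trials over a duration-matched window
#' starting 70 ms after release (same window in both groups, so movement
#' transients cancel under the null; see the vignette).
#'
#' @param spikes Single-unit spike data.frame (`trial_id`, `t_spike`).
#' @param trials Trial table.
#' @param schedule `"random"` or `"repeat"`.
#' @param alpha Significance level.
#' @param var_equal Pooled-variance test when `TRUE`.
#' @param min_trials Minimum trials per group.
#' @return List with `p.value`, `flag`, group sizes and mean rates.
#' @export
perturbation_response_test <- function(spikes, trials,
                                       schedule = c("random", "repeat"),
                                       alpha = 0.05, var_equal = TRUE,
                                       min_trials = 5) {
  schedule <- match.arg(schedule)
  pert <- trials[trials$schedule == schedule & trials$perturbation != "none", ]
  ctrl <- .control_trials(trials)
  if (nrow(pert) < min_trials || nrow(ctrl) < min_trials)
    stop("need at least ", min_trials, " trials in each group")
  pd <- mean(pert$t_perturbation - pert$t_center_release)
  dur <- mean(pert$t_target_hit - pert$t_perturbation)
  # perturbed group: the trial's own PR epoch
  m <- match(spikes$trial_id, pert$trial_id)
  inside <- !is.na(m) & spikes$t_spike >= pert$t_perturbation[m] &
    spikes$t_spike < pert$t_target_hit[m]
  cnt <- numeric(nrow(pert))
  if (any(inside)) {
    agg <- rowsum(rep(1, sum(inside)), m[inside], reorder = FALSE)
    cnt[as.integer(rownames(agg))] <- agg[, 1]
  }
  x <- cnt / (pert$t_target_hit - pert$t_perturbation)
  y <- .window_rates(spikes, ctrl, pd, dur)
  ht <- .rate_t_test(x, y, var_equal = var_equal)
  list(p.value = ht$p.value, flag = ht$p.value < alpha,
       n_perturbed = nrow(pert), n_control = nrow(ctrl),
       mean_perturbed = mean(x), mean_control = mean(y))
}

#' Anticipatory-activity test of one unit
#'
#' One-sided two-sample t-test (repeat > unperturbed) on firing rates in the
#' pre-perturbation window `[release, release + 70 ms)`, identical in both
#' groups.  Elevated pre-perturbation firing under the predictable schedule
#' is the signature of perturbation anticipation.
#'
#' @inheritParams perturbation_response_test
#' @return List with `p.value`, `flag`, group sizes and mean rates.
#' @export
anticipatory_test <- function(spikes, trials, alpha = 0.05, var_equal = TRUE,
                              min_trials = 5) {
  rep_tr <- trials[trials$schedule == "repeat", ]
  ctrl <- .control_trials(trials)
  if (nrow(rep_tr) < min_trials || nrow(ctrl) < min_trials)
    stop("need at least ", min_trials, " trials in each group")
  pd <- mean(rep_tr$t_perturbation - rep_tr$t_center_release)
  x <- .window_rates(spikes, rep_tr, 0, pd)
  y <- .window_rates(spikes, ctrl, 0, pd)
  ht <- .rate_t_test(x, y, alternative = "greater", var_equal = var_equal)
  list(p.value = ht$p.value, flag = ht$p.value < alpha,
       n_repeat = nrow(rep_tr), n_control = nrow(ctrl),
       mean_repeat = mean(x), mean_control = mean(y))
}

#' Two-way ANOVA on unperturbed epoch rates
#'
#' Fixed-effects two-way analysis of variance with interaction of movement
#' epoch rates on unperturbed (set 1) trials, factors movement direction
#' (target side, 2 levels) and target orientation (3 levels).  The standard
#' balanced design has 15 trials per cell; unbalanced input is accepted and
#' decomposed sequentially (Type I, direction before orientation).
#'
#' @param rates Single-unit rate table from [epoch_firing_rates()].
#' @param trials Trial table.
#' @param epoch Which epoch's rates to analyse (default `"mt"`).
#' @param alpha Significance level for the returned flags.
#' @return Data.frame with one row per effect (`direction`, `orientation`,
#'   `interaction`): `F`, `p`, `flag`.
#' @export
two_way_anova <- function(rates, trials, epoch = "mt", alpha = 0.05) {
  un <- trials[trials$set_index == 1L, ]
  r <- rates[rates$trial_id %in% un$trial_id, ]
  m <- match(r$trial_id, un$trial_id)
  d <- data.frame(rate = r[[epoch]],
                  direction = factor(un$target_side[m]),
                  orientation = factor(un$initial_orientation[m]))
  if (any(table(d$direction, d$orientation) == 0))
    stop("data error: empty design cell")
  fit <- stats::lm(rate ~ direction * orientation, data = d)
  av <- stats::anova(fit)
  eff <- c("direction", "orientation", "direction:orientation")
  out <- data.frame(effect = c("direction", "orientation", "interaction"),
                    F = av[eff, "F value"], p = av[eff, "Pr(>F)"])
  out$flag <- out$p < alpha
  rownames(out) <- NULL
  out
}

#' Classify a single unit
#'
#' Runs the full per-unit pipeline: epoch rates, the 2-SD task-related rule,
#' the baseline stability filter, perturbation-response tests under both
#' schedules, the anticipatory test, and the direction-by-orientation ANOVA,
#' then assigns the perturbation-correlation category (`random_only`,
#' `repeat_only`, `both`, `unperturbed_only`; `NA` for units that are not
#' task-related).
#'
#' @param spikes Single-unit spike data.frame.
#' @param trials Trial table.
#' @param alpha Significance level used throughout.
#' @param epochs Optional precomputed [compute_epochs()] table.
#' @param var_equal Pooled-variance t-tests when `TRUE`.
#' @return One-row data.frame of flags and p-values.
#' @export
classify_unit <- function(spikes, trials, alpha = 0.05, epochs = NULL,
                          var_equal = TRUE) {
  if (is.null(epochs)) epochs <- compute_epochs(trials)
  rates <- epoch_firing_rates(spikes, epochs)
  det <- detect_task_related(rates)
  stab <- baseline_stability_filter(rates, trials, alpha = alpha,
                                    var_equal = var_equal)
  pr_rand <- perturbation_response_test(spikes, trials, "random",
                                        alpha = alpha, var_equal = var_equal)
  pr_rep <- perturbation_response_test(spikes, trials, "repeat",
                                       alpha = alpha, var_equal = var_equal)
  ant <- anticipatory_test(spikes, trials, alpha = alpha,
                           var_equal = var_equal)
  av <- two_way_anova(rates, trials, alpha = alpha)
  category <- NA_character_
  if (det$task_related) {
    category <- if (pr_rand$flag && pr_rep$flag) "both"
    else if (pr_rand$flag) "random_only"
    else if (pr_rep$flag) "repeat_only"
    else "unperturbed_only"
  }
  nid <- if (!is.null(spikes$neuron_id) && nrow(spikes) > 0)
    spikes$neuron_id[1] else det$neuron_id
  data.frame(neuron_id = nid,
             task_related = det$task_related,
             excluded_unstable_baseline = stab$excluded_unstable_baseline,
             corrective_random = pr_rand$flag, p_random = pr_rand$p.value,
             corrective_repeat = pr_rep$flag, p_repeat = pr_rep$p.value,
             anticipatory = ant$flag, p_anticipatory = ant$p.value,
             direction_effect = av$flag[1], orientation_effect = av$flag[2],
             interaction_effect = av$flag[3],
             p_direction = av$p[1], p_orientation = av$p[2],
             p_interaction = av$p[3],
             category = category, stringsAsFactors = FALSE)
}

#' Classify a whole population
#'
#' Applies [classify_unit()] to every unit of a ground-truth table,
#' simulating each unit's spikes on the fly (memory-light streaming) unless a
#' precomputed spike table is supplied.  Uses the current RNG state when
#' simulating; seed the session for reproducibility.
#'
#' @param neurons Ground-truth data.frame from [generate_population()].
#' @param trials Trial table.
#' @param spikes Optional long spike table (`neuron_id`, `trial_id`,
#'   `t_spike`); simulated per unit when `NULL`.
#' @param alpha Significance level.
#' @return Data.frame with one row per unit (see [classify_unit()]).
#' @export
classify_population <- function(neurons, trials, spikes = NULL,
                                alpha = 0.05) {
  epochs <- compute_epochs(trials)
  rows <- lapply(seq_len(nrow(neurons)), function(i) {
    sp <- if (is.null(spikes)) {
      simulate_neuron_session(neuron_from_row(neurons[i, ]), trials)
    } else {
      spikes[spikes$neuron_id == neurons$neuron_id[i], ]
    }
    cl <- classify_unit(sp, trials, alpha = alpha, epochs = epochs)
    cl$neuron_id <- neurons$neuron_id[i]
    cl
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Population category fractions
#'
#' Fractions of task-related, baseline-stable units falling into each
#' perturbation-correlation category, plus the anticipatory and
#' corrective-under-random fractions used by the recovery harness.
#'
#' @param classification Output of [classify_population()].
#' @return List with `n_task_related`, `fractions` (named, summing to 1) and
#'   `anticipatory_fraction`, `corrective_random_fraction`.
#' @export
categorize_population <- function(classification) {
  keep <- classification$task_related &
    !classification$excluded_unstable_baseline
  cl <- classification[keep, ]
  lev <- c("random_only", "repeat_only", "both", "unperturbed_only")
  fr <- table(factor(cl$category, levels = lev)) / max(nrow(cl), 1L)
  list(n_task_related = nrow(cl),
       fractions = as.numeric(fr) |> stats::setNames(lev),
       anticipatory_fraction = mean(cl$anticipatory),
       corrective_random_fraction = mean(cl$corrective_random))
}
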