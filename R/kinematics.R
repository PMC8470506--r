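#' Unperturbed-trajectory reference band
#'
#' Pointwise mean and 95% band of the hand-orientation angle across
#' unperturbed 90-degree trials, on a common 10 ms grid aligned to
#' central-pad release.  The default band is a normal-range band
#' (mean +/- 1.96 sd), appropriate for judging whether a *single* trial
#' deviates; `type = "sem"` gives the narrower confidence band of the mean.
#'
#' @param traj Long trajectory data.frame (`trial_id`, `t`, `angle_deg`).
#' @param trials Trial table (used for alignment times and trial selection).
#' @param grid Time grid in seconds relative to release.
#' @param type `"normal"` (mean +/- z sd) or `"sem"` (mean +/- z sd/sqrt(n)).
#' @param level Coverage level of the band.
#' @param min_trials Minimum number of unperturbed trials required.
#' @param eps Floor on the band half-width (degrees).
#' @return An object of class `trajectory_band`: list with `time`, `mean`,
#'   `half_width`, `n_trials`, `type`.
#' @export
build_band <- function(traj, trials, grid = seq(-0.2, 0.6, by = 0.010),
                       type = c("normal", "sem"), level = 0.95,
                       min_trials = 10, eps = 1e-6) {
  type <- match.arg(type)
  ctrl <- trials[trials$perturbation == "none" &
                   trials$initial_orientation == 90 &
                   trials$trial_id %in% traj$trial_id, ]
  if (nrow(ctrl) < min_trials)
    stop("need at least ", min_trials, " unperturbed trials to build a band")
  mat <- vapply(seq_len(nrow(ctrl)), function(i) {
    tri <- traj[traj$trial_id == ctrl$trial_id[i], ]
    stats::approx(tri$t - ctrl$t_center_release[i], tri$angle_deg,
                  xout = grid, rule = 2)$y
  }, numeric(length(grid)))
  z <- stats::qnorm(1 - (1 - level) / 2)
  mu <- rowMeans(mat)
  sd_ <- apply(mat, 1, stats::sd)
  hw <- if (type == "normal") z * sd_ else z * sd_ / sqrt(ncol(mat))
  structure(list(time = grid, mean = mu, half_width = pmax(hw, eps),
                 n_trials = ncol(mat), type = type, level = level),
            class = "trajectory_band")
}

#' Estimate perturbation reaction times by band deviation
#'
#' For each perturbed trial, finds the first time at or after central-pad
#' release at which `k` consecutive samples lie outside the reference band on
#' the side of the new target orientation (the directional requirement stops
#' primary-movement variability on the far side from counting).  The
#' perturbation reaction time is that deviation time minus the perturbation
#' onset; it is negative when the correction starts before the perturbation
#' (anticipation).  Trials with no qualifying crossing before target hit are
#' returned with `detected = FALSE`.
#'
#' @param traj Long trajectory data.frame.
#' @param trials Trial table (perturbed trials are analysed).
#' @param band A [build_band()] object.
#' @param k Number of consecutive out-of-band samples required.
#' @return Data.frame with `trial_id`, `deviation_time` (s from release),
#'   `rtp` (s), `detected`.
#' @export
estimate_rtp <- function(traj, trials, band, k = 3) {
  stopifnot(inherits(band, "trajectory_band"), k >= 1)
  pert <- trials[trials$perturbation != "none", ]
  res <- lapply(seq_len(nrow(pert)), function(i) {
    tr <- pert[i, ]
    tri <- traj[traj$trial_id == tr$trial_id, ]
    rel <- tr$t_center_release
    ang <- stats::approx(tri$t - rel, tri$angle_deg, xout = band$time,
                         rule = 2)$y
    s <- sign(tr$final_orientation - tr$initial_orientation)
    outside <- s * (ang - band$mean) > band$half_width
    eligible <- band$time >= 0 & band$time <= (tr$t_target_hit - rel)
    dev_t <- NA_real_
    idx <- which(eligible)
    if (length(idx) >= k) {
      run <- 0L
      for (j in idx) {
        run <- if (outside[j]) run + 1L else 0L
        if (run == k) { dev_t <- band$time[j - k + 1L]; break }
      }
    }
    detected <- !is.na(dev_t)
    data.frame(trial_id = tr$trial_id, deviation_time = dev_t,
               rtp = if (detected) dev_t - (tr$t_perturbation - rel)
                     else NA_real_,
               detected = detected)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Adaptation series of perturbation reaction times
#'
#' Summarises RTp estimates the way the adaptation figures do: per repeat
#' condition (perturbation direction x target side), the mean RTp at each
#' within-condition trial index averaged over blocks; for the random
#' condition, the overall mean with a Student-t 95% confidence interval of
#' the mean.  A repeat-condition point whose mean RTp falls below the lower
#' random CI bound is flagged as evidence that the perturbation was
#' predicted.
#'
#' @param rtp_df Output of [estimate_rtp()].
#' @param trials Trial table.
#' @param level Confidence level for the random-condition CI.
#' @return List with `series` (data.frame: `condition`, `target_side`,
#'   `trial_index`, `mean_rtp`, `n`, `predicted`) and `random` (list:
#'   `mean`, `ci_low`, `ci_high`, `n`).
#' @export
rtp_adaptation_series <- function(rtp_df, trials, level = 0.95) {
  m <- match(rtp_df$trial_id, trials$trial_id)
  d <- cbind(rtp_df, trials[m, c("condition", "target_side", "schedule",
                                 "repeat_index")])
  rand <- d[d$schedule == "random" & d$detected, ]
  if (nrow(rand) < 2)
    stop("need at least 2 detected random-perturbation trials")
  mu <- mean(rand$rtp)
  se <- stats::sd(rand$rtp) / sqrt(nrow(rand))
  tq <- stats::qt(1 - (1 - level) / 2, df = nrow(rand) - 1)
  random <- list(mean = mu, ci_low = mu - tq * se, ci_high = mu + tq * se,
                 n = nrow(rand))
  rep_d <- d[d$schedule == "repeat" & d$detected, ]
  series <- NULL
  if (nrow(rep_d)) {
    agg <- stats::aggregate(rtp ~ condition + target_side + repeat_index,
                            data = rep_d, FUN = mean)
    cnt <- stats::aggregate(rtp ~ condition + target_side + repeat_index,
                            data = rep_d, FUN = length)
    series <- data.frame(condition = agg$condition,
                         target_side = agg$target_side,
                         trial_index = agg$repeat_index,
                         mean_rtp = agg$rtp, n = cnt$rtp)
    series <- series[order(series$condition, series$target_side,
                           series$trial_index), ]
    series$predicted <- series$mean_rtp < random$ci_low
    rownames(series) <- NULL
  }
  list(series = series, random = random)
}
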