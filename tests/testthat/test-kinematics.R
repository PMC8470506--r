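# shared session for band / RTp tests: unperturbed 90-degree trials for the
# reference band plus perturbed trials to detect on
make_session <- function(n_ctrl = 60, n_pert = 60, behavior = behavior_params(),
                         schedule = "random") {
  ctrl <- make_trials(n_ctrl, "random_none", behavior = behavior)
  pert <- rbind(
    make_trials(n_pert / 2, paste0(schedule, "_CW"), behavior = behavior),
    make_trials(n_pert / 2, paste0(schedule, "_CCW"), behavior = behavior))
  pert$trial_id <- n_ctrl + seq_len(nrow(pert))
  trials <- rbind(ctrl, pert)
  list(trials = trials,
       traj = simulate_block_trajectories(trials, behavior))
}

test_that("band construction: floor, closed form and coverage", {
  b0 <- behavior_params(trajectory_noise_sd = 0)
  s <- local({ set.seed(90); make_session(20, 2, b0) })
  band <- build_band(s$traj, s$trials)
  # identical noiseless trajectories: half-width collapses to the eps floor
  expect_true(all(band$half_width == 1e-6))
  expect_equal(band$n_trials, 20L)
  # Gaussian noise sd 2 deg: half-width ~ 1.96 * 2 = 3.92 deg inside
  b2 <- behavior_params(trajectory_noise_sd = 2)
  s2 <- local({ set.seed(91); make_session(150, 2, b2) })
  band2 <- build_band(s2$traj, s2$trials)
  interior <- band2$time > 0 & band2$time < 0.2
  expect_equal(mean(band2$half_width[interior]), 1.96 * 2, tolerance = 0.1)
  # sem band is sqrt(n) narrower
  band2s <- build_band(s2$traj, s2$trials, type = "sem")
  expect_equal(mean(band2s$half_width[interior]) * sqrt(band2s$n_trials),
               mean(band2$half_width[interior]), tolerance = 1e-6)
  # ~95% of held-out unperturbed samples fall inside the band
  set.seed(92)
  held <- make_trials(100, "random_none", behavior = b2)
  held$trial_id <- 9000 + seq_len(100)
  htraj <- simulate_block_trajectories(held, b2)
  inside <- vapply(seq_len(100), function(i) {
    tri <- htraj[htraj$trial_id == held$trial_id[i], ]
    ang <- approx(tri$t - held$t_center_release[i], tri$angle_deg,
                  xout = band2$time, rule = 2)$y
    mean(abs(ang - band2$mean) <= band2$half_width)
  }, 0)
  expect_gt(mean(inside), 0.90)
  expect_lt(mean(inside), 0.99)
  expect_error(build_band(s$traj[s$traj$trial_id < 6, ], s$trials),
               "at least")
})

test_that("deviation detection is exact on noiseless trajectories", {
  b0 <- behavior_params(trajectory_noise_sd = 0)
  s <- local({ set.seed(93); make_session(20, 40, b0) })
  band <- build_band(s$traj, s$trials)
  est <- estimate_rtp(s$traj, s$trials, band)
  expect_true(all(est$detected))
  # bias no larger than one sample period (10 ms)
  expect_true(all(est$rtp >= 0.100 - 1e-9))
  expect_true(all(est$rtp <= 0.100 + 0.010 + 1e-9))
  expect_equal(est$rtp, est$deviation_time -
                 (s$trials$t_perturbation[match(est$trial_id,
                                                s$trials$trial_id)] -
                    s$trials$t_center_release[match(est$trial_id,
                                                    s$trials$trial_id)]),
               tolerance = 1e-12)
})

test_that("a trajectory equal to the band mean is never detected", {
  b0 <- behavior_params(trajectory_noise_sd = 0)
  s <- local({ set.seed(94); make_session(20, 4, b0) })
  band <- build_band(s$traj, s$trials)
  flat <- s$trials[s$trials$perturbation != "none", ][1, ]
  tj <- data.frame(trial_id = flat$trial_id,
                   t = seq(0, flat$t_target_release, 0.01))
  tj$angle_deg <- approx(band$time, band$mean,
                         xout = tj$t - flat$t_center_release, rule = 2)$y
  est <- estimate_rtp(tj, flat, band)
  expect_false(est$detected)
  expect_true(is.na(est$rtp))
})

test_that("estimator is equivariant under joint time shifts", {
  b0 <- behavior_params(trajectory_noise_sd = 0)
  s <- local({ set.seed(95); make_session(15, 10, b0) })
  band <- build_band(s$traj, s$trials)
  est <- estimate_rtp(s$traj, s$trials, band)
  sh <- 0.75
  tr2 <- s$trials
  for (cc in c("t_pad_hit", "t_light_on", "t_center_release",
               "t_perturbation", "t_target_hit", "t_target_release"))
    tr2[[cc]] <- tr2[[cc]] + sh
  tj2 <- s$traj; tj2$t <- tj2$t + sh
  band2 <- build_band(tj2, tr2)
  est2 <- estimate_rtp(tj2, tr2, band2)
  expect_equal(est$rtp, est2$rtp, tolerance = 1e-9)
})

test_that("mean estimated RTp increases with the true corrective delay", {
  ms <- vapply(c(0.100, 0.150), function(d0) {
    b <- behavior_params(true_rtp_initial = d0)
    s <- local({ set.seed(96); make_session(60, 200, b) })
    band <- build_band(s$traj, s$trials)
    est <- estimate_rtp(s$traj, s$trials, band)
    mean(est$rtp[est$detected])
  }, 0)
  expect_gt(ms[2], ms[1] + 0.030)
})

test_that("late repeat trials recover near-zero reaction times", {
  b <- behavior_params()
  s <- local({ set.seed(97); make_session(60, 2, b) })
  band <- build_band(s$traj, s$trials)
  set.seed(97)
  rep_tr <- make_trials(30, "repeat_CW", behavior = b)
  rep_tr$trial_id <- 500 + seq_len(30)
  rtraj <- simulate_block_trajectories(rep_tr, b)
  est <- estimate_rtp(rtraj, rep_tr, band)
  early <- est$rtp[est$trial_id <= 505 & est$detected]
  late <- est$rtp[est$trial_id > 520 & est$detected]
  # adaptation: late delays are far below early ones and essentially zero
  # (the detector's ~15 ms lag cancels the -20 ms floor; see vignette)
  expect_lt(mean(late), mean(early) - 0.030)
  expect_lt(mean(late), 0.015)
})

test_that("adaptation series averages, CIs and prediction flags", {
  # slow decay so the ground-truth delay crosses the random CI mid-series:
  # true_rtp(1) = 96 ms (inside the CI), true_rtp(15) = 53 ms (far below)
  b <- behavior_params(rtp_decay_constant = 30)
  set.seed(98)
  ctrl <- make_trials(60, "random_none", behavior = b)
  rnd <- rbind(make_trials(40, "random_CW", behavior = b),
               make_trials(40, "random_CCW", behavior = b))
  rnd$trial_id <- 60 + seq_len(80)
  # six "blocks" of the same repeat condition, averaged per trial index
  reps <- do.call(rbind, lapply(1:6, function(bk) {
    x <- make_trials(15, "repeat_CW", behavior = b)
    x$trial_id <- 200 + 100 * bk + seq_len(15)
    x
  }))
  trials <- rbind(ctrl, rnd, reps)
  traj <- simulate_block_trajectories(trials, b)
  band <- build_band(traj, trials)
  est <- estimate_rtp(traj, trials, band)
  out <- rtp_adaptation_series(est, trials)
  expect_lt(out$random$ci_low, out$random$mean)
  expect_gt(out$random$ci_high, out$random$mean)
  # per-index means over the six blocks
  expect_true(all(out$series$n >= 5))
  expect_equal(nrow(out$series), 15L)
  rep_est <- est[est$trial_id > 200 & est$detected, ]
  k1 <- rep_est$rtp[trials$repeat_index[match(rep_est$trial_id,
                                              trials$trial_id)] == 1]
  expect_equal(out$series$mean_rtp[out$series$trial_index == 1], mean(k1))
  # flags: late trials predicted, first trial not
  expect_false(out$series$predicted[out$series$trial_index == 1])
  expect_true(all(out$series$predicted[out$series$trial_index >= 12]))
  # identical rtp values everywhere -> no flags
  est_flat <- est
  est_flat$rtp[] <- 0.1
  est_flat$detected <- TRUE
  est_flat$deviation_time[] <- 0.17
  out_flat <- rtp_adaptation_series(est_flat, trials)
  expect_false(any(out_flat$series$predicted))
})
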