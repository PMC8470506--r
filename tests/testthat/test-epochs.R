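test_that("epoch windows follow the event times and partition MT", {
  tr <- fixture_trial(release = 0.550, pert = 0.620, hit = 0.950,
                      condition = "random_CCW")
  ep <- compute_epochs(tr)
  expect_equal(ep$pd_off - ep$pd_on, 0.070)
  expect_equal(ep$pr_off - ep$pr_on, 0.330)
  expect_equal(ep$cht_on, 0); expect_equal(ep$cht_off, 0.40)
  expect_equal(ep$rtc_on, 0.40); expect_equal(ep$rtc_off, 0.550)
  # PD + PR = MT to float tolerance, on any generated block
  tr2 <- generate_block(seed = 3)
  ep2 <- compute_epochs(tr2)
  p <- !is.na(ep2$pd_on)
  expect_equal((ep2$pd_off - ep2$pd_on + ep2$pr_off - ep2$pr_on)[p],
               (ep2$mt_off - ep2$mt_on)[p], tolerance = 1e-12)
  expect_true(all(is.na(ep2$pd_on[!p])))
})

test_that("degenerate or inconsistent trials raise data errors", {
  bad <- fixture_trial()
  bad$t_target_hit <- bad$t_center_release     # zero-length MT
  expect_error(compute_epochs(bad), "data error")
  bad2 <- fixture_trial(condition = "random_CW", pert = NA)
  expect_error(compute_epochs(bad2), "lacks t_perturbation")
})

test_that("epoch rates: arithmetic, boundaries, empty trains", {
  tr <- fixture_trial(release = 0.55, hit = 0.80)   # 0.25 s MT
  ep <- compute_epochs(tr)
  sp <- fixture_spikes(c(0.56, 0.60, 0.65, 0.70, 0.75))
  r <- epoch_firing_rates(sp, ep)
  expect_equal(r$mt, 20)                            # 5 spikes / 0.25 s
  # spike exactly at the window end is not counted (half-open)
  r2 <- epoch_firing_rates(fixture_spikes(0.80), ep)
  expect_equal(r2$mt, 0)
  expect_equal(r2$tht, 1 / (1.25 - 0.80))
  # empty train: all rates zero, trial still present
  r3 <- epoch_firing_rates(fixture_spikes(numeric(0)), ep)
  expect_equal(nrow(r3), 1L)
  expect_true(all(r3[, c("cht", "rtc", "mt", "tht")] == 0))
  expect_true(is.na(r3$pd))
})

test_that("2-SD task-related rule applies exact arithmetic", {
  # 12 trials engineered to baseline mean 10, sd 2; MT mean 15 -> z = 2.5
  cht <- c(8, 12, 8, 12, 8, 12, 8, 12, 8, 12, 12, 8)
  mt <- rep(15, 12)
  rates <- data.frame(neuron_id = 1L, trial_id = 1:12, cht = cht,
                      rtc = rep(10, 12), mt = mt, pd = NA, pr = NA,
                      tht = rep(10, 12))
  d <- detect_task_related(rates)
  expect_true(d$task_related)
  expect_equal(d$z_mt, (15 - 10) / sd(cht))
  # all epochs equal to baseline: not task-related
  rates2 <- rates; rates2$mt <- rates2$cht; rates2$rtc <- rates2$cht
  rates2$tht <- rates2$cht
  expect_false(detect_task_related(rates2)$task_related)
  expect_error(detect_task_related(rates[1:5, ]), "at least")
})

test_that("t-tests and ANOVA agree with textbook formulas to 1e-10", {
  set.seed(41)
  for (i in 1:100) {
    x <- rnorm(5 + rpois(1, 10)); y <- rnorm(5 + rpois(1, 10), 0.3)
    ours <- perturbreach:::.rate_t_test(x, y)
    ora <- oracle_t_pooled(x, y)
    expect_equal(ours$p.value, ora$p.value, tolerance = 1e-10)
    ours1 <- perturbreach:::.rate_t_test(x, y, alternative = "greater")
    ora1 <- oracle_t_pooled(x, y, alternative = "greater")
    expect_equal(ours1$p.value, ora1$p.value, tolerance = 1e-10)
  }
  # balanced 2x3 tables against the explicit sum-of-squares decomposition
  trials <- generate_block(seed = 42)
  un <- trials[trials$set_index == 1L, ]
  for (i in 1:20) {
    rate <- rnorm(nrow(un), 10, 3) +
      2 * (un$initial_orientation == 45) + (un$target_side == "left")
    rates <- data.frame(neuron_id = 1L, trial_id = un$trial_id, cht = 0,
                        rtc = 0, mt = rate, pd = NA, pr = NA, tht = 0)
    av <- two_way_anova(rates, trials)
    ora <- oracle_anova2(rate, un$target_side, un$initial_orientation)
    expect_equal(av$F, ora$F, tolerance = 1e-10)
    expect_equal(av$p, ora$p, tolerance = 1e-10)
  }
  # identical rates in all cells: F ~ 0, p ~ 1
  rates0 <- data.frame(neuron_id = 1L, trial_id = un$trial_id, cht = 0,
                       rtc = 0, mt = rep(7, nrow(un)), pd = NA, pr = NA,
                       tht = 0)
  av0 <- suppressWarnings(two_way_anova(rates0, trials))
  expect_false(any(av0$flag %in% TRUE))
})

test_that("identical samples give p = 1 and no flag", {
  x <- rep(3, 10)
  expect_equal(perturbreach:::.rate_t_test(x, x)$p.value, 1)
  tr <- generate_block(seed = 50)
  # a silent neuron is flagged by nothing
  empty <- fixture_spikes(numeric(0))
  pr <- perturbation_response_test(empty, tr, "random")
  expect_equal(pr$p.value, 1)
  expect_false(pr$flag)
  ant <- anticipatory_test(empty, tr)
  expect_false(ant$flag)
})

test_that("baseline stability filter keeps stable units, drops shifted ones", {
  tr <- generate_block(seed = 51)
  # equalise the baseline window so a fixed spike count is a fixed rate
  tr$t_light_on <- 0.40
  tr$t_center_release <- pmax(tr$t_center_release, 0.45)
  tr$t_target_hit <- pmax(tr$t_target_hit, tr$t_center_release + 0.1)
  tr$t_target_release <- pmax(tr$t_target_release, tr$t_target_hit + 0.1)
  tr$t_perturbation <- ifelse(tr$perturbation != "none",
                              tr$t_center_release + 0.07, NA)
  ep <- compute_epochs(tr)
  # stable: same CHT rate everywhere -> every pairwise p = 1
  sp <- do.call(rbind, lapply(tr$trial_id, function(id) {
    fixture_spikes(c(0.05, 0.15, 0.25), trial_id = id)
  }))
  r <- epoch_firing_rates(sp, ep)
  st <- baseline_stability_filter(r, tr)
  expect_false(st$excluded_unstable_baseline)
  # set 3 baseline grossly shifted -> excluded
  r2 <- r
  r2$cht[tr$set_index[match(r2$trial_id, tr$trial_id)] == 3L] <- 40
  st2 <- baseline_stability_filter(r2, tr)
  expect_true(st2$excluded_unstable_baseline)
})

test_that("null exclusion rate matches a brute-force simulation oracle", {
  # equal Poisson baselines in all four sets; the oracle applies the
  # textbook pooled t-test to counts drawn directly from the same Poisson
  # law (independent of the thinning sampler and the filter implementation)
  tr <- generate_block(seed = 52)
  nu <- neuron_params(1L, baseline_rate = 10, movement_gain = 0)
  set.seed(52)
  excl <- replicate(300, {
    sp <- simulate_neuron_session(nu, tr)
    r <- epoch_firing_rates(sp, compute_epochs(tr))
    baseline_stability_filter(r, tr)$excluded_unstable_baseline
  })
  dur <- tr$t_light_on - tr$t_pad_hit
  sets <- split(dur, tr$set_index)
  set.seed(53)
  oracle <- replicate(1500, {
    g <- lapply(sets, function(d) rpois(length(d), 10 * d) / d)
    pairs <- combn(4, 2)
    any(apply(pairs, 2, function(ij)
      oracle_t_pooled(g[[ij[1]]], g[[ij[2]]])$p.value) < 0.05)
  })
  expect_lt(abs(mean(excl) - mean(oracle)), 0.06)
  # and the familywise rate of six uncorrected 5% tests is the right scale
  expect_lt(abs(mean(oracle) - (1 - 0.95^6)), 0.12)
})

test_that("perturbation-response and anticipatory tests have power and size", {
  tr <- generate_block(seed = 60)
  # power: strongly corrective unit flagged on (almost) every seed
  set.seed(61)
  flags <- replicate(20, {
    sp <- simulate_neuron_session(neuron_preset("corrective_only"), tr)
    perturbation_response_test(sp, tr, "random")$flag
  })
  expect_gte(mean(flags), 0.95)
  # power: anticipatory unit flagged on (almost) every seed
  set.seed(62)
  aflags <- replicate(20, {
    sp <- simulate_neuron_session(neuron_preset("anticipatory_only"), tr)
    anticipatory_test(sp, tr)$flag
  })
  expect_gte(mean(aflags), 0.95)
  # size: a non-responsive unit is flagged at ~ the nominal 5% level
  set.seed(63)
  nu_null <- neuron_params(1L, baseline_rate = 12)
  nulls <- replicate(300, {
    sp <- simulate_neuron_session(nu_null, tr)
    c(perturbation_response_test(sp, tr, "random")$flag,
      anticipatory_test(sp, tr)$flag)
  })
  expect_lt(abs(mean(nulls[1, ]) - 0.05), 0.04)
  expect_lt(abs(mean(nulls[2, ]) - 0.05), 0.04)
})

test_that("orientation-tuned units light up the orientation ANOVA effect", {
  tr <- generate_block(seed = 70)
  ep <- compute_epochs(tr)
  nu <- neuron_params(1L, baseline_rate = 8, orientation_gain = 20,
                      preferred_orientation = 45)
  set.seed(70)
  flags <- replicate(20, {
    sp <- simulate_neuron_session(nu, tr)
    av <- two_way_anova(epoch_firing_rates(sp, ep), tr)
    c(orientation = av$flag[2], direction = av$flag[1])
  })
  expect_gte(mean(flags["orientation", ]), 0.90)
  expect_lt(mean(flags["direction", ]), 0.30)
  # direction-tuned units light up the direction effect instead
  nud <- neuron_params(1L, baseline_rate = 8, direction_gain = 20,
                       preferred_side = "left")
  set.seed(71)
  dflags <- replicate(20, {
    sp <- simulate_neuron_session(nud, tr)
    av <- two_way_anova(epoch_firing_rates(sp, ep), tr)
    av$flag[1]
  })
  expect_gte(mean(dflags), 0.90)
})

test_that("classification is invariant to uniform time translation", {
  tr <- generate_block(seed = 80)
  set.seed(80)
  sp <- simulate_neuron_session(neuron_preset("strong"), tr)
  cl <- classify_unit(sp, tr)
  shift <- 5.0
  tr2 <- tr
  for (cc in c("t_pad_hit", "t_light_on", "t_center_release",
               "t_perturbation", "t_target_hit", "t_target_release"))
    tr2[[cc]] <- tr2[[cc]] + shift
  sp2 <- sp; sp2$t_spike <- sp2$t_spike + shift
  cl2 <- classify_unit(sp2, tr2)
  expect_equal(cl, cl2)
})

test_that("categories partition task-related units", {
  cl <- data.frame(neuron_id = 1:4, task_related = c(TRUE, TRUE, TRUE, FALSE),
                   excluded_unstable_baseline = FALSE,
                   corrective_random = c(TRUE, FALSE, TRUE, FALSE),
                   corrective_repeat = c(TRUE, FALSE, FALSE, FALSE),
                   anticipatory = c(TRUE, FALSE, FALSE, FALSE),
                   category = c("both", "unperturbed_only", "random_only",
                                NA))
  fr <- categorize_population(cl)
  expect_equal(fr$n_task_related, 3L)
  expect_equal(sum(fr$fractions), 1)
  expect_equal(unname(fr$fractions["both"]), 1 / 3)
})
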