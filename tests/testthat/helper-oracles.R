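# Textbook-formula oracles, kept independent of the implementation paths
# they check.

# pooled two-sample t-test from first principles
oracle_t_pooled <- function(x, y, alternative = "two.sided") {
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
  tt <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  df <- nx + ny - 2
  p <- switch(alternative,
              two.sided = 2 * pt(-abs(tt), df),
              greater = pt(tt, df, lower.tail = FALSE),
              less = pt(tt, df))
  list(statistic = tt, p.value = p)
}

# balanced two-way fixed-effects ANOVA with interaction, via explicit sums
# of squares
oracle_anova2 <- function(rate, a, b) {
  a <- factor(a); b <- factor(b)
  gm <- mean(rate)
  cell <- tapply(rate, list(a, b), mean)
  am <- tapply(rate, a, mean)
  bm <- tapply(rate, b, mean)
  n_cell <- table(a, b)
  stopifnot(length(unique(as.vector(n_cell))) == 1) # balanced only
  nc <- n_cell[1, 1]
  ss_a <- sum(table(a) * (am - gm)^2)
  ss_b <- sum(table(b) * (bm - gm)^2)
  ss_cell <- sum(nc * (cell - gm)^2)
  ss_ab <- ss_cell - ss_a - ss_b
  ss_err <- sum((rate - cell[cbind(a, b)])^2)
  df_a <- nlevels(a) - 1; df_b <- nlevels(b) - 1
  df_ab <- df_a * df_b
  df_err <- length(rate) - nlevels(a) * nlevels(b)
  ms_err <- ss_err / df_err
  F_ <- c(ss_a / df_a, ss_b / df_b, ss_ab / df_ab) / ms_err
  p <- pf(F_, c(df_a, df_b, df_ab), df_err, lower.tail = FALSE)
  data.frame(effect = c("a", "b", "ab"), F = F_, p = p)
}

# closed-form minimum-jerk position for oracle comparison
oracle_min_jerk <- function(t, t0, t1, x0, x1) {
  tau <- pmin(pmax((t - t0) / (t1 - t0), 0), 1)
  x0 + (x1 - x0) * (10 * tau^3 - 15 * tau^4 + 6 * tau^5)
}

# small deterministic spike/trial fixture builders -------------------------

# a single trial with hand-picked event times
fixture_trial <- function(light = 0.40, release = 0.65, pert = NA,
                          hit = 0.95, release_target = 1.25,
                          condition = "unperturbed", side = "right",
                          orientation = 90, trial_id = 1L) {
  pertn <- switch(condition, random_CW = , repeat_CW = "CW45",
                  random_CCW = , repeat_CCW = "CCW45", "none")
  schedule <- switch(condition, unperturbed = "fixed",
                     repeat_CW = , repeat_CCW = "repeat", "random")
  data.frame(trial_id = trial_id, set_index = 1L, target_side = side,
             initial_orientation = orientation,
             final_orientation = orientation +
               ifelse(pertn == "CW45", 45, ifelse(pertn == "CCW45", -45, 0)),
             perturbation = pertn, schedule = schedule,
             condition = condition,
             repeat_index = if (schedule == "repeat") 1L else NA_integer_,
             t_pad_hit = 0, t_light_on = light, t_center_release = release,
             t_perturbation = pert, t_target_hit = hit,
             t_target_release = release_target, success = TRUE,
             stringsAsFactors = FALSE)
}

fixture_spikes <- function(times, trial_id = 1L, neuron_id = 1L) {
  n <- length(times)
  data.frame(neuron_id = rep(neuron_id, length.out = n),
             trial_id = rep(trial_id, length.out = n), t_spike = times)
}
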