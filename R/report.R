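#' Pipeline run configuration
#'
#' A fully serialisable description of one analysis run; together with its
#' seed it reproduces a run exactly.
#'
#' @param seed Integer master seed.
#' @param n_neurons Population size.
#' @param preset Class-mixture preset name (see [class_mixture_preset()]).
#' @param alpha Significance level of all epoch tests.
#' @param band_type Trajectory band type (`"normal"` or `"sem"`).
#' @param k Deviation persistence (consecutive samples).
#' @param decode_side,decode_window,decode_bin,decode_hidden,decode_lr,decode_epochs
#'   Decoder settings for the example single-unit decode.
#' @param out_dir Output directory (`NULL` for in-memory only).
#' @return An object of class `run_config` (a named list).
#' @export
run_config <- function(seed = 1L, n_neurons = 60L, preset = "paper_mixture",
                       alpha = 0.05, band_type = "normal", k = 3L,
                       decode_side = "right",
                       decode_window = c(-0.300, 0.500),
                       decode_bin = 0.200, decode_hidden = 5L,
                       decode_lr = 0.05, decode_epochs = 1500L,
                       out_dir = NULL) {
  structure(list(seed = as.integer(seed), n_neurons = as.integer(n_neurons),
                 preset = preset, alpha = alpha, band_type = band_type,
                 k = as.integer(k), decode_side = decode_side,
                 decode_window = decode_window, decode_bin = decode_bin,
                 decode_hidden = as.integer(decode_hidden),
                 decode_lr = decode_lr,
                 decode_epochs = as.integer(decode_epochs),
                 out_dir = out_dir),
            class = "run_config")
}

#' Restore a run configuration from a plain list
#'
#' Inverse of JSON serialisation: validates the fields and restores the
#' class, so `run_config` objects round-trip through
#' `jsonlite::toJSON()`/`fromJSON()`.
#'
#' @param x A named list (e.g. parsed JSON).
#' @return A `run_config` object.
#' @export
as_run_config <- function(x) {
  do.call(run_config, x[setdiff(names(x), character(0))])
}

#' Write a simulated session as delimited text
#'
#' Writes `trials.tsv`, `spikes.tsv`, `traj.tsv` and `ground_truth.tsv`
#' (tab-separated, header row; times in seconds, angles in degrees) to a
#' directory.
#'
#' @param dir Output directory (created if needed).
#' @param trials,spikes,traj,neurons Session tables; `NULL` entries are
#'   skipped.
#' @return `dir`, invisibly.
#' @export
write_session <- function(dir, trials = NULL, spikes = NULL, traj = NULL,
                          neurons = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(x, f) utils::write.table(
    x, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(trials)) wt(trials, "trials.tsv")
  if (!is.null(spikes)) wt(spikes, "spikes.tsv")
  if (!is.null(traj)) wt(traj, "traj.tsv")
  if (!is.null(neurons)) wt(neurons, "ground_truth.tsv")
  invisible(dir)
}

#' Read a session written by [write_session()]
#'
#' @param dir Session directory.
#' @return List with `trials`, `spikes`, `traj`, `neurons` (missing files
#'   yield `NULL`).
#' @export
read_session <- function(dir) {
  rd <- function(f) {
    p <- file.path(dir, f)
    if (file.exists(p))
      utils::read.table(p, header = TRUE, sep = "\t",
                        stringsAsFactors = FALSE)
    else NULL
  }
  list(trials = rd("trials.tsv"), spikes = rd("spikes.tsv"),
       traj = rd("traj.tsv"), neurons = rd("ground_truth.tsv"))
}

#' Run the full analysis pipeline on a synthetic session
#'
#' Orchestrates simulate -> epochs -> kinematics -> psth -> decode for one
#' block: generates the block, trajectories and a ground-truth population;
#' classifies every unit; estimates perturbation reaction times and the
#' adaptation series; builds an example perievent histogram; decodes the
#' perturbation condition from one strongly modulated unit; and assembles a
#' summary (category fractions, RTp series, decode rate and cluster) together
#' with a ground-truth-versus-recovered comparison.  When `out_dir` is set,
#' all tables and a `summary.json` are written there.
#'
#' @param config A [run_config()] object.
#' @return List with `trials`, `neurons`, `classification`, `rtp`, `series`,
#'   `psth`, `decode`, `summary` (invisibly also written to disk when
#'   configured).
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  set.seed(config$seed)
  behavior <- behavior_params()
  trials <- generate_block(design = design_params(), behavior = behavior)
  traj <- simulate_block_trajectories(trials, behavior)
  pop <- generate_population(config$n_neurons,
                             class_mixture_preset(config$preset))
  classification <- classify_population(pop$neurons, trials,
                                        alpha = config$alpha)
  cat_frac <- categorize_population(classification)

  band <- build_band(traj, trials, type = config$band_type)
  rtp <- estimate_rtp(traj, trials, band, k = config$k)
  series <- rtp_adaptation_series(rtp, trials)

  # exemplar unit for the decode / psth stages: strong corrective +
  # anticipatory modulation, simulated on top of the population
  ex <- neuron_preset("strong", neuron_id = config$n_neurons + 1L)
  ex_sp <- simulate_neuron_session(ex, trials)
  al <- align_spikes(ex_sp, trials, "center_release")
  hist <- build_psth(al, window = c(-0.4, 0.6), bin = 0.020)
  dec <- decode_unit(ex_sp, trials, task = "condition",
                     side = config$decode_side,
                     window = config$decode_window, bin = config$decode_bin,
                     hidden = config$decode_hidden, lr = config$decode_lr,
                     epochs = config$decode_epochs)

  truth_frac <- table(factor(pop$neurons$class,
                             levels = c("corrective_only", "mixed",
                                        "corrective_anticipatory",
                                        "orientation_tuned",
                                        "direction_tuned",
                                        "non_responsive"))) /
    nrow(pop$neurons)
  summary <- list(
    seed = config$seed, n_neurons = config$n_neurons,
    n_task_related = cat_frac$n_task_related,
    category_fractions = as.list(cat_frac$fractions),
    anticipatory_fraction = cat_frac$anticipatory_fraction,
    corrective_random_fraction = cat_frac$corrective_random_fraction,
    truth_anticipatory_fraction =
      unname(truth_frac[["corrective_anticipatory"]]),
    truth_corrective_random_fraction =
      unname(truth_frac[["corrective_only"]] + truth_frac[["mixed"]]),
    rtp_random_mean_ms = 1000 * series$random$mean,
    rtp_random_ci_ms = 1000 * c(series$random$ci_low,
                                series$random$ci_high),
    n_rtp_detected = sum(rtp$detected),
    decode_rate = dec$result$rate,
    decode_cluster = as.character(dec$result$cluster))

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_session(config$out_dir, trials = trials, traj = traj,
                  neurons = pop$neurons)
    utils::write.table(classification,
                       file.path(config$out_dir, "classification.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(rtp, file.path(config$out_dir, "rtp.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(series$series))
      utils::write.table(series$series,
                         file.path(config$out_dir, "rtp_series.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(as.data.frame(hist),
                       file.path(config$out_dir, "psth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(list(trials = trials, neurons = pop$neurons,
                 classification = classification, rtp = rtp,
                 series = series, psth = hist, decode = dec,
                 summary = summary))
}
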