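#' Align spike times to a trial event
#'
#' Re-references spike times to a task event on each trial.  Trials on which
#' the event is undefined (e.g. alignment to the perturbation on unperturbed
#' trials) are excluded and counted.
#'
#' @param spikes Single-unit spike data.frame (`trial_id`, `t_spike`).
#' @param trials Trial table.
#' @param event One of `"center_release"`, `"light_on"`, `"perturbation"`,
#'   `"target_hit"`.
#' @return An object of class `aligned_spikes`: list with `spikes`
#'   (`trial_id`, `t_rel`), `trial_ids` (trials retained, including ones
#'   without spikes), `n_trials`, `n_excluded`, `event`.
#' @export
align_spikes <- function(spikes, trials,
                         event = c("center_release", "light_on",
                                   "perturbation", "target_hit")) {
  event <- match.arg(event)
  col <- c(center_release = "t_center_release", light_on = "t_light_on",
           perturbation = "t_perturbation", target_hit = "t_target_hit")[event]
  ev <- trials[[col]]
  keep <- !is.na(ev)
  n_excluded <- sum(!keep)
  if (n_excluded > 0)
    message(n_excluded, " trial(s) lack event '", event, "' and were excluded")
  kept <- trials[keep, ]
  m <- match(spikes$trial_id, kept$trial_id)
  sel <- !is.na(m)
  structure(list(spikes = data.frame(trial_id = spikes$trial_id[sel],
                                     t_rel = spikes$t_spike[sel] -
                                       ev[keep][m[sel]]),
                 trial_ids = kept$trial_id, n_trials = nrow(kept),
                 n_excluded = n_excluded, event = event),
            class = "aligned_spikes")
}

#' Perievent time histogram
#'
#' Trial-averaged firing rate in uniform bins around an alignment event.
#' Bin edges are placed at integer multiples of the bin width so that one
#' edge falls exactly at time zero, making peak-latency readouts
#' reproducible.  Rates are in Hz: `count / (bin * n_trials)`.  The histogram
#' conserves spikes: `sum(rate) * bin * n_trials` equals the number of
#' aligned spikes inside the window.
#'
#' @param aligned An [align_spikes()] object.
#' @param window Two-element window around the event (s); each bound must be
#'   an integer multiple of `bin`.
#' @param bin Bin width in seconds (default 20 ms).
#' @return An object of class `psth`: data.frame with `bin_left`,
#'   `bin_center`, `rate`, plus attributes `n_trials`, `bin`, `window`,
#'   `n_spikes`.
#' @export
build_psth <- function(aligned, window = c(-0.5, 1.0), bin = 0.020) {
  stopifnot(inherits(aligned, "aligned_spikes"), length(window) == 2L,
            window[1] < window[2], bin > 0)
  if (max(abs(window / bin - round(window / bin))) > 1e-8)
    stop("window bounds must be integer multiples of the bin width")
  edges <- seq(window[1], window[2], by = bin)
  t_rel <- aligned$spikes$t_rel
  inside <- t_rel >= window[1] & t_rel < window[2]
  cnt <- if (any(inside))
    tabulate(findInterval(t_rel[inside], edges), nbins = length(edges) - 1L)
  else rep(0L, length(edges) - 1L)
  out <- data.frame(bin_left = edges[-length(edges)],
                    bin_center = edges[-length(edges)] + bin / 2,
                    rate = cnt / (bin * aligned$n_trials))
  attr(out, "n_trials") <- aligned$n_trials
  attr(out, "bin") <- bin
  attr(out, "window") <- window
  attr(out, "n_spikes") <- sum(cnt)
  class(out) <- c("psth", "data.frame")
  out
}
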