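#' Binned-rate feature matrix for decoding
#'
#' One row per trial: spike counts in uniform bins of a window aligned to
#' central-pad release, divided by bin width (Hz).  A final partial bin is
#' retained and normalised by its actual width, so windows such as
#' `[-0.300, +0.070]` (everything up to perturbation onset) are usable.
#'
#' @param spikes Single-unit spike data.frame (`trial_id`, `t_spike`).
#' @param trials Trial table (all rows become feature rows).
#' @param window Two-element feature window relative to release (s).
#' @param bin Bin width (s).
#' @return List with `X` (matrix, trials x bins), `trial_id`.
#' @export
extract_features <- function(spikes, trials, window = c(-0.300, 0.500),
                             bin = 0.100) {
  stopifnot(length(window) == 2L, window[1] < window[2], bin > 0)
  edges <- seq(window[1], window[2], by = bin)
  if (edges[length(edges)] < window[2] - 1e-12)
    edges <- c(edges, window[2])
  widths <- diff(edges)
  nb <- length(widths)
  X <- matrix(0, nrow(trials), nb)
  m <- match(spikes$trial_id, trials$trial_id)
  t_rel <- spikes$t_spike - trials$t_center_release[m]
  sel <- !is.na(m) & t_rel >= window[1] & t_rel < window[2]
  if (any(sel)) {
    b <- findInterval(t_rel[sel], edges)
    ij <- cbind(m[sel], b)
    for (r in seq_len(sum(sel))) X[ij[r, 1], ij[r, 2]] <-
        X[ij[r, 1], ij[r, 2]] + 1
  }
  X <- sweep(X, 2, widths, "/")
  list(X = X, trial_id = trials$trial_id,
       window = window, bin = bin)
}

#' Trial class labels for the decoding tasks
#'
#' The condition task codes random perturbation trials -1, unperturbed
#' 90-degree trials (including the unperturbed trials interleaved in the
#' random set) 0, and repeat perturbation trials +1.  The direction task
#' codes repeat 45 CCW as -1, unperturbed 90-degree trials 0, and repeat 45
#' CW as +1.  Trials outside the task (e.g. set-1 reaches to 45/135 targets)
#' get `NA`.
#'
#' @param trials Trial table.
#' @param task `"condition"` or `"direction"`.
#' @return Numeric vector of -1 / 0 / +1 / NA labels.
#' @export
decode_labels <- function(trials, task = c("condition", "direction")) {
  task <- match.arg(task)
  unp <- trials$perturbation == "none" & trials$initial_orientation == 90
  if (task == "condition") {
    ifelse(trials$schedule == "random" & trials$perturbation != "none", -1,
           ifelse(unp, 0,
                  ifelse(trials$schedule == "repeat", 1, NA_real_)))
  } else {
    ifelse(trials$condition == "repeat_CCW", -1,
           ifelse(unp, 0,
                  ifelse(trials$condition == "repeat_CW", 1, NA_real_)))
  }
}

#' Stratified half split with a fixed-size test set
#'
#' Half of each class (rounded down) is assigned to training; `test_per_class`
#' trials per class are drawn from the remainder for testing, mirroring the
#' 18-trial (6 per class) test sets of the single-unit analyses.  Uses the
#' current RNG state.
#'
#' @param labels Vector of class labels (`NA` rows are ignored).
#' @param test_per_class Test trials per class.
#' @return List with integer index vectors `train` and `test`.
#' @export
split_train_test <- function(labels, test_per_class = 6) {
  idx_by_class <- split(which(!is.na(labels)), labels[!is.na(labels)])
  if (length(idx_by_class) < 2L)
    stop("need at least two classes to split")
  train <- integer(0); test <- integer(0)
  for (cl in idx_by_class) {
    n <- length(cl)
    n_train <- floor(n / 2)
    if (n_train < 1L || n - n_train < test_per_class)
      stop("class too small for the requested split")
    cl <- sample(cl)
    train <- c(train, cl[seq_len(n_train)])
    rest <- cl[-seq_len(n_train)]
    test <- c(test, rest[seq_len(test_per_class)])
  }
  list(train = sort(train), test = sort(test))
}

.bp_forward <- function(net, X) {
  H <- tanh(X %*% t(net$W1) + matrix(net$b1, nrow(X), length(net$b1),
                                     byrow = TRUE))
  list(H = H, out = drop(H %*% net$w2 + net$b2))
}

.bp_scale <- function(X, center, scale) {
  sweep(sweep(X, 2, center, "-"), 2, scale, "/")
}

#' Train the two-layer backpropagation decoder
#'
#' A classical two-layer network: `n` input nodes, a hyperbolic-tangent
#' sigmoid hidden layer, and one linear output node coding the perturbation
#' condition on a -1 / 0 / +1 scale.  Inputs are z-scored with
#' *training-set* statistics (zero-variance features are left unscaled).
#' Weights are trained by full-batch gradient descent on the training-set sum
#' squared error; the per-epoch loss trace is kept so monotone convergence
#' can be checked.
#'
#' @param X Feature matrix (trials x features), training rows only.
#' @param y Target labels in `{-1, 0, 1}`.
#' @param hidden Hidden-layer size.
#' @param lr Learning rate (on the mean-squared-error gradient, which shares
#'   its minimiser with the SSE).
#' @param epochs Gradient-descent epochs.
#' @param seed Optional integer seed for the weight initialisation.
#' @return An object of class `bp_network` (weights, scaling, loss trace).
#' @export
train_bp <- function(X, y, hidden = 10, lr = 0.05, epochs = 1500,
                     seed = NULL) {
  stopifnot(nrow(X) == length(y))
  if (length(unique(y)) < 2L)
    stop("a class is absent from the training set")
  if (!is.null(seed)) set.seed(as.integer(seed))
  center <- colMeans(X)
  scale_ <- apply(X, 2, stats::sd)
  scale_[!is.finite(scale_) | scale_ < 1e-8] <- 1
  Xs <- .bp_scale(X, center, scale_)
  n_in <- ncol(X)
  net <- list(W1 = matrix(stats::runif(hidden * n_in, -1, 1) /
                            sqrt(n_in), hidden, n_in),
              b1 = numeric(hidden),
              w2 = stats::runif(hidden, -1, 1) / sqrt(hidden),
              b2 = 0,
              center = center, scale = scale_, hidden = hidden)
  n <- nrow(Xs)
  loss <- numeric(epochs)
  for (e in seq_len(epochs)) {
    fw <- .bp_forward(net, Xs)
    err <- fw$out - y                      # d(MSE)/d(out) * n/2
    loss[e] <- sum(err^2)
    d_out <- 2 * err / n
    g_w2 <- drop(crossprod(fw$H, d_out))
    g_b2 <- sum(d_out)
    d_h <- (d_out %o% net$w2) * (1 - fw$H^2)
    g_W1 <- crossprod(d_h, Xs)
    g_b1 <- colSums(d_h)
    net$W1 <- net$W1 - lr * g_W1
    net$b1 <- net$b1 - lr * g_b1
    net$w2 <- net$w2 - lr * g_w2
    net$b2 <- net$b2 - lr * g_b2
  }
  net$loss <- loss
  class(net) <- "bp_network"
  net
}

#' Forward pass of a trained decoder
#'
#' @param object A `bp_network`.
#' @param newdata Feature matrix on the original (unscaled) scale.
#' @param ... Unused.
#' @return Numeric vector of raw network outputs.
#' @export
predict.bp_network <- function(object, newdata, ...) {
  Xs <- .bp_scale(newdata, object$center, object$scale)
  .bp_forward(object, Xs)$out
}

#' Train an ensemble of backpropagation decoders
#'
#' Trains `n_ensemble` independently initialised networks on the same
#' training data and averages their outputs at prediction time.  With a
#' handful of training trials per class a single network's raw output is
#' noisy; averaging over initialisations is the standard variance-reduction
#' remedy and leaves each member exactly the spec'd two-layer network.
#'
#' @inheritParams train_bp
#' @param n_ensemble Number of member networks.
#' @return An object of class `bp_ensemble` (list of `bp_network`s).
#' @export
train_bp_ensemble <- function(X, y, n_ensemble = 15, hidden = 5, lr = 0.05,
                              epochs = 1500, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  nets <- lapply(seq_len(n_ensemble), function(e)
    train_bp(X, y, hidden = hidden, lr = lr, epochs = epochs))
  structure(list(nets = nets), class = "bp_ensemble")
}

#' @rdname train_bp_ensemble
#' @param object A `bp_ensemble`.
#' @param newdata Feature matrix on the original (unscaled) scale.
#' @param ... Unused.
#' @export
predict.bp_ensemble <- function(object, newdata, ...) {
  rowMeans(vapply(object$nets, function(n) predict(n, newdata),
                  numeric(nrow(newdata))))
}

#' Threshold decision rule and correct prediction rate
#'
#' Raw outputs are mapped to class decisions with the 60% threshold rule:
#' outputs at or below -0.6 decide -1, at or above +0.6 decide +1, and
#' outputs within `[-zero_band, +zero_band]` decide 0.  Outputs in the dead
#' zones between `zero_band` and the threshold yield no decision and are
#' counted incorrect.  The correct prediction rate is the fraction of test
#' trials whose decision equals the true label.
#'
#' @param outputs Raw network outputs.
#' @param labels True labels in `{-1, 0, 1}`.
#' @param threshold Outer decision threshold (default 0.6).
#' @param zero_band Half-width of the zero-decision region (default 0.4).
#' @return List of class `decode_result`: `outputs`, `decisions` (`NA` = no
#'   decision), `correct`, `rate`, `cluster`.
#' @export
classify_trials <- function(outputs, labels, threshold = 0.6,
                            zero_band = 0.4) {
  stopifnot(length(outputs) == length(labels), zero_band < threshold)
  dec <- ifelse(outputs <= -threshold, -1,
                ifelse(outputs >= threshold, 1,
                       ifelse(abs(outputs) <= zero_band, 0, NA_real_)))
  correct <- !is.na(dec) & dec == labels
  rate <- mean(correct)
  structure(list(outputs = outputs, decisions = dec, correct = correct,
                 rate = rate, cluster = cluster_rates(rate)),
            class = "decode_result")
}

#' Cluster correct prediction rates
#'
#' Fixed-boundary grouping of per-unit correct prediction rates: low
#' `[0, 0.2]`, fair `(0.2, 0.5]`, high `(0.5, 1]` (boundaries belong to the
#' lower group).
#'
#' @param rates Numeric rates in `[0, 1]`.
#' @return Factor with levels `low`, `fair`, `high`.
#' @export
cluster_rates <- function(rates) {
  stopifnot(all(rates >= 0 & rates <= 1))
  cut(rates, breaks = c(-Inf, 0.2, 0.5, Inf),
      labels = c("low", "fair", "high"), right = TRUE)
}

#' Single-unit decoding run
#'
#' End-to-end per-unit decoding: restrict to one target side (left and right
#' targets are analysed separately), build binned-rate features, label trials
#' for the requested task, split stratified 50/50 with a 6-per-class test
#' set, train the network on the training half and score the held-out trials
#' with the threshold rule.
#'
#' @param spikes Single-unit spike data.frame.
#' @param trials Trial table.
#' @param task `"condition"` or `"direction"`.
#' @param side Target side analysed.
#' @param window,bin Feature window and bin (see [extract_features()]).
#' @param test_per_class Held-out trials per class.
#' @param hidden,lr,epochs Network hyper-parameters (see [train_bp()]).
#' @param n_ensemble Ensemble size (see [train_bp_ensemble()]); 1 trains a
#'   single network.
#' @param seed Optional seed covering split and initialisation.
#' @return List with the trained `net`, the `result` ([classify_trials()]),
#'   feature/label objects and the split.
#' @export
decode_unit <- function(spikes, trials, task = c("condition", "direction"),
                        side = "right", window = c(-0.300, 0.500),
                        bin = 0.200, test_per_class = 6, hidden = 5,
                        lr = 0.05, epochs = 1500, n_ensemble = 15,
                        seed = NULL) {
  task <- match.arg(task)
  if (!is.null(seed)) set.seed(as.integer(seed))
  tr <- trials[trials$target_side == side, ]
  fx <- extract_features(spikes, tr, window = window, bin = bin)
  y <- decode_labels(tr, task)
  sp <- split_train_test(y, test_per_class = test_per_class)
  net <- if (n_ensemble > 1) {
    train_bp_ensemble(fx$X[sp$train, , drop = FALSE], y[sp$train],
                      n_ensemble = n_ensemble, hidden = hidden, lr = lr,
                      epochs = epochs)
  } else {
    train_bp(fx$X[sp$train, , drop = FALSE], y[sp$train],
             hidden = hidden, lr = lr, epochs = epochs)
  }
  out <- predict(net, fx$X[sp$test, , drop = FALSE])
  list(net = net, result = classify_trials(out, y[sp$test]),
       features = fx, labels = y, split = sp, side = side, task = task)
}

#' Cross-test a direction-task network on random-perturbation trials
#'
#' Feeds the random-perturbation trials of the same side through a network
#' trained on the repeat-direction task and scores them -- labelled by their
#' actual perturbation direction -- with the same threshold rule.  For a unit
#' whose modulation exists only before the perturbation on predictable
#' trials, random trials are feature-identical to unperturbed ones, outputs
#' stay near zero and the correct rate is zero.
#'
#' @param fit A [decode_unit()] fit (direction task).
#' @param spikes,trials The same spike and trial data.
#' @return A [classify_trials()] result over random perturbed trials.
#' @export
cross_test_random <- function(fit, spikes, trials) {
  tr <- trials[trials$target_side == fit$side &
                 trials$schedule == "random" &
                 trials$perturbation != "none", ]
  if (nrow(tr) == 0L) stop("no random-perturbation trials on this side")
  fx <- extract_features(spikes, tr, window = fit$features$window,
                         bin = fit$features$bin)
  y <- ifelse(tr$perturbation == "CW45", 1, -1)
  out <- predict(fit$net, fx$X)
  classify_trials(out, y)
}
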