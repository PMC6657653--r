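#' Sparse logistic decoding of state reactivations
#'
#' One L1-regularized binomial logistic classifier is trained per state on a
#' single post-onset time slice of labeled epochs. Negative examples are the
#' other states' trials at the same slice plus "null" samples drawn from the
#' pre-onset (fixation-like) window; the null data let all classifiers
#' report low probabilities simultaneously on resting data. Applying a
#' decoder set to an unlabeled recording yields one reactivation-probability
#' time series per state (per-state independent binomials: rows need not sum
#' to one).
#'
#' @name decoding
NULL

new_reactivation_matrix <- function(values, rate) {
  stopifnot(is.matrix(values), all(is.finite(values)),
            all(values > 0), all(values < 1))
  structure(list(values = values, rate = rate), class = "reactivation_matrix")
}

#' @export
print.reactivation_matrix <- function(x, ...) {
  cat(sprintf("reactivation_matrix: %d samples x %d states @ %g Hz\n",
              nrow(x$values), ncol(x$values), x$rate))
  invisible(x)
}

slice_at <- function(ep, time_ms) {
  ti <- which.min(abs(ep$times - time_ms))
  if (abs(ep$times[ti] - time_ms) > 1000 / ep$rate)
    stop("time ", time_ms, " ms outside the epoch window")
  ep$trials[, , ti, drop = TRUE]
}

# Null (pre-onset) samples: random (trial, pre-onset time) picks.
null_slices <- function(ep, n, seed = NULL) {
  pre <- which(ep$times < 0)
  if (!length(pre)) stop("epochs contain no pre-onset window for null data")
  with_seed(seed, {
    tr <- sample.int(dim(ep$trials)[1], n, replace = TRUE)
    ti <- sample(pre, n, replace = TRUE)
    t(vapply(seq_len(n), function(k) ep$trials[tr[k], , ti[k]],
             numeric(dim(ep$trials)[2])))
  })
}

fit_one_state <- function(x, y, l1_penalty) {
  # fit along a short decreasing path ending at the target penalty (the
  # recommended way to reach a single lambda) and read coefficients there;
  # small-class warnings are routine at desk-scale fixture sizes
  fit <- withCallingHandlers(
    glmnet::glmnet(x, y, family = "binomial", alpha = 1,
                   lambda = l1_penalty * c(16, 8, 4, 2, 1),
                   standardize = FALSE),
    warning = function(w) {
      if (grepl("fewer than 8", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  co <- as.numeric(stats::coef(fit, s = l1_penalty))
  list(intercept = co[1L], weights = co[-1L])
}

#' Train one-vs-rest lasso logistic decoders
#'
#' @param ep an `epoch_set` with state labels.
#' @param null_data optional matrix (`n_null x n_channels`) of null
#'   negatives; if `NULL`, `null_per_state` samples per classifier are drawn
#'   from the pre-onset window of `ep`.
#' @param train_time_ms the single training slice, ms after onset.
#' @param l1_penalty lasso penalty (glmnet `lambda`); if `NULL`, chosen by
#'   [tune_penalty()] over its default grid via leave-one-run-out.
#' @param null_per_state number of null negatives per classifier (default:
#'   as many as one state's positives).
#' @param seed seed for null-sample draws.
#' @return A `decoder_set`: `weights` (`n_states x n_channels`),
#'   `intercepts`, `train_time_ms`, `l1_penalty`.
#' @export
train_decoders <- function(ep, null_data = NULL, train_time_ms = 200,
                           l1_penalty = NULL, null_per_state = NULL,
                           seed = NULL) {
  stopifnot(inherits(ep, "epoch_set"))
  ns <- ep$n_states
  if (length(unique(ep$labels)) < 2L) stop("need at least two states")
  if (is.null(l1_penalty))
    l1_penalty <- tune_penalty(ep, train_time_ms = train_time_ms, seed = seed)
  X <- slice_at(ep, train_time_ms)
  counts <- tabulate(ep$labels, ns)
  if (any(counts == 0)) stop("state(s) without positive examples: ",
                             paste(which(counts == 0), collapse = ", "))
  if (is.null(null_per_state)) null_per_state <- max(counts)
  if (is.null(null_data) && null_per_state > 0)
    null_data <- null_slices(ep, null_per_state, seed = seed)
  W <- matrix(0, ns, ncol(X))
  b <- numeric(ns)
  for (s in seq_len(ns)) {
    xs <- rbind(X, null_data)
    ys <- c(as.integer(ep$labels == s), integer(NROW(null_data)))
    f <- fit_one_state(xs, ys, l1_penalty)
    W[s, ] <- f$weights
    b[s] <- f$intercept
  }
  structure(list(weights = W, intercepts = b, train_time_ms = train_time_ms,
                 l1_penalty = l1_penalty, n_states = ns),
            class = "decoder_set")
}

#' @export
print.decoder_set <- function(x, ...) {
  cat(sprintf("decoder_set: %d states x %d channels, trained at %g ms, lambda = %g\n",
              nrow(x$weights), ncol(x$weights), x$train_time_ms, x$l1_penalty))
  invisible(x)
}

#' Choose the lasso penalty by leave-one-run-out cross-validation
#'
#' Fits the full decoder set on all runs but one at each grid value, scores
#' argmax accuracy on the held-out run, and returns the grid value with the
#' highest mean accuracy (ties: the larger penalty, i.e., the sparser model).
#'
#' @param ep an `epoch_set` with a `run` field.
#' @param grid candidate penalties.
#' @param train_time_ms training slice.
#' @param seed seed for null draws inside the fits.
#' @return the selected penalty (scalar).
#' @export
tune_penalty <- function(ep, grid = c(0.001, 0.003, 0.01, 0.03, 0.1),
                         train_time_ms = 200, seed = NULL) {
  stopifnot(inherits(ep, "epoch_set"), !is.null(ep$run))
  runs <- sort(unique(ep$run))
  X <- slice_at(ep, train_time_ms)
  acc <- matrix(NA_real_, length(grid), length(runs))
  for (gi in seq_along(grid)) {
    for (ri in seq_along(runs)) {
      tr <- ep$run != runs[ri]
      sub <- subset_epochs(ep, tr)
      d <- train_decoders(sub, train_time_ms = train_time_ms,
                          l1_penalty = grid[gi], seed = child_seed(seed, gi))
      pr <- plogis(sweep(X[!tr, , drop = FALSE] %*% t(d$weights), 2L,
                         d$intercepts, "+"))
      acc[gi, ri] <- mean(max.col(pr, ties.method = "first") == ep$labels[!tr])
    }
  }
  m <- rowMeans(acc)
  grid[max(which(m == max(m)))]
}

subset_epochs <- function(ep, keep) {
  out <- ep
  out$trials <- ep$trials[keep, , , drop = FALSE]
  out$labels <- ep$labels[keep]
  out$run <- ep$run[keep]
  if (!is.null(ep$stimulus)) out$stimulus <- ep$stimulus[keep]
  out
}

#' Cross-validated decoding accuracy over time
#'
#' Prediction is the argmax over the per-state probabilities. Two holdout
#' schemes are available: `"leave_one_trial"` (leave-one-out over trials, or
#' grouped `folds`-fold CV when `folds` is given) and `"leave_one_stimulus"`
#' (hold out every trial of one stimulus at a time; requires an `ep$stimulus`
#' field and at least two stimuli per label class, and is the scheme that
#' penalizes classifiers exploiting stimulus-unique rather than shared
#' class features).
#'
#' @param ep an `epoch_set`.
#' @param scheme holdout scheme.
#' @param times ms grid to evaluate (default: all epoch times).
#' @param l1_penalty lasso penalty (fixed; no inner tuning).
#' @param folds optional number of folds for `"leave_one_trial"`.
#' @param seed seed for fold assignment and null draws.
#' @return An `accuracy_curve` data frame with columns `time_ms` and
#'   `accuracy`; chance level `1/n_classes` is in `attr(, "chance")`.
#' @export
cross_validate <- function(ep, scheme = c("leave_one_trial", "leave_one_stimulus"),
                           times = NULL, l1_penalty = 0.01, folds = NULL,
                           seed = NULL) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(ep, "epoch_set"))
  if (is.null(times)) times <- ep$times
  ntr <- dim(ep$trials)[1]
  if (scheme == "leave_one_stimulus") {
    if (is.null(ep$stimulus)) stop("leave_one_stimulus needs an `ep$stimulus` field")
    per_class <- tapply(ep$stimulus, ep$labels, function(s) length(unique(s)))
    if (any(per_class < 2))
      stop("leave_one_stimulus requires >= 2 stimuli per label class")
    groups <- ep$stimulus
  } else if (!is.null(folds)) {
    groups <- with_seed(seed, sample(rep(seq_len(folds), length.out = ntr)))
  } else {
    groups <- seq_len(ntr)   # leave-one-out
  }
  acc <- vapply(times, function(tm) {
    X <- slice_at(ep, tm)
    hits <- logical(ntr)
    for (g in unique(groups)) {
      te <- groups == g
      d <- train_decoders(subset_epochs(ep, !te), train_time_ms = tm,
                          l1_penalty = l1_penalty, seed = child_seed(seed, g))
      pr <- plogis(sweep(X[te, , drop = FALSE] %*% t(d$weights), 2L,
                         d$intercepts, "+"))
      hits[te] <- max.col(pr, ties.method = "first") == ep$labels[te]
    }
    mean(hits)
  }, numeric(1))
  out <- data.frame(time_ms = times, accuracy = acc)
  class(out) <- c("accuracy_curve", "data.frame")
  attr(out, "chance") <- 1 / length(unique(ep$labels))
  out
}

#' Apply trained decoders to a recording
#'
#' @param d a `decoder_set`.
#' @param rec a `sensor_recording` with matching channel count.
#' @return a `reactivation_matrix` (`n_samples x n_states` probabilities).
#' @export
apply_decoders <- function(d, rec) {
  stopifnot(inherits(d, "decoder_set"), inherits(rec, "sensor_recording"))
  if (ncol(d$weights) != nrow(rec$data))
    stop("channel mismatch: decoders have ", ncol(d$weights),
         " channels, recording has ", nrow(rec$data))
  eta <- sweep(t(rec$data) %*% t(d$weights), 2L, d$intercepts, "+")
  vals <- plogis(eta)
  # keep probabilities strictly inside (0,1) for downstream regressions
  eps <- 1e-12
  vals[vals <= eps] <- eps
  vals[vals >= 1 - eps] <- 1 - eps
  new_reactivation_matrix(vals, rec$rate)
}

#' Pearson correlation between decoder weight maps
#'
#' @param d a `decoder_set` with at least two decoders.
#' @return the `n_states x n_states` correlation matrix of the weight
#'   vectors (unit diagonal).
#' @export
decoder_spatial_correlation <- function(d) {
  stopifnot(inherits(d, "decoder_set"), nrow(d$weights) >= 2L)
  C <- stats::cor(t(d$weights))
  diag(C) <- 1
  C
}

#' Per-sensor contribution to decoding accuracy
#'
#' Repeats cross-validated decoding on random sensor subsets and scores each
#' sensor by the mean accuracy of the subsets it participated in. Sensors
#' never sampled get `NA`.
#'
#' @param ep an `epoch_set`.
#' @param n_iter number of random subsets (default 2000).
#' @param subset_size sensors per subset (default 50).
#' @param l1_penalty lasso penalty for the subset fits.
#' @param train_time_ms training/evaluation slice.
#' @param folds folds for the inner grouped CV.
#' @param seed integer seed.
#' @return numeric vector of per-sensor scores.
#' @export
sensor_contribution <- function(ep, n_iter = 2000L, subset_size = 50L,
                                l1_penalty = 0.01, train_time_ms = 200,
                                folds = 4L, seed = NULL) {
  stopifnot(inherits(ep, "epoch_set"))
  nch <- dim(ep$trials)[2]
  if (subset_size > nch) stop("subset_size exceeds channel count")
  sums <- numeric(nch)
  hits <- numeric(nch)
  with_seed(seed, {
    for (it in seq_len(n_iter)) {
      ch <- sample.int(nch, subset_size)
      sub <- ep
      sub$trials <- ep$trials[, ch, , drop = FALSE]
      a <- cross_validate(sub, "leave_one_trial", times = train_time_ms,
                          l1_penalty = l1_penalty, folds = folds)$accuracy
      sums[ch] <- sums[ch] + a
      hits[ch] <- hits[ch] + 1
    }
  })
  out <- sums / hits
  out[hits == 0] <- NA_real_
  out
}

#' Residualize factor decoders against stimulus decoders
#'
#' For each factor-code decoder (e.g., "position 2"), regresses its weight
#' vector on the weight vectors of the stimuli composing that factor class
#' and keeps the residual, removing spatial patterns explainable by the
#' constituent stimulus codes. Operates on weights, not on decoded time
#' series.
#'
#' @param factor_d a `decoder_set` of factor codes.
#' @param stim_d a `decoder_set` of stimulus codes on the same channels.
#' @param groups list: for each factor class, the indices of its constituent
#'   stimuli in `stim_d`.
#' @return `factor_d` with residualized weights.
#' @export
residualize_factor_decoders <- function(factor_d, stim_d, groups) {
  stopifnot(inherits(factor_d, "decoder_set"), inherits(stim_d, "decoder_set"),
            ncol(factor_d$weights) == ncol(stim_d$weights),
            length(groups) == nrow(factor_d$weights))
  for (k in seq_along(groups)) {
    Z <- t(stim_d$weights[groups[[k]], , drop = FALSE])  # channels x constituents
    w <- factor_d$weights[k, ]
    fit <- stats::lm.fit(cbind(1, Z), w)
    factor_d$weights[k, ] <- stats::residuals(fit)
  }
  factor_d
}
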