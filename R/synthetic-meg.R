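#' Synthetic MEG with known ground truth
#'
#' The generator emulates the validation simulation used for the replay
#' pipeline: a labeled functional localizer in which each trial carries one
#' state's spatial pattern at a fixed post-onset latency, and unlabeled
#' "resting" recordings into which four-state replay sequences are injected
#' at a fixed state-to-state lag (forward or reverse along a chosen
#' transition structure), on top of white sensor noise and a strong shared
#' 10 Hz (alpha) oscillation with a fixed random topography. All amplitudes
#' are in arbitrary femtotesla-scaled units.
#'
#' @name synthetic_meg
NULL

half_cosine_env <- function(times_s, center_s, width_s) {
  u <- (times_s - center_s) / width_s
  ifelse(abs(u) <= 0.5, 0.5 * (1 + cos(2 * pi * u)), 0)
}

#' Draw state-evoked spatial patterns
#'
#' Each state is assigned a unit-norm random topography over channels.
#' Patterns are redrawn (as a set) until all pairwise Pearson correlations
#' are below `max_abs_cor`; with `orthogonalize = TRUE` the random set is
#' QR-orthogonalized instead, giving exactly zero correlations up to
#' centering.
#'
#' @param n_channels number of sensors (must be >= `n_states`).
#' @param n_states number of decodable states.
#' @param seed integer seed.
#' @param evoked_latency_ms latency after stimulus onset at which the evoked
#'   pattern peaks in localizer trials (default 200 ms).
#' @param max_abs_cor pairwise correlation bound for the drawn patterns.
#' @param orthogonalize orthogonalize the patterns exactly.
#' @param max_redraws redraw attempts before giving up.
#' @return A `pattern_set`: `patterns` (`n_states x n_channels`, unit-norm
#'   rows), `evoked_latency_ms`, `seed`.
#' @export
make_state_patterns <- function(n_channels, n_states = 8L, seed = NULL,
                                evoked_latency_ms = 200, max_abs_cor = 0.3,
                                orthogonalize = FALSE, max_redraws = 100L) {
  stopifnot(n_channels >= n_states)
  pat <- with_seed(seed, {
    for (i in seq_len(max_redraws)) {
      M <- matrix(stats::rnorm(n_states * n_channels), n_states, n_channels)
      if (orthogonalize) M <- t(qr.Q(qr(t(M)))[, seq_len(n_states)])
      M <- M / sqrt(rowSums(M^2))
      C <- stats::cor(t(M))
      if (max(abs(C[upper.tri(C)])) < max_abs_cor) break
      M <- NULL
    }
    if (is.null(M))
      stop("could not draw patterns satisfying the correlation bound; ",
           "increase `max_abs_cor` or `n_channels`")
    M
  })
  structure(list(patterns = pat, evoked_latency_ms = evoked_latency_ms,
                 n_states = n_states, n_channels = n_channels,
                 seed = if (is.null(seed)) NA_integer_ else as.integer(seed)),
            class = "pattern_set")
}

new_recording <- function(data, rate) {
  stopifnot(is.matrix(data), all(is.finite(data)), rate > 0)
  structure(list(data = data, rate = rate), class = "sensor_recording")
}

#' @export
print.sensor_recording <- function(x, ...) {
  cat(sprintf("sensor_recording: %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$rate, ncol(x$data) / x$rate))
  invisible(x)
}

#' Simulate a labeled functional localizer
#'
#' Each trial contains its state's spatial pattern, injected at the pattern
#' set's evoked latency under a half-cosine temporal envelope, plus white
#' sensor noise. The epoch window includes a pre-onset segment of pure noise
#' that stands in for fixation-period "null" data used as decoder negatives.
#' Trials are split into `n_runs` runs with randomized state order.
#'
#' @param p a `pattern_set`.
#' @param n_trials_per_state trials per state (default 24).
#' @param noise_sd white-noise standard deviation per channel.
#' @param seed integer seed.
#' @param rate sampling rate in Hz.
#' @param window_ms epoch window relative to onset, `c(first, last)` ms.
#' @param envelope_width_ms full width of the half-cosine evoked envelope.
#' @param amplitude peak scaling of the (unit-norm) pattern.
#' @param n_runs number of runs the trials are split into.
#' @return An `epoch_set`: `trials` (`n_trials x n_channels x n_times`),
#'   `labels` (state per trial), `times` (ms), `run`, `rate`, plus the
#'   generating parameters.
#' @export
simulate_localizer <- function(p, n_trials_per_state = 24L, noise_sd = 0.2,
                               seed = NULL, rate = 100,
                               window_ms = c(-200, 500),
                               envelope_width_ms = 100, amplitude = 1,
                               n_runs = 2L) {
  stopifnot(inherits(p, "pattern_set"), noise_sd >= 0)
  times <- seq(window_ms[1], window_ms[2], by = 1000 / rate)
  ns <- p$n_states
  nt <- ns * n_trials_per_state
  env <- half_cosine_env(times / 1000, p$evoked_latency_ms / 1000,
                         envelope_width_ms / 1000)
  with_seed(seed, {
    labels <- sample(rep(seq_len(ns), n_trials_per_state))
    trials <- array(stats::rnorm(nt * p$n_channels * length(times), sd = noise_sd),
                    dim = c(nt, p$n_channels, length(times)))
    for (tr in seq_len(nt)) {
      add <- amplitude * outer(p$patterns[labels[tr], ], env)
      trials[tr, , ] <- trials[tr, , ] + add
    }
    run <- rep(seq_len(n_runs), length.out = nt)
    structure(list(trials = trials, labels = labels, times = times,
                   run = run, rate = rate, n_states = ns,
                   envelope_width_ms = envelope_width_ms,
                   evoked_latency_ms = p$evoked_latency_ms,
                   noise_sd = noise_sd, amplitude = amplitude),
              class = "epoch_set")
  })
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("epoch_set: %d trials x %d channels x %d times (%g..%g ms), %d states\n",
              dim(x$trials)[1], dim(x$trials)[2], dim(x$trials)[3],
              min(x$times), max(x$times), x$n_states))
  invisible(x)
}

# Uniform draw of `n_events` sorted onsets with spacing >= span + gap:
# lay down the minimum spacings and distribute the remaining slack as order
# statistics of a uniform sample (exact uniform over the admissible set).
place_event_onsets <- function(n_events, n_samples, event_span, min_gap) {
  spacing <- event_span + min_gap
  slack <- (n_samples - event_span) - (n_events - 1L) * spacing - 1L
  if (slack < 0)
    stop("could not place ", n_events, " non-overlapping events; ",
         "increase duration_s or reduce n_events/min_gap")
  u <- sort(stats::runif(n_events, 0, slack + 1))
  as.integer(1L + floor(u) + (seq_len(n_events) - 1L) * spacing)
}

#' Simulate a resting recording with injected replay sequences
#'
#' Generates `duration_s` seconds of white sensor noise, adds a shared
#' 10 Hz sinusoid with a fixed random unit-norm topography (the alpha
#' nuisance the lagged nuisance regressors are designed to absorb), and
#' injects `n_events` four-state replay events. Each event walks one of the
#' two chains of the chosen transition structure (chain picked at random per
#' event), in the given direction, with consecutive state activations
#' exactly `lag_ms` apart; each activation places that state's pattern under
#' a half-cosine envelope.
#'
#' @param p a `pattern_set`.
#' @param spec a `state_spec`.
#' @param which_order `"rule"` or `"visual"`: transition structure the
#'   injected sequences follow (`"visual"` only for designs whose visual
#'   order is chain-decomposable; events walk maximal paths).
#' @param lag_ms injected state-to-state lag; must be a multiple of the
#'   sample period.
#' @param direction `"forward"` or `"reverse"`.
#' @param n_events number of injected events (0 gives a pure null record).
#' @param alpha_amp amplitude of the shared 10 Hz oscillation.
#' @param duration_s record duration in seconds.
#' @param noise_sd white-noise standard deviation.
#' @param seed integer seed.
#' @param rate sampling rate in Hz.
#' @param envelope_width_ms full width of the activation envelope.
#' @param amplitude peak scaling of each injected (unit-norm) pattern.
#' @param min_gap_ms minimum spacing between the end of one event and the
#'   onset of the next.
#' @return `list(recording = sensor_recording, truth = ground_truth_events)`
#'   where `truth` holds `event_times` (sample index of every state
#'   activation), `event_states`, `sequence_ids` (grouping into events),
#'   `onsets` (first-activation sample of each event), `direction`,
#'   `lag_ms`.
#' @export
simulate_rest <- function(p, spec, which_order = c("rule", "visual"),
                          lag_ms = 50, direction = c("forward", "reverse"),
                          n_events = 60L, alpha_amp = 0.5, duration_s = 300,
                          noise_sd = 0.2, seed = NULL, rate = 100,
                          envelope_width_ms = 100, amplitude = 1,
                          min_gap_ms = 500) {
  which_order <- match.arg(which_order)
  direction <- match.arg(direction)
  stopifnot(inherits(p, "pattern_set"), inherits(spec, "state_spec"))
  step <- 1000 / rate
  if (abs(lag_ms / step - round(lag_ms / step)) > 1e-9)
    stop("lag_ms must be a multiple of the sample period (", step, " ms)")
  n_samples <- round(duration_s * rate)
  lag_smp <- round(lag_ms / step)
  P <- if (which_order == "rule") spec$rule_order else spec$visual_order
  paths <- chain_paths(P)
  if (!length(paths)) stop("transition structure has no chains to inject")

  with_seed(seed, {
    data <- matrix(stats::rnorm(p$n_channels * n_samples, sd = noise_sd),
                   p$n_channels, n_samples)
    tt <- (seq_len(n_samples) - 1L) / rate
    if (alpha_amp > 0) {
      topo <- stats::rnorm(p$n_channels)
      topo <- topo / sqrt(sum(topo^2))
      phase <- stats::runif(1, 0, 2 * pi)
      data <- data + alpha_amp * outer(topo, sin(2 * pi * 10 * tt + phase))
    }
    ev_times <- integer(0); ev_states <- integer(0); ev_ids <- integer(0)
    onsets <- integer(0)
    if (n_events > 0) {
      span <- (max(lengths(paths)) - 1L) * lag_smp +
        ceiling(envelope_width_ms / step)
      onsets <- place_event_onsets(n_events, n_samples, span,
                                   round(min_gap_ms / step))
      which_path <- sample.int(length(paths), n_events, replace = TRUE)
      env_halfw <- envelope_width_ms / 2000   # seconds
      for (e in seq_len(n_events)) {
        states <- paths[[which_path[e]]]
        if (direction == "reverse") states <- rev(states)
        for (k in seq_along(states)) {
          smp <- onsets[e] + (k - 1L) * lag_smp
          ev_times <- c(ev_times, smp)
          ev_states <- c(ev_states, states[k])
          ev_ids <- c(ev_ids, e)
          ctr <- (smp - 1L) / rate
          lo <- max(1L, floor((ctr - env_halfw) * rate))
          hi <- min(n_samples, ceiling((ctr + env_halfw) * rate) + 1L)
          idx <- lo:hi
          env <- half_cosine_env((idx - 1L) / rate, ctr, envelope_width_ms / 1000)
          data[, idx] <- data[, idx] +
            amplitude * outer(p$patterns[states[k], ], env)
        }
      }
    }
    truth <- structure(list(event_times = ev_times, event_states = ev_states,
                            sequence_ids = ev_ids, onsets = onsets,
                            direction = direction, lag_ms = lag_ms,
                            envelope_width_ms = envelope_width_ms,
                            which_order = which_order),
                       class = "ground_truth_events")
    list(recording = new_recording(data, rate), truth = truth)
  })
}

# Decompose a chain-structured transition matrix into its maximal paths.
chain_paths <- function(P) {
  starts <- unname(which(rowSums(P) > 0 & colSums(P) == 0))
  lapply(starts, function(s) {
    path <- s
    repeat {
      nxt <- unname(which(P[path[length(path)], ] != 0))
      if (!length(nxt)) break
      path <- c(path, nxt[1L])
    }
    path
  })
}

#' Add oscillatory bursts to a recording at given onsets
#'
#' Utility for spectral-contrast validation: injects short sinusoidal bursts
#' (e.g., 140 Hz, ripple-band) with a random topography at each onset.
#'
#' @param rec a `sensor_recording`.
#' @param onsets sample indices of burst onsets.
#' @param freq_hz burst frequency (requires `rec$rate >= 2 * freq_hz`).
#' @param duration_ms burst duration.
#' @param amplitude burst amplitude.
#' @param seed integer seed (topography and phases).
#' @return the modified `sensor_recording`.
#' @export
inject_bursts <- function(rec, onsets, freq_hz = 140, duration_ms = 100,
                          amplitude = 1, seed = NULL) {
  stopifnot(inherits(rec, "sensor_recording"), rec$rate >= 2 * freq_hz)
  n <- ncol(rec$data)
  len <- round(duration_ms / 1000 * rec$rate)
  with_seed(seed, {
    topo <- stats::rnorm(nrow(rec$data))
    topo <- topo / sqrt(sum(topo^2))
    for (on in onsets) {
      idx <- on:min(n, on + len - 1L)
      ph <- stats::runif(1, 0, 2 * pi)
      burst <- sin(2 * pi * freq_hz * (idx - on) / rec$rate + ph) *
        half_cosine_env(seq_along(idx), length(idx) / 2, length(idx))
      rec$data[, idx] <- rec$data[, idx] + amplitude * outer(topo, burst)
    }
    rec
  })
}

#' Compose factorized stimulus patterns
#'
#' Builds stimulus topographies as an additive mixture of a stimulus-unique
#' component, a component shared by all states at the same ordinal position,
#' and a component shared by all states of the same sequence:
#' `pattern(s) = w_stim * u_s + w_pos * p_pos(s) + w_seq * q_seq(s)`.
#' Setting `w_pos = w_seq = 0` produces a world in which position/sequence
#' classifiers can only exploit stimulus-unique features.
#'
#' @param n_channels number of sensors.
#' @param spec a `state_spec` providing the factor labels.
#' @param w_stim,w_pos,w_seq mixture weights.
#' @param seed integer seed.
#' @param evoked_latency_ms evoked latency passed to the `pattern_set`.
#' @return list with `stim` (a `pattern_set` of composite patterns),
#'   `pos_patterns` (4 x channels), `seq_patterns` (2 x channels).
#' @export
make_factor_patterns <- function(n_channels, spec, w_stim = 1, w_pos = 1,
                                 w_seq = 1, seed = NULL,
                                 evoked_latency_ms = 200) {
  stopifnot(inherits(spec, "state_spec"))
  with_seed(seed, {
    unitrows <- function(k) {
      M <- matrix(stats::rnorm(k * n_channels), k, n_channels)
      M / sqrt(rowSums(M^2))
    }
    U <- unitrows(spec$n_states)
    Ppos <- unitrows(4L)
    Qseq <- unitrows(2L)
    comp <- w_stim * U + w_pos * Ppos[spec$position_of, , drop = FALSE] +
      w_seq * Qseq[spec$sequence_of, , drop = FALSE]
    comp <- comp / sqrt(rowSums(comp^2))
    ps <- structure(list(patterns = comp, evoked_latency_ms = evoked_latency_ms,
                         n_states = spec$n_states, n_channels = n_channels,
                         seed = if (is.null(seed)) NA_integer_ else as.integer(seed)),
                    class = "pattern_set")
    list(stim = ps, pos_patterns = Ppos, seq_patterns = Qseq)
  })
}
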