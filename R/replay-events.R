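#' Replay event detection and event-locked statistics
#'
#' Momentary replay strength at time `t` is the evidence that some state is
#' active at `t` while its transition-matrix successor is active at
#' `t + dt`: with reactivation matrix `Y`, `Orig = Y %*% P` is the expected
#' next-state activation and `Proj(t, ) = Y(t + dt, )` the activation one
#' lag later; `r(t) = sum_i Orig(t, i) * Proj(t, i)`. Onsets are samples
#' exceeding the 95th percentile of `r` with no suprathreshold sample in the
#' preceding 100 ms ("replay-free" pre-window).
#'
#' @name replay_events
NULL

#' Momentary replay strength
#'
#' @param Y a `reactivation_matrix`.
#' @param P transition matrix defining the sequence direction of interest.
#' @param lag_ms the state-to-state lag (typically the sequenceness peak).
#' @param rate sampling rate if `Y` is a bare matrix.
#' @return a `strength_series` list: `r` (length `N`; the trailing `lag`
#'   samples, where the lead term is undefined, are zero), `lag_ms`, `rate`,
#'   `P`.
#' @export
replay_strength <- function(Y, P, lag_ms, rate = NULL) {
  ym <- reactivation_values(Y, rate)
  if (ncol(ym$values) != nrow(P)) stop("shape mismatch between Y and P")
  step <- 1000 / ym$rate
  k <- round(lag_ms / step)
  if (abs(lag_ms / step - k) > 1e-9) stop("lag_ms not on the sample grid")
  n <- nrow(ym$values)
  orig <- ym$values %*% P
  r <- numeric(n)
  if (k < n) {
    rows <- 1L:(n - k)
    r[rows] <- rowSums(orig[rows, , drop = FALSE] *
                         ym$values[rows + k, , drop = FALSE])
  }
  structure(list(r = r, lag_ms = lag_ms, rate = ym$rate, P = P),
            class = "strength_series")
}

#' Detect replay onsets from a strength series
#'
#' @param ss a `strength_series` (or bare numeric vector with `rate`).
#' @param percentile threshold percentile of `r` (default 95). Samples must
#'   *strictly* exceed the threshold, so a constant series yields no onsets.
#' @param refractory_ms required suprathreshold-free time before an onset
#'   (default 100 ms).
#' @param rate sampling rate if `ss` is a bare vector.
#' @return an `event_list`: `onsets` (sample indices), `threshold_value`,
#'   `percentile`, `refractory_ms`, `rate`, `strength` (r at the onsets).
#' @export
detect_onsets <- function(ss, percentile = 95, refractory_ms = 100,
                          rate = NULL) {
  if (inherits(ss, "strength_series")) {
    r <- ss$r; rate <- ss$rate
  } else {
    r <- as.numeric(ss)
    if (is.null(rate)) stop("supply `rate` for a bare strength vector")
  }
  if (percentile <= 0 || percentile >= 100) stop("percentile must be in (0, 100)")
  thr <- as.numeric(stats::quantile(r, percentile / 100))
  supra <- r > thr
  k <- round(refractory_ms / 1000 * rate)
  idx <- which(supra)
  onsets <- idx[vapply(idx, function(i) {
    lo <- max(1L, i - k)
    !any(supra[lo:(i - 1L)]) || i == 1L
  }, logical(1))]
  structure(list(onsets = onsets, threshold_value = thr,
                 percentile = percentile, refractory_ms = refractory_ms,
                 rate = rate, strength = r[onsets]),
            class = "event_list")
}

#' @export
print.event_list <- function(x, ...) {
  cat(sprintf("event_list: %d onsets (threshold %.4g at p%g, refractory %g ms)\n",
              length(x$onsets), x$threshold_value, x$percentile,
              x$refractory_ms))
  invisible(x)
}

#' Match detected onsets against ground-truth activation times
#'
#' A detected onset is a true positive if it falls within `tol_ms` of any
#' ground-truth time; a ground-truth event is recalled if any detected onset
#' falls within `tol_ms` of its first activation.
#'
#' @param ev an `event_list`.
#' @param truth a `ground_truth_events` (from [simulate_rest()]).
#' @param tol_ms matching tolerance (default: the envelope half-width).
#' @return list `precision`, `recall`, `median_onset_error_ms`, `n_detected`.
#' @export
match_events <- function(ev, truth, tol_ms = NULL) {
  stopifnot(inherits(ev, "event_list"), inherits(truth, "ground_truth_events"))
  if (is.null(tol_ms)) tol_ms <- truth$envelope_width_ms / 2
  tol <- tol_ms / 1000 * ev$rate
  if (!length(ev$onsets))
    return(list(precision = NA_real_, recall = 0,
                median_onset_error_ms = NA_real_, n_detected = 0L))
  gt <- truth$event_times
  derr <- vapply(ev$onsets, function(o) min(abs(gt - o)), numeric(1))
  tp <- derr <= tol
  first <- truth$onsets
  recalled <- vapply(first, function(f) any(abs(ev$onsets - f) <= tol), logical(1))
  list(precision = mean(tp),
       recall = mean(recalled),
       median_onset_error_ms = stats::median(derr) * 1000 / ev$rate,
       n_detected = length(ev$onsets))
}

morlet_power <- function(x, rate, freqs, n_cycles = 7) {
  n <- length(x)
  nf <- stats::nextn(2L * n)
  Xf <- stats::fft(c(x, numeric(nf - n)))
  out <- matrix(0, length(freqs), n)
  for (fi in seq_along(freqs)) {
    f <- freqs[fi]
    sd_t <- n_cycles / (2 * pi * f)
    hw <- ceiling(5 * sd_t * rate)
    tt <- (-hw:hw) / rate
    w <- exp(2i * pi * f * tt) * exp(-tt^2 / (2 * sd_t^2))
    w <- w / sqrt(sum(Mod(w)^2))
    Wf <- stats::fft(c(w, complex(real = numeric(nf - length(w)))))
    conv <- stats::fft(Xf * Wf, inverse = TRUE) / nf
    out[fi, ] <- Mod(conv[(hw + 1L):(hw + n)])^2
  }
  out
}

#' Event-locked time-frequency power contrast
#'
#' Morlet-wavelet power (frequency-proportional bandwidth, fixed number of
#' cycles) is computed per channel across the whole recording, epoched
#' around each onset, averaged over events and channels, and
#' baseline-corrected per frequency by subtracting the mean over the
#' baseline window. Events with another event inside their baseline window,
#' or too close to the record edges, are excluded.
#'
#' @param rec a `sensor_recording` (rate must support `2 * max(freqs)`).
#' @param ev an `event_list` (onset sample indices on `rec`'s clock).
#' @param freqs frequency grid in Hz (default 20..150 in steps of 5).
#' @param window_ms epoch window around onsets (default -100..200 ms).
#' @param baseline_ms baseline window (default -100..-50 ms).
#' @param n_cycles wavelet cycles.
#' @return a `tf_contrast` list: `power_change` (freq x time, averaged),
#'   `freqs`, `times_ms`, `n_events_used`.
#' @export
event_locked_power <- function(rec, ev, freqs = seq(20, 150, by = 5),
                               window_ms = c(-100, 200),
                               baseline_ms = c(-100, -50), n_cycles = 7) {
  stopifnot(inherits(rec, "sensor_recording"))
  onsets <- if (inherits(ev, "event_list")) ev$onsets else as.integer(ev)
  if (rec$rate < 2 * max(freqs))
    stop("sampling rate too low for the requested frequencies")
  n <- ncol(rec$data)
  pre <- round(-window_ms[1] / 1000 * rec$rate)
  post <- round(window_ms[2] / 1000 * rec$rate)
  keep <- onsets[onsets - pre >= 1 & onsets + post <= n]
  # exclude events with another event in their baseline window
  b0 <- round(baseline_ms[1] / 1000 * rec$rate)
  b1 <- round(baseline_ms[2] / 1000 * rec$rate)
  keep <- keep[vapply(keep, function(o) {
    others <- setdiff(onsets, o)
    !any(others >= o + b0 & others <= o + b1)
  }, logical(1))]
  if (!length(keep)) stop("no usable events (all too close to edges or to other events)")
  times_idx <- (-pre):post
  acc <- matrix(0, length(freqs), length(times_idx))
  for (ch in seq_len(nrow(rec$data))) {
    pw <- morlet_power(rec$data[ch, ], rec$rate, freqs, n_cycles)
    for (o in keep) acc <- acc + pw[, o + times_idx, drop = FALSE]
  }
  acc <- acc / (length(keep) * nrow(rec$data))
  times_ms <- times_idx * 1000 / rec$rate
  bl <- times_ms >= baseline_ms[1] & times_ms <= baseline_ms[2]
  acc <- acc - rowMeans(acc[, bl, drop = FALSE])
  structure(list(power_change = acc, freqs = freqs, times_ms = times_ms,
                 n_events_used = length(keep)),
            class = "tf_contrast")
}

# Connected components (4-neighbourhood) of a logical matrix; returns an
# integer label matrix (0 = background).
label_components <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  cur <- 0L
  nr <- nrow(mask); nc <- ncol(mask)
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (!mask[i, j] || lab[i, j] != 0L) next
    cur <- cur + 1L
    queue <- matrix(c(i, j), 1L)
    lab[i, j] <- cur
    while (nrow(queue)) {
      p <- queue[1L, ]; queue <- queue[-1L, , drop = FALSE]
      for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
        q <- p + d
        if (q[1L] >= 1L && q[1L] <= nr && q[2L] >= 1L && q[2L] <= nc &&
            mask[q[1L], q[2L]] && lab[q[1L], q[2L]] == 0L) {
          lab[q[1L], q[2L]] <- cur
          queue <- rbind(queue, q)
        }
      }
    }
  }
  lab
}

cluster_masses <- function(tmap, t_thresh) {
  lab <- label_components(tmap > t_thresh)
  if (!max(lab)) return(list(masses = numeric(0), labels = lab))
  list(masses = vapply(seq_len(max(lab)), function(k) sum(tmap[lab == k]),
                       numeric(1)),
       labels = lab)
}

#' Cluster-based permutation test on per-subject maps
#'
#' Computes a one-sample t map across subjects, forms clusters of contiguous
#' cells with `t > t_thresh` (4-neighbourhood), scores each cluster by its
#' summed t, and builds the null by randomly sign-flipping whole subject
#' maps and recording the maximum cluster mass per permutation. Cluster
#' p values are `(1 + #{null >= observed}) / (n_perm + 1)`.
#'
#' @param maps list of per-subject matrices (e.g., `tf_contrast$power_change`),
#'   all the same shape; at least 2.
#' @param t_thresh cluster-forming threshold (default 3.1).
#' @param n_perm number of sign-flip permutations (default 5000).
#' @param seed integer seed.
#' @return a `cluster_test` list: `t_map`, `clusters` (data frame: `id`,
#'   `mass`, `p`), `labels` (cluster label matrix), `null_max_mass`.
#' @export
cluster_permutation <- function(maps, t_thresh = 3.1, n_perm = 5000L,
                                seed = NULL) {
  maps <- lapply(maps, function(m)
    if (inherits(m, "tf_contrast")) m$power_change else m)
  stopifnot(length(maps) >= 2L)
  dims <- dim(maps[[1L]])
  stopifnot(all(vapply(maps, function(m) all(dim(m) == dims), logical(1))))
  S <- length(maps)
  M <- vapply(maps, as.numeric, numeric(prod(dims)))   # cells x subjects
  ssq <- rowSums(M^2)                                  # sign-flip invariant
  tmap_of <- function(signs) {
    mu <- as.numeric(M %*% signs) / S
    v <- (ssq - S * mu^2) / (S - 1)
    v[v <= 0] <- Inf
    matrix(mu / sqrt(v / S), dims[1L], dims[2L])
  }
  tmap <- tmap_of(rep(1, S))
  obs <- cluster_masses(tmap, t_thresh)
  null_max <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    cm <- cluster_masses(tmap_of(sample(c(-1, 1), S, replace = TRUE)),
                         t_thresh)$masses
    if (length(cm)) max(cm) else 0
  }, numeric(1)))
  p <- vapply(obs$masses, function(m) (1 + sum(null_max >= m)) / (n_perm + 1),
              numeric(1))
  structure(list(t_map = tmap,
                 clusters = data.frame(id = seq_along(obs$masses),
                                       mass = obs$masses, p = p),
                 labels = obs$labels, null_max_mass = null_max,
                 t_thresh = t_thresh, n_perm = n_perm),
            class = "cluster_test")
}

#' Cross-code lag analysis
#'
#' Sequenceness machinery applied across two reactivation matrices (e.g., a
#' position code and a stimulus code): forward evidence at lag `dt` is the
#' pairing-consistent prediction of `Yb` by `dt`-lagged `Ya` (does code `a`
#' lead code `b`?), reverse evidence the transpose direction, each computed
#' with the same nuisance-lag OLS apparatus.
#'
#' @param Ya,Yb `reactivation_matrix` objects with equal sample counts
#'   (or bare matrices with `rate`).
#' @param pairing either an integer vector mapping each `a` state to its
#'   paired `b` state, or a rectangular 0/1 pairing matrix
#'   (`a_states x b_states`).
#' @param lags_ms lag grid.
#' @param nuisance_offsets_ms nuisance lag offsets.
#' @param rate sampling rate for bare matrices.
#' @return a `sequenceness_curve` data frame (`lag_ms`, `zf`, `zb`, `diff`);
#'   positive `diff` means `a` leads `b`.
#' @export
cross_code_lag <- function(Ya, Yb, pairing, lags_ms = NULL,
                           nuisance_offsets_ms = seq(100, 600, 100),
                           rate = NULL) {
  ya <- reactivation_values(Ya, rate)
  yb <- reactivation_values(Yb, rate)
  if (nrow(ya$values) != nrow(yb$values)) stop("sample counts differ")
  if (!is.matrix(pairing)) {
    M <- matrix(0, ncol(ya$values), ncol(yb$values))
    M[cbind(seq_along(pairing), pairing)] <- 1
  } else M <- pairing
  if (is.null(lags_ms)) lags_ms <- lag_grid(ya$rate)
  # regress each Yb state on lagged Ya states (forward) and vice versa
  beta_ab <- cross_betas(ya$values, yb$values, ya$rate, lags_ms,
                         nuisance_offsets_ms)
  beta_ba <- cross_betas(yb$values, ya$values, ya$rate, lags_ms,
                         nuisance_offsets_ms)
  zf <- vapply(beta_ab, function(b) sum(b * M), numeric(1))
  zb <- vapply(beta_ba, function(b) sum(b * t(M)), numeric(1))
  out <- data.frame(lag_ms = lags_ms, zf = zf, zb = zb, diff = zf - zb)
  class(out) <- c("sequenceness_curve", "data.frame")
  out
}

# beta[i, j]: coefficient of predictor-set state i (lagged) predicting
# target-set state j. Nuisance: lagged copies of the predictor set.
cross_betas <- function(pred, targ, rate, lags_ms, nuisance_offsets_ms) {
  step <- 1000 / rate
  n <- nrow(pred); sp <- ncol(pred)
  lapply(lags_ms, function(dt) {
    k <- round(dt / step)
    shifts <- c(k, round((dt + nuisance_offsets_ms) / step))
    maxk <- max(shifts)
    if (maxk >= n) stop("lag ", dt, " ms exceeds data length")
    rows <- (maxk + 1L):n
    X <- do.call(cbind, lapply(shifts, function(kk)
      pred[rows - kk, , drop = FALSE]))
    X <- cbind(X, 1)
    B <- qr.coef(qr(X), targ[rows, , drop = FALSE])
    B[seq_len(sp), , drop = FALSE]
  })
}

#' Coincidence of a reactivation series with event onsets
#'
#' Tests whether `x` is elevated at event onsets against a circular-shift
#' null (shifting preserves the autocorrelation of `x`): the statistic is
#' the mean of `x` at the onsets minus the average of that mean over the
#' shifted onset sets; `p` is the proportion of shifts whose onset mean is
#' at least the observed one.
#'
#' @param x numeric reactivation time series.
#' @param ev an `event_list` (or integer onset vector); must be non-empty.
#' @param n_perm number of circular shifts (default 1000).
#' @param seed integer seed.
#' @return list `statistic`, `p`, `observed_mean`, `null_means`.
#' @export
onset_coincidence <- function(x, ev, n_perm = 1000L, seed = NULL) {
  onsets <- if (inherits(ev, "event_list")) ev$onsets else as.integer(ev)
  if (!length(onsets)) stop("event list is empty")
  n <- length(x)
  stopifnot(all(onsets >= 1), all(onsets <= n))
  obs <- mean(x[onsets])
  null_means <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    sh <- sample.int(n - 1L, 1L)
    mean(x[((onsets - 1L + sh) %% n) + 1L])
  }, numeric(1)))
  list(statistic = obs - mean(null_means),
       p = (1 + sum(null_means >= obs)) / (n_perm + 1),
       observed_mean = obs, null_means = null_means)
}
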