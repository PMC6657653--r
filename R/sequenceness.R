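#' Time-lagged regression sequenceness
#'
#' Sequenceness quantifies, per time lag `dt`, the evidence that decoded
#' state reactivations follow a hypothesized transition matrix `P`. For each
#' target state `i`, the reactivation series `Y_i(t)` is regressed (OLS) on
#' the `dt`-lagged series of all states, together with nuisance copies
#' lagged at `dt + 100, ..., dt + 600` ms (absorbing any pattern repeating
#' at ~10 Hz, e.g. a resting alpha rhythm) and a constant. Collecting the
#' lag-`dt` coefficients over targets gives an empirical transition matrix
#' `beta(dt)` whose entry `(i, j)` measures how strongly state `i` at
#' `t - dt` predicts state `j` at `t`. Projecting `beta(dt)` onto `P`
#' (Frobenius inner product) gives forward evidence `zf`; onto `t(P)`,
#' backward evidence `zb`; sequenceness is `zf - zb`, which cancels
#' autocorrelation common to both directions. Positive values indicate
#' forward, negative reverse sequences.
#'
#' Family-wise error over the lag grid is controlled with a max-statistic
#' permutation null: state labels are permuted (equivalently, rows and
#' columns of `P` together), the full curve is recomputed per permutation,
#' and the threshold is the maximum over permutations of the per-permutation
#' peak `|zf - zb|`.
#'
#' @name sequenceness
NULL

#' Lag grid
#'
#' @param rate sampling rate (Hz).
#' @param max_ms largest lag (default 600 ms).
#' @param min_ms smallest lag (default one sample period).
#' @return ascending vector of lags in ms, in steps of the sample period.
#' @export
lag_grid <- function(rate = 100, max_ms = 600, min_ms = 1000 / rate) {
  step <- 1000 / rate
  seq(from = step * round(min_ms / step), to = max_ms, by = step)
}

default_nuisance <- function(lag_ms) lag_ms + seq(100, 600, by = 100)

# Samples x states matrix shifted down by `k` samples (first k rows NA).
lag_shift <- function(M, k) {
  n <- nrow(M)
  out <- matrix(NA_real_, n, ncol(M))
  if (k < n) out[(k + 1L):n, ] <- M[1L:(n - k), , drop = FALSE]
  out
}

#' Empirical transition matrix at one lag
#'
#' @param Y a `reactivation_matrix` (or plain `samples x states` matrix with
#'   a `rate` attribute/argument).
#' @param lag_ms the lag of interest `dt` (multiple of the sample period).
#' @param nuisance_lags_ms nuisance lags; default `dt + 100, ..., dt + 600`
#'   ms. Use `numeric(0)` to omit.
#' @param rate sampling rate if `Y` is a bare matrix.
#' @return `s x s` matrix `beta` with `beta[i, j]` the OLS coefficient of
#'   state `i`'s reactivation at `t - dt` in the prediction of state `j` at
#'   `t` (rows: earlier state, columns: later state). Rows of the design
#'   with undefined lagged values are dropped listwise.
#' @export
empirical_transitions <- function(Y, lag_ms, nuisance_lags_ms = NULL,
                                  rate = NULL) {
  ym <- reactivation_values(Y, rate)
  if (is.null(nuisance_lags_ms)) nuisance_lags_ms <- default_nuisance(lag_ms)
  if (any(nuisance_lags_ms <= lag_ms))
    stop("nuisance lags must all exceed the lag of interest")
  betas_at_lags(ym$values, ym$rate, lag_ms, nuisance_lags_ms - lag_ms)[[1L]]
}

reactivation_values <- function(Y, rate = NULL) {
  if (inherits(Y, "reactivation_matrix")) return(list(values = Y$values, rate = Y$rate))
  stopifnot(is.matrix(Y))
  if (is.null(rate)) rate <- attr(Y, "rate")
  if (is.null(rate)) stop("supply `rate` for a bare matrix Y")
  list(values = Y, rate = rate)
}

# Workhorse: beta matrices for several lags of interest, one OLS per lag
# (all s targets solved jointly). Nuisance lags are taken relative to each
# lag of interest (absolute nuisance lag = dt + offset).
betas_at_lags <- function(vals, rate, lags_ms, nuisance_offsets_ms) {
  step <- 1000 / rate
  n <- nrow(vals); s <- ncol(vals)
  lapply(lags_ms, function(dt) {
    k <- round(dt / step)
    if (abs(dt / step - k) > 1e-9) stop("lag ", dt, " ms not on the sample grid")
    nuis_k <- round((dt + nuisance_offsets_ms) / step)
    shifts <- c(k, nuis_k)
    maxk <- max(shifts)
    if (maxk >= n) stop("lag ", dt, " ms (plus nuisance) exceeds data length")
    rows <- (maxk + 1L):n
    X <- do.call(cbind, lapply(shifts, function(kk)
      vals[rows - kk, , drop = FALSE]))
    X <- cbind(X, 1)
    qrX <- qr(X)
    if (qrX$rank < ncol(X)) {
      bad <- qrX$pivot[(qrX$rank + 1L):ncol(X)]
      stop("rank-deficient design at lag ", dt, " ms (columns ",
           paste(bad, collapse = ", "), ")")
    }
    B <- qr.coef(qrX, vals[rows, , drop = FALSE])
    B[seq_len(s), , drop = FALSE]     # lag-of-interest block: rows = predictor state
  })
}

#' Frobenius projection of an empirical transition matrix
#'
#' @param beta `s x s` empirical coefficients (rows: earlier state).
#' @param P binary transition matrix of the hypothesized structure.
#' @return `c(zf, zb)`: inner products of `beta` with `P` and `t(P)`.
#' @export
project_sequenceness <- function(beta, P) {
  if (!all(dim(beta) == dim(P))) stop("shape mismatch between beta and P")
  c(zf = sum(beta * P), zb = sum(beta * t(P)))
}

#' Sequenceness curve over a lag grid
#'
#' @param Y a `reactivation_matrix`.
#' @param P hypothesized transition matrix.
#' @param lags_ms lag grid (default [lag_grid()] at `Y`'s rate).
#' @param nuisance_offsets_ms nuisance lag offsets relative to each lag
#'   (default `+100, ..., +600` ms); `numeric(0)` to omit.
#' @param rate sampling rate if `Y` is a bare matrix.
#' @return a `sequenceness_curve` data frame: `lag_ms`, `zf`, `zb`, `diff`.
#' @export
sequenceness_curve <- function(Y, P, lags_ms = NULL,
                               nuisance_offsets_ms = seq(100, 600, 100),
                               rate = NULL) {
  ym <- reactivation_values(Y, rate)
  if (is.null(lags_ms)) lags_ms <- lag_grid(ym$rate)
  bl <- betas_at_lags(ym$values, ym$rate, lags_ms, nuisance_offsets_ms)
  zz <- t(vapply(bl, project_sequenceness, numeric(2), P = P))
  out <- data.frame(lag_ms = lags_ms, zf = zz[, 1L], zb = zz[, 2L],
                    diff = zz[, 1L] - zz[, 2L])
  class(out) <- c("sequenceness_curve", "data.frame")
  out
}

#' Peak lag of a sequenceness curve
#'
#' @param curve a `sequenceness_curve`.
#' @param what `"diff"` (signed, forward-positive), `"abs"` (magnitude),
#'   or `"reverse"` (most negative diff).
#' @return the lag (ms) at the peak; ties broken toward the smallest lag.
#' @export
peak_lag <- function(curve, what = c("diff", "abs", "reverse")) {
  what <- match.arg(what)
  v <- switch(what, diff = curve$diff, abs = abs(curve$diff),
              reverse = -curve$diff)
  curve$lag_ms[which.max(v)]
}

#' State-label permutations for the sequenceness null
#'
#' Exhaustive when the number of distinct non-identity permutations is at
#' most `n_perm` (always the case for `s <= 5` at the default), otherwise a
#' seeded uniform sample without replacement. The identity permutation is
#' never part of the null set.
#'
#' @param s number of states.
#' @param n_perm requested number of permutations.
#' @param seed integer seed for sampling.
#' @return integer matrix, one permutation per row.
#' @export
state_permutations <- function(s, n_perm = 1000L, seed = NULL) {
  total <- factorial(s) - 1
  if (n_perm > total)
    stop("requested ", n_perm, " permutations but only ", total,
         " non-identity permutations exist")
  if (s <= 5 || total <= n_perm) {
    all <- all_permutations(s)
    all <- all[rowSums(all != matrix(seq_len(s), nrow(all), s, byrow = TRUE)) > 0, ,
               drop = FALSE]
    if (nrow(all) > n_perm)
      all <- with_seed(seed, all[sample.int(nrow(all), n_perm), , drop = FALSE])
    return(all)
  }
  with_seed(seed, {
    seen <- new.env(hash = TRUE)
    out <- matrix(0L, n_perm, s)
    k <- 0L
    while (k < n_perm) {
      p <- sample.int(s)
      if (all(p == seq_len(s))) next
      key <- paste(p, collapse = ",")
      if (!is.null(seen[[key]])) next
      seen[[key]] <- TRUE
      k <- k + 1L
      out[k, ] <- p
    }
    out
  })
}

#' Permutation null and corrected threshold for a sequenceness curve
#'
#' For each state-label permutation `sigma`, the curve is recomputed against
#' the relabeled structure `P[sigma, sigma]` (the per-lag `beta` matrices
#' are computed once and reused), and the peak over lags of `|zf - zb|` is
#' recorded. The corrected threshold is the maximum of these peaks
#' (configurable to a quantile).
#'
#' @param Y a `reactivation_matrix`.
#' @param P hypothesized transition matrix.
#' @param lags_ms lag grid (default [lag_grid()]).
#' @param perms either an integer count (sampled via [state_permutations()])
#'   or an explicit permutation matrix (rows = permutations). The identity
#'   permutation is rejected.
#' @param seed seed for permutation sampling.
#' @param nuisance_offsets_ms nuisance lag offsets.
#' @param quantile_prob threshold quantile of the null peaks (default 1 =
#'   the maximum).
#' @param rate sampling rate if `Y` is a bare matrix.
#' @return a `sequenceness_null` list: `curve` (the observed
#'   `sequenceness_curve`), `null_peaks`, `threshold`, `exceeds` (does the
#'   observed `max |diff|` exceed the threshold), `permutations`.
#' @export
permutation_null <- function(Y, P, lags_ms = NULL, perms = 100L, seed = NULL,
                             nuisance_offsets_ms = seq(100, 600, 100),
                             quantile_prob = 1, rate = NULL) {
  ym <- reactivation_values(Y, rate)
  if (is.null(lags_ms)) lags_ms <- lag_grid(ym$rate)
  s <- ncol(ym$values)
  if (is.matrix(perms)) {
    if (any(apply(perms, 1L, function(p) all(p == seq_len(s)))))
      stop("the identity permutation must not be part of the null set")
  } else {
    perms <- state_permutations(s, perms, seed = seed)
  }
  bl <- betas_at_lags(ym$values, ym$rate, lags_ms, nuisance_offsets_ms)
  zz <- t(vapply(bl, project_sequenceness, numeric(2), P = P))
  curve <- data.frame(lag_ms = lags_ms, zf = zz[, 1L], zb = zz[, 2L],
                      diff = zz[, 1L] - zz[, 2L])
  class(curve) <- c("sequenceness_curve", "data.frame")
  null_peaks <- apply(perms, 1L, function(sg) {
    Pp <- P[sg, sg]
    max(abs(vapply(bl, function(b) {
      z <- project_sequenceness(b, Pp)
      z[1L] - z[2L]
    }, numeric(1))))
  })
  threshold <- as.numeric(stats::quantile(null_peaks, quantile_prob, type = 1))
  structure(list(curve = curve, null_peaks = null_peaks,
                 threshold = threshold,
                 exceeds = max(abs(curve$diff)) > threshold,
                 permutations = perms),
            class = "sequenceness_null")
}

#' @export
print.sequenceness_null <- function(x, ...) {
  cat(sprintf(paste0("sequenceness_null: %d permutations, threshold = %.4g; ",
                     "observed peak |diff| = %.4g at %g ms (%s)\n"),
              nrow(x$permutations), x$threshold, max(abs(x$curve$diff)),
              peak_lag(x$curve, "abs"),
              if (x$exceeds) "exceeds" else "below threshold"))
  invisible(x)
}

#' Extra evidence for length-n sequences
#'
#' Measures evidence for chained sequences of `n` states at a common
#' state-to-state lag, controlling for all shorter chains: for a path
#' `a1 -> a2 -> ... -> an` and lag `dt`, the terminal state's reactivation
#' is regressed on the origin state lagged by `(n-1) * dt`, with the
#' intermediate states at their respective multiples of `dt` (and a
#' constant) as controls. The reported value is the origin coefficient,
#' averaged over all length-`n` subpaths of the supplied paths; the reverse
#' variant runs the same on the reversed paths, and `diff` is forward minus
#' reverse.
#'
#' @param Y a `reactivation_matrix`.
#' @param paths list of ordered state index vectors (e.g., the two chains).
#' @param n chain length, `3 <= n <= max path length`.
#' @param lags_ms lag grid; defaults to [lag_grid()] capped so that
#'   `(n - 1) * max(lags_ms)` fits in the data.
#' @param rate sampling rate if `Y` is a bare matrix.
#' @return data frame `lag_ms`, `fwd`, `bwd`, `diff`.
#' @export
lengthn_sequenceness <- function(Y, paths, n = 3L, lags_ms = NULL,
                                 rate = NULL) {
  ym <- reactivation_values(Y, rate)
  stopifnot(n >= 3L, n <= max(lengths(paths)))
  step <- 1000 / ym$rate
  nsmp <- nrow(ym$values)
  if (is.null(lags_ms)) {
    lags_ms <- lag_grid(ym$rate)
    lags_ms <- lags_ms[(n - 1) * lags_ms / step < nsmp - 10]
  }
  if ((n - 1) * max(lags_ms) / step >= nsmp)
    stop("(n-1) * max lag exceeds the data length")
  subpaths <- unlist(lapply(paths, function(p) {
    if (length(p) < n) return(NULL)
    lapply(seq_len(length(p) - n + 1L), function(i) p[i:(i + n - 1L)])
  }), recursive = FALSE)
  if (!length(subpaths)) stop("no length-", n, " subpaths in the given paths")
  evidence <- function(path, k) {   # k: lag in samples
    maxk <- (n - 1L) * k
    rows <- (maxk + 1L):nsmp
    # predictors: origin at (n-1)k, intermediates at their multiples
    X <- vapply(seq_len(n - 1L), function(j)
      ym$values[rows - (n - j) * k, path[j]], numeric(length(rows)))
    y <- ym$values[rows, path[n]]
    co <- stats::lm.fit(cbind(X, 1), y)$coefficients
    co[1L]   # origin-state coefficient
  }
  res <- t(vapply(lags_ms, function(dt) {
    k <- round(dt / step)
    fwd <- mean(vapply(subpaths, evidence, numeric(1), k = k))
    bwd <- mean(vapply(lapply(subpaths, rev), evidence, numeric(1), k = k))
    c(fwd = fwd, bwd = bwd)
  }, numeric(2)))
  data.frame(lag_ms = lags_ms, fwd = res[, 1L], bwd = res[, 2L],
             diff = res[, 1L] - res[, 2L])
}
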