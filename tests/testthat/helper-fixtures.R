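# Shared fixture builders. Everything is generated in code at test time;
# sizes are kept small so the whole suite stays within a desk-scale budget.

fix_spec1 <- make_study_structure("study1")

# Probability-scale reactivation matrix with half-cosine activation bumps
# injected at given (sample, state) pairs. Used to exercise the sequenceness
# machinery without running decoders.
bump_Y <- function(n_samples, n_states = 8L, times = integer(0),
                   states = integer(0), width = 9L, peak = 0.8,
                   base = 0.05, noise = 0.02, seed = 1L) {
  stopifnot(length(times) == length(states))
  hw <- width %/% 2L
  env <- 0.5 * (1 + cos(2 * pi * seq(-hw, hw) / width))
  Y <- matrix(base, n_samples, n_states)
  for (k in seq_along(times)) {
    idx <- times[k] + seq(-hw, hw)
    ok <- idx >= 1 & idx <= n_samples
    Y[idx[ok], states[k]] <- pmin(0.95, Y[idx[ok], states[k]] + peak * env[ok])
  }
  if (noise > 0) {
    set.seed(seed)
    Y <- Y + matrix(stats::runif(n_samples * n_states, 0, noise),
                    n_samples, n_states)
  }
  attr(Y, "rate") <- 100
  Y
}

# Y containing injected 4-state chain events of fix_spec1's rule order.
chain_Y <- function(n_samples = 6000L, n_events = 30L, lag_smp = 5L,
                    seed = 1L, reverse = FALSE, n_states = 8L) {
  set.seed(seed)
  onsets <- sort(sample(seq(50L, n_samples - 50L, by = 40L), n_events))
  chain <- sample(list(1:4, 5:8), n_events, replace = TRUE)
  times <- integer(0); states <- integer(0)
  for (e in seq_len(n_events)) {
    st <- if (reverse) rev(chain[[e]]) else chain[[e]]
    times <- c(times, onsets[e] + (seq_along(st) - 1L) * lag_smp)
    states <- c(states, st)
  }
  bump_Y(n_samples, n_states, times, states, seed = seed + 1000L)
}

# "B-event" worlds for the length-n analysis: every event has a B
# activation; A precedes and C follows with independent coin flips
# (pairwise-only world) or always (chained world).
ab_bc_Y <- function(n_samples = 12000L, n_b = 120L, chained = FALSE,
                    lag_smp = 5L, seed = 1L) {
  set.seed(seed)
  tb <- round(seq(60, n_samples - 60, length.out = n_b) +
                stats::runif(n_b, -10, 10))
  has_a <- if (chained) rep(TRUE, n_b) else stats::runif(n_b) < 0.5
  has_c <- if (chained) rep(TRUE, n_b) else stats::runif(n_b) < 0.5
  times <- c(tb, tb[has_a] - lag_smp, tb[has_c] + lag_smp)
  states <- c(rep(2L, n_b), rep(1L, sum(has_a)), rep(3L, sum(has_c)))
  bump_Y(n_samples, 8L, times, states, seed = seed + 1000L)
}

# Small localizer + patterns for decoder tests (cheap but decodable).
quick_localizer <- function(n_channels = 32L, n_states = 8L,
                            n_trials_per_state = 12L, noise_sd = 0.1,
                            seed = 1L, ...) {
  p <- make_state_patterns(n_channels, n_states, seed = seed,
                           max_abs_cor = 0.5)
  list(patterns = p,
       epochs = simulate_localizer(p, n_trials_per_state, noise_sd = noise_sd,
                                   seed = seed + 1L, ...))
}

# Reduced pipeline config used wherever the full stated world is not needed.
quick_cfg <- function(seed = 1L, ...) {
  run_config(seed = seed,
             sim = list(n_channels = 32L, duration_s = 60, n_events = 12L),
             sequenceness = list(n_perm = 50L), ...)
}

mode_of <- function(x) as.numeric(names(sort(table(x), decreasing = TRUE))[1L])
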