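test_that("a constructed shift puts unit weight on the right beta entry", {
  set.seed(1)
  n <- 2000
  Y <- matrix(runif(n * 4, 0.2, 0.8), n, 4)
  Y[6:n, 2] <- Y[1:(n - 5), 1]          # state 1 leads state 2 by 5 samples
  b <- empirical_transitions(Y, lag_ms = 50, nuisance_lags_ms = numeric(0),
                             rate = 100)
  expect_equal(b[1, 2], 1, tolerance = 1e-8)
  off <- b; off[1, 2] <- 0
  expect_lt(max(abs(off)), 0.1)
})

test_that("empirical transitions agree with an independent lm() oracle", {
  # brute-force oracle: build the lagged design explicitly and call lm()
  oracle <- function(Y, k, nuis_k) {
    s <- ncol(Y); n <- nrow(Y)
    maxk <- max(c(k, nuis_k))
    rows <- (maxk + 1):n
    X <- do.call(cbind, lapply(c(k, nuis_k), function(kk) Y[rows - kk, ]))
    B <- sapply(seq_len(s), function(i)
      stats::coef(stats::lm(Y[rows, i] ~ X))[1 + seq_len(s)])
    B          # column i = coefficients for target i; rows = predictors
  }
  set.seed(2)
  for (rep in 1:20) {
    n <- 150 + sample(100, 1)
    s <- sample(3:5, 1)
    Y <- matrix(runif(n * s, 0.1, 0.9), n, s)
    lag_ms <- sample(c(10, 20, 30), 1)
    nuis <- lag_ms + c(100, 200)
    b <- empirical_transitions(Y, lag_ms, nuisance_lags_ms = nuis, rate = 100)
    bo <- oracle(Y, lag_ms / 10, nuis / 10)
    expect_equal(b, unname(bo), tolerance = 1e-8)
  }
})

test_that("Frobenius projections count edges and swap under transposition", {
  P <- fix_spec1$rule_order
  z <- project_sequenceness(P, P)
  expect_equal(unname(z["zf"]), 6)      # 6 edges, no symmetric pairs
  expect_equal(unname(z["zb"]), 0)
  zt <- project_sequenceness(t(P), P)
  expect_equal(unname(zt["zf"]), 0)
  expect_equal(unname(zt["zb"]), 6)
  set.seed(3)
  beta <- matrix(rnorm(64), 8, 8)
  z2 <- project_sequenceness(beta, P)
  expect_equal(unname(z2["zf"]), sum(beta[P == 1]))   # elementwise oracle
  expect_error(project_sequenceness(matrix(0, 3, 3), P), "shape")
})

test_that("sequenceness is exactly antisymmetric under transposing P", {
  set.seed(4)
  for (rep in 1:10) {
    Y <- matrix(runif(1500 * 8, 0.1, 0.9), 1500, 8)
    lags <- seq(10, 80, 10)
    a <- sequenceness_curve(Y, fix_spec1$rule_order, lags, rate = 100)
    b <- sequenceness_curve(Y, t(fix_spec1$rule_order), lags, rate = 100)
    expect_equal(b$diff, -a$diff, tolerance = 1e-12)
    expect_equal(b$zf, a$zb, tolerance = 1e-12)
  }
})

test_that("injected forward chains at 50 ms peak the curve at 50 ms and clear the threshold", {
  Y <- chain_Y(n_samples = 6000, n_events = 40, lag_smp = 5, seed = 5)
  null <- permutation_null(Y, fix_spec1$rule_order, lags_ms = seq(10, 200, 10),
                           perms = 60, seed = 6, rate = 100)
  expect_equal(peak_lag(null$curve), 50)
  expect_true(null$exceeds)
  # reverse injection flips the sign at the injected lag
  Yr <- chain_Y(n_samples = 6000, n_events = 40, lag_smp = 5, seed = 5,
                reverse = TRUE)
  cr <- sequenceness_curve(Yr, fix_spec1$rule_order, seq(10, 200, 10),
                           rate = 100)
  expect_lt(cr$diff[cr$lag_ms == 50], 0)
})

test_that("permutation machinery rejects the identity and respects the relabeling identity", {
  Y <- matrix(runif(800 * 4, 0.2, 0.8), 800, 4)
  P4 <- transition_matrix(4, cbind(1:3, 2:4))
  expect_error(permutation_null(Y, P4, lags_ms = c(10, 20),
                                perms = matrix(1:4, 1), rate = 100),
               "identity")
  # projecting the permuted P equals projecting the inversely relabeled beta
  set.seed(7)
  beta <- matrix(rnorm(16), 4, 4)
  sg <- c(3, 1, 4, 2)
  inv <- order(sg)
  expect_equal(project_sequenceness(beta, P4[sg, sg]),
               project_sequenceness(beta[inv, inv], P4), tolerance = 1e-12)
})

test_that("the max-statistic threshold is monotone in the permutation set", {
  Y <- chain_Y(n_samples = 3000, n_events = 15, seed = 8)
  perms <- state_permutations(8, 40, seed = 9)
  thr <- vapply(c(10, 20, 40), function(k) {
    permutation_null(Y, fix_spec1$rule_order, lags_ms = seq(10, 100, 10),
                     perms = perms[seq_len(k), , drop = FALSE],
                     rate = 100)$threshold
  }, numeric(1))
  expect_true(all(diff(thr) >= 0))
})

test_that("state permutation sets are exhaustive for small s and unique for sampled s", {
  ps <- state_permutations(3, 5)
  expect_equal(nrow(ps), 5)
  expect_error(state_permutations(3, 6), "only 5")
  ps8 <- state_permutations(8, 200, seed = 10)
  expect_equal(nrow(unique(ps8)), 200)
  expect_false(any(apply(ps8, 1, function(p) all(p == 1:8))))
})

test_that("nuisance lags absorb a shared 10 Hz oscillation from the directional projections", {
  # A common-phase alpha rhythm inflates zf and zb symmetrically (so the
  # forward-minus-backward difference is protected by construction); the
  # lagged nuisance set must remove the inflation from the directional
  # projections themselves.
  lags <- seq(10, 200, 10)
  for (s in 1:3) {
    set.seed(s)
    n <- 6000
    alpha <- 0.25 * sin(2 * pi * 10 * (1:n) / 100)
    base <- matrix(runif(n * 8, 0.3, 0.7), n, 8)
    Y <- plogis(qlogis(base) + outer(alpha, runif(8, 0.5, 1.5)))
    with_n <- sequenceness_curve(Y, fix_spec1$rule_order, lags, rate = 100)
    without <- sequenceness_curve(Y, fix_spec1$rule_order, lags,
                                  nuisance_offsets_ms = numeric(0),
                                  rate = 100)
    expect_gt(max(abs(without$zf)), 2 * max(abs(with_n$zf)))
  }
})

test_that("length-n evidence requires genuinely chained activations", {
  paths <- list(1:4, 5:8)
  l3 <- lengthn_sequenceness(ab_bc_Y(chained = TRUE, seed = 12), paths,
                             n = 3, lags_ms = c(40, 50, 60), rate = 100)
  expect_gt(l3$diff[l3$lag_ms == 50], 0.05)
  expect_error(lengthn_sequenceness(bump_Y(100), paths, n = 5), "n <= ")
  expect_error(lengthn_sequenceness(bump_Y(60), paths, n = 3,
                                    lags_ms = c(300), rate = 100),
               "exceeds the data length")
})
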