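# Disjoint-support patterns: state k lives on channels (k-1)*4 + 1..4.
support_patterns <- function(n_states = 4L, per = 4L) {
  M <- matrix(0, n_states, n_states * per)
  for (k in seq_len(n_states)) M[k, (k - 1L) * per + seq_len(per)] <- 0.5
  structure(list(patterns = M, evoked_latency_ms = 200, n_states = n_states,
                 n_channels = n_states * per, seed = NA_integer_),
            class = "pattern_set")
}

test_that("decoders separate orthogonal patterns and weight their support channels", {
  p <- support_patterns()
  ep <- simulate_localizer(p, n_trials_per_state = 10, noise_sd = 0.02, seed = 1)
  d <- train_decoders(ep, train_time_ms = 200, l1_penalty = 0.01, seed = 1)
  X <- ep$trials[, , which(ep$times == 200)]
  pr <- plogis(sweep(X %*% t(d$weights), 2, d$intercepts, "+"))
  expect_equal(mean(max.col(pr) == ep$labels), 1)
  for (k in 1:4)
    expect_true(which.max(abs(d$weights[k, ])) %in% ((k - 1) * 4 + 1:4))
})

test_that("sparsity is monotone in the l1 penalty", {
  lz <- quick_localizer(n_channels = 24, n_states = 4, seed = 2)
  nz <- vapply(c(0.002, 0.01, 0.03, 0.1, 0.3), function(lam) {
    d <- train_decoders(lz$epochs, train_time_ms = 200, l1_penalty = lam,
                        seed = 3)
    sum(d$weights != 0)
  }, numeric(1))
  expect_true(all(diff(nz) <= 0))
})

test_that("training at the evoked latency beats training at onset", {
  lz <- quick_localizer(seed = 4, noise_sd = 0.25)
  a200 <- cross_validate(lz$epochs, times = 200, l1_penalty = 0.01,
                         folds = 4, seed = 1)$accuracy
  a0 <- cross_validate(lz$epochs, times = 0, l1_penalty = 0.01,
                       folds = 4, seed = 1)$accuracy
  expect_gt(a200, a0)
  expect_gt(a200, 0.5)          # far above 1/8 chance at this SNR
})

test_that("applying decoders matches the logistic closed form and saturates", {
  p <- support_patterns()
  ep <- simulate_localizer(p, n_trials_per_state = 10, noise_sd = 0.02, seed = 5)
  d <- train_decoders(ep, train_time_ms = 200, l1_penalty = 0.01, seed = 5)
  zero <- structure(list(data = matrix(0, 16, 7), rate = 100),
                    class = "sensor_recording")
  Y0 <- apply_decoders(d, zero)
  expect_equal(Y0$values, matrix(plogis(d$intercepts), 7, 4, byrow = TRUE),
               tolerance = 1e-9)
  big <- structure(list(data = matrix(50 * p$patterns[2, ], 16, 3), rate = 100),
                   class = "sensor_recording")
  Yb <- apply_decoders(d, big)
  expect_gt(min(Yb$values[, 2]), 0.999)
  expect_error(apply_decoders(d, structure(list(data = matrix(0, 5, 3),
                                                rate = 100),
                                           class = "sensor_recording")),
               "channel mismatch")
})

test_that("decoding is invariant to a consistent channel permutation", {
  lz <- quick_localizer(n_channels = 16, n_states = 4, seed = 6)
  d <- train_decoders(lz$epochs, train_time_ms = 200, l1_penalty = 0.01, seed = 6)
  set.seed(7)
  rec <- structure(list(data = matrix(rnorm(16 * 50), 16, 50), rate = 100),
                   class = "sensor_recording")
  Y1 <- apply_decoders(d, rec)
  perm <- sample(16)
  d2 <- d; d2$weights <- d$weights[, perm]
  rec2 <- rec; rec2$data <- rec$data[perm, ]
  Y2 <- apply_decoders(d2, rec2)
  expect_equal(Y1$values, Y2$values, tolerance = 1e-12)
})

test_that("decoder spatial correlation has unit diagonal and obvious limits", {
  d <- structure(list(weights = rbind(c(1, 0, 0, 1), c(0, 1, 1, 0)),
                      intercepts = c(0, 0), train_time_ms = 200,
                      l1_penalty = 0.1, n_states = 2L),
                 class = "decoder_set")
  C <- decoder_spatial_correlation(d)
  expect_equal(diag(C), c(1, 1))
  d$weights <- rbind(c(1, 2, 3, 4), c(2, 4, 6, 8))   # identical up to scale
  expect_equal(decoder_spatial_correlation(d)[1, 2], 1)
})

test_that("shuffled labels decode at chance", {
  lz <- quick_localizer(n_channels = 24, n_states = 4,
                        n_trials_per_state = 16, seed = 8)
  ep <- lz$epochs
  set.seed(9)
  ep$labels <- sample(ep$labels)
  acc <- cross_validate(ep, times = 200, l1_penalty = 0.01, folds = 4,
                        seed = 2)$accuracy
  expect_lt(abs(acc - 0.25), 0.12)
})

test_that("leave-one-stimulus-out guards its preconditions", {
  lz <- quick_localizer(n_channels = 16, n_states = 4, seed = 10)
  ep <- lz$epochs
  expect_error(cross_validate(ep, "leave_one_stimulus", times = 200),
               "stimulus")
  ep$stimulus <- ep$labels     # one stimulus per class
  expect_error(cross_validate(ep, "leave_one_stimulus", times = 200),
               ">= 2 stimuli")
})

test_that("sensor contribution ranks informative channels above noise channels", {
  # signal confined to channels 1..8 of 20
  M <- matrix(0, 4, 20)
  for (k in 1:4) M[k, (k - 1) * 2 + 1:2] <- 0.7
  p <- structure(list(patterns = M, evoked_latency_ms = 200, n_states = 4L,
                      n_channels = 20L, seed = NA_integer_),
                 class = "pattern_set")
  ep <- simulate_localizer(p, n_trials_per_state = 10, noise_sd = 0.1, seed = 11)
  sc <- sensor_contribution(ep, n_iter = 60, subset_size = 6,
                            l1_penalty = 0.01, folds = 3, seed = 12)
  expect_lt(stats::wilcox.test(sc[1:8], sc[9:20], alternative = "greater",
                               exact = FALSE)$p.value, 0.01)
  # degenerate single iteration: unsampled channels are NA
  sc1 <- sensor_contribution(ep, n_iter = 1, subset_size = 6,
                             l1_penalty = 0.01, folds = 3, seed = 13)
  expect_equal(sum(!is.na(sc1)), 6)
})

test_that("residualizing factor decoders projects out stimulus weight spans", {
  set.seed(14)
  stim_w <- matrix(rnorm(4 * 12), 4, 12)
  stim <- structure(list(weights = stim_w, intercepts = numeric(4),
                         train_time_ms = 200, l1_penalty = 0.1, n_states = 4L),
                    class = "decoder_set")
  groups <- list(1:2, 3:4)
  # factor weights = exact linear combination of their stimuli -> residual ~ 0
  fac_w <- rbind(2 * stim_w[1, ] - stim_w[2, ], stim_w[3, ] + stim_w[4, ])
  fac <- structure(list(weights = fac_w, intercepts = numeric(2),
                        train_time_ms = 200, l1_penalty = 0.1, n_states = 2L),
                   class = "decoder_set")
  out <- residualize_factor_decoders(fac, stim, groups)
  expect_lt(max(abs(out$weights)), 1e-10)
  # residual is orthogonal to the regressor span
  fac$weights <- matrix(rnorm(2 * 12), 2, 12)
  out2 <- residualize_factor_decoders(fac, stim, groups)
  for (k in 1:2)
    expect_lt(max(abs(stim_w[groups[[k]], ] %*% out2$weights[k, ])), 1e-8)
  # already-orthogonal weights are unchanged (up to the centered intercept)
  w_orth <- rep(0, 12)
  base <- cbind(1, t(stim_w[1:2, ]))
  w_orth <- stats::residuals(stats::lm.fit(base, rnorm(12)))
  fac$weights <- rbind(w_orth, w_orth)
  out3 <- residualize_factor_decoders(fac, stim, groups)
  expect_equal(out3$weights[1, ], w_orth, tolerance = 1e-8)
})
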