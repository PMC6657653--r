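#' End-to-end seeded replay pipeline
#'
#' `run_pipeline()` chains the stages simulate -> preprocess -> train ->
#' decode -> sequenceness -> events on a single configuration, and returns a
#' JSON-serializable report. Given identical config and seed, the report is
#' bitwise identical.
#'
#' @name pipeline
NULL

#' Default pipeline configuration
#'
#' All values the analysis convention fixes are fixed here: a 200 ms
#' decoder-training slice; lags up to 600 ms; nuisance lags at
#' `dt + 100 ... dt + 600` ms; replay threshold at the 95th percentile with
#' a 100 ms refractory window; cluster-forming `t > 3.1` with 5000
#' permutations. Simulator values (channel count, event count, SNR, alpha
#' amplitude) are the package's documented synthetic world.
#'
#' @param ... named overrides, e.g. `run_config(sim = list(lag_ms = 30))`
#'   (partial lists are merged into the defaults).
#' @return a `run_config` list.
#' @export
run_config <- function(...) {
  cfg <- list(
    design = "study1",
    seed = 1L,
    sim = list(
      n_channels = 64L, n_states = 8L,
      n_trials_per_state = 24L,
      lag_ms = 50, direction = "forward", which_order = "rule",
      n_events = 60L, duration_s = 300, rate = 100,
      noise_sd = 0.2, alpha_amp = 0.5, amplitude = 1,
      envelope_width_ms = 100, evoked_latency_ms = 200,
      max_abs_cor = 0.3
    ),
    preprocess = list(highpass_hz = 0.5),
    decoder = list(train_time_ms = 200, l1_penalty = 0.01),
    sequenceness = list(max_lag_ms = 600,
                        nuisance_offsets_ms = seq(100, 600, 100),
                        n_perm = 100L),
    events = list(percentile = 95, refractory_ms = 100)
  )
  over <- list(...)
  merge_in <- function(base, over) {
    for (nm in names(over)) {
      if (is.list(base[[nm]]) && is.list(over[[nm]]))
        base[[nm]] <- merge_in(base[[nm]], over[[nm]])
      else base[[nm]] <- over[[nm]]
    }
    base
  }
  structure(merge_in(cfg, over), class = "run_config")
}

#' Run the full replay analysis pipeline
#'
#' Stages: build the task structure; draw state patterns; simulate the
#' localizer and the resting recording; high-pass the rest record; train
#' lasso-logistic decoders at the training slice; decode rest into
#' reactivation probabilities; compute the sequenceness curve with its
#' permutation threshold; detect replay onsets at the peak lag; score
#' detections against the simulation ground truth.
#'
#' @param cfg a `run_config`.
#' @param keep_stages also return the intermediate objects (recording,
#'   decoders, reactivations, ...) under `$stages`.
#' @return a `run_report` list: `peak_lag_ms`, `peak_diff`, `threshold`,
#'   `exceeds_threshold`, `n_events_detected`, `precision`, `recall`,
#'   `median_onset_error_ms`, `decoder_penalty`, `config_hash`, `seed`.
#' @export
run_pipeline <- function(cfg = run_config(), keep_stages = FALSE) {
  stopifnot(inherits(cfg, "run_config"))
  sm <- cfg$sim
  seed <- cfg$seed
  spec <- make_study_structure(cfg$design, seed = child_seed(seed, 1L))
  pat <- make_state_patterns(sm$n_channels, sm$n_states,
                             seed = child_seed(seed, 2L),
                             evoked_latency_ms = sm$evoked_latency_ms,
                             max_abs_cor = sm$max_abs_cor)
  loc <- simulate_localizer(pat, sm$n_trials_per_state, noise_sd = sm$noise_sd,
                            seed = child_seed(seed, 3L), rate = sm$rate,
                            envelope_width_ms = sm$envelope_width_ms,
                            amplitude = sm$amplitude)
  rest <- simulate_rest(pat, spec, which_order = sm$which_order,
                        lag_ms = sm$lag_ms, direction = sm$direction,
                        n_events = sm$n_events, alpha_amp = sm$alpha_amp,
                        duration_s = sm$duration_s, noise_sd = sm$noise_sd,
                        seed = child_seed(seed, 4L), rate = sm$rate,
                        envelope_width_ms = sm$envelope_width_ms,
                        amplitude = sm$amplitude)
  rec <- rest$recording
  if (!is.null(cfg$preprocess$highpass_hz))
    rec <- highpass_recording(rec, cfg$preprocess$highpass_hz)
  dec <- train_decoders(loc, train_time_ms = cfg$decoder$train_time_ms,
                        l1_penalty = cfg$decoder$l1_penalty,
                        seed = child_seed(seed, 5L))
  Y <- apply_decoders(dec, rec)
  P <- if (sm$which_order == "rule") spec$rule_order else spec$visual_order
  lags <- lag_grid(sm$rate, cfg$sequenceness$max_lag_ms)
  null <- permutation_null(Y, P, lags_ms = lags,
                           perms = cfg$sequenceness$n_perm,
                           seed = child_seed(seed, 6L),
                           nuisance_offsets_ms = cfg$sequenceness$nuisance_offsets_ms)
  pk_what <- if (sm$direction == "forward") "diff" else "reverse"
  pk <- peak_lag(null$curve, pk_what)
  ss <- replay_strength(Y, P, pk)
  ev <- detect_onsets(ss, cfg$events$percentile, cfg$events$refractory_ms)
  sc <- match_events(ev, rest$truth)
  report <- list(
    peak_lag_ms = pk,
    peak_diff = null$curve$diff[null$curve$lag_ms == pk],
    threshold = null$threshold,
    exceeds_threshold = null$exceeds,
    n_events_detected = length(ev$onsets),
    precision = sc$precision, recall = sc$recall,
    median_onset_error_ms = sc$median_onset_error_ms,
    decoder_penalty = dec$l1_penalty,
    config_hash = config_hash(unclass(cfg)),
    seed = seed
  )
  class(report) <- "run_report"
  if (keep_stages)
    attr(report, "stages") <- list(spec = spec, patterns = pat, localizer = loc,
                                   rest = rest, decoders = dec, Y = Y,
                                   null = null, strength = ss, events = ev)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("run_report [%s] seed %s\n", x$config_hash, x$seed))
  cat(sprintf("  peak lag %g ms (diff %.4g, threshold %.4g, %s)\n",
              x$peak_lag_ms, x$peak_diff, x$threshold,
              if (x$exceeds_threshold) "significant" else "n.s."))
  cat(sprintf("  events: %d detected, precision %.2f, recall %.2f, median onset error %.1f ms\n",
              x$n_events_detected, x$precision, x$recall,
              x$median_onset_error_ms))
  invisible(x)
}

#' Write a run report as JSON
#'
#' @param report a `run_report`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  writeLines(jsonlite::toJSON(unclass(report), auto_unbox = TRUE, digits = NA),
             path)
  invisible(path)
}
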