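library(megreplay)
p <- make_state_patterns(32, 8, seed = 1)
sp <- make_study_structure("study1")
out <- simulate_rest(p, sp, lag_ms = 50, n_events = 10, duration_s = 60, seed = 4, alpha_amp = 0.3)
tr <- out$truth
for (e in 1:3) { idx <- tr$sequence_ids == e; print(tr$event_states[idx]); print(diff(tr$event_times[idx])) }
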