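library(megreplay)
spec <- make_study_structure("study1")
print(spec)
cfg <- run_config(seed = 1L, sim = list(duration_s = 120, n_events = 60L, noise_sd = 0.1))
report <- run_pipeline(cfg)
print(report)
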