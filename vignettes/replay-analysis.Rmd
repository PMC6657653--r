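---
title: "Measuring fast neural replay: decoding, sequenceness, and event detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring fast neural replay}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(megreplay)
```

## The problem

During rest, the brain spontaneously reactivates representations of recently
experienced states in rapid, time-compressed sequences ("replay"). In
non-invasive multichannel recordings (MEG-like data) these events are not
directly visible: each state must first be *decoded* from sensor patterns,
and sequentiality must then be established statistically in the resulting
probability time series. This package implements that analysis chain
end-to-end, together with a synthetic data generator that provides ground
truth for validating every stage.

The task structure assumed throughout is a two-sequence design: eight
states form two disjoint chains of four, `A -> B -> C -> D` and
`A' -> B' -> C' -> D'` (the *rule-defined* order), presented visually in a
scrambled order. `make_study_structure()` builds both transition matrices:
in the `"study1"` design the scrambled stream preserves every individual
rule pair (pair stages `[CD, C'D'] [AB, A'B'] [BC, B'C']`); in `"study2"`
the presentation is a randomized permutation, alternating between the two
sequences within each stage, which guarantees that *no* directed rule pair
is ever experienced. Each state also carries factor labels — ordinal
position (1–4) and sequence identity (1–2) — supporting decoders of
abstract structure in addition to stimulus identity.

## The model

### Decoding

One L1-regularized binomial logistic classifier per state is trained on a
single time slice of labeled localizer epochs (default 200 ms after onset,
where the evoked response peaks). Negatives are the other states' trials
plus "null" samples from the pre-onset window; the null data lower the
classifiers' operating baselines so that all states can report low
probability simultaneously during rest. Applied to a resting recording, the
decoders give an `N x s` matrix `Y` of per-state reactivation probabilities
(independent binomials; rows do not sum to 1).

### Sequenceness

For a lag $\Delta t$ and target state $i$, we fit by OLS

$$Y_i(t) = \sum_{j=1}^{s} Y_j(t - \Delta t)\,\beta_{ji}(\Delta t)
  + \text{nuisance} + \text{const},$$

collecting the coefficients into an empirical transition matrix
$\beta(\Delta t)$ with rows indexing the *earlier* state. Evidence that
reactivations follow a hypothesized binary transition matrix $P$ is the
Frobenius inner product $Z^f_{\Delta t} = \langle \beta(\Delta t), P
\rangle$; backward evidence uses $P^\top$. Sequenceness is
$Z^f_{\Delta t} - Z^b_{\Delta t}$: any influence that is symmetric in time
— autocorrelation, common oscillations — loads both terms equally and
cancels. Positive values mean forward replay, negative reverse.

The nuisance block contains lagged copies of all state time series at
$\Delta t + 100, \dots, \Delta t + 600$ ms. Resting alpha (10 Hz) is the
motivating confound: a shared oscillation repeats every 100 ms, so these
regressors absorb it. Note what they protect: a common-phase oscillation
inflates $Z^f$ and $Z^b$ *symmetrically*, so the difference is already
insensitive to it; the nuisance set removes the inflation from the
directional projections themselves and thereby reduces the variance of the
difference (we verify the ~3x inflation of $|Z^f|$ and its removal in the
test suite).

Family-wise error over the lag grid (10–600 ms in sample-period steps) is
controlled with a max-statistic permutation null: state labels are permuted
(equivalently, rows and columns of $P$ together), the full curve is
recomputed per permutation, and the corrected threshold is the maximum over
permutations of the peak $|Z^f - Z^b|$. The permutation set is explicit and
user-controllable (`state_permutations()`): exhaustive for $s \le 5$
(position codes), a seeded uniform sample otherwise. The identity
permutation is never part of the null.

### Length-n sequences

Pairwise evidence cannot distinguish genuinely chained replay
(`A -> B -> C`) from independent pairwise co-activations (`A -> B` and
`B -> C` at unrelated times). `lengthn_sequenceness()` regresses the
terminal state on the origin state at $(n-1)\Delta t$ while *controlling*
for the intermediate states at their multiples of $\Delta t$; the origin
coefficient is the extra evidence for the full chain, averaged over all
length-$n$ subpaths of both sequences. The validation worlds make the
distinction explicit: in the "pairwise-only" world, whether an A precedes a
B-event and whether a C follows it are independent coin flips, so the
origin coefficient is zero in expectation even though both pairwise links
are strong.

### Replay onsets and event-locked spectra

Momentary replay strength is
$R(t) = \sum_i (YP)(t, i) \cdot Y(t + \Delta t, i)$ — the expected
next-state activation times the actually observed activation one lag later.
Onsets are samples strictly exceeding the 95th percentile of $R$ with no
suprathreshold sample in the preceding 100 ms ("replay-free" is interpreted
as no suprathreshold sample, not merely no detected onset). Detection is
invariant to positive rescaling of $R$ by construction.

Around onsets, `event_locked_power()` computes Morlet-wavelet power
(fixed cycle count, hence frequency-proportional bandwidth; default 7
cycles), averages over events and channels, and subtracts the per-frequency
mean of the −100…−50 ms baseline. Events with another event inside their
baseline window are excluded. Group-level inference uses a cluster-based
sign-flip permutation test (`cluster_permutation()`; cluster-forming
`t > 3.1`, 5000 permutations by default, cluster mass = summed t,
4-neighbourhood contiguity, positive clusters).

### Cross-code lags

`cross_code_lag()` applies the same lagged-OLS apparatus across two decoded
code sets (e.g., position codes versus stimulus codes) under a rectangular
pairing matrix: forward evidence is the pairing-consistent prediction of
code *b* by lagged code *a*, reverse the transpose direction. This is how
"the abstract code leads the sensory code by ~50 ms" style questions are
asked. `onset_coincidence()` tests whether a single reactivation series is
elevated at detected onsets against a circular-shift null (shifts preserve
autocorrelation, unlike onset relabeling).

## The synthetic world

`make_state_patterns()` draws unit-norm random sensor topographies per
state (pairwise |r| < 0.3 by redraw, or exactly orthogonal on request).
`simulate_localizer()` injects each trial's pattern under a half-cosine
envelope (default width 100 ms — the evoked waveform is a modeling choice,
not something the analysis convention fixes) at a 200 ms latency, plus
white sensor noise; the pre-onset window provides the null data.
`simulate_rest()` injects four-state chain events with consecutive
activations exactly `lag_ms` apart, adds white noise and a 10 Hz sinusoid
with one fixed random topography per run (so the nuisance regressors are
genuinely needed), and returns full ground truth. All functions are
deterministic given their seed.

What the generator does *not* emulate: realistic head geometry or source
mixing, eye-blink/mains artifacts, non-stationary noise, clustered
inter-event intervals, and the unknown true SNR of spontaneous
reactivation. A green recovery test therefore establishes the correctness
of the *analysis machinery* under a known world, not sensitivity on any
particular real dataset.

### Operating points

Two documented regimes are used in tests (amplitudes are relative to
unit-norm patterns):

* **Lag recovery (t1 world).** 64 channels, 24 localizer trials/state,
  300 s of rest at 100 Hz with 60 forward rule-order events at 50 ms lag,
  `noise_sd = 0.2`, `alpha_amp = 0.5`. The forward sequenceness peak lands
  on 50 ms in essentially every seed (mode over 10 seeds is the reported
  acceptance value).
* **Event detection.** 0.5 events/s at `noise_sd = 0.1`. Because the onset
  threshold is a fixed percentile of R, the suprathreshold budget is always
  5% of samples; precision can only be high when replay actually occupies a
  comparable fraction of the record. This density is consistent with
  empirical reports that resting replay events are frequent and clustered.
  At this operating point precision and recall exceed 0.9 and the median
  onset error is within the 50 ms envelope half-width.

The SNR floor for lag recovery was established once by sweeping noise
levels (peak-lag mode remains 50 ms up to at least `noise_sd = 0.2` with
occasional one-step excursions per seed) and is not revisited by the tests.

## Numerical choices

* Lag grid = sample period (10 ms at 100 Hz); peak ties break toward the
  smallest lag, deterministically.
* Rows of the lagged design with any undefined (pre-record) value are
  dropped listwise; edge handling is not part of the analysis convention.
* OLS via QR; rank deficiency raises an error naming the pivoted-out
  columns rather than silently dropping them.
* Decoder probabilities are clamped to `(1e-12, 1 - 1e-12)` before
  regression.
* glmnet is run along a short decreasing lambda path ending at the target
  penalty (single-lambda calls can fail to converge on near-separable
  subsets); no feature standardization (all channels share units). The
  default penalty can be chosen by leave-one-run-out cross-validation over
  the grid {0.001, 0.003, 0.01, 0.03, 0.1} (`tune_penalty()`); ties prefer
  the sparser model.
* The first-order high-pass is a bilinear-transform one-pole filter,
  causal by default with a zero-phase (forward-backward) option; the −3 dB
  point sits at the cutoff. Resampling is Fourier-domain truncation at the
  new Nyquist (band-limited interpolation and anti-aliasing in one step);
  the new Nyquist bin is zeroed to keep the output exactly real.
* The preprocessing order follows the convention resample-then-filter.

## Open design points, resolved

* **Residualizing factor decoders** operates on weight vectors (regress the
  factor decoder's weights on its constituent stimuli's weights, keep the
  residual), not on decoded time series: it is the spatial pattern overlap
  one wants to remove, and weight-space residualization leaves the decoder
  applicable to new data.
* **Null-to-positive ratio** for decoder training defaults to one state's
  positive count per classifier, exposed as `null_per_state`.
* **Permutation count for 8-state nulls** defaults to a seeded sample of
  100–1000 rather than all 8! relabelings; the max-statistic threshold is
  monotone in the set, so larger samples are strictly more conservative.
* **Onset-coincidence statistic** is the mean-at-onsets against a
  circular-shift null (a correlation-style variant would weight strength;
  the mean is the more robust default at desk scale).

## Known limitations

Sequenceness magnitudes depend on decoder calibration and are not
comparable across decoder sets; only within-curve structure (peak location,
threshold exceedance, sign) is interpreted. The cluster test assumes
exchangeability under sign flips across subjects. The event detector
inherits the percentile threshold's scale-free but budget-fixed behaviour
discussed above. None of the anatomical questions (source localization,
region contrasts) are in scope.
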