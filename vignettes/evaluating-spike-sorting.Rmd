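---
title: "Evaluating spike sorting against ground truth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating spike sorting against ground truth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spikescore)
```

# The problem

A spike sorter turns a multichannel extracellular voltage trace into a set
of labeled spike trains, one per putative neuron. When ground truth exists —
a paired intracellular recording, or a simulation where every inserted event
is known — the sorter's output can be scored unit by unit. `spikescore`
implements that scoring pipeline: spike-train matching, per-unit metrics,
quality metrics usable without ground truth, and study-level aggregation,
together with a synthetic generator that makes the whole stack testable in
isolation.

# Matching and per-unit metrics

A sorted event matches a true event when their times differ by at most a
tolerance Δ, 1 ms by default. Results are insensitive to the exact value as
long as Δ stays below half the refractory period of any true neuron; under
that assumption a single sorted event can never account for two true events
of the same unit. The match count for a (true unit, sorted unit) pair is the
number of true events with *at least one* sorted event in their window —
multiple sorted events inside one window count once. `count_matches()`
implements this as a vectorized interval search and is tested for exact
equality against a quadratic brute-force evaluation on hundreds of random
instances.

Because data arrive in sample units, Δ is converted with
`delta_samples = round(delta_ms × rate / 1000)` (floored at 1) and the
comparison `|t − s| ≤ delta_samples` is done in integer samples; fractional
event times are tolerated but compared after this rounding. Ground-truth
trains that violate the refractory assumption (any within-unit gap below
2Δ) are still scored literally, with a warning.

From the match count, misses and false positives follow by subtraction, and
the pair accuracy `a = n_match / (n_match + n_miss + n_fp)` balances both
error types. Each true unit is assigned its best-matching sorted unit by
maximizing pair accuracy, with deterministic tie-breaking toward the
smallest sorted label; when the best accuracy is zero the unit is reported
unmatched with all metrics zero. Several true units may legitimately share a
best match (e.g. after a merge failure); `compare_sorting()` reports the
shared labels rather than forbidding them. No penalty is applied for sorted
units that match nothing — false-positive *units* are out of scope here, as
is any confusion-matrix analysis.

`categorize_events()` labels individual events (matched / missed /
false-positive) for waveform-level displays. It uses a greedy one-to-one
assignment (each true event takes the nearest unused sorted event in its
window) so both sides' matched counts agree; under the refractory assumption
this equals the existence count used for the metrics.

# Quality metrics

SNR is measured on a bandpass-filtered trace. The filter multiplies the FFT
of each full channel by the real gain

$$A(f) = \tfrac12\sqrt{1+\mathrm{erf}\!\left(\frac{|f|-f_{\min}}{w_{\text{low}}}\right)}
             \sqrt{1-\mathrm{erf}\!\left(\frac{|f|-f_{\max}}{w_{\text{high}}}\right)}$$

with `fmin = 300` Hz, `fmax = 6000` Hz and roll-off widths 100 and 1000 Hz,
then inverts the FFT. The square root on each factor makes the passband gain
exactly 1 (without them it would be 2, which no self-consistent reading
supports); the gain is ≈ 0.7071 at each band edge and ≤ 0.005 at DC.
Negative frequencies use `A(|f|)`, so real input stays real. One full-length
FFT per channel is used — desk-scale recordings fit in memory comfortably,
and no windowing artifacts arise. Note the passband is flat to about 1e-3
except within ~2 roll-off widths of the edges (at 4000 Hz the deviation is
1.2e-3).

The noise level is the median absolute deviation of the filtered trace
divided by 0.6745 — a robust estimate of the noise standard deviation that
ignores the spikes riding on it. The constant is passed explicitly to
`stats::mad()` rather than relying on its rounded default. SNR is the peak
absolute amplitude of the unit's average waveform (window 1 ms before to
2 ms after the event — wide enough for typical spike widths; the window is a
package choice, with boundary-clipped events dropped and counted) divided by
the noise on the channel where the peak occurs. Only that channel's samples
feed the noise estimate. SNR is invariant under rescaling the whole
recording, and a zero noise estimate is flagged as infinite SNR rather than
an error.

The ISI-violation ratio divides the observed count of inter-spike intervals
below 2.5 ms by the count expected from a homogeneous Poisson process at the
unit's mean rate: each of the N−1 intervals falls below t_ref with
probability `1 − exp(−λ t_ref)`, λ = N/T, so
`E = (N−1)(1 − exp(−λ t_ref))`. This normalization is chosen so a Poisson
train calibrates to 1 by construction; alternative pairwise-rate formulas
would change the ratio only by a near-constant factor. With fewer than two
events the ratio is undefined and flagged `NA`.

`fit_accuracy_predictor()` regresses per-unit accuracy on SNR, firing rate
and log ISI-violation ratio (OLS with intercept), the standard exercise for
asking which quality metrics predict accuracy when ground truth is absent.
Zero ratios are floored at half the smallest positive observed value before
the log; collinear predictors are dropped with a warning.

# Aggregation and missing data

Study tables average the chosen per-unit metric *unweighted* over
ground-truth units with SNR at or above a threshold (default 8) — never
weighting by event counts — and roll studies up to study sets as the
unweighted mean of study means (the roll-up rule is a package choice; only
the per-study averaging is canonical). When a sorting run fails or times
out, excluding it would flatter sorters that happen to crash on hard
recordings, and imputing zero would punish them; instead the per-recording
mean accuracy is imputed by ordinary least squares on the sorters with no
missing data, evaluated at the same recordings, with predictions clipped to
[0, 1]. The regression operates on per-recording means (one model per
sorter and study set) because whole runs, not single units, go missing. To
combine imputed recordings with observed units while keeping the unit-level
average exact, an imputed recording contributes its mean weighted by its
count of qualifying ground-truth units — a quantity known independently of
the failed sorter. When no complete sorter exists or the fit is
under-determined, the fallback is the sorter's observed mean (logged); with
nothing observed the cell stays missing. Counts of units above an accuracy
threshold are *never* imputed — missing runs simply contribute nothing and
the cell is flagged incomplete.

# The synthetic generator

`simulate_recording()` emulates the phenomenological simulation style of
benchmark study sets: smooth biphasic templates (difference of Gaussians,
1 ms before / 2 ms after the event) on randomly placed sources whose
per-channel amplitude decays exponentially with electrode distance
(25 µm constant by default, a typical cortical length scale); Poisson event
times thinned to enforce within-unit gaps of at least 2 × 1 ms so the
matching assumption holds by construction (rates high enough that thinning
would remove over half the events are rejected); per-event amplitude
scaling from Gamma(k, 1/k) with k = 20 by default — mean 1 and ~22%
coefficient of variation, a realistic amplitude jitter given that only the
distribution family is canonical; and iid Gaussian noise. Optional drift
moves each unit's source linearly or sinusoidally (±10 µm over a 600 s
period by default) and re-derives the spatial profile per event by
Gaussian-kernel interpolation over a 0.5 µm virtual vertical grid; zero
displacement reproduces the static simulation bit for bit.

Target SNR is defined operationally: the generator calibrates inserted
amplitudes so that `compute_snr()` — whose bandpass attenuates the iid
noise by the factor `sqrt(mean A(f)²)` and the template peak slightly —
recovers the requested value. `make_templates()` alone keeps the plain
normalization (peak = target × noise sd) for direct inspection.

What the generator does *not* emulate: spectrally colored or spatially
correlated noise, overlapping-spike statistics of dense probes, bursting
with amplitude decrement, electrode nonstationarities other than smooth
drift, and biophysical waveform diversity. Tests passing on this generator
therefore validate the *scoring machinery*, not any claim about how well a
sorter handles real tissue.

`perturb_sorting()` turns ground truth into pseudo-sortings with known
expected metrics — deletions (recall ≈ 1 − p), uniform insertions
(precision ≈ kept/(kept+inserted)), sub-tolerance timing jitter, merges and
splits — which is what makes the comparison code testable end to end.

# Numerical and testing choices

All randomness is seeded; the generator restores the caller's RNG state.
Recordings are stored channels × samples as float32 MDA with a JSON sidecar;
firings as 3 × L matrices (channel, sample, label) in MDA or CSV. MDA headers
follow the little-endian signed-int32 convention with negative type codes;
unsigned 32-bit payloads go through explicit byte assembly because R lacks
an unsigned 32-bit integer type. Content provenance uses `sha1://` URIs with
a local directory store standing in for a networked content-addressable
system.

Test problem sizes are chosen to keep the suite fast while leaving
Monte-Carlo margins: the end-to-end identity and perturbation checks share
one 8-channel, 5-unit, 300 s simulation (~2400 events per unit, so a 20%
deletion rate is recovered within ±0.03 with >3σ margin); SNR recovery uses
60 s single-unit recordings (~600 events); ISI calibration pools 40/8/2
independent hour-long trains at 1/5/20 Hz because the expected violation
count at 1 Hz is only ~9 per train, making a single train's ratio far too
noisy to check at ±10%.

# Known limitations

Matching is evaluated per (unit, unit) pair independently; no global
assignment is enforced, and false-positive units are unpenalized. The
imputation model is linear across sorters with no uncertainty estimate. The
ISI-vr expectation assumes homogeneous Poisson firing; strongly bursty units
inflate the ratio by design. The filter's full-length FFT is O(n log n) for
composite lengths but degrades for pathological (large prime) sample counts.
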