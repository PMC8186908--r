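---
title: "Methods: detecting and characterizing population ON/OFF cortical responses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting and characterizing population ON/OFF cortical responses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(popgate)
```

## The phenomenon and the analysis model

Auditory cortex can respond to a fixed stimulus in an all-or-none fashion:
on some trials the whole imaged population activates ("population ON"), on
others nothing happens ("population OFF"), while the inferior colliculus and
the auditory thalamus (MGB) respond every time. `popgate` packages the
analysis chain needed to quantify this gating across modalities and a
phenomenological generative model of it.

The analysis rests on three quantitative pillars:

1. **Trial classification.** Every trial's response trace is converted to
   percent Δf/f against a 2 s pre-stimulus baseline and classified ON iff
   the in-window peak exceeds a z-score of 3 (relative to the baseline mean
   and SD on the Δf/f scale) *and* shows a resolved rising and falling
   phase. Percent-ON is then summarized per stimulus level or current, and
   the level dependence is fitted with a binomial-logistic gating curve
   `p(level) = 1/(1 + exp(-(level - s50)/k))`.
2. **Thalamic synchrony.** For each trial, the peak latencies of all
   *activated* cells are collected and their unbiased sample variance is
   the (de)synchronization measure; ON and OFF trials are paired within a
   field of view and compared with a paired test.
3. **Synaptic charge.** Voltage-clamp currents (+10 mV for IPSCs, -60 mV
   for EPSCs) are integrated (trapezoidal, baseline-subtracted, rectified)
   over a post-stimulus window; per cell, the mean OFF-trial charge is
   normalized to the mean ON-trial charge, so 1 means "no state
   difference" and values above 1 mean more charge on OFF trials.

Assumptions: traces are uniformly sampled and baseline-stationary over the
2 s pre-stimulus window; the baseline mean is strictly positive (raw
fluorescence counts); response windows are half-open `[onset, onset + W)`;
pixel coordinates are 0-based `(row, col)` and ellipse membership uses the
inclusive test `((r-c_r)/r_r)^2 + ((c-c_c)/r_c)^2 <= 1`.

## Detection: operationalizing "a rising and falling phase"

The z > 3 criterion is exact as stated; the shape criterion needs a
definition. A tempting one — strict monotone runs of two samples on each
side of the detected peak — turns out to be unusable on sampled data: right
at a smooth maximum the expected increment between adjacent samples is
approximately zero, so strict per-sample monotonicity next to the peak
fails with probability approaching one half *at any signal-to-noise ratio*.
With the indicator kernels and frame rates used here (calcium
τ = 0.05/0.6 s at 10 Hz; FA τ = 0.5/2.5 s at 4 Hz) that rule caps
sensitivity near 60–75% even for very large transients, which no
z-threshold adjustment can repair.

`detect_evoked()` therefore uses a flanking-support formulation:

- the raw in-window maximum provides the amplitude, z-score and latency
  (ties to the earliest sample);
- shape is assessed at the in-window maximum of a 3-sample moving-average
  copy of the trace, a noise-robust peak locator;
- *rising phase*: the smoothed peak is interior to the window and the
  `min_rise_samples` (default 2) smoothed samples before it lie strictly
  below it — this rejects monotone drift and window-edge artifacts;
- *falling phase*: the `min_fall_samples` (default 2) **raw** samples after
  the smoothed peak stay above baseline + `support_fraction` (default
  0.25) of the smoothed peak height — a decay resolved above the noise
  floor, which rejects single-sample noise spikes. Raw flanking samples
  are used because, under the null, they are independent of the smoothed
  peak value, which makes the criterion a strong noise filter while a real
  τ ≳ 0.6 s decay passes it with a margin of several baseline SDs.

The choice of `support_fraction = 0.25` is an SNR argument, not a fit to
data: at a threshold-level (z ≈ 3) noise peak the support level sits around
0.8 baseline SDs, which two independent noise samples rarely both clear,
while two samples into a calcium decay the kernel still retains ≳ 70% of
its peak. The operating characteristics that result — the null
false-positive rate, and sensitivity/specificity on transients with peak
z ≥ 6 — are measured, not asserted, by `scripts/acceptance.R` and the
acceptance test suite (10,000 simulated null trials; 4,000 signal trials).

Rejections are labelled `low_z`, `no_rise`, `no_fall` in that order of
precedence, so a sub-threshold monotone ramp reports `low_z`.

## Δf/f conventions

- `f0` is the mean raw signal over `[onset - 2 s, onset)`; Δf/f is reported
  in percent everywhere.
- The in vivo two-condition design (10 s silent C0, 10 s C1 with the sound
  at the 5th second) is mapped per pixel as **C1 − C0**, each condition
  using the mean over its 1 s response window against its own 5 s
  pre-window baseline. The difference is oriented so that sound-evoked
  activation is positive; the map is antisymmetric under swapping the
  conditions.
- Neuropil correction operates on raw counts *before* Δf/f:
  `corrected = cell_mean - 0.4 * background_mean`, with the background an
  ellipse of 2.25× the cell radii minus the union of all cell ROIs. For
  mask-only cell ROIs the equivalent ellipse is the mask centroid with
  per-axis radii of twice the RMS pixel deviation (the uniform-ellipse
  second-moment radius).

## Tunable parameters

| Parameter | Default | Unit | Rationale |
|---|---|---|---|
| `z_threshold` | 3 | – | the study's stated criterion |
| `baseline_len_s` | 2 | s | stated baseline window |
| `response_window_s` | 1 (in vivo) / 3 (slice) | s | 1 s stated for the in vivo design; slice FA transients span seconds |
| `min_rise_samples`, `min_fall_samples` | 2 | samples | minimal resolved flank |
| `support_fraction` | 0.25 | – | see detection section |
| `shape_smooth_samples` | 3 | samples | shortest symmetric smoother |
| neuropil `ellipse_scale` | 2.25 | – | stated |
| neuropil `subtraction_fraction` | 0.40 | – | stated |
| histogram `bin_width` | 1 | % Δf/f | stated bin size |
| LFP low-pass | 300 | Hz (−3 dB) | stated; Gaussian FIR, zero phase |
| LFP notch | 60 (Q = 30) | Hz | stated frequency; biquad applied forward–backward |
| Vm decimation | 2000 | Hz | stated analysis rate |
| spike excision | > −20 mV ± 2 ms | – | conservative, parameter-light |
| artifact blanking | 10 | ms | covers electrical-stimulus artifacts |
| PSC window | 1 | s | covers the evoked current; configurable |

## The synthetic generator: what it emulates and what it does not

`gating_params()` fixes the study conditions: levels 37–80 dB SPL, logistic
gating with `s50 = 55` dB and `k = 5`; an ON-trial cortical amplitude of
10% Δf/f on a baseline of 100 counts with 1% Gaussian sensor noise (so the
default peak z ≈ 10); difference-of-exponential indicator kernels
(calcium 0.05/0.6 s, FA 0.5/2.5 s, respecting the 10 Hz / 4 Hz acquisition
rates); thalamic cells responding on *every* trial with latency jitter
σ_OFF = 2 σ_ON; an MGB IPSC OFF/ON charge ratio ρ = 1.5 with
state-independent EPSCs and cortical PSCs present only on ON trials; half
of MGB cells receiving their OFF-trial IPSCs 20 ms early; and UP states as
a plateau from −65 to −50 mV for 0.5 s carrying 20 Hz Poisson spikes.

Two generator values deserve comment. The thalamic latency mean (1.0 s) and
jitters (σ_ON = 0.15 s, σ_OFF = 0.3 s) are chosen so the jitter exceeds the
100 ms calcium frame period: a jitter below one frame period is not
resolvable in sampled peak latencies (quantization variance
`Δ²/12 ≈ 8 × 10⁻⁴ s²` plus peak-relocation noise would dominate), and
calcium peak times are in any case much slower than the underlying
electrical events. Event times are truncated to `[0.05 s, post - 0.8 s]`,
placed > 3 SD from the mean so the truncation bias on the variance is
negligible. Second, peak-latency measurement noise adds a near-constant
variance (~5 × 10⁻³ s² at these settings) to both states, so the *measured*
OFF/ON variance ratio sits slightly below the generative ratio of 4 — the
acceptance script reports the measured value.

Deliberately not modelled: photobleaching and slow drift (kept out so
closed-form oracles are exact), hemodynamic or motion artifacts, biophysics
of the corticothalamic loop (the generator is phenomenological), spike
shape diversity, and any trial-history dependence — gating is independent
Bernoulli per trial, with an optional `first_trial_on` constraint (off by
default) mirroring the empirical observation that OFF responses do not
occur on the first stimulation. Passing tests on these data therefore
demonstrate the correctness of the *computations*, not robustness to every
artifact of real recordings.

## Numerical choices and degenerate inputs

- **Peak ties** go to the earliest sample, making classification
  deterministic.
- **Baselines with zero SD** (constant traces) are an error for detection:
  a z-score is undefined.
- **RM-ANOVA degeneracies**: identical conditions give F = 0; a perfect
  condition effect with zero residual gives F = ∞; post hoc pairs with
  zero-variance differences report t = 0, p = 1 (or p = 0 for a nonzero
  constant difference).
- **Wilcoxon zeros** are dropped before ranking (the classical
  convention); with n ≤ 25 and untied ranks the two-sided p is exact
  (signed-rank distribution ≡ full 2ⁿ enumeration), otherwise the normal
  approximation with tie correction and continuity correction is used.
- **Lilliefors gate**: `nortest::lillie.test` for n ≥ 5; for n of 3–4 the
  same D statistic is referred to a 2,000-replicate Monte Carlo null.
- **Dunn post hocs** use the pooled-rank z with the standard tie correction
  and Bonferroni adjustment (`p_adj = min(1, m p)`), the adjustment also
  used for the RM-ANOVA pairwise t-tests.
- **Log base**: the amplitude–current fit regresses on log₁₀(current).
  R² is base-invariant; the slope is per decade.
- **LFP filtering** is zero-phase throughout: the Gaussian low-pass is a
  symmetric FIR (σ = √(ln 2)/(2π f₀), truncated at ±4σ, unit DC gain,
  reflected edges) and the notch is applied with `signal::filtfilt`. The
  Gaussian filter is *not* idempotent near its corner (applying it twice
  narrows the band by √2), so the idempotence property holds for
  LFP-band (≲ 40 Hz) content, which is what the response calls use.
- **Mixture fitting** uses `mclust` with G = 2 unequal-variance
  components; means are reported in increasing order and Ashman's D > 2
  declares bimodality. On truly unimodal data the two fitted components
  overlap heavily and D stays well below 2.
- **Latency-variance pairing**: the study's "n pairs" construction is not
  fully specified, so two rules are provided — nearest-in-time ON trial
  per OFF trial within a field of view (default; each ON used once), or
  one pair per field from the ON and OFF means. Neither is asserted to be
  the original; both feed the same paired tests.
- **Bundled datasets** are directory bundles (TIFF + annotated CSV + JSON
  + a versioned manifest) rather than a single binary container, keeping
  every member human-readable and diffable; `read_dataset()` validates all
  trial cross-references on load. Stacks with non-integer counts are
  stored as float32 with a JSON scale sidecar, lossless to single
  precision; integer stacks round-trip bit-exactly as uint16.

## Problem sizes used by the test suite

The acceptance checks run at the design sizes of the study where those are
meaningful and at desk scale otherwise: 10,000 null trials for the
false-positive rate; 4,000 transients at peak z = 6 for sensitivity;
200 trials per level across 9 levels (37–80 dB) for gating recovery;
14 ON/OFF pairs × 24 cells for the synchrony comparison, with 1,000
replicates for power and 2,000 for the null rejection rate; 20
voltage-clamped cells for the ρ recovery; 2,000 replicates per test for
the exchangeable-null type-I checks. A full run of the suite plus the
acceptance script completes in a few minutes on a single core.

## Known limitations

- The detector assumes a single evoked transient per window; multi-peaked
  responses are classified by their largest peak only.
- Peak latencies at 4–10 Hz frame rates carry quantization noise of order
  `Δ/√12`; latency *variances* are therefore upward-biased by a
  near-constant term, which cancels only partially in ON/OFF ratios.
- The LFP response call applies the imaging criteria to a rectified,
  smoothed, decimated envelope; this is an extension of the imaging rule
  (selected via configuration), not a criterion the original analysis
  states for LFPs.
- `reproduce_printed_stats()` recomputes the published paired-t, F and R²
  values from the deposited per-figure source tables, but those tables are
  not redistributable with the package; the corresponding acceptance check
  reports a failure when they are absent instead of passing vacuously.
- No motion correction, registration, hemodynamic correction, series
  resistance compensation, or spike sorting; inputs are assumed
  preprocessed to that point.
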