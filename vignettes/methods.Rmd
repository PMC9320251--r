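---
title: "Methods: walking-test HRV and chronotropic response"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: walking-test HRV and chronotropic response}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(walkHRV)
```

# The measurement problem

The autonomic nervous system modulates the heart beat to beat; the
resulting fluctuation of RR intervals (heart-rate variability, HRV) is a
non-invasive window on autonomic function. In frail older adults the
deficit is often invisible at rest and emerges only under a stressor, so
the protocol studied here wraps a moderate stressor — a 160 m walk at
self-selected pace — between two 5-min standing rests. The analysis asks
two questions: how does HR respond to and recover from the walk
(chronotropic response), and which resting HRV indices separate frail
from non-frail subjects well enough to serve as biomarkers (ROC
analysis).

This vignette documents the models, the tunable parameters, the numerical
choices, and the limits of what the package's synthetic data can show.

# Synthetic data: the IPFM model

No raw recordings ship with the package, so every stage is testable
against generated data with known ground truth.

RR series are generated by integral pulse frequency modulation (IPFM): a
beat is emitted whenever

$$\int_0^{t_k} \frac{1 + m(u)}{T}\,du = k,$$

with `T` the mean cardiac period and the modulation
`m(u) = a_LF sin(2π f_LF u) + a_HF sin(2π f_HF u) + ν(u)`. The IPFM model
is the standard way to prescribe spectral content exactly: a sinusoid at
`f` in `m` produces a tachogram line at `f`, so the spectral analysis can
be validated against construction. The noise term `ν` is built from
Gaussian increments low-pass filtered at 0.5 Hz (2nd-order Butterworth,
zero-phase), keeping the modulation band-limited below the upper HF edge;
its amplitude is rescaled to the configured SD. The invariant
`a_LF + a_HF + 3·sd(ν) < 1` keeps the instantaneous rate positive.

Numerically, the integral is accumulated by trapezoidal rule on a 100 Hz
grid and each integer crossing is refined by linear interpolation between
grid points, giving sub-millisecond beat placement without symbolic
integration. With zero modulation the crossings are exact: intervals
equal `meanRR` to floating precision (the unit tests assert 1e-9).

## Walking-test trajectories

The target HR is piecewise: a flat baseline at `hrBaseline`; during the
walk an exponential rise `hrBaseline + (hrMax − hrBaseline)(1 −
e^{−t/riseTau})` minus a slow linear pacing decline `paceDrift·t`; during
recovery an exponential decay with constant `recoveryTau` toward
`hrBaseline + recoveryOffset`. Two terms encode the frail phenotype:

* `recoveryOffset > 0` (bpm) — the subject does not return to baseline
  within the 5-min recovery, making the recovery-vs-baseline change
  ΔHR_RB positive.
* `paceDrift` (bpm/s) — without it an exponential rise is monotone, the
  smoothed maximum sits at the walk's end for *every* subject, and the
  time-to-maximum Δt cannot discriminate. A small decline after the
  initial effort (pacing adaptation, 0.02–0.05 bpm/s here) puts the peak
  at the closed-form time `t* = τ·ln(A/(τ·drift))`, which the response
  module recovers within ±2 s in the tests.

IPFM modulation is superposed multiplicatively on the instantaneous rate,
and the configured phase boundaries are attached to the output series
exactly.

## Synthetic ECG

Each beat contributes a Mexican-hat (Ricker) pulse (width 80 ms by
default, σ = width/6) centred at the continuous beat time; R amplitudes
are modulated sinusoidally at a configurable respiratory frequency — this
is the signal the EDR estimator recovers — and Gaussian noise is added. A
half-second lead-in keeps edge templates intact. The record keeps its
ground-truth beat times, so detector performance is scored exactly, not
against another algorithm. P and T waves, realistic QRS morphology and
arrhythmias are deliberately out of scope: the template has exactly
enough structure for a band-pass/derivative detector.

## The synthetic cohort

Group labels follow the study design (`C1` young, `C2` middle-aged, `nF`
non-frail older, `F` frail older; default sizes 21/16/15/28). The source
tables give medians per group but no generative parameters, so the
per-group distributions are the package's own choices, fixed once, tuned
to reproduce the *direction* of the observed group differences, not their
magnitudes:

| parameter | C1 | C2 | nF | F | rationale (direction) |
|---|---|---|---|---|---|
| baseline HR (bpm) | 81 ± 6 | 74 ± 6 | 76 ± 5 | 74 ± 6 | groups similar at rest |
| HR max target (bpm) | 107 ± 5 | 104 ± 6 | 98 ± 4 | 90 ± 4 | lower peak with age |
| rise τ (s) | 12 ± 2 | 13 ± 2 | 18 ± 3 | 55 ± 10 | frail respond slowly (Δt↑, vresp↓) |
| recovery τ (s) | 25 ± 5 | 30 ± 6 | 40 ± 8 | 90 ± 15 | slower recovery with frailty |
| recovery offset (bpm) | 0 | 0.5 | 0.5 | 4 ± 1.5 | ΔHR_RB > 0 only in frail |
| gait speed (m/s) | 1.30 | 1.25 | 1.00 | 0.70 | walk duration = 160 m / speed |
| LF amplitude | 0.085 | 0.070 | 0.050 | 0.035 | overall HRV falls with age |
| HF amplitude | 0.042 | 0.040 | 0.023 | 0.029 | LF:HF ratio lowest in frail → LF(nu)↓ |
| respiratory f (Hz) | 0.25 | 0.24 | 0.22 | 0.29 | frail breathe faster (EDR↑) |

The frail LF:HF *amplitude* ratio 0.035:0.029 puts the power fraction at
`0.035²/(0.035²+0.029²) ≈ 0.59`, i.e. LF(nu) near 60 against roughly 80
in the non-frail group — the direction and rough location of the observed
contrast. Everything downstream of these numbers (medians, AUCs) is
*recovered* by the pipeline, not asserted.

What the generator does **not** emulate: real beat-to-beat dynamics are
non-stationary and fractal; sinusoid-plus-noise modulation is neither.
Consequently the entropy and DFA indices of synthetic subjects do not
reproduce the real groups' ordering (real frail subjects show *lower*
SampEn and α₁; the synthetic frail group, with its relatively stronger HF
line, comes out more irregular). Tests passing on this cohort therefore
validate the *computations* and the response/spectral signature — they do
not show that the entropy indices would behave identically on real data.

# Beat detection and cleaning

The detector follows the canonical band-pass (5–15 Hz, zero-phase
2nd-order Butterworth) → five-point derivative → squaring → 150 ms
moving-window integration → adaptive threshold chain, with running
signal/noise peak estimates (`THR = noise + 0.25(signal − noise)`,
exponential updates with weight 0.125) and a 200 ms refractory period.
The named algorithm's constants are fixed per its canonical description
since the protocol source names the method without parameters. Each
accepted detection is refined to the raw-signal maximum within ±40 ms.
Degenerate inputs are contracts, not crashes: records under 2 s are
errors; a flat line returns an *empty* beat series.

Visual inspection of the RR series is replaced by a deterministic
surrogate: interval `i` is flagged when it deviates from the median of
its 11-interval window by more than 25 % of that median (window median
via `runmed`, global-median fallback below 11 intervals) or falls outside
the 250–3000 ms physiologic gate. A recording is excluded when *more
than* 5 % of intervals are flagged — strictly, so exactly 5 % is kept.
Flagged intervals are replaced by a natural cubic spline through the
unflagged intervals as a function of beat time ("third-order polynomial"
read as cubic-spline replacement, the standard practice, not a global
polynomial regression); runs longer than 5 consecutive flagged intervals
are refused with a warning rather than inventing physiology, and normal
intervals are never altered (asserted bitwise in the tests). The upstream
description is ambiguous about whether *all* intervals or only flagged
ones were interpolated; this module corrects flagged intervals only.

# HRV indices

All defaults live in `analysisSettings()`.

**Time domain.** SDNN uses the n−1 sample convention; every
variance-based index shares it so the Poincaré identities close. CV is
the conventional `100·SDNN/meanRR` (%); the source tables print CV values
about ten times this scale, which is inconsistent with their own SDNN and
mean RR columns — the package implements the conventional definition and
documents the discrepancy rather than matching the table's scale. pNNx
thresholds are strict (`> x` ms).

**Frequency domain.** The RR series is spline-interpolated (natural
cubic) onto a uniform 4 Hz grid — 4 Hz resolves the 0.4 Hz HF edge with
margin — then linearly detrended (configurable off; the detrend stands in
for smoothness-priors detrending, which the protocol source does not
describe). The PSD is a Welch average of Hann-windowed 64 s segments at
50 % overlap with per-segment mean removal: on a 5-min segment that gives
at least four averages while still resolving the 0.04 Hz LF edge
(Δf ≈ 0.016 Hz). Band powers are trapezoidal integrals with interpolated
band-edge ordinates; normalized units are `100·band/(LF+HF)`, chosen
because the reported normalized rows sum to ≈100. Undefined quantities
(zero LF+HF, zero HF) propagate as `NA` with a warning, never as zeros.
The Welch scaling is checked against Parseval (total power within 10 % of
the series variance on white noise).

**EDR.** The reference software's respiration estimator is unpublished;
the package's documented stand-in resamples the R-amplitude sequence at
4 Hz, detrends, and takes the Welch-PSD peak in 0.1–0.5 Hz (respiration
modulates R amplitude through electrode-axis motion). Without amplitudes
it falls back to the HF-band peak of the tachogram PSD (respiratory sinus
arrhythmia imprints the breathing rate there); the path used is part of
the return value. Records under 60 beats refuse the estimate.

**Poincaré.** `SD1 = RMSSD/√2` by the zero-mean second-moment convention
on successive differences, and `SD2 = √(2·SDNN² − SD1²)` with the
radicand clamped at zero (warning) against rounding. With these matched
conventions `SD1² + SD2² = 2·SDNN²` holds to 1e-6 on every fixture. (A
mean-subtracted variance of the differences would break the RMSSD
identity by `O(((last−first)/(n−1))²)`; the package prefers the exact
identities.)

**Entropies.** ApEn includes self-matches, SampEn excludes them (their
canonical definitions); both use Chebyshev distance, `m = 2`,
`r = 0.2·SD` of the segment. SampEn uses the same `N − m` template set
for both lengths. A constant segment returns 0 with a `degenerate` flag
by convention; zero (m+1)-matches make SampEn `NA` with a warning. Both
are verified against brute-force triple-loop oracles for every fixture of
length ≤ 50.

**DFA α₁** integrates the mean-centred series, splits it into
non-overlapping boxes of 4–11 beats (trailing partial box dropped),
removes a least-squares line per box, and fits `log₁₀F(n)` on `log₁₀n`.
One calibration fact matters when interpreting values: the textbook
"white noise → 0.5" is an asymptotic statement. Over boxes 4–11 the exact
discrete expectation for white noise is `E[F²(n)] = σ²(n²−4)/(15n)`,
whose log–log slope is 0.617 — the well-documented small-scale bias of
first-order DFA. The package implements the canonical estimator and its
tests assert this exact finite-size value (and ≈1.5 for Brownian noise,
≈1.0 for spectrally synthesized 1/f noise, where the bias is small); a
bias-corrected variant was considered and rejected because it is not what
the field's HRV software computes and it would distort the Brownian
calibration.

# Chronotropic response

Each interval belongs to the phase containing its *end* time; an interval
ending exactly on a boundary goes to the later phase (walk-onset effects
belong to walking). Phase mean HR is `60000/mean(RR)` over the phase. The
instantaneous HR curve `60000/RRᵢ` is smoothed by a 10 s centred moving
average before locating the maximum — beat-to-beat maxima are noise
dominated — and Δt is the time from walk onset to the *first* attainment
of the smoothed maximum (ties to the earliest; the Δt clock starts at
walk onset, the natural reading, since the baseline is defined as
pre-stimulus). `vresp = HRMax/Δt`, with Δt = 0 returning a missing value
flagged "instantaneous response" rather than an infinity. "HR during
walking" in the percentage change ΔHR_WB is read as the phase *mean*
(configurable to the maximum), since the source defines the contrast but
not the summary.

# Biomarker evaluation

ROC curves are built over all observed thresholds plus ±∞ sentinels, so
(0,0) and (1,1) are always on the curve; classification is non-strict on
the positive side. The orientation (whether low or high values indicate
frailty) is chosen automatically as the direction with AUC ≥ 0.5 and is
always printed with the cut-off as an explicit inequality. That matters
because the source's own tables are internally inconsistent on one row
(an LF/HF "greater than" rule alongside a frail group with *lower*
LF/HF); resolving orientation from data and printing it avoids imitating
the inconsistency.

The trapezoidal AUC equals the midrank Mann–Whitney estimator
`U/(n₁n₂)` (asserted exactly in the tests); its CI uses the Hanley–McNeil
standard error (the default family of the statistics package the study
used), with the radicand clamped at zero against rounding at AUC = 1. The
optimal cut-off minimizes the orthogonal distance `√(FPR² + (1−TPR)²)` to
the ideal corner (0, 1); ties break toward higher sensitivity, then
toward the threshold closest to the score median (infinite sentinels
lose). An exhaustive scan over every threshold is the test oracle.

Sensitivity, specificity, PPV and NPV are percentages with 95 % Wald
intervals `100(p̂ ± 1.96√(p̂(1−p̂)/n))` on their own denominators,
deliberately *not* clipped to [0, 100]: the unclipped Wald form is the
one that exactly regenerates the published intervals, including an upper
bound above 100 %. Each estimate always carries its own `n`, because the
published sample sizes are inconsistent between tables (one printed
specificity row back-solves only with 14, not 15, negative subjects).

Group statistics mirror the study's recipe: Shapiro–Wilk normality gate
logged per group, Kruskal–Wallis omnibus across ≥3 groups, pairwise
Mann–Whitney, paired Wilcoxon signed-rank for baseline-vs-recovery,
chi-squared for nominal variables switching to Fisher's exact test when
any expected cell is below 5 (the stated rule; note a rule-vs-example
ambiguity at expected counts of exactly 5, resolved in favour of the
rule). No multiplicity correction is applied by default, mirroring the
source analysis; Holm is available behind a flag.

# Pipeline and problem sizes

`runPipeline()` takes exactly one input source (simulation config XOR
file manifest), isolates per-subject failures in a run log that accounts
for every subject exactly once, and writes byte-identical CSVs under a
fixed seed. The acceptance script exercises ten cohorts of 30 frail + 30
non-frail subjects (600 subjects end to end, about a minute of
computation), a size chosen to give stable medians and ROC estimates
while keeping a full run interactive; unit tests use smaller records
(1–5 min) except the DFA calibrations, which need n = 10000 to pin the
scaling exponents.

# Known limitations

* The generator's sinusoid-plus-filtered-noise modulation does not
  reproduce fractal or entropy properties of real HR series (see above);
  group orderings for SampEn/ApEn/α₁ on synthetic cohorts are not
  evidence about real cohorts.
* The detector is tuned for single-lead, clean-to-moderately-noisy ECG;
  it performs no arrhythmia classification, and the artifact rule is a
  deterministic stand-in for expert visual inspection.
* EDR via R-amplitude modulation is a documented surrogate for an
  unpublished commercial estimator.
* 5-min spectral indices assume quasi-stationarity; the walking phase is
  too short and heterogeneous for spectral HRV, which is why only
  baseline and recovery are analysed in the frequency domain.
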