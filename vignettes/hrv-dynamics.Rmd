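---
title: "Methods: symbolic dynamics of heart-rate variability in hrvdyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: symbolic dynamics of heart-rate variability in hrvdyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hrvdyn)
```

## The model

A tachogram is the ordered series of normal-to-normal RR intervals
{RR(n), n = 0..N} of one recording, in milliseconds. Its first difference,
δRR(n) = RR(n) − RR(n−1), is the heart-rate *action* at beat n: a
deceleration (`d`) when positive, an acceleration (`a`) when negative and
no action (`0`) when zero. Because a digital recorder samples at a fixed
rate (128 Hz gives an 8 ms quantum, Δ = 7.8125 ms), actions live on an
integer lattice i = δRR/Δ with |i| ≤ M, where M is the largest absolute
index observed in the signal. Sliding windows of one, two and three
consecutive actions define the pattern spaces Π1, Π2 and Π3; their
empirical distributions are summarised by Shannon entropies (natural
logarithm, nats):

- E1, E2, E3 — entropies of Π1, Π2, Π3;
- ST = E2 − E1 — the conditional entropy of the next action given the
  current one, i.e. the entropy rate of a first-order Markov model of the
  action sequence;
- sTE = 2·E2 − E1 − E3 — the conditional mutual information
  I(Xₙ₋₂; Xₙ | Xₙ₋₁), a transfer-entropy-type measure of the memory that a
  first-order model cannot capture.

Two analytic limits anchor these definitions. If actions occur
independently, E2 = 2·E1 and E3 = 3·E1, hence ST = E1 and sTE = 0. If the
actions follow a first-order Markov chain, ST converges to the chain's
entropy rate while sTE still vanishes; sTE > 0 requires genuine
higher-order memory. A note on signs: some presentations write the pair as
E1 − E2 and (E2 − E3) − ST, which is the same magnitude with the opposite
sign; we use the orientation under which both quantities are nonnegative
for true distributions and the independence limits ST = E1 and sTE = 0
hold as stated.

Fragmentation indices count alternation-type patterns in the symbol
sequence: PIP = [p(ad) + p(da)]·100% (inflection points),
PAS = [p(ada) + p(dad)]·100% (alternation segments) and
PSS = [1 − p(aaa) − p(ddd)]·100% (short segments; implemented exactly in
this form, which differs from some other published PSS definitions). The
octant probabilities p(ad), ..., p(ddd) are sums of the quantized pattern
distribution over strictly signed indices, so zero actions fall in the
complement; their share is reported separately as `nzero`. The matching
partial entropies E(ad), ..., E(ddd) are the −Σ p ln p contributions of
each sign octant *without renormalization*, so the eight octants of Π3
plus the zero-containing terms sum exactly to E3. We resolve the open
choice of whether PIP-type counters use raw symbol pairs or octant sums in
favour of the octant sums, which keeps counters and partial entropies
defined on the same objects; with ~6% zero actions the two conventions
differ by at most that mass.

## Signal editing

The editing chain mirrors standard Holter practice:

1. **Window selection.** The nocturnal rest period is defined
   operationally as the contiguous window (default 240 min) with the
   minimal mean heart rate, found by a sliding search at 1-min stride.
   A human analyst picks this window by inspection; the minimal-mean-HR
   rule is a reproducible operationalisation of the same criterion.
2. **Gap filling.** Gaps of one or two missing beats are filled with the
   median of the three preceding and three following intervals; larger
   gaps stay annotated, and no action, pair or triple window ever crosses
   one.
3. **Clipping.** Increments beyond ±300 ms are set to ±300 ms. Clipping
   applies to the *action* series only; stored RR values are untouched,
   and the clipped action does not feed back into later intervals.
4. **Quantization.** The quantum Δ is inferred as the greatest common
   divisor of the observed interval values (tolerance-robust Euclid), and
   can be overridden; 7.8125 ms is the documented value for a 128 Hz
   recorder.

Shuffle surrogates are uniformly random permutations of the intervals:
they preserve the RR distribution exactly while destroying every temporal
pattern, and the surrogate action distribution converges to the discrete
self-convolution of the interval distribution. Ten replicates with seeds
`seed + 0..9` are the package convention (`surrogate_ensemble()`), and
downstream statistics average them. Cohort z-scoring statistics are always
computed on the original cohort and re-applied to surrogate cohorts so
both live on one scale.

## Standard measures

`meanHR` is the mean of the per-beat instantaneous rates 60000/RR, not
60000/meanRR. RMSSD, pNN50 and pNN20 use gap-free adjacent differences
with strict inequalities at the thresholds. Poincaré sd1 uses the
population variance of the differences (sd1 = √(var(δRR)/2), numerically
RMSSD/√2 up to the vanishing mean-difference term) and
sd2 = √(2·var(RR) − sd1²), clamped at zero if rounding makes it negative.

Spectra come from the classic tau-shifted Lomb–Scargle periodogram
evaluated on the beat times, which handles the uneven sampling of a
tachogram without resampling. The frequency grid oversamples the
fundamental 1/T five-fold from 0.003 to 0.4 Hz; band powers (VLF
0.003–0.04, LF 0.04–0.15, HF 0.15–0.4 Hz) are trapezoidal integrals, and
the periodogram is rescaled so its integral over the grid equals the
variance of the mean-removed series — `total` = VLF + LF + HF is then in
ms² and comparable to stdRR². Relative powers are each band over `total`.
Recordings shorter than one VLF cycle (333 s) still yield a VLF value, but
with a warning. Band powers are stable to within ±2% under grid
refinement, which the test suite asserts.

## The synthetic cohort generator

No public cohort accompanies the package, so `generate_cohort()` creates
one with the statistical structure every analysis stage probes:

| parameter | default | meaning |
|---|---|---|
| baseline | 987 − 0.850·age ms | age-dependent mean RR |
| variability | 115 − 0.651·age ms (floor 15) | target sd of RR |
| lf_freq / hf_freq | 0.10 / 0.25 Hz | band-limited oscillators |
| lf_amp / hf_amp | 25 / 30 ms | oscillator amplitudes |
| ar_coef | 0.8 | AR(1) short-term noise memory |
| delta | 7.8125 ms | recorder quantum (128 Hz) |
| gap_rate | 1 / h | 1–2-beat gap injection rate |
| duration | 240 min | nocturnal window length |
| decade counts | 30, 21, 33, 31, 27, 22, 17 | subjects per decade, 20s–80s (181 total) |

The baseline and variability trends are set to regression coefficients
typical of nocturnal recordings in healthy adults; oscillator amplitudes and the AR
coefficient are chosen so that a young subject shows clear LF/HF peaks
over a correlated noise floor, and quantization produces a realistic share
of zero actions. The AR(1)-plus-oscillators form is the minimal model
exhibiting everything the measures respond to: short-term correlation,
band-limited rhythms, age trends and quantization. Beat times are built in
two passes — first from baseline plus noise, then the oscillators are
evaluated at those times and times are recomputed from the final quantized
intervals; the oscillators' bounded contribution to elapsed time makes the
first-pass phase error < 0.1 rad, with no cumulative drift.

What it deliberately does not emulate: sleep-stage architecture, ectopic
beats and their editing artifacts, circadian non-stationarity, respiratory
frequency drift, or any mechanistic autonomic feedback. Passing tests on
this generator therefore demonstrate correctness of the *measures and
machinery*, not physiological validity on real recordings.

Two direct action-level modes support analytic oracles.
`simulate_action_series(mode = "iid")` draws quantized actions
independently from a discretized Gaussian (sd 1.5 quanta, truncated to
±4). The small support is intentional: at N = 10⁵ the plug-in entropy bias
(≈ (m−1)/2N for m observed patterns) stays negligible against sampling
noise, so the independence limits are tested rather than a bias artifact.
Note that actions derived from *shuffled intervals* are not iid — adjacent
actions share an interval and carry lag-1 correlation −½ — which is why
the independence-limit checks use the action-level generator while
surrogate checks use the convolution law. `mode = "markov"` runs a
supplied first-order transition matrix (ST → analytic entropy rate,
sTE → 0) and `mode = "markov2"` repeats the lag-2 state with probability
0.7, i.e. two interleaved first-order chains, for which
sTE = ln 3 − H(row) exactly.

## Cohort analyses

**Factor analysis** is the principal-component eigendecomposition of the
feature correlation matrix: loadings are eigenvectors scaled by √λ,
factors are retained while λ > 1 (Kaiser–Guttman; the comparison is
guarded by a 10⁻⁹ tolerance so an exact-identity input retains nothing),
and percent variance is λ/p·100. No rotation is applied by default, since
unrotated components are what the eigendecomposition description implies;
varimax is available behind a flag for users who want simple structure,
and neither variant is claimed to reproduce any particular published
loading table. Zero-variance features are flagged and their correlations
set to 0 rather than failing the run.

**Strong-correlation graphs** connect features with |r| ≥ θ (default 0.8)
and report edges and connected components.

**SVM classification** uses libsvm's one-vs-one scheme with
pairwise-coupled Platt posteriors (via `e1071`), Gaussian kernel with
γ = 0.2 and C = 1 by default — deliberately below the common γ = 0.5 to
keep the decision surface smooth at cohort sizes of order 10². Scores
(fraction of rows whose argmax posterior matches their decade) are
reported as mean ± sd over 50 runs; per-run variation enters through the
calibration's internal resampling, seeded deterministically from the
master seed so the whole aggregate is reproducible. The default evaluation
is resubstitution — posterior tables over the full cohort — because that
is the protocol whole-cohort probability matrices describe; it
overestimates generalisation, so k-fold cross-validation is provided and
is the evaluation to report for any claim about unseen subjects.

**Age regression** fits feature = a0 + a1·age by OLS per feature, then
screens decade groups with Shapiro–Wilk (on group-model residuals) and
Brown–Forsythe (Levene with median centres). Group differences use
one-way ANOVA with pairwise t tests when normality passes, and
Kruskal–Wallis with tie-corrected Dunn z tests otherwise — rank-based
testing is triggered by the normality screen alone, with the
equal-variance result reported alongside. Pairwise p-values are
multiplicity-adjusted (Holm by default; any `p.adjust` method). Constant
features are reported with slope 0, R² = 0 and a degeneracy flag instead
of erroring.

## Numerical choices

- Probabilities are maximum-likelihood frequencies; no pseudocounts or
  bias corrections. Bias is handled where it matters — by comparing
  against surrogate replicates, not by adjusting estimates.
- Plug-in E1 and E2 come from slightly different window sets, so
  near-deterministic series can violate E1 ≤ E2 by O(1/N);
  `dynamic_landscape()` tolerates violations up to 10⁻⁶ and errors beyond.
- Extreme-segment selection breaks ties toward the earliest segment index;
  flagged (NA) segments are skipped, and all-flagged input errors.
- Time windows are half-open, 0-based, on beat onset times, so segments
  partition the recording exactly; a 240-min window yields exactly 48
  five-minute segments.
- A failed feature never disappears: it becomes NA with its name recorded
  in the row's `flags` field.
- Decades are floor(age/10)·10; ages 18–19 join the 20s group with a
  warning.

## Problem sizes

The test suite exercises: exact brute-force enumeration oracles on 100
random series of up to 200 actions; independence and Markov limits on
10⁵-action simulations with 20 replicate seeds for the 3σ tolerance; and
end-to-end parameter recovery on 20 cohorts of 181 subjects × 240 min
(time-domain features), requiring the generated age slopes of meanRR and
stdRR to be detected (negative, p < 0.05) in at least 90% of seeds.
Full-spectrum feature extraction in tests uses shorter windows or a
2× frequency grid, since the measures themselves are grid-stable.

## Limitations

- The analytic anchors validate the estimators, not any physiological
  interpretation of factors or classifiers; interpretation requires real
  cohorts.
- Resubstitution SVM scores are optimistic by construction; use k-fold.
- PSS follows the printed three-pattern definition, not segment-length
  bookkeeping used elsewhere in the fragmentation literature; comparisons
  across software should check definitions.
- The Lomb–Scargle `total` equals VLF+LF+HF over 0.003–0.4 Hz; power
  outside that range (and any definition of "total power" tied to a
  different band) is out of scope.
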