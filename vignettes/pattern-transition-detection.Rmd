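---
title: "Detecting critical instability and pattern transitions in daily process data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting critical instability and pattern transitions in daily process data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(patternshift)
```

## The problem

Psychotherapy process monitoring produces intensive longitudinal data: a
patient rates themselves daily on a multi-item questionnaire (here modeled
on a 43-item instrument with 7 factors, each item a 0–100 visual analog
scale), often alongside a free-text diary that is later coded into
categories such as perceived pattern stability, critical instability, or
Kairos (the felt right moment for change). From a dynamic-systems view,
therapeutic change is not gradual: a temporarily stable
cognition–emotion–behavior pattern (an attractor) destabilizes — often
visible as a window of elevated fluctuation, a *critical instability* — and
the system jumps discontinuously to a new regime (a *pattern transition*).

`patternshift` implements the quantitative side of this analysis as a
tested pipeline:

1. **Dynamic complexity (DC)** with surrogate-based significance — the
   early-warning statistic for critical instability;
2. the **complexity resonance diagram (CRD)** — an items × days heatmap of
   significant DC cells with a per-day exceedance histogram;
3. a **pattern transition detection algorithm (PTDA)** that pools six
   change points per channel — mean, variance, and linear trend of the raw
   series, plus mean changes of the DC series, the recurrence-plot lines,
   and the time–frequency rows — into a transition day, a probability, and
   a surrogate p value;
4. a **synthetic generator** that emits questionnaire-like multichannel
   series with planted regimes plus coupled diary-category timelines, since
   real patient series of this kind are not publicly shareable.

## Data model and preprocessing

A `process_series` is a channels × days matrix on a fixed daily grid with a
missingness mask. Loading from long CSV fills skipped days as missing, so
the grid is always contiguous. Missing values are imputed by
last-observation-carried-forward, the standard rule for this kind of daily
monitoring; leading gaps take the first observed value
(next-observation-carried-backward), which preserves series length without
inventing a trend. Factor scores are unweighted means of the factor's
items: the instrument's true scoring rule is unpublished, and the plain
mean preserves the 0–100 bounds and treats items symmetrically.

## Dynamic complexity

DC is the product of a fluctuation measure F and a distribution measure D,
computed in a sliding window of `window_m = 7` days (one week of daily
ratings; the conventional width for this statistic) and attributed to the
window's **last** day, matching the real-time monitoring perspective — the
first six days are undefined.

- **F** partitions the window into maximal monotone segments and sums
  |change across segment| / segment length, normalized by the largest
  attainable value (full-scale alternation every step). Plateaus extend the
  current segment: a flat stretch is not a turning point, which avoids
  spurious zero-length segments. F is order-sensitive — it reacts to both
  the amplitude and the frequency of oscillation.
- **D** sorts the window and compares all pairwise gaps with those of an
  ideal equidistant spread across the scale; only deficits count. D is
  permutation-invariant and measures how evenly the values scatter over the
  admissible range.

Both lie in [0, 1], are zero exactly for constant windows, and are
invariant under jointly rescaling values and scale bounds. The C++
implementation is cross-checked in the test suite against independent
direct-summation oracles over the exhaustive set of 3^5 windows.

### Surrogate significance

Significance is assessed nonparametrically: each channel's values are
permuted `n_surrogates` times (default 1000), DC is recomputed, and the
empirical cells are compared against the channel's pooled surrogate
quantiles — gray cells above the 95% quantile, black above 99%. Masks are
quantile-based rather than Gaussian-z-based because DC is bounded and
skewed; z values are still computed for display. Value permutation
preserves each channel's marginal distribution and destroys temporal order,
which is precisely the null of interest ("the same ratings in random
order"). Whether pooling should be per-channel or case-wide is not settled
in the methods literature this follows; per-channel empirical quantiles
were chosen because channels differ in variance and hence in attainable DC.

Instability periods flag days whose case-mean (or per-channel) DC exceeds
the (1 − α) surrogate quantile, bridge single-day gaps, and attach a
Monte-Carlo p value: the add-one-corrected fraction of surrogates whose
*maximum* same-length rolling mean reaches the period's mean DC. Comparing
maximum against maximum makes the p value of the most complex window
exactly calibrated under the null (verified in the acceptance tests).

## Second-order representations

The PTDA scans two derived matrices per channel:

- **Recurrence plot**: delay embedding with `embed_dim = 3`, `delay_tau =
  1` — coarse defaults appropriate for short daily series, where heavy
  embedding would consume the series length. The distance threshold ε is
  set per channel to the 10% quantile of all pairwise embedded distances
  (fixed recurrence rate), which makes recurrence structure comparable
  across channels with different variances. Downstream change-point
  analysis consumes the binary rows.
- **Time–frequency distribution**: a plain windowed periodogram (window 7,
  matching the DC window; mean-removed, no taper) with rows at frequencies
  k/7 cycles/day. No estimator is canonical here; the plain periodogram is
  the most transparent choice for 7-point windows where tapering would
  discard most of the data.

## Change points and the PTDA

All three raw-series detectors are exhaustive single-split scans (the
analysis targets *one* transition per case): constant-mean SSE for the
mean, `len · log(var + δ)` per segment for the variance (δ = 1e-9 guards
constant segments; each segment needs ≥ 2 points), and two independent OLS
lines for the trend. The reported day is the **first day of the new
regime**; ties break to the earliest day. A best split that reduces the
cost by numerically nothing is *degenerate*: day undefined, confidence 0.

Each detector's confidence is the add-one-corrected fraction of
value-permuted surrogates whose best score falls strictly below the
empirical score. This permutation bootstrap assumes exchangeability; on
strongly autocorrelated null series it is anti-conservative (wandering AR
paths look like steps to a permutation null). This is a known property of
the method, not a bug — the transition-level surrogate p below inherits no
such bias because empirical and surrogate runs use the identical procedure.

For the recurrence and time–frequency matrices, the mean detector runs on
every line; degenerate lines are excluded (they would otherwise vote for an
arbitrary day), a day histogram with bin width 1 is built, and the matrix
change point is the histogram mode (earliest on ties) with confidence = the
fraction of non-degenerate lines within ±3 days of the mode. Second-order
days are mapped back to raw-day coordinates with the right-aligned
(window/embedding end) convention, consistent with the DC alignment.

**Pooling.** All points (default: 6 × 7 factor channels = 42) enter a
day histogram weighted by confidence. The transition day is the weighted
mode; the probability is the summed confidence within ±`mode_window_w`
(default 3) days of the mode, divided by the total number of points —
*including* degenerate ones, which are evidence of absence of change. The
published description of this algorithm states only that the probability is
"based on all change points"; this confidence-weighted mode-window fraction
is this package's normative rule. It reproduces the qualitative behavior of
the published case values (tight clustering of confident points yields high
probabilities; typical planted-transition values land in the 0.3–0.7
range) but is not claimed to replicate any study's exact numbers, which
would require the restricted patient data and unpublished constants.

**Transition-level surrogate p.** The full pooled probability is recomputed
on `n_surrogates` copies with every channel independently permuted;
p = (r + 1)/(n + 1) where r counts surrogates reaching the empirical
probability. Surrogate runs use the identical confidence procedure
(same `cp_boot`), so the p value is exchangeable by construction and
approximately uniform under the null (verified in the acceptance tests).

## The synthetic generator

No public data of this kind exists, so the generator is a first-class
module and defines the study conditions the pipeline is validated under:

- 43 items / 7 factors, 90 days (the emulated studies ran 60–100 days);
- per factor, a latent AR(1) path (φ = 0.6) around the regime mean; item
  values add independent noise (`noise_sd` = 6 VAS units) and are clipped
  to [0, 100] (VAS bounds are hard);
- the latent innovations run at `noise_sd / 2`: the latent factor state is
  the slow common component while day-to-day variation is dominated by
  item-level measurement noise. This split makes the generator's stated
  conditions internally consistent — a level shift of 1.5 × `noise_sd` on
  70% of the factors at day 60 is then recoverable within ±3 days in well
  over 90% of seeds, which is the calibration the design targets. With
  equal scales the factor-level shift would be barely 1.1 sd and no method
  could meet that target;
- an optional instability window multiplies the noise sd by
  `instability_gain` (default 3) *and* adds a day-alternating latent
  component of amplitude `gain/2 · noise_sd` — so both the order-sensitive
  F and the distribution-sensitive D respond;
- an optional transient relapse pulls the shifted factors against the
  shift direction just before the transition;
- ratings go missing completely at random at 1.6% and diary entries at
  15.2%, the descriptive rates reported for this kind of monitoring data.

The coupled category timeline draws one or two codes per day from
regime-dependent distributions (stability codes before, critical
instability and broadening-perspective inside the window, elevated Kairos
within ±3 days of the transition, improvement codes after).

What the generator does **not** emulate: cross-factor correlation beyond
the shared missingness regime, item-specific reliabilities, floor/ceiling
usage styles, weekly cycles, or any feedback between diary writing and
ratings. Passing recovery tests therefore shows the pipeline detects the
planted structure it was designed for — not that real patient data contain
such structure.

## Alignment of diaries and indicators

`align_categories()` cross-tabulates category-group days against indicator
windows (significant-DC periods, transition ± w) and attaches a permutation
p from *circular shifts* of the timeline, preserving the run structure of
diary phases — an i.i.d. shuffle would treat autocorrelated category runs
as independent days and overstate significance. The price is granularity:
shifting a coherent in-window run across its own window loses only about
one overlap day per day of shift, so the attainable p is floored near
(window span − overlap)/n_days. At the default study conditions (16-day
window in 90 days, 15% missing entries) about half of the seeds reach
p < 0.05 while the null rejection rate is conservative (≈ 0); the test
suite asserts exactly these measured properties.

## Numerical choices and degenerate inputs

- Add-one Monte-Carlo convention everywhere: p values and confidences never
  reach exactly 0.
- Constant channels: DC ≡ 0, a degenerate surrogate null (sd = 0) is only
  an error if the empirical DC is nonconstant; all six change points
  degenerate; the recurrence matrix degenerates to all-ones with a warning.
- The transition band smooths the pooled histogram with a *triangular*
  kernel of half-width `mode_window_w`; a boxcar would tie across several
  days around the mode, the triangular kernel has its unique maximum at the
  estimated transition day.
- Ties in all mode/argmin decisions break to the earliest day, keeping the
  "first day of the new regime" reading.
- CSV serialization writes doubles at full precision (`%.17g`), so
  write → load round-trips are bit-identical.

## Problem sizes used in the validation suite

The packaged tests run the full recovery studies at the sizes the design
calls for: 100 seeds for transition recovery and monotonicity (shifts 0.5σ,
1.5σ, 3σ, paired seeds), 50 seeds for instability recovery, 300–500
surrogates for mask calibration over ≥ 2000 cells, and 20 × 100 surrogate
runs for the transition-p uniformity check; the whole suite completes in a
few minutes on one core. The acceptance script
(`scripts/acceptance.R`) recomputes the headline quantities from scratch at
the same conditions.

## Known limitations

- Single change point per signal: staged or multiple transitions within
  one case are out of scope by design.
- Permutation confidences are anti-conservative on autocorrelated
  no-change series; interpret per-detector confidences descriptively and
  rely on the transition-level surrogate p for inference.
- The probability aggregation rule is this package's own fixed convention;
  absolute probabilities are comparable within this package only.
- The embedding and window defaults (m = 3, τ = 1, ε at 10% recurrence,
  window 7) are reasonable for daily coarse-grained data but unstated in
  the emulated analyses; other choices shift second-order change points
  quantitatively.
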