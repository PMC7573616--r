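---
title: "Methods: lick microstructure, standardized lick ratios, and CT response quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lick microstructure, standardized lick ratios, and CT response quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lickometry)
library(dplyr)
```

## What this package computes

`lickometry` implements the desk-side analysis chain for two standard rodent
taste-behaviour paradigms and for whole-nerve chorda tympani (CT) recording,
together with the statistical battery typically applied to them:

1. **Brief-access gustometry.** Seconds-scale stimulus presentations isolate
   orosensory (taste) influence from post-ingestive feedback. Licking per
   trial is converted to a *standardized lick ratio* (SLR) that removes
   individual differences in the stereotyped lick rhythm.
2. **Long-term (23-h) lickometry.** Single-bottle sessions are segmented into
   meals and bursts, yielding whole-meal measures (lick count, duration) and
   intra-meal measures (bursts, burst size and duration, pauses, first-minute
   and first-burst licks) that separate taste-motivated from
   post-ingestively-motivated drinking.
3. **CT nerve responses.** Raw whole-nerve activity is rectified and
   leaky-integrated, response heights are measured against a pre-stimulus
   baseline, and each response is normalized to bracketing reference
   (NH~4~Cl) applications, with a stability QC on the bracket.
4. **Statistics.** Two-tailed t tests (paired, pooled, Welch), the classical
   split-plot (mixed between-by-within) ANOVA, and Bonferroni-adjusted
   pairwise post-hoc comparisons.

A synthetic-data module generates lick-event streams and raw nerve traces
with known ground truth, so the full chain is testable end to end without
proprietary gustometer files or archived recordings.

## Brief-access analysis

Each trial gives the animal a fixed time (default 30 s) to initiate licking;
the trial then runs for a fixed duration (default 15 s) from the first lick.
`assemble_trials()` counts licks in the **half-open** window
`[first_lick, first_lick + duration)`: a lick exactly at the closing
boundary is excluded, which makes counts unambiguous. Trials never initiated
are *missing*, not zero — a zero would confound motivation with taste — and
`n_trials_used` records how many of the (typically three) block
presentations entered each average.

The subject baseline comes from water training: interlick intervals (ILIs)
are filtered to the open interval (50, 200) ms, which retains the
stereotyped intraburst rhythm (rodents lick at roughly 6–9 Hz) and discards
pauses and double-contact artefacts. All water-training sessions of a
subject are pooled; the maximum potential lick rate is

$$\mathrm{MPL} = \frac{\text{trial duration}}{\overline{\mathrm{ILI}}_{\text{valid}}},
\qquad \mathrm{SLR} = \frac{\text{mean licks per trial}}{\mathrm{MPL}}.$$

SLR values above 1 (licking faster than during training) are possible and
are reported with a note rather than clipped; clipping would destroy
information. When several test days are present the default is to average
over days; `by_session = TRUE` keeps them separate.

The 15-s trial duration is the default but is exposed as an argument
(`trial_duration_s`) because published figure captions sometimes describe
the same paradigm with a 30-s trial; the two conventions scale MPL but not
the qualitative ordering of SLRs.

## Meal and burst segmentation

Two thresholds define the hierarchy, both exposed as arguments with the
field-standard defaults:

* a **meal** is initiated by 5 licks within 1 s and terminated by a pause of
  600 s (threshold-inclusive: a gap of exactly 600 s terminates);
* a **burst** ends at any ILI strictly greater than 1 s (an ILI of exactly
  1 s stays within the burst).

The initiation scan slides a window of exactly `init_count` licks forward
from the end of the previous meal and takes the *earliest* qualifying lick
as onset; licks that never join a qualifying run are orphans belonging to no
meal. Orphans still count toward `session_licks` (conservation: meal licks
plus orphans equal session licks, and burst licks partition meal licks —
both are asserted in the test suite against lick-by-lick reference
implementations).

Variables are computed per meal and then averaged **unweighted** across
meals ("the average of each variable per meal, averaged across all meals");
a lick-weighted average is available via `weight = "lick"` but is not the
default. Mean burst size is meal licks divided by bursts in the meal.
Single-burst meals contribute no pause observations (excluded from the pause
mean, not zero). Because "licks in the first minute" is described in the
literature both as the first minute of testing and as the first minute of
the meal, both are emitted: `licks_first_minute` (anchored at the session's
first lick; the default headline value) and `licks_first_minute_meal`
(per-meal, averaged). `licks_first_burst` is the lick count of the first
burst of the first meal.

## CT response quantification

`integrate_trace()` applies full-wave rectification followed by the exact
discrete first-order integrator

$$y_n = y_{n-1} + \left(1 - e^{-\Delta t/\tau}\right)\,(|x_n| - y_{n-1}),
\qquad y_1 = |x_1|,$$

with $\tau = 1.5$ s by default, matching the analogue integrators used with
whole-nerve amplifiers. Rectification precedes integration because raw
multi-unit activity is zero-mean. Two closed-form facts anchor the tests:
the unit-step response at $t = \tau$ is $1 - e^{-1}$, and a constant input
is a fixed point.

`response_magnitude()` reads the integrated trace at the sample nearest
onset + 20 s (an instantaneous value, not a window mean — the conventional
"height at 20 s") and subtracts the mean over the 5 s preceding onset. The
baseline window length is a package choice (the convention states only
"subtracting the baseline") and is configurable. Negative magnitudes are
reported, not clamped.

Normalization divides each test magnitude by the mean of the nearest
reference response before and after it; a single reference application may
close one series and open the next. The bracket-stability deviation is
$|pre - post| / \mathrm{mean}(pre, post)$ — the mean-referenced form is used
because it is symmetric in the two references; alternatives (relative to the
first, or to the max) are not offered implicitly, but the tolerance
(default 10%, inclusive) is. Failing series keep their computed values and
are flagged `excluded`, so the analyst decides.

## The statistical battery

`t_p_two_tailed()` is the exact central-t conversion
$p = 2\,(1 - F_t(|t|; \nu))$; display formatting (3 decimals, floored at
`<0.001`) is separate from the full-precision value. `paired_t()` implements
$t = \bar d / (s_d / \sqrt n)$ with $\nu = n - 1$ and rejects zero-variance
differences. `mixed_anova()` computes the classical balanced split-plot
decomposition: the between-groups effect is tested against
subjects-within-groups; the within effect and the interaction against the
level-by-subject-within-group stratum. No sphericity correction is applied
(the classical table assumes none); unbalanced designs are rejected rather
than imputed, because silent imputation changes the error strata. With a
single group the same routine reduces to a one-way repeated-measures ANOVA.
`bonferroni_pairwise()` multiplies raw pairwise p-values by the family size
(by default the number of comparisons conducted in the call, recorded in
the output) and caps at 1.

The test suite verifies the split-plot sums of squares against explicit
design-matrix least-squares projections to 1e-8, against `aov()` error
strata, and calibrates the group-effect type-I error under a 5000-replicate
null simulation (acceptance band 0.04–0.06 at $\alpha = 0.05$).

## The synthetic-data generator

The generator is the package's test bed, emulating the three timescales the
segmentation rules target:

* **within-burst ILIs**: truncated normal, mean 120 ms, SD 20 ms, truncated
  to (50, 300) ms — the stereotyped rodent lick rhythm;
* **bursts**: geometric lick counts (default mean 30 licks, giving burst
  durations of a few seconds) separated by gamma intra-meal pauses (default
  mean 50 s), truncated to stay strictly between the burst and meal
  thresholds;
* **meals**: Poisson bursts-per-meal (default mean 40) at renewal times with
  inter-meal gaps of 650 s plus an exponential excess (default mean 1800 s
  total), so every generated gap terminates a meal.

These defaults were chosen once to land the simulated sessions in the range
reported for mice drinking sucrose in 23-h tests — roughly 10 meals and
around 10^4 session licks, with meal durations of tens of minutes — and are
not adjusted per analysis. The first burst of each meal is forced to at
least 5 licks so the generator's annotated meal onsets coincide exactly with
the 5-licks-in-1-s initiation rule; recovery tests compare rule-based
segmentation to these annotations.

Concentration is mapped to a lick drive in (0, 1] by a Hill-type curve
(rising for appetitive tastants, falling for aversive ones; the literature
constrains only monotonicity, not the functional form). Treatment groups
multiply the drive of suppressible (sweet and salt) tastants by a factor in
(0, 1]. In brief-access trials the animal continues its rhythmic ILI with
probability equal to the drive and otherwise pauses 1–3 s, so a drive of 1
produces continuous licking and an SLR near 1; in long-term sessions the
drive scales the expected bursts per meal, making expected session licks
monotone in the suppression factor.

CT traces are zero-mean noise whose instantaneous SD follows the stimulus
envelope (linear ramp to plateau within 2 s, exponential decay after rinse,
scaled by the true amplitude) on top of a baseline-noise floor. Because
normalization is a ratio, the rectified-noise scale factor
($\mathbb{E}|Z| = \sqrt{2/\pi}$ for Gaussian activity) cancels, and
normalized magnitudes recover true amplitude ratios.

All randomness flows from one master seed through per-(subject, session,
purpose) derived streams, so adding subjects or sessions never perturbs
existing streams, and every generated object is bit-reproducible.

**What the generator does not emulate:** circadian structure in meal timing,
lick-duration waveforms, satiation within a session (drive is stationary),
electrode drift other than the injected reference-amplitude drift, and any
physiological mechanism behind group differences. Passing recovery tests
therefore certify the *analysis chain*, not the realism of any biological
effect size.

## Numerical choices and degenerate inputs

* Timestamps are integer milliseconds; sub-millisecond inputs are rejected,
  not rounded, so no two analyses can disagree by a rounding policy.
* Duplicate or backward timestamps within a subject-session are errors with
  the offending row index.
* Empty lick streams and sessions with no meals return zero counts with
  missing meal-derived fields rather than errors.
* The ANOVA guards the all-constant corner (zero error mean square) by
  reporting `NA` F and p rather than dividing by zero; tiny negative
  round-off in difference-based sums of squares is clamped at zero.
* Problem sizes in the test suite (1000 oracle streams of up to 200 licks,
  500 SLR null replicates at 20 subjects/group, 5000 ANOVA null replicates)
  were chosen to put Monte-Carlo standard errors well inside the asserted
  bands while keeping the default test run in minutes.

## Known limitations

* The split-plot ANOVA covers one between- and one within-subject factor —
  the designs used here — not general factorial layouts; no
  Greenhouse–Geisser correction is offered yet.
* `bonferroni_pairwise()` uses two-sample t tests; it does not recycle the
  ANOVA error strata for post-hoc contrasts.
* Vendor-proprietary gustometer binary formats are out of scope; events
  arrive as CSV.
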