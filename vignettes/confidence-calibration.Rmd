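---
title: "Measuring confidence calibration in clinical risk judgments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring confidence calibration in clinical risk judgments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(confcal)
```

## The measurement problem

A judge assesses a clinical scenario, states a dichotomous judgment (the
patient is / is not at risk of a critical event) and attaches a confidence
rating on 0–100. Calibration asks whether those ratings mean what they say:
among judgments made with confidence near *p*, do a fraction *p* turn out
correct? `confcal` implements the binned verification statistics that answer
this, the reliability diagrams that display it, the MEWS-based definition of
task difficulty, and the group/condition comparisons, with a synthetic
cohort generator providing ground-truth-known data for every stage.

## The statistics and their assumptions

All computation happens on the probability scale; ratings are elicited on
0–100 and divided by 100 at entry (`scale = "auto"` treats a vector with any
value above 1 as percent — the one ambiguous case, a table whose ratings are
all 0 or 1 on the percent scale, can be forced with `scale = "percent"`).
Whole tables are converted once, before any stratification, so every subset
shares one convention.

Confidence is grouped into ordinal categories. The default edges are
`[0, 0.5)` followed by deciles `[0.5, 0.6) … [0.9, 1.0]`, membership
lower-inclusive and the top bin closed, so a rating of 59 sits in
`[0.5, 0.6)`. Half-scale instruments of this kind label categories from 0.50
upward and leave sub-0.5 ratings unspecified; we pool them into a single
bottom bin for the statistics so that the bin counts sum to `n` and the
`1/n` weighting of the calibration score stays exact. (Sub-0.5 ratings are
excluded from *curves*, not from statistics — see below. Both the edges and
the curve threshold are arguments, so other conventions are one call away.)

With `n_j`, `p̄_j`, `ē_j` the count, mean confidence and proportion correct
of bin `j`, and `ē` the overall proportion correct:

* calibration score `(1/n) Σ n_j (p̄_j − ē_j)²` ∈ [0, 1];
* over/underconfidence `p̄ − ē` ∈ [−1, 1], positive = overconfident;
* resolution `(1/n) Σ n_j (ē_j − ē)²` ∈ [0, ē(1−ē)];
* normalised resolution = resolution / `ē(1−ē)` ∈ [0, 1].

These are descriptive statistics of the binned table; they assume nothing
about the data-generating process. Two degenerate inputs need decisions:
an empty record set is an error everywhere, and when `ē ∈ {0, 1}` the
knowledge index is zero, so no discrimination is measurable — normalised
resolution is then defined as 0 and flagged via a `degenerate` attribute
(and column), rather than returning NaN, because "no measurable
discrimination" is the scientifically accurate summary of such a judge.
The worked extremes pin the scale: a responder with confidence 100 on every
incorrect and 0 on every correct judgment scores calibration 1; at 50%
accuracy the same responder has resolution `0.25 = ē(1−ē)` and normalised
resolution 1 — terrible calibration, perfect discrimination.

Statistics are computed per judge (`calibrate_judges()`) for group
comparisons, and on pooled strata (`calibration_summary()` by difficulty ×
time pressure) for the hard-easy analysis; with 25 judgments per judge,
per-judge bins are far too sparse to support per-judge curves, so curves are
always pooled.

## Calibration curves

`curve_points()` plots `ē_j` (y) against `p̄_j` (x) for each non-empty bin —
the bin's *mean confidence*, not its midpoint, keeping the x coordinate
consistent with the calibration score's `p̄_j`. Ratings below
`min_confidence` (default 0.5) are dropped before binning and the excluded
fraction is reported: the handful of low-confidence ratings would otherwise
yield wildly unstable points. `deviation_summary()` condenses a curve to the
n-weighted mean of `x − y`, which with `min_confidence = 0` is algebraically
identical to over/underconfidence — a cross-check the tests exploit.

## MEWS scoring and task difficulty

Scenarios present five cues: systolic blood pressure (mmHg), heart rate
(beats/min), respiratory rate (breaths/min), temperature (°C) and AVPU
consciousness. Each maps to a 0–3 subscore through a cut-off table; the
package embeds the Subbe 2001 MEWS intervals as a documented CSV
(`inst/extdata/mews_subbe2001.csv`) rather than hard-coding them, and
`read_mews_table()` accepts other dialects in the same layout. Intervals are
half-open lower-inclusive with each cue's topmost interval closed; their
union defines the admissible physiological range, and values outside it are
rejected with the cue and value named — silent clamping would hide data
errors. Consciousness is scored through the same interval mechanism by
coding AVPU as 0–3.

A total above 5 (`classify_risk()`, threshold configurable since trigger
conventions vary between MEWS dialects) classifies the patient at risk.
Task difficulty is score/outcome concordance (`classify_difficulty()`): a
scenario whose MEWS-implied classification matches the patient's actual
outcome is an *easy* judgment task; one where the cues point away from the
truth is *difficult*.

## The synthetic cohort generator

`cohort_config()` defaults encode the emulated study design: 63 student and
34 experienced judges, 25 scenarios with 8 difficult, the first 12 scenario
ids forming the time-pressured block (difficult scenarios are spread evenly
across the sequence so both blocks contain both difficulties). Per record,
correctness is Bernoulli with the stratum's success probability; confidence
is truncated-normal on [0, 1], centred at the stratum accuracy plus a
group-level bias plus (under pressure) a difficulty-specific shift, with
standard deviation `1/self_knowledge`, then rescaled to 0–100 and rounded —
bounded, unimodal, integer-valued like the elicitation instrument, and with
simple analytic expectations (with moderate means and `self_knowledge ≳ 20`
truncation distorts the mean by far less than Monte-Carlo error, so the
downstream over/underconfidence estimate recovers the configured bias).

Default parameter choices, made once:

* `p_correct_easy = 0.85`, `p_correct_difficult = 0.5`: difficult tasks are
  ones whose cues mislead, so accuracy near chance is the realistic choice;
  the implied overall accuracy `(17·0.85 + 8·0.5)/25 = 0.738` sits where
  published cohorts of this design land.
* `confidence_bias = (−0.0105, +0.0656)` for students/experienced: a mildly
  underconfident student group and a more clearly overconfident experienced
  group, the pattern this literature reports.
* `self_knowledge = 7` (≈14 confidence points of scatter): enough noise that
  ratings spread over several bins, as real 0–100 ratings do.
* `tp_conf_shift_easy = +0.03`, `tp_conf_shift_difficult = −0.04`: a small
  opposed pressure effect, the built-in interaction.
* `at_risk_rate = 0.4`: the truly-at-risk share among scenarios is a free
  design parameter exposed in the config (it only shapes the judgment
  labels, which no downstream statistic consumes); 0.4 reflects an
  emergency-admission case mix.
* `difficulty_blind = FALSE`: when TRUE, confidence centres on *overall*
  accuracy instead of per-stratum accuracy — the mechanism that produces a
  hard-easy effect (overconfident on difficult, underconfident on easy)
  without any global bias.

Randomness is hierarchical: the single seed derives one sub-stream per
judge (plus one for scenario-level truth labels), so enlarging the cohort
never perturbs earlier judges' draws. What the generator does *not* emulate:
vital-sign trajectories, judge-specific skill heterogeneity beyond the
participant mean structure, correlated errors across judges within a
scenario, or any psychological process beyond the bias/precision/shift
parameters. Passing tests therefore demonstrate that the pipeline measures
what it claims on data with this statistical skeleton — not that real
judges behave this way.

## Comparisons

Group differences in per-judge statistics use Student's pooled-variance t
test (63 + 34 judges giving 95 df) and the Wilcoxon rank-sum test via the
tie-corrected normal approximation; the z statistic is computed directly
(base R's `wilcox.test` reports W, not z) and agrees with `wilcox.test`'s
normal-approximation p value exactly, which the tests assert. Tests are
two-sided with significance at 0.05 and no multiplicity adjustment.

The factorial ANOVA operates on judge × condition *cell means* (one value
per judge per time-pressure × difficulty cell), fitted by sequential sums of
squares as time pressure + difficulty + participant + interaction. This
layout yields factor df 1, participant df 96 and residual df 288 for a
97-judge study. Reports of this design sometimes print 289 residual df;
288 is what the cell-mean decomposition gives (388 cells − 1 − 99 model df),
and we keep the computed value. Cell means are used rather than raw trials
because only that error structure matches the published df pattern; the
cells have unequal item counts (4–9), a mild heteroscedasticity that
simulation shows leaves the interaction test's size near nominal
(≈0.058 over 500 null cohorts at study scale, inside the 0.05 ± 0.02 band
the tests enforce). A constant response returns F = 0, p = 1 on every term
rather than 0/0.

## Numerical and testing choices

Problem sizes were chosen to give tight Monte-Carlo bands at desk scale:
parameter recovery uses 200 judges × 200 scenarios × 20 seeds per bias
value (3 Monte-Carlo-SE criterion), the hard-easy sign check 100 study-scale
replicates, the type-I-error check 500 study-scale replicates, and oracle
equivalence 100 random tables against a brute-force per-record
recomputation at 1e-12. The brute-force oracle shares no code with the
binned implementation. All tolerance-free assertions (calibration 1 and 0,
resolution 0.25, NRS 1) hold exactly in floating point because the
arithmetic involves only dyadic rationals.

## Limitations

The package analyses one-shot dichotomous judgments with a single
confidence rating each; it does not cover multi-category judgments,
Brier-score covariance decompositions beyond the three statistics above,
continuous (unbinned) calibration estimators, repeated-measures or
mixed-model alternatives to the cell-mean ANOVA, or NEWS-style successors
to the embedded MEWS table. Curve exclusion below 0.5 discards genuinely
low-confidence behaviour by design; analyses of that region should use the
statistics (which always keep it) rather than the curves.
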