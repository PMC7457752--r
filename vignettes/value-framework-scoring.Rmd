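---
title: "Scoring clinical benefit: ASCO-VF and ESMO-MCBS in oncovalue"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring clinical benefit: ASCO-VF and ESMO-MCBS in oncovalue}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oncovalue)
```

## What the package computes

Value frameworks translate a randomized trial's published results into a
single measure of clinical benefit. `oncovalue` implements the two scales
used across oncology health-policy work:

* the **ASCO Value Framework** (2016 update), a continuous net health
  benefit (NHB) built from the hazard ratio, the grade 3–4 toxicity
  burden, and bonus points for durable survival, palliation, quality of
  life and treatment-free interval; and
* the **ESMO-MCBS v1.1**, an ordinal grade (1–5 in the non-curative
  setting, A–C in the adjuvant setting) built from the lower confidence
  limit of the hazard ratio, the absolute gain in median survival or in
  landmark survival, and QOL/toxicity/plateau adjustments.

Both engines take the same input: a `trial_arm_record`, one experimental
arm compared against its control. Multi-arm trials are scored arm by arm
and an indication is represented by its higher-scoring arm.

## The ASCO-VF model

Treatment-effect points are `(1 - HR) * 100 * w` with `w = 1` for OS and
RFS/DFS and `w = 0.8` for PFS. Points go negative for HR > 1; we do not
floor them, so a harmful or mis-transcribed effect stays visible rather
than silently clamping to zero.

Toxicity points compare the per-arm grade 3–4 burden, the sum of
published incidences. The published assessments this package reproduces
never print their toxicity arithmetic, only the resulting scores, so the
formula here is a design choice: the relative difference scaled into the
framework's ±20-point band,

```
20 * (B_control - B_experimental) / max(B_control, B_experimental)
```

chosen because it is bounded by construction, antisymmetric under arm
swap, and well-defined when either burden is zero (two burden-free arms
score 0). Records can instead carry a transcribed `toxicity_points_override`,
which is what the packaged cohort uses; the raw-table path is exercised by
the synthetic cohorts.

The tail-of-the-curve bonus asks whether, at **twice the control-arm
median**, the experimental survival proportion is at least **1.5×** the
control proportion, with control survival at least **20%**. A qualifying
OS or RFS/DFS tail earns 20 points, a PFS tail 16. Two numerical choices
matter:

* *Landmark matching*: the landmark whose timepoint lies within ±10% of
  twice the control median is used. With no such landmark the bonus is
  **not assessable** and scores 0 — deliberately distinguished (via the
  attached reason and the run log) from a landmark that was assessed and
  **not qualified**, because immature follow-up and a genuinely absent
  plateau are different scientific statements.
* *Transcribed bonuses*: published assessments sometimes print a bonus
  whose award level disagrees with the computed rule (e.g. a 16-point
  bonus on an OS-evaluated arm). Overrides are honoured as data and the
  conflict is logged, never silently corrected.

Palliation, QOL and treatment-free-interval improvements are flat
10-point bonuses on their respective flags. The NHB is the exact sum of
the six components; components are *reported* to one decimal but summed
unrounded.

## The ESMO-MCBS model

Grading thresholds are **data, not code**: `esmo_rules()` loads a YAML
table holding the lower-CI ceiling (0.65), the median-gain band edges per
form and control-median stratum, the landmark-gain threshold (10%) with
its stratum timepoints, and the curative-form boundaries. The packaged
defaults are the minimal banding consistent with the published grades the
package reproduces — form 2a with control median ≤ 12 months: score 4 at
a gain ≥ 3.0 months, 3 at ≥ 2.0, 2 at ≥ 1.5 (so the canonical worked
example, lower CI 0.52 with a 2.4-month gain, scores 3); the > 12-month
stratum uses proportionally larger bands (4 at ≥ 5.0, 3 at ≥ 3.0) and a
3-year rather than 2-year reference landmark. Users grading other cohorts
should substitute the full published scorecard; the engine logic does not
change.

The preliminary score is a dual rule. Clause one requires the lower CI
limit at or below the ceiling and then reads the score off the gain
bands (a limit above the ceiling scores 1 regardless of gain). Clause
two confers the form's top preliminary score — 4 on form 2a, 3 on form
2b, the PFS form's cap — for an absolute landmark-survival gain at or
above 10% at the reference timepoint. The higher fired clause wins; a
clause with missing inputs cannot fire, and if neither can the grade is
not computable and the error names the missing fields rather than
guessing.

Three boundary decisions are encoded deliberately:

* CI comparisons use **≤ 0.65**, so a printed lower limit of exactly
  0.64–0.65 clears the gate.
* Positive adjustments (improved QOL, reduced toxicity, PFS plateau)
  collapse to a **single** +1 however many apply; toxic-death excess is
  −1. The final grade is clamped to [1, 5].
* Form 2b grades are capped at 4: a PFS-primary evaluation cannot reach
  the top grade, and the landmark plateau that would lift an OS trial is
  reported as a long-term-benefit *flag* (an additional
  curative-framework annotation), never a grade change.

Long-term benefit itself is endpoint-specific: a ≥ 10% absolute PFS gain
at 1 year, or an OS advantage of the same size persisting at 5 years
(control median ≤ 12 months) or 7 years (otherwise). OS trials with
immature follow-up therefore simply do not meet it — no imputation.

When the raw landmark proportions behind a published qualification are
unavailable, a record may carry `landmark_gain_qualifies = TRUE` as a
transcription; the packaged cohort uses this for the PFS one-year
qualifications its sources print verbatim.

## The packaged cohort and what can be re-derived

`load_fixtures()` returns the per-arm assessment data for the 18
FDA-approved checkpoint-inhibitor indications: 23 initial-phase arms
(five indications contributed two separately scored arms; two are
adjuvant) and 18 updated-phase arms, each with the published score
components and grades attached as `expected` columns.

The sources print hazard ratios, CIs, score components and grades, but
not the per-arm medians or landmark proportions behind most ESMO grades.
Consequently:

* every ASCO component and NHB is re-derived from the engine (treatment
  effect from the printed HR; toxicity and tail from the printed
  overrides) and checked against the printed totals to within 0.15 NHB
  points, the headroom implied by components printed to one decimal;
* ESMO grades are re-derived wherever inputs suffice — both adjuvant
  trials, the six PFS arms (via the printed one-year qualification), and
  the fully worked head-and-neck example in both phases — and match the
  printed grades; the remaining OS arms carry their printed grades as
  transcription, flagged per-arm (`esmo_transcribed`) in
  `cmd_reproduce()` output, and the cohort tallies (8 grade-5, 8
  grade-4, 2 grade-A indications) are therefore transcription-dependent
  rather than fully derived.

One cohort convention is worth stating: the published arm-level median
NHB (55.3 over all 23 arms) differs from the indication-level median over
best arms (55.15); `summarize_cohort()` exposes both levels and the
reproduction pipeline reports the arm-level figure. In the
initial-vs-updated comparison, "improved" means a strictly positive
best-arm NHB delta at indication level, which yields a median improvement
of 10 (range 2–20) with one sole decrease — the consolidation-therapy
indication whose re-assessment moved from PFS to mature OS results.

## The synthetic-data generator

`generate_trials()` emulates the kind of trial evidence the scoring rules
consume, without patient-level simulation. Each arm's survival follows a
mixture-cure exponential, `S(t) = π + (1 − π) e^{−rt}` — the simplest
family with a genuine plateau, which is exactly the feature the tail
rules reward. The control rate is solved from the drawn control median;
the experimental rate is the control rate times the drawn hazard ratio
(log-normal); each arm's median then solves its own curve, so generated
records are internally consistent (a cure fraction ≥ 0.5 makes the median
undefined and is rejected at configuration time). Landmark lists always
include twice the control median plus the 1/2/3/5/7-year reference
timepoints, CIs are built on the log-HR scale with a half-width of
`z · 2 / √n` from a nominal sample size, adverse-event incidences are
Beta-distributed per arm, and the bonus flags are Bernoulli.

What the generator does *not* emulate — censoring processes,
non-proportional hazards beyond the cure fractions, correlated adverse
events, within-trial arm dependence — bounds what passing tests show:
they validate the scoring rules against curves with known properties,
not the package against the messiness of real extracted data.

Two study configurations are used in testing. The *engineered-tail*
cohort fixes cure fractions at 0.25 (control) and 0.375 (experimental):
control survival at twice its median is then exactly 1/3 regardless of
the median, and the 50%-improvement gate reduces in closed form to
HR ≤ ln 5 / (2 ln 3) ≈ 0.7325, so drawing HR log-normal(log 0.6, 0.03)
keeps every draw below the bound and the qualification rate is 100% by
construction. The *null* cohort centres log-HR at 0 with no cure-fraction
advantage and no flags, so the median NHB should sit near 0 (within ±3,
the width implied by the HR spread). Test problem sizes — 500-trial
cohorts for these checks, a 320-point threshold grid and 1000 random
adverse-event tables for the property tests — were chosen as the smallest
sizes at which the distributional checks are stable.

## Auditability and limitations

Every scored arm gets exactly one run-log section recording which bonus
gates fired and why, every override substitution, and every
missing-input fallback; nothing is defaulted silently, because the point
of a value framework is that the score can be argued with. Known
limitations: the ESMO band edges outside the ranges exercised by the
packaged cohort are placeholder defaults pending the full scorecard; the
toxicity formula is this package's construction, not the published
assessments' (their overrides shield reproduction from the difference);
and single-arm trial forms, non-inferiority designs and response-rate
fallback scoring are out of scope.
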