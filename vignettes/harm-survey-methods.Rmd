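---
title: "Methods: point-prevalence harm surveys, composite harm-free care, and SPC planning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: point-prevalence harm surveys, composite harm-free care, and SPC planning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(harmsurvey)
```

## The measurement problem

Frontline teams need a harm measure that is collectable at the bedside in
minutes, works in any care setting, and aggregates cleanly from a ward to a
national programme. The design answer implemented here is a **monthly
point-prevalence survey**: on one census day per month every patient is
surveyed for four nursing-sensitive harms — pressure ulcers, recent falls,
urinary tract infection in patients with a urethral catheter, and venous
thromboembolism (VTE) — plus the patient-level composite **harm-free
care**, the absence of all four harms in the same patient on the survey
day. Prevalence on a survey day is not incidence: a harm that appears and
resolves between census days is invisible, and long-stay patients are
over-represented. Those are properties of the design, not defects of the
implementation.

## The record model

One row per patient per monthly survey: survey date, organization, ward,
care setting, age band (`under_18`, `18_70`, `over_70`), gender, specialty,
and the four harm findings. All categorical fields are closed vocabularies
(`survey_levels()`); the instrument forces a choice at collection, so the
parser (`as_survey()`, `read_surveys()`) rejects unknown tokens and missing
values in always-present fields rather than coercing them. There is no
"unknown" level.

Operational details encoded in the schema:

* **Pressure ulcers** record only the patient's *worst* ulcer, category
  2–4 (category 1 is not recordable), flagged `old` (present on admission
  or developed within 72 h of admission) or `new` (after 72 h). Old and
  new are therefore mutually exclusive per patient, which is what makes
  P1 + P2 = P3 an exact identity rather than an approximation.
* **Falls** count a fall in a care setting in the last 72 h (including
  home for patients on a community caseload); `severity = "none"` is a
  valid value for a fall without harm, and harm severity is an ordinal
  scale kept opaque beyond its ordering.
* **Catheter/UTI** joins an in-dwelling *urethral* catheter (in situ on
  the survey day or removed within 72 h; supra-pubic catheters are
  excluded by definition and carry no field) with antibiotic treatment for
  a clinically diagnosed UTI. A treated UTI without a catheter is legal
  and feeds its own published view.
* **VTE** is a three-step cascade: risk assessment documented, prophylaxis
  for at-risk patients, anticoagulant treatment for a documented event;
  every step admits `not_applicable`.

Cross-field consistency (detail present exactly when its governing flag is
set; prophylaxis only for at-risk patients) is checked by
`validate_surveys()`, which reports violations as data rather than raising,
mirroring how a collection tool flags rather than discards a bad form.

## The measure catalogue

Thirteen published measures plus the composite, all as
numerator/denominator proportions with exact binomial intervals. Two
denominator conventions deserve comment because they are easy to get
wrong:

* **C2/C3 use all surveyed patients**, not catheterised patients. The
  published national figures read as percentages of everyone surveyed
  (about 2% of patients had a catheter *and* a treated UTI against a 16.7%
  catheterisation rate); a catheterised-only denominator would print ~12%.
  The catheterised-only view remains available by filtering records before
  calling `compute_measure()`.
* **V1 excludes patients for whom assessment is `not_applicable`; V2's
  denominator is patients assessed as at risk** — the cascade reading of
  "if at risk, has the patient received prophylaxis". The published V2
  value's denominator is not stated in the source material, so no attempt
  is made to reproduce it; the package documents its own convention and
  applies it consistently.

The **harm-free composite** is published only as "absence of all four
outcomes", so which variant of each harm counts is a configuration
(`harm_definition()`). The defaults — any pressure ulcer, a fall *with*
harm, catheter with any treated UTI, new VTE only — pick, for each harm,
the variant most attributable to current care while keeping the pressure
ulcer definition maximally inclusive. Any batch satisfies the
inclusion–exclusion bounds
`1 - sum(q_i) <= HARM_FREE <= 1 - max(q_i)` over the four component
proportions, which the test suite exercises on a thousand random cohorts.

## Aggregation

`merge_surveys()` is a record multiset union with provenance tracking and
no deduplication (the survey carries no patient identifiers, so apparent
duplicates are legal data). `rollup()` computes the full dashboard per
(group, month) at ward, organization, region (a supplied `org -> region`
mapping, not a record field) or national level; numerators and
denominators are conserved exactly up the hierarchy, and the tests assert
this conservation rather than trusting it. `comparison_report()` flags a
group when the reference proportion falls outside the group's exact
interval and attaches an uncorrected chi-square p-value — and carries a
"not for ranking" note, because monthly point prevalences from samples of
tens of patients cannot order teams meaningfully.

## Control charts and sample-size planning

`pchart()` is a Shewhart proportions chart with variable subgroup sizes:
centre line `p̄ = Σx_i / Σn_i` over the baseline points, per-point limits
`p̄ ± 3·sqrt(p̄(1-p̄)/n_i)` clamped to [0, 1], each point judged against
limits computed from its *own* denominator. `runchart()` applies the two
standard quality-improvement rules: shift = ≥6 consecutive points on one
side of the median with on-median points skipped, trend = ≥5 consecutive
strictly monotone points. The source material names run charts without
stating rules; 6/5 is the common convention and is documented as such.

Two planners answer "how many patients must we survey each month":

* `min_n_for_expected_events(p̄, k = 3)` — smallest `n` with `n·p̄ ≥ k`.
  The published planning table's "n for p chart" row is reproduced in
  full by this ≥3-expected-events rule applied to the printed averages;
  the rule itself is an interpretation (the source states the numbers,
  not the formula), documented as such.
* `min_n_for_positive_lcl(p̄)` — smallest `n` whose 3-sigma LCL is
  *strictly* positive, i.e. the smallest integer strictly greater than
  `9(1-p̄)/p̄`. A positive LCL is what lets a chart register a reduction
  in harm as a special-cause signal, so the overall recommendation
  (`sample_size_plan()`) is the maximum of this quantity over the
  selected harms — the rarest harm dictates the sample.

**Numerical tie handling.** When `9(1-p̄)/p̄` lands exactly on an integer
(p̄ = 0.5 gives 9, p̄ = 0.02 gives 441) the LCL at that `n` is exactly
zero in real arithmetic and the strict rule excludes it. In floating
point, the chart's computed limit at such ties can land at ±1e-17 of
zero, so `min_n_for_positive_lcl()` seeds with the algebraic threshold
and then confirms the result against the chart's own limit expression.
The returned `n` therefore agrees exactly with the sign of `pchart()`
limits for every input, ties included, and the equivalence is asserted
over a 500-point grid in the acceptance suite.

Some published positive-LCL cells are consistent only with unrounded
average proportions, not the printed two-decimal ones; those cells cannot
be reconstructed from printed inputs and are not asserted. The cells that
are reconstructible from printed averages (catheters 43, old pressure
ulcers 138, all pressure ulcers 100, and the full expected-events row)
are asserted exactly.

## Statistical conventions

"Exact binomial" is read as **Clopper–Pearson** (`exact_binomial_ci()`),
computed from beta quantiles with the x = 0 / x = n boundary identities
exact; Wilson and Jeffreys intervals exist behind a `method` flag but are
never a default. The exact interval is conservative — realised coverage
exceeds the nominal level — which the suite verifies by simulation
(10,000 replicates at n = 200, p = 0.07). `chisq_gof()` implements the
classic `Σ(O-E)²/E` statistic with optional complement-cell augmentation
for non-exhaustive categories; `two_proportion_test()` is the 2×2 Pearson
chi-square without continuity correction. Both are cross-checked in the
tests against `stats::chisq.test()`. No multiple-testing correction is
applied anywhere; reports print raw p-values.

## The synthetic generator

`scenario_config()` / `generate_cohort()` emulate the data-generating
situation of a multi-organization pilot: a configurable frame of
organizations × wards × patients, surveyed on the 15th of each month, with
settings drawn from the published mix (90% hospital ward, 3% own home, 2%
nursing home, 5% other) and harms drawn **independently per patient** from
configured probabilities. The published national proportions are the
default parameters; where the source prints no value the defaults are
fixed once at clinically plausible levels and documented here:

| parameter | default | basis |
|---|---|---|
| `p_pu_old`, `p_pu_new` | 0.065, 0.0102 | published old/new split (their sum, 7.52%, is taken over the separately rounded any-PU figure) |
| `p_fall`, `p_fall_harm_given_fall` | 0.0322, 0.391 | published falls and falls-with-harm rates |
| `p_cath`, `p_uti_given_cath`, `p_uti_new_given_uti` | 0.1673, 0.121, 0.512 | published C1, C2/C1, C3/C2 |
| `p_uti_no_cath` | 0.03 | not published; plausible treated-UTI rate in non-catheterised patients |
| `p_vte_na`, `p_at_risk` | 0.05, 0.55 | not published; small not-applicable fraction, majority of assessed inpatients at risk |
| `p_vte_assessed`, `p_prophylaxis_given_risk` | 0.6927, 0.5516 | published V1, V2 |
| `p_vte_treated`, `p_vte_new_given_treated` | 0.0364, 0.415 | published V3 + V4 and their ratio |
| category / severity / type mixes | 0.6/0.3/0.1; 0.75/0.18/0.05/0.02; 0.55/0.35/0.10 | not published; typical clinical gradients (most worst ulcers category 2, most fall harm low, DVT commoner than PE) |

Age band, gender and specialty are uniform because no distributions are
published; they are deliberately non-representative and should not be used
to study case mix. Harm independence is likewise a modelling default, not
a clinical claim: real harms cluster in frail patients. A shared lognormal
frailty multiplier (`frailty_sd > 0`) is available to induce positive
correlation, and the generator's tests demonstrate that it does; it is off
by default because independence is what makes the harm-free product
`Π(1-q_i)` an exact oracle for the composite. Passing tests on synthetic
cohorts therefore show that the *computational pipeline* is correct under
known conditions — they say nothing about data-quality phenomena of real
collection (misclassification, training effects, incomplete submission),
which are out of scope.

`generate_series()` draws independent monthly cohorts from a single
stream seeded once; `step_change` multiplies chosen probabilities from a
given month onward (clamped to [0, 1]), a minimal model of an
intervention for exercising charts and two-group comparisons.

## Problem sizes and determinism

The test suite works at sizes chosen to make sampling error negligible
relative to the assertions: parameter recovery uses one 50,000-patient
cohort (every configured prevalence within 3 binomial standard errors),
the measure-algebra properties run over 1,000 random 30-patient cohorts,
interval coverage uses 10,000 replicates, and mix-recovery uses a
100,000-patient draw. All randomness flows from explicit integer seeds;
generation restores the caller's RNG state, and the same scenario written
twice is byte-identical on disk.

## Known limitations

* Point prevalence cannot measure incidence or total harm burden; the
  72-hour windows systematically miss short-lived events.
* The published between-group chi-square values and interval widths are
  not reconstructible from the printed proportions and sample sizes (the
  printed intervals are far wider than patient-level exact intervals at
  the stated n, indicating an undocumented unit of analysis); the package
  computes its own statistics and does not attempt to reproduce those
  numbers.
* No risk adjustment, case-mix standardisation or avoidability
  attribution is performed; comparisons are descriptive and explicitly
  not for ranking.
* The harm-free composite treats the four harms symmetrically; a weighted
  composite is out of scope.
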