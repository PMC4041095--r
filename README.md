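# harmsurvey

A toolkit for monthly **point-prevalence patient-safety surveys**: on one
census day per month, every patient in a ward, organization or whole
system is surveyed for four nursing-sensitive harms — pressure ulcers
(worst ulcer, category 2–4, old/new by a 72-hour rule), falls in a care
setting in the last 72 hours, urinary tract infection in patients with a
urethral catheter, and venous thromboembolism (risk assessment,
prophylaxis, treated events) — plus the patient-level composite
**harm-free care**: no surveyed harm at all in the same patient on the
survey day.

It is written for measurement leads and analysts in quality-improvement
programmes who need the whole pipeline, not just the arithmetic:

* a validated patient-level record schema with forced-choice vocabularies
  and cross-field rules (`as_survey()`, `validate_surveys()`);
* the published measure catalogue — P1–P3, F1–F2, C1–C3, treated UTI
  without catheter, V1–V4 — and the configurable harm-free composite,
  every proportion with a Clopper–Pearson exact interval
  (`dashboard()`, `compute_measure()`, `harm_free_proportion()`);
* merge and ward → organization → region → national rollup with exact
  conservation of numerators and denominators (`merge_surveys()`,
  `rollup()`, `comparison_report()`);
* statistical process control: run charts with shift/trend rules and
  variable-denominator 3-sigma p-charts, with limits
  `p̄ ± 3·√(p̄(1−p̄)/nᵢ)` (`runchart()`, `pchart()`);
* the attribute-chart sample-size planners that decide how many patients
  to survey monthly: smallest `n` with `n·p̄ ≥ 3` for a workable chart,
  and smallest `n` with `p̄ − 3·√(p̄(1−p̄)/n) > 0` — a strictly positive
  lower control limit, without which a chart can never signal
  *improvement* (`min_n_for_expected_events()`,
  `min_n_for_positive_lcl()`, `sample_size_plan()`);
* a synthetic multi-organization cohort generator parameterised by the
  published national prevalences and setting mix, so the entire pipeline
  is testable without any real patient data (`scenario_config()`,
  `generate_cohort()`, `generate_series()`).

A thin command-line dispatcher over the same functions
(`validate` / `merge` / `report` / `chart` / `samplesize` / `simulate`)
is installed at `system.file("cli", "harmsurvey.R", package = "harmsurvey")`.

## Worked example

Simulate six months of a ten-organization survey at the published
national prevalences, pool the months, and read the dashboard:

```r
library(harmsurvey)

cfg    <- national_pilot_scenario(seed = 2012)   # 10 orgs x 5 wards x 25 patients x 6 months
batch  <- merge_surveys(generate_series(cfg))
dashboard(batch)
#> # A tibble: 14 × 7
#>    measure_id  numerator denominator proportion  ci_low ci_high
#>  1 P1                456        7500    0.0608  0.0555   0.0664
#>  2 P2                 88        7500    0.0117  0.00942  0.0144
#>  3 P3                544        7500    0.0725  0.0668   0.0786
#>  4 F1                220        7500    0.0293  0.0256   0.0334
#>  5 F2                 93        7500    0.0124  0.0100   0.0152
#>  6 C1               1315        7500    0.175   0.167    0.184
#>  ...
#> 14 HARM_FREE        6641        7500    0.885   0.878    0.893
```

Each row is events / patients with its exact 95% interval: here 7.25% of
7,500 simulated patients had a pressure ulcer (P3), 17.5% a urethral
catheter (C1), and 88.5% were harm-free — close to the configured
generator inputs (7.52%, 16.73%), as they should be at this sample size.

Chart the monthly catheterisation series and plan the sample size:

```r
nat <- rollup(batch, "national")
c1  <- nat[nat$measure_id == "C1", c("period", "numerator", "denominator")]
glance(pchart(c1))
#> # A tibble: 1 × 4
#>   centre_line n_points n_signals sigma
#> 1       0.175        6         0     3

sample_size_plan(c(pressure_ulcers = 0.0828, falls_harm = 0.0143,
                   catheters = 0.1764, catheter_uti = 0.025))
#>   measure_id       p_bar n_chart n_lcl selected
#> 1 pressure_ulcers 0.0828      37   100 TRUE
#> 2 falls_harm      0.0143     210   621 TRUE
#> 3 catheters       0.176       18    43 TRUE
#> 4 catheter_uti    0.025      120   352 TRUE
#> recommended monthly sample: 621 patients (criterion: lcl)
```

The stable catheter series shows no special-cause signal
(`autoplot(pchart(c1))` draws the chart). The plan says a chart for
catheters becomes workable at 18 patients a month and gains a positive
lower control limit at 43, but harm from falls — the rarest harm —
needs 621; since the monthly sample must serve *all* the harms, the
rarest one dictates the recommendation, which is why programmes of this
design end up surveying every patient.

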