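---
title: "Cost-minimization modeling of DVT diagnostic pathways"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cost-minimization modeling of DVT diagnostic pathways}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dvtcostmin)
```

## The question and the model

Suspected lower-extremity deep venous thrombosis (DVT) that is not ruled out
by Wells risk scoring and D-dimer needs an ultrasound. Two strategies exist:
refer the patient to a hospital emergency department (ED) for a
radiologist-performed whole-leg scan, or perform a limited compression
ultrasound (LCUS) in primary health care, repeating a negative scan after
about one week in moderate-to-high-risk patients. The literature treats the
two as clinically equivalent (similar three-month thromboembolic complication
rates), which justifies a *cost-minimization* comparison: only costs are
modelled, never diagnostic accuracy or downstream outcomes.

The unit of accounting is a *standardized patient* — the field-wise mean of a
cohort of suspected-DVT patients — costed under each pathway as a vector of
eight components: primary-care visit time (monetized), primary-care visit
price and patient fee, travel time (monetized), travel expenses, ED time
(monetized), ED visit price and patient fee. Time is monetized with the human
capital approach, `minutes / 60 × hourly wage`. Each component carries a
payer tag (public: municipal visit prices and publicly subsidised taxi
travel; private: patient fees and all monetized time) and a cost-class tag
(indirect: monetized lost working/leisure time; direct: everything else).
Both partitions sum to the total, which the test suite enforces on
randomized configurations.

## Parameters and defaults

All parameters live in one validated configuration (`default_config()`),
serializable to YAML with unknown keys rejected as typos.

| Parameter | Default | Unit | Meaning |
|---|---|---|---|
| `hourly_wage` | 18.70 | EUR/h | 2017 average hourly pay used to monetize time |
| `ed_visit_price` / `ed_patient_fee` | 503.45 / 41.20 | EUR | hospital ED episode, municipal price and patient fee |
| `phc_visit_price` / `phc_patient_fee` | 96 / 28.30 | EUR | primary-care visit price and urgent-appointment fee |
| `phc_visit_referred_min` | 30 | min | primary-care visit when the patient is referred |
| `phc_visit_lcus_min` / `phc_followup_min` | 35 / 20 | min | LCUS visit and repeat visit |
| `ed_length_of_stay_min` | 212 | min | mean ED stay (3 h 32 min) |
| `driving_speed_kmh` | 80 | km/h | distance-to-time conversion |
| counts | 60 / 44 / 20 / 16 | per year | baseline referrals; LCUS-handled; repeats; residual referrals |
| training | 3500 € + 6568 €/21 d × 12 | EUR | course fee plus one working day of salary per participating GP |

The annual counts satisfy a partition identity
(`n_referred_after + n_lcus_initial = n_referred_baseline`), enforced by the
validator. The repeat proportion is implemented as the count ratio
`20/44 ≈ 0.455`, because only the count ratio reproduces the count-weighted
table cells (e.g. `96 × 64/44 = 139.64`); the literature estimate 0.459 is
retained as `p_repeat_literature` for documentation and sensitivity work.

### Calibrated travel and component overrides

The published travel cells derive from 2017 Finnish taxi fares whose formula
is not available, so travel is *calibrated* by default: one standard hospital
episode carries 145.77 min of travel time and 361.73 € of expenses, one LCUS
visit 24.45 min and 64.0819 €, back-solved from the published per-patient
cells. Four further cells (the LCUS pathway's visit-time cell and the
real-life scenario's time/travel cells) cannot be reproduced from the stated
visit durations at all — the stated 35 + 20×20/44 minutes monetize to
13.74 €, not the published 16.86 € — so the default configuration pins them
via `component_overrides`. This is a deliberate design split:

* **default (overrides active)**: reproduces the published tables cell by
  cell, which is what a reader auditing the model needs;
* **`clear_overrides(cfg)`, optionally `travel_mode = "mechanistic"`**: a
  self-consistent mechanistic model computed from visit durations, distances
  at 80 km/h and a per-km fare (default 1.79 €/km, the calibrated standard
  episode expense divided by its 202 round-trip km), for sensitivity
  analysis.

## Numerical conventions

Monetary values are carried at full precision; cent rounding (half away from
zero) happens only at presentation. One consequence is accepted and
documented rather than hidden: the LCUS pathway's components sum to 301.95 €,
while the source table prints a total of 301.94 € that disagrees with its own
printed components. Difference checks therefore carry a ±0.02 € tolerance.
Annual totals multiply the *cent-rounded* per-patient total by the yearly
count (1151.53 × 60 = 69 091.80), matching the published convention; the
training salary cost rounds to whole euros (6568/21 × 12 = 3753.14 → 3753 €);
and the suspected-case back-calculation rounds half up (60/0.77 = 77.9 → 78).

## The synthetic cohort

The original cohort of 76 patients is not publicly deposited, so the package
generates one. Each distance is a Beta variate rescaled to its published
range with the second shape parameter fixed at 2 and the first solved in
closed form so the expectation equals the published mean (home to health care
centre: mean 16 km on 1–49 km; home to hospital: mean 85 km on 30–131 km).
This respects the hard bounds and hits the means in expectation while staying
mildly right-skewed, which is realistic for rural travel distances; the
source reports no distributional form, so this is the package's choice. The
ED stay is normal (mean 212, sd 60 min) truncated to 30–720 min via the
inverse CDF, one uniform draw per record; the sd and bounds are configurable
because only the mean is published. The centre-to-hospital leg, whose
distribution is never reported, is the home-to-hospital minus home-to-centre
difference perturbed uniformly within ±10 km and clamped. Fields are drawn in
field-major order from a single seeded stream, so adding a field cannot
reshuffle earlier ones, and the caller's RNG state is restored.

What passing tests on this cohort do *not* show: the generator reproduces
published marginal means and ranges, not the joint geography of real
addresses, road-network travel times, or any correlation between distance
and ED stay. Confidence intervals computed on simulated cohorts are
therefore validated by *coverage* (a 95% interval covers the known simulated
truth in ≈95% of replicates), never by comparison with the published
intervals, which depend on the unavailable patient-level data.

## Statistical comparison

Per-patient costs under both strategies are computed on the *same* cohort —
a paired design — and each component is summarised by a one-sample Student t
on the difference vector. Only the paired form reproduces the degenerate
intervals of constant-cost rows, e.g. `(503.45 to 503.45)` for the hospital
price every referred patient pays identically. Zero-variance differences
return the point interval with p reported as 0 (rendered `<0.001`) for a
nonzero mean and 1 for a zero mean; the source prints 0.001 and 0.000
inconsistently on such rows, and a bound is the defensible rendering.
Whether the original analysis was paired is not stated; the paired
construction is this package's documented choice. Patient-level variation
enters through each record's own ED stay (and distances in mechanistic
mode); prices and fees are constant across patients.

In reports (`run_all()`), the pathway cost columns and the difference column
are the standardized-patient point estimates — the published construction —
while the intervals and p-values come from the patient-level paired
comparison.

## Problem sizes used in the test suite

Golden-value checks are closed-form and instantaneous. Stochastic properties
use: 10 000 records for mean-recovery of the generator (Monte-Carlo
tolerances 0.5 km and 1.5 km), 300 replicate cohorts at n = 50 vs 200 for the
1/√n law of the standard error, and 500 simulated cohorts of 20–25 patients
for the 95% CI coverage check (acceptance band 92–98%). These sizes make the
full suite run in well under a minute while keeping the Monte-Carlo error a
small fraction of each tolerance.

## Degenerate inputs and tie-breaks

Empty cohorts are rejected by `standardize()` and `per_patient_costs()`;
`n_lcus_initial = 0` is rejected by the LCUS pathway (no visits to weight)
but allowed in the real-life mixture, where counts weight the baseline
directly; `p_ruleout = 1` is rejected in the back-calculation. Cent and euro
rounding use ties-away-from-zero, matching the published figures, not R's
banker's rounding.

## Known limitations

* Costs only: sensitivity/specificity of LCUS, missed DVTs, pulmonary
  embolism, false positives and etiologic work-up imaging are out of scope,
  as are device purchase costs and multi-year amortization of training.
* Single-year, single-currency model: no discounting or inflation
  adjustment.
* Four published table cells are reproduced by override, not derivation;
  their provenance in the source is unrecoverable and the mechanistic mode
  is the honest alternative.
* The generator emulates marginal summaries of one rural Finnish catchment;
  results do not transfer to other geographies or fee schedules without
  reconfiguration.
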