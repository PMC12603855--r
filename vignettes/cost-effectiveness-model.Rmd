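---
title: "A Markov cohort model for ePRO symptom-monitoring cost-effectiveness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Markov cohort model for ePRO symptom-monitoring cost-effectiveness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(schcea)
```

## The decision problem

Symptom Care at Home (SCH) is an ePRO system in which patients on
chemotherapy report the presence and 0–10 severity of 11 common
treatment-related symptoms by daily automated call; severities of 4 or more
trigger nurse-practitioner (NP) telephone follow-up. A five-arm randomized
component evaluation asked which combination of components — automated
self-management coaching (SCC), a visible activity tracker (AT), NP
follow-up, NP follow-up with decision support (DSS), or the complete system
— delivers the most symptom control per dollar. This package implements the
economic model behind that comparison, plus a synthetic patient-level
generator so the whole pipeline is testable without the (unreleased) trial
data.

## Model structure and assumptions

The engine is a cohort model with a 1-week cycle and a 26-week horizon, run
on 10,000 hypothetical patients per strategy (or in closed form). Each week
a patient independently incurs

* **any ED visit**, with arm-specific weekly probability `p_ed`; an
  event-week carries `n_ed` visits on average, each costing $1,135;
* **any unplanned hospitalization**, with probability `p_hosp`; an
  event-week carries `n_hosp` stays, each of mean length `LOS` nights at
  $3,574 per night;

and returns to the Well state. Assumptions worth making explicit:

* **No mortality** — none was observed over the 6-month trial horizon.
* **No discounting and no half-cycle correction** — the horizon is six
  months and costs are expected weekly accruals.
* **ED visits and hospitalizations are parallel, independent outcomes**
  within a week, and weeks are independent: an event does not modify later
  risk.
* **Conditional visit counts are per-event-week multiplicities.** The
  source tabulations report a mean count "for patients with ≥ 1 visit"
  without stating the window; treating it as the expected multiplicity of
  an event-week is the reading whose totals line up with the published
  per-arm costs, and it is the one the generator, the estimator and the
  engine all share, so calibration round-trips exactly.
* **The visit multiplier defaults on.** The narrative weekly-cost formula
  is `p * c` (and `p * c_night * LOS`); only the multiplier-on form
  `p * n * c` lands within ~1% of the published totals for NP-DSS, SCC-AT
  and NP, so that is the default, with `visit_multiplier = FALSE` giving
  the literal single-visit form.

Effectiveness never enters the weekly cycle: it is the arm's **horizon-mean
symptom burden** (0–10, lower better), the mean over [0, T] of a quadratic
`S(t) = a + b t + c t²` fitted by least squares to weekly mean burden
scores. For a constant curve the horizon mean is the constant, whatever the
integration bounds. Incremental comparisons convert effect to burden
*reduction* against a fixed anchor of 10 (the worst possible score), which
leaves ICERs and NMB differences anchor-invariant.

## Inputs and tunable parameters

| Parameter | Units | Default | Why |
|---|---|---|---|
| `horizon` | weeks | 26 | maximum trial participation (6 months) |
| `cohort_size` | patients | 10,000 | microsimulation cohort |
| `c_ed_visit` | $/visit | 1,135 (SD 33) | national expenditure estimate, 2023 USD |
| `c_night` | $/night | 3,574 (SD 122) | national expenditure estimate, 2023 USD |
| `dev_per_patient` | $/patient | 1,253 | development share of per-patient intervention cost |
| `intervention_cost_per_patient` | $/patient | 1,253–1,343 | per-arm totals (development + labor/operations) |
| `psa_outer` | draws | 1,000 | second-order Monte Carlo draws |
| `wtp_grid` | $/point | 0–20,000 by 250 | covers the frontier ICER region |

The $491,118 development total is carried as metadata: no printed
denominator reproduces the $1,253 per-patient share, so the share itself is
the configurable constant, and `include_development = FALSE` removes it
uniformly — which shifts every arm equally and therefore changes no ICER or
frontier status. Likewise the published per-patient intervention costs are
primary inputs: the NP wage (\$59.80/h) and monthly hours (19.79 DSS, 11.46
non-DSS) are recorded but do not re-derive the \$56–\$90 labor components
from first principles.

## The synthetic cohort

`generate_trial()` emulates the trial's statistical signatures, not its
content:

* **Time in study**: truncated normal, mean 69.6 d, SD 25.6 d, support
  [7, 182] d; weeks are 7 consecutive study days, indexed 1–26, and no
  events are generated past the last week on study.
* **Weekly events**: any-event Bernoulli draws at the arm's `p`; an
  event-week's count is `1 + Poisson(n − 1)` (support {1, 2, …}, one
  parameter, exact conditional mean).
* **Length of stay**: `1 + s(Γ)` nights per stay, where `Γ` has mean
  `LOS − 1` and the tabulated SD and `s(·)` is *stochastic rounding*
  (round down with probability 1 − frac, up otherwise). Deterministic
  rounding up would inflate the mean by about half a night and break
  calibration recovery; stochastic rounding yields whole nights ≥ 1 with
  exactly the target mean.
* **Daily severities**: each of the 11 symptoms is the burden curve value
  at that day plus Gaussian noise (SD 1.5 points), clipped to [0, 10] and
  stochastically rounded, so weekly mean burden tracks the curve
  essentially unbiasedly mid-scale.
* **Adherence**: per-patient reporting probability drawn from
  Beta(0.2, 0.1474) — median 0.756 with IQR (0.056, 0.997), chosen to match
  the reported median daily adherence of 75.6% (IQR 3.9%–100%); days report
  independently given the patient's adherence.
* **Default burden curves**: a shared gentle rise-then-decline shape
  (b = 0.06, c = −0.003, peak near week 10) with intercepts set so each
  arm's horizon mean equals its published 6-month burden score (6.5, 6.9,
  5.2, 5.3, 4.5). The supplementary weekly scores behind those means are
  not public; any curve with the right horizon mean is observationally
  equivalent downstream.

What the generator does **not** emulate: across-patient heterogeneity in
event risk beyond binomial variation (the tabulated SDs of weekly
likelihoods are slightly overdispersed relative to a common-p binomial;
the PSA consumes the tabulated SDs directly, so this does not propagate),
within-patient symptom autocorrelation, and any content of coaching or NP
interactions. Passing calibration-recovery tests therefore shows the
pipeline is self-consistent at the published parameter values — not that
real trial data would reproduce them.

## Calibration choices

* Weekly event likelihood = mean over patients of (event-weeks / weeks on
  study); its SD is the across-patient SD of those proportions (the
  tabulated SDs exceed what a binomial on the mean would allow, so a
  patient-level SD is the only consistent reading).
* Conditional counts = total visits / total event-weeks; missing (never
  zero) when the arm has no event, flagged via `missing_conditional`.
* Weekly burden: reported days only; a patient contributes the mean of
  their reported days in the week, patients are then averaged. Internal
  missing weeks are linearly interpolated before the quadratic fit (neutral
  for affine series); leading/trailing gaps are dropped and flagged. At
  least 3 non-missing weeks are required.
* Beta/gamma method-of-moments maps are exact (round-trip to 1e-9). An
  infeasible beta SD (sd² ≥ m(1−m)) is shrunk to 0.95·√(m(1−m)) with a
  warning — never triggered by the shipped inputs — so extreme user
  configurations still run.

## PSA design

1,000 second-order draws vary all transition probabilities (beta),
unit costs, conditional-count excesses and LOS (gamma) simultaneously;
burden scores stay fixed (no individual-level variability is available to
estimate). Counts are drawn as `1 + gamma` on the excess to preserve the
≥ 1 support. Unit costs are drawn once per realization and shared across
arms — they are national prices, not arm properties. Intervention and
development costs have no published uncertainty and stay fixed (a config
toggle could vary them). The inner loop defaults to the closed form: a
1,000-patient microsimulation inner loop (available via
`psa_inner_microsim = TRUE`) adds only first-order noise to the mean, at
substantial cost. Acceptability is computed by counting NMB maximizers per
draw, ties split equally, so probabilities sum to one at every threshold.

## Numerical notes and limitations

* Every stochastic entry point (`generate_trial`, `run_cohort_simulation`,
  `draw_psa_inputs`, `run_psa`) refuses to run without an explicit seed;
  seeded runs are bitwise reproducible and restore the caller's RNG state.
* Cost/effect exact ties in the frontier break deterministically (better
  effect first, then arm name; an exact double tie marks the later-sorted
  arm dominated).
* Problem sizes used by the shipped tests: 10,000 patients per arm for
  calibration recovery and microsimulation-versus-closed-form checks, 1,000
  PSA draws, 1,000 random instances for the frontier oracle comparison —
  the full published study dimensions.
* The published PSA summary rows (which report effectiveness values that
  differ from the held-constant base-case scores) are internally
  inconsistent as printed and are not reproduced; the acceptability-curve
  comparison is qualitative: above the crossover threshold the complete
  intervention is the most frequently cost-effective strategy.
* Reproducing the published ICER of exactly $4,957 requires the unrounded
  effectiveness difference (≈ 0.73) available only in the non-public
  supplement; with one-decimal scores the denominator is 0.8 and the
  deterministic model yields ≈ $5,487, inside the rounding envelope of
  roughly $4,000–$5,500 implied by the printed precision.

```{r frontier}
bc <- base_case()
find_frontier(bc)
```

```{r ceac, eval = FALSE}
psa <- run_psa(config = model_config(seed = 42))
plot(ceac(psa))
```
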