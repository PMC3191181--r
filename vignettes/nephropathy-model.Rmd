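---
title: "A Markov cohort model of diabetic nephropathy: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Markov cohort model of diabetic nephropathy: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nephroCEA)
```

## The decision problem

Diabetic nephropathy progresses through well-defined stages — normal
urinary albumin excretion, microalbuminuria (30–300 mg/d), macroalbuminuria
(>300 mg/d) — and may end in end-stage renal disease (ESRD), whose
treatment (dialysis or transplantation) costs around €42 000 per patient
per year. ACE inhibitors (with an ARB substituted when dry cough forces a
switch) slow each progression step. The policy question for a newly
diagnosed, normotensive 50-year-old with type 2 diabetes is *when* to start
the drug: immediately at diagnosis ("treat all"), after a positive annual
screen for microalbuminuria, or after a positive annual screen for
macroalbuminuria.

`nephroCEA` answers this with a lifetime Markov cohort model from a
health-insurance perspective, measuring benefit in quality-adjusted life
years (QALYs).

## Model structure

The model has five health states — normo-, micro-, macroalbuminuria, ESRD,
death — with a one-year cycle and a horizon at age 99, by which point the
cohort is essentially extinct. Progression never skips a stage.
Internally each albuminuria stage is split into an untreated (`_U`) and a
treated (`_T`) compartment so that each screening strategy can track who is
on therapy; the eight compartments project back onto the five states for
reporting (`project_states()`).

Each cycle, death is applied first as a competing risk: occupants of the
albuminuria compartments die with probability `min(1, SMR × q(age))`, the
general-population probability scaled by the standardised mortality ratio
of diabetes (1.41). Survivors progress one stage with annual probability
*q* untreated, or *q* × RR on therapy (RR 0.60 for normo→micro, 0.45 for
micro→macro, 0.61 for macro→ESRD). Applying death before progression is the
standard cohort-model convention and keeps each row of the transition
matrix stochastic without renormalisation.

ESRD occupants die with `max(0.09, SMR × q(age))`. The 0.09 is the
registry-derived annual ESRD death probability; the floor at the
age-matched diabetic background mortality is this package's own choice.
Without it, a flat age-independent 0.09 would fall *below* general
mortality above roughly age 85, implying that kidney failure confers a
survival advantage in old age and leaving several percent of the cohort
alive at 99 — contradicting both common sense and the near-complete
extinction the model is built around. The floor only binds at high ages,
where the registry rate (dominated by younger prevalent patients) is least
representative.

Strategy-specific therapy entry is encoded as edges from `_U` to `_T`
compartments at cycle start:

* **treat_all** — everyone enters therapy at diagnosis (the initial cohort
  is placed directly in the treated compartments);
* **screen_micro** — micro- (and macro-)albuminuric patients are detected
  by the annual quantitative test and start therapy; the test's sensitivity
  is taken as 1, so detection is certain and synchronous with the screen.
  With specificity below 1, normoalbuminuric patients become false
  positives with probability 1 − specificity per screen and receive the
  drug (and its protective effect and cost) thereafter;
* **screen_macro** — as above but only macroalbuminuria triggers therapy;
* **no_intervention** — computed internally as a floor comparator; no one
  is treated.

Therapy, once started, continues for life: trial-derived relative risks
already average over real-world discontinuation, so modelling separate
drop-out would double-count it. Patients already on therapy are no longer
screened (screening an already-treated patient cannot change management),
so screening fees accrue only to the untreated compartments at or upstream
of the detection stage.

## Payoffs, discounting, half-cycle correction

Utilities: 0.88 per year with diabetes in any albuminuria stage (treated
utility multiplied by 1.00 in the base case — the drug itself is taken to
be utility-neutral, with 0.95 as a sensitivity bound), 0.62 in ESRD, 0 when
dead. Costs per alive person-year: an age-dependent background health-care
expenditure; plus €547 diabetes excess, the annual drug cost (€62.70 for
the ACE-inhibitor/ARB mix) for treated compartments and the per-test
screening fee (€7.00 micro, €1.12 macro) for screened compartments — all
three excluded in ESRD; ESRD instead adds its state cost of €42 110 on top
of the background expenditure (a switch,
`esrd_cost_replaces_background`, makes it replace the background instead).
The €42 110 is taken as the charged value; `weighted_dialysis_cost()` and
`esrd_annual_cost()` reproduce it from its components (prevalence-weighted
dialysis-modality costs mixed with transplantation by the 43% dialysis
share) to within 0.3%, the residual being an unpublished first-year
transplant adjustment.

The mixed drug cost is an atomic input: no documented fee/VAT allocation of
the component prices (€6.96 enalapril, €298.68 irbesartan, 9.9% ARB share)
reproduces €62.70 exactly, so the printed figure is used directly and the
components are retained for scenario work. When the ARB share itself is
varied, the mixed cost shifts linearly by `(rate − 0.099) × (c_arb −
c_ace)` anchored at the printed value.

Costs are discounted at 4%/year and effects at 1.5%/year (the Dutch
pharmacoeconomic convention of differential discounting). Each cycle
boundary contributes occupancy-weighted annual payoffs with trapezoid
weights — 0.5 at the first and last boundary, 1 elsewhere — the half-cycle
correction acknowledging that transitions occur mid-cycle. Undiscounted
life years are reported alongside discounted QALYs.

## Synthetic demography

Two inputs normally come from national statistics and are synthesised
deterministically here:

* **Life table.** `synthesize_life_table()` uses a Gompertz–Makeham hazard
  `h(age) = a·e^(b·age) + c`, the classical two-parameter description of
  adult human mortality plus an age-independent floor. The packaged
  constants `a = 1.4e-5`, `b = 0.105`, `c = 5e-4` were calibrated once to
  two targets: remaining life expectancy at 50 of about 31 years (band
  28–34, matching a contemporary Western European population) and >99%
  cohort extinction by the age-99 boundary under SMR 1.41. The table ships
  as `inst/extdata/life_table_synthetic.csv` ("synthetic" in the name on
  purpose) and any real table with columns `age,qx` can replace it.
* **Expenditure curve.** Only the two endpoint values of the age-dependent
  background expenditure are published (€3 310.23 and €23 626.23); the
  ages they belong to are not. They are anchored at the entry age 50 and
  the horizon 99 — an assumption, not an inference — and joined
  log-linearly, since health expenditure grows multiplicatively with age.
  Both anchors and the interpolation rule are overridable.

Because the demography is synthetic, absolute discounted costs and QALYs
differ from what the real national inputs would give (our totals run some
20% higher than with the real table, driven by the expenditure
anchoring). *Incremental* quantities between strategies — the outputs that
matter — are far less sensitive: they are driven by the published
transition, cost and utility inputs. Passing tests therefore validate the
model mechanics and the incremental economics, not the absolute Dutch
totals.

## Analyses

**Base case** (`evaluate_strategies()`, `compare_strategies()`): the three
strategies' discounted costs, discounted QALYs and undiscounted life years;
strict dominance, then extended dominance along the cost-sorted frontier;
ICERs between adjacent frontier members and pairwise differences against
the customary reference, microalbuminuria screening. A strategy that costs
less and yields more than the reference is labelled *dominant* rather than
being given a negative ICER, whose sign is ambiguous; raw ratios stay in
the machine-readable columns.

**One-way sensitivity analysis** (`univariate_sa()`): each parameter with a
published range is set to each bound in turn (95% CI limits where the
source reports them), holding everything else at base case. The published
lower bound of the micro→macro probability is negative (−0.02) and is
clamped to 0. Varying the normoalbuminuria prevalence reallocates the
remainder to micro/macro in their base 18:3 ratio. Discount rates are
varied over 0–10%.

**Breakeven threshold** (`threshold_drug_cost()`): the annual drug cost at
which treat-all stops saving money versus microalbuminuria screening, found
by bisection on `[base cost, €5 000]` to €0.01. If the incremental cost
never changes sign on the bracket the function returns `NA` with a warning
rather than a fabricated root.

**Probabilistic sensitivity analysis** (`run_psa()`): 1 000 Monte Carlo
replications. Probabilities, relative risks, utilities and the ARB share
draw from method-of-moments betas (they live in [0, 1]); the ESRD state
cost and the SMR from gammas (positive support); the initial prevalence
triple from a Dirichlet with effective sample size 100 (the source
cohort's size is unpublished; overridable). Standard deviations are
reconstructed from the 95% CIs as `(upper − lower)/3.92`, isolated in
`sd_from_ci()` so another reading can be swapped in. The treatment-utility
multiplier and the test specificity have base-case means of exactly 1.00 —
the boundary of the beta's support — so no beta can carry them and they are
held fixed (each is explored deterministically in the one-way analysis
instead). The drug-cost range is a price scenario, not a sampling
distribution, and discount rates are varied deterministically only.
Incremental results are summarised as the probability of savings
(`probability_of_savings()`), net monetary benefit (`nmb()`) and the
cost-effectiveness acceptability curve (`ceac()`, default willingness-to-pay
grid €0–€100 000 in €1 000 steps). The default seed 20110 is fixed and
recorded in run manifests.

## Numerical conventions and degenerate inputs

* Row-stochasticity of every transition matrix is exact by construction;
  traces conserve probability to 1e-9 and the death column is monotone.
* `annual_prob_from_cumulative()` rejects a cumulative probability of 1
  (infinite hazard) rather than returning one silently.
* `compute_icer()` returns `NA` (an explicit undefined flag) when the QALY
  difference is zero.
* Validation (`validate_parameters()`) returns *all* violations with field
  names rather than stopping at the first.
* Ties in dominance: a strategy is dominated only with at least one strict
  inequality, so exactly equal results produce no dominance labels.

## Problem sizes

The shipped analyses use the full 50-cycle horizon throughout. The test
suite exercises the complete base case, the full one-way table (17
parameters × 2 bounds), the breakeven search, a 1 000-draw PSA and a
100 000-draw sampler-moment check; the whole suite runs in about a minute
on one CPU.

## Known limitations

* Cohort simulation on population means; no patient-level heterogeneity or
  tunnel states (e.g. transplant vintage).
* No cardiovascular effects of ACE inhibition — their inclusion would only
  increase the savings from treating early.
* Mortality and utilities are identical across albuminuria stages, as the
  evidence does not support stage-specific values.
* No correlation between sampled PSA parameters.
* The synthetic demography reproduces the *shape* of Western European
  mortality and expenditure, not any specific country's values; absolute
  cost/QALY totals should be read accordingly.
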