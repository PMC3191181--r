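# nephroCEA

A lifetime Markov cohort model of diabetic nephropathy in newly diagnosed
type 2 diabetes, for health economists asking when renin–angiotensin-system
blockade (an ACE inhibitor, or an ARB when cough forces a switch) should
start: at diagnosis for everyone, or only after a positive annual screen
for micro- or macroalbuminuria.

## The model

A cohort enters at age 50 and is followed in one-year cycles to age 99
through five states — normoalbuminuria, microalbuminuria (30–300 mg/d),
macroalbuminuria (>300 mg/d), end-stage renal disease (ESRD) and death —
without stage skipping. Death acts first as a competing risk at
`min(1, SMR·q(age))` with SMR = 1.41; survivors progress with annual
probabilities

```
q(normo→micro) = 0.056   q(micro→macro) = 0.094   q(macro→ESRD) = 0.056
```

multiplied on therapy by relative risks RR = 0.60, 0.45, 0.61
respectively. ESRD mortality is max(0.09, SMR·q(age)). Utilities are 0.88
with diabetes, 0.62 in ESRD; costs (2010 euros, health-insurance
perspective) combine an age-dependent background expenditure, a €547
diabetes excess, €62.70/year mixed drug cost, per-test screening fees and
an ESRD state cost of €42 110/year assembled as

```
X = β₁x₁ + β₂x₂ + β₃x₃          (prevalence-weighted dialysis cost)
cost(ESRD) = p·X + (1−p)·Y      (p = dialysis share, Y = transplant cost)
```

Costs discount at 4%, effects at 1.5%, with a half-cycle (trapezoid)
correction on both. The national life table and expenditure profile are
replaced by a deterministic synthetic demography module (Gompertz–Makeham
hazard; log-linear expenditure between the published endpoints) — see the
methods vignette (`vignettes/nephropathy-model.Rmd`) for why and with what
consequences.

## Worked example

```r
library(nephroCEA)

ps  <- default_parameters()        # published base-case inputs
dem <- default_demography(ps)      # synthetic life table + expenditure curve

res <- evaluate_strategies(ps, dem)
compare_strategies(res)
#> <nephro_comparison> reference: screen_micro
#>      strategy      cost   qalys    status     label
#>     treat_all 119625.80 18.8931  dominant  dominant
#>  screen_micro 122617.37 18.7976 dominated dominated
#>  screen_macro 133720.66 18.4295 dominated dominated

threshold_drug_cost(ps, dem)
#> [1] 445.2408
```

Treating everyone at diagnosis costs the least *and* yields the most
QALYs, so both screening strategies are dominated; against
microalbuminuria screening, treat-all saves about €2 992 and gains 0.096
QALYs per patient. The breakeven search says the conclusion would only
flip if the annual drug cost rose from €62.70 to about €445 — far above
even branded ARB prices. Parameter uncertainty is propagated with

```r
samples <- run_psa(ps, demography = dem, n_draws = 1000, seed = 20110)
psa_summary(samples)$probability_of_savings
#> [1] 0.986
head(ceac(samples))                # acceptability curve for plotting
```

One-way sensitivity analysis over every published range is
`univariate_sa(ps, demography = dem)`; file-based reports (CSV/JSON plus a
reproducibility manifest) are written by `report_base_case()`,
`report_sensitivity()` and `report_psa()`, also reachable from a shell via
`inst/cli/nephroCEA.R base-case|sensitivity|psa|make-lifetable`.

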