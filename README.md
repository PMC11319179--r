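# screencea

Cost-effectiveness analysis of one-shot screening for undiagnosed type 2
diabetes with three tests — point-of-care fingertip HbA1c (POCT), venous
HbA1c, and fasting capillary glucose (FCG) — in urban and rural settings.
The package is aimed at health-economic modellers who want a tested,
reusable implementation of the standard decision-tree-plus-Markov design
for this question rather than a spreadsheet or a proprietary tree.

## The model

A screened cohort with undiagnosed prevalence *p* splits by test
sensitivity *Se* and specificity *Sp* into diagnosed (*p·Se*), missed
(*p·(1−Se)*), misdiagnosed ((1−p)(1−Sp), ruled out by a gold-standard
OGTT) and true negative ((1−p)·Sp). Diagnosed and missed diabetics then
progress through a 13-state annual-cycle Markov model (uncomplicated
diabetes, six complications, three progressed complications, a lumped
multi-complication state, death) to age 80; missed cases progress under
published hazard ratios (microvascular 1.391, macrovascular 1.287, death
1.290), and rural cohorts under additional rural hazard ratios (stroke
1.25, blindness 2.09, foot ulcer 1.42, CVD and end-stage renal disease
1.15). Non-diabetics walk a two-state alive/dead model under age-specific
background mortality. Costs (USD) and QALYs accrue per cycle with
half-cycle correction and 5% annual discounting.

Strategies are compared by incremental cost-utility ratio
ICUR = ΔC/ΔE against a willingness-to-pay threshold of three times
per-capita GDP (3 × $12,551 = $37,653/QALY), with dominance handling.
One-way sensitivity analysis (±20% or explicit ranges, tornado output)
and probabilistic sensitivity analysis (beta for probabilities, lognormal
for costs, uniform otherwise; 1,000 joint draws; acceptability curves and
ICUR scatters) quantify robustness. A seeded individual-level
microsimulation cross-checks the deterministic cohort engine.

Published parameter values for this model live in supplementary material
of the originating study; the package ships a synthetic generator with
the same structure instead, so everything is testable self-contained.
Exact reproduction of published headline ICURs requires loading the real
parameter values through the documented JSON schema
(`inst/schema/parameters.schema.json`).

## Worked example

```r
library(screencea)
params <- generate_parameter_set(synthetic_spec(seed = 42))  # urban bundle
fit <- screen_cea(params)
summary(fit)
```

```
Setting: urban  (mode: cohort)
Willingness to pay: 37,653 USD/QALY

Screening-stage cost per capita (USD):
  POCT_HBA1C VENOUS_HBA1C          FCG
        8.39        15.50         4.57

Lifetime discounted outcomes and pairwise comparisons:
     strategy comparator    cost incr_cost utility incr_utility cu_ratio     icur        verdict
          FCG       <NA> 3177.80        NA   13.24           NA   240.05       NA           <NA>
   POCT_HBA1C        FCG 3173.34     -4.45   13.26         0.02   239.38  -244.23       dominant
 VENOUS_HBA1C        FCG 3182.38      4.59   13.25         0.01   240.14   328.01 cost_effective
 VENOUS_HBA1C POCT_HBA1C 3182.38      9.04   13.25         0.00   240.14 -2127.35      dominated
```

Reading the table: under this synthetic parameter set POCT HbA1c is
cheaper over a lifetime than FCG despite its higher per-test cost (its
higher sensitivity averts complication costs in missed diabetics) and
yields more QALYs, so it dominates; venous HbA1c gains QALYs over FCG at
$328 per QALY — far below the $37,653 threshold — but is dominated by
POCT. Probabilistic sensitivity analysis propagates parameter uncertainty:

```r
ps <- psa(params, n_iter = 1000, seed = 42)
ps                 # P(cost-effective) per comparison at the threshold
plot(ceac(ps))     # acceptability curves over a threshold grid
```

A full run (comparison table, tornado, PSA samples, acceptability curves,
cohort traces, manifest) from parameter files:

```sh
Rscript inst/cli/screencea.R generate --seed 1 --setting urban --out urban.json
Rscript inst/cli/screencea.R run --params-urban urban.json --out results/
```

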