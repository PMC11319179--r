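---
title: "A decision-tree plus Markov model for type 2 diabetes screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A decision-tree plus Markov model for type 2 diabetes screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question the model answers

Large parts of the adult population live with undiagnosed type 2 diabetes.
Screening finds them earlier, which delays complications, but every test
costs money and imperfect tests miss cases (who then progress untreated)
and flag healthy people (who then need a confirmatory work-up). `screencea`
models this trade-off for three one-shot screening strategies — fingertip
point-of-care HbA1c (POCT), laboratory venous HbA1c, and fasting capillary
glucose (FCG) — in an urban or rural setting, and asks which strategy buys
quality-adjusted life years (QALYs) at an acceptable price.

## Model structure

**Decision tree.** Screening happens exactly once at baseline. With
undiagnosed prevalence $p$ and a test with sensitivity $Se$ and specificity
$Sp$, the cohort splits into

* diagnosed: $p \cdot Se$ — screen-positive, confirmed by OGTT;
* missed: $p (1 - Se)$ — screen-negative diabetics;
* misdiagnosed: $(1 - p)(1 - Sp)$ — false positives ruled out by OGTT;
* true negative: $(1 - p) \, Sp$.

The oral glucose tolerance test is treated as a perfect gold standard
($Se = Sp = 1$): the confirmatory stage has no error branch, so false
positives incur the OGTT cost but nothing else, and nobody is re-screened.
Everyone pays the strategy's per-test cost (direct medical, direct
non-medical, indirect); all screen-positives additionally pay the OGTT.
The screening-stage cost is charged at time zero and therefore neither
discounted nor half-cycle corrected.

**Disease progression.** Diagnosed and missed diabetics enter a
thirteen-state annual-cycle Markov model: uncomplicated diabetes; six
primary complications (cardiovascular disease, stroke, diabetic kidney
disease, foot ulcer, retinopathy, peripheral neuropathy); three progressed
complications reachable only from their precursor (end-stage renal disease
from kidney disease, amputation from foot ulcer, blindness from
retinopathy); one lumped multi-complication state; and death, which is
absorbing. The lumped state carries a single transition probability and a
single annual cost from every complication, reflecting how sparse the
evidence on specific complication combinations is. Non-diabetics
(misdiagnosed and true negative) walk a two-state model — alive vs dead
under age-specific background mortality — encoded as the `NON_DM` row of
the same transition table, with no incident diabetes (a deliberate
simplification: the comparison between strategies concerns the prevalent
undiagnosed pool).

**Hazard-ratio adjustment.** Missed diabetics progress faster: every
transition into a microvascular state is multiplied by 1.391, into a
macrovascular state by 1.287, and into death by 1.290. In the rural
setting, transitions into cardiovascular disease, stroke, blindness, foot
ulcer and end-stage renal disease are additionally multiplied by 1.15,
1.25, 2.09, 1.42 and 1.15 for every arm. Multiplication acts on the
probabilities directly (not on rates), each product is capped at 1, and
each row is re-closed through its self-loop; should the scaled outflows
exceed 1, they are rescaled proportionally with the self-loop set to 0 and
a warning — a defined contract for a degenerate case that realistic
parameter sets never trigger. Because both adjustments are per-entry
multiplications they commute whenever no capping occurs. The
missed-diagnosis mortality ratio is applied to diabetic-state death only,
never to background (non-diabetic) mortality, and the lumped
multi-complication state carries no vascular class tag, so neither ratio
scales entry into it; both choices are configurable through the transition
table itself if a user disagrees.

**Accrual.** Cycles are one year; the cohort runs until it reaches age 80.
With discount rate $r$ (default 5%, sensitivity range 0–8%) cycle $t$
(first cycle $t = 0$, undiscounted) accrues
$\sum_s \tilde{o}_{t}(s)\, c(s) / (1+r)^t$ in cost and the analogue in
utility, where $\tilde{o}_t = (o_t + o_{t+1})/2$ is the half-cycle-corrected
occupancy — the trapezoid rule over the trace, applied to both costs and
QALYs. The baseline population is a weighted set of single-year ages; each
age stratum runs to the horizon and strata are averaged by weight.

Two engines share this contract. The forward cohort recursion
(`run_cohort`) produces full traces. A backward value sweep computes the
expected discounted cost and QALY from every state at every age in a
single pass over ages, which makes one-way and probabilistic sensitivity
analysis cheap; the two are algebraically identical and the test suite
holds them to within $10^{-9}$. A seeded microsimulation
(`run_microsimulation`) walks individuals through the same matrices with
transitions taken to happen mid-cycle (half weight to origin and
destination states), so its expectation coincides with the cohort engine;
it exists to validate the recursion and to quantify between-individual
variance, at a desk-scale number of individuals rather than the millions a
production run would use.

## Cost-utility comparison

For strategies with lifetime cost $C$ and utility $U$, the package reports
$C/U$ per strategy and pairwise incremental cost-utility ratios
$\mathrm{ICUR} = \Delta C / \Delta U$, with the usual quadrant logic: a
comparator that saves cost and gains QALYs dominates; one that adds cost
and loses QALYs is dominated, and its negative ICUR is reported signed
rather than suppressed, matching how such rows are conventionally printed.
Otherwise the verdict compares the ICUR with the willingness-to-pay
threshold $\lambda$, taken as three times per-capita GDP:
$3 \times \$12{,}551 = \$37{,}653$ per QALY. Comparisons are pairwise
(each strategy against FCG, and venous against POCT), not an efficiency
frontier, because that is how results for these three strategies are
conventionally tabulated.

## Sensitivity analysis

*One-way:* every cost, probability, utility and hazard ratio is varied to
base ± 20% (probabilities clipped to [0, 1]), the discount rate across
0–8%, or across explicit interval endpoints where a confidence interval is
available; each endpoint is a full re-run with everything else at base,
and bars are sorted by width to form a tornado. Perturbed transition rows
are re-closed through the self-loop under the same contract as the hazard
ratios.

*Probabilistic:* every parameter is drawn jointly and independently — no
correlation structure is assumed — for 1,000 iterations by default.
Probabilities get beta distributions, parameterized by event counts
($\alpha$ events, $\beta$ non-events) where known and otherwise by an
assumed effective sample size of 1,000 behind the point estimate; a half
count is added when a count is zero. Costs get lognormal distributions
with the point estimate as the median ($\mu = \ln m$) and dispersion
$\sigma = \sqrt{\ln(1 + 0.1^2)} \approx 0.09975$, chosen so that the
draw's standard deviation is exactly 10% of its mean; reading "sd = 10% of
the mean" as $\sigma = 0.1$ instead differs by under 0.3% and is available
via the `sigma` argument. Everything else (utilities, hazard ratios, the
discount rate) falls back to uniform distributions. A transition
parameter's draw scales all its age bands proportionally, preserving the
age gradient. Probability draws are clipped to [0, 1] and draws that still
fail validation are rejected and redrawn, both with reported counts. The
acceptability curve reports, per threshold, the fraction of draws with
strictly positive net monetary benefit $\lambda \Delta E - \Delta C$ —
ties count as not cost-effective, a fixed convention that matters only on
a measure-zero event.

## The synthetic generator

Published parameter values for this model live in supplementary material
that the package deliberately does not embed; `generate_parameter_set`
instead produces internally consistent bundles with the same structure, so
every stage is testable self-contained, and real values can be loaded
through the same JSON schema (`inst/schema/parameters.schema.json`) when
available. The generator's defaults are fixed at what the field would call
realistic magnitudes: undiagnosed prevalence drawn from 10–14% (urban) or
9–13% (rural); HbA1c tests with sensitivity 0.80–0.94 against FCG's
0.60–0.70, anchored on the ~65% screening sensitivity reported for
capillary glucose in Chinese adults; annual state costs from ~\$400
(uncomplicated) to ~\$10,000 (end-stage renal disease); a strictly ordered
utility ladder from ~0.93 (non-diabetic) down through complications to the
lumped state, with death at 0; Gompertz-like background mortality rising
from ~4 per 10,000 at age 20 to ~7% at 79 over 5-year bands; age-constant
complication incidence (the published tables' age granularity is unknown,
and mortality is where age dependence matters most over an 18–80 horizon);
and a single-year-age adult pyramid near sex parity. Rural bundles embed
the rural hazard ratios, raise non-medical and indirect screening costs,
and shade utilities slightly down.

What the generator does **not** emulate: correlation between parameters,
secular trends in costs or mortality, incident diabetes among
screen-negatives, treatment compliance below 100%, and the actual
published parameter values — so passing tests demonstrate that the
machinery is correct and directionally sound (missed worse than diagnosed,
rural worse than urban, higher sensitivity never harmful), not that any
particular published ICUR is reproduced. Reproducing a published headline
number requires loading that study's parameter values through the schema.

## Numerical choices and edge cases

* Discounting at integer cycle boundaries with the first cycle
  undiscounted; the backward sweep uses the same convention.
* Transition rows are validated to sum to 1 within $10^{-6}$ and then
  renormalized exactly; HR application preserves row sums to $10^{-9}$ or
  better.
* A cohort starting at or above the horizon age yields a zero-cycle
  outcome; a single-row trace cannot be half-cycle corrected and is
  returned unchanged with a warning.
* Strategy-level outcomes are the classification-weighted mixture of the
  three distinct arm runs (diagnosed, missed, negative); misdiagnosed and
  true-negative individuals share the negative arm and differ only through
  the OGTT cost already charged at the screening stage.
* Problem sizes in the shipped tests: microsimulation checks run at
  $10^5$ individuals (standard errors small enough for 3-SE agreement
  tests), distribution-moment checks at $10^5$ draws, probabilistic
  sensitivity at its default 1,000 iterations.

## Worked example

```{r, eval = FALSE}
library(screencea)
params <- generate_parameter_set(synthetic_spec(seed = 42))
fit <- screen_cea(params)
summary(fit)
ps <- psa(params, n_iter = 1000, seed = 42)
plot(ceac(ps))
```

## Known limitations

Single screening round; no incident diabetes in the negative arm; missed
cases never convert to diagnosed before a complication forces the issue;
one lumped multi-complication state; independence of PSA draws; treatment
effects enter only through the missed-diagnosis hazard ratios rather than
an explicit treatment model. These mirror the simplifications of the
modelling tradition the package implements, and each is the natural next
extension point.
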