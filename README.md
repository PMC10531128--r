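# seqcua

Cohort state-transition (Markov) modelling for cost-utility analysis of
**ordered treatment sequences**, built for health-economic questions of the
form *"where in an escalation ladder should a therapy be inserted?"*. The
bundled application is sequential knee-osteoarthritis management in Vietnam
— analgesic → NSAID(+PPI) → (second NSAID) → corticosteroid injection →
total knee arthroplasty (TKA) → death — with crystalline glucosamine
sulfate inserted before or after the NSAID stage, giving six strategies
(PD, PDE, PGD, PDG, PGDE, PDEG). The intended users are health-economics
analysts who want the full pipeline (simulation, discounting, incremental
comparison, WTP classification, tornado sensitivity) as composable, tested
R functions rather than a spreadsheet.

## The model

A closed cohort occupies mutually exclusive health states along a strictly
ordered, no-backtracking sequence; each cycle it either stays or escalates
to the next line, ending in an absorbing death state. With transition
matrix *P*, occupancy row π₀ and cycle length *c* (years):

    π_{t+1} = π_t P,      t = 0 … T − 1,   T = ⌈(L − a₀)/c⌉

    Cost  = Σ_t Σ_s π_t(s) · k(s) · (1+r)^(−tc)
    QALY  = Σ_t Σ_s π_t(s) · u(s) · c · (1+r)^(−tc)

    ICER  = ΔCost / ΔQALY

ICERs are classified against GDP-per-capita willingness-to-pay thresholds
(<1× highly cost-effective, 1–3× cost-effective, >3× not), and dominance
quadrants are resolved to labels instead of misleading signed ratios.
One-way sensitivity reruns the whole pipeline at ±20% per parameter and
ranks parameters by ICER spread (a tornado).

## Worked example

Published incremental arithmetic — the published cost/QALY totals ship as
a data fixture (`table2_base_case()`) and feed straight into the
comparator:

```r
library(seqcua)
cmp <- compare_strategies(
  list(strategy = "PGD", total_cost = 348133295, total_qalys = 100.7445),
  list(strategy = "PD",  total_cost = 314758471, total_qalys = 56.9374))
cmp
#> Incremental comparison PGD vs PD
#>   dCost : 33,374,824 VND
#>   dQALY : 43.8071
#>   ICER  : 761,859 VND/QALY
wtp_classify(cmp, economy_params(3756, 23486))
#> [1] "highly_cost_effective"
```

Adding glucosamine before the NSAID costs 33.4 million VND more over the
published horizon, gains 43.81 QALYs, and the resulting 761,859 VND per
QALY sits far below the 88,213,416 VND (1× GDP per capita) threshold —
highly cost-effective.

Running the package's own cohort model on the bundled inputs:

```r
fit <- cua(c("PD", "PGD", "PDG"), comparisons = "vs_first")
summary(fit)
#> Strategies:
#>  strategy total_cost_vnd total_cost_usd total_qalys
#>        PD     69,182,927        2945.71     15.0744
#>       PGD     66,786,384        2843.67     15.0161
#>       PDG     66,795,363        2844.05     15.0171
#>
#> Incremental comparisons (WTP thresholds at 1x and 3x GDP/capita = 88,213,416 VND):
#>  strategy comparator delta_cost delta_qaly       icer      wtp_class
#>       PGD         PD -2,396,543    -0.0583 41,100,222 not_applicable
#>       PDG         PD -2,387,564    -0.0573 41,635,475 not_applicable
```

Here each person-scale strategy accrues ~15 discounted QALYs over 68
half-year cycles from age 40; inserting glucosamine *saves* ~2.4 million
VND (it delays the expensive arthroplasty) while forgoing ~0.06 QALYs, so
the ratio is savings per QALY forgone — flagged, and deliberately not
classified against a cost-per-QALY-gained threshold. The published totals
are far larger than any single-person lifetime can produce and are
therefore treated as data, not as a reproduction target; see the methods
vignette (`vignettes/seqcua-methods.Rmd`) for the full reasoning.

One-way sensitivity and reporting:

```r
tor <- tornado(oa_inputs(), c("PGD", "PD"))   # ±20% on costs and utilities
head(tor)                                     # ranked ICER spreads
plot(tor)                                     # tornado bars

fit <- run_base_case("config.yaml")           # config-driven run
write_run_outputs(fit, "out/")                # cea.csv, comparisons.csv, results.json
```

A thin command-line wrapper lives at `inst/cli/seqcua.R`
(`run` / `tornado` / `simulate` / `validate` verbs over the same YAML
configuration).

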