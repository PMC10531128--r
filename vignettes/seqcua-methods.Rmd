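---
title: "Markov cohort cost-utility analysis of sequential treatment pathways"
author: "seqcua"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Markov cohort cost-utility analysis of sequential treatment pathways}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seqcua)
```

## The model

`seqcua` implements a cohort state-transition (Markov) model for
cost-utility analysis of *ordered* treatment sequences: a closed cohort
enters the first treatment line and, in each cycle, either stays (the
treatment still controls symptoms) or escalates to the next line (treatment
failure), never moving backwards. The final line is a surgical procedure,
followed by an absorbing death state. The bundled application is the
sequential management of knee osteoarthritis — analgesic, NSAID (with a
proton-pump inhibitor), optionally a second NSAID, a symptomatic slow-acting
drug (crystalline glucosamine sulfate) inserted at different positions,
intra-articular corticosteroid injection, and finally total knee
arthroplasty (TKA) — but every component takes arbitrary sequences.

For a transition matrix $P$ (upper triangular plus diagonal, death row a
unit vector) and initial occupancy row $\pi_0$, the trace is
$\pi_{t+1} = \pi_t P$ over $T = \lceil (L - a_0)/c \rceil$ cycles, where
$a_0$ is the entry age, $L$ the stop age and $c$ the cycle length in years.
Discounted totals are

$$\mathrm{Cost} = \sum_{t=1}^{T} \sum_s \pi_t(s)\, k(s)\, (1+r)^{-tc},
\qquad
\mathrm{QALY} = \sum_{t=1}^{T} \sum_s \pi_t(s)\, u(s)\, c\, (1+r)^{-tc},$$

with per-cycle cost $k(s)$, utility $u(s) \in [0,1]$ and annual discount
rate $r$. Two strategies are compared by
$\mathrm{ICER} = \Delta\mathrm{Cost}/\Delta\mathrm{QALY}$, with the four
quadrants of the cost-effectiveness plane resolved explicitly (dominant,
dominated, undefined, or a numeric ratio — flagged as *savings per QALY
forgone* in the south-west quadrant). Willingness-to-pay classification is
anchored on GDP per capita: below $1\times$ GDP per QALY is highly
cost-effective, between $1\times$ and $3\times$ cost-effective, above
$3\times$ not cost-effective.

## Parameters that matter

| parameter | unit | fixture default | notes |
|---|---|---|---|
| cycle length | years | 0.5 | escalation probabilities are per cycle |
| entry age | years | 40 | typical symptomatic onset age modelled |
| stop age | years | 73.6 | average Vietnamese life expectancy (2021); configurable |
| discount rate | 1/year | 0.03 | applied to costs and QALYs alike |
| GDP per capita | USD | 3756 | times 23,486 VND/USD = 88,213,416 VND |
| tornado range | relative | ±20% | the source analysis states no ranges |

The fixture (`oa_inputs()`) freezes the published input table: per-cycle
escalation probabilities (e.g. acetaminophen 0.3380, glucosamine 0.3857),
per-cycle drug costs in VND as printed, utilities per state (TKA 0.7600,
corticosteroid injection 0.6400), and the one-month post-surgery recovery
costs. The published absenteeism figure (7,342,373 VND/month) is retained
as printed even though the published annual GDP divided by twelve gives
7,351,118; `indirect_cost()` computes the latter for synthetic scenarios.

## Conventions and open choices

**Cycle timing.** Membership is counted at cycle end by default; the
half-cycle (trapezoidal) correction is an explicit flag, off by default,
because nothing in the source analysis adjudicates between the two. Both
accrue identically on a constant trace, and `time_in_state()` exposes both.

**Mortality.** No per-cycle death probabilities are published. By default
death enters the model only through the horizon: the surgery row is
absorbing (`surgery = "stay"`), and simulation simply stops at the stop
age. The alternative closure (`surgery = "escalate"`) sends the published
post-arthroplasty transition probability (0.5122) on to death, which reads
that figure as mortality/failure rather than as response. Under the default
the 0.5122 figure is carried in the fixture but does not enter the matrix.

**Cost timing.** Drug costs are interpreted as cost per 6-month cycle of
residence, as printed (a cost-period multiplier can rescale them). The
arthroplasty is different: a one-off procedure. Charging its 88.7 million
VND per cycle of an absorbing state would accrue roughly 2 billion VND per
patient — economically meaningless — so the surgery state's procedure cost,
together with the one-month recovery food/transport and absenteeism costs,
is charged once, on entry (`cost_timing = "on_entry"`), to the entrant mass
of that cycle. This is the package's own design choice; the per-cycle
interpretation remains available on any `treatment_spec`.

**Boundary classification.** ICERs exactly at $1\times$ or $3\times$ GDP
fall in the middle band by default (the published wording covers neither
boundary); `boundary = "favourable"` moves them down a band.

**Numerical choices.** Transition-matrix rows within $10^{-8}$ of 1 are
renormalized with a message, worse is an error; validation uses $10^{-12}$
on row sums. All monetary arithmetic is double-precision VND; rounding
(half-up to whole VND, USD to two decimals) happens only when report files
are written. Tornado ties are broken lexicographically by parameter path,
making rankings fully deterministic.

## Why the published totals are not reproduction targets

The published per-strategy totals (e.g. 314,758,471 VND and 56.9374 QALYs
for the standard sequence) cannot be reproduced by any single-person closed
cohort: a lifetime of at most 33.6 discounted years bounds achievable QALYs
far below 56.9, and the cohort aggregation, mortality and cost-accrual
conventions behind those magnitudes are not stated in the source. The
package therefore treats the published base-case table as *data*
(`table2_base_case()`): feeding its printed operands through
`compare_strategies()` reproduces every published ICER (761,858; 678,386;
1,133,615; 723,519; 758,326; 705,735; 979,981 VND/QALY) to printed
precision, which is exactly the arithmetic surface the tests and the
acceptance script verify. Model-generated traces are validated against
mechanical invariants (mass conservation, monotone absorption, matrix-power
equivalence) and degenerate closed forms instead.

A consequence worth stating plainly: with a feasible-lifetime cohort, the
glucosamine-insertion comparisons land in the south-west quadrant (the
insertion delays the high-utility arthroplasty state, so it both saves
money and forgoes a small number of QALYs, $|\Delta\mathrm{QALY}| \approx
0.06$). The reported ICER is then savings per QALY forgone, flagged as
such. In the one-way sensitivity analysis this near-zero denominator makes
the ICER hypersensitive to utility perturbations of high-occupancy states —
the corticosteroid-injection bottleneck (mean residence about 25 cycles)
and the inserted glucosamine state itself — which consequently outrank the
arthroplasty cost and utility that dominate in the published large-ΔQALY
analysis. The acceptance suite computes and reports this ranking rather
than assuming either ordering.

## The scenario generator

`random_model()` draws instances with the same statistical structure as the
application: 2–8 treatment lines with uniform escalation probabilities and
utilities inside configurable sub-intervals, log-uniform costs around a
configurable scale split across the three cost classes, a surgery line with
a one-off entry cost, and a synthetic economy. One integer seed drives a
private RNG stream; the global `.Random.seed` is saved and restored, so
generation never perturbs user code. `paired_variant()` mirrors the
before/after insertion construction for property tests.

The generator emulates structure, not epidemiology: it does not calibrate
to any real population, does not draw parameter uncertainty (no
probabilistic sensitivity analysis), and has no adverse-event or tunnel
states. Green property tests therefore certify the mechanics of the
pipeline — conservation, ordering, linearity, determinism — not the
clinical realism of any particular instance.

## Problem sizes

The test suite runs 1000 generated instances (up to 8 treatment states,
horizons up to 100 cycles) for conservation and absorption properties,
with matrix-power cross-checks on every tenth instance; the bundled
fixture's analyses run 68 half-year cycles over 5–7 states, and each
tornado evaluates 13 parameters at two excursions. The full suite completes
in well under a minute.

## Limitations

Beyond the generator's scope above: transition matrices are
time-homogeneous (no age-dependent mortality), the model is cohort-level
(no microsimulation), sequences cannot branch, and adverse events are not
modelled as states. These mirror the boundaries of the source analysis.
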