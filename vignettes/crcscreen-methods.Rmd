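---
title: "Model and methods behind crcscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods behind crcscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crcscreen)
```

## The model

`crcscreen` is a discrete-time Markov microsimulation of colorectal
cancer (CRC) natural history with screening overlays, built for
cost-effectiveness analysis from a healthcare-payer perspective. Each
simulated person occupies one of 15 health states:

* **Normal** epithelium;
* **low-risk polyps** (non-advanced adenomas) at 1–4 mm and 5–9 mm;
* **high-risk polyps** (advanced adenomas: ≥10 mm, high-grade
  dysplasia, or a substantial villous component);
* **preclinical CRC**, Dukes stages A–D (present but undiagnosed);
* **clinical CRC**, Dukes A–D (diagnosed, accruing treatment costs and
  stage utilities);
* **post-polypectomy** (resected, with its own new-adenoma
  probability);
* two absorbing states: **death from CRC** and **death from other
  causes**.

Progression follows the adenoma–carcinoma sequence: normal → small
low-risk polyp → medium low-risk polyp → high-risk polyp → preclinical
Dukes A, with stage-to-stage progression of preclinical disease and a
stage-specific annual probability of clinical presentation. The
serrated pathway is deliberately out of scope. Cycles are one year;
persons are simulated from their starting age (40–74) to death.

### Competing mortality

Other-cause mortality comes from a life table of annual death
probabilities by single year of age (40–100) and sex, never from the
disease-transition rows. Within a cycle the two hazards compete by a
sequential draw with disease first: CRC death (clinical states only)
keeps its full probability *m*; other-cause death then gets
*(1 − m)·h*; every live successor is scaled by *(1 − h)*. This
tie-break is a documented model decision, as is the absence of a
half-cycle correction: utilities and costs are booked at cycle start
with that cycle's discount factor `1/(1+r)^t`. The maximum simulated
age is 100; survivors accrue that final year and then die of other
causes. These conventions are shared *exactly* by the two engines
(microsimulation and expected-value cohort), which is what makes the
oracle comparison below meaningful.

### Screening strategies

Three strategy families mirror organized programs:

1. **FIT-based** — a fecal immunochemical test offered annually
   (configurable) between ages 40 and 74. FIT positives are referred to
   total colonoscopy (TCS) in the same cycle, attended with the
   follow-up uptake rate. Non-attenders of follow-up simply return to
   the routine schedule; no recall model.
2. **TCS-based** — primary screening colonoscopy offered every 10
   years (configurable). The 10-year default is a conventional choice
   for colonoscopy rescreening, flagged here because program designs
   vary.
3. **Combined** — a one-time, lifelong 80/20 split between the two
   programs. The split is persistent by design (a population-level
   allocation, not per-round re-randomization).

Offers are anchored to the simulation calendar: every person is
invited in the same rounds, so with an interval of one year each
eligible, alive, undiagnosed person receives exactly one offer per
cycle. Polyps detected at any colonoscopy are resected; the person
enters surveillance with guideline intervals (defaults: 3 years after
a high-risk finding, 5 after low-risk; editable per strategy), attended
with 70% uptake. A due surveillance supersedes routine screening and is
offered once; attended or not, the person afterwards returns to the
routine schedule unless new findings reschedule it. Diagnosed persons
exit screening. Colonoscopy perforation books a management cost and an
optional one-off disutility (default 0), with no perforation mortality.

Uptake draws are independent across rounds by default. A
`"persistent"` mode instead fixes one latent uniform per person, so
the same marginal uptake splits the cohort into habitual participants
and never-participants — a deliberately extreme alternative, since only
marginal uptake rates are specified.

## Parameters

All inputs live in one `crc_parameters` object: disease-transition
rows by 5-year age band (40–44 … 85+) and sex, test characteristics,
unit costs (JPY), utilities, the life table, and economic constants
(2%/year discounting, willingness-to-pay 5,000,000 JPY/QALY, 145.52
JPY/USD). Files in YAML or JSON are loaded fail-closed — unknown
fields are errors, not silently ignored — and any omitted block is
filled from package defaults and flagged `"synthetic"` in `meta`.
Reports built from synthetic blocks carry a visible banner, because
such results are not comparable to analyses fitted to real parameter
tables.

### What the synthetic generator emulates

`synthesize_parameters()` jitters the documented defaults as a pure
function of its seed while preserving structure (row-stochastic
transitions, FIT sensitivity non-decreasing in lesion severity,
colonoscopy dearer than FIT, non-decreasing life table). The defaults
were calibrated once, a priori, to magnitudes reported for average-risk
Japanese screening populations: an unscreened cohort shows a lifetime
CRC incidence around 5%–6% with roughly one death per three cases, and
discounted QALYs near 20.5 per person. Mean lifetime cost is of order
a few hundred thousand JPY per person, higher than published per-person
costs for comparable analyses — the model accrues an annual
stage-specific treatment cost for every year spent in a clinical
state, and the real cost tables behind published analyses are not
public. Synthetic sets therefore support *structural* and
*directional* conclusions (which uptake changes help, what dominates
what), not absolute cost levels. Passing tests demonstrate internal
consistency and the published qualitative directions, nothing more
about any real population.

## Economics

`compare_strategies()` classifies the incremental plane exhaustively:
Dominant (cheaper, more effective), Dominated (dearer, less
effective), an ICER `ΔC/ΔQ` when more effective and dearer, the same
ratio with an explicit *southwest* flag when cheaper and less
effective (a saving per QALY forgone reads differently from a cost per
QALY gained), Equivalent when both deltas sit inside tolerance, and an
"equal effect, cost differs" verdict when only the QALY delta does —
rather than dividing by a numerically meaningless difference.
Tolerances are 1e-9 QALY and 1e-6 JPY per person, far below
Monte-Carlo resolution. Net monetary benefit is `WTP·ΔQ − ΔC`;
its sign agrees with the classification away from the tolerance band.
Currency is converted only in reports (JPY integers, USD to one
decimal); internal values are never rounded.

## Probabilistic sensitivity analysis

Each uncertain parameter gets a distribution with mean equal to its
base value and standard deviation `base × range_fraction / 2`, so the
±25% default range spans mean ± 2 sd (moment matching). Probabilities
with numerator/denominator data behind them (test sensitivities and
specificity, perforation, the post-polypectomy new-adenoma
probability) use beta distributions; costs and the remaining
transition probabilities use gamma. Two numerical details:

* For a probability above 1/2 a ±25% *relative* sd can exceed the
  feasible beta variance (e.g. sensitivity 0.98). The draw is then
  taken on the complement scale — the miss rate is perturbed instead —
  which keeps the mean and a proportionate spread.
* Whether "±25%" means a dispersion statement or a hard support bound
  is genuinely ambiguous; moment matching is the default, and
  `bound_mode = "hard"` switches to a scaled symmetric beta supported
  exactly on `[0.75·base, 1.25·base]`.

Parameters are drawn independently (no correlation structure is
specified anywhere to estimate one). Utilities are left at base values
by default: a gamma on a quantity capped at 1 would need ad-hoc
truncation, and the perturbation list is configuration anyway. Each
draw simulates both strategies on the same cohort with common random
numbers; a draw is cost-effective when its NMB is strictly positive
(an exact tie counts against). Per-draw cohort size trades variance
for runtime — 20,000 by default, smaller in tests.

## Numerical design

Randomness is split into two independent Mersenne-Twister streams
derived from one seed — one for disease transitions, one for
screening — with a fixed per-cycle draw layout (every person consumes
one transition uniform and five screening uniforms per cycle whether
or not they are used). Consequences: screening never perturbs disease
trajectories, strategy comparisons are paired person-by-person (common
random numbers), and a strategy with all uptakes zero is *bit-identical*
to the no-screening comparator. Successor states are drawn by
comparing one uniform against row-cumulative transition probabilities,
composed once per parameter set for every (age, sex, state)
combination; the whole cohort advances one cycle at a time in
vectorized form, which keeps 100,000-person lifetime simulations in
the low seconds in pure R.

The deterministic engine `run_cohort_expected()` propagates the
state-occupancy vector through the same composed matrices and accrual
rules, with no RNG. It supports only the no-screening comparator:
surveillance schedules and arm assignments are person-level memory
outside the health-state space, and anything needing them raises an
unsupported-strategy error rather than silently approximating.

Problem sizes used by the test suite were chosen to keep the full run
around half a minute while leaving comfortable statistical margins:
oracle agreement at n = 100,000 on five synthetic seeds (each field
within 3 Monte-Carlo SE), uptake-direction checks at n = 40,000 with
paired differences, binomial checks at 5,000–30,000 draws with 3.3σ
bands.

## Known limitations

* No serrated-pathway carcinogenesis; all cancer arises through the
  adenoma sequence.
* Transition probabilities are not calibrated to registry incidence
  data; synthetic sets are plausible, not fitted.
* Clinical CRC treatment cost accrues annually for life in the state;
  initial/continuing/terminal cost phases are not distinguished.
* Perforation carries cost and optional disutility but no mortality.
* Pairwise comparisons only; no efficiency frontier across more than
  two strategies, no acceptability curves or value-of-information.

## A worked comparison

```{r example}
p <- synthesize_parameters(seed = 1)
pop <- sample_population(population_spec(20000, seed = 1))
fit <- run_cohort(pop, p, strategy_spec("FIT_based", fit_uptake = 0.4,
                                        tcs_after_fit_uptake = 0.7), seed = 2)
none <- run_cohort(pop, p, NULL, seed = 2)
fit
compare_strategies(fit, none, p$econ)
```
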