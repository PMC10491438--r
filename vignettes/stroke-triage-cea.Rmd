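---
title: "Modelling the cost-effectiveness of direct-to-angiography-suite stroke triage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the cost-effectiveness of direct-to-angiography-suite stroke triage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dtascea)
```

## The decision problem

Patients with an acute ischemic stroke caused by a large vessel occlusion
(LVO) benefit from endovascular thrombectomy (EVT), and every minute between
hospital door and groin puncture erodes that benefit. Two triage pathways
compete for patients who *might* have an LVO (identified prehospital by
scales such as RACE and NIHSS):

* **DTAS** — direct transfer to the angiography suite: flat-panel CT rules
  out hemorrhage, angiography confirms the occlusion, and EVT starts with
  minimal delay. Faster for true LVOs, but every false positive occupies the
  suite and undergoes an invasive work-up.
* **ITER** — initial transfer to the emergency room: conventional CT/CTA
  work-up first, then transfer to the suite when EVT is indicated.

`dtascea` implements a decision-analytic model that prices this trade-off
from a health-care payer perspective: a one-year decision tree over 90-day
functional outcomes feeding a nine-year Markov cohort model, yielding
discounted per-patient costs, quality-adjusted life years (QALYs), the
incremental cost-effectiveness ratio (ICER), and net monetary benefit (NMB),
with scenario, one-way, and probabilistic sensitivity analyses on top.

## Model structure

### Health states

Disability is measured on the modified Rankin Scale (mRS, 0 = no symptoms to
6 = death) and grouped into five model states: `MRS01`, `MRS23`, `MRS4`,
`MRS5`, and absorbing `DEAD`. mRS 0 and 1 are pooled because trials report
"excellent outcome" as mRS 0–1; mRS 2 and 3 are pooled because their
utilities and annual care costs are close.

### Stage 1: the one-year decision tree

A patient entering the pathway has a confirmed LVO with probability
$p_{\mathrm{LVO}}$ (base case $147/174 = 0.845$, the confirmation rate of
the source trial; `base_p_lvo_from_trial()`). Confirmed-LVO patients incur
the strategy's acute cost and realise the strategy's 90-day mRS distribution
$p^{90}_s$. Because functional status is not settled at 90 days, the 90-day
vector is propagated through a 90-day-to-1-year transition matrix $T_{90}$:

$$p^{1y}_s = p^{90}_s \, T_{90}.$$

Non-LVO patients contribute only the strategy-specific diagnostic cost:
their downstream care is assumed identical under either strategy, so those
(identical) terms cancel in every increment and are excluded from totals by
default. The flag `options$include_non_lvo_outcomes` plus a user-supplied
`non_lvo_profile` adds an identical outcome stream to both arms when totals
comparable to an all-comers table are wanted.

Year-1 care costs and utilities accrue on the one-year (post-transition)
distribution — the model's anchor state — and year 1 is the present, so it
is undiscounted.

### Stage 2: the Markov cohort model

The one-year distribution enters an annual-cycle Markov model run for
`markov_years` cycles (default 9, for a 10-year horizon: at entry age 74 the
residual life expectancy is around 12 years, so little mass survives the
horizon anyway). Within each cycle, **mortality acts first**: a patient in
living state $s$ at age $a$ dies with probability

$$q(s, a) = 1 - \bigl(1 - q_0(a)\bigr)^{\mathrm{HR}_s},$$

where $q_0(a)$ is the general-population life table and $\mathrm{HR}_s$ a
state-specific hazard multiplier applied on the annual survival scale — this
keeps $q$ a probability for any $\mathrm{HR} \ge 0$. Survivors are then
redistributed by the annual transition matrix, renormalized over living
destinations. This ordering keeps the two evidence sources orthogonal: the
transition matrices describe mRS change *conditional on survival*, while
mortality comes from the separate life-table construction. If a source
instead tabulates absolute death probabilities by state and age, the schema
accepts a `q_abs` table which takes precedence over the multipliers.

Cycle $k$ (calendar year $1+k$) accrues
$\sum_s \pi_k(s)\,c(s)\,(1+r_c)^{-k}$ and
$\sum_s \pi_k(s)\,u(s)\,(1+r_e)^{-k}$, weighted by $p_{\mathrm{LVO}}$, with
Dutch-guideline discount rates $r_c = 4\%$ for costs and $r_e = 1.5\%$ for
QALYs.

Three structural conventions were genuinely open and are exposed as flags
rather than hidden:

* **Accrual timing** (`options$accrual`, default `"end"`): whether a cycle's
  costs/QALYs accrue on the end-of-cycle or start-of-cycle occupancy. The
  default charges the year to the state the patient ends it in; the
  alternative is more generous to survivors. The choice shifts totals by low
  single-digit percent.
* **Half-cycle correction** (`options$half_cycle`, default `FALSE`):
  averaging start and end occupancy. With annual cycles over nine years the
  correction is second-order; since accrual is linear in occupancy, the
  half-cycle result is exactly the mean of the two accrual conventions
  (tested).
* **Discount exponent**: cycle $k$ carries $(1+r)^{-k}$ with year 1
  undiscounted — the standard present-value convention anchored at
  treatment.

## Parameters, units, and provenance

A complete parameterization is one JSON document (schema
`dtascea-parameters-v1`, read/written by `load_parameters()` /
`write_parameters()` with full floating-point precision, so round-trips are
exact). All computation happens in EUR (2021 price level); USD figures are
produced at reporting time with the fixed rate 1.1827 (`convert_currency()`).

| block | meaning | units / default |
|---|---|---|
| `outcome90d` | 90-day mRS distribution per strategy, confirmed LVOs | simplex |
| `t90`, `t_annual` | mRS transitions 90 d→1 y and annual | row-stochastic |
| `mortality` | life table `q0(a)` + per-state hazard multipliers | annual probability |
| `utilities` | QALY weight per living state, `DEAD` = 0 | [−1, 1], monotone |
| `costs` | acute per strategy; non-LVO diagnostic; annual care per state | EUR 2021 |
| `triage.p_lvo` | probability of confirmed LVO | (0, 1]; 147/174 |
| `econ` | discounting 4%/1.5%, horizon 1 + 9 y, entry age 74, thresholds EUR 50k/80k | — |

Validation (`validate_parameters()`) checks every invariant — simplex sums to
1 within $10^{-9}$, absorbing death row, utility ordering, non-negative
costs, life-table coverage of the whole horizon, resolvable sensitivity
paths — and reports **all** violations at once, not just the first.

The packaged file `extdata/params_synthetic_base.json`
(`example_parameters()`) separates provenance explicitly in its `sources`
block: publicly stated quantities (the 147/174 confirmation rate, arm sizes
74/73, entry age 74, the discount rates, the EUR 50,000/80,000 thresholds,
the exchange rate, the scenario overrides, and the base value 0.2838 of
P(mRS 0–1 | DTAS), recovered as the midpoint of its published ±20%
sensitivity range 22.70–34.06%) are used verbatim; every other clinical and
economic entry is a clearly marked *synthetic placeholder*, chosen once for
clinical plausibility (e.g. annual care EUR 2,800 for mRS 0–1 up to EUR
44,000 for bedridden patients; utilities 0.85/0.62/0.32/0.05; hazard
multipliers 1.5–4.9). Results computed from this file exercise and
illustrate the pipeline; they are **not** estimates for any real setting,
and the packaged acceptance checks against published results are expected to
fail until a user transcribes the real supplementary tables into the file.

Two source-data ambiguities were resolved as follows: the 90-day
distributions are treated as conditional on *confirmed* LVO (the triage
split happens first, matching the model diagram's branch order), and acute
costs are carried as one aggregate per strategy — a user whose cost source
separates IVT/EVT unit costs and rates (e.g. EVT in 100% of DTAS vs 87.7% of
ITER patients) should enter the rate-weighted sum.

## Scenarios

`apply_scenario()` implements three predefined deviations from the base
case: scenario 1 sets $p_{\mathrm{LVO}} = 0.42$ (the positive predictive
value of RACE > 4 alone, dropping the NIHSS > 10 criterion); scenario 2 sets
$p_{\mathrm{LVO}} = 0.12$ (LVO incidence among all FAST-positive suspected
strokes — the all-comers setting); scenario 3 shortens the Markov stage to
4 years. Overrides touch nothing else and are idempotent.

## Sensitivity analyses

**One-way / tornado** (`one_way()`, `tornado()`): a parameter is set to its
low and high bound and the whole pipeline re-run. When the parameter is one
component of a probability vector, the remaining components are rescaled by
$(1-p')/(1-p)$ — the least-informative simplex repair; bounds that cannot
be renormalized raise an error. Where a range is not supplied the
conventional ±20% of the base value is used. Entries are ordered by the
absolute ICER spread. For spread computation the signed incremental ratio
$\Delta C / \Delta E$ is used, which stays continuous when a bound crosses
into a dominance quadrant ($\Delta E = 0$ yields `NA`).

**Probabilistic** (`sample_psa()`): each declared parameter is drawn from
its distribution family — Dirichlet for whole outcome vectors and transition
rows (sampled jointly, which preserves the simplex and the negative
correlation between components; componentwise beta sampling is available by
simply declaring beta descriptors for the components instead), beta for
single probabilities and utilities, gamma for costs and hazard multipliers.
Where a source gives only a mean, hyperparameters are moment-matched with a
standard error of 20% of the mean (`psa_beta_spec()`, `psa_gamma_spec()`),
and Dirichlet concentrations equal the source arm's effective sample size.
Sampling is deterministic given the seed (default 20230905), with
parameters drawn in lexicographic path order.

**Acceptability** (`ceac()`): a draw counts the intervention cost-effective
at threshold $\lambda$ iff $\mathrm{NMB} = \lambda\,\Delta E - \Delta C > 0$
— the NMB rule handles all four quadrants without the sign pathologies of
the ICER, and ties go to the comparator. The default grid spans 0 to
150,000 per QALY in 1,000 steps with the decision thresholds inserted
exactly. Because NMB positivity is invariant to rescaling costs and
$\lambda$ by the same factor, acceptance probabilities at EUR 50,000/80,000
are identical to those at USD 59,135/94,616.

## The synthetic generator and the microsimulation oracle

`generate_parameter_set(synthetic_spec(...))` draws complete, valid
parameter sets: 90-day vectors are Dirichlet around a proportional-odds
(ordinal-shift) pair — the two arms differ by a shift of `effect_shift` on
the cumulative log-odds (default 0.7, an odds ratio around 2, a plausible
magnitude for a workflow intervention; 0 makes the arms exchangeable) —
with concentration equal to the trial arm sizes (74/73); transition rows
are Dirichlet with diagonal dominance (the annual matrix more strongly
diagonal, since disability is largely stable after the first year);
utilities are ordered draws; costs gamma draws around Dutch-magnitude
means; background mortality is Gompertz,
$q_0(a) = 1 - \exp\{-A e^{B(a-70)}\}$ with $A = 0.02$, $B = 0.09$ (about
2.8% at 74, 6.8% at 84, life-table-like for a Western European population).

What the generator deliberately does **not** emulate: correlation between a
strategy's costs and its outcomes, time-varying utilities or costs,
recurrent-stroke tunnel states, and covariate heterogeneity within an arm.
Passing tests on generated sets therefore demonstrate the *mechanics* of the
pipeline under realistic magnitudes, not the validity of any particular
clinical parameterization.

`microsimulate()` is the independent oracle: it pushes individual patients
through the same event sequence (triage Bernoulli, categorical 90-day
outcome, categorical 90-day-to-1-year move, then per cycle a death Bernoulli
followed by a categorical survivor transition) and accrues identically
discounted amounts per patient. It shares no code with the cohort engine's
matrix recursion, so agreement of its mean with the cohort totals within
Monte Carlo error is a genuine cross-validation. The test suite checks this
at 3 standard errors for 20 generated parameter sets with 200,000 patients
each, plus exact equality on a fully degenerate chain; the default suite
adds smaller runs (50,000 patients) across accrual configurations. These
problem sizes — like the 1,000-set conservation sweep and the 10,000-draw
PSA — were chosen as the package's own test scale; a 10,000-draw PSA takes
on the order of 15 seconds on one core.

## Numerical choices and degenerate inputs

* Simplex and row-sum tolerance: $10^{-9}$ throughout validation and
  propagation checks.
* Life-table coverage outside the tabulated ages clamps to the nearest
  tabulated $q_0$ (the packaged table covers 74–85, the full horizon).
* A living transition row with zero mass on living destinations but nonzero
  survivors is an error (renormalization undefined), not a silent repair.
* Renormalizing a probability component that holds all the mass
  ($p = 1 \to p' < 1$) is an error for the same reason.
* Parameter files serialize doubles at 17 significant digits, so
  write/load round-trips are bit-exact.
* Zero Dirichlet concentrations are accepted as the degenerate limit (the
  category stays at zero), which structural zeros in transition rows
  require.
* `markov_years = 0` collapses the result exactly to the decision-tree
  stage (used as a limit check).

## Known limitations

Two strategies only (no multi-way frontier), no expected value of perfect
information, no two-way sensitivity analysis, no tunnel states or
time-varying rewards, and no cost indexation — inputs are assumed to be at
the 2021 price level already. The packaged parameter file is a structural
stand-in: all headline numbers computed from it are illustrative until the
supplementary evidence tables are transcribed.

## A worked run

```{r, eval = FALSE}
params <- example_parameters()
base <- run_cea(params)
base

tor <- tornado(params)
psa <- sample_psa(params, n = 10000, seed = 20230905)
curve <- ceac(psa)

report_table(list(base = base,
                  "1" = run_scenario(params, "1"),
                  "2" = run_scenario(params, "2"),
                  "3" = run_scenario(params, "3")),
             currency = "USD")

plot_ce_plane(psa); plot_ceac(curve); plot_tornado(tor, base_icer = base$icer)
```
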