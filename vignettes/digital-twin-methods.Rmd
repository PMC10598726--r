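---
title: "Predictive digital twins for glioma radiotherapy: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predictive digital twins for glioma radiotherapy: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gliotwin)
```

## The problem

High-grade glioma is treated after surgery with six weeks of fractionated
radiotherapy (RT) and concomitant chemotherapy. The standard of care (SOC)
delivers 30 fractions of 2 Gy — the same 60 Gy schedule for every patient —
yet response to radiation varies widely between patients. `gliotwin`
implements a *predictive digital twin* of one patient's tumor: a mechanistic
growth model whose parameters are uncertain, updated from that patient's
imaging-derived tumor-burden measurements, and then used to search for a
weekly RT dose schedule that controls the tumor at acceptable toxicity —
with the uncertainty carried through every step.

## Mechanistic model

Tumor burden $N(t)$ (total cell count) follows logistic growth

$$\frac{dN}{dt} = \rho N \left(1 - \frac{N}{K}\right), \qquad N(0) = N_\mathrm{initial},$$

with net proliferation rate $\rho$ (day$^{-1}$) and tissue carrying capacity
$K$ (cells). Each treatment day multiplies the cell count instantaneously by
a linear-quadratic surviving fraction

$$S(d) = S_C \, e^{-\alpha_{RT} d - \beta_{RT} d^2}, \qquad
  \beta_{RT} = \alpha_{RT} / 10,$$

where $d$ is the day's RT dose in Gy, $\alpha_{RT}$ (Gy$^{-1}$) is the
patient's radiosensitivity, and $S_C = 0.82$ accounts for the concurrent
chemotherapy dose. The uncertain, patient-specific *digital state* is
$\theta = (\rho, K, N_\mathrm{initial}, \alpha_{RT})$; $S_C$ and
$\alpha/\beta = 10$ Gy are fixed.

The ODE is integrated by forward Euler with step $dt = 0.2$ days over a
152-day horizon. At that step the no-treatment solution stays within 0.5% of
the exact logistic solution over the whole horizon (the error halves with
the step; both are tested against `closed_form_logistic()`). Kill events are
applied at the beginning of their day, before that day's growth steps. The
recorded trajectory value at a grid time is the **pre-event** state; this
convention makes $N(20)$ the pre-RT burden even though day 20 is the first
RT day, which is exactly the progression threshold the risk analysis needs.

### Treatment calendar

RT runs for six weeks starting on day 20, five consecutive fraction days
per week (days 20–24, 27–31, …, 55–59), ending on day 62. A regimen is a
vector of six weekly doses $u$ (Gy/day, each in $[0, 10]$); the total
physical dose is $5\|u\|_1$. The SOC is $u = (2,2,2,2,2,2)$, i.e. 60 Gy.

Chemotherapy is administered **daily** throughout the six treatment weeks —
weekends and zero-RT-dose weeks included — matching how concomitant
temozolomide is actually given in the Stupp protocol. The weekly cadence is
a genuine modeling choice (the clinical description fixes only that
chemotherapy continues "throughout" the treatment weeks), and it matters:
under a 5-day chemotherapy week the prior-implied cohort is dominated by
early progressors (about a quarter of ground-truth patients progress within
a month of the end of RT), whereas the daily cadence reproduces the
early/intermediate/late composition expected of this population. The
cadence is a single constant (`chemo_days_per_week`, default 7), and
`expand_regimen()` (the 30 RT fractions) is kept separate from
`treatment_events()` (the full 42-event schedule) so either convention can
be simulated.

## Virtual patients and observations

No clinical data enter the package. An in-silico cohort stands in for a
patient population: each patient's ground truth $\theta_\mathrm{true}$ is
drawn from independent truncated normal priors informed by literature
population values —

| parameter | mean | sd | bounds |
|---|---|---|---|
| $\rho$ (day$^{-1}$) | 0.09 | 0.15 | [0.007, 0.25] |
| $K$ (cells) | $10^{11}$ | $2\times10^{10}$ | $[9\times10^{10}, 1.8\times10^{11}]$ |
| $N_\mathrm{initial}$ (cells) | $1.9\times10^{10}$ | $1.2\times10^{10}$ | $[4.7\times10^{9}, 4.7\times10^{10}]$ |
| $\alpha_{RT}$ (Gy$^{-1}$) | 0.05 | 0.025 | [0.001, 0.1] |

Observations emulate MRI-derived tumor-burden estimates on days 0
(post-surgery), 20 (pre-RT) and 27 (end of the first RT week, acquired under
SOC dosing): $o_i = N(t_i; \theta_\mathrm{true}, u) + \varepsilon_i$ with
$\varepsilon_i \sim TN(0, \sigma^2, -N(t_i), \infty)$, so observations are
never negative. The noise scale $\sigma = 2\times10^9$ cells is 10% of the
prior mean initial burden and is treated as known throughout.

What this generator does *not* emulate: the MRI post-processing that turns
images into cell counts (and its volume-dependent error), spatial
heterogeneity, measurement drift between visits, or model misspecification —
the virtual patient is governed by the same ODE the twin uses. Passing tests
therefore demonstrate the *inferential and decision machinery*, not clinical
accuracy on real data.

## Calibration

Personalization is a two-step Bayesian update.

**Step 1.** The day-0 observation only informs the initial burden; its
posterior is taken as $TN(o_0, \sigma^2, \max\{0, o_0 - 2\sigma\},
o_0 + 2\sigma)$ (`initial_burden_update()`), and replaces the population
prior on $N_\mathrm{initial}$.

**Step 2.** The remaining observations enter a likelihood built from the
same truncated normal noise model as the generator (support $o \ge 0$) —
matching the generative and inference models is the defensible default. The
joint posterior of $(\rho, K, N_\mathrm{initial}, \alpha_{RT})$ is sampled
by MCMC on log-transformed parameters (with Jacobian correction; $K$ and
$N_\mathrm{initial}$ span $10^{10}$–$10^{11}$ so log-scale conditioning
matters), and the day-0 observation is excluded from the Step-2 likelihood
to avoid double counting.

With three observations and four parameters the posterior concentrates on a
strongly curved, nearly one-dimensional ridge: $\rho$, $K$ and
$\alpha_{RT}$ trade off against each other (sample correlations of
$\pm 0.95$–$0.98$). Covariance-adapted random-walk Metropolis mixes poorly
on this geometry, so the sampler is an affine-invariant ensemble
(stretch-move) sampler: each of the (default four) "chains" is an
independent ensemble of 32 walkers started in a small ball around the
posterior mode found by a Nelder–Mead search, with warmup discarded and
optional thinning between retained ensemble snapshots. Convergence is
gated on split-$\hat R < 1.01$ across chains; a run that misses the gate
fails loudly with the diagnostics attached rather than returning a dubious
posterior. Recovery of known ground truths (posterior mean within 2
posterior sd on all four parameters, posterior sd below the prior sd) is
part of the test suite at the scaled setting of 4 chains × 5000 retained
draws, warmup 20000, thinning 24.

## Risk: time to progression and the superquantile

Tumor control is summarized by the time to progression (TTP): the time after
RT ends (day 62) at which the burden first exceeds its pre-RT value
$N_\mathrm{th} = N(20)$, measured from day 20 and right-censored at
$152 - 20 = 132$ days by the simulation horizon. Detection uses the
integration grid, so TTP has resolution 0.2 days and its smallest attainable
value under the defaults is 42.2 days. Censoring is applied inside the TTP
computation, which caps every downstream statistic at 132 days.

The quantity of interest is $M = -T_\mathrm{TTP}$ (so smaller is better),
and risk is the $\alpha$-superquantile (conditional value-at-risk)

$$\bar Q_\alpha[M] = Q_\alpha[M] + \frac{1}{1-\alpha}
  \mathbb{E}\big[[M - Q_\alpha[M]]^+\big],$$

the mean of the worst $100(1-\alpha)\%$ of outcomes, with $\alpha = 0.95$ by
default. The plug-in estimator uses the upper order statistic
$\lceil\alpha n\rceil$ without interpolation, so it coincides exactly with
the mean of the worst $\lceil(1-\alpha)n\rceil$ samples whenever
$(1-\alpha)n$ is an integer; any consistent convention satisfies the
defining identity, and this one makes the tail-average property testable
exactly. The per-patient scalar used in every cohort analysis is the TTP
$\alpha$-superquantile, $-\bar Q_\alpha[-T_\mathrm{TTP}]$ — a conservative,
tail-aware summary of tumor control.

## Dose optimization under uncertainty

Week 1 is fixed at the SOC 2 Gy/day (the mid-RT scan that informs
$\alpha_{RT}$ is acquired at the end of that week); the doses of weeks 2–6
are optimized:

$$u^\ast = \arg\min_{u}\; \bar Q_\alpha[-T_\mathrm{TTP}(u,\theta)]
  + \lambda\|u\|_1 \quad \text{s.t.}\quad 5\|u\|_1 \le D_\mathrm{max},\;
  u_i \in [0, 10].$$

The dose penalty $\lambda = 0.001$ (days of risk per Gy/day summed over
weeks) is far below the 0.2-day TTP resolution, so it can never trade tumor
control for dose; its only effect is to drive the dose down along TTP
plateaus — most visibly for patients whose posterior is fully controlled,
where the risk saturates at $-132$ and the optimizer walks to the lowest
feasible dose. Sweeping $D_\mathrm{max}$ over $\{40, 50, 60, 70, 80, 100\}$
Gy traces the Pareto front between tumor control and toxicity
(epsilon-constraint scalarization).

Numerical choices that matter:

* **Common random numbers.** The Monte-Carlo draw subset (default
  $n_{MC} = 5000$) is frozen once per optimization, so the objective is a
  deterministic function of the doses and the whole optimization is
  reproducible from `(posterior, seed)`.
* **Derivative-free local search.** The objective is piecewise constant in
  the doses at the TTP grid resolution, so gradient methods are out. Each
  restart runs a log-barrier Nelder–Mead search (`stats::constrOptim`) under
  the box and total-dose constraints; restart 1 starts at the SOC (projected
  into the feasible set when $D_\mathrm{max} < 60$), the rest at uniform
  random feasible points.
* **Best-evaluated-candidate bookkeeping.** Every feasible point the search
  evaluates is tracked and the best one is returned, with ties broken toward
  lower total dose. Because the SOC itself is evaluated whenever feasible,
  the returned plan is non-inferior to the SOC on the frozen draw set by
  construction — the optimizer can only add improvement.
* **Degenerate budget.** At $D_\mathrm{max} = 10$ Gy only the fixed week-1
  dose fits; the unique feasible vertex is returned directly since the
  feasible set has no interior for the barrier method.

## Cohort analysis

Each patient contributes one number per treatment policy — the TTP
$\alpha$-superquantile — to the cohort analyses. Patients are stratified by
their SOC value: *early* progressors within one month (30 days) of the end
of RT (≤ 72 days), *late* progressors at the 132-day cap (controlled through
the horizon), *intermediate* in between; the cap makes "≥ 3 months after the
end of RT" and "censored" the same set. Survival to progression is estimated
with the Kaplan–Meier product-limit estimator, with values at the cap
treated as right-censored, and policies are compared with the standard
two-sample logrank test (both implemented from their defining forms and
cross-checked against the `survival` package in the tests). Uncertainty in
the survival curve is available by bootstrap over each patient's TTP
Monte-Carlo draws (`survival_variance_bootstrap()`) rather than a
Greenwood-type approximation. The dose-reduction analysis reports, per
patient, how far below 60 Gy one can go along the Pareto front while keeping
the TTP superquantile within ±1 day of (or better than) the SOC value.

## Scaled study sizes

The package defaults mirror the full study conditions (100 patients, 4
chains × 100000 MCMC draws, $n_{MC} = 5000$, 20 restarts × 200 evaluations,
six $D_\mathrm{max}$ values). The test suite exercises the same pipeline at
reduced sizes chosen to keep the full suite comfortably reproducible on a
single CPU while leaving Monte-Carlo error well inside the asserted
tolerances: recovery tests at 4 × 5000 draws; invariant checks on a
10-patient cohort with $n_{MC} = 1000$ and 5 × 100 evaluations; and a
30-patient end-to-end reproduction with $n_{MC} = 500$, 8 restarts × 150
evaluations and the $\{40, 50, 60\}$ Gy grid. These sizes are stated here so
that any reported number can be traced to the problem size that produced
it.

## Known limitations

* The virtual cohort is generated by the same model family the twin fits;
  there is no model misspecification, so calibration performance on real
  data will be worse than the recovery tests suggest.
* TTP resolution is tied to the integration step; schedules whose true TTPs
  differ by less than 0.2 days are indistinguishable to the optimizer.
* The multi-start local search carries no global-optimality certificate; on
  plateau-heavy objectives different budgets can return different (equally
  feasible, near-tied) schedules.
* Chemotherapy scheduling, daily-resolution dose painting and imaging-visit
  timing are out of scope by design.
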