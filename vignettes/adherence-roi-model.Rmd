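---
title: "Modeling the return on investment of adherence-enhancing chronic disease policies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling the return on investment of adherence-enhancing chronic disease policies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(roisim)
```

## The model

`roisim` evaluates chronic-disease management policies by simulating, in
continuous time, the interplay of three processes over a multi-year
horizon:

1. **Disease progression.** Severity follows a logistic worsening curve
   $D(s) = D_{\max} / (1 + e^{-k(s - s_0)})$, rising from near zero toward
   the ceiling $D_{\max}$ with rate $k$ and midpoint $s_0$.
2. **Medication adherence.** A fraction-like level $A(s) \in [0, 1]$,
   shifted by a policy according to one of five trajectory shapes
   (see below).
3. **Cost accumulation.** Instantaneous cost combines disease burden,
   adherence effort, policy expenditure and an optional monetized health
   term,
   $$c(s) = \alpha D(s) + \beta A(s)^2 + \gamma P(s) + \lambda H(s),$$
   and cumulative cost is its discounted integral
   $C(t) = \omega\,\bigl(C_0 + \int_0^t e^{-\rho s} c(s)\,ds\bigr)$ with
   continuous discount rate $\rho$.

A policy design is summarized by two levers: the adherence gain $\delta$
it produces and the cost scale $\gamma$ it requires. Economic value is
measured by the return on investment
$$\mathrm{ROI}(\delta,\gamma) = 100 \cdot
  \frac{C_{\text{baseline}} - C_{\text{policy}}(\delta,\gamma)}
       {C_{\text{policy}}(\delta,\gamma)},$$
the percent relative savings against a no-intervention counterfactual.
Note the denominator is the *total* policy-scenario cost, not the
incremental policy spend; we implement the definition as stated even
though it is unconventional, because all downstream break-even and
sensitivity analyses inherit it.

### Adherence-progression coupling

Scenario-dependent severity requires a mechanism by which adherence slows
progression. We use the minimal multiplicative coupling

$$\frac{dD}{ds} = k\,\bigl(1 - \eta\,(A(s) - A_{0,\mathrm{ref}})\bigr)\,
  D\,\Bigl(1 - \frac{D}{D_{\max}}\Bigr), \qquad A_{0,\mathrm{ref}} = 0.5,$$

with $D(0)$ on the closed-form logistic curve. Its two properties drove
the choice:

* at the reference adherence ($A \equiv 0.5$) it reproduces the
  closed-form logistic *exactly*, so the flat baseline's disease cost term
  is the printed logistic term; and
* in logit space the equation is linear,
  $\frac{d}{ds}\,\mathrm{logit}(D/D_{\max}) =
  k(1 - \eta(A - A_{0,\mathrm{ref}}))$, which yields an exact quadrature
  oracle for piecewise-constant adherence that the test suite checks the
  integrator against.

The coupling strength $\eta$ (default 0.8) is bounded at validation so the
effective rate stays non-negative for any admissible adherence. We chose
not to let adherence modulate $D_{\max}$; interventions delay, rather than
cap, progression here.

### Scenario shapes

The canonical registry (`scenario_table()`) holds six designs:

| Scenario | Start $\tau$ | Gain $\delta$ | Cost $\gamma$ | Shape |
|---|---|---|---|---|
| Baseline | -- | 0 | 0 | constant $A_0$ |
| Early Adherence | 2 | +0.3 | 1.5 | step |
| Delayed Intervention | 5 | +0.3 | 1.5 | step |
| Regressive Adherence | 2 | +0.3 decaying | 1.2 | $\delta e^{-\theta(s-\tau)}$ |
| Adaptive Nudges | 2 | +0.3 stepwise | 2.0 | decay with resets |
| Low-Impact Policy | 2 | +0.05 | 3.0 | step |

The indicator convention is $I(x) = 1$ for $x \ge 0$: the gain applies at
$\tau$ itself. The adaptive shape resets adherence to $A_0 + \delta$
whenever it would fall below the threshold `A_thresh`; each re-activation
adds an impulse cost $e^{-\rho t_e}\,\gamma\cdot\text{nudge\_cost}$
directly to the cumulative integral ("cost proportional to the number of
activations"), not to the expenditure rate. Two semantic choices were
open and are resolved as follows: the adaptive start time is $\tau = 2$
(the registry's source marks it only as "varies"), and a nudge *resets*
adherence to $A_0 + \delta$ rather than adding $\delta$ on top — the reset
is bounded by construction and cannot ratchet adherence to 1.

A decaying baseline counterfactual $A_0 e^{-\theta_b s}$ is available via
`baseline_decay_rate`, for studying how constant-adherence baselines
overstate incremental benefit. The exponential form is our choice; only
the qualitative behavior (slow erosion of untreated adherence) is
prescribed.

## Parameters, units and defaults

| Symbol | Field | Unit | Default | Rationale |
|---|---|---|---|---|
| $C_0$ | `C0` | model-cost | 1 | one year of baseline care as offset; keeps every design in the default $(\delta,\gamma)$ ranges at positive total cost, as the ROI denominator requires |
| $\rho$ | `rho` | 1/yr | 0.03 | standard 3% discounting |
| $\alpha$ | `alpha` | model-cost/yr | 1.0 | disease cost sets the unit |
| $D_{\max}$ | `D_max` | -- | 1.0 | severity on [0, 1] |
| $k$ | `k` | 1/yr | 0.7 | reaches $\approx 0.88$ severity at year 10 untreated |
| $s_0$ | `s0` | yr | 5/0.7 | midpoint at $k s_0 = 5$ |
| $\beta$ | `beta` | model-cost/yr | $-0.3$ | adherence saves money |
| $\lambda$ | `lam` | USD/outcome | 0 | direct expenditure only |
| $\eta$ | `eta` | -- | 0.8 | strong but admissible coupling |
| -- | `p_unit` | model-cost/yr | 0.05 | policy rate before $\gamma$ scaling |
| $\omega$ | `omega` | USD/model-cost | 1 | set by calibration |
| $T$ | `horizon` | yr | 10 | standard evaluation window |
| $h$ | `grid_step` | yr | 0.01 | see numerics |

`theta` (0.5/yr), `sigma` (0.05), `A_thresh` (0.75) and `nudge_cost`
(0.25) have no published values; they are documented placeholders, all
overridable through configuration files.

### Model currency and dollar calibration

The cost integral is dimensionless; published dollar figures live on a
different scale (policy cost scales of order 1 in the scenario table
versus break-even budgets of order $10^3$ per person). A single affine
map reconciles them: `calibrate_to_anchors()` takes the published
baseline and policy totals ($3953.07 and $3602.26 for the flat baseline
versus Early Adherence) and solves the two-equation linear system for
$(C_{0,\mathrm{USD}}, \omega)$, after which both anchors — and hence
their 9.7% ROI — are reproduced exactly. Quantities that are invariant
under this affine map (break-even $\gamma^*$, cost orderings, payback
times) are meaningful without calibration; ROI magnitudes are not, which
is why the package reports model-unit ROI only as a relative measure
until anchored.

## Numerical choices

* **Grid.** All trajectories live on the uniform grid
  $0, h, 2h, \dots, T$ with $h$ = 0.01 yr (about 3.7 days); $h$ must
  divide $T$. Policy starts and nudge events are grid-aligned.
* **Severity integration.** Fixed-step explicit 4th-order Runge-Kutta, for
  determinism and direct comparability with the logit-space oracle.
  Adherence jumps occur only at grid points, so each trajectory carries
  both right-limits and left-limits; within a step the stages use the
  right-limit at the left endpoint and the left-limit at the right
  endpoint. This integrates piecewise-constant adherence exactly (the
  stage rates are constant within each step) instead of smearing each
  jump by $O(h)$, and is second-order consistent for smooth shapes.
* **Cost quadrature.** Trapezoid rule with the same left/right-limit
  treatment, so the cost jump at the policy start is integrated exactly;
  adaptive impulses are added as discounted step increments at their
  event times. Halving $h$ moves the 10-year total by less than $10^{-5}$
  relative.
* **Break-even search.** Bisection on $\gamma \in [0, \gamma_{\max}]$
  (default bound 10), justified by the monotone decrease of ROI in
  $\gamma$; tolerance $10^{-4}$ percentage points on ROI; designs still
  profitable at the bound are flagged unbounded rather than extrapolated.
* **Payback.** First grid point of *strict* cumulative savings, no
  interpolation; `Inf` is the no-payback sentinel.
* **Adaptive events.** Threshold crossings are detected on the grid (no
  sub-step root finding) with a one-step refractory period; the timing
  error vanishes as $h \to 0$. An adaptive configuration whose threshold
  exceeds $A_0 + \delta$ is rejected at validation ("threshold
  unreachable").
* **Stochastic draws.** A single seeded generator consumed in draw order;
  the truncated normal uses inverse-CDF sampling on the truncated
  interval rather than rejection, so a draw consumes exactly one uniform
  and results are bit-reproducible for any seed. Design-space scans seed
  each cell as `master_seed + (i-1)*|gamma grid| + (j-1)`.
* **Contours.** Iso-ROI curves come from marching squares with linear
  edge interpolation (the base-R contour engine). Polylines are not
  smoothed or joined across saddle cells.

## Uncertainty propagation and design-space exploration

`run_monte_carlo()` propagates behavioral heterogeneity in $\delta$
(Beta, truncated-normal, two-point responder mixture, or degenerate
point) through the full simulator, sharing one baseline run per
parameter set. `subgroup_roi()` exposes the high/low responder
decomposition. `scan_grid()` sweeps $(\delta, \gamma)$ — default grids
$\delta \in \{0, 0.05, \dots, 0.40\}$, $\gamma \in \{0, 0.25, \dots, 3\}$
— and feeds `contour_levels()` and `cost_effectiveness_frontier()`. The
frontier marks Pareto-undominated designs (no cheaper design with higher
ROI); along it, ROI is non-decreasing in cost by construction.
`robustness_suite()` re-evaluates every scenario under cost inflation
(gamma and nudge cost scaled; default +20%) and accelerated progression
(time-axis compression $k \to k/(1-0.15)$, $s_0 \to 0.85\,s_0$, applied
to policy run and counterfactual alike).

## What the scenario generator does and does not emulate

The registry and defaults emulate the *study conditions*: a cohort whose
untreated severity rises from about 0.007 to 0.88 over ten years, a
baseline adherence of 0.5, policy gains up to +0.3, and the six published
policy archetypes. They do **not** emulate real claims or survey
microdata: there is no income stratification, no fitted Beta parameters,
no mortality, multimorbidity or random clinical events, and the dollar
scale exists only through the two-anchor calibration. Passing tests
therefore demonstrate internal correctness (integration accuracy,
monotonicities, orderings, reproducibility) and consistency with the
published worked numbers — not predictive validity on any real
population.

## Known limitations

* Under the placeholder nudge economics (`nudge_cost` = 0.25 at
  $\gamma = 2$, threshold 0.75), the adaptive scenario re-triggers every
  ~0.37 yr and its impulse costs dominate, leaving it strongly
  ROI-negative — unlike the published ranking, which presumably rests on
  calibrated nudge costs. The mechanism is implemented and tested; the
  placeholder is kept (and documented) rather than tuned to a ranking.
* Dollar-scale break-even figures depend on an unpublished calibration;
  the package verifies the *ordering* $\gamma^*(0.10) \le \gamma^*(0.15)
  \le \gamma^*(0.25)$ and solver contracts instead.
* ROI covers direct healthcare expenditure only ($\lambda = 0$); the DALY
  pathway is exposed through `monetize_health_outcomes()` applied to
  totals, mirroring the illustrative $50{,}000 \times 0.05 = \$2{,}500$
  example.
* The discount rate is constant; there is no inflation-indexed $\rho$ and
  no societal/productivity costs.

## Problem sizes

Examples and tests run at the default grid ($h$ = 0.01, 1001 points)
where single simulations are checked against closed forms, and at a
coarser $h$ = 0.05 for search and scan loops; Monte Carlo tests use
$n$ = 2,000 draws for convergence checks and smaller $n$ elsewhere. These
sizes were chosen so the entire suite exercises every code path in well
under a minute of compute while keeping Monte Carlo standard errors small
enough for the convergence assertions to be informative.
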