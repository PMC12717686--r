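# roisim

Simulation-based return-on-investment (ROI) evaluation of
adherence-enhancing chronic disease policies.

Health systems spend heavily on programs that try to improve medication
adherence — reminders, counseling, behavioral nudges — with limited
ex-ante evidence that the spending pays for itself. `roisim` is a
continuous-time health-economic simulator for that question, aimed at
modelers and policy analysts. It couples three processes over a 10-year
horizon:

* **logistic disease progression**
  `D(s) = D_max / (1 + exp(-k (s - s0)))`, with the progression rate
  slowed by adherence through
  `dD/ds = k (1 - eta (A(s) - 0.5)) D (1 - D/D_max)`;
* **time-varying adherence** `A(s)` under five policy shapes (sustained
  step, delayed step, exponentially decaying gain, threshold-triggered
  adaptive nudges, and a high-cost/low-impact step) against a
  no-intervention baseline; and
* **discounted cost accumulation**
  `c(s) = alpha D(s) + beta A(s)^2 + gamma P(s) + lambda H(s)`,
  `C(t) = omega (C0 + \int_0^t exp(-rho s) c(s) ds)`.

Policies are compared by
`ROI = 100 (C_baseline - C_policy) / C_policy`, payback time, break-even
cost scale `gamma*(delta)`, Monte Carlo ROI distributions under
behavioral uncertainty in the adherence gain `delta`, a
`(delta, gamma)` design-space scan with iso-ROI contours and a
cost-effectiveness frontier, and robustness stress tests (20% cost
inflation, 15% accelerated progression). See the methods vignette
(`vignettes/adherence-roi-model.Rmd`) for the model, assumptions, and
numerical choices.

## Worked example

Calibrate the dollar scale to the two published cost anchors (baseline
$3953.07, Early Adherence $3602.26), then compare the Early Adherence
policy (start year 2, adherence gain +0.3, cost scale 1.5) with the
no-intervention baseline:

```r
library(roisim)

params <- calibrate_to_anchors(3953.07, 3602.26, scenario_table()$early)
base   <- simulate_scenario(scenario_table()$baseline, params)
early  <- simulate_scenario(scenario_table()$early, params)

roi(base$total_cost, early$total_cost)
#> [1] 9.738609
payback_time(base$cumulative_cost, early$cumulative_cost)
#> [1] 2.01
tail(early$severity$values, 1); tail(base$severity$values, 1)
#> [1] 0.6583613
#> [1] 0.8807971
```

The policy returns 9.7% over ten years, pays back immediately after its
start at year 2 (the adherence savings outweigh the policy spend from the
first step onward), and lowers year-10 disease severity from 0.88 to
0.66. Break-even analysis shows how the maximum affordable cost scale
grows with the adherence gain:

```r
sapply(c(0.10, 0.15, 0.25), function(d)
  breakeven_gamma(d, scenario_table()$early, params)$gamma_star)
#> [1] 1.454849 2.239771 3.909445
```

and the robustness suite recomputes every scenario's ROI under cost
inflation and accelerated progression:

```r
robustness_suite(scenario_table(), params)
#>               scenario roi_baseline roi_inflated roi_accelerated
#> 1      Early Adherence         9.74         8.77            9.49
#> 2 Delayed Intervention         4.28         3.76            3.54
#> 3 Regressive Adherence         0.52        -0.13            0.65
#> 4      Adaptive Nudges       -39.17       -49.13          -37.67
#> 5    Low-Impact Policy        -5.83        -7.24           -5.54
```

Early intervention stays profitable under a 20% cost increase; the
near-break-even regressive design collapses below zero; the adaptive
design's ROI is dominated by its (placeholder) per-nudge cost — see the
vignette's limitations section.

A command-line interface wraps the same functions
(`exec/roisim simulate|scan|breakeven|montecarlo|robustness|calibrate|fixtures`,
each with `--config`, `--seed`, `--out`).

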