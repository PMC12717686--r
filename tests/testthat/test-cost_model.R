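test_that("policy expenditure follows the scenario shapes", {
  p <- default_parameters()
  tab <- scenario_table()
  P0 <- policy_expenditure(tab$baseline, params = p)
  expect_true(all(P0$values == 0))
  Pe <- policy_expenditure(tab$early, params = p)
  expect_equal(Pe$values[Pe$times == 1], 0)
  expect_equal(Pe$values[Pe$times == 3], p$p_unit)
})

test_that("cost decomposition reproduces hand arithmetic and sums exactly", {
  p <- default_pars(alpha = 1, D_max = 1, k = 1, s0 = 5, beta = -0.3,
                    lam = 0)
  sc <- scenario_config("s", "step", tau = 2, delta = 0.3, gamma = 1.5)
  sev <- constant_trajectory(p, 0.5)      # logistic midpoint value
  adh <- constant_trajectory(p, 0.8)
  pol <- constant_trajectory(p, 0.05)
  bd <- cost_decomposition(sev, adh, pol, sc, p)
  expect_equal(bd$disease[1], 0.5)
  expect_equal(bd$adherence[1], -0.3 * 0.64)   # -0.192
  expect_equal(bd$policy[1], 1.5 * 0.05)       # 0.075
  expect_equal(bd$health[1], 0)
  expect_lt(max(abs(bd$total - (bd$disease + bd$adherence + bd$policy +
                                  bd$health))), 1e-12)
  expect_equal(bd$discounted_total, exp(-p$rho * bd$times) * bd$total)
  # grid mismatch is rejected
  short <- trajectory(seq(0, 1, 0.01), rep(1, 101))
  expect_error(cost_decomposition(short, adh, pol, sc, p), "common grid")
})

test_that("trapezoid cumulative cost matches the exponential-discount closed form", {
  # constant c(s) = 100 realized through the health term
  p <- default_pars(alpha = 0, beta = 0, lam = 1, C0 = 0, omega = 1)
  sc <- scenario_config("h", "baseline", gamma = 0)
  zero <- constant_trajectory(p, 0)
  H <- constant_trajectory(p, 100)
  bd <- cost_decomposition(zero, zero, zero, sc, p, health = H)
  C <- cumulative_cost(bd, p)
  exact <- discounted_constant_integral(100, 0.03, 10)
  expect_equal(exact, 863.93935, tolerance = 1e-7)
  got <- C$values[length(C$values)]
  expect_lt(abs(got - exact) / exact, 1e-6)
  # whole path, not just the endpoint
  exact_path <- discounted_constant_integral(100, 0.03, C$times)
  expect_lt(max(abs(C$values - exact_path) / pmax(exact_path, 1)), 1e-6)

  # undiscounted limit: C(t) = C0 + c0 * t
  p0 <- default_pars(alpha = 0, beta = 0, lam = 1, rho = 0, C0 = 7)
  bd0 <- cost_decomposition(zero, zero, zero, sc, p0, health = H)
  C0t <- cumulative_cost(bd0, p0)
  expect_equal(C0t$values, 7 + 100 * C0t$times, tolerance = 1e-10)
  expect_equal(C0t$values[1], 7)  # C(0) is the offset
})

test_that("cumulative cost converges under grid refinement", {
  sc <- scenario_table()$early
  c_h <- simulate_scenario(sc, default_pars(grid_step = 0.01))$total_cost
  c_h2 <- simulate_scenario(sc, default_pars(grid_step = 0.005))$total_cost
  expect_lt(abs(c_h - c_h2) / abs(c_h2), 1e-5)
})

test_that("adaptive impulses add one discounted nudge cost per activation", {
  p <- default_parameters()
  sc <- scenario_table()$adaptive
  adh <- adherence_trajectory(sc, p)
  pol <- policy_expenditure(sc, adh$activations, p)
  sev <- severity_coupled(adh$adherence, p)
  bd <- cost_decomposition(sev, adh$adherence, pol, sc, p)
  with_imp <- cumulative_cost(bd, p, sc, adh$activations)
  without <- cumulative_cost(bd, p)
  expected_impulse <- sum(exp(-p$rho * adh$activations$activation_times) *
                            sc$gamma * sc$nudge_cost)
  n <- length(with_imp$values)
  expect_equal(with_imp$values[n] - without$values[n], expected_impulse)
  # impulses arrive as steps at the activation times
  t_first <- adh$activations$activation_times[1]
  before <- max(which(with_imp$times < t_first))
  expect_equal(with_imp$values[before], without$values[before])
})

test_that("with beta < 0, higher adherence never increases total cost", {
  p <- default_parameters()
  tmpl <- scenario_table()$early
  costs <- sapply(c(0.0, 0.1, 0.2, 0.3), function(d) {
    sc <- tmpl; sc$delta <- d
    simulate_scenario(sc, p)$total_cost
  })
  expect_true(all(diff(costs) < 0))
})

test_that("health-outcome monetization is the stated linear valuation", {
  expect_equal(monetize_health_outcomes(0.05, 50000), 2500)
  expect_equal(monetize_health_outcomes(0, 1e9), 0)
  expect_equal(monetize_health_outcomes(0.10, 50000), 5000)
  expect_error(monetize_health_outcomes(1, -5), ">= 0")
})

test_that("cost inflation scales gamma and nudge_cost only", {
  sc <- scenario_table()$early
  up <- inflate_costs(sc, 1.2)
  expect_equal(up$gamma, 1.8)
  expect_equal(up$nudge_cost, 0.3)
  up$gamma <- sc$gamma; up$nudge_cost <- sc$nudge_cost
  expect_identical(up, sc)
  expect_identical(inflate_costs(sc, 1), sc)
  expect_error(inflate_costs(sc, 0), "positive")
})

test_that("simulation results export as tidy CSV", {
  dir <- withr::local_tempdir()
  res <- simulate_scenario(scenario_table()$early, default_parameters())
  df <- write_simulation_csv(res, file.path(dir, "traj.csv"))
  back <- read.csv(file.path(dir, "traj.csv"))
  expect_equal(names(back),
               c("time", "adherence", "severity", "policy_rate",
                 "cost_disease", "cost_adherence", "cost_policy",
                 "cost_total", "cumulative_cost"))
  expect_equal(nrow(back), 1001)
  expect_equal(back$cumulative_cost[1001], res$total_cost, tolerance = 1e-9)
  # cumulative cost is non-decreasing wherever instantaneous cost >= 0
  # (with beta < 0 the adherence savings make early net cost negative)
  nonneg <- df$cost_total[-1] >= 0 & df$cost_total[-nrow(df)] >= 0
  expect_true(all(diff(df$cumulative_cost)[nonneg] >= 0))
  expect_true(any(nonneg))
})
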