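# Shared fixtures: everything is generated in code.

default_pars <- function(...) {
  p <- default_parameters()
  upd <- list(...)
  if (length(upd)) p <- do.call(model_parameters, utils::modifyList(unclass(p), upd))
  p
}

# Exact discounted integral of a constant instantaneous cost c0:
# integral_0^t e^(-rho s) c0 ds
discounted_constant_integral <- function(c0, rho, t) {
  if (rho == 0) c0 * t else c0 * (1 - exp(-rho * t)) / rho
}

# Exact logit-slope oracle for the coupled severity ODE under
# piecewise-constant adherence: logit D(t) = logit D(0) + k * sum over
# segments of (1 - eta*(A_seg - A0_ref)) * segment length.
logit_slope_severity <- function(t, segments, params, A0_ref = 0.5) {
  # segments: data.frame(from, to, A); must tile [0, t]
  L0 <- -params$k * params$s0
  L <- L0
  for (r in seq_len(nrow(segments))) {
    lo <- max(segments$from[r], 0)
    hi <- min(segments$to[r], t)
    if (hi > lo)
      L <- L + params$k * (1 - params$eta * (segments$A[r] - A0_ref)) * (hi - lo)
  }
  params$D_max / (1 + exp(-L))
}

# Build a piecewise-constant trajectory with a jump at a grid-aligned time.
step_trajectory <- function(params, before, after, tau) {
  times <- time_grid(params)
  vals <- ifelse(times >= tau - 1e-12, after, before)
  left <- ifelse(times > tau + 1e-12, after, before)
  trajectory(times, vals, values_left = left)
}

constant_trajectory <- function(params, value) {
  times <- time_grid(params)
  trajectory(times, rep(value, length(times)))
}

# Deterministic ROI of a template at (delta, gamma) against its baseline.
det_roi <- function(delta, gamma, template, params) {
  sc <- template; sc$delta <- delta; sc$gamma <- gamma
  base <- scenario_config("Baseline", "baseline", delta = 0, gamma = 0,
                          A0 = template$A0,
                          baseline_decay_rate = template$baseline_decay_rate)
  roi(simulate_scenario(base, params)$total_cost,
      simulate_scenario(sc, params)$total_cost)
}
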