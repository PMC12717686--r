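#' Uniform time grid
#'
#' @param params a \code{\link{model_parameters}} record.
#' @return Numeric vector \code{seq(0, horizon, by = grid_step)}.
#' @export
time_grid <- function(params) {
  m <- round(params$horizon / params$grid_step)
  params$grid_step * (0:m)
}

#' Trajectory container
#'
#' A sampled function of time on the uniform simulation grid. Jumps are
#' allowed only at grid points; \code{values} holds the right-limits and
#' the optional \code{values_left} attribute the left-limits (they differ
#' only at discontinuities such as the policy start or adaptive
#' re-activations).
#'
#' @param times uniform time grid (yr).
#' @param values numeric vector of the same length.
#' @param values_left optional left-limit values (defaults to \code{values}).
#' @return An object of class \code{trajectory}.
#' @export
trajectory <- function(times, values, values_left = NULL) {
  if (length(times) != length(values))
    stop("times and values must have equal length")
  if (length(times) > 1) {
    h <- diff(times)
    if (max(abs(h - h[1])) > 1e-9) stop("time grid must be uniform")
  }
  out <- structure(list(times = as.numeric(times),
                        values = as.numeric(values)),
                   class = "trajectory")
  if (!is.null(values_left)) {
    if (length(values_left) != length(values))
      stop("values_left length mismatch")
    attr(out, "values_left") <- as.numeric(values_left)
  }
  out
}

values_left_of <- function(traj) {
  vl <- attr(traj, "values_left")
  if (is.null(vl)) traj$values else vl
}

same_grid <- function(a, b) {
  length(a$times) == length(b$times) &&
    max(abs(a$times - b$times)) <= 1e-9
}

#' Record of adaptive nudge activations
#'
#' @param activation_times strictly increasing event times (yr).
#' @return An object of class \code{adaptive_record} with fields
#'   \code{activation_times} and \code{count}.
#' @export
adaptive_record <- function(activation_times = numeric(0)) {
  at <- as.numeric(activation_times)
  if (length(at) > 1 && any(diff(at) <= 0))
    stop("activation_times must be strictly increasing")
  structure(list(activation_times = at, count = length(at)),
            class = "adaptive_record")
}

#' Build the adherence trajectory of a policy scenario
#'
#' Evaluates the scenario's adherence function A(s) on the simulation grid:
#' constant (or exponentially decaying) baseline, sustained step gain,
#' exponentially decaying gain, or the adaptive-nudge form that resets
#' adherence to \eqn{A_0 + \delta} whenever it would fall below
#' \code{A_thresh}. All values are clipped to [0, 1]. The indicator
#' convention is \eqn{I(x) = 1} for \eqn{x \ge 0}, so the gain applies at
#' \code{s = tau} itself.
#'
#' Adaptive crossings are detected on the grid (no sub-step root finding):
#' an activation fires at the first grid point whose decayed value would
#' drop below the threshold, and a one-step refractory period prevents
#' re-triggering at the reset point.
#'
#' @param scenario a \code{\link{scenario_config}}.
#' @param params a \code{\link{model_parameters}}.
#' @return A list with components \code{adherence} (a
#'   \code{\link{trajectory}} carrying left-limits at its jump points) and
#'   \code{activations} (an \code{\link{adaptive_record}}, empty for
#'   non-adaptive shapes).
#' @examples
#' pars <- default_parameters()
#' early <- scenario_table()$early
#' A <- adherence_trajectory(early, pars)$adherence
#' A$values[A$times == 1]  # 0.5 (before the policy starts)
#' A$values[A$times == 3]  # 0.8
#' @export
adherence_trajectory <- function(scenario, params) {
  validate_inputs(params, scenario)
  times <- time_grid(params)
  h <- params$grid_step
  A0 <- scenario$A0
  delta <- scenario$delta
  tau <- scenario$tau
  theta <- scenario$theta
  record <- adaptive_record()

  base_vals <- if (scenario$baseline_decay_rate > 0)
    A0 * exp(-scenario$baseline_decay_rate * times) else rep(A0, length(times))

  if (scenario$shape == "baseline") {
    vals <- base_vals
    left <- vals
  } else if (scenario$shape %in% c("step", "low_impact")) {
    on <- times >= tau - 1e-12
    vals <- base_vals + delta * on
    left <- base_vals + delta * (times > tau + 1e-12)
  } else if (scenario$shape == "decay") {
    on <- times >= tau - 1e-12
    gain <- ifelse(on, delta * exp(-theta * pmax(times - tau, 0)), 0)
    vals <- base_vals + gain
    # the only discontinuity is at tau (left-limit is the bare baseline)
    left <- vals
    left[abs(times - tau) <= 1e-12] <- base_vals[abs(times - tau) <= 1e-12]
  } else if (scenario$shape == "adaptive") {
    vals <- base_vals
    left <- base_vals
    acts <- numeric(0)
    last_reset <- NA_real_
    for (i in seq_along(times)) {
      s <- times[i]
      if (s < tau - 1e-12) next
      if (is.na(last_reset)) {      # initial activation at tau
        last_reset <- s
        vals[i] <- base_vals[i] + delta
        next
      }
      cand <- base_vals[i] + delta * exp(-theta * (s - last_reset))
      refractory <- (s - last_reset) <= h + 1e-12
      if (!refractory && cand < scenario$A_thresh) {
        acts <- c(acts, s)
        last_reset <- s
        left[i] <- cand               # value just before the nudge fires
        vals[i] <- base_vals[i] + delta
      } else {
        vals[i] <- cand
        left[i] <- cand
      }
    }
    left[abs(times - tau) <= 1e-12] <- base_vals[abs(times - tau) <= 1e-12]
    record <- adaptive_record(acts)
  } else stop("unknown shape: ", scenario$shape)

  vals <- pmin(pmax(vals, 0), 1)
  left <- pmin(pmax(left, 0), 1)
  list(adherence = trajectory(times, vals, values_left = left),
       activations = record)
}

#' Sample adherence gains from a behavioral-uncertainty distribution
#'
#' Draws n values of the adherence gain delta according to a
#' \code{\link{delta_spec}}. All draws lie in [0, 1]; the same seed gives
#' identical draws. The truncated normal is sampled by inverse-CDF on the
#' truncated interval (deterministic in the uniform stream; no rejection).
#'
#' @param spec a \code{\link{delta_spec}}.
#' @param n number of draws (>= 1).
#' @param seed integer seed.
#' @return Numeric vector of n draws in [0, 1].
#' @export
sample_delta <- function(spec, n, seed) {
  stopifnot(inherits(spec, "delta_spec"))
  if (n < 1) stop("n must be at least 1")
  withr::with_seed(as.integer(seed), {
    switch(spec$kind,
      point = rep(spec$delta, n),
      beta = stats::rbeta(n, spec$a, spec$b),
      truncnorm = {
        if (spec$sigma == 0) rep(min(max(spec$delta, 0), 1), n)
        else {
          lo <- stats::pnorm(0, spec$delta, spec$sigma)
          hi <- stats::pnorm(1, spec$delta, spec$sigma)
          u <- stats::runif(n, lo, hi)
          pmin(pmax(stats::qnorm(u, spec$delta, spec$sigma), 0), 1)
        }
      },
      two_point = ifelse(stats::runif(n) < spec$p, spec$delta_hi,
                         spec$delta_lo),
      stop("unknown delta_spec kind: ", spec$kind)
    )
  })
}
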