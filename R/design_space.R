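#' Default design-space grids
#'
#' Adherence gains delta from 0 to 0.40 in steps of 0.05 and policy cost
#' scales gamma from 0 to 3 in steps of 0.25, covering the canonical
#' scenario registry.
#'
#' @return List with components \code{delta} and \code{gamma}.
#' @export
default_design_grids <- function() {
  list(delta = seq(0, 0.40, by = 0.05), gamma = seq(0, 3, by = 0.25))
}

#' Scan the (delta, gamma) policy design space
#'
#' Simulates the policy template at every grid combination of adherence
#' gain and cost scale and records ROI and total cost. With a
#' \code{\link{delta_spec}} supplied, each cell instead runs a seeded Monte
#' Carlo of n draws (cell seed = master seed + (i-1)*|gamma grid| + (j-1))
#' and records mean ROI and the positive-ROI rate.
#'
#' @param delta_grid,gamma_grid increasing numeric grids.
#' @param template a \code{\link{scenario_config}}.
#' @param params a \code{\link{model_parameters}}.
#' @param spec optional \code{\link{delta_spec}} centered per cell at the
#'   cell's delta (its \code{delta} location is overridden).
#' @param n draws per cell for stochastic scans.
#' @param seed master seed for stochastic scans.
#' @return An object of class \code{roi_surface}: list with
#'   \code{delta_grid}, \code{gamma_grid}, \code{roi_matrix} (percent,
#'   |delta| x |gamma|), \code{cost_matrix} (USD), and
#'   \code{positive_rate_matrix} (NULL for deterministic scans).
#' @export
scan_grid <- function(delta_grid, gamma_grid, template,
                      params = default_parameters(), spec = NULL,
                      n = 200, seed = 1) {
  if (length(delta_grid) == 0 || length(gamma_grid) == 0)
    stop("grids must be non-empty")
  if (any(diff(delta_grid) <= 0) || any(diff(gamma_grid) <= 0))
    stop("grids must be strictly increasing")
  nd <- length(delta_grid); ng <- length(gamma_grid)
  roi_m <- matrix(NA_real_, nd, ng)
  cost_m <- matrix(NA_real_, nd, ng)
  pos_m <- if (is.null(spec)) NULL else matrix(NA_real_, nd, ng)
  c_base <- simulate_scenario(baseline_of(template), params)$total_cost
  for (i in seq_len(nd)) {
    for (j in seq_len(ng)) {
      sc <- template
      sc$delta <- delta_grid[i]
      sc$gamma <- gamma_grid[j]
      if (is.null(spec)) {
        cost <- simulate_scenario(sc, params)$total_cost
        roi_m[i, j] <- roi(c_base, cost)
        cost_m[i, j] <- cost
      } else {
        cell_spec <- spec
        cell_spec$delta <- delta_grid[i]
        cell_seed <- seed + (i - 1L) * ng + (j - 1L)
        mc <- run_monte_carlo(sc, cell_spec, n, cell_seed, params)
        roi_m[i, j] <- mc$mean_roi
        cost_m[i, j] <- mean(mc$total_costs)
        pos_m[i, j] <- mc$positive_rate
      }
    }
  }
  structure(list(delta_grid = delta_grid, gamma_grid = gamma_grid,
                 roi_matrix = roi_m, cost_matrix = cost_m,
                 positive_rate_matrix = pos_m),
            class = "roi_surface")
}

#' Iso-ROI contour extraction
#'
#' Extracts level sets of the ROI surface in the (delta, gamma) plane by
#' marching squares with linear edge interpolation (via
#' \code{grDevices::contourLines}). Cells entirely above or below a level
#' contribute nothing.
#'
#' @param surface a \code{\link{scan_grid}} result.
#' @param levels ROI levels in percent (e.g. \code{c(0, 50, 100)}).
#' @return Named list (one element per level, name = level) of lists of
#'   polylines; each polyline is a data frame with columns \code{delta}
#'   and \code{gamma}.
#' @export
contour_levels <- function(surface, levels) {
  stopifnot(inherits(surface, "roi_surface"))
  if (any(!is.finite(levels))) stop("levels must be finite")
  out <- vector("list", length(levels))
  names(out) <- as.character(levels)
  for (k in seq_along(levels)) {
    zmin <- min(surface$roi_matrix); zmax <- max(surface$roi_matrix)
    if (levels[k] < zmin || levels[k] > zmax ||
        length(surface$delta_grid) < 2 || length(surface$gamma_grid) < 2) {
      out[[k]] <- list()
      next
    }
    cl <- grDevices::contourLines(surface$delta_grid, surface$gamma_grid,
                                  surface$roi_matrix, levels = levels[k])
    out[[k]] <- lapply(cl, function(seg)
      data.frame(delta = seg$x, gamma = seg$y))
  }
  out
}

#' Cost-effectiveness frontier
#'
#' Collects every (total cost, ROI) pair of a design-space scan and marks
#' the Pareto-efficient subset: designs for which no design of equal or
#' lower cost attains strictly higher ROI.
#'
#' @param surface a \code{\link{scan_grid}} result with populated
#'   \code{cost_matrix}.
#' @return Data frame sorted by cost with columns \code{delta},
#'   \code{gamma}, \code{total_cost}, \code{roi}, \code{on_frontier}.
#' @export
cost_effectiveness_frontier <- function(surface) {
  stopifnot(inherits(surface, "roi_surface"))
  if (all(is.na(surface$cost_matrix))) stop("cost_matrix not populated")
  grid <- expand.grid(i = seq_along(surface$delta_grid),
                      j = seq_along(surface$gamma_grid))
  df <- data.frame(delta = surface$delta_grid[grid$i],
                   gamma = surface$gamma_grid[grid$j],
                   total_cost = surface$cost_matrix[cbind(grid$i, grid$j)],
                   roi = surface$roi_matrix[cbind(grid$i, grid$j)])
  df <- df[order(df$total_cost, -df$roi), ]
  best <- cummax(df$roi)
  df$on_frontier <- df$roi >= best - 1e-12
  rownames(df) <- NULL
  df
}

#' Robustness stress tests of a scenario set
#'
#' For each scenario, ROI is recomputed under (a) the stated conditions,
#' (b) inflated implementation costs (gamma and nudge_cost scaled by
#' \code{inflation_factor}), and (c) accelerated disease progression
#' (progression intervals shortened by \code{shortening} for both the
#' policy run and its baseline counterfactual).
#'
#' @param scenarios list of \code{\link{scenario_config}} records
#'   (baseline shapes are skipped).
#' @param params a \code{\link{model_parameters}}.
#' @param inflation_factor cost multiplier (default 1.2, i.e. +20\%).
#' @param shortening progression-interval shortening (default 0.15).
#' @return Data frame with columns \code{scenario}, \code{roi_baseline},
#'   \code{roi_inflated}, \code{roi_accelerated} (percent).
#' @export
robustness_suite <- function(scenarios, params = default_parameters(),
                             inflation_factor = 1.2, shortening = 0.15) {
  scenarios <- Filter(function(s) s$shape != "baseline", scenarios)
  if (length(scenarios) == 0) stop("no policy scenarios supplied")
  acc <- accelerate_progression(params, shortening)
  rows <- lapply(scenarios, function(sc) {
    c_base <- simulate_scenario(baseline_of(sc), params)$total_cost
    c_base_acc <- simulate_scenario(baseline_of(sc), acc)$total_cost
    data.frame(
      scenario = sc$name,
      roi_baseline = roi(c_base, simulate_scenario(sc, params)$total_cost),
      roi_inflated = roi(c_base,
                         simulate_scenario(inflate_costs(sc,
                                                         inflation_factor),
                                           params)$total_cost),
      roi_accelerated = roi(c_base_acc,
                            simulate_scenario(sc, acc)$total_cost))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Export an ROI surface in long CSV format
#'
#' Columns: delta, gamma, roi, total_cost, positive_rate (NA for
#' deterministic scans).
#'
#' @param surface a \code{\link{scan_grid}} result.
#' @param path output file path.
#' @return Invisibly, the exported data frame.
#' @export
write_surface_csv <- function(surface, path) {
  stopifnot(inherits(surface, "roi_surface"))
  grid <- expand.grid(i = seq_along(surface$delta_grid),
                      j = seq_along(surface$gamma_grid))
  idx <- cbind(grid$i, grid$j)
  df <- data.frame(delta = surface$delta_grid[grid$i],
                   gamma = surface$gamma_grid[grid$j],
                   roi = surface$roi_matrix[idx],
                   total_cost = surface$cost_matrix[idx],
                   positive_rate = if (is.null(surface$positive_rate_matrix))
                     NA_real_ else surface$positive_rate_matrix[idx])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}

#' Export iso-ROI contours as CSV
#'
#' Columns: level, polyline_id, delta, gamma.
#'
#' @param contours a \code{\link{contour_levels}} result.
#' @param path output file path.
#' @return Invisibly, the exported data frame.
#' @export
write_contours_csv <- function(contours, path) {
  rows <- list()
  pid <- 0L
  for (lev in names(contours)) {
    for (seg in contours[[lev]]) {
      pid <- pid + 1L
      rows[[pid]] <- data.frame(level = as.numeric(lev), polyline_id = pid,
                                delta = seg$delta, gamma = seg$gamma)
    }
  }
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(level = numeric(0), polyline_id = integer(0),
               delta = numeric(0), gamma = numeric(0))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}

#' Export a break-even table as CSV
#'
#' Columns: delta, gamma_star, bounded_flag.
#'
#' @param deltas adherence gains to evaluate.
#' @param template a \code{\link{scenario_config}}.
#' @param params a \code{\link{model_parameters}}.
#' @param path output file path.
#' @param gamma_max,tol passed to \code{\link{breakeven_gamma}}.
#' @return Invisibly, the exported data frame.
#' @export
write_breakeven_csv <- function(deltas, template,
                                params = default_parameters(), path,
                                gamma_max = 10, tol = 1e-4) {
  rows <- lapply(deltas, function(d) {
    be <- breakeven_gamma(d, template, params, gamma_max, tol)
    data.frame(delta = d, gamma_star = be$gamma_star,
               bounded_flag = be$bounded)
  })
  df <- do.call(rbind, rows)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}
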