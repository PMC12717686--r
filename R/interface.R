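#' Load a run configuration from JSON or YAML
#'
#' The config file may carry two top-level keys: \code{parameters}
#' (overrides of \code{\link{model_parameters}} fields) and
#' \code{scenarios} (a list of \code{\link{scenario_config}} field sets;
#' each needs at least \code{name} and \code{shape}). Anything absent
#' falls back to the package defaults; unknown keys are an error. An empty
#' file yields the pure defaults with the canonical scenario registry.
#'
#' @param path path to a \code{.json}, \code{.yaml} or \code{.yml} file.
#' @return List with \code{parameters} (validated
#'   \code{\link{model_parameters}}) and \code{scenarios} (named list of
#'   validated \code{\link{scenario_config}}).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else
    jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  if (is.null(raw)) raw <- list()
  unknown <- setdiff(names(raw), c("parameters", "scenarios"))
  if (length(unknown))
    stop(sprintf("unknown top-level key(s) in %s: %s", path,
                 paste(unknown, collapse = ", ")))

  params <- default_parameters()
  if (!is.null(raw$parameters)) {
    bad <- setdiff(names(raw$parameters), names(params))
    if (length(bad))
      stop(sprintf("unknown parameter key(s) in %s: %s", path,
                   paste(bad, collapse = ", ")))
    for (nm in names(raw$parameters)) params[[nm]] <- raw$parameters[[nm]]
    params <- do.call(model_parameters, unclass(params))
  }
  validate_inputs(params)

  scenarios <- if (is.null(raw$scenarios)) scenario_table() else {
    sc_fields <- names(formals(scenario_config))
    out <- lapply(raw$scenarios, function(entry) {
      bad <- setdiff(names(entry), sc_fields)
      if (length(bad))
        stop(sprintf("unknown scenario key(s) in %s: %s", path,
                     paste(bad, collapse = ", ")))
      if (is.null(entry$name) || is.null(entry$shape))
        stop("each scenario needs 'name' and 'shape' fields")
      do.call(scenario_config, entry)
    })
    names(out) <- vapply(out, function(s) s$name, character(1))
    out
  }
  for (sc in scenarios) validate_inputs(params, sc)
  list(parameters = params, scenarios = scenarios)
}

#' Serialize a configuration to JSON
#'
#' Inverse of \code{\link{load_config}} for the JSON format; round-trips
#' the canonical scenario registry bit-identically.
#'
#' @param parameters a \code{\link{model_parameters}}.
#' @param scenarios list of \code{\link{scenario_config}} records.
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
write_config <- function(parameters, scenarios, path) {
  payload <- list(parameters = unclass(parameters),
                  scenarios = lapply(unname(scenarios), unclass))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' Generate the packaged configuration fixtures
#'
#' Writes \code{table2_scenarios.json} (defaults plus the canonical
#' six-scenario registry) and \code{smoke.json} (a coarse-grid,
#' small-sample configuration for fast end-to-end runs) into a directory.
#'
#' @param output_dir writable directory (created if missing).
#' @return Character vector of the two file paths.
#' @export
generate_fixtures <- function(output_dir) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  f1 <- file.path(output_dir, "table2_scenarios.json")
  write_config(default_parameters(), scenario_table(), f1)
  f2 <- file.path(output_dir, "smoke.json")
  smoke_params <- model_parameters(grid_step = 0.05)
  write_config(smoke_params, scenario_table(), f2)
  c(f1, f2)
}

# --- command-line interface ------------------------------------------------

cli_usage <- function() {
  paste(
    "usage: roisim <command> [--config FILE] [--seed INT] [--out DIR] ...",
    "",
    "commands:",
    "  simulate    --scenario NAME   one scenario vs baseline ->",
    "              trajectories CSV + ROI summary JSON",
    "  scan        [--n INT]         (delta, gamma) ROI surface CSV +",
    "              iso-ROI contours CSV (stochastic when --n given)",
    "  breakeven   [--deltas a,b,..] break-even gamma* table CSV",
    "  montecarlo  --n INT [--kind truncnorm|beta|two_point|point]",
    "              draws CSV + summary JSON",
    "  robustness  [--inflation F] [--shortening F]  comparison CSV",
    "  calibrate   --anchors BASE,POLICY [--scenario NAME]",
    "              writes calibrated parameter JSON",
    "  fixtures                      writes packaged example configs",
    sep = "\n")
}

parse_cli_args <- function(argv) {
  opts <- list()
  i <- 1L
  while (i <= length(argv)) {
    a <- argv[i]
    if (!startsWith(a, "--"))
      stop("unexpected argument: ", a)
    key <- substring(a, 3)
    if (i == length(argv)) stop("missing value for --", key)
    opts[[key]] <- argv[i + 1L]
    i <- i + 2L
  }
  opts
}

cli_log <- function(out_dir, params, seed, extra = list()) {
  log <- c(list(package_version =
                  as.character(utils::packageVersion("roisim")),
                seed = seed, grid_step = params$grid_step,
                parameters = unclass(params)), extra)
  jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = I(17), pretty = TRUE)
}

pick_scenario <- function(scenarios, name) {
  if (name %in% names(scenarios)) return(scenarios[[name]])
  labels <- vapply(scenarios, function(s) s$name, character(1))
  hit <- which(tolower(labels) == tolower(name))
  if (length(hit) != 1)   # unique case-insensitive prefix, e.g. "early"
    hit <- grep(paste0("^", tolower(name)), tolower(labels))
  if (length(hit) == 1) return(scenarios[[hit]])
  stop("unknown or ambiguous scenario '", name, "'; available: ",
       paste(labels, collapse = ", "))
}

#' Command-line entry point
#'
#' Implements the \code{roisim} command-line tool (see \code{exec/roisim}):
#' subcommands \code{simulate}, \code{scan}, \code{breakeven},
#' \code{montecarlo}, \code{robustness}, \code{calibrate} and
#' \code{fixtures}, each accepting \code{--config}, \code{--seed} and
#' \code{--out}. Data goes to files under \code{--out} (plus a
#' \code{run_log.json} sidecar recording the resolved parameters, seed,
#' grid step and package version); messages go to standard error. Numbers
#' are written at full precision.
#'
#' @param argv character vector of command-line arguments (excluding the
#'   program name).
#' @return The process exit status, invisibly: 0 on success, 2 on usage
#'   errors, 1 on runtime failure.
#' @export
cli_main <- function(argv = commandArgs(trailingOnly = TRUE)) {
  commands <- c("simulate", "scan", "breakeven", "montecarlo",
                "robustness", "calibrate", "fixtures")
  if (length(argv) == 0 || !argv[1] %in% commands) {
    message(cli_usage())
    return(invisible(2L))
  }
  cmd <- argv[1]
  opts <- tryCatch(parse_cli_args(argv[-1]),
                   error = function(e) e)
  if (inherits(opts, "error")) {
    message(conditionMessage(opts), "\n\n", cli_usage())
    return(invisible(2L))
  }
  status <- tryCatch({
    cfg <- if (!is.null(opts$config)) load_config(opts$config)
           else list(parameters = default_parameters(),
                     scenarios = scenario_table())
    params <- cfg$parameters
    seed <- as.integer(opts$seed %||% 1L)
    out_dir <- opts$out %||% "."
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

    if (cmd == "simulate") {
      sc <- pick_scenario(cfg$scenarios, opts$scenario %||% "early")
      res <- simulate_scenario(sc, params)
      base <- simulate_scenario(baseline_of(sc), params)
      write_simulation_csv(res, file.path(out_dir, "trajectories.csv"))
      summary <- list(
        scenario = sc$name,
        total_cost = res$total_cost,
        baseline_cost = base$total_cost,
        roi_percent = roi(base$total_cost, res$total_cost),
        payback_years = payback_time(base$cumulative_cost,
                                     res$cumulative_cost),
        activations = res$activations$count)
      jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                           auto_unbox = TRUE, digits = I(17), pretty = TRUE)
      message(sprintf("%s: ROI = %.1f%% (cost %.2f vs %.2f USD)",
                      sc$name, summary$roi_percent, res$total_cost,
                      base$total_cost))
    } else if (cmd == "scan") {
      grids <- default_design_grids()
      template <- pick_scenario(cfg$scenarios, opts$scenario %||% "early")
      spec <- if (!is.null(opts$n))
        delta_spec("truncnorm", sigma = as.numeric(opts$sigma %||% 0.05))
      surf <- scan_grid(grids$delta, grids$gamma, template, params,
                        spec = if (is.null(opts$n)) NULL else spec,
                        n = as.integer(opts$n %||% 200), seed = seed)
      write_surface_csv(surf, file.path(out_dir, "surface.csv"))
      cont <- contour_levels(surf, c(0, 50, 100))
      write_contours_csv(cont, file.path(out_dir, "contours.csv"))
      message(sprintf("scanned %d x %d design grid",
                      length(grids$delta), length(grids$gamma)))
    } else if (cmd == "breakeven") {
      deltas <- if (is.null(opts$deltas)) c(0.10, 0.15, 0.25)
                else as.numeric(strsplit(opts$deltas, ",")[[1]])
      template <- pick_scenario(cfg$scenarios, opts$scenario %||% "early")
      write_breakeven_csv(deltas, template, params,
                          file.path(out_dir, "breakeven.csv"))
      message("break-even table written for delta = ",
              paste(deltas, collapse = ", "))
    } else if (cmd == "montecarlo") {
      template <- pick_scenario(cfg$scenarios, opts$scenario %||% "early")
      spec <- delta_spec(opts$kind %||% "truncnorm",
                         delta = template$delta,
                         sigma = as.numeric(opts$sigma %||% 0.05))
      mc <- run_monte_carlo(template, spec,
                            n = as.integer(opts$n %||% 2000),
                            seed = seed, params = params)
      write_monte_carlo_csv(mc, file.path(out_dir, "draws.csv"))
      jsonlite::write_json(list(mean_roi = mc$mean_roi,
                                positive_rate = mc$positive_rate,
                                n = length(mc$draws), seed = mc$seed),
                           file.path(out_dir, "mc_summary.json"),
                           auto_unbox = TRUE, digits = I(17), pretty = TRUE)
      message(sprintf("Monte Carlo: mean ROI = %.1f%%", mc$mean_roi))
    } else if (cmd == "robustness") {
      tab <- robustness_suite(cfg$scenarios, params,
                              inflation_factor =
                                as.numeric(opts$inflation %||% 1.2),
                              shortening =
                                as.numeric(opts$shortening %||% 0.15))
      utils::write.csv(tab, file.path(out_dir, "robustness.csv"),
                       row.names = FALSE)
      message("robustness table written (", nrow(tab), " scenarios)")
    } else if (cmd == "calibrate") {
      if (is.null(opts$anchors))
        stop("calibrate requires --anchors BASELINE,POLICY")
      anchors <- as.numeric(strsplit(opts$anchors, ",")[[1]])
      if (length(anchors) != 2 || any(!is.finite(anchors)))
        stop("--anchors must be two numbers: BASELINE,POLICY")
      template <- pick_scenario(cfg$scenarios, opts$scenario %||% "early")
      cal <- calibrate_to_anchors(anchors[1], anchors[2], template, params)
      jsonlite::write_json(unclass(cal),
                           file.path(out_dir, "calibrated_parameters.json"),
                           auto_unbox = TRUE, digits = I(17), pretty = TRUE)
      message(sprintf("calibrated: omega = %.6g, C0 = %.6g",
                      cal$omega, cal$C0))
    } else if (cmd == "fixtures") {
      files <- generate_fixtures(out_dir)
      message("wrote ", paste(basename(files), collapse = ", "))
    }
    cli_log(out_dir, params, seed, extra = list(command = cmd))
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
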