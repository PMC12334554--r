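#' Default run configuration
#'
#' The reference configuration used throughout: literature kinetic rates
#' (polymerization 100, depolymerization 1e-3, fragmentation 1e-4,
#' monomer degradation 5e-4, concatenation 10/2.5/1.67/1.25/1.11/0.83/
#' 0.625), the free parameters fixed at `s = m = 1e-4`, `K = 1`, a pure
#' monomer inoculum `M(0) = 1e-3`, unit burden weights, linear treatment
#' costs 1e-5, quadratic side-effect weights 2, interaction weight 1e-5,
#' control bounds 0.03, and a 1000 s horizon on a 1 s grid.
#'
#' @param scenario Scenario tag, default `"CMO"`.
#' @return An `abeta_config`: list with `model`, `initial`, `weights`,
#'   `bounds`, `scenario`, `T`, `dt`, `sweep`.
#' @export
#' @examples
#' cfg <- default_config("CM")
#' cfg$T / cfg$dt
default_config <- function(scenario = "CMO") {
  structure(list(model = abeta_parameters(),
                 initial = abeta_state(M = 1e-3),
                 weights = abeta_weights(),
                 bounds = abeta_control_bounds(),
                 scenario = abeta_scenario(scenario),
                 T = 1000, dt = 1,
                 sweep = sweep_settings()),
            class = "abeta_config")
}

config_grid <- function(config) {
  n_steps <- config$T / config$dt
  if (abs(n_steps - round(n_steps)) > 1e-9) {
    stop("T must be an integer multiple of dt")
  }
  seq(0, config$T, by = config$dt)
}

#' @export
print.abeta_config <- function(x, ...) {
  cat(sprintf("<abeta_config> scenario %s, T = %g s, dt = %g s\n",
              x$scenario$tag, x$T, x$dt))
  invisible(x)
}

#' Run one treatment scenario
#'
#' Runs the configured scenario in one of three modes: `"none"` (no
#' treatment), `"max"` (both active controls held constant at their
#' bound), or `"optimal"` (forward-backward sweep).
#'
#' @param config An `abeta_config` (see [default_config()],
#'   [read_config()]).
#' @param mode `"optimal"`, `"max"` or `"none"`.
#' @return An `abeta_report`: `scenario`, `mode`, `J`, `dose_v`,
#'   `dose_u`, `final_state`, `trajectory`, `controls`, `iterations`,
#'   `converged`.
#' @export
#' @examples
#' rep <- run_scenario(default_config("CM"), mode = "none")
#' rep$J
run_scenario <- function(config, mode = c("optimal", "max", "none")) {
  mode <- match.arg(mode)
  grid <- config_grid(config)
  scen <- config$scenario
  p <- config$model
  p$alpha0 <- scen$alpha0
  p$alpha1 <- scen$alpha1
  if (mode == "optimal") {
    res <- fbsm_solve(config$model, config$initial, grid, config$weights,
                      config$bounds, scen, config$sweep)
    traj <- res$trajectory; ctl <- res$controls
    J <- res$J; iterations <- res$iterations; converged <- res$converged
  } else {
    if (mode == "none") {
      v <- 0; u <- 0
    } else if (scen$shared) {
      v <- config$bounds$w_max; u <- config$bounds$w_max
    } else {
      v <- scen$alpha0 * config$bounds$v_max
      u <- scen$alpha1 * config$bounds$u_max
    }
    ctl <- abeta_controls(grid, v, u)
    traj <- simulate_forward(p, config$initial, ctl, grid)
    J <- objective(traj, ctl, config$weights, scen)
    iterations <- 0L; converged <- NA
  }
  structure(list(scenario = scen$tag, mode = mode, J = J,
                 dose_v = dose(grid, ctl$v), dose_u = dose(grid, ctl$u),
                 final_state = traj$states[length(grid), ],
                 trajectory = traj, controls = ctl,
                 iterations = iterations, converged = converged),
            class = "abeta_report")
}

#' @export
print.abeta_report <- function(x, ...) {
  cat(sprintf("<abeta_report> %s (%s): J = %.6g, dose_v = %.4g, dose_u = %.4g\n",
              x$scenario, x$mode, x$J, x$dose_v, x$dose_u))
  cat("final state:\n")
  print(x$final_state)
  invisible(x)
}

#' Serialize a run report to JSON
#'
#' @param report An `abeta_report`.
#' @param path Optional file path; if `NULL` the JSON string is
#'   returned.
#' @return JSON string (invisibly when written to file).
#' @export
report_json <- function(report, path = NULL) {
  doc <- list(scenario = report$scenario, mode = report$mode, J = report$J,
              dose_v = report$dose_v, dose_u = report$dose_u,
              final_state = as.list(report$final_state),
              iterations = report$iterations,
              converged = report$converged)
  js <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, na = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Sweep one configuration entry over a set of values
#'
#' Re-runs the optimal-control problem for each value of a single
#' configuration entry, identified by a dotted path into the config
#' (e.g. `"model.s"`, `"weights.c5"`, `"initial.M"`). Per-value failures
#' are recorded and the sweep continues. Each row also carries
#' qualitative control-shape summaries: the peak value and peak time of
#' each control and its plateau value (the median over the middle half
#' of the horizon).
#'
#' @param base An `abeta_config` to perturb.
#' @param path Dotted path to the swept entry.
#' @param values Numeric values to substitute.
#' @param mode Run mode, default `"optimal"`.
#' @return A data frame with one row per value: `value`, `J`, `dose_v`,
#'   `dose_u`, final `M_T`/`O_T`, peak/plateau summaries, `converged`,
#'   `error`.
#' @export
run_sweep <- function(base, path, values, mode = "optimal") {
  parts <- strsplit(path, ".", fixed = TRUE)[[1]]
  if (length(parts) == 2L) {
    cur <- tryCatch(base[[parts[1]]][[parts[2]]], error = function(e) NULL)
    if (is.null(cur)) stop(sprintf("unknown config entry '%s'", path))
  }
  rows <- lapply(values, function(val) {
    out <- tryCatch({
      cfg <- set_config_value(base, parts, val)
      rep <- run_scenario(cfg, mode = mode)
      grid <- rep$controls$grid
      mid <- grid >= 0.25 * max(grid) & grid <= 0.75 * max(grid)
      data.frame(value = val, J = rep$J, dose_v = rep$dose_v,
                 dose_u = rep$dose_u,
                 M_T = rep$final_state[["M"]], O_T = rep$final_state[["O"]],
                 v_peak = max(rep$controls$v),
                 v_peak_time = grid[which.max(rep$controls$v)],
                 v_plateau = stats::median(rep$controls$v[mid]),
                 u_peak = max(rep$controls$u),
                 u_peak_time = grid[which.max(rep$controls$u)],
                 u_plateau = stats::median(rep$controls$u[mid]),
                 converged = isTRUE(rep$converged) || is.na(rep$converged),
                 error = NA_character_)
    }, error = function(e) {
      data.frame(value = val, J = NA, dose_v = NA, dose_u = NA,
                 M_T = NA, O_T = NA, v_peak = NA, v_peak_time = NA,
                 v_plateau = NA, u_peak = NA, u_peak_time = NA,
                 u_plateau = NA, converged = FALSE,
                 error = conditionMessage(e))
    })
    out
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(value = numeric(), J = numeric(), dose_v = numeric(),
                      dose_u = numeric(), M_T = numeric(), O_T = numeric(),
                      v_peak = numeric(), v_peak_time = numeric(),
                      v_plateau = numeric(), u_peak = numeric(),
                      u_peak_time = numeric(), u_plateau = numeric(),
                      converged = logical(), error = character())
  }
  attr(out, "path") <- path
  out
}

set_config_value <- function(config, parts, value) {
  section <- parts[1]
  if (length(parts) == 1L) {
    config[[section]] <- value
    return(config)
  }
  field <- parts[2]
  obj <- config[[section]]
  if (is.null(obj) || is.null(obj[[field]])) {
    stop(sprintf("unknown config entry '%s'", paste(parts, collapse = ".")))
  }
  if (inherits(obj, "abeta_scenario")) {
    config[[section]] <- abeta_scenario(value)
    return(config)
  }
  obj[[field]] <- value
  # re-validate through the constructor
  config[[section]] <- switch(section,
    model = do.call(abeta_parameters, unclass(obj)),
    initial = do.call(abeta_state, as.list(obj)),
    weights = do.call(abeta_weights, unclass(obj)),
    bounds = do.call(abeta_control_bounds, unclass(obj)),
    sweep = do.call(sweep_settings, unclass(obj)),
    { config[[section]] <- obj; obj })
  config
}

#' Write a configuration to a YAML file
#'
#' Every value is written explicitly, so a saved configuration is fully
#' self-describing and round-trips byte-identically through
#' [read_config()].
#'
#' @param config An `abeta_config`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  doc <- list(scenario = config$scenario$tag,
              T = config$T, dt = config$dt,
              model = unclass(config$model),
              initial = as.list(config$initial),
              weights = unclass(config$weights),
              bounds = unclass(config$bounds),
              sweep = unclass(config$sweep))
  yaml::write_yaml(doc, path, precision = 15)
  invisible(path)
}

#' Read a configuration from a YAML file
#'
#' @param path File written by [write_config()] (or hand-edited in the
#'   same layout).
#' @return An `abeta_config`.
#' @export
read_config <- function(path) {
  doc <- yaml::read_yaml(path)
  structure(list(model = do.call(abeta_parameters, doc$model),
                 initial = do.call(abeta_state, doc$initial),
                 weights = do.call(abeta_weights, doc$weights),
                 bounds = do.call(abeta_control_bounds, doc$bounds),
                 scenario = abeta_scenario(doc$scenario),
                 T = doc$T, dt = doc$dt,
                 sweep = do.call(sweep_settings, doc$sweep)),
            class = "abeta_config")
}

#' Generate the preset configuration fixtures
#'
#' Writes the default configuration plus named variants probing the
#' sensitivity studies: the monomer growth rate `s` in
#' \{1e-4, 0.1, 1\}, carrying capacity `K` and competition rate `m`
#' over four values spanning their plausible ranges (log-spaced over
#' [1e-4, 1e3] for `K`; \{0, 1e-3, 0.1, 1\} for `m`), treatment-cost
#' weights `c5`/`c7` up to 1, side-effect and interaction weights
#' `c6`/`c8`/`c9` (with `c9` in \{0, 0.01, 2\}, all keeping the
#' convexity margin positive), and initial monomer/oligomer
#' concentrations in \{0, 1e-3, 0.1\}.
#'
#' @param dir Destination directory (created if missing).
#' @return Character vector of the written file paths, invisibly.
#' @export
fixture_generator <- function(dir) {
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(dir)) stop("cannot create directory: ", dir)
  }
  base <- default_config()
  variants <- list(default = base)
  add <- function(vs, name, path, value) {
    vs[[name]] <- set_config_value(base, strsplit(path, ".", fixed = TRUE)[[1]],
                                   value)
    vs
  }
  for (s in c(1e-4, 0.1, 1)) {
    variants <- add(variants, sprintf("s_%g", s), "model.s", s)
  }
  for (K in 10^seq(-4, 3, length.out = 4)) {
    variants <- add(variants, sprintf("K_%g", K), "model.K", K)
  }
  for (m in c(0, 1e-3, 0.1, 1)) {
    variants <- add(variants, sprintf("m_%g", m), "model.m", m)
  }
  for (c5 in c(1e-5, 1e-3, 1)) {
    variants <- add(variants, sprintf("c5_%g", c5), "weights.c5", c5)
  }
  for (c7 in c(1e-5, 1e-3, 1)) {
    variants <- add(variants, sprintf("c7_%g", c7), "weights.c7", c7)
  }
  for (c6 in c(0.5, 2, 8)) {
    variants <- add(variants, sprintf("c6_%g", c6), "weights.c6", c6)
  }
  for (c8 in c(0.5, 2, 8)) {
    variants <- add(variants, sprintf("c8_%g", c8), "weights.c8", c8)
  }
  for (c9 in c(0, 0.01, 2)) {
    variants <- add(variants, sprintf("c9_%g", c9), "weights.c9", c9)
  }
  for (M0 in c(0, 1e-3, 0.1)) {
    variants <- add(variants, sprintf("M0_%g", M0), "initial.M", M0)
  }
  for (O0 in c(0, 1e-3, 0.1)) {
    variants <- add(variants, sprintf("O0_%g", O0), "initial.O", O0)
  }
  paths <- vapply(names(variants), function(nm) {
    path <- file.path(dir, paste0(gsub("[^A-Za-z0-9_.-]", "-", nm), ".yaml"))
    write_config(variants[[nm]], path)
    path
  }, character(1))
  invisible(unname(paths))
}
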