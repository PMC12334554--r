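#' Settings for the forward-backward sweep
#'
#' @param tolerance Relative L2 convergence threshold applied to the
#'   change in every active control and in the state between sweeps.
#' @param max_iterations Iteration cap; hitting it returns a result with
#'   `converged = FALSE` rather than an error.
#' @param relaxation Mixing weight in `(0, 1]` for the control update:
#'   `new = relaxation * characterized + (1 - relaxation) * previous`.
#' @param initial_v,initial_u Initial control guesses on the grid
#'   (scalars are recycled); the zero default makes iteration 0 the
#'   no-treatment baseline.
#' @return An `abeta_sweep_settings` object.
#' @export
sweep_settings <- function(tolerance = 1e-3, max_iterations = 50,
                           relaxation = 0.5, initial_v = 0, initial_u = 0) {
  if (tolerance <= 0) stop("tolerance must be > 0")
  if (relaxation <= 0 || relaxation > 1) stop("relaxation must be in (0, 1]")
  structure(list(tolerance = tolerance, max_iterations = max_iterations,
                 relaxation = relaxation, initial_v = initial_v,
                 initial_u = initial_u),
            class = "abeta_sweep_settings")
}

#' Backward adjoint solve
#'
#' Integrates the adjoint system from `t = T` down to `t = 0` with the
#' transversality values `lambda(T) = (c1, 0, 0, 0, c2)`, using the same
#' fixed-step fourth-order Runge-Kutta scheme as the forward pass on the
#' reversed grid. State values at half-steps are obtained by cubic
#' spline interpolation of the stored forward trajectory, keeping the
#' backward solve at the same order as the forward one.
#'
#' @param traj Forward `abeta_trajectory`.
#' @param controls An [abeta_controls()] object on the same grid.
#' @param p An [abeta_parameters()] object.
#' @param weights An [abeta_weights()] object.
#' @param scenario An [abeta_scenario()] (or its tag).
#' @return An `n x 5` matrix of adjoint values (`lambda1..lambda5`) on
#'   the grid.
#' @export
backward_solve <- function(traj, controls, p, weights, scenario) {
  if (is.character(scenario)) scenario <- abeta_scenario(scenario)
  grid <- traj$grid
  if (length(grid) != length(controls$grid) ||
      any(grid != controls$grid)) {
    stop("trajectory and controls must share the same grid")
  }
  n <- length(grid)
  S <- traj$states
  sf <- lapply(seq_len(5), function(j) {
    stats::splinefun(grid, S[, j], method = "fmm")
  })
  state_at <- function(t) vapply(sf, function(f) f(t), numeric(1))
  vf <- controls$v_fun; uf <- controls$u_fun
  L <- matrix(0, n, 5,
              dimnames = list(NULL, paste0("lambda", 1:5)))
  L[n, ] <- c(weights$c1, 0, 0, 0, weights$c2)
  cap <- 1e6 * max(1, weights$c1, weights$c2)
  for (k in n:2) {
    t0 <- grid[k]; h <- grid[k] - grid[k - 1L]
    tm <- t0 - h / 2; t1 <- t0 - h
    lam <- L[k, ]
    x0 <- S[k, ]; xm <- state_at(tm); x1 <- S[k - 1L, ]
    k1 <- adjoint_rhs(x0, lam, vf(t0), uf(t0), p, weights, scenario)
    k2 <- adjoint_rhs(xm, lam - h / 2 * k1, vf(tm), uf(tm), p, weights,
                      scenario)
    k3 <- adjoint_rhs(xm, lam - h / 2 * k2, vf(tm), uf(tm), p, weights,
                      scenario)
    k4 <- adjoint_rhs(x1, lam - h * k3, vf(t1), uf(t1), p, weights, scenario)
    ln <- lam - h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    if (any(!is.finite(ln)) || max(abs(ln)) > cap) {
      stop(sprintf("adjoint divergence at t = %g", grid[k - 1L]))
    }
    L[k - 1L, ] <- ln
  }
  L
}

rel_l2 <- function(new, old, floor = 1e-12) {
  sqrt(sum((new - old)^2)) / max(sqrt(sum(new^2)), floor)
}

#' Solve an optimal treatment problem by forward-backward sweep
#'
#' Iterates (i) a forward state solve under the current controls, (ii) a
#' backward adjoint solve with transversality conditions, (iii) the
#' projected pointwise control characterization, relaxed against the
#' previous iterate, until the relative L2 change of every active
#' control and of the state trajectory falls below the tolerance. The
#' zero initial guess makes the first forward pass the no-treatment
#' baseline.
#'
#' @param p An [abeta_parameters()] object (treatment switches are set
#'   from the scenario).
#' @param initial Non-negative initial state.
#' @param grid Strictly increasing solver times spanning `[0, T]`.
#' @param weights An [abeta_weights()] object.
#' @param bounds An [abeta_control_bounds()] object.
#' @param scenario An [abeta_scenario()] (or its tag).
#' @param settings An [sweep_settings()] object.
#' @return An `abeta_sweep_result`: `controls`, `trajectory`, `adjoints`,
#'   scalar `J`, `dose_v`, `dose_u`, `iterations`, `converged`, and a
#'   per-iteration `history` data frame (`iteration`, `J`, `dv_norm`,
#'   `du_norm`, `dstate_norm`).
#' @export
#' @examples
#' cfg <- default_config()
#' res <- fbsm_solve(cfg$model, cfg$initial, seq(0, 100, by = 1),
#'                   cfg$weights, cfg$bounds, "CM")
#' res$J
fbsm_solve <- function(p, initial, grid, weights, bounds, scenario,
                       settings = sweep_settings()) {
  if (is.character(scenario)) scenario <- abeta_scenario(scenario)
  check_convexity(weights, scenario)
  grid <- as.numeric(grid)
  n <- length(grid)
  p$alpha0 <- scenario$alpha0
  p$alpha1 <- scenario$alpha1
  v_bound <- if (scenario$shared) bounds$w_max else bounds$v_max
  u_bound <- if (scenario$shared) bounds$w_max else bounds$u_max
  vv <- pmin(rep_len(settings$initial_v, n), v_bound)
  uu <- pmin(rep_len(settings$initial_u, n), u_bound)
  active_v <- scenario$alpha0 == 1
  active_u <- scenario$alpha1 == 1 && !scenario$shared
  prev_states <- NULL
  hist <- vector("list", settings$max_iterations)
  converged <- FALSE
  it <- 0L
  traj <- NULL; adj <- NULL
  repeat {
    it <- it + 1L
    ctl <- abeta_controls(grid, vv, uu)
    traj <- simulate_forward(p, initial, ctl, grid)
    adj <- backward_solve(traj, ctl, p, weights, scenario)
    upd <- control_update(traj$states[, "M"], traj$states[, "O"],
                          adj[, "lambda1"], adj[, "lambda5"],
                          weights, bounds, scenario)
    r <- settings$relaxation
    vn <- if (active_v || scenario$shared) r * upd$v + (1 - r) * vv else vv
    un <- if (active_u || scenario$shared) r * upd$u + (1 - r) * uu else uu
    dv <- if (active_v || scenario$shared) rel_l2(vn, vv) else 0
    du <- if (active_u) rel_l2(un, uu) else 0
    ds <- if (is.null(prev_states)) Inf else
      rel_l2(as.numeric(traj$states), as.numeric(prev_states))
    J_it <- objective(traj, ctl, weights, scenario)
    hist[[it]] <- data.frame(iteration = it, J = J_it, dv_norm = dv,
                             du_norm = du, dstate_norm = ds)
    prev_states <- traj$states
    vv <- vn; uu <- un
    if (max(dv, du) <= settings$tolerance && ds <= settings$tolerance) {
      converged <- TRUE
      break
    }
    if (it >= settings$max_iterations) break
  }
  ctl <- abeta_controls(grid, vv, uu)
  traj <- simulate_forward(p, initial, ctl, grid)
  adj <- backward_solve(traj, ctl, p, weights, scenario)
  J <- objective(traj, ctl, weights, scenario)
  structure(list(controls = ctl, trajectory = traj, adjoints = adj, J = J,
                 dose_v = dose(grid, vv), dose_u = dose(grid, uu),
                 iterations = it, converged = converged,
                 history = do.call(rbind, hist[seq_len(it)]),
                 scenario = scenario$tag),
            class = "abeta_sweep_result")
}

#' @export
print.abeta_sweep_result <- function(x, ...) {
  cat(sprintf("<abeta_sweep_result> %s: J = %.6g (%s, %d iterations)\n",
              x$scenario, x$J,
              if (x$converged) "converged" else "NOT converged",
              x$iterations))
  cat(sprintf("dose_v = %.4g  dose_u = %.4g\n", x$dose_v, x$dose_u))
  invisible(x)
}

#' Export the sweep iteration history as CSV
#'
#' One row per iteration with columns
#' `iteration,J,dv_norm,du_norm,dstate_norm`.
#'
#' @param result An `abeta_sweep_result`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_history_csv <- function(result, path) {
  utils::write.csv(result$history, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
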