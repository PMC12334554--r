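#' Right-hand side of the aggregation model
#'
#' Time derivatives of the five populations under mass-action kinetics:
#' logistic monomer production, polymerization (`r_l M U_l`),
#' depolymerization (`b`), fragmentation (`beta` per bond), concatenation
#' (`a_jk U_j U_k`), monomer degradation (`delta`), oligomer intraspecific
#' competition (`m O^2`), and the treatment sinks `-alpha0*v*M` and
#' `-alpha1*u*O`.
#'
#' @param state Numeric state vector `(M, U2, U3, U4, O)` (molar).
#' @param v,u Treatment rates (1/s), applied only when the corresponding
#'   switch `alpha0`/`alpha1` in `p` is 1.
#' @param p An [abeta_parameters()] object.
#' @return Named numeric vector of the five time derivatives (M/s).
#' @export
#' @examples
#' p <- abeta_parameters()
#' abeta_rhs(abeta_state(M = 1e-3), v = 0, u = 0, p)
abeta_rhs <- function(state, v = 0, u = 0, p) {
  x <- as_state(state)
  if (!is.finite(v) || !is.finite(u) || v < 0 || u < 0) {
    stop("controls must be finite and >= 0")
  }
  M <- x[[1]]; U2 <- x[[2]]; U3 <- x[[3]]; U4 <- x[[4]]; O <- x[[5]]
  bb <- p$b + 2 * p$beta
  c(M = p$s * M * (1 - M / p$K) - M * (p$r2 * U2 + p$r3 * U3 + p$r4 * U4) +
      bb * U3 + bb * U4 + 2 * p$beta * U2 - p$a11 * M^2 - p$delta * M -
      p$alpha0 * v * M,
    U2 = -p$r2 * M * U2 - p$beta * U2 + bb * U3 + 2 * p$beta * U4 -
      p$a23 * U2 * U3 - p$a24 * U2 * U4 - p$a22 * U2^2 + p$a11 * M^2,
    U3 = -M * (p$r3 * U3 - p$r2 * U2) - bb * U3 + bb * U4 -
      p$a23 * U2 * U3 - p$a34 * U3 * U4 - p$a33 * U3^2,
    U4 = -M * (p$r4 * U4 - p$r3 * U3) - (p$b + 3 * p$beta) * U4 -
      p$a24 * U2 * U4 - p$a34 * U3 * U4 - p$a44 * U4^2 + p$a22 * U2^2,
    O = p$r4 * M * U4 + p$a23 * U2 * U3 + p$a24 * U2 * U4 +
      p$a34 * U3 * U4 + p$a33 * U3^2 + p$a44 * U4^2 - p$m * O^2 -
      p$alpha1 * u * O)
}

#' Analytical Jacobian of the model
#'
#' The 5x5 matrix of partial derivatives of [abeta_rhs()] with respect to
#' the state. With `v = u = 0` (the default) this is the Jacobian used
#' for linear stability analysis; non-zero controls add `-alpha0*v` to
#' entry (1,1) and `-alpha1*u` to entry (5,5), which is what the adjoint
#' system needs.
#'
#' @inheritParams abeta_rhs
#' @return A 5x5 numeric matrix with rows/columns named after the states.
#' @export
abeta_jacobian <- function(state, p, v = 0, u = 0) {
  x <- as_state(state)
  M <- x[[1]]; U2 <- x[[2]]; U3 <- x[[3]]; U4 <- x[[4]]; O <- x[[5]]
  bb <- p$b + 2 * p$beta
  J <- matrix(c(
    p$s * (1 - 2 * M / p$K) - (p$r2 * U2 + p$r3 * U3 + p$r4 * U4) -
      2 * p$a11 * M - p$delta - p$alpha0 * v,
    -p$r2 * M + 2 * p$beta, -p$r3 * M + bb, -p$r4 * M + bb, 0,

    -p$r2 * U2 + 2 * p$a11 * M,
    -p$r2 * M - p$beta - p$a23 * U3 - p$a24 * U4 - 2 * p$a22 * U2,
    bb - p$a23 * U2, 2 * p$beta - p$a24 * U2, 0,

    -p$r3 * U3 + p$r2 * U2, p$r2 * M - p$a23 * U3,
    -p$r3 * M - bb - p$a23 * U2 - p$a34 * U4 - 2 * p$a33 * U3,
    bb - p$a34 * U3, 0,

    -p$r4 * U4 + p$r3 * U3, -p$a24 * U4 + 2 * p$a22 * U2,
    p$r3 * M - p$a34 * U4,
    -p$r4 * M - p$b - 3 * p$beta - p$a24 * U2 - p$a34 * U3 - 2 * p$a44 * U4,
    0,

    p$r4 * U4, p$a23 * U3 + p$a24 * U4,
    p$a23 * U2 + p$a34 * U4 + 2 * p$a33 * U3,
    p$r4 * M + p$a24 * U2 + p$a34 * U3 + 2 * p$a44 * U4,
    -2 * p$m * O - p$alpha1 * u
  ), nrow = 5, ncol = 5, byrow = TRUE,
  dimnames = list(state_names, state_names))
  J
}

#' Integrate the model forward in time
#'
#' Solves the model on a fixed time grid. The default integrator is the
#' classical fixed-step fourth-order Runge-Kutta scheme evaluated on the
#' supplied grid (the same grid the sweep solver shares between forward
#' and backward passes); `method = "lsoda"` instead delegates to the
#' adaptive solver in \pkg{deSolve} as an accuracy cross-check. Controls
#' are evaluated between nodes by the piecewise-linear interpolants of
#' the [abeta_controls()] object.
#'
#' Solutions from non-negative initial data are non-negative up to
#' integrator error: undershoots above `-neg_tol` are clamped to 0, an
#' undershoot below `-neg_tol` raises an error (it would indicate an
#' integrator problem, not round-off). Any component exceeding
#' `cap = 1e6 * max(initial, K)` raises a divergence error naming the
#' failure time, since exact solutions are a-priori bounded.
#'
#' @param p An [abeta_parameters()] object.
#' @param initial Non-negative state vector at `grid[1]`.
#' @param controls An [abeta_controls()] object, or `NULL` for no
#'   treatment.
#' @param grid Strictly increasing times (s).
#' @param method `"rk4"` (fixed step, default) or `"lsoda"` (adaptive,
#'   via \pkg{deSolve}).
#' @param neg_tol Undershoot tolerance (molar), default `1e-10`.
#' @return An `abeta_trajectory`: list with `grid` and the `n x 5` matrix
#'   `states`.
#' @export
#' @examples
#' p <- abeta_parameters()
#' tr <- simulate_forward(p, abeta_state(M = 1e-3), grid = 0:100)
#' tail(as.data.frame(tr), 2)
simulate_forward <- function(p, initial, controls = NULL, grid,
                             method = c("rk4", "lsoda"), neg_tol = 1e-10) {
  method <- match.arg(method)
  x0 <- as_state(initial)
  if (any(x0 < 0)) stop("initial state must be non-negative")
  grid <- as.numeric(grid)
  if (length(grid) < 2L || any(diff(grid) <= 0)) {
    stop("grid must be strictly increasing")
  }
  if (is.null(controls)) controls <- abeta_controls(range(grid), 0, 0)
  vf <- controls$v_fun; uf <- controls$u_fun
  cap <- 1e6 * max(x0, p$K)
  n <- length(grid)

  if (method == "lsoda") {
    fn <- function(t, y, parms) list(unname(abeta_rhs(y, vf(t), uf(t), p)))
    sol <- deSolve::ode(y = x0, times = grid, func = fn, parms = NULL,
                        method = "lsoda", rtol = 1e-10, atol = 1e-14)
    states <- unname(sol[, -1, drop = FALSE])
    states <- guard_state(states, grid, cap, neg_tol)
    return(new_trajectory(grid, states))
  }

  states <- matrix(0, n, 5)
  states[1, ] <- x0
  for (k in seq_len(n - 1L)) {
    t0 <- grid[k]; h <- grid[k + 1L] - grid[k]
    tm <- t0 + h / 2; t1 <- t0 + h
    x <- states[k, ]
    k1 <- abeta_rhs(x, vf(t0), uf(t0), p)
    k2 <- abeta_rhs(x + h / 2 * k1, vf(tm), uf(tm), p)
    k3 <- abeta_rhs(x + h / 2 * k2, vf(tm), uf(tm), p)
    k4 <- abeta_rhs(x + h * k3, vf(t1), uf(t1), p)
    xn <- x + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    if (any(!is.finite(xn)) || max(xn) > cap) {
      stop(sprintf("divergence at t = %g: component exceeded cap %g",
                   grid[k + 1L], cap))
    }
    if (min(xn) < -neg_tol) {
      stop(sprintf("negative undershoot %.3e below tolerance at t = %g",
                   min(xn), grid[k + 1L]))
    }
    states[k + 1L, ] <- pmax(xn, 0)
  }
  new_trajectory(grid, states)
}

guard_state <- function(states, grid, cap, neg_tol) {
  if (any(!is.finite(states)) || max(states) > cap) {
    bad <- which(!is.finite(rowSums(states)) |
                   apply(states, 1, max) > cap)[1]
    stop(sprintf("divergence at t = %g: component exceeded cap %g",
                 grid[bad], cap))
  }
  if (min(states) < -neg_tol) {
    stop(sprintf("negative undershoot %.3e below tolerance", min(states)))
  }
  pmax(states, 0)
}

new_trajectory <- function(grid, states) {
  colnames(states) <- state_names
  structure(list(grid = grid, states = states), class = "abeta_trajectory")
}

#' @export
print.abeta_trajectory <- function(x, ...) {
  n <- length(x$grid)
  cat(sprintf("<abeta_trajectory> %d nodes on [%g, %g]\n",
              n, x$grid[1], x$grid[n]))
  cat("final state:\n")
  print(x$states[n, ])
  invisible(x)
}

#' @export
as.data.frame.abeta_trajectory <- function(x, ...) {
  data.frame(t = x$grid, x$states)
}

#' Export a trajectory as CSV
#'
#' Writes one row per grid node with header `t,M,U2,U3,U4,O` at full
#' precision.
#'
#' @param traj An `abeta_trajectory`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  df <- as.data.frame(traj)
  utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = NA),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
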