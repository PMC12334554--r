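running_cost <- function(v, u, w, scenario) {
  switch(scenario$tag,
    CMO = w$c5 * v + w$c6 * v^2 + w$c7 * u + w$c8 * u^2 + w$c9 * v * u,
    CM = w$c5 * v + w$c6 * v^2,
    CO = w$c7 * u + w$c8 * u^2,
    CMOST = w$c5 * v + w$c6 * v^2)
}

check_convexity <- function(w, scenario) {
  if (scenario$tag == "CMO" && 4 * w$c6 * w$c8 - w$c9^2 <= 0) {
    stop("CMO requires 4*c6*c8 - c9^2 > 0 (convexity in the controls)")
  }
  invisible(TRUE)
}

trapz <- function(grid, y) {
  sum(diff(grid) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Treatment objective functional
#'
#' The cost to be minimized: terminal burden `c1*M(T) + c2*O(T)` plus the
#' time integral of the running burden `c3*M + c4*O` and the
#' scenario-specific treatment cost (CM: `c5*v + c6*v^2`; CO:
#' `c7*u + c8*u^2`; CMO: both plus the interaction `c9*v*u`; CMOST:
#' `c5*w + c6*w^2` with the shared control `w` carried in the `v` slot).
#' Integrals use the composite trapezoid rule on the trajectory grid,
#' matching the piecewise-linear control representation.
#'
#' @param traj An `abeta_trajectory`.
#' @param controls An [abeta_controls()] object on the same grid.
#' @param weights An [abeta_weights()] object; for CMO the convexity
#'   condition `4*c6*c8 - c9^2 > 0` is enforced.
#' @param scenario An [abeta_scenario()] (or its tag).
#' @return The scalar objective value.
#' @export
objective <- function(traj, controls, weights, scenario) {
  if (is.character(scenario)) scenario <- abeta_scenario(scenario)
  check_convexity(weights, scenario)
  if (length(traj$grid) != length(controls$grid) ||
      any(traj$grid != controls$grid)) {
    stop("trajectory and controls must share the same grid")
  }
  n <- length(traj$grid)
  S <- traj$states
  run <- weights$c3 * S[, "M"] + weights$c4 * S[, "O"] +
    running_cost(controls$v, controls$u, weights, scenario)
  unname(weights$c1 * S[n, "M"] + weights$c2 * S[n, "O"] +
           trapz(traj$grid, run))
}

#' Adjoint (costate) derivatives
#'
#' Right-hand side of the Pontryagin adjoint system
#' `dlambda/dt = -dH/dx = -J(x; v, u)^T lambda - (c3, 0, 0, 0, c4)`,
#' where `J` is the analytical model Jacobian including the treatment
#' sink terms active in the scenario. Because the treatment enters the
#' dynamics identically in every formulation (only which controls are
#' switched on differs), a single expression serves CM, CO, CMO and
#' CMOST. Integrated backward from the transversality values
#' `lambda(T) = (c1, 0, 0, 0, c2)`.
#'
#' @param state State vector at time `t`.
#' @param adjoint Adjoint vector `(lambda1..lambda5)` at time `t`.
#' @param v,u Control rates at time `t` (for CMOST pass the shared
#'   control in both).
#' @param p An [abeta_parameters()] object; its `alpha0`/`alpha1` are
#'   overridden by the scenario switches.
#' @param weights An [abeta_weights()] object.
#' @param scenario An [abeta_scenario()] (or its tag).
#' @return Numeric vector of the five adjoint derivatives.
#' @export
adjoint_rhs <- function(state, adjoint, v, u, p, weights, scenario) {
  if (is.character(scenario)) scenario <- abeta_scenario(scenario)
  lam <- as.numeric(adjoint)
  if (length(lam) != 5L || any(!is.finite(lam))) stop("invalid adjoint vector")
  p$alpha0 <- scenario$alpha0
  p$alpha1 <- scenario$alpha1
  J <- abeta_jacobian(state, p, v = v, u = u)
  dL <- c(weights$c3, 0, 0, 0, weights$c4)
  as.numeric(-(crossprod(J, lam) + dL))
}

#' Pointwise optimal-control characterization
#'
#' The stationary point of the Hamiltonian in the controls, projected
#' onto the admissible box `[0, bound]`:
#' \itemize{
#'   \item CM: `v* = clip((lambda1*M - c5) / (2*c6))`
#'   \item CO: `u* = clip((lambda5*O - c7) / (2*c8))`
#'   \item CMO: the coupled pair
#'     `v* = clip(((lambda1*M - c5)*2*c8 - (lambda5*O - c7)*c9) / (4*c6*c8 - c9^2))`,
#'     `u* = clip(((lambda5*O - c7)*2*c6 - (lambda1*M - c5)*c9) / (4*c6*c8 - c9^2))`
#'   \item CMOST: `w* = clip((lambda1*M + lambda5*O - c5) / (2*c6))`
#' }
#' with `clip(x) = min(bound, max(0, x))`. Inputs may be vectors over the
#' grid.
#'
#' @param M,O Monomer and oligomer values (scalar or vector).
#' @param lambda1,lambda5 Corresponding adjoint values.
#' @param weights An [abeta_weights()] object.
#' @param bounds An [abeta_control_bounds()] object.
#' @param scenario An [abeta_scenario()] (or its tag).
#' @return A list with elements `v` and `u` (for CMOST both equal the
#'   shared control).
#' @export
control_update <- function(M, O, lambda1, lambda5, weights, bounds, scenario) {
  if (is.character(scenario)) scenario <- abeta_scenario(scenario)
  check_convexity(weights, scenario)
  clip <- function(x, hi) pmin(hi, pmax(0, x))
  gv <- lambda1 * M - weights$c5
  gu <- lambda5 * O - weights$c7
  switch(scenario$tag,
    CM = list(v = clip(gv / (2 * weights$c6), bounds$v_max),
              u = rep(0, length(M))),
    CO = list(v = rep(0, length(M)),
              u = clip(gu / (2 * weights$c8), bounds$u_max)),
    CMO = {
      D <- 4 * weights$c6 * weights$c8 - weights$c9^2
      list(v = clip((gv * 2 * weights$c8 - gu * weights$c9) / D,
                    bounds$v_max),
           u = clip((gu * 2 * weights$c6 - gv * weights$c9) / D,
                    bounds$u_max))
    },
    CMOST = {
      wstar <- clip((lambda1 * M + lambda5 * O - weights$c5) /
                      (2 * weights$c6), bounds$w_max)
      list(v = wstar, u = wstar)
    })
}

#' Total administered dose
#'
#' The time integral of a treatment rate over the horizon, by the
#' composite trapezoid rule on the grid.
#'
#' @param grid Times (s).
#' @param values Control values at the grid nodes (1/s).
#' @return The dose (dimensionless: rate times time).
#' @export
#' @examples
#' dose(0:1000, rep(0.03, 1001))
dose <- function(grid, values) {
  if (length(grid) != length(values)) stop("grid and values lengths differ")
  trapz(grid, values)
}
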