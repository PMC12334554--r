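#' A-priori bounds on the five populations
#'
#' Computes the explicit constants `q1..q5` that bound each population
#' for all time (an invariant region): trajectories started inside
#' `[0, q1] x ... x [0, q5]` never leave it. Each `q_j` is a maximum of
#' the initial value and ratios of kinetic rates; the carrying capacity
#' `K` enters `q1` only when net monomer growth `s - delta` is positive.
#'
#' A rate appearing in a denominator may be zero, in which case the
#' corresponding bound degenerates to `+Inf` with a warning (the
#' population is still bounded, but not by this formula).
#'
#' The oligomer bound `q5` involves the fourth power `a44*q4^4` of the
#' proto-oligomer bound; the dimensionally symmetric variant with
#' `a44*q4^2` is returned alongside as `q5_alt`, and a message flags the
#' two when they differ. The componentwise invariant-region property is
#' the authoritative check either way.
#'
#' @param p An [abeta_parameters()] object.
#' @param initial Non-negative initial state.
#' @return An `abeta_bounds` object: named list `q1..q5` plus `q5_alt`.
#' @export
#' @examples
#' compute_bounds(abeta_parameters(), abeta_state(M = 1e-3))
compute_bounds <- function(p, initial) {
  x0 <- as_state(initial)
  if (any(x0 < 0)) stop("initial state must be non-negative")
  div <- function(num, den, what) {
    if (den == 0) {
      warning(sprintf("zero rate in denominator of %s: bound is +Inf", what))
      Inf
    } else num / den
  }
  q1 <- max(x0[["M"]],
            div(p$b + 2 * p$beta, p$r3, "q1"),
            div(p$b + 2 * p$beta, p$r4, "q1"),
            div(2 * p$beta, p$r2, "q1"),
            if (p$s - p$delta > 0) p$K else 0)
  q2 <- max(x0[["U2"]],
            div(p$b + 2 * p$beta, p$a23, "q2"),
            div(2 * p$beta, p$a24, "q2"),
            div(p$a11 * q1, p$r2, "q2"))
  q3 <- max(x0[["U3"]],
            div(p$b + 2 * p$beta, p$a34, "q3"),
            div(p$r2 * q1 * q2,
                2 * p$beta + p$b + q1 * p$r3 + p$a23 * q2, "q3"))
  q4 <- max(x0[["U4"]],
            div(p$b + 2 * p$beta, p$a34, "q4"),
            div(q1 * q3 * p$r3 + p$a22 * q2^2,
                q1 * p$r4 + p$b + 3 * p$beta + p$a24 * q2 + p$a34 * q3, "q4"))
  prod4 <- p$r4 * q1 * q4 + p$a23 * q2 * q3 + p$a24 * q2 * q4 +
    p$a34 * q3 * q4 + p$a33 * q3^2
  q5 <- max(x0[["O"]], div(prod4 + p$a44 * q4^4, p$m, "q5"))
  q5_alt <- max(x0[["O"]], div(prod4 + p$a44 * q4^2, p$m, "q5_alt"))
  if (is.finite(q5) && is.finite(q5_alt) && q5 != q5_alt) {
    message(sprintf(
      "q5 = %.6g (quartic proto-oligomer term) vs q5_alt = %.6g (quadratic)",
      q5, q5_alt))
  }
  structure(list(q1 = q1, q2 = q2, q3 = q3, q4 = q4, q5 = q5,
                 q5_alt = q5_alt),
            class = "abeta_bounds")
}

#' @export
print.abeta_bounds <- function(x, ...) {
  cat("<abeta_bounds> population upper bounds\n")
  print(unlist(unclass(x)))
  invisible(x)
}

#' Sandwich bounds on the oligomer population
#'
#' For a positive initial oligomer concentration `O(0) > 0`, the oligomer
#' population is squeezed between the solution of pure intraspecific
#' decay, `O0 / (1 + m t O0)`, and the solution of a logistic-type
#' comparison equation driven by `Q`, the supremum of the oligomer
#' production term `r4 M U4 + a23 U2 U3 + a24 U2 U4 + a34 U3 U4 +
#' a33 U3^2 + a44 U4^2` over time. The supremum over infinite time is
#' evaluated as the maximum over the supplied (computed) trajectory grid:
#' trajectories are bounded and settle well before the end of the
#' horizons used here.
#'
#' When `Q = 0` (pure oligomer decay) both bounds collapse onto the
#' explicit solution. The upper bound is evaluated in an
#' overflow-safe form (numerator and denominator scaled by
#' `exp(-2*sqrt(m*Q)*t)`).
#'
#' @param p An [abeta_parameters()] object.
#' @param traj An `abeta_trajectory` with `O(0) > 0`.
#' @return An `abeta_sandwich` object: `Q`, vectorized functions
#'   `lower(t)`, `upper(t)`, and the logical `holds` (bounds verified on
#'   the grid, with a small relative slack for integrator error).
#' @export
oligomer_sandwich <- function(p, traj) {
  O0 <- unname(traj$states[1, "O"])
  if (O0 <= 0) stop("sandwich bounds require O(0) > 0")
  S <- traj$states
  prod_term <- p$r4 * S[, "M"] * S[, "U4"] + p$a23 * S[, "U2"] * S[, "U3"] +
    p$a24 * S[, "U2"] * S[, "U4"] + p$a34 * S[, "U3"] * S[, "U4"] +
    p$a33 * S[, "U3"]^2 + p$a44 * S[, "U4"]^2
  Q <- max(prod_term)
  m <- p$m
  lower <- function(t) O0 / (1 + m * t * O0)
  upper <- if (Q == 0) {
    lower
  } else {
    function(t) {
      # scaled by exp(-2*sqrt(mQ)*t) and written with expm1 so that both
      # the large-t and the mQ -> 0 limits are evaluated without overflow
      # or cancellation
      rmq <- sqrt(m * Q)
      x <- 2 * rmq * t
      e <- exp(-x)
      om <- -expm1(-x) # 1 - exp(-x), accurate for small x
      (Q * om + O0 * rmq * (1 + e)) / (rmq * (1 + e) + m * O0 * om)
    }
  }
  O <- S[, "O"]
  # slack for integrator error: the bounds are exact, the trajectory is not
  tol <- 1e-6 * max(O) + 1e-14
  holds <- all(O >= lower(traj$grid) - tol) && all(O <= upper(traj$grid) + tol)
  structure(list(Q = Q, lower = lower, upper = upper, holds = holds),
            class = "abeta_sandwich")
}

#' Oligomer concentration at equilibrium
#'
#' At a steady state the oligomer balance gives the unique non-negative
#' root `O = sqrt((r4 M U4 + a23 U2 U3 + a24 U2 U4 + a34 U3 U4 +
#' a33 U3^2 + a44 U4^2) / m)`.
#'
#' @param M,U2,U3,U4 Equilibrium values of the other four populations.
#' @param p An [abeta_parameters()] object with `m > 0`.
#' @return The equilibrium oligomer concentration (molar).
#' @export
equilibrium_oligomer <- function(M, U2, U3, U4, p) {
  if (p$m <= 0) stop("equilibrium oligomer level undefined for m = 0")
  rad <- (p$r4 * M * U4 + p$a23 * U2 * U3 + p$a24 * U2 * U4 +
            p$a34 * U3 * U4 + p$a33 * U3^2 + p$a44 * U4^2) / p$m
  if (rad < 0) stop("negative radicand: populations must be non-negative")
  sqrt(rad)
}

#' Locate and classify equilibria
#'
#' Refines each initial guess by a damped Newton iteration on the
#' (uncontrolled) right-hand side, using the analytical Jacobian, then
#' classifies local stability from the Jacobian eigenvalues at the
#' refined point. A zero real part (within `zero_tol`) makes the
#' linearization inconclusive, which is in particular the case at the
#' extinction equilibrium `(0,0,0,0,0)` where one eigenvalue is exactly
#' zero.
#'
#' @param p An [abeta_parameters()] object (treatment switches must be
#'   off: equilibria are a property of the untreated model).
#' @param guesses List of state vectors to refine.
#' @param tol Residual target, relative to `max(1, |point|)`.
#' @param max_iter Newton iteration cap.
#' @param zero_tol Threshold below which an eigenvalue real part counts
#'   as zero.
#' @return A list of `abeta_equilibrium` reports: `point`, `residual`,
#'   `eigenvalues`, `classification` (`"stable"`, `"unstable"`,
#'   `"inconclusive"`, or `"not-converged"`) and `converged`.
#' @export
#' @examples
#' eq <- find_equilibria(abeta_parameters(), list(abeta_state()))
#' eq[[1]]$eigenvalues
find_equilibria <- function(p, guesses, tol = 1e-12, max_iter = 100,
                            zero_tol = 1e-10) {
  if (p$alpha0 != 0 || p$alpha1 != 0) {
    stop("equilibrium analysis requires alpha0 = alpha1 = 0")
  }
  lapply(guesses, function(g) {
    x <- as_state(g)
    res <- abeta_rhs(x, 0, 0, p)
    for (it in seq_len(max_iter)) {
      scale <- max(1, sqrt(sum(x^2)))
      if (sqrt(sum(res^2)) <= tol * scale) break
      J <- abeta_jacobian(x, p)
      step <- tryCatch(solve(J, -res), error = function(e) NULL)
      if (is.null(step)) break
      lam <- 1
      for (h in 0:30) { # step halving
        xn <- as_state(pmax(x + lam * step, 0))
        rn <- abeta_rhs(xn, 0, 0, p)
        if (sqrt(sum(rn^2)) < sqrt(sum(res^2)) || sum(abs(lam * step)) == 0)
          break
        lam <- lam / 2
      }
      x <- as_state(pmax(x + lam * step, 0))
      res <- abeta_rhs(x, 0, 0, p)
    }
    residual <- max(abs(res))
    converged <- residual <= tol * max(1, sqrt(sum(x^2)))
    ev <- eigen(abeta_jacobian(x, p), only.values = TRUE)$values
    re <- Re(ev)
    classification <- if (!converged) {
      "not-converged"
    } else if (any(abs(re) < zero_tol)) {
      "inconclusive"
    } else if (all(re < 0)) {
      "stable"
    } else {
      "unstable"
    }
    structure(list(point = x, residual = residual, eigenvalues = ev,
                   classification = classification, converged = converged),
              class = "abeta_equilibrium")
  })
}

#' @export
print.abeta_equilibrium <- function(x, ...) {
  cat(sprintf("<abeta_equilibrium> %s (residual %.3e)\n",
              x$classification, x$residual))
  print(x$point)
  cat("eigenvalues:", format(x$eigenvalues, digits = 4), "\n")
  invisible(x)
}

#' Serialize an equilibrium report to JSON
#'
#' @param report An `abeta_equilibrium` from [find_equilibria()].
#' @param path Optional file path; if `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to file).
#' @export
equilibrium_json <- function(report, path = NULL) {
  doc <- list(point = as.list(report$point),
              residual = report$residual,
              eigenvalues = lapply(report$eigenvalues,
                                   function(z) list(re = Re(z), im = Im(z))),
              classification = report$classification,
              converged = report$converged)
  js <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Early monotonicity of a small monomer inoculum
#'
#' From an initial datum `(M0, 0, 0, 0, 0)` with `M0` small, the monomer
#' population initially grows like `M0 * exp((s - delta) * t)`: it is
#' increasing when `s - delta >= 0` and decreasing otherwise. The
#' classification is cross-checked against one integrator step.
#'
#' @param p An [abeta_parameters()] object.
#' @param M0 Small initial monomer concentration (must be `<= eps`).
#' @param eps Smallness threshold for `M0` (molar).
#' @param dt Step used for the numerical cross-check (s).
#' @return `"increasing"` or `"decreasing"`, with attribute `verified`
#'   (logical: the one-step simulation agrees).
#' @export
small_M_monotonicity <- function(p, M0, eps = 1e-2, dt = 0.1) {
  if (M0 < 0 || M0 > eps) stop("M0 must lie in [0, eps]")
  cls <- if (p$s - p$delta >= 0) "increasing" else "decreasing"
  tr <- simulate_forward(p, abeta_state(M = M0), grid = c(0, dt))
  dM <- tr$states[2, "M"] - M0
  verified <- if (M0 == 0 || p$s == p$delta) {
    TRUE # degenerate: M stays flat, consistent with the non-strict branch
  } else if (cls == "increasing") dM > 0 else dM < 0
  structure(cls, verified = verified)
}
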