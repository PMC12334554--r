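#' Kinetic parameters of the aggregation model
#'
#' Bundles every rate constant of the five-population amyloid-beta
#' aggregation model together with the two treatment switches. The
#' populations are monomers `M`, proto-oligomers `U2`, `U3`, `U4` (lengths
#' 2-4) and oligomers `O` (length >= 5, inert except for intraspecific
#' competition and treatment).
#'
#' Monomers follow logistic growth with intrinsic rate `s` (1/s) and
#' carrying capacity `K`. `K` is treated as a concentration (molar)
#' throughout: the logistic term `s*M*(1 - M/K)` is only dimensionally
#' consistent when `M/K` is a pure number, so the inverse-molar unit
#' sometimes quoted for `K` is read as a concentration here.
#'
#' @param s Monomer intrinsic growth rate (1/s).
#' @param K Monomer carrying capacity (molar).
#' @param r2,r3,r4 Polymerization rates for proto-oligomers of length 2-4
#'   (1/(M s)): a monomer extends a proto-oligomer by one unit.
#' @param b Depolymerization rate (1/s): loss of a terminal monomer.
#' @param beta Fragmentation rate per bond (1/s); a chain of length `l`
#'   fragments at total rate `beta*(l-1)`.
#' @param delta Proteolytic degradation rate of monomers (1/s).
#' @param a11,a22,a23,a24,a33,a34,a44 Concatenation rates (1/(M s)):
#'   fusion of two monomers/proto-oligomers of the subscripted lengths.
#' @param m Oligomer intraspecific competition rate (1/(M s)).
#' @param alpha0,alpha1 Treatment switches, exactly 0 or 1: `alpha0`
#'   enables the monomer-degrading control `v(t)`, `alpha1` the
#'   oligomer-degrading control `u(t)`.
#'
#' @return An object of class `abeta_parameters` (a named list).
#' @export
#' @examples
#' p <- abeta_parameters()
#' p$r2
abeta_parameters <- function(s = 1e-4, K = 1,
                             r2 = 100, r3 = 100, r4 = 100,
                             b = 1e-3, beta = 1e-4, delta = 5e-4,
                             a11 = 10, a22 = 2.5, a23 = 1.67, a24 = 1.25,
                             a33 = 1.11, a34 = 0.83, a44 = 0.625,
                             m = 1e-4, alpha0 = 0, alpha1 = 0) {
  p <- list(s = s, K = K, r2 = r2, r3 = r3, r4 = r4, b = b, beta = beta,
            delta = delta, a11 = a11, a22 = a22, a23 = a23, a24 = a24,
            a33 = a33, a34 = a34, a44 = a44, m = m,
            alpha0 = alpha0, alpha1 = alpha1)
  rates <- p[setdiff(names(p), c("alpha0", "alpha1"))]
  bad <- vapply(rates, function(x) !is.numeric(x) || length(x) != 1L ||
                  !is.finite(x) || x < 0, logical(1))
  if (any(bad)) {
    stop("non-negative finite scalar required for: ",
         paste(names(rates)[bad], collapse = ", "))
  }
  if (K <= 0) stop("K must be > 0")
  if (!alpha0 %in% c(0, 1) || !alpha1 %in% c(0, 1)) {
    stop("alpha0 and alpha1 must be exactly 0 or 1")
  }
  structure(p, class = "abeta_parameters")
}

#' @export
print.abeta_parameters <- function(x, ...) {
  cat("<abeta_parameters>\n")
  print(unlist(unclass(x)))
  invisible(x)
}

state_names <- c("M", "U2", "U3", "U4", "O")

#' Construct a state vector
#'
#' A state of the model is the five concentrations (molar) of monomers,
#' proto-oligomers of length 2-4, and oligomers, in that order.
#'
#' @param M,U2,U3,U4,O Concentrations (molar).
#' @return A named numeric vector of length 5.
#' @export
#' @examples
#' abeta_state(M = 1e-3)
abeta_state <- function(M = 0, U2 = 0, U3 = 0, U4 = 0, O = 0) {
  x <- c(M = M, U2 = U2, U3 = U3, U4 = U4, O = O)
  if (!is.numeric(x) || length(x) != 5L || any(!is.finite(x))) {
    stop("state components must be finite scalars")
  }
  x
}

as_state <- function(x) {
  if (!is.numeric(x) || length(x) != 5L) stop("a state has 5 components")
  if (any(!is.finite(x))) stop("invalid state: non-finite component")
  stats::setNames(as.numeric(x), state_names)
}

#' Sampled treatment controls on a time grid
#'
#' Represents the two treatment rates `v(t)` (monomer degradation) and
#' `u(t)` (oligomer degradation) sampled on a strictly increasing time
#' grid. Between nodes the controls are evaluated by piecewise-linear
#' interpolation (constant extrapolation beyond the grid ends), which is
#' the value convention used by all solvers and quadratures in the
#' package.
#'
#' @param grid Strictly increasing times (s) spanning the horizon.
#' @param v,u Control values (1/s) at the grid nodes; scalars are
#'   recycled.
#' @param v_max,u_max Optional box bounds checked at every node.
#' @return An object of class `abeta_controls` with elements `grid`, `v`,
#'   `u` and interpolants `v_fun`, `u_fun`.
#' @export
#' @examples
#' ctl <- abeta_controls(0:10, v = 0.03, u = 0)
#' ctl$v_fun(2.5)
abeta_controls <- function(grid, v = 0, u = 0, v_max = Inf, u_max = Inf) {
  grid <- as.numeric(grid)
  if (length(grid) < 2L || any(diff(grid) <= 0)) {
    stop("grid must be strictly increasing with at least 2 nodes")
  }
  n <- length(grid)
  v <- rep_len(as.numeric(v), n)
  u <- rep_len(as.numeric(u), n)
  if (any(!is.finite(v)) || any(!is.finite(u))) stop("non-finite control value")
  if (any(v < 0) || any(v > v_max)) stop("v outside [0, v_max] at some node")
  if (any(u < 0) || any(u > u_max)) stop("u outside [0, u_max] at some node")
  structure(list(grid = grid, v = v, u = u,
                 v_fun = stats::approxfun(grid, v, rule = 2),
                 u_fun = stats::approxfun(grid, u, rule = 2)),
            class = "abeta_controls")
}

#' Objective-functional weights
#'
#' Weights of the treatment objective: terminal monomer/oligomer burden
#' (`c1`, `c2`), running burden (`c3`, `c4`), linear treatment costs
#' (`c5` for the monomer drug, `c7` for the oligomer drug), quadratic
#' side-effect costs (`c6`, `c8`) and the interaction cost `c9` of giving
#' both drugs at once. For the two-drug scenario the objective is convex
#' in the controls iff `4*c6*c8 - c9^2 > 0`; this is validated lazily by
#' [objective()] and the sweep solver so that single-drug scenarios are
#' unaffected.
#'
#' @param c1,c2,c3,c4,c5,c6,c7,c8,c9 Non-negative weights.
#' @return An object of class `abeta_weights`.
#' @export
abeta_weights <- function(c1 = 1, c2 = 1, c3 = 1, c4 = 1,
                          c5 = 1e-5, c6 = 2, c7 = 1e-5, c8 = 2, c9 = 1e-5) {
  w <- list(c1 = c1, c2 = c2, c3 = c3, c4 = c4, c5 = c5,
            c6 = c6, c7 = c7, c8 = c8, c9 = c9)
  bad <- vapply(w, function(x) !is.numeric(x) || length(x) != 1L ||
                  !is.finite(x) || x < 0, logical(1))
  if (any(bad)) stop("weights must be non-negative scalars: ",
                     paste(names(w)[bad], collapse = ", "))
  structure(w, class = "abeta_weights")
}

#' Control box bounds
#'
#' @param v_max,u_max,w_max Maximum administration rates (1/s) for the
#'   monomer drug, the oligomer drug, and the shared single drug.
#' @return An object of class `abeta_bounds_box`.
#' @export
abeta_control_bounds <- function(v_max = 0.03, u_max = 0.03, w_max = 0.03) {
  if (min(v_max, u_max, w_max) < 0) stop("control bounds must be >= 0")
  structure(list(v_max = v_max, u_max = u_max, w_max = w_max),
            class = "abeta_bounds_box")
}

scenario_tags <- c("CM", "CO", "CMO", "CMOST")

#' Treatment scenario
#'
#' The four treatment formulations: `"CM"` treats monomers only
#' (`alpha0 = 1, alpha1 = 0`), `"CO"` oligomers only (`0, 1`), `"CMO"`
#' both with two independent drugs (`1, 1`), `"CMOST"` both with one
#' shared drug (`1, 1` and `u = v = w`).
#'
#' @param tag One of `"CM"`, `"CO"`, `"CMO"`, `"CMOST"`.
#' @return An object of class `abeta_scenario` with fields `tag`,
#'   `alpha0`, `alpha1`, `shared` (logical: single shared control).
#' @export
abeta_scenario <- function(tag) {
  tag <- match.arg(tag, scenario_tags)
  structure(list(tag = tag,
                 alpha0 = as.numeric(tag %in% c("CM", "CMO", "CMOST")),
                 alpha1 = as.numeric(tag %in% c("CO", "CMO", "CMOST")),
                 shared = tag == "CMOST"),
            class = "abeta_scenario")
}
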