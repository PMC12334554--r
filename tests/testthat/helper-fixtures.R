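# Shared fixtures: random parameter draws and independent hand-built oracles.

# log-uniform rate draw in [1e-4, 1e2]
draw_rate <- function() 10^stats::runif(1, -4, 2)

draw_parameters <- function() {
  abeta_parameters(s = draw_rate(), K = max(draw_rate(), 1e-3),
                   r2 = draw_rate(), r3 = draw_rate(), r4 = draw_rate(),
                   b = draw_rate(), beta = draw_rate(), delta = draw_rate(),
                   a11 = draw_rate(), a22 = draw_rate(), a23 = draw_rate(),
                   a24 = draw_rate(), a33 = draw_rate(), a34 = draw_rate(),
                   a44 = draw_rate(), m = draw_rate())
}

draw_state <- function(scale = 1) {
  abeta_state(M = stats::runif(1, 0, scale), U2 = stats::runif(1, 0, scale),
              U3 = stats::runif(1, 0, scale), U4 = stats::runif(1, 0, scale),
              O = stats::runif(1, 0, scale))
}

# independent term-by-term oracle for the right-hand side: every reaction
# channel is listed separately (production and loss entries per species)
# so the oracle shares no algebra with abeta_rhs
oracle_rhs <- function(x, v, u, p) {
  M <- x[[1]]; U2 <- x[[2]]; U3 <- x[[3]]; U4 <- x[[4]]; O <- x[[5]]
  dM <- p$s * M * (1 - M / p$K)            # logistic production
  dM <- dM - p$r2 * M * U2 - p$r3 * M * U3 - p$r4 * M * U4 # polymerization
  dM <- dM + (p$b + 2 * p$beta) * U3       # depoly + fragmentation from U3
  dM <- dM + (p$b + 2 * p$beta) * U4       # depoly + fragmentation from U4
  dM <- dM + 2 * p$beta * U2               # fragmentation of dimers
  dM <- dM - p$a11 * M^2                   # dimerization loss
  dM <- dM - p$delta * M                   # proteolysis
  dM <- dM - p$alpha0 * v * M              # treatment

  dU2 <- p$a11 * M^2 - p$r2 * M * U2 - p$beta * U2 +
    (p$b + 2 * p$beta) * U3 + 2 * p$beta * U4 -
    p$a22 * U2^2 - p$a23 * U2 * U3 - p$a24 * U2 * U4

  dU3 <- p$r2 * M * U2 - p$r3 * M * U3 - (p$b + 2 * p$beta) * U3 +
    (p$b + 2 * p$beta) * U4 - p$a23 * U2 * U3 - p$a33 * U3^2 -
    p$a34 * U3 * U4

  dU4 <- p$r3 * M * U3 - p$r4 * M * U4 - (p$b + 3 * p$beta) * U4 +
    p$a22 * U2^2 - p$a24 * U2 * U4 - p$a34 * U3 * U4 - p$a44 * U4^2

  dO <- p$r4 * M * U4 + p$a23 * U2 * U3 + p$a24 * U2 * U4 +
    p$a34 * U3 * U4 + p$a33 * U3^2 + p$a44 * U4^2 - p$m * O^2 -
    p$alpha1 * u * O

  c(dM, dU2, dU3, dU4, dO)
}

# central finite-difference Jacobian of abeta_rhs at v = u = 0
fd_jacobian <- function(x, p, h = 1e-6) {
  J <- matrix(0, 5, 5)
  for (j in 1:5) {
    e <- rep(0, 5); e[j] <- h * max(1, abs(x[[j]]))
    J[, j] <- (abeta_rhs(x + e, 0, 0, p) - abeta_rhs(x - e, 0, 0, p)) /
      (2 * e[j])
  }
  J
}

default_grid <- function() seq(0, 1000, by = 1)

rel_l2_test <- function(new, old) {
  sqrt(sum((new - old)^2)) / max(sqrt(sum(new^2)), 1e-12)
}

# memoized scenario runs on the default configuration, shared across files
.run_cache <- new.env(parent = emptyenv())
cached_run <- function(tag, mode = "optimal") {
  key <- paste(tag, mode, sep = "_")
  if (is.null(.run_cache[[key]])) {
    .run_cache[[key]] <- run_scenario(default_config(tag), mode = mode)
  }
  .run_cache[[key]]
}
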