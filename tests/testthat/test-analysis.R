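test_that("a-priori bounds evaluate the max-formulas", {
  p <- abeta_parameters() # s - delta < 0: carrying capacity excluded
  q <- compute_bounds(p, abeta_state(M = 1e-3))
  # direct evaluation of the monomer formula: the initial value dominates
  expect_identical(q$q1, max(1e-3, (p$b + 2 * p$beta) / p$r3,
                             (p$b + 2 * p$beta) / p$r4, 2 * p$beta / p$r2))
  expect_identical(q$q1, 1e-3)
  # with net monomer growth the carrying capacity dominates
  pg <- abeta_parameters(s = 1e-3, K = 1)
  qg <- compute_bounds(pg, abeta_state(M = 1e-3))
  expect_identical(qg$q1, 1)
  # each bound dominates its initial value
  x0 <- abeta_state(M = 0.5, U2 = 0.4, U3 = 0.3, U4 = 0.2, O = 0.1)
  qq <- suppressMessages(compute_bounds(p, x0))
  expect_true(all(unlist(qq[c("q1", "q2", "q3", "q4", "q5")]) >= x0))
})

test_that("zero rates in bound denominators degenerate to +Inf with warning", {
  p <- abeta_parameters(m = 0)
  msgs <- capture_warnings(q <- compute_bounds(p, abeta_state(M = 1e-3)))
  expect_match(msgs, "\\+Inf", all = TRUE)
  expect_identical(q$q5, Inf)
  expect_identical(q$q5_alt, Inf)
})

test_that("quartic and quadratic oligomer-bound variants are both reported", {
  p <- abeta_parameters()
  expect_message(q <- compute_bounds(p, abeta_state(M = 1e-3)), "q5_alt")
  expect_false(q$q5 == q$q5_alt)
  # both agree on the production part; they differ only in the a44 term
  expect_equal(q$q5 - q$q5_alt, p$a44 * (q$q4^4 - q$q4^2) / p$m)
})

test_that("the bounds are an invariant region for random configurations", {
  set.seed(505)
  for (i in 1:50) {
    p <- draw_parameters()
    x0 <- abeta_state(M = runif(1, 0, 1e-2), O = runif(1, 1e-6, 1))
    q <- suppressMessages(compute_bounds(p, x0))
    tr <- simulate_forward(p, x0, grid = seq(0, 5, length.out = 201),
                           method = "lsoda")
    peak <- apply(tr$states, 2, max)
    qv <- unlist(q[c("q1", "q2", "q3", "q4", "q5")])
    expect_true(all(peak <= qv * (1 + 1e-9) + 1e-12))
  }
})

test_that("default forward trajectory respects its own bounds", {
  p <- abeta_parameters()
  x0 <- abeta_state(M = 1e-3)
  q <- suppressMessages(compute_bounds(p, x0))
  tr <- simulate_forward(p, x0, grid = default_grid())
  peak <- apply(tr$states, 2, max)
  expect_true(all(peak <= unlist(q[c("q1", "q2", "q3", "q4", "q5")])))
})

test_that("oligomer sandwich collapses onto the explicit decay solution", {
  p <- abeta_parameters()
  a <- 1e-3
  tr <- simulate_forward(p, abeta_state(O = a), grid = default_grid())
  sw <- oligomer_sandwich(p, tr)
  expect_identical(sw$Q, 0)
  expect_equal(sw$lower(0), a)
  expect_equal(sw$upper(0), a)
  expect_equal(sw$lower(500), sw$upper(500))
  expect_true(sw$holds)
  expect_equal(unname(tr$states[, "O"]), sw$lower(tr$grid),
               tolerance = 1e-10)
})

test_that("sandwich holds on the default configuration and random draws", {
  p <- abeta_parameters()
  tr <- simulate_forward(p, abeta_state(M = 1e-3, O = 1e-3),
                         grid = default_grid())
  sw <- oligomer_sandwich(p, tr)
  expect_true(sw$holds)
  expect_gt(sw$Q, 0)
  expect_true(all(sw$lower(tr$grid) <= sw$upper(tr$grid)))

  set.seed(606)
  for (i in 1:50) {
    p2 <- draw_parameters()
    x0 <- abeta_state(M = runif(1, 0, 1e-2), O = runif(1, 1e-6, 1))
    tr2 <- simulate_forward(p2, x0, grid = seq(0, 5, length.out = 201),
                            method = "lsoda")
    sw2 <- oligomer_sandwich(p2, tr2)
    expect_true(sw2$holds)
    expect_true(all(sw2$lower(tr2$grid) <= sw2$upper(tr2$grid) + 1e-14))
  }

  expect_error(oligomer_sandwich(p, simulate_forward(p, abeta_state(M = 1e-3),
                                                     grid = 0:10)),
               "O\\(0\\) > 0")
})

test_that("equilibrium oligomer level is the square root of the balance", {
  # hand evaluation: six unit production channels against unit competition
  p <- abeta_parameters(r4 = 1, a23 = 1, a24 = 1, a33 = 1, a34 = 1, a44 = 1,
                        m = 1)
  expect_equal(equilibrium_oligomer(1, 1, 1, 1, p), sqrt(6))
  # no proto-oligomers, no production
  expect_identical(equilibrium_oligomer(0.7, 0, 0, 0, abeta_parameters()), 0)
  expect_error(equilibrium_oligomer(1, 1, 1, 1, abeta_parameters(m = 0)),
               "m = 0")
})

test_that("the extinction equilibrium has the closed-form spectrum", {
  p <- abeta_parameters()
  eq <- find_equilibria(p, list(abeta_state()))[[1]]
  expect_identical(unname(eq$point), rep(0, 5))
  expect_identical(eq$residual, 0)
  expect_equal(sort(Re(eq$eigenvalues)),
               sort(c(p$s - p$delta, -p$beta, -p$b - 2 * p$beta,
                      -p$b - 3 * p$beta, 0)))
  expect_identical(max(abs(Im(eq$eigenvalues))), 0)
  # zero eigenvalue: linearization cannot classify
  expect_identical(eq$classification, "inconclusive")
  # the zero eigenvalue is structural, not parameter-specific
  set.seed(707)
  for (i in 1:10) {
    ev <- find_equilibria(draw_parameters(),
                          list(abeta_state()))[[1]]$eigenvalues
    expect_true(any(abs(ev) < 1e-14))
  }
})

test_that("a coexistence equilibrium is found from a long-run endpoint", {
  # net monomer growth regime: the five populations settle to coexistence
  p <- abeta_parameters(s = 0.1)
  tr <- simulate_forward(p, abeta_state(M = 1e-3),
                         grid = seq(0, 5000, by = 1))
  eq <- find_equilibria(p, list(tr$states[nrow(tr$states), ]))[[1]]
  expect_true(eq$converged)
  expect_true(all(eq$point > 0))
  expect_lt(eq$residual, 1e-12 * max(1, sqrt(sum(eq$point^2))))
  # the oligomer component satisfies the steady-state balance
  x <- eq$point
  expect_equal(x[["O"]], equilibrium_oligomer(x[["M"]], x[["U2"]],
                                              x[["U3"]], x[["U4"]], p),
               tolerance = 1e-8)
  json <- equilibrium_json(eq)
  parsed <- jsonlite::fromJSON(json)
  expect_equal(parsed$point$O, x[["O"]])
  expect_identical(parsed$classification, eq$classification)
})

test_that("small-inoculum monotonicity follows the sign of net growth", {
  expect_identical(as.character(
    small_M_monotonicity(abeta_parameters(), 1e-3)), "decreasing")
  expect_true(attr(small_M_monotonicity(abeta_parameters(), 1e-3),
                   "verified"))
  # boundary case s = delta counts as the non-strict increasing branch
  pb <- abeta_parameters(s = 5e-4)
  expect_identical(as.character(small_M_monotonicity(pb, 1e-3)),
                   "increasing")
  pg <- abeta_parameters(s = 1)
  r <- small_M_monotonicity(pg, 1e-6, dt = 0.01)
  expect_identical(as.character(r), "increasing")
  expect_true(attr(r, "verified"))
  expect_error(small_M_monotonicity(abeta_parameters(), 1), "eps")
})

test_that("early monomer growth is exponential at rate s - delta", {
  set.seed(808)
  for (i in 1:10) {
    p <- draw_parameters()
    M0 <- 1e-6
    t_end <- 0.1 / (abs(p$s - p$delta) + 1)
    grid <- seq(0, t_end, length.out = 11)
    tr <- simulate_forward(p, abeta_state(M = M0), grid = grid,
                           method = "lsoda")
    expect_equal(unname(tr$states[, "M"]), M0 * exp((p$s - p$delta) * grid),
                 tolerance = 1e-2)
  }
})
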