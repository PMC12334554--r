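---
title: "Modelling and optimizing amyloid-beta degradation treatments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling and optimizing amyloid-beta degradation treatments}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`abetaoc` models the early aggregation of amyloid-beta peptide in a small
volume of brain tissue with five coupled populations: free monomers $M$,
proto-oligomers $U_2, U_3, U_4$ of lengths 2-4 that still react, and
oligomers $O$ of length $\ge 5$, taken to be chemically inert except for
intraspecific competition for space and for treatment. The reaction
channels are mass-action:

* **polymerization** — a monomer extends a proto-oligomer of length $l$
  at rate $r_l$ (1/(M s));
* **depolymerization** — a proto-oligomer of length 3 or 4 sheds a
  terminal monomer at rate $b$ (1/s);
* **fragmentation** — each of the $l-1$ bonds of a length-$l$ chain
  breaks at rate $\beta$ (1/s), with uniform breakpoints, so total
  fragmentation is $\beta(l-1)$;
* **concatenation** — chains of lengths $j$ and $k$ fuse at rate
  $a_{jk}$; products of length $\ge 5$ feed the oligomer pool;
* **monomer supply and loss** — logistic production $sM(1-M/K)$ and
  proteolytic degradation $\delta M$;
* **oligomer competition** — a quadratic loss $mO^2$;
* **treatment** — a monomer-degrading drug at rate $v(t)$ and an
  oligomer-degrading drug at rate $u(t)$, gated by switches
  $\alpha_0, \alpha_1 \in \{0,1\}$.

The capped maximum length 5 keeps the system small enough for a complete
control analysis; simulations with larger caps behave qualitatively the
same, so nothing essential is lost. One unit note: concentration-like
quantities, including the carrying capacity $K$, are treated as molar
concentrations throughout — the logistic term $sM(1-M/K)$ only makes
dimensional sense if $M/K$ is a pure number, so the inverse-molar unit
occasionally quoted for $K$ in parameter tables is read as molar here.

`abeta_rhs()` implements the vector field, `abeta_jacobian()` its exact
derivative (validated in the tests against central finite differences to
1e-6 relative error on random states), and `simulate_forward()`
integrates it.

## Analytic structure the tests lean on

Three exact facts anchor the numerical work.

**A-priori bounds.** Each population admits an explicit constant bound
$q_j$ built from maxima of rate ratios (`compute_bounds()`); the box
$[0,q_1]\times\dots\times[0,q_5]$ is an invariant region. Two printed
details of the underlying derivation are ambiguous: the oligomer bound
$q_5$ contains a quartic term $a_{44}q_4^4$ where dimensional symmetry
with its neighbours suggests $a_{44}q_4^2$, and the $q_3$, $q_4$ maxima
both carry the ratio $(b+2\beta)/a_{34}$. We evaluate the formulas
verbatim, expose the quadratic variant as `q5_alt`, flag the two when
they differ, and treat the empirical invariant-region property — checked
on 50 random configurations per test run — as the authoritative
statement.

**Sandwich bounds on O.** When $O(0) > 0$, comparison with the pure
competition equation gives $O_0/(1+mtO_0) \le O(t)$, and comparison with
$\hat O' = Q - m\hat O^2$, where $Q$ is the supremum of the oligomer
production term, gives a closed-form upper bound
(`oligomer_sandwich()`). $Q$ is defined as a supremum over all time; we
evaluate it as the maximum over the computed trajectory, which is safe
because trajectories are bounded and settle well inside the horizons
used. The upper bound is evaluated in a form scaled by
$e^{-2\sqrt{mQ}\,t}$ and written with `expm1`: the naive expression
overflows for large $mQ\,t$ and, worse, loses up to six digits to
cancellation when $mQ \to 0$, which showed up as spurious bound
violations of order 1e-2 before the rewrite.

**Equilibria.** The origin is always an equilibrium with spectrum
$\{s-\delta, -\beta, -b-2\beta, -b-3\beta, 0\}$; the structural zero
eigenvalue makes linearization inconclusive there, which
`find_equilibria()` reports honestly rather than guessing. Any
non-trivial equilibrium has all five components positive, with $O$ given
by a square-root balance (`equilibrium_oligomer()`). `find_equilibria()`
refines guesses by damped Newton (step halving up to 30 times, because
the rates span 1e-4 to 1e2 and undamped steps overshoot), with residual
target 1e-12 relative to the point's scale and a 1e-10 threshold on
eigenvalue real parts below which classification is declared
inconclusive. A coexistence equilibrium is exhibited in the tests in the
net-growth regime $s = 0.1 > \delta$, seeded with the endpoint of a
5000 s simulation; the choice of $s$ is ours — any $s > \delta$ regime
works, and the default $s = 10^{-4} < \delta$ decays instead.

## The four treatment formulations

The objective to minimize weighs terminal burden, running burden and
treatment cost:

$$J = c_1 M(T) + c_2 O(T) + \int_0^T \big[c_3 M + c_4 O +
\text{cost}(v,u)\big]\,dt$$

with $\text{cost} = c_5 v + c_6 v^2$ (CM, monomer drug only),
$c_7 u + c_8 u^2$ (CO, oligomer drug only), their sum plus an
interaction $c_9 vu$ (CMO, both drugs), or $c_5 w + c_6 w^2$ for a
single shared drug $w = v = u$ (CMOST). For CMO the objective is convex
in the controls iff $4c_6c_8 - c_9^2 > 0$, which the package enforces
before any solve. Controls live in the box $[0, 0.03]$ 1/s; the 0.03
ceiling is the maximum administration rate used in all reference runs.

Pontryagin's principle turns each problem into a two-point boundary
value problem: costates $\lambda_1..\lambda_5$ solve
$\dot\lambda = -(\partial f/\partial x)^{\!\top}\lambda - (c_3,0,0,0,c_4)$
backward from $\lambda(T) = (c_1,0,0,0,c_2)$, and the optimal control is
the projection onto the box of the Hamiltonian's stationary point —
e.g. $v^* = \mathrm{clip}\big((\lambda_1 M - c_5)/(2c_6)\big)$ for CM,
the analogous coupled pair for CMO, and
$w^* = \mathrm{clip}\big((\lambda_1 M + \lambda_5 O - c_5)/(2c_6)\big)$
for CMOST.

Because the drugs enter the *dynamics* identically in every formulation
(only the switches differ), a single adjoint implementation driven by
the analytical Jacobian transpose serves all four scenarios
(`adjoint_rhs()`). This also sidesteps a transcription slip in one
published form of the oligomer costate equation, where the competition
feedback appears as $-2MO$ instead of $-2mO$: the Jacobian route has no
separate formula to mistype. The decisive correctness check is
behavioural: for each scenario the directional derivative of $J$ under a
localized control perturbation, computed by central finite differences,
must match the adjoint-based gradient
$\int (\partial H/\partial \text{control})\,\text{bump}\,dt$ to 1e-3
relative error. In practice the two agree to about 1e-5.

## The forward-backward sweep

`fbsm_solve()` iterates: forward state solve under the current controls,
backward adjoint solve, projected control update, relaxation. The
numerical choices, and why:

* **Integrator**: classical fixed-step RK4 with $\Delta t = 1$ s on
  $[0, 1000]$ s (1001 nodes). The sweep needs forward and backward
  solves on a shared grid; at the default rates the fastest timescale is
  ~100 s, so 1 s resolves the dynamics with error far below the
  modelling uncertainty. `method = "lsoda"` (deSolve) is the adaptive
  cross-check; the two agree to ~1e-8 on the default run.
* **Control interpolation**: piecewise linear, because RK4 needs
  off-node control values at half-steps; **state interpolation** in the
  backward pass: cubic splines of the stored forward solution, keeping
  the backward solve at the forward solve's order.
* **Initial guess**: zero controls, so iteration 0 reproduces the
  untreated baseline. **Relaxation**: new $=\tfrac12$ update
  $+\tfrac12$ previous, the standard sweep stabilization.
* **Convergence**: relative $L^2$ change $\le 10^{-3}$ for every active
  control *and* for the state trajectory, with floor 1e-12 in the
  denominator. Non-convergence after 50 iterations returns a result
  flagged `converged = FALSE` with the full iteration history, not an
  error. On the default configuration all four scenarios converge in
  9-12 iterations.
* **Positivity and blow-up guards**: undershoots above $-10^{-10}$ are
  clamped to zero (round-off), anything larger aborts with the failure
  time; components beyond $10^6 \max(\text{initial}, K)$ abort as
  divergence, since exact solutions are a-priori bounded.

Quadratures ($J$ and doses) use the composite trapezoid rule on the
solver grid, consistent with piecewise-linear controls. One consequence:
a constant control 0.03 on $[0,1000]$ integrates to exactly 30, where
reference tables list 29.97 (a 999-step grid convention); the 0.1%
difference is far inside the comparison slack and we report our grid's
value.

## Default configuration and what the generator emulates

`default_config()` carries the literature kinetic rates (polymerization
100, depolymerization 1e-3, fragmentation 1e-4, monomer degradation
5e-4, concatenations 10 down to 0.625 — all 1/(M s) or 1/s as
appropriate), the free parameters fixed at $s = m = 10^{-4}$, $K = 1$, a
pure monomer inoculum $M(0) = 10^{-3}$ M, unit burden weights
$c_{1..4} = 1$, linear costs $c_5 = c_7 = c_9 = 10^{-5}$, quadratic
side-effect weights $c_6 = c_8 = 2$, and the 0.03 1/s control ceiling.
`fixture_generator()` writes YAML presets for the sensitivity studies:
$s \in \{10^{-4}, 0.1, 1\}$, $K$ log-spaced over $[10^{-4}, 10^3]$ and
$m$ over $\{0, 10^{-3}, 0.1, 1\}$ (four values each; the original study
states the ranges but not the grid, so the spacing is our choice),
treatment costs up to 1, interaction weights $c_9 \in \{0, 0.01, 2\}$,
and inocula $M(0), O(0) \in \{0, 10^{-3}, 0.1\}$.

These are idealized study conditions: spatially homogeneous, noiseless,
with a hard length-5 oligomer cap and mass-action kinetics. Passing
tests therefore demonstrate correctness of the solver and of the
control characterization under those assumptions — not calibration to
any clinical measurement.

For the fast-growth preset $s = 1$ the monomer subsystem is stiff on the
1 s grid (aggregation timescale ~0.05 s once $M$ approaches $K$), and
the RK4 stability guard fires; runs in that regime use
$\Delta t = 0.1$ s, stated where they appear. This is a property of the
preset, not of the default configuration.

## What the package reproduces

With the default configuration the package reproduces the reference
study's headline numbers: untreated burden $J = 0.2529$ with
$O(1000) = 2.14\times10^{-4}$ M; optimal objectives
$J(v^*) \approx 0.153$ (CM), $J(u^*) \approx 0.138$ (CO),
$J(v^*,u^*) \approx 0.115$ (CMO), $J(w^*) \approx 0.104$ (CMOST) with
doses near 2.06, 2.91 and (CMO) 1.44/2.31; and the qualitative control
shapes — the monomer drug front-loaded, the oligomer drug rising to a
mid-treatment peak, the shared drug interpolating between the two. All
of these are recomputed from scratch by `scripts/acceptance.R` and by
the test suite; none is hard-coded.

## Known limitations

* The oligomer pool is a single lumped compartment; no fibril or plaque
  stage is modelled, so conclusions stop at the oligomer stage.
* The sweep solves a first-order optimality system; it finds the
  minimizer here because the problems are convex in the controls, but
  no second-order certificate is computed.
* Fixed-step RK4 requires the user to respect stability when pushing
  rate parameters orders of magnitude above the defaults (use a smaller
  `dt` or `method = "lsoda"` for forward runs).
* The equilibrium classifier is linear; a zero eigenvalue — structural
  at the origin — yields "inconclusive" by design.
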