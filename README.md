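# abetaoc

Optimal scheduling of amyloid-beta degradation treatments in an early
Alzheimer's disease aggregation model.

## The problem

The aggregation of misfolded amyloid-beta peptide — monomers nucleating
into proto-oligomers and then into neurotoxic oligomers — is a leading
candidate mechanism for early Alzheimer's disease, and both
monomer-targeting and oligomer-targeting degradation therapies (e.g.
anti-amyloid antibodies) are under active development. This package is
for modellers who want to ask: *given a kinetic model of aggregation and
a bounded administration rate, what treatment schedule minimizes the
amyloid burden at acceptable cost?*

The state model is a five-population mass-action ODE system for monomers
$M$, proto-oligomers $U_2,U_3,U_4$, and inert oligomers $O$, with
polymerization ($r_l$), depolymerization ($b$), fragmentation ($\beta$
per bond), concatenation ($a_{jk}$), logistic monomer supply ($s$, $K$),
monomer proteolysis ($\delta$), oligomer competition ($m O^2$), and two
treatment sinks $-\alpha_0 v(t) M$ and $-\alpha_1 u(t) O$. Four
treatment formulations are supported: **CM** (monomer drug only), **CO**
(oligomer drug only), **CMO** (both, independent) and **CMOST** (both,
one shared drug). Each minimizes

$$J = c_1 M(T) + c_2 O(T) + \int_0^T \big[ c_3 M + c_4 O +
\text{cost}(v, u) \big]\, dt ,
\qquad 0 \le v, u \le 0.03\ \mathrm{s}^{-1},$$

with linear + quadratic (+ interaction, for CMO) control costs. The
optimality system — state ODEs forward, Pontryagin costates backward
from $\lambda(T) = (c_1,0,0,0,c_2)$, projected closed-form control
updates such as $v^* = \min(v_{\max}, \max(0, (\lambda_1 M - c_5)/2c_6))$
— is solved by the forward-backward sweep method on a shared fixed RK4
grid (1 s steps over a 1000 s horizon by default).

The package also implements the model's testable analytics: explicit
a-priori bounds forming an invariant region, sandwich bounds on the
oligomer population, equilibrium location by damped Newton, and linear
stability classification.

## Worked example

```r
library(abetaoc)

cfg <- default_config("CO")          # oligomer-drug scenario, defaults
untreated <- run_scenario(cfg, "none")
optimal   <- run_scenario(cfg, "optimal")

untreated
#> <abeta_report> CO (none): J = 0.252856, dose_v = 0, dose_u = 0
#> final state:
#>            M           U2           U3           U4            O
#> 7.780339e-06 2.551097e-05 2.262200e-05 1.517573e-05 2.141261e-04

optimal
#> <abeta_report> CO (optimal): J = 0.138086, dose_v = 0, dose_u = 2.915
#> final state:
#>            M           U2           U3           U4            O
#> 7.780339e-06 2.551097e-05 2.262200e-05 1.517573e-05 2.596004e-05
```

The optimal oligomer treatment cuts the objective from 0.253 to 0.138
and the final oligomer concentration from 2.14e-4 M to 2.60e-5 M, at a
total administered dose of 2.9 (the time integral of the control). The
monomer population is untouched — the oligomer drug has no upstream
effect — whereas the monomer-drug scenario (`default_config("CM")`)
depletes every population downstream of the monomers. Comparing all four
scenarios: $J(w^*) < J(v^*,u^*) < J(u^*) < J(v^*)$ — a single shared
treatment acting on both populations does best.

Other entry points: `simulate_forward()` (fixed-step RK4 or `lsoda`),
`fbsm_solve()` (the sweep solver with iteration history),
`compute_bounds()` / `oligomer_sandwich()` / `find_equilibria()` (the
analytics), `run_sweep()` (parameter sweeps), `fixture_generator()`
(YAML presets for the sensitivity studies), and a thin CLI at
`inst/cli/abetaoc.R` with `simulate` / `control` / `sweep` / `fixtures`
subcommands.

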