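# undulate

A coupled muscle–structure–hydrodynamics model of steady undulatory
swimming energetics, with two-objective evolutionary optimization of
swimmers over body shape and motion.

## What it computes, and for whom

For researchers in biomechanics and computational physiology studying
fish and cetacean locomotion. Given a swimmer's mass, shape (elliptical
sections, 5 coefficients) and undulatory kinematics (tail-beat frequency
plus a 3-coefficient envelope), the package computes:

- the steady sustained swimming speed *U* from the balance of
  slender-body reactive thrust and empirical drag, with a discontinuous
  laminar–turbulent transition at *Re*<sub>cr</sub> = 5×10⁵ and with
  rigid-body recoil solved from whole-body force/moment balance;
- the muscle bending moment *M*(x,t) from an Euler–Bernoulli balance of
  inertial, elastic, visco-elastic and hydrodynamic loads;
- per-cross-section muscle behavior under cyclic (sinusoidal) loading
  from a Hill-type force–velocity law with an eccentric branch:
  activation fraction μ(x,t), mechanical output p̄(x), metabolic
  consumption q̄(x), local efficiency η<sub>m</sub>(x) = p̄/q̄, phase lag
  Φ(x), and physiological feasibility (μ ≤ 1, v̂ < v<sub>max</sub>);
- whole-body energetics: COT = (P<sub>s</sub> + Q)/(m g U), the muscle,
  internal, hydrodynamic and total efficiencies
  η<sub>T</sub> = η<sub>H</sub> η<sub>M</sub> η<sub>I</sub>, and specific
  powers Ψ = P/m<sub>M</sub>, Θ = Q/m<sub>M</sub>;
- Pareto-optimal populations under (maximize *U*, minimize COT) via a
  seeded elitist multi-objective evolution strategy, plus scans across
  body mass.

The analytic core of the muscle model: fiber efficiency peaks at 45.1%
(v<sub>r</sub> = 0.23); constant-rate power peaks at
v<sub>r</sub> = (√5−1)/4 ≈ 0.31 (71.6 W/kg for F₀ = 150 kN/m²,
v<sub>max</sub> = 5 s⁻¹, ρ<sub>m</sub> = 1000 kg/m³); cyclic contraction
halves the obtainable specific power (35.8 W/kg) and caps muscle
efficiency at 44.5% (amplitude 0.27), with maximum specific consumption
81.2 W/kg. See `vignette("swimming-energetics")` for the full model.

## Worked example

```r
library(undulate)
rep <- evaluate_swimmer(reference_params(1), m = 1)
print(rep)
#> Swimmer report (m = 1 kg, L = 0.5111 m)
#>   U = 0.6258 m/s  (Re = 3.2e+05, laminar branch)
#>   COT = 0.1696   P = 0.333 W  Q = 0.9085 W  P_s = 0.1327 W
#>   P_H = 0.04097 W  P_V = 0.2921 W
#>   eta_H = 0.624  eta_M = 0.367  eta_I = 0.123  eta_T = 0.028
#>   Psi = 6.66 W/kg  Theta = 18.17 W/kg  feasible = TRUE
```

A 1 kg reference swimmer (51 cm) cruises at 0.63 m/s in the laminar
regime. Of the 0.91 W its red muscle consumes, 0.33 W becomes mechanical
work (η_M = 37%, below the 44.5% cyclic ceiling); most of that work is
lost to visco-elastic tissue damping (P_V), the remainder reaches the
fluid (P_H), and 62% of the fluid power becomes thrust power. COT ≈ 0.17
means about 0.17 J per newton of weight per meter traveled, including
the 0.13 W standard metabolic rate.

Optimization at fixed mass:

```r
front <- pareto_optimize(m = 1, pop_size = 40, generations = 60, seed = 1)
front$U_opt$U      # fastest non-dominated swimmer
front$COT_opt$COT  # thriftiest non-dominated swimmer
```

A command-line front end with `muscle-curves`, `simulate`, `optimize`
and `scan` subcommands is installed at
`system.file("cli", "swim.R", package = "undulate")`.

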