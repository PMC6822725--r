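---
title: "A coupled muscle-structure-hydrodynamics model of undulatory swimming energetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A coupled muscle-structure-hydrodynamics model of undulatory swimming energetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(undulate)
```

## The problem

Steady undulatory swimmers — most fish, and cetaceans — power themselves by
passing a wave of bending down the body. How much metabolic energy that
costs, how efficiently muscle work becomes thrust, and how these quantities
trade off against swimming speed across nine orders of magnitude in body
mass are questions that cannot be answered by hydrodynamics alone: the
muscle's force-velocity physiology, the passive mechanics of the body, and
the fluid forces are tightly coupled. `undulate` implements that coupled
model end to end and optimizes swimmers against the two conflicting
objectives that matter most ecologically: maximum sustained speed $U$ and
minimum cost of transport $\mathrm{COT}$.

## Muscle model

A fully activated fiber shortening at relative rate $v_r = v/v_{\max}$
produces force (relative to the isometric stress $F_0$) and consumes
metabolic power (relative to $F_0 v_{\max}$) according to a Hill-type
constitutive law with an eccentric branch for active lengthening:

$$\frac{F_f}{F_0} = \begin{cases}
1.8 - 0.8\,\dfrac{1+v_r}{1-7.56\,G\,v_r}, & -1 \le v_r < 0\\[4pt]
\dfrac{1-v_r}{1+G\,v_r}, & 0 \le v_r \le 1
\end{cases}
\qquad
\frac{Q_f}{F_0 v_{\max}} = \begin{cases}
0.01 - 0.11 v_r + 0.06 e^{23 v_r}, & v_r < 0\\[2pt]
0.23 - 0.16 e^{-8 v_r}, & v_r \ge 0
\end{cases}$$

with $G = 4$. Both branches join continuously at $v_r = 0$ (force 1,
consumption 0.07); the kink in $F_f$ at zero rate is kept exact — no
smoothing — because it produces the characteristic kink in the activation
trace at the end of each braking interval.

During steady swimming each cross section experiences a *cyclic* load: a
single-harmonic required force $F_m(t) = \hat F_m \sin\omega t$ (sign
selecting the active body side) and contraction rate
$v_R(t) = \hat v_r \sin(\omega t - \Phi)$. Muscle is recruited by the
activation fraction $\mu = |F_m| / (F_f(v_a) A_m)$, where $v_a$ is the
rate experienced by the active side; $\mu > 1$ means the motion is
physiologically infeasible. Cycle averages give the local output
$\bar p = \tfrac12 \hat F_m \hat v_r \cos\Phi$ (closed form), the
consumption $\bar q$ (by quadrature), and the local muscle efficiency
$\eta_m = \bar p / \bar q$, defined as 0 when $\bar p \le 0$ — a separate
braking fraction records time spent in eccentric contraction.

Key analytic consequences, reproduced by the package and pinned by tests:
the fiber efficiency maximum (45.1% at $v_r = 0.23$), the peak-power rate
$(\sqrt5 - 1)/4 \approx 0.31$ for $G=4$, the maximum cyclic specific power
(35.8 W/kg — exactly half the constant-rate peak of 71.6 W/kg, a direct
consequence of sinusoidal averaging), the maximum cyclic specific
consumption (81.2 W/kg, with zero-amplitude limit $\tfrac2\pi Q_f(0)$),
and the maximum cyclic muscle efficiency (44.5% at amplitude 0.27).

## Body, kinematics, hydrodynamics, structure

**Geometry.** Elliptical sections with height $d(x)$ and width $b(x)$ from
a five-coefficient family ($D_L$, $B_L$, $c_{d1}$, $c_{d2}$, $c_{b1}$; see
`?shape_params`). Two properties of the family are deliberate. The height
vanishes at the snout and the width at both ends, so the sectional added
mass $m_a = \rho\pi d^2/4$ is zero at the leading edge — making the
tail-only thrust formula energetically consistent (verified by the wake
energy identity test) — and the bending stiffness $EI$ vanishes at both
ends, so the beam's free-end boundary terms drop. The width exponent is
restricted to $c_{b1} \le 1$ so the muscle force demand relative to
capacity, $|M|/(0.5\,b \cdot F_0 A_m) \sim M / (d\,b^2)$, stays finite at
the tapering ends ($M$ vanishes quadratically there). The length follows
from the target mass under neutral buoyancy; one-side muscle area is
$A_m = 0.5\mu_0 A$ with $\mu_0 = 0.1$.

**Kinematics.** A single-harmonic traveling wave
$h = r(x)\cos(2\pi x/\lambda_b - \omega t)$ with $\lambda_b = L$ fixed.
The envelope is the *square* of a 3-term Chebyshev series in $x/L$: the
square enforces non-negativity smoothly, which matters because the muscle
strain rate $v = \pm\tfrac12 b\,\partial_t \partial_{xx} h$ involves two
spatial derivatives — a clamped (kinked) envelope would corrupt them.
Motion has 4 parameters ($\omega$ plus 3 coefficients), shape 5, for 9 in
total.

**Hydrodynamics.** Slender-body reactive theory in the frequency domain:
$F_L = (\partial_t + U\partial_x)[m_a(\partial_t + U\partial_x)\hat h]$
applied to complex amplitudes, with the total deflection
$\hat h = h + y_0 + x\varphi$ including the lateral and angular rigid-body
recoil solved from the whole-body force and moment balances (a 2×2 complex
system). Mean thrust is the tail term
$\bar F_T = \tfrac12 m_a(L)[\langle \hat h_t^2\rangle - U^2\langle \hat
h_x^2\rangle]_{x=L}$; drag is $\tfrac12\rho U^2 S C_D$ with the friction
coefficient jumping discontinuously at $Re_{cr} = 5\times10^5$ (laminar
$1.33\,Re^{-1/2}$, turbulent $0.072\,Re^{-1/5}$, shape factor
$1 + 1.5 D_L^{1.5} + 7 D_L^3$). The steady speed solves thrust = drag
per branch; roots are accepted only when their Reynolds number is
consistent with the branch. For some kinematics *neither* branch has a
consistent root — the model's transition gap; the speed solver reports
this as "no steady speed" and the optimizer treats such candidates as
infeasible. This gap is the mechanism behind optimal swimmers holding
$Re$ just below critical.

**Structure.** The Euler-Bernoulli balance
$\rho A \hat h_{tt} + (EI\hat h_{xx})_{xx} + (\nu_b I \hat h_{xxt})_{xx} +
F_L = -M_{xx}$ is double-integrated from the snout with $M(0) = M'(0) = 0$
to extract the muscle bending moment; the recoil balance guarantees the
tail end also closes ($|M(L)|/\max|M|$ at round-off), which is checked,
not imposed. The muscle force follows as $F_m = M / (0.5\,b)$, and the
per-section amplitudes and phase lag feed the cyclic muscle model above.
Visco-elastic losses are $P_V = \nu_b \int I \langle \hat h_{xxt}^2
\rangle dx$.

**A note on $\nu_b$ units.** We take the aggregate visco-elastic
coefficient as $\nu_b = 10^4\,\mathrm{N\,s/m^2}$, i.e. a dynamic
(Pa·s-type) coefficient. This is the only reading under which the term
$\nu_b I \hat h_{xxt}$ carries moment units alongside $E I \hat h_{xx}$
with $E$ in N/m²; it yields internal efficiencies between roughly 0.1 (a
1 kg swimmer) and 0.9 (large swimmers), consistent with the spread
between muscle efficiency and combined muscle-internal efficiency
reported for fish.

**Sign convention.** The extracted moment is paired with the
contraction-rate side convention (positive force = right side active) so
that the muscles do *net positive work*; the convention is fixed globally
by the energy closure $\int \bar p\,dx = P_H + P_V$, which the test suite
enforces to 0.5% on randomized swimmers (the inertial and elastic terms
average to zero over a cycle; the residual is quadrature error).

## Integral energetics

With $P = \int\bar p\,dx$ (net, signed — braking subtracts), $Q =
\int\bar q\,dx$ (consumption counts everywhere, including eccentric
sections), standard metabolic rate $P_s = 0.1327\,m^{0.80}$ W, and $g$
used purely for nondimensionalization:

$$\mathrm{COT} = \frac{P_s + Q}{m g U}, \quad
\eta_M = \frac{P}{Q}, \quad
\eta_I = \frac{1}{1 + P_V/P_H}, \quad
\eta_T = \frac{\bar F_T U}{Q} = \eta_H \eta_M \eta_I.$$

Specific powers $\Psi = P/m_M$ and $\Theta = Q/m_M$ are per one-side
muscle mass $m_M = 0.5\mu_0 m$. The cyclic-contraction bound
$\eta_M \le 44.5\%$ holds on every feasible evaluation.

## Optimization

Two objectives: maximize $U$, minimize COT, over the 9 shape/motion
parameters at fixed mass. No multi-objective CMA-ES implementation is
available as an R package dependency, so the package provides its own
elitist multi-objective evolution strategy — a scalar-step simplification
of MO-CMA-ES: each individual carries a step size multiplying the
box-bound widths, every parent produces one Gaussian offspring, parents
and offspring compete jointly under non-dominated sorting with
crowding-distance tie-breaks, and step sizes adapt by a success rule
(grow when the offspring survives, shrink otherwise). Initialization is
rejection sampling with the frequency drawn log-uniformly, since
feasibility is sharply frequency-dependent. Infeasible candidates
(no steady speed, $\hat v_r \ge 1$, or $\hat\mu > 1$ anywhere) never
enter the surviving population. Runs are fully reproducible by seed.

Desk-scale defaults are population 40 and 60 generations (about 2,500
model evaluations, a couple of minutes on one core) at grid resolution
192 and 512 quadrature samples per cycle; single evaluations default to
256 and 1024. These budgets resolve the structure of the optimal
population — the front, its extremes, and their orderings — not
publication-grade converged fronts, which require populations and
generation counts an order of magnitude larger (exposed through the same
interface).

At 1 kg the desk-scale optimal population already shows the expected
physics: the front spans roughly a factor 2 in speed and 2.5 in COT;
the $U$-optimal extreme attains the maximum muscle efficiency and
specific powers within the front and the COT-optimal extreme the
minimum specific powers; optimal Reynolds numbers crowd just below
$Re_{cr}$; and the $U$-optimal power distribution peaks anterior to the
COT-optimal one. Near-ties along the front do occur at this budget, so
individual orderings should be read per run (seeded) rather than as
converged statements.

## Reference fixture

`reference_params(m)` supplies a deterministic feasible swimmer at any
mass from 1 g to 1000 t: fixed fusiform shape ($D_L = 0.15$,
$B_L = 0.12$, $c_{d1} = 0.06$, $c_{d2} = 1.5$, $c_{b1} = 1$), envelope
coefficients $(0.121, 0.066, 0.011)$ (tail amplitude $\approx 0.04 L$),
and tail-beat frequency $14\,m^{-1/3}$ rad/s above 1 kg (isometric;
keeps the activation envelope roughly mass-invariant) flattened to
$14\,m^{-0.065}$ below 1 kg, where the visco-elastic moment would
otherwise outgrow the muscle capacity of fast-beating small bodies.
Masses whose base frequency falls into the drag-transition gap are
deterministically nudged to 30% higher frequency (repeatedly if needed),
which lands them on the turbulent branch. These choices were calibrated
once, against feasibility margins across the full mass range, and are
not tuned to any particular output quantity.

What the fixture emulates: a plausible steady swimmer at every size, with
activation headroom ($\hat\mu$ between about 0.1 and 0.8) and moderate
contraction rates ($\hat v_r < 0.3$). What it does not emulate: optimized
or species-specific morphology and kinematics, body-wave amplitudes at
the high end of those observed, intermittent (burst-and-coast) gaits, or
any Reynolds regime below $\sim 10^3$. Tests passing on the fixture and
on jittered neighborhoods of it therefore validate the model's internal
consistency and scaling behavior, not agreement with any particular
species' measurements.

## Numerical choices

- Uniform 256-point grid (192 inside the optimizer); 4th-order central
  finite differences with one-sided closures for all spatial derivatives;
  trapezoidal quadrature throughout.
- The recoil moment balance uses the repeated-trapezoid functional — the
  exact discrete adjoint of the double integration that extracts $M$ —
  so the free-free tail closure holds to round-off on the grid; it is a
  consistent $O(\Delta x^2)$ quadrature of the continuous moment balance.
- Cycle integrals use 1024 uniform samples per period by default
  (periodic trapezoid, spectrally exact for the sinusoidal output term);
  scalar maximizations use `stats::optimize` with tolerance $10^{-6}$ on
  the rate axis.
- Speed root-finding: coarse log-spaced bracket scan per drag branch,
  then `stats::uniroot` to $10^{-10}$ relative.
- Degenerate inputs: zero-amplitude motion raises a "no steady speed"
  condition; sections with zero muscle area report zero relative force
  amplitude; $\mu > 1$ and $\hat v_r \ge 1$ are feasibility flags, not
  errors.

## Limitations

Small-amplitude, single-harmonic, linear hydro-structural theory: no CFD,
no large-amplitude elongated-body corrections, no lunate-tail theory, no
vortex wake structure. Muscle is quasi-steady red muscle only — no
length-tension effects, activation transients, or anaerobic fibers. The
empirical drag law with a sharp laminar-turbulent jump is a deliberate
simplification; its discontinuity is the point, not an artifact. Tendons
and longitudinally varying passive stiffness are not modeled.
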