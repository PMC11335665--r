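---
title: "Eddy-dissipation risk assessment for perfusion bioreactors: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Eddy-dissipation risk assessment for perfusion bioreactors: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eddyrisk)
```

## The problem

Suspended cells in perfusion culture (T cells being the motivating case)
are exposed to hydrodynamic stress from the media feed. Two damage routes
matter here. First, wall shear stress: stresses above roughly 3 Pa
(30 dyn/cm^2) are generally held to kill cells, and around 5 Pa
(50 dyn/cm^2) to lyse them outright. Second, and less obviously, the
turbulent energy cascade: recirculation zones (eddies) shed off walls and
baffles decay into progressively smaller eddies until viscosity
dissipates their energy at the Kolmogorov microscale

$$\eta = \left(\frac{\nu^3}{\epsilon}\right)^{1/4},$$

where $\nu$ is the kinematic viscosity and $\epsilon$ the mean rate of
dissipation of turbulent kinetic energy per unit mass. A cell whose
diameter is comparable to or larger than the smallest eddies experiences
opposing velocity gradients across its membrane and very high local
shear; a cell smaller than $\eta$ rides inside an eddy and is spared.
A smallest-eddy scale at or below about 20 µm — a typical expanded
T-cell diameter — is therefore treated as dangerous.

## The cascade model

Approximating the large-eddy turnover time by $L/U$ gives the standard
estimate $\epsilon \sim U^3/L$, and substituting into $\eta$ yields the
classical scaling for the ratio of largest to smallest eddy size,

$$\frac{L}{\eta} \sim \left(\frac{UL}{\nu}\right)^{3/4} = Re^{3/4}.$$

`eddyrisk` applies this as an equality (the order-one constant dropped in
$\epsilon \sim U^3/L$ is taken as exactly 1, which is how the tabulated
reference values are reproduced): given a measured largest eddy $L_e$ and
the inlet Reynolds number, the predicted smallest eddy is
$L_e / Re^{3/4}$, and a condition is *at risk* when that falls at or
below the cell diameter. The boundary case (smallest eddy exactly equal
to the cell diameter) is classified conservatively as at risk. Inverting
the relation gives the critical curve
$L_{min}(Re) = d_{danger}\,Re^{3/4}$: flows whose largest eddy lies below
the curve dissipate to cell scale.

```{r}
assess_risk(reynolds = 2.7, largest_eddy_mm = 3.1)
```

Units: SI internally (m, s, Pa); the reporting boundary uses mm for eddy
sizes and mL/min for feed rates, because the published measurement tables
this model is checked against print eddy sizes and the 0.02 mm cell
diameter in mm.

## Flow conditions and the characteristic length

Feed rates of 0.1–100 mL/min through a circular inlet port of radius
3 mm give mean inlet velocities of 5.8946e-5 to 5.8946e-2 m/s. The
medium is water-like at 37 °C: density 994 kg/m^3, dynamic viscosity
7.191e-4 Pa·s. The characteristic length entering the inlet Reynolds
number is not independently documented for the reference geometry; we
back-solve it from the published velocity–Reynolds pairs
($L = Re\,\nu/U$), which gives 3.31 mm, and use that as the default
inlet opening of the 2-D slice. With these defaults the inlet Reynolds
number is 2.7 per mL/min of feed. Both the port area and the
characteristic length are configurable.

The model distinguishes the *characteristic length* of the flow (used in
$Re$) from the *measured largest eddy* (fed into the cascade ratio);
conflating them is common in back-of-envelope use, but the tabulated
reference arithmetic applies $Re^{3/4}$ to the measured eddy, and the
package follows that convention.

## The 2-D vessel model

The solver domain is a 2-D longitudinal slice of a generic cuboidal
perfusion vessel. The slice dimensions are not documented for the
reference geometry; the defaults — 120 mm long, 25 mm high, inlet and
outlet openings of 3.31 mm centred at mid-height on opposite walls — were
chosen once so that the vessel comfortably contains the largest reported
eddies (44.4 mm) and the tallest baffles (8 mm), and they are fully
configurable. Eleven standard baffle layouts (A–K) cover the design
sweep: unbaffled; three or nine fins of 2 or 4 mm on the base; nine fins
of 2 or 4 mm on the top; and four-fin top arrays (uniform 4 mm, or
graded 4-8-8-8 mm) tilted ±45° into or away from the flow. Baffle
thickness (1 mm) and even spacing over the central 80 % of the vessel
length are likewise undocumented upstream and config-exposed here.

Geometries are rasterized to a structured Cartesian grid by cell-centre
inclusion, so tilted fins are stair-stepped; the rasterizer refuses grids
that put fewer than two cells across a fin's thickness.

## The flow solver

All inlet Reynolds numbers in the study conditions are at most 270, far
below the transition range for internal flow, so the package solves the
steady *laminar* incompressible Navier–Stokes equations rather than a
RANS closure with an eddy-viscosity model. This is the largest modelling
choice in the package: at these Reynolds numbers a turbulence model
mostly adds an eddy viscosity that is negligible against the molecular
one, while a laminar solve is exactly reproducible. The inlet turbulence
intensity that a RANS setup would require is accepted in configuration
but has no laminar counterpart and is ignored.

Discretization: staggered (MAC) finite volumes — pressure at cell
centres, velocities on faces — which avoids pressure checkerboarding
without stabilization. Diffusion is central second order; wall-normal
no-slip is enforced through a quadratic ghost fit through the wall point
and the two nearest interior values (the linear mirror ghost would make
wall shear first-order accurate, the quadratic ghost restores second
order, observed order ≈ 2 on the channel case). Convection is
first-order upwind, optionally with a deferred central correction
(second order at convergence; used for the cavity verification).
Boundary conditions: uniform normal velocity on the inlet, fixed gauge
pressure with zero-gradient velocity on the outlet, no-slip elsewhere.
The outlet mass flow printed in the reference boundary-condition table
is about one quarter of the inlet mass flux ρQ (plausibly a four-outlet
3-D device); the solver does not impose it and conserves mass globally
instead, which the reports verify to machine precision.

The coupled momentum–continuity system is solved by a sparse direct
factorization. Nonlinearity is handled by damped Newton iteration with
an analytic Jacobian (including the advector derivatives of the upwind
fluxes) and a residual line search, started from the creeping-flow
solution. When a plain Newton step cannot reduce the residual, the
solver switches to pseudo-transient continuation: an inertial term
$\rho/\Delta t$ is added to the velocity diagonal, steps are accepted
non-monotonically, and $\Delta t$ grows with the ratio of successive
residual norms, recovering full Newton as $\Delta t \to \infty$.
Convergence is only declared after an undamped full Newton step changes
the velocity field by less than the tolerance (default 1e-6 relative),
so a "converged" flag always denotes a genuine steady solution.

At 100 mL/min the inlet jet over baffled geometries is genuinely
oscillatory — no steady attractor is found. The solver then falls back
to a strongly damped pseudo-time march and returns the mean of the
trailing two-thirds of the iterates, flagged `converged = FALSE,
time_averaged = TRUE`. This mirrors how one would time-average an
unsteady flow, at desk scale: the averaging window is a fixed number of
damped iterates (pseudo-time, not physical time), which is adequate for
mean/max wall-shear summaries but should not be read as a time-accurate
unsteady simulation.

For the 0.1 mL/min feed (inlet Re 0.27) the pipeline uses the Stokes
solver: one linear solve, exactly linear in the inlet velocity, which
the tests exploit (field ratios are exact, and the ×10 feed-rate scaling
of mean WSS between 0.1 and 1 mL/min is reproduced to well within 20 %).

## Post-processing

The streamfunction is accumulated from the staggered `u` velocities
column-by-column (`psi = 0` on the base); because the discrete field is
divergence-free, row-wise integration agrees to machine precision, and
the discrepancy is reported as a path-independence error with a 1 % hard
limit. Through-flow streamlines carry `psi` between the base and top
values, so *recirculation zones* are connected components of nodes whose
`psi` leaves that band (beyond a tolerance of 1e-6 of the band width).
Each region is labelled by the wall it touches; the base-attached
largest-eddy size — defined as the largest bounding-box extent, a
reproducible stand-in for measuring eddies off streamline plots — feeds
the cascade model. Interior and top regions are reported but excluded
from the base measurement.

Wall shear stress is extracted as
$\tau = \mu\,(9u_1 - u_2)/(3\,\Delta y)$ — the one-sided second-order
difference through the wall, exact for a parabolic profile — excluding
baffle footprints. The channel verification holds it to within 1 % of
the Poiseuille closed form $6\mu U_m/h$ on a 64-cell-high grid.

## Verification strategy

Every stage is testable without external data:

- *Analytic flows*: plane Poiseuille (profile, flux, WSS closed forms);
  uniform streams; creeping-flow linearity.
- *Constructed vortex fields*: an exact nodal streamfunction (uniform
  stream plus a compact C¹ patch) differenced to staggered velocities,
  divergence-free to machine precision, with a known patch diameter that
  eddy detection must recover within two grid cells.
- *Lid-driven cavity at Re 100*: the 64² solution is compared against a
  frozen 256² self-converged run of the same solver (central-deferred
  convection), with 2 % L2 agreement on the centreline profiles; the
  256² minimum streamfunction (−0.1035) sits at the textbook value.
- *Grid convergence*: Richardson analysis of the developed-region mean
  base WSS on the entrance-flow channel across three grids; the
  slip/no-slip inlet corner is excluded from the functional because the
  singularity there dominates a whole-base mean and masks the interior
  order.

What the synthetic fixtures do *not* emulate: three-dimensionality,
turbulent fluctuations, free surfaces, and any biology. Passing tests
show that the discrete operators, the cascade arithmetic and the
detection topology are right — not that a particular physical vessel
behaves as simulated.

## Problem sizes and defaults

The full design sweep (11 layouts × 4 feed rates) runs on a 240 × 50
grid (0.5 mm cells — the coarsest grid that resolves 1 mm fins with two
cells), with solver tolerance 1e-6 and at most 60 coupled iterations per
condition before the time-averaging fallback engages. Verification
cases use 48×16 up to 192×64 channel grids and the 64² cavity. These
sizes keep a complete sweep plus the verification suite at desk scale
on a single core while leaving the headline quantities
grid-insensitive at the precision they are reported.

## Known limitations

- The 2-D slice ignores spanwise confinement; absolute eddy sizes and
  WSS differ from any real 3-D vessel (and from 3-D RANS results on an
  undocumented geometry), so agreement on those is expected in order of
  magnitude and in verdict, not digit-for-digit.
- Stair-stepped 45° fins perturb near-fin shear at the cell scale.
- The cascade model is a scaling law: it predicts *risk*, not damage
  rates, and ignores osmotic, gas-transport and nutrient effects.
- Time-averaged (non-converged) conditions report pseudo-time means;
  oscillation amplitudes are not quantified.
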