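---
title: "Modeling intrathecal drug dispersion in oscillatory CSF flow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling intrathecal drug dispersion in oscillatory CSF flow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(csfsim)
```

## The physical problem

During spinal anesthesia a local anesthetic is injected through a fine needle
into the cerebrospinal fluid (CSF) of the lumbar subarachnoid space, between
the L4 and L5 vertebrae. How far and how fast the drug spreads decides both
the quality of the block and the risk of complications. The CSF is not still:
every heartbeat displaces about 1 mL of fluid craniocaudally through the
cervical canal, respiration superimposes a slower oscillation, and choroidal
production adds a steady ~0.4 mL/min drift. Dispersion of the drug is
therefore set by the interplay of the injection jet (needle gauge, speed,
duration), these physiological oscillations, and molecular diffusion.

`csfsim` implements a desk-scale simulator of this system: an idealized
axisymmetric spinal canal, a finite-volume incompressible Navier-Stokes
solver for the oscillatory flow, and a conservative advection-diffusion
update for the drug volume fraction, with the nine-run needle/speed/duration
experiment matrix and the reporting metrics built in.

## Governing equations

The CSF is water-like and Newtonian (density $\rho = 998.3$ kg/m$^3$,
viscosity $\mu = 0.89$ mPa·s), and the flow laminar:

$$\nabla\cdot\mathbf{u} = 0, \qquad
\rho\left(\frac{\partial\mathbf{u}}{\partial t}
 + \mathbf{u}\cdot\nabla\mathbf{u}\right)
 = -\nabla P + \mu\nabla^2\mathbf{u} + \mathbf{F},$$

with $\mathbf{F} = 0$ by default (supine position; no buoyancy — drug and
CSF share properties). The drug is a passive, miscible volume fraction
$C \in [0,1]$:

$$\frac{\partial C}{\partial t} + \mathbf{u}\cdot\nabla C = D\nabla^2 C.$$

No diffusivity is established for the agent at hand; the default
$D = 5\times10^{-10}$ m$^2$/s is the small-molecule aqueous scale and is
configurable. All headline checks are either $D$-independent or use the
configured value explicitly.

## The idealized geometry

Patient-specific image-derived geometry is not available, so the domain is
an axisymmetric annulus: a dural tube whose radius tapers from 8 mm
(lumbar) to 6.5 mm (cervical) over 0.60 m, containing a spinal cord of up
to ~4.6 mm radius that ends at the conus medullaris near L1-L2 (caudal to
that the section is a full circle). A vertebral-level map (S1 at $z=0$ up
to C1) assigns each level a half-open axial interval, so windows such as
"L4-L5" (injection), "T12-L1" (local retention) and "C7-T1" (cranial
transport) are well defined. Two lumped compartments close the domain: a
cranial reservoir (240 mL default) standing for the intracranial CSF, and
a small closed sacral stub (5 mL) below the caudal opening. The defaults
put the total CSF volume at ~322 mL, inside the physiological 250-400 mL
range; because no canonical canal volume exists, any volume-sensitive
result should be read against the configured volume, which the manifest
records.

Two geometric-fidelity rules matter numerically:

* the conus taper is not resolved below a 1 mm cord radius — a no-slip
  filament thinner than that has wall drag that converges only
  logarithmically under refinement, so sub-cutoff cord keeps its volume but
  carries no wall stress;
* the radial grid uses cosine (wall-clustered) spacing by default, because
  the oscillatory Stokes layer at cardiac frequency is
  $\delta = \sqrt{2\nu/\omega} \approx 0.5$ mm and uniform desk-scale grids
  under-resolve the wall shear that sets the axial pressure distribution.

## Waveforms and boundary conditions

The driving waveform is synthesized rather than traced from a published
measurement (none is tabulated): a zero-mean truncated Fourier series with
a sharp systolic peak (harmonic weights 1, 0.5, 0.15 at 60 beats/min),
scaled exactly so its positive-phase integral per cycle — the stroke or
pulse volume — equals 1.0 mL; a zero-mean respiratory sinusoid (12
breaths/min) calibrated to 0.5 mL/cycle; and a 0.4 mL/min steady
production offset. A measured trace can be substituted through
`waveform_from_table()`. Heart and respiratory rates and the tidal volume
are physiological defaults, not published values; every calibration check
depends only on the integral calibrations, not the shape.

The combined waveform drives a uniform normal velocity at the caudal
opening (positive = cranially directed), the cranial end is a pressure
outlet coupled to the reservoir, and all dural/pial walls are no-slip.
Fluid and drug swept through the caudal opening enter the closed sacral
stub and return on the inflow phase, so the opening does not destroy drug
mass. Verification cases can instead open both ends (`driven = "none"`) or
close them (`closed = TRUE`) and force the flow with a body force.

## Numerics

The solver is a staggered (MAC) finite-volume scheme on the annular
$r$-$z$ grid, advanced by an incremental pressure-projection method: a
momentum predictor with Adams-Bashforth-2 limited second-order upwind
convection (minmod limiter), Crank-Nicolson implicit radial viscosity (the
stiff direction), explicit axial viscosity, and corrector sweeps that
solve a pressure Poisson equation (direct sparse Cholesky, factored once
per mesh) until the normalized successive-difference criterion
$\max_{i,j,k} |\delta^{n+1}-\delta^n| / |\delta^{n+1}| < 10^{-6}$ is met;
where $|\delta^{n+1}|$ falls below a guard floor the absolute difference is
used (the criterion does not define the zero-denominator case). The
discrete divergence of every accepted step is zero to direct-solver
precision, and kinetic energy decays monotonically without forcing.

The scalar update is flux-form MUSCL with a van Leer limiter by default
(grid-convergence order ~1.9 on smooth profiles; minmod and first-order
upwind — the volume-fraction scheme of reference CFD practice — are config
options), integrated with SSP-RK2 and explicit central diffusion. Because
the update is conservative and the boundary fluxes feed the two lumped
compartments, the ledger identity injected = resident + reservoir + stub
holds to machine precision; it is asserted to 0.1% in the tests.

The outer time step defaults to 0.01 s; the advective CFL (cap 0.45,
per-cell) and explicit-term stability engage automatic sub-stepping, e.g.
during the high-momentum phase of a 22G injection. Halving the default
step changes the 10-s velocity field by ~0.5% in L2 (the `timestep_study()`
check), so 0.01 s sits in the converged regime.

The needle bore ($10^{-7}$ m$^2$ scale) is far below any desk-scale face
area, so the injection enters by sub-face weighting as a tip-cell source
triple: volume at the protocol's rate (speed x bore area), jet momentum
$\rho Q v$ along the needle axis (perpendicular dural entry by default,
with a configurable cranial/caudal tilt), and drug inflow at volume
fraction 1. Needle inner diameters follow ISO 9626 regular-wall nominal
values (22G: 0.413 mm, 25G: 0.260 mm, 27G: 0.210 mm) and are overridable,
since delivered volumes scale with them. When the needle-exit Reynolds
number exceeds 2300 (runs 1 and 4), the run report flags that the local
jet is beyond the laminar model's regime; the laminar model is retained as
the modeling choice.

## Verification

Three independent oracles check the physics end to end:

* steady annular Poiseuille flow against the closed form (< 1% L2 at 16
  radial cells);
* oscillatory annular flow against a Womersley-type analytic series,
  evaluated by an independent fine-grid complex boundary-value solve
  (< 3% amplitude/phase at Womersley number ~4);
* pure diffusion of a Gaussian blob against $\mathrm{Var}(t) = 2Dt$
  (< 2%).

The mesh-independence procedure re-runs the baseline (no-injection)
oscillatory case at three refinements — (48, 6), (96, 12), (192, 24)
axial x radial cells — and tracks the area-weighted mean pressure over all
wall boundaries at the final step of 10 s; the finest-pair relative change
is ~0.6%, below the 1% convergence criterion, which is what justifies
running production cases at millimeter rather than sub-millimeter element
scales.

## Reporting metrics

* `window_mean()` — volume-weighted mean volume fraction x 100 over a
  vertebral window, reported at 1/3/6 min for C7-T1 and T12-L1;
* `domain_mean_percentage()` — the "average drug percentage", defined here
  (the source figure does not define it) as drug volume over the spinal
  CSF compartment (canal + sacral stub) x 100, reported at 60/200/300 s;
  this definition is conserving, so the percentage cannot decrease while
  nothing has reached the cranial outlet. The canal-only variant is
  available via `include_stub = FALSE`. Published absolute percentages
  (e.g. 1.625%) depend on an unshared patient geometry and an unstated
  averaging region and are not reproduction targets; the time-monotone
  trend and the gauge/speed orderings are;
* `cranial_arrival()` / `cranial_transport_ordering()` — earliest time the
  C7-T1 window mean exceeds a threshold (default 0.01%), with non-arrival
  encoded as +Inf.

## What the desk-scale model does and does not show

The reduction from a patient-specific 3D tetrahedral domain to a 2D
axisymmetric annulus preserves area-varying oscillatory flow, Stokes-layer
shear dispersion, jet momentum injection and strict conservation — the
transport physics the parameter sweep interrogates. It does not preserve
nerve rootlets, denticulate ligaments, anatomical asymmetry, or genuinely
three-dimensional jet mixing; an axisymmetric momentum source is a ring
jet, which recirculates differently from a localized 3D jet. Consequently
cranial transport is slower here than in the full 3D study: at default
settings neither the fastest (22G, 3.8 m/s) nor the slowest (27G,
0.21 m/s) run lifts the C7-T1 window above the 0.01% threshold within
6 min, and the ordering claim is satisfied as "no later than" rather than
by a strict early arrival. Local retention at T12-L1, the speed/gauge
contrast near the injection site, and the time-monotone drug percentage
all reproduce as qualitative trends.

Also out of scope, matching the source study's own limitations:
pharmacological properties (baricity, binding, uptake), posture change,
compliant dura, and pathological CSF.

## Problem sizes used by the checks

The bundled tests and the acceptance script run the calibration checks
analytically (seconds), the oracle suite on 8 x 16-24 annulus grids, the
mesh study up to 192 x 24 cells for 10 s of physical time, and the
nine-run sweep at 48 x 4 cells for 300 s of physical time — sizes chosen so
the whole verification cycle completes on one CPU in minutes while staying
inside the asymptotic regimes the convergence studies demonstrate.
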