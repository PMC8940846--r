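---
title: "Homogenized constrained mixture growth and remodeling: model and numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Homogenized constrained mixture growth and remodeling: model and numerics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`hcmgr` simulates the slow structural adaptation (growth and remodeling,
G&R) of an arterial wall modelled as a constrained mixture of load-bearing
constituents: an elastin-rich matrix (elastin plus ground substance),
smooth muscle, and four collagen fiber families oriented at 0, ±45 and 90
degrees from the circumferential direction in the local tangent plane.
All constituents share the total deformation gradient `F`, which is split
multiplicatively per constituent into an elastic part and an inelastic
part, `F = F_e^j F_gr^j`.  The inelastic part pools the entire deposition
history of constituent `j` into a single tensor (the *homogenized*
constrained mixture idea), so the state of a material point is one
inelastic deformation and one reference density per constituent rather
than a deposition-time integral.

The mixture strain energy per unit reference volume is the density-weighted
sum of per-unit-mass constituent energies evaluated on the elastic part of
the right Cauchy-Green tensor:

* matrix: nearly incompressible neo-Hookean,
  `psi = mu/2 (Je^{-2/3} tr(Ce) - 3) + kappa/2 (Je - 1)^2`;
* fibers (collagen and passive smooth muscle):
  `psi = k1/(2 k2) [exp(k2 (lambda_e^2 - 1)^2) - 1]`, tension-only by
  default;
* active smooth-muscle tone (only where a scenario provides active
  constants): a parabolic length-tension law
  `sigma_act = sigma_actmax (rho_m/rho_m0) [1 - ((lambda_max -
  lambda_act)/(lambda_max - lambda_0))^2]` with the active stretch held at
  its nominal value.

Units are millimetres, kilopascals, days, with densities in kg/m^3 and
moduli in J/kg (so density times modulus is a stress in Pa).

The fiber energy prefactor is a convention that differs between related
models (`k1/(2k2)` versus `k1/(4k2)`); it is exposed as the option
`prefactor` (`"2k2"`, the default, or `"4k2"`).  The default was fixed by
reproducing the straight-tube verification case, whose printed stress and
collagen extrema the `"2k2"` form matches.

## Prestretch and the in-vivo reference configuration

The reference geometry is the pressurized in-vivo configuration, so it is
not stress free.  Collagen and smooth muscle are deposited at a scalar
prestretch `lambda_h` along their fiber axis (a unimodular rank-one
stretch).  The matrix receives a diagonal elastic prestretch in the local
(axial, radial, circumferential) frame whose radial component always closes
local incompressibility, `lambda_R = 1/(lambda_ax lambda_th)`.

* **Straight tube.** The axial component is pinned to the in-vivo axial
  stretch; the circumferential component is found by a one-dimensional root
  solve of the layered thick-wall force balance
  `sum_layers (sigma_th - sigma_r) ln(r_out/r_in) = p`.
* **Torus slice (idealized aortic arch).** The axial (toroidal) and
  circumferential (poloidal) components vary linearly across the arch
  diameter between inner-curvature (IC) and outer-curvature (OC) endpoint
  values.  The axial OC endpoint equals the in-vivo stretch and the axial
  IC endpoint starts from the arc-length ratio `lambda_iv R_IC/R_OC`.  The
  circumferential endpoints start from the cross-section ring balance; at
  the OC the toroidal membrane pressure factor `(2R + a)/(2(R + a))` is
  applied (robust statics on the dome-like outer curvature), while at the
  saddle-side IC the straight-tube balance is kept — for a wall this thick
  at this arch ratio the saddle-side membrane correction is unreliable, and
  the subsequent distortion iteration is the authority in any case.
* **Calibration loop.** A fixed-point iteration solves the forward
  equilibrium, measures the diameter and thickness distortion of the
  computed state against the reference geometry on the mid-sweep IC-OC
  metric line, and updates the axial IC endpoint while the thickness
  distortion exceeds its tolerance (default 3%), otherwise the
  circumferential endpoints while the diameter distortion exceeds its
  tolerance.  Updates are secant steps with under-relaxation 0.5, bounded
  to [0.5, 2]; the circumferential endpoints are driven by the luminal
  radial offsets at IC and OC separately, which is what allows the two
  endpoints to differentiate.  The loop stops as soon as both tolerances
  hold (so vacuous tolerances return the initial guess unchanged), and the
  accepted field is always re-verified by the forward solve that produced
  its distortion report.

Thickness on the metric line is taken as the average of the IC and OC wall
cuts; distortions are normalized by the reference dimension.

## Elastin degradation and mass turnover

Elastin never regenerates.  Its density follows either pure first-order
aging, `rho(t) = rho0 exp(-t/T_l)` with `T_l` = 101 years, or an insult:
the aging term plus a spatially Gaussian, temporally transient loss with
peak fraction `D_max` = 0.5, width `L_dam` = 10 mm and time constant
`t_dam` = 40 days.  The spatial distance to the insult centre is either a
signed projection on an axial direction (a band around the vessel — the
default, and the convention of the straight-tube verification case, where
the centre sits at mid-length) or the Euclidean distance (a patch).  For
the toric arch the centre defaults to the mid-sweep outer-curvature
luminal point with the axial (along-arch) mode.

Collagen and smooth muscle turn over under stress control.  The driver is
the mass-specific fiber-direction Cauchy stress scaled by the inverse
mixture volume ratio, `s = k1 (x - 1) exp(k2 (x-1)^2) x / J` with
`x = lambda_e^2` (plus the active contribution for smooth muscle), and the
homeostatic target `s_h` is recorded per quadrature point from the
converged pressurized state at the reference time, so curved geometries
have spatially varying targets and the initial state is an exact fixed
point.  Mass production follows

```
d rho / dt = rho k_sigma (s - s_h) / s_h
```

and remodeling relaxes the inelastic fiber stretch so that the stress
returns to target at the rate `(rho_dot/rho + 1/T)(s - s_h)`, the
homogenized turnover rate (turnover time `T` = 101 days).  Three candidate
stress measures were implemented for the driver — the intensive measure
`s(x)`, the density-weighted partial stress, and the volume-ratio-damped
form above.  Only the third both reproduces the printed verification
extrema and keeps the through-thickness load partition stable; the other
two let quadrature-level perturbations feed back into runaway local
deposition.  The `1/J` factor acts as the volumetric damping of the
homogenized deposition state: where grown volume accumulates, the driver
per unit deposited mass falls.

Growth changes volume along the local wall normal: every constituent
shares `F_g = I + (rho_tot/rho_tot0 - 1) e_R (x) e_R`, so the inelastic
volume tracks the net mass change at constant true density.

Time integration is explicit forward Euler with a default step of 10 days;
halving the step changes a 10-year diameter by less than 0.5% (this is an
always-on test), and the elastin density is evaluated from its closed form
rather than integrated.

## Finite elements

Equilibrium at each step is solved with total-Lagrangian trilinear
hexahedra (VTK cell-type-12 node ordering), Newton-Raphson with the
analytic consistent tangent, and 2x2x2 Gauss quadrature.  The volumetric
term of the matrix energy is integrated at the element centre only
(selective reduced integration), which removes volumetric locking at the
bulk ratios used here (kappa/mu of 20-100); output stresses evaluate that
term at the centre as well so reported fields are consistent with the
discrete equilibrium.  The luminal pressure is a follower load on the
deformed surface with its exact load stiffness.  Tube ends carry radial
rollers: end nodes move only radially within their cross-section plane
(configurable to full in-plane motion), resisted by distributed springs
with tributary end areas; spring stiffnesses are in Pa/m as configured
(1 Pa/m = 1e-6 kPa/mm, so the literature values act as regularizers, not
constraints).  Quarter-model symmetry planes are enforced exactly.

Pressure and prestretch are activated together over five geodesic
increments at the reference time (stretch powers `lambda^s`), with
automatic halving of the increment on divergence.  The Newton tolerance is
a relative residual of 1e-8.  The linearized system is solved with a
symmetrized sparse LDL' factorization by default (the tangent is symmetric
up to the small follower-load and active-tone terms), which converges at a
fast linear terminal rate of the order of the skipped asymmetry (a few
percent per iteration, so the extra iterations are cheaper than the
unsymmetric factorization they avoid); the option `solver = "lu"` requests
the exact unsymmetric factorization of the full consistent tangent, under
which Newton exhibits textbook quadratic convergence — asserted by a test.

Field extrema (von Mises stress, normalized collagen density) are reported
from element-averaged quadrature values: the element is the resolution
scale of the discretization, and sub-element quadrature scatter of a
trilinear element is not a resolved feature of the field.

## Geometry, meshes, and the layer split

Built-in generators produce structured hexahedral meshes of quarter/full
cylinders and torus slices, with exact node placement on the named radii
(so the diameter and thickness metrics are exact at the reference), layer
labels, boundary node/facet sets and per-quadrature-point orthonormal
material frames.  gmsh (`.msh` v2.2/v4.1 ASCII) and legacy ASCII VTK
unstructured grids round-trip through the reader/writer; external meshes
can carry `media`/`adventitia` physical volumes.

The media/adventitia thickness fractions of the bi-layer arch are not
fixed by the source material tables.  With the layer densities used here,
an equal split reproduces the reported homeostatic distortion bounds of
the idealized arch (diameter within 2%, thickness within 3%), while a 2/3
media split does not; the generator therefore defaults to an equal split
with a mesh line exactly at the interface, and the fraction is a config
field.

## Problem sizes and defaults used by the tests

The verification cylinder runs on a 2x10x40-element quarter mesh (the
coarser of the two published discretizations) with a 10-day step over 15
years; the idealized arch uses a 2x16x12-element eighth-torus for
calibration and a decade-long insult scenario.  These sizes were chosen so
the full suite exercises every pipeline stage at useful accuracy; the
mesh-refinement and step-halving properties are asserted separately.

## What the built-in scenarios do and do not show

The two built-in scenarios emulate the published idealized test cases: an
axisymmetric insult on a straight tube and a band insult on an idealized
toric arch.  They share the features of real aneurysm G&R that the model
represents — prestretched in-vivo reference, layered wall, stress-driven
turnover, unstable dilatation at low gain — but none of the features of
patient-specific practice: irregular geometry and thickness, imaging noise,
hemodynamic loading, hypertension coupling, or aortic unfolding.  Passing
the built-in checks therefore validates the mechanics and the
implementation, not predictions for a specific patient.

Reproduction of the verification table is close but not exact: the maxima
of the von Mises field and the stable-gain collagen peak match the printed
values within a few percent, while the printed field minimum and the
low-gain collagen peak are reproduced less tightly (the suite computes
roughly +50% and -35% on those two numbers).  The constitutive details of
the original supplements are not available verbatim; the residual gaps are
consistent with the spread the original comparison itself reports against
its own reference implementation (up to 45%).

## Known limitations

* Linear prestretch gradients only; no polynomial distributions.
* No damage mechanics beyond prescribed elastin loss, no viscoelasticity,
  no fluid coupling, no contact, and no membrane/shell elements.
* The explicit G&R update assumes the equilibrium path is smooth at the
  10-day scale; strongly unstable late-stage aneurysms eventually fail the
  Newton solve, and the driver then reports a truncated series rather than
  extrapolating.
* Patient-specific meshes are read but no patient data ships with the
  package.
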