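# hcmgr — homogenized constrained mixture growth and remodeling of arteries

`hcmgr` is a finite-element simulator for the long-term growth and
remodeling (G&R) of arterial walls, aimed at vascular biomechanics
researchers studying aneurysm initiation and progression in curved vessels
such as the ascending thoracic aorta.

The wall is a constrained mixture of an elastin-rich matrix, smooth muscle
and four collagen fiber families that share the total deformation gradient
`F`, split per constituent into elastic and inelastic parts,
`F = F_e^j F_gr^j` (the *homogenized* constrained mixture: the whole
deposition history is pooled into one inelastic tensor per constituent).
The mixture energy is `W(C) = sum_j rho_R^j psi^j(C_e^j)` with a nearly
incompressible neo-Hookean matrix, Fung-exponential fibers
`psi = k1/(2k2)[exp(k2(lambda_e^2-1)^2)-1]` deposited at prestretch
`lambda_h`, and an optional parabolic active smooth-muscle tone.  Mass
turnover is stress-driven,

    d rho^j/dt = rho^j k_sigma (s^j - s_h^j)/s_h^j,

with remodeling of the inelastic fiber stretch at rate
`(rho_dot/rho + 1/T)(s - s_h)` and wall-normal volumetric growth
`F_g = I + (rho_tot/rho_tot0 - 1) e_R (x) e_R`.  Elastin only degrades:
first-order aging with a 101-year lifetime, optionally plus a localized
Gaussian insult that triggers aneurysm-like G&R.

Because the in-vivo reference geometry is loaded, each constituent carries
a deposition prestretch.  For curved (toric) vessels the package assigns
the elastin prestretch as linear gradients between the inner and outer
arch curvature and calibrates the gradient endpoints iteratively until the
computed pressurized state reproduces the reference geometry within
diameter/thickness distortion tolerances.

The solver is an in-package total-Lagrangian trilinear-hexahedron code:
Newton-Raphson with consistent tangents, selective reduced integration of
the volumetric term, follower pressure on the deformed lumen, and radial
rollers with Robin springs at the tube ends.  Meshes are generated
internally (cylinders, torus slices) or read from gmsh `.msh` / legacy VTK
files; fields export to VTK.

## Worked example

Calibrate the elastin prestretch gradients of an idealized aortic arch
(eighth of a torus, lumen diameter 36 mm, arch radius 65 mm, wall
thickness 2.38 mm, 80 mmHg) and inspect the homeostatic state:

```r
library(hcmgr)
cfg <- toric_arch_scenario(horizon_days = 0,
                           prestretch = list(mode = "calibrate",
                                             lam_iv = 1.3,
                                             eps_t = 3, eps_d = 2))
res <- run_scenario(cfg)
res$prestretch
#> <prestretch_field> axial IC/OC = 0.7361 / 1.3, circumferential IC/OC = 1.454 / 1.354 (lam_iv = 1.3)
res$distortion
#> <distortion_report> delta_d = 0.629%, delta_t = 0.875%
```

The calibrated field shortens the inner curvature axially
(`lambda = 0.74` against the in-vivo stretch 1.3 at the outer curvature)
and tensions the inner-curvature circumference more than the outer
(1.45 vs 1.35); with it, the computed pressurized configuration matches
the imaged reference to 0.6% in diameter and 0.9% in thickness, i.e. the
state is a usable homeostatic starting point for G&R.

A decade of G&R after a localized elastin insult with a low gain
(`k_sigma = 0.09/T`) then dilates the arch past the 55-mm surgical
threshold:

```r
cfg <- toric_arch_scenario(gain_frac = 0.09, horizon_days = 10 * 365,
                           insult_mode = "insult")
res <- run_scenario(cfg)
max(res$series$diameter)
#> [1] 55.58915
```

`res$series` carries the diameter/thickness time series together with the
extrema of the von Mises stress and of the normalized collagen density;
`export_result_vtk()` writes the final deformed field for a VTK viewer.
A command-line wrapper with the same functionality lives in
`inst/cli/hcmgr.R` (subcommands `verify-cylinder`, `run-torus`,
`calibrate-prestretch`, `run-config`).

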