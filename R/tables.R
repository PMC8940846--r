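# Built-in parameter sets for the two benchmark scenarios: the straight
# quarter-cylinder verification case and the idealized toric aortic arch.
# All values are in the units used throughout: mm, mmHg (converted to kPa
# internally), J/kg, kg/m^3, days.

cyl_collagen <- function(rho, angle) list(
  kind = "collagen", rho = rho, k1 = 568, k2 = 11.2, angle = angle,
  lambda_h = 1.062, turnover = 101)

#' Material table of the cylinder verification benchmark
#'
#' Single-layer mixture: neo-Hookean elastin-rich matrix (prestretched
#' 1.25 axially and 1.34 circumferentially, radial component from
#' incompressibility), passive+active smooth muscle and four collagen
#' families at 0, +/-45 and 90 degrees from the circumferential direction.
#'
#' @return named list of per-layer constituent parameter lists.
#' @export
cylinder_benchmark_materials <- function() {
  list(single = list(
    list(kind = "matrix", rho = 241.5, mu = 72, kappa = 100 * 72,
         lambda_h = c(1.25, 1 / (1.25 * 1.34), 1.34)),
    list(kind = "smc", rho = 157.5, k1 = 7.6, k2 = 11.4, angle = 0,
         lambda_h = 1.1, sigma_actmax = 54, lambda_0 = 0.8,
         lambda_max = 1.4, lambda_act = 1.0, turnover = 101),
    cyl_collagen(65.1, 0),
    cyl_collagen(241.5, pi / 4),
    cyl_collagen(241.5, -pi / 4),
    cyl_collagen(65.1, pi / 2)))
}

#' Scenario: aneurysm development in an idealized cylinder
#'
#' Quarter cylinder (inner radius 10 mm, length 90 mm, thickness 1.41 mm)
#' under 100 mmHg, with a localized elastin insult at mid-length and
#' stress-driven collagen/smooth-muscle turnover.
#'
#' @param gain_frac gain as a fraction of 1/T (0.05 ... 0.15).
#' @param horizon_days simulated horizon (default 15 years).
#' @param dt_days explicit step.
#' @param divisions mesh divisions c(thickness, circumferential, axial).
#' @param insult_mode `"insult"` (localized degradation) or `"aging"` or
#'   `"none"`.
#' @return a [scenario_config()].
#' @export
cylinder_benchmark_scenario <- function(gain_frac = 0.05,
                                        horizon_days = 15 * 365,
                                        dt_days = 10,
                                        divisions = c(2, 15, 60),
                                        insult_mode = "insult") {
  scenario_config(
    name = sprintf("cylinder-benchmark-k%.2f", gain_frac),
    geometry = list(type = "cylinder", radius = 10, length = 90,
                    thickness = 1.41, quarter = TRUE, divisions = divisions),
    materials = cylinder_benchmark_materials(),
    pressure_mmHg = 100,
    boundary = list(k_pro = 0, k_dis = 0, radial_only = TRUE),
    insult = list(mode = insult_mode, D_max = 0.5, L_dam = 10, t_dam = 40),
    gain_frac = gain_frac, horizon_days = horizon_days, dt_days = dt_days,
    prestretch = list(mode = "as_given"), output_every = 100)
}

ata_collagen <- function(rho, angle) list(
  kind = "collagen", rho = rho, k1 = 292, k2 = 5.6, angle = angle,
  lambda_h = 1.1, turnover = 101)

#' Material tables of the idealized toric aortic arch
#'
#' Bi-layer wall (media/adventitia) with layer-specific densities; smooth
#' muscle is passive here (no active tone parameters for this scenario)
#' and absent from the adventitia.
#'
#' @param beta bulk modulus multiplier (kappa = beta * mu).
#' @return named list with `media` and `adventitia` constituent tables.
#' @export
toric_arch_materials <- function(beta = 40) {
  smc <- function(rho) list(kind = "smc", rho = rho, k1 = 13.8, k2 = 6.0,
                            angle = 0, lambda_h = 1.1, turnover = 101)
  list(
    media = list(
      list(kind = "matrix", rho = 169, mu = 80, kappa = beta * 80,
           lambda_h = c(1.3, 1 / (1.3 * 1.3), 1.3)),
      smc(735),
      ata_collagen(14.6, 0), ata_collagen(58.4, pi / 4),
      ata_collagen(58.4, -pi / 4), ata_collagen(14.6, pi / 2)),
    adventitia = list(
      list(kind = "matrix", rho = 565, mu = 80, kappa = beta * 80,
           lambda_h = c(1.3, 1 / (1.3 * 1.3), 1.3)),
      smc(0),
      ata_collagen(48.5, 0), ata_collagen(194, pi / 4),
      ata_collagen(194, -pi / 4), ata_collagen(48.5, pi / 2)))
}

#' Scenario: growth and remodeling of an idealized toric aortic arch
#'
#' Eighth of a torus (lumen diameter 36 mm, arch radius 65 mm, wall
#' thickness 2.38 mm) under 80 mmHg with radial-roller + spring end
#' conditions (1 and 0.2 Pa/m) and a linearly graded elastin prestretch.
#'
#' @param gain_frac gain as a fraction of 1/T.
#' @param horizon_days simulated horizon.
#' @param dt_days explicit step.
#' @param divisions mesh divisions c(thickness, poloidal, toroidal).
#' @param insult_mode `"none"`, `"aging"` or `"insult"` (localized, centred
#'   mid-sweep on the outer-curvature luminal wall).
#' @param prestretch prestretch block; default calibrates the gradient
#'   endpoints with tolerances 3%/2% (thickness/diameter).
#' @param beta bulk modulus multiplier.
#' @return a [scenario_config()].
#' @export
toric_arch_scenario <- function(gain_frac = 0.09, horizon_days = 0,
                                dt_days = 10, divisions = c(2, 16, 12),
                                insult_mode = "none",
                                prestretch = list(mode = "calibrate",
                                                  lam_iv = 1.3, eps_t = 3,
                                                  eps_d = 2),
                                beta = 40) {
  scenario_config(
    name = sprintf("toric-arch-k%.2f-%s", gain_frac, insult_mode),
    geometry = list(type = "torus", lumen_diameter = 36, arch_radius = 65,
                    thickness = 2.38, sweep_angle = pi / 2,
                    layer_split = 1 / 2, divisions = divisions),
    materials = toric_arch_materials(beta),
    pressure_mmHg = 80,
    boundary = list(k_pro = 1, k_dis = 0.2, radial_only = TRUE),
    insult = list(mode = insult_mode, D_max = 0.5, L_dam = 10, t_dam = 40),
    gain_frac = gain_frac, horizon_days = horizon_days, dt_days = dt_days,
    prestretch = prestretch, output_every = 100)
}
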