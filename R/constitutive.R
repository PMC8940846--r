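# Constitutive model of the mixture: neo-Hookean elastin-rich matrix,
# Fung-exponential collagen/smooth-muscle fibers deposited under prestretch,
# and an active smooth-muscle tone.  Energies are per unit mass (J/kg);
# stresses are in kPa with densities in kg/m^3.

KPA <- 1e-3  # (J/kg * kg/m^3) = Pa -> kPa

#' Constituent parameter record
#'
#' One component of the arterial mixture: the elastin-rich matrix
#' (`"matrix"`), smooth muscle (`"smc"`) or a collagen fiber family
#' (`"collagen"`).  Fiber constituents carry a direction angle measured from
#' the circumferential axis in the (circumferential, axial) tangent plane, a
#' deposition (homeostatic) stretch, a mass-production gain and a turnover
#' time; the matrix carries shear/bulk moduli and a prestretch triple.
#'
#' @param kind `"matrix"`, `"smc"` or `"collagen"`.
#' @param rho reference mass density (kg/m^3).
#' @param mu,kappa neo-Hookean shear and bulk modulus (J/kg), matrix only.
#' @param k1,k2 Fung-exponential fiber parameters (J/kg, dimensionless).
#' @param angle fiber angle from the circumferential direction (rad).
#' @param lambda_h deposition stretch (fibers) or the triple
#'   (axial, radial, circumferential) of elastic prestretches (matrix).
#' @param sigma_actmax,lambda_0,lambda_max,lambda_act active stress
#'   parameters (kPa and stretches); `sigma_actmax = 0` disables tone.
#' @param gain mass-production gain k_sigma (1/days).
#' @param turnover turnover time T (days).
#' @param tension_only if `TRUE` the fiber bears no compression.
#' @return object of class `hcm_constituent`.
#' @export
constituent <- function(kind = c("matrix", "smc", "collagen"), rho,
                        mu = NULL, kappa = NULL, k1 = NULL, k2 = NULL,
                        angle = 0, lambda_h = 1, sigma_actmax = 0,
                        lambda_0 = 0.8, lambda_max = 1.4, lambda_act = 1.0,
                        gain = 0, turnover = Inf, tension_only = TRUE) {
  kind <- match.arg(kind)
  stopifnot(rho >= 0)
  if (kind != "matrix") {
    stopifnot(k2 > 0, lambda_max > lambda_0, all(lambda_h > 0))
  }
  structure(list(kind = kind, rho = rho, mu = mu, kappa = kappa, k1 = k1,
                 k2 = k2, angle = angle, lambda_h = lambda_h,
                 sigma_actmax = sigma_actmax, lambda_0 = lambda_0,
                 lambda_max = lambda_max, lambda_act = lambda_act,
                 gain = gain, turnover = turnover,
                 tension_only = tension_only),
            class = "hcm_constituent")
}

#' Deposition prestretch tensor of a fiber
#'
#' Unimodular stretch along the fiber axis:
#' `lambda_h a0 (x) a0 + lambda_h^(-1/2) (I - a0 (x) a0)`.
#'
#' @param lambda_h deposition stretch (> 0).
#' @param a0 fiber direction (normalized if not unit, with a warning).
#' @return 3x3 matrix with determinant 1.
#' @export
fiber_prestretch_tensor <- function(lambda_h, a0) {
  stopifnot(lambda_h > 0)
  n <- sqrt(sum(a0^2))
  if (abs(n - 1) > 1e-8) {
    warning("a0 is not a unit vector; normalizing")
    a0 <- a0 / n
  }
  M <- tcrossprod(a0)
  lambda_h * M + (diag(3) - M) / sqrt(lambda_h)
}

#' Cauchy stress of the elastin-rich matrix
#'
#' Nearly incompressible neo-Hookean response evaluated from the elastic
#' part of the deformation gradient: an isochoric term
#' `(rho/J) mu Je^(-2/3) dev(b_e)` plus a volumetric term
#' `(rho/J) kappa Je (Je - 1) I`.
#'
#' @param F_e_l elastic deformation gradient of the matrix (3x3).
#' @param mu,kappa shear and bulk modulus in J/kg.
#' @param rho_R reference density in kg/m^3.
#' @param J mixture volume ratio (defaults to `det(F_e_l)`).
#' @return symmetric 3x3 Cauchy stress in kPa.
#' @export
matrix_cauchy_stress <- function(F_e_l, mu, kappa, rho_R, J = det(F_e_l)) {
  Je <- det(F_e_l)
  if (Je <= 0) stop("inverted elastic state: det(F_e) <= 0")
  b <- tcrossprod(F_e_l)
  dev <- mu * Je^(-2 / 3) * (b - sum(diag(b)) / 3 * diag(3))
  vol <- kappa * Je * (Je - 1) * diag(3)
  (rho_R * KPA / J) * (dev + vol)
}

#' Elastic fiber stretch
#'
#' `lambda_e = || F F_gr^-1 a0 ||`, the stretch of the fiber measured from
#' its evolving natural (stress-free) configuration.
#'
#' @param F total deformation gradient.
#' @param F_gr inelastic (growth/remodeling) deformation gradient.
#' @param a0 unit fiber direction in the reference configuration.
#' @return positive scalar.
#' @export
fiber_elastic_stretch <- function(F, F_gr, a0) {
  d <- det(F_gr)
  if (!is.finite(d) || abs(d) < 1e-14) stop("singular F_gr")
  v <- F %*% solve(F_gr, a0)
  sqrt(sum(v^2))
}

fiber_psi_prefactor <- function(prefactor = c("2k2", "4k2")) {
  if (match.arg(prefactor) == "2k2") 2 else 1
}

#' Second Piola-Kirchhoff stress of a Fung-exponential fiber
#'
#' Rank-one tension along `a0 (x) a0` derived from the per-unit-mass energy
#' `psi = k1/(2 c k2) [exp(k2 (lambda_e^2 - 1)^2) - 1]` (prefactor
#' convention selectable, default the `2k2` form, i.e. c = 1).
#'
#' @param lambda_e elastic fiber stretch.
#' @param k1,k2 fiber stiffness parameters (J/kg, dimensionless).
#' @param rho_R reference density (kg/m^3).
#' @param a0 unit fiber direction.
#' @param tension_only zero response in compression (`lambda_e < 1`).
#' @param prefactor `"2k2"` (default) or `"4k2"` energy normalization.
#' @return 3x3 second Piola-Kirchhoff stress contribution in kPa.
#' @export
fiber_pk2_stress <- function(lambda_e, k1, k2, rho_R, a0,
                             tension_only = TRUE, prefactor = "2k2") {
  stopifnot(lambda_e > 0)
  x <- lambda_e^2
  if (x - 1 > 10) stop("fiber stretch out of range: lambda_e^2 - 1 > 10 overflows exp")
  if (tension_only && x < 1) return(matrix(0, 3, 3))
  pref <- fiber_psi_prefactor(prefactor)
  s <- pref * rho_R * KPA * k1 * (x - 1) * exp(k2 * (x - 1)^2)
  s * tcrossprod(a0)
}

#' Active smooth-muscle Cauchy stress
#'
#' Parabolic length-tension law
#' `sigma = sigma_actmax rho_ratio [1 - ((lambda_max - lambda)/(lambda_max -
#' lambda_0))^2]` acting along the smooth-muscle direction, clamped to its
#' physiological range.
#'
#' @param lambda_act_current current active stretch (clamped to
#'   `[lambda_0, lambda_max]`).
#' @param sigma_actmax peak active stress (kPa).
#' @param lambda_0,lambda_max zero- and peak-tension stretches.
#' @param rho_ratio current-to-initial smooth muscle density ratio.
#' @param direction unit vector of the smooth-muscle axis.
#' @return 3x3 Cauchy stress (kPa).
#' @export
active_smc_stress <- function(lambda_act_current, sigma_actmax, lambda_0,
                              lambda_max, rho_ratio = 1,
                              direction = c(0, 1, 0)) {
  stopifnot(lambda_0 < lambda_max)
  lam <- min(max(lambda_act_current, lambda_0), lambda_max)
  val <- sigma_actmax * rho_ratio *
    (1 - ((lambda_max - lam) / (lambda_max - lambda_0))^2)
  val * tcrossprod(direction)
}

# Build the per-point state arrays consumed by the C++ kernels from a frame,
# a list of constituents and their current inelastic state.
# frame: 3x3 matrix, columns e_ax, e_R, e_Theta; fg: growth factor along e_R.
point_state_arrays <- function(frame, constituents, fg = 1, prefactor = "2k2") {
  pref <- fiber_psi_prefactor(prefactor)
  e_ax <- frame[, 1]; e_R <- frame[, 2]; e_th <- frame[, 3]
  rmu <- 0; rkap <- 0
  H6 <- matrix(0, 1, 6); gdet <- 1
  fib <- list(A = NULL, K1 = NULL, K2 = NULL, Lr2 = NULL, Act = NULL,
              Tens = NULL, Rho = NULL, K1s = NULL)
  for (cn in constituents) {
    if (cn$kind == "matrix") {
      lam <- cn$lambda_h  # (axial, radial, circumferential) elastic prestretch
      if (length(lam) == 1) lam <- rep(lam, 3)
      # F_gr = Rf diag(1/lam_ax, fg/lam_R, 1/lam_th) Rf^T ; H = G G^T, G = F_gr^-1
      dg <- c(lam[1], lam[2] / fg, lam[3])
      Rf <- cbind(e_ax, e_R, e_th)
      G <- Rf %*% diag(dg) %*% t(Rf)
      H <- tcrossprod(G)
      H6 <- matrix(c(H[1, 1], H[2, 2], H[3, 3], H[1, 2], H[2, 3], H[1, 3]), 1)
      gdet <- prod(dg)
      rmu <- cn$rho * cn$mu * KPA
      rkap <- cn$rho * cn$kappa * KPA
    } else {
      a0 <- cos(cn$angle) * e_th + sin(cn$angle) * e_ax
      lr <- if (!is.null(cn$lambda_r)) cn$lambda_r else 1 / cn$lambda_h
      act <- 0
      if (cn$kind == "smc" && cn$sigma_actmax > 0) {
        lamc <- min(max(cn$lambda_act, cn$lambda_0), cn$lambda_max)
        act <- cn$sigma_actmax *
          (1 - ((cn$lambda_max - lamc) / (cn$lambda_max - cn$lambda_0))^2)
      }
      fib$A <- cbind(fib$A, matrix(a0, 1))
      fib$K1 <- cbind(fib$K1, pref * cn$rho * cn$k1 * KPA)
      fib$K2 <- cbind(fib$K2, cn$k2)
      fib$Lr2 <- cbind(fib$Lr2, lr^2)
      fib$Act <- cbind(fib$Act, act)
      fib$Tens <- c(fib$Tens, as.integer(isTRUE(cn$tension_only)))
      fib$Rho <- cbind(fib$Rho, cn$rho * KPA)
      fib$K1s <- cbind(fib$K1s, pref * cn$k1)
    }
  }
  if (is.null(fib$A)) {  # no fibers: dummy zero fiber
    fib$A <- matrix(c(1, 0, 0), 1); fib$K1 <- matrix(0, 1, 1)
    fib$K2 <- matrix(1, 1, 1); fib$Lr2 <- matrix(1, 1, 1)
    fib$Act <- matrix(0, 1, 1); fib$Tens <- 0L
    fib$Rho <- matrix(0, 1, 1); fib$K1s <- matrix(0, 1, 1)
  }
  list(H6 = H6, gdet = gdet, rmu = matrix(rmu, 1), rkap = matrix(rkap, 1),
       fib = fib)
}

#' Mixture stress and consistent tangent at a material point
#'
#' Density-weighted sum of all constituent responses, each evaluated in its
#' own natural configuration through the inelastic deformation gradient
#' pull-back.  Returns the second Piola-Kirchhoff stress, the Voigt 6x6
#' material tangent (`C = 2 dS/dC`, order 11, 22, 33, 12, 23, 13) and the
#' Cauchy stress.
#'
#' @param state list with `F` (3x3 deformation gradient), `frame` (3x3 local
#'   frame, columns e_ax, e_R, e_Theta; default identity-frame with axial z)
#'   and optional growth factor `fg` (default 1, no growth).
#' @param constituents list of [constituent()] records.
#' @param prefactor fiber energy prefactor convention, see
#'   [fiber_pk2_stress()].
#' @return list with `S` (kPa), `tangent` (6x6), `cauchy` (kPa), `J`.
#' @export
mixture_stress_and_tangent <- function(state, constituents,
                                       prefactor = "2k2") {
  F <- state$F
  frame <- if (!is.null(state$frame)) state$frame else
    cbind(c(0, 0, 1), c(1, 0, 0), c(0, 1, 0))
  fg <- if (!is.null(state$fg)) state$fg else 1
  arr <- point_state_arrays(frame, constituents, fg, prefactor)
  C <- crossprod(F)
  res <- mixPoint(C, arr$H6, arr$gdet, arr$rmu, arr$rkap, arr$fib$A,
                  arr$fib$K1, arr$fib$K2, arr$fib$Lr2, arr$fib$Act,
                  as.integer(arr$fib$Tens), TRUE)
  J <- det(F)
  list(S = res$S, tangent = res$D, cauchy = F %*% res$S %*% t(F) / J, J = J)
}
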