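# Temporal evolution of the mixture: prescribed elastin degradation (aging
# and localized insult), stress-driven collagen/smooth-muscle mass turnover
# and remodeling of the inelastic deformation, integrated with an explicit
# forward-Euler scheme.

DAYS_PER_YEAR <- 365

#' Elastin insult specification
#'
#' Spatially Gaussian, temporally transient loss of elastin density centred
#' at `P0`, on top of the slow first-order aging decay with lifetime `T_l`.
#'
#' @param D_max peak degradation fraction in `[0, 1]`.
#' @param L_dam spatial width of the insult (mm).
#' @param t_dam temporal constant of the insult (days).
#' @param P0 centre point (length-3).
#' @param v unit axial direction used by the `"axial"` distance mode.
#' @param T_l elastin lifetime (days); default 101 years.
#' @param mode `"axial"` (signed projection on `v`) or `"radial"`
#'   (Euclidean distance to `P0`).
#' @return object of class `hcm_insult`.
#' @export
insult_spec <- function(D_max = 0.5, L_dam = 10, t_dam = 40,
                        P0 = c(0, 0, 0), v = c(0, 0, 1),
                        T_l = 101 * DAYS_PER_YEAR,
                        mode = c("axial", "radial")) {
  mode <- match.arg(mode)
  stopifnot(D_max >= 0, D_max <= 1, L_dam > 0, t_dam > 0, T_l > 0)
  v <- v / sqrt(sum(v^2))
  structure(list(D_max = D_max, L_dam = L_dam, t_dam = t_dam, P0 = P0,
                 v = v, T_l = T_l, mode = mode), class = "hcm_insult")
}

#' Elastin density under aging
#'
#' First-order decay `rho(t) = rho0 exp(-t / T_l)`.
#'
#' @param t time (days, >= 0).
#' @param rho_R0 initial density (kg/m^3).
#' @param T_l elastin lifetime (days).
#' @return density at time t; vectorized over any argument.
#' @export
elastin_density_aging <- function(t, rho_R0, T_l) {
  stopifnot(all(t >= 0))
  rho_R0 * exp(-t / T_l)
}

#' Distance to the insult centre
#'
#' Euclidean distance in `"radial"` mode, signed projection on the axial
#' direction `v` in `"axial"` mode.
#'
#' @param P_x point(s): length-3 vector or n x 3 matrix.
#' @param insult an [insult_spec()].
#' @param mode distance mode; defaults to the insult's own.
#' @return distances in mm.
#' @export
damage_distance <- function(P_x, insult, mode = insult$mode) {
  if (is.null(dim(P_x))) P_x <- matrix(P_x, 1)
  d <- sweep(P_x, 2, insult$P0)
  if (mode == "radial") sqrt(rowSums(d^2)) else as.vector(d %*% insult$v)
}

#' Elastin density under a localized insult
#'
#' Aging decay plus a spatially Gaussian, temporally transient degradation
#' term; reduces to [elastin_density_aging()] far from the insult and
#' removes at most the fraction `D_max` at its centre.
#'
#' @param P_x point(s) at which to evaluate (length-3 or n x 3).
#' @param t time (days).
#' @param rho_R0 initial elastin density.
#' @param insult an [insult_spec()].
#' @return density at time t (vectorized over points).
#' @export
elastin_density_insult <- function(P_x, t, rho_R0, insult) {
  stopifnot(all(t >= 0))
  if (abs(insult$t_dam - insult$T_l) < 1e-9)
    stop("degenerate insult parameters: t_dam equals T_l")
  Xd <- damage_distance(P_x, insult)
  Tl <- insult$T_l; td <- insult$t_dam
  base <- rho_R0 * exp(-t / Tl)
  extra <- rho_R0 * (insult$D_max / td) * exp(-0.5 * (Xd / insult$L_dam)^2) *
    (td * Tl / (td - Tl)) * (exp(-t / Tl) - exp(-t / td))
  pmax(base + extra, 0)
}

#' Stress-driven mass production rate
#'
#' `d rho / dt = rho k_sigma (sigma - sigma_h) / sigma_h`: mass is added
#' above the homeostatic fiber stress and removed below it.
#'
#' @param sigma current fiber-direction stress (any consistent measure).
#' @param sigma_h homeostatic target of the same measure (> 0).
#' @param rho current reference density.
#' @param k_sigma gain in 1/days (typically a fraction of the inverse
#'   turnover time).
#' @return density rate (kg/m^3 per day); vectorized.
#' @export
mass_production_rate <- function(sigma, sigma_h, rho, k_sigma) {
  out <- rho * k_sigma * (sigma - sigma_h) / sigma_h
  out[!is.finite(out)] <- 0
  out
}

# remodeling rate of the inelastic fiber stretch: relaxes the elastic
# stretch toward the deposition stretch at rate (rho_dot/rho + 1/T),
# linearized through the fiber stiffness so that d(sigma)/dt|rem =
# -(rho_dot/rho + 1/T)(sigma - sigma_h)
remodeling_rate <- function(x, lambda_r, s, sigma_h, k1s, k2, J,
                            rho_rate_frac, turnover) {
  E <- exp(pmin(k2 * (x - 1)^2, 700))
  dsdle_le <- 2 * x * k1s * E * ((2 * x - 1) + 2 * k2 * x * (x - 1)^2) / J
  rate <- (rho_rate_frac + 1 / turnover) * (s - sigma_h) / dsdle_le * lambda_r
  rate[!is.finite(rate) | x <= 1 | dsdle_le <= 1e-12] <- 0
  rate
}

#' Advance the growth state by one explicit Euler step
#'
#' Applies density rates (floored at zero), inelastic fiber stretch rates,
#' optionally replaces the elastin density by its closed-form value, and
#' updates the wall-normal growth stretch so that the inelastic volume
#' tracks the net mass change.
#'
#' @param state a `growth_state`.
#' @param dt time step in days (> 0).
#' @param rates list with `rho_dot` (nqp x nconst, zero column for the
#'   matrix), `lambda_r_dot` (nqp x nfiber) and optionally `elastin_rho`
#'   (nqp closed-form elastin densities at `t + dt`).
#' @return updated `growth_state` with `t` advanced by `dt`.
#' @export
update_growth_state <- function(state, dt, rates) {
  stopifnot(dt > 0)
  st <- state
  if (!is.null(rates$rho_dot)) st$rho <- pmax(st$rho + dt * rates$rho_dot, 0)
  if (!is.null(rates$lambda_r_dot)) {
    st$lambda_r <- st$lambda_r + dt * rates$lambda_r_dot
    if (any(st$lambda_r <= 0))
      stop("negative inelastic stretch after update; reduce the time step")
  }
  if (!is.null(rates$elastin_rho)) st$rho[, 1] <- rates$elastin_rho
  st$fg <- rowSums(st$rho) / rowSums(st$rho0)
  st$t <- state$t + dt
  st
}

# average a per-quadrature-point field over each element: the turnover laws
# act on element-homogenized stress measures (the element is the
# homogenization scale of the mixture), which suppresses sub-element
# quadrature noise from feeding back into growth
elem_avg <- function(v) {
  ne <- length(v) / 8L
  rep(colMeans(matrix(v, 8L, ne)), each = 8L)
}

# one full growth-and-remodeling step: rates from the current equilibrium
# fields, Euler update, new equilibrium
gr_step <- function(ctx, st, dt, elastin_rho_at) {
  fl <- qp_state_fields(ctx, st)
  rho_f <- st$rho[, ctx$fib_idx, drop = FALSE]
  kq <- ctx$gain
  rd <- mass_production_rate(fl$fib_s, st$sigma_h, rho_f, kq)
  rd[st$sigma_h <= 0] <- 0
  frac <- ifelse(rho_f > 0, rd / rho_f, 0)
  lrd <- remodeling_rate(fl$fib_x, st$lambda_r, fl$fib_s, st$sigma_h,
                         ctx$k1s, ctx$K2, fl$J, frac, ctx$turn)
  rho_dot <- matrix(0, ctx$nqp, ctx$nconst)
  rho_dot[, ctx$fib_idx] <- rd
  st <- update_growth_state(st, dt, list(
    rho_dot = rho_dot, lambda_r_dot = lrd,
    elastin_rho = elastin_rho_at(st$t + dt)))
  sol <- solve_equilibrium(ctx, st, load_steps = 1)
  st$u <- sol$u
  st
}
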