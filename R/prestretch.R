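# Initial elastin-matrix prestretch: uniform for straight tubes, linearly
# graded from the inner to the outer curvature for toric tubes, with the
# radial component closing the local incompressibility condition.  The
# gradient endpoints are calibrated iteratively against diameter/thickness
# distortions of the computed pressurized state relative to the reference
# geometry.

#' Elastin prestretch field
#'
#' Linear gradients of the axial (toroidal) and circumferential (poloidal)
#' elastin prestretch across the arch diameter, from the inner curvature
#' (IC, arch-plane radius `R_ic`) to the outer curvature (OC, `R_oc`), plus
#' the in-vivo axial stretch.  A uniform field (straight tube) has equal IC
#' and OC endpoints.
#'
#' @param lam_phi_ic,lam_phi_oc axial (toroidal) endpoints.
#' @param lam_theta_ic,lam_theta_oc circumferential (poloidal) endpoints.
#' @param lam_iv in-vivo axial stretch (the axial OC endpoint).
#' @param R_ic,R_oc arch-plane radii of the inner/outer curvature (mm).
#' @return object of class `prestretch_field`.
#' @export
prestretch_field <- function(lam_phi_ic, lam_phi_oc, lam_theta_ic,
                             lam_theta_oc, lam_iv = lam_phi_oc,
                             R_ic = 0, R_oc = 1) {
  stopifnot(lam_phi_ic > 0, lam_phi_oc > 0, lam_theta_ic > 0,
            lam_theta_oc > 0, R_oc > R_ic)
  structure(list(lam_phi_ic = lam_phi_ic, lam_phi_oc = lam_phi_oc,
                 lam_theta_ic = lam_theta_ic, lam_theta_oc = lam_theta_oc,
                 lam_iv = lam_iv, R_ic = R_ic, R_oc = R_oc,
                 d = R_oc - R_ic), class = "prestretch_field")
}

#' @export
print.prestretch_field <- function(x, ...) {
  cat(sprintf(paste0("<prestretch_field> axial IC/OC = %.4g / %.4g, ",
                     "circumferential IC/OC = %.4g / %.4g (lam_iv = %.3g)\n"),
              x$lam_phi_ic, x$lam_phi_oc, x$lam_theta_ic, x$lam_theta_oc,
              x$lam_iv))
  invisible(x)
}

clamp_R <- function(R_pos, field) {
  if (any(R_pos < field$R_ic - 1e-9) || any(R_pos > field$R_oc + 1e-9))
    warning("R_pos outside [R_IC, R_OC]; clamping to the wall range")
  pmin(pmax(R_pos, field$R_ic), field$R_oc)
}

#' Axial (toroidal) prestretch profile
#'
#' Linear interpolation of the elastin axial prestretch between the inner
#' and outer curvature endpoints; positions outside the range are clamped
#' with a warning.
#'
#' @param R_pos arch-plane radial position(s), mm.
#' @param field a [prestretch_field()].
#' @return prestretch value(s).
#' @export
axial_profile <- function(R_pos, field) {
  R_pos <- clamp_R(R_pos, field)
  field$lam_phi_ic + (field$lam_phi_oc - field$lam_phi_ic) *
    (R_pos - field$R_ic) / field$d
}

#' Circumferential (poloidal) prestretch profile
#'
#' @inheritParams axial_profile
#' @return prestretch value(s).
#' @export
circ_profile <- function(R_pos, field) {
  R_pos <- clamp_R(R_pos, field)
  field$lam_theta_ic + (field$lam_theta_oc - field$lam_theta_ic) *
    (R_pos - field$R_ic) / field$d
}

#' Radial prestretch from incompressibility
#'
#' `lam_R = 1 / (lam_phi lam_theta)` so the elastin prestretch tensor is
#' exactly unimodular.
#'
#' @param lam_phi,lam_theta axial and circumferential prestretches.
#' @return radial prestretch.
#' @export
radial_closure <- function(lam_phi, lam_theta) {
  stopifnot(all(lam_phi > 0), all(lam_theta > 0))
  1 / (lam_phi * lam_theta)
}

# evaluate the (axial, radial, circumferential) elastin prestretch triple at
# every quadrature point of a mesh
eval_prestretch_qp <- function(mesh, field) {
  qp <- qp_coords(mesh)
  if (mesh$meta$type == "torus") {
    R_pos <- sqrt(qp[, 1]^2 + qp[, 2]^2)
    R_pos <- pmin(pmax(R_pos, field$R_ic), field$R_oc)  # wall overhang
  } else {
    R_pos <- rep(field$R_ic, nrow(qp))  # uniform field
  }
  la <- field$lam_phi_ic + (field$lam_phi_oc - field$lam_phi_ic) *
    (R_pos - field$R_ic) / field$d
  lt <- field$lam_theta_ic + (field$lam_theta_oc - field$lam_theta_ic) *
    (R_pos - field$R_ic) / field$d
  cbind(la, radial_closure(la, lt), lt)
}

# assign a prestretch field to a solver context
set_prestretch <- function(ctx, field) {
  ctx$prestretch <- field
  ctx$elast_lam <- eval_prestretch_qp(ctx$mesh, field)
  invisible(ctx)
}

# thick-wall force balance of a (layered) ring with uniform prestretch:
# (sigma_theta - sigma_r) ln(ro/ri) integrated per layer must carry the
# pressure, scaled by `p_factor` (1 for a straight tube; the toroidal
# membrane factors (2R -+ a)/(2(R -+ a)) at the outer/inner curvature)
ring_residual <- function(lam_theta, lam_z, layers, pressure,
                          p_factor = 1) {
  tot <- 0
  frame <- cbind(c(0, 0, 1), c(1, 0, 0), c(0, 1, 0))
  for (ly in layers) {
    cons <- ly$constituents
    cons[[1]]$lambda_h <- c(lam_z, radial_closure(lam_z, lam_theta), lam_theta)
    res <- mixture_stress_and_tangent(list(F = diag(3), frame = frame), cons)
    sig <- res$cauchy
    tot <- tot + (sig[2, 2] - sig[1, 1]) * log(ly$r_out / ly$r_in)
  }
  tot - p_factor * pressure
}

# circumferential prestretch endpoints of a torus from the local radial
# equilibrium of the cross-section ring at the in-vivo axial stretch.  At
# the outer curvature the toroidal membrane factor (2R + a)/(2(R + a))
# reduces the hoop-stress demand (dome-like double curvature); at the
# saddle-side inner curvature, where the membrane correction is unreliable
# for a thick wall at this arch ratio, the straight-tube balance is used
# and the distortion iteration remains the authority.
solve_torus_theta_endpoints <- function(meta, materials, pressure, field) {
  sp <- meta$layer_split
  ri <- meta$lumen_diameter / 2; t <- meta$thickness
  R <- meta$arch_radius; a <- ri
  layers <- list(
    list(constituents = materials$media, r_in = ri, r_out = ri + sp * t),
    list(constituents = materials$adventitia, r_in = ri + sp * t,
         r_out = ri + t))
  solve_at <- function(lam_phi, p_factor) {
    f <- function(lt) ring_residual(lt, lam_phi, layers, pressure, p_factor)
    tryCatch(uniroot(f, c(0.5, 3), tol = 1e-10)$root,
             error = function(e) stop(
               "prestretch calibration failed: no equilibrium root in [0.5, 3]"))
  }
  c(ic = solve_at(field$lam_iv, 1),
    oc = solve_at(field$lam_iv, (2 * R + a) / (2 * (R + a))))
}

#' Calibrate the uniform prestretch of a straight tube
#'
#' Fixes the axial elastin prestretch to the in-vivo stretch, closes the
#' radial component by incompressibility and root-solves the
#' circumferential component so that the thick-wall force balance of the
#' pressurized ring holds in the reference geometry.
#'
#' @param geometry list with `radius` (inner, mm), `thickness` (mm) and
#'   optionally `layer_split` when two layers are given.
#' @param materials named list of constituent lists per layer (`single`, or
#'   `media`/`adventitia`).
#' @param pressure luminal pressure (kPa).
#' @param lam_iv in-vivo axial stretch.
#' @return a uniform [prestretch_field()].
#' @export
solve_cylinder_prestretch <- function(geometry, materials, pressure,
                                      lam_iv = 1.3) {
  ri <- geometry$radius; t <- geometry$thickness
  if (!is.null(materials$single)) {
    layers <- list(list(constituents = materials$single, r_in = ri,
                        r_out = ri + t))
  } else {
    sp <- if (!is.null(geometry$layer_split)) geometry$layer_split else 2 / 3
    layers <- list(
      list(constituents = materials$media, r_in = ri, r_out = ri + sp * t),
      list(constituents = materials$adventitia, r_in = ri + sp * t,
           r_out = ri + t))
  }
  f <- function(lt) ring_residual(lt, lam_iv, layers, pressure)
  sol <- tryCatch(uniroot(f, c(0.5, 3), tol = 1e-10),
                  error = function(e) stop(
                    "prestretch calibration failed: no equilibrium root in [0.5, 3]"))
  lt <- sol$root
  prestretch_field(lam_phi_ic = lam_iv, lam_phi_oc = lam_iv,
                   lam_theta_ic = lt, lam_theta_oc = lt, lam_iv = lam_iv)
}

#' Diameter and thickness distortion of a computed equilibrium state
#'
#' Relative change (%) of the lumen diameter and wall thickness measured on
#' the metric line (mid-sweep IC-OC line of a torus, max-diameter
#' cross-section of a cylinder) between the reference geometry and the
#' displaced configuration.
#'
#' @param mesh a `hex_mesh` built by the package generators.
#' @param u displacement vector (3 dof per node).
#' @return list of class `distortion_report`: `delta_d`, `delta_t`
#'   (non-negative, %), their signed counterparts, and the IC/OC luminal
#'   radial offsets (mm, torus only) used by the calibration loop.
#' @export
distortion_metrics <- function(mesh, u) {
  ref <- measure_diameter_thickness(mesh, u = NULL)
  def <- measure_diameter_thickness(mesh, u = u)
  sd_ <- 100 * (def$d - ref$d) / ref$d
  st_ <- 100 * (def$t - ref$t) / ref$t
  out <- list(delta_d = abs(sd_), delta_t = abs(st_),
              signed_d = sd_, signed_t = st_,
              d_ref = ref$d, t_ref = ref$t)
  if (!is.null(def$r_oc)) {
    out$u_oc <- def$r_oc - ref$r_oc    # + outward at the outer curvature
    out$u_ic <- ref$r_ic - def$r_ic    # + outward (toward the axis) at IC
  }
  class(out) <- "distortion_report"
  out
}

#' @export
print.distortion_report <- function(x, ...) {
  cat(sprintf("<distortion_report> delta_d = %.3f%%, delta_t = %.3f%%\n",
              x$delta_d, x$delta_t))
  invisible(x)
}

secant_update <- function(hist, relax = 0.5, lo = 0.5, hi = 2.0,
                          first_scale = 0.005) {
  n <- nrow(hist)
  p1 <- hist$p[n]; r1 <- hist$r[n]
  if (n == 1 || abs(hist$r[n] - hist$r[n - 1]) < 1e-12) {
    step <- -first_scale * r1 * p1
  } else {
    p0 <- hist$p[n - 1]; r0 <- hist$r[n - 1]
    step <- -r1 * (p1 - p0) / (r1 - r0)
  }
  min(max(p1 + relax * step, lo), hi)
}

#' Iterative calibration of the prestretch gradient endpoints
#'
#' Fixed-point loop over forward equilibrium solves: after each solve the
#' axial IC endpoint is updated (secant with under-relaxation) while the
#' thickness distortion exceeds its tolerance, otherwise the
#' circumferential endpoints are updated from the luminal IC/OC radial
#' offsets while the diameter distortion exceeds its tolerance.  The axial
#' OC endpoint stays pinned to the in-vivo stretch.
#'
#' @param ctx solver context for a toric (or quasi-toric) mesh.
#' @param lam_iv in-vivo axial stretch.
#' @param eps_t,eps_d thickness and diameter tolerances in percent.
#' @param init optional initial [prestretch_field()]; by default the axial
#'   IC endpoint starts from the arc-length ratio `lam_iv R_IC / R_OC` and
#'   the circumferential endpoints from the straight-tube calibration of
#'   the cross-section.
#' @param max_iter iteration budget.
#' @return the calibrated [prestretch_field()] with attributes `log`
#'   (iteration data frame) and `report` (final [distortion_metrics()]).
#' @export
calibrate_prestretch_gradients <- function(ctx, lam_iv = 1.3, eps_t = 3,
                                           eps_d = 6, init = NULL,
                                           max_iter = 15) {
  mesh <- ctx$mesh
  if (mesh$meta$type == "cylinder") {
    # gradient degenerates: one straight-tube solve
    geom <- list(radius = mesh$meta$radius, thickness = mesh$meta$thickness)
    mats <- lapply(ctx$materials, identity)
    return(solve_cylinder_prestretch(geom, mats, ctx$bc$pressure, lam_iv))
  }
  meta <- mesh$meta
  if (is.null(init)) {
    init <- prestretch_field(lam_phi_ic = lam_iv * meta$R_IC / meta$R_OC,
                             lam_phi_oc = lam_iv,
                             lam_theta_ic = 1, lam_theta_oc = 1,
                             lam_iv = lam_iv, R_ic = meta$R_IC,
                             R_oc = meta$R_OC)
    ep <- solve_torus_theta_endpoints(meta, ctx$materials, ctx$bc$pressure,
                                      init)
    init$lam_theta_ic <- ep[["ic"]]
    init$lam_theta_oc <- ep[["oc"]]
  }
  field <- init
  log <- data.frame()
  h_phi <- data.frame(p = numeric(0), r = numeric(0))
  h_tic <- data.frame(p = numeric(0), r = numeric(0))
  h_toc <- data.frame(p = numeric(0), r = numeric(0))
  best <- NULL
  for (it in seq_len(max_iter)) {
    set_prestretch(ctx, field)
    st <- init_growth_state(ctx)
    sol <- solve_equilibrium(ctx, st, load_steps = ctx$opts$load_steps)
    rep_ <- distortion_metrics(mesh, sol$u)
    log <- rbind(log, data.frame(
      iter = it, lam_phi_ic = field$lam_phi_ic,
      lam_theta_ic = field$lam_theta_ic, lam_theta_oc = field$lam_theta_oc,
      delta_d = rep_$delta_d, delta_t = rep_$delta_t))
    if (is.null(best) || rep_$delta_d + rep_$delta_t <
        best$rep$delta_d + best$rep$delta_t)
      best <- list(field = field, rep = rep_, u = sol$u)
    if (rep_$delta_t <= eps_t && rep_$delta_d <= eps_d) {
      attr(field, "log") <- log
      attr(field, "report") <- rep_
      attr(field, "u") <- sol$u
      return(field)
    }
    if (rep_$delta_t > eps_t) {
      # thickness criterion: update the axial gradient at the IC
      h_phi <- rbind(h_phi, data.frame(p = field$lam_phi_ic, r = rep_$signed_t))
      field$lam_phi_ic <- secant_update(h_phi)
    } else {
      # diameter criterion: update the circumferential endpoints from the
      # luminal radial offsets at IC and OC
      h_tic <- rbind(h_tic, data.frame(p = field$lam_theta_ic,
                                       r = 100 * rep_$u_ic / rep_$d_ref))
      h_toc <- rbind(h_toc, data.frame(p = field$lam_theta_oc,
                                       r = 100 * rep_$u_oc / rep_$d_ref))
      field$lam_theta_ic <- secant_update(h_tic)
      field$lam_theta_oc <- secant_update(h_toc)
    }
  }
  cond <- structure(class = c("hcmgr_calibration_failure", "error", "condition"),
                    list(message = sprintf(
                      paste0("prestretch calibration did not converge in %d ",
                             "iterations (best delta_d = %.2f%%, delta_t = ",
                             "%.2f%%)"), max_iter, best$rep$delta_d,
                      best$rep$delta_t), call = sys.call(-1),
                      best_field = best$field, log = log))
  stop(cond)
}
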