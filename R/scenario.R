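# Scenario definitions, metrics and the simulation driver: calibrate the
# homeostatic state, apply an elastin insult, run the explicit
# growth-and-remodeling time loop and collect diameter/thickness series and
# stress/collagen fields.

MMHG_KPA <- 0.133322

#' Scenario configuration
#'
#' Full description of a growth-and-remodeling run: geometry (built-in
#' cylinder/torus or an external mesh file), per-layer material tables,
#' pressure, boundary stiffnesses, elastin degradation block, turnover
#' gains, horizon and step, prestretch assignment and output cadence.  The
#' pipeline is deterministic: the same configuration yields identical
#' output.
#'
#' @param name scenario name.
#' @param geometry list: `type` (`"cylinder"`, `"torus"`, `"external"`) plus
#'   dimensions (`radius`, `length`, `thickness`, `quarter`;
#'   `lumen_diameter`, `arch_radius`, `sweep_angle`, `layer_split`;
#'   `path` for external meshes) and `divisions = c(nt, nc, na)`.
#' @param materials named list per layer; each layer a list of constituent
#'   parameter lists (see [constituent()]).
#' @param pressure_mmHg luminal pressure in mmHg.
#' @param boundary list with `k_pro`, `k_dis` (Pa/m), `radial_only`.
#' @param insult list: `mode` (`"none"`, `"aging"`, `"insult"`), and for
#'   insults `D_max`, `L_dam`, `t_dam`, optional `center`, `distance_mode`.
#' @param gain_frac mass-production gain as a fraction of the inverse
#'   turnover time (e.g. 0.05 means k_sigma = 0.05/T).
#' @param horizon_days,dt_days simulated horizon and explicit step (days).
#' @param prestretch list: `mode` = `"as_given"` (elastin triple from the
#'   material table), `"cylinder"` (straight-tube solve), `"endpoints"`
#'   (given gradient endpoints), `"calibrate"` (iterative gradient
#'   calibration); plus `lam_iv`, `eps_t`, `eps_d`, `endpoints`.
#' @param output_every output cadence in days.
#' @param options solver options (`tol`, `load_steps`, `prefactor`).
#' @return object of class `scenario_config`.
#' @export
scenario_config <- function(name, geometry, materials, pressure_mmHg,
                            boundary = list(k_pro = 0, k_dis = 0,
                                            radial_only = TRUE),
                            insult = list(mode = "none"),
                            gain_frac = 0.05, horizon_days = 0,
                            dt_days = 10, prestretch = list(mode = "as_given"),
                            output_every = 50, options = list()) {
  cfg <- list(name = name, geometry = geometry, materials = materials,
              pressure_mmHg = pressure_mmHg, boundary = boundary,
              insult = insult, gain_frac = gain_frac,
              horizon_days = horizon_days, dt_days = dt_days,
              prestretch = prestretch, output_every = output_every,
              options = options)
  class(cfg) <- "scenario_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  req <- function(ok, field, why) if (!ok)
    stop("invalid scenario config field '", field, "': ", why)
  req(is.list(cfg$geometry) && !is.null(cfg$geometry$type), "geometry",
      "must contain a type")
  req(cfg$geometry$type %in% c("cylinder", "torus", "external"),
      "geometry$type", "must be cylinder, torus or external")
  req(is.list(cfg$materials) && length(cfg$materials) >= 1, "materials",
      "need at least one layer table")
  req(is.numeric(cfg$pressure_mmHg), "pressure_mmHg", "must be numeric")
  req(cfg$horizon_days >= 0, "horizon_days", "must be >= 0")
  req(cfg$dt_days > 0, "dt_days", "must be > 0")
  req(cfg$insult$mode %in% c("none", "aging", "insult"), "insult$mode",
      "must be none, aging or insult")
  req(cfg$prestretch$mode %in% c("as_given", "cylinder", "endpoints",
                                 "calibrate"), "prestretch$mode",
      "unknown mode")
  invisible(cfg)
}

#' Read / write a scenario configuration as YAML
#'
#' @param path file path.
#' @return a `scenario_config`.
#' @export
read_scenario_config <- function(path) {
  if (!file.exists(path)) abort_io(paste("file not found:", path),
                                   class = "hcmgr_file_not_found")
  raw <- yaml::read_yaml(path)
  do.call(scenario_config, raw)
}

#' @rdname read_scenario_config
#' @param config a `scenario_config`.
#' @export
write_scenario_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path, precision = 15)
  invisible(path)
}

build_materials <- function(cfg) {
  lapply(cfg$materials, function(tab) {
    lapply(tab, function(par) {
      cn <- do.call(constituent, par)
      if (cn$kind != "matrix" && is.finite(cn$turnover) && cn$turnover > 0 &&
          cn$gain == 0)
        cn$gain <- cfg$gain_frac / cn$turnover
      cn
    })
  })
}

build_geometry <- function(cfg) {
  g <- cfg$geometry
  dv <- g$divisions
  if (g$type == "cylinder") {
    build_cylinder_mesh(g$radius, g$length, g$thickness,
                        n_thick = dv[1], n_circ = dv[2], n_axial = dv[3],
                        quarter = isTRUE(g$quarter))
  } else if (g$type == "torus") {
    build_torus_mesh(g$lumen_diameter, g$arch_radius, g$thickness,
                     sweep_angle = if (is.null(g$sweep_angle)) pi / 2
                                   else g$sweep_angle,
                     n_thick = dv[1], n_circ = dv[2], n_sweep = dv[3],
                     layer_split = if (is.null(g$layer_split)) 2 / 3
                                   else g$layer_split)
  } else {
    m <- read_mesh(g$path)
    compute_local_frames(m, geometry = g$frame_geometry %||% "centerline",
                         centerline = g$centerline)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

default_insult_center <- function(mesh) {
  meta <- mesh$meta
  if (meta$type == "cylinder") {
    list(P0 = c(0, 0, meta$length / 2), v = c(0, 0, 1), mode = "axial")
  } else {
    # mid-sweep, outer-curvature luminal wall; distance measured along the
    # arch direction so the insult is a band around the cross-section
    phi <- meta$sweep_angle / 2
    r <- meta$R_OC
    list(P0 = c(r * cos(phi), r * sin(phi), 0), v = c(-sin(phi), cos(phi), 0),
         mode = "axial")
  }
}

#' Lumen diameter and wall thickness metrics
#'
#' For a torus: lumen diameter along the mid-sweep line joining the inner
#' and outer curvature, wall thickness on the same line (average of the IC
#' and OC wall cuts), and the maximum lumen diameter over all sweep
#' stations.  For a cylinder: twice the maximum luminal radius and the
#' thickness of that cross-section.
#'
#' @param mesh a generated `hex_mesh`.
#' @param u displacement vector or `NULL` for the reference geometry.
#' @return list with `d` (metric-line diameter, mm), `t` (thickness, mm),
#'   `d_max` (max lumen diameter), and torus luminal radii `r_oc`, `r_ic`.
#' @export
measure_diameter_thickness <- function(mesh, u = NULL) {
  g <- mesh$meta$grid
  if (is.null(g)) stop("metric line undefined: mesh lacks grid structure")
  pos <- mesh$nodes
  if (!is.null(u)) pos <- pos + matrix(u, ncol = 3, byrow = TRUE)
  id <- function(k, j, i) grid_id(k, j %% g$ncn, i, g$ntn, g$ncn)
  if (mesh$meta$type == "torus") {
    axr <- function(n) sqrt(pos[n, 1]^2 + pos[n, 2]^2)
    i_mid <- round(g$na / 2)
    j_ic <- g$nc %/% 2L
    r_oc <- axr(id(0L, 0L, i_mid)); r_ic <- axr(id(0L, j_ic, i_mid))
    r_oc_out <- axr(id(g$nt, 0L, i_mid)); r_ic_out <- axr(id(g$nt, j_ic, i_mid))
    d <- r_oc - r_ic
    t <- 0.5 * ((r_oc_out - r_oc) + (r_ic - r_ic_out))
    # maximum lumen diameter: largest chord of the deformed luminal ring at
    # any sweep station (the bulge need not stay on the IC-OC line)
    d_all <- vapply(0:g$na, function(i) {
      ring <- pos[vapply(0:(g$nc - 1L), function(j) id(0L, j, i), 0L), ,
                  drop = FALSE]
      max(stats::dist(ring))
    }, 0)
    list(d = d, t = t, d_max = max(d_all), r_oc = r_oc, r_ic = r_ic)
  } else {
    rad <- function(n) sqrt(pos[n, 1]^2 + pos[n, 2]^2)
    lum <- mesh$node_sets$proximal  # placeholder; use all luminal nodes
    nlum <- as.vector(vapply(0:g$na, function(i)
      vapply(0:(g$ncn - 1L), function(j) id(0L, j, i), 0L), integer(g$ncn)))
    rl <- rad(nlum)
    istar <- (which.max(rl) - 1L) %/% g$ncn  # axial station of max radius
    jrange <- 0:(g$ncn - 1L)
    rin <- mean(rad(vapply(jrange, function(j) id(0L, j, istar), 0L)))
    rout <- mean(rad(vapply(jrange, function(j) id(g$nt, j, istar), 0L)))
    list(d = 2 * max(rl), t = rout - rin, d_max = 2 * max(rl))
  }
}

#' Von Mises equivalent stress
#'
#' `sqrt(3/2 dev(sigma) : dev(sigma))`; accepts a symmetric 3x3 tensor or a
#' matrix of Voigt rows (11, 22, 33, 12, 23, 13).
#'
#' @param sigma stress tensor(s), kPa.
#' @return scalar or vector of equivalent stresses.
#' @export
von_mises <- function(sigma) {
  if (is.matrix(sigma) && ncol(sigma) == 3 && nrow(sigma) == 3) {
    s <- sigma - sum(diag(sigma)) / 3 * diag(3)
    return(sqrt(3 / 2 * sum(s * s)))
  }
  m <- rowMeans(sigma[, 1:3, drop = FALSE])
  d1 <- sigma[, 1] - m; d2 <- sigma[, 2] - m; d3 <- sigma[, 3] - m
  sqrt(3 / 2 * (d1^2 + d2^2 + d3^2 +
                2 * (sigma[, 4]^2 + sigma[, 5]^2 + sigma[, 6]^2)))
}

#' Normalized total collagen density
#'
#' Sum of the collagen-family reference densities divided by their value at
#' the reference time, per quadrature point.
#'
#' @param state a `growth_state`.
#' @return vector of normalized densities.
#' @export
normalized_collagen <- function(state) {
  idx <- which(state$kinds == "collagen")
  if (!length(idx)) stop("no collagen constituents in state")
  den <- rowSums(state$rho0[, idx, drop = FALSE])
  if (any(den <= 0)) stop("zero initial collagen density: field undefined")
  rowSums(state$rho[, idx, drop = FALSE]) / den
}

#' Run a growth-and-remodeling scenario
#'
#' Executes the full pipeline: build geometry and materials, assign or
#' calibrate the elastin prestretch, solve the initial pressurized
#' equilibrium (recording per-point homeostatic fiber stresses), then march
#' the explicit growth-and-remodeling loop over the requested horizon.
#'
#' @param config a [scenario_config()].
#' @param verbose print progress.
#' @return object of class `simulation_result`: `series` (data frame of
#'   time, diameter, thickness, von Mises extrema, normalized collagen
#'   extrema), `state` (final `growth_state`), `mesh`, `ctx`,
#'   `distortion` (initial [distortion_metrics()]), `prestretch` and
#'   `calibration_log`.
#' @export
run_scenario <- function(config, verbose = FALSE) {
  validate_config(config)
  say <- function(...) if (verbose) message(sprintf(...))
  stage <- "geometry"
  out <- tryCatch({
    mesh <- build_geometry(config)
    mats <- build_materials(config)
    bc <- boundary_spec(k_pro = config$boundary$k_pro %||% 0,
                        k_dis = config$boundary$k_dis %||% 0,
                        pressure = config$pressure_mmHg * MMHG_KPA,
                        radial_only = config$boundary$radial_only %||% TRUE)
    ctx <- make_solver_context(mesh, mats, bc, config$options)
    stage <- "prestretch"
    ps <- config$prestretch
    cal_log <- NULL
    field <- NULL
    if (ps$mode == "as_given") {
      lam <- mats[[mesh$layer[1]]][[ctx$mat_idx]]$lambda_h
      if (length(lam) == 1) lam <- rep(lam, 3)
      ctx$elast_lam <- matrix(lam, ctx$nqp, 3, byrow = TRUE)
    } else if (ps$mode == "cylinder") {
      field <- solve_cylinder_prestretch(
        list(radius = mesh$meta$radius, thickness = mesh$meta$thickness),
        mats, bc$pressure, ps$lam_iv %||% 1.3)
      set_prestretch(ctx, field)
    } else if (ps$mode == "endpoints") {
      ep <- ps$endpoints
      field <- prestretch_field(ep[1], ep[2], ep[3], ep[4],
                                lam_iv = ps$lam_iv %||% ep[2],
                                R_ic = mesh$meta$R_IC, R_oc = mesh$meta$R_OC)
      set_prestretch(ctx, field)
    } else {
      field <- calibrate_prestretch_gradients(
        ctx, lam_iv = ps$lam_iv %||% 1.3, eps_t = ps$eps_t %||% 3,
        eps_d = ps$eps_d %||% 6)
      cal_log <- attr(field, "log")
      set_prestretch(ctx, field)
    }
    stage <- "homeostasis"
    st <- init_growth_state(ctx)
    st$kinds <- ctx$kinds
    sol <- solve_equilibrium(ctx, st, load_steps = ctx$opts$load_steps %||% 5)
    st$u <- sol$u
    fl <- qp_state_fields(ctx, st)
    st$sigma_h <- fl$fib_s
    dist0 <- distortion_metrics(mesh, st$u)
    say("homeostatic state: delta_d = %.2f%%, delta_t = %.2f%%",
        dist0$delta_d, dist0$delta_t)
    stage <- "growth-remodeling"
    ins <- config$insult
    elastin_rho_at <- local({
      qp <- qp_coords(mesh)
      rho0_l <- st$rho0[, ctx$mat_idx]
      Tl <- 101 * DAYS_PER_YEAR
      if (ins$mode == "none") function(t) rho0_l
      else if (ins$mode == "aging")
        function(t) elastin_density_aging(t, rho0_l, ins$T_l %||% Tl)
      else {
        ctr <- default_insult_center(mesh)
        spec <- insult_spec(D_max = ins$D_max %||% 0.5,
                            L_dam = ins$L_dam %||% 10,
                            t_dam = ins$t_dam %||% 40,
                            P0 = ins$center %||% ctr$P0,
                            v = ins$v %||% ctr$v,
                            T_l = ins$T_l %||% Tl,
                            mode = ins$distance_mode %||% ctr$mode)
        function(t) elastin_density_insult(qp, t, rho0_l, spec)
      }
    })
    # field extrema are reported from element-averaged quantities (the
    # element is the resolution scale; sub-element quadrature scatter is
    # not a resolved feature of the field)
    ne <- nrow(mesh$elems)
    snap <- function(st) {
      fl <- qp_state_fields(ctx, st)
      cav <- vapply(1:6, function(k) colMeans(matrix(fl$cauchy[, k], 8, ne)),
                    numeric(ne))
      svm <- von_mises(cav)
      rc <- colMeans(matrix(normalized_collagen(st), 8, ne))
      mm <- measure_diameter_thickness(mesh, st$u)
      data.frame(time = st$t, diameter = mm$d_max, thickness = mm$t,
                 svm_min = min(svm), svm_max = max(svm),
                 rhoc_min = min(rc), rhoc_max = max(rc))
    }
    series <- snap(st)
    nsteps <- if (config$horizon_days > 0)
      ceiling(config$horizon_days / config$dt_days) else 0
    every <- max(1L, round(config$output_every / config$dt_days))
    truncated <- FALSE
    if (nsteps > 0) for (k in seq_len(nsteps)) {
      stres <- tryCatch(gr_step(ctx, st, config$dt_days, elastin_rho_at),
                        error = function(e) e)
      if (inherits(stres, "error")) {
        warning(sprintf(
          "growth-remodeling stopped at t = %.0f days: %s",
          st$t, conditionMessage(stres)))
        truncated <- TRUE
        break
      }
      st <- stres
      if (k %% every == 0 || k == nsteps) series <- rbind(series, snap(st))
      if (verbose && k %% 50 == 0)
        say("t = %5.0f d: d = %.2f mm", st$t, series$diameter[nrow(series)])
    }
    res <- list(series = series, state = st, mesh = mesh, ctx = ctx,
                distortion = dist0, prestretch = field,
                calibration_log = cal_log, truncated = truncated,
                config = config)
    class(res) <- "simulation_result"
    res
  }, error = function(e) {
    if (inherits(e, "hcmgr_stage_error")) stop(e)
    stop(structure(class = c("hcmgr_stage_error", "error", "condition"),
                   list(message = sprintf("[stage: %s] %s", stage,
                                          conditionMessage(e)),
                        call = conditionCall(e))))
  })
  out
}

#' @export
print.simulation_result <- function(x, ...) {
  n <- nrow(x$series)
  cat(sprintf("<simulation_result> '%s': %d snapshots over %.0f days%s\n",
              x$config$name, n, x$series$time[n],
              if (isTRUE(x$truncated)) " (truncated)" else ""))
  cat(sprintf("  diameter %.2f -> %.2f mm, thickness %.3f -> %.3f mm\n",
              x$series$diameter[1], x$series$diameter[n],
              x$series$thickness[1], x$series$thickness[n]))
  cat(sprintf("  final von Mises range [%.1f, %.1f] kPa, collagen max %.2f\n",
              x$series$svm_min[n], x$series$svm_max[n], x$series$rhoc_max[n]))
  invisible(x)
}

#' Export simulation fields to VTK
#'
#' Writes the deformed configuration with nodal displacement and
#' element-averaged von Mises stress and normalized collagen density.
#'
#' @param result a `simulation_result`.
#' @param path output `.vtk` path.
#' @export
export_result_vtk <- function(result, path) {
  ctx <- result$ctx; st <- result$state
  fl <- qp_state_fields(ctx, st)
  svm <- von_mises(fl$cauchy)
  rc <- normalized_collagen(st)
  ne <- nrow(result$mesh$elems)
  el_avg <- function(v) colMeans(matrix(v, 8, ne))
  write_fields(path, result$mesh,
               point_data = list(displacement = matrix(st$u, ncol = 3,
                                                       byrow = TRUE)),
               cell_data = list(von_mises = el_avg(svm),
                                collagen_norm = el_avg(rc)))
}
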