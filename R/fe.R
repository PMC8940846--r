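# Quasi-static finite-strain equilibrium of the mixture: total-Lagrangian
# trilinear hexahedra, Newton-Raphson with consistent tangent (including the
# follower-pressure load stiffness), radial-roller + spring (Robin) end
# conditions applied through per-node local frames.

#' Boundary condition specification
#'
#' Radial rollers with linear springs at the tube ends and a follower
#' pressure on the luminal surface.  End nodes are constrained to move in
#' their cross-section plane; with `radial_only = TRUE` (default) only the
#' radial in-plane component is free, resisted by a distributed spring.
#'
#' @param k_pro,k_dis spring stiffness per unit end area at the proximal /
#'   distal end, in Pa/m (as configured; 1 Pa/m = 1e-6 kPa/mm).
#' @param pressure luminal pressure in kPa.
#' @param radial_only restrict in-plane motion of end nodes to the radial
#'   direction.
#' @return object of class `hcm_boundary_spec`.
#' @export
boundary_spec <- function(k_pro = 0, k_dis = 0, pressure = 0,
                          radial_only = TRUE) {
  stopifnot(k_pro >= 0, k_dis >= 0)
  structure(list(k_pro = k_pro, k_dis = k_dis, pressure = pressure,
                 radial_only = radial_only), class = "hcm_boundary_spec")
}

PA_PER_M <- 1e-6  # Pa/m -> kPa/mm

#' Roller/spring end constraints for a mesh
#'
#' Builds the per-node local-frame transformation, the list of fixed
#' transformed degrees of freedom (out-of-plane always; in-plane tangential
#' when `radial_only`), symmetry-plane constraints, and the diagonal spring
#' contributions with tributary end areas.
#'
#' @param mesh a `hex_mesh` with node frames.
#' @param bc an [boundary_spec()] object.
#' @return list with sparse transformation `T`, integer vector `fixed`,
#'   numeric vector `spring_diag` (transformed space).
#' @export
apply_end_conditions <- function(mesh, bc) {
  if (is.null(mesh$node_frames)) stop("mesh has no local frames")
  nn <- nrow(mesh$nodes)
  ndof <- 3L * nn
  prox <- mesh$node_sets$proximal
  dist <- mesh$node_sets$distal
  endn <- union(prox, dist)
  # block-diagonal transformation: identity except local frames at end nodes
  ti <- seq_len(ndof); tj <- seq_len(ndof); tx <- rep(1, ndof)
  for (n in endn) {
    B <- matrix(mesh$node_frames[n, ], 3, 3)  # cols e_ax, e_R, e_th
    rows <- rep(3L * (n - 1L) + 1:3, times = 3)
    cols <- rep(3L * (n - 1L) + 1:3, each = 3)
    keep <- !(ti %in% (3L * (n - 1L) + 1:3))
    ti <- c(ti[keep], rows); tj <- c(tj[keep], cols); tx <- c(tx[keep], as.vector(B))
  }
  T <- Matrix::sparseMatrix(i = ti, j = tj, x = tx, dims = c(ndof, ndof))
  fixed <- integer(0)
  for (n in endn) {
    fixed <- c(fixed, 3L * (n - 1L) + 1L)             # out-of-plane (e_ax)
    if (bc$radial_only) fixed <- c(fixed, 3L * (n - 1L) + 3L)  # e_th
  }
  for (nm in c("sym_y0", "sym_x0")) {
    ns <- mesh$node_sets[[nm]]
    if (is.null(ns)) next
    comp <- if (nm == "sym_y0") 2L else 1L
    ns <- setdiff(ns, endn)  # end-node symmetry is implied by the rollers
    fixed <- c(fixed, 3L * (ns - 1L) + comp)
  }
  fixed <- sort(unique(fixed))
  # distributed springs on the free in-plane components, tributary area
  spring_diag <- numeric(ndof)
  end_area <- function(nodes) {
    r2 <- rowSums(mesh$nodes[nodes, , drop = FALSE]^2)
    # annular cross-section area estimate from node radii spread
    if (!is.null(mesh$meta$radius)) {
      ri <- mesh$meta$radius; ro <- ri + mesh$meta$thickness
      a <- pi * (ro^2 - ri^2)
      if (isTRUE(mesh$meta$quarter)) a <- a / 4
      a
    } else if (!is.null(mesh$meta$lumen_diameter)) {
      ri <- mesh$meta$lumen_diameter / 2; ro <- ri + mesh$meta$thickness
      pi * (ro^2 - ri^2)
    } else length(nodes)  # unit tributary area fallback
  }
  for (side in c("pro", "dis")) {
    nodes <- if (side == "pro") prox else dist
    k <- (if (side == "pro") bc$k_pro else bc$k_dis) * PA_PER_M
    if (k <= 0 || !length(nodes)) next
    atrib <- end_area(nodes) / length(nodes)
    for (n in nodes) {
      spring_diag[3L * (n - 1L) + 2L] <- spring_diag[3L * (n - 1L) + 2L] + k * atrib
      if (!bc$radial_only)
        spring_diag[3L * (n - 1L) + 3L] <- spring_diag[3L * (n - 1L) + 3L] + k * atrib
    }
  }
  list(T = T, fixed = fixed, spring_diag = spring_diag)
}

# Solver context: precomputed quadrature tables, sparsity pattern, boundary
# machinery and per-quadrature-point constant material data.
make_solver_context <- function(mesh, materials, bc,
                                options = list()) {
  opts <- modifyList(list(prefactor = "2k2", tol = 1e-8, max_iter = 30,
                          load_steps = 5, solver = "ldl"), options)
  ne <- nrow(mesh$elems)
  nqp <- ne * 8L
  nn <- nrow(mesh$nodes)
  ndof <- 3L * nn
  layers <- unique(mesh$layer)
  for (l in layers) if (is.null(materials[[l]]))
    stop("no material table for layer: ", l)
  # constituents must come in the same kind order in every layer
  kinds <- lapply(materials[layers], function(cl) vapply(cl, `[[`, "", "kind"))
  if (length(unique(vapply(kinds, paste, "", collapse = ","))) != 1)
    stop("constituent order differs between layers")
  nconst <- length(materials[[layers[1]]])
  fib_idx <- which(kinds[[1]] != "matrix")
  mat_idx <- which(kinds[[1]] == "matrix")
  stopifnot(length(mat_idx) == 1)
  nf <- length(fib_idx)
  qp_layer <- rep(match(mesh$layer, layers), each = 8L)
  pref <- fiber_psi_prefactor(opts$prefactor)

  lay_par <- function(get) matrix(vapply(layers, function(l)
    vapply(materials[[l]], function(cn) {
      v <- get(cn); if (is.null(v)) 0 else v
    }, 0), numeric(nconst)), nrow = nconst)
  # per-layer matrices nconst x nlayer
  P_rho <- lay_par(function(cn) cn$rho)
  P_k1 <- lay_par(function(cn) cn$k1)
  P_k2 <- lay_par(function(cn) cn$k2)
  P_mu <- lay_par(function(cn) cn$mu)
  P_kap <- lay_par(function(cn) cn$kappa)
  P_ang <- lay_par(function(cn) cn$angle)
  P_lh <- lay_par(function(cn) cn$lambda_h[1])
  P_gain <- lay_par(function(cn) cn$gain)
  P_turn <- lay_par(function(cn) cn$turnover)
  P_act <- lay_par(function(cn) {
    if (cn$kind != "smc" || cn$sigma_actmax <= 0) return(0)
    lamc <- min(max(cn$lambda_act, cn$lambda_0), cn$lambda_max)
    cn$sigma_actmax * (1 - ((cn$lambda_max - lamc) /
                            (cn$lambda_max - cn$lambda_0))^2)
  })
  tens <- vapply(materials[[layers[1]]][fib_idx],
                 function(cn) isTRUE(cn$tension_only), TRUE)

  fr <- mesh$qp_frames
  e_ax <- fr[, 1:3]; e_R <- fr[, 4:6]; e_th <- fr[, 7:9]
  fibA <- matrix(0, nqp, 3 * nf)
  for (f in seq_len(nf)) {
    ang <- P_ang[fib_idx[f], qp_layer]
    fibA[, 3 * f - 2] <- cos(ang) * e_th[, 1] + sin(ang) * e_ax[, 1]
    fibA[, 3 * f - 1] <- cos(ang) * e_th[, 2] + sin(ang) * e_ax[, 2]
    fibA[, 3 * f]     <- cos(ang) * e_th[, 3] + sin(ang) * e_ax[, 3]
  }
  qp_of <- function(P, idx) t(P[idx, qp_layer, drop = FALSE])
  # sparsity pattern from element + facet dof pairs
  facets0 <- mesh$facet_sets$lumen
  edofs <- t(apply(mesh$elems, 1, function(nd) as.vector(t(cbind(
    3L * (nd - 1L) + 1L, 3L * (nd - 1L) + 2L, 3L * (nd - 1L) + 3L)))))
  ii <- as.vector(apply(edofs, 1, function(d) rep(d, each = 24)))
  jj <- as.vector(apply(edofs, 1, function(d) rep(d, times = 24)))
  if (!is.null(facets0) && nrow(facets0)) {
    fdofs <- t(apply(facets0, 1, function(nd) as.vector(t(cbind(
      3L * (nd - 1L) + 1L, 3L * (nd - 1L) + 2L, 3L * (nd - 1L) + 3L)))))
    fi <- as.vector(apply(fdofs, 1, function(d) rep(d, each = 12)))
    fj <- as.vector(apply(fdofs, 1, function(d) rep(d, times = 12)))
  } else { fi <- integer(0); fj <- integer(0) }
  K0 <- Matrix::sparseMatrix(i = c(ii, fi), j = c(jj, fj),
                             x = 0, dims = c(ndof, ndof))
  xmapE <- cscIndex(K0@p, K0@i, ii - 1L, jj - 1L)
  xmapF <- if (length(fi)) cscIndex(K0@p, K0@i, fi - 1L, fj - 1L) else integer(0)
  cons <- apply_end_conditions(mesh, bc)
  free <- setdiff(seq_len(ndof), cons$fixed)

  ctx <- new.env(parent = emptyenv())
  ctx$mesh <- mesh; ctx$bc <- bc; ctx$opts <- opts
  ctx$nqp <- nqp; ctx$nn <- nn; ctx$ndof <- ndof
  ctx$layers <- layers; ctx$materials <- materials
  ctx$qp_layer <- qp_layer; ctx$fib_idx <- fib_idx; ctx$mat_idx <- mat_idx
  ctx$nf <- nf; ctx$nconst <- nconst; ctx$kinds <- kinds[[1]]
  ctx$rho0_tab <- qp_of(P_rho, seq_len(nconst))         # nqp x nconst
  ctx$k1s <- pref * qp_of(P_k1, fib_idx)                # specific, J/kg
  ctx$K2 <- qp_of(P_k2, fib_idx)
  ctx$mu_l <- qp_of(P_mu, mat_idx)[, 1]
  ctx$kap_l <- qp_of(P_kap, mat_idx)[, 1]
  ctx$act_max <- qp_of(P_act, fib_idx)                  # kPa at rho ratio 1
  ctx$lam_h_fib <- qp_of(P_lh, fib_idx)
  ctx$gain <- qp_of(P_gain, fib_idx)
  ctx$turn <- qp_of(P_turn, fib_idx)
  ctx$tens <- as.integer(tens)
  ctx$fibA <- fibA
  ctx$e_R <- e_R
  ctx$elast_lam <- matrix(1, nqp, 3)  # (axial, radial, circumferential)
  ctx$facets0 <- if (!is.null(facets0)) facets0 - 1L else matrix(0L, 0, 4)
  ctx$K0 <- K0; ctx$xmapE <- xmapE; ctx$xmapF <- xmapF
  ctx$Tmat <- cons$T; ctx$fixed <- cons$fixed; ctx$free <- free
  ctx$spring_diag <- cons$spring_diag
  ctx$elems0 <- mesh$elems - 1L
  ctx
}

# initial growth state at t0 (homeostatic targets recorded after the first
# equilibrium solve)
init_growth_state <- function(ctx) {
  st <- list(t = 0,
             rho = ctx$rho0_tab,
             rho0 = ctx$rho0_tab,
             lambda_r = 1 / ctx$lam_h_fib,
             sigma_h = NULL,
             fg = rep(1, ctx$nqp),
             u = numeric(ctx$ndof))
  class(st) <- "growth_state"
  st
}

# per-qp arrays consumed by the C++ kernels; ramp in (0, 1] scales the
# prestretches geodesically and the active tone linearly
build_arrays <- function(ctx, st, ramp = 1) {
  nqp <- ctx$nqp
  lam <- ctx$elast_lam
  if (ramp != 1) lam <- lam^ramp
  fg <- st$fg
  d1 <- lam[, 1]; d2 <- lam[, 2] / fg; d3 <- lam[, 3]
  fr <- ctx$mesh$qp_frames
  H6 <- matrix(0, nqp, 6)
  # H = d1^2 ax(x)ax + d2^2 R(x)R + d3^2 th(x)th
  cmb <- function(i, j)
    d1^2 * fr[, i] * fr[, j] + d2^2 * fr[, 3 + i] * fr[, 3 + j] +
      d3^2 * fr[, 6 + i] * fr[, 6 + j]
  H6[, 1] <- cmb(1, 1); H6[, 2] <- cmb(2, 2); H6[, 3] <- cmb(3, 3)
  H6[, 4] <- cmb(1, 2); H6[, 5] <- cmb(2, 3); H6[, 6] <- cmb(1, 3)
  gdet <- d1 * d2 * d3
  rho_l <- st$rho[, ctx$mat_idx]
  lr <- st$lambda_r
  if (ramp != 1) lr <- lr^ramp
  rho_f <- st$rho[, ctx$fib_idx, drop = FALSE]
  rho_f0 <- st$rho0[, ctx$fib_idx, drop = FALSE]
  ratio <- ifelse(rho_f0 > 0, rho_f / rho_f0, 0)
  list(H6 = H6, gdet = gdet,
       rmu = rho_l * ctx$mu_l * KPA,
       rkap = rho_l * ctx$kap_l * KPA,
       fibA = ctx$fibA,
       fibK1 = ctx$k1s * rho_f * KPA,
       fibK2 = ctx$K2,
       fibLr2 = lr^2,
       fibAct = ctx$act_max * ratio * ramp,
       fibTens = ctx$tens,
       fibRho = rho_f * KPA,
       fibK1spec = ctx$k1s)
}

assemble_full <- function(ctx, u, arr, pressure, wantK = TRUE) {
  feAssemble(ctx$mesh$nodes, ctx$elems0, ctx$mesh$pre$dNdX,
             ctx$mesh$pre$detJw, ctx$mesh$pre$dNdX0, ctx$mesh$pre$detJ0,
             u, arr$H6, arr$gdet, arr$rmu, arr$rkap, arr$fibA, arr$fibK1,
             arr$fibK2, arr$fibLr2, arr$fibAct, arr$fibTens, ctx$facets0,
             pressure, ctx$xmapE, ctx$xmapF, length(ctx$K0@x), wantK)
}

#' Assemble internal forces and stiffness
#'
#' Discrete divergence of the total mixture stress and the consistent
#' tangent, without external loads.
#'
#' @param ctx solver context from `make_solver_context`.
#' @param state growth state.
#' @param u displacement vector (3 dof per node).
#' @return list with `residual` (internal force vector) and sparse `K`.
#' @export
assemble_internal <- function(ctx, state, u = state$u) {
  arr <- build_arrays(ctx, state)
  res <- assemble_full(ctx, u, arr, pressure = 0, wantK = TRUE)
  K <- ctx$K0; K@x <- res$xvals
  list(residual = res$fint, K = K)
}

#' Assemble the follower pressure load
#'
#' Pressure acting normal to the deformed luminal surface, with its load
#' stiffness.
#'
#' @param ctx solver context.
#' @param u displacement vector.
#' @param pressure luminal pressure (kPa).
#' @return list with `f_ext` and sparse load stiffness `K_load` (to be
#'   subtracted from the tangent).
#' @export
assemble_pressure <- function(ctx, u, pressure) {
  arr <- build_arrays(ctx, init_growth_state(ctx))
  z <- matrix(0, ctx$nqp, ctx$nf)
  arr$rmu <- arr$rmu * 0; arr$rkap <- arr$rkap * 0
  arr$fibK1 <- z; arr$fibAct <- z
  res <- assemble_full(ctx, u, arr, pressure, wantK = TRUE)
  K <- ctx$K0; K@x <- -res$xvals
  list(f_ext = res$fext, K_load = K)
}

newton_solve <- function(ctx, st, u, pressure, ramp = 1, tol = ctx$opts$tol,
                         max_iter = ctx$opts$max_iter) {
  arr <- build_arrays(ctx, st, ramp)
  Tm <- ctx$Tmat; free <- ctx$free; sd <- ctx$spring_diag
  resid_t <- function(u, wantK) {
    out <- assemble_full(ctx, u, arr, pressure * ramp, wantK)
    ut <- as.vector(Matrix::crossprod(Tm, u))
    rt <- as.vector(Matrix::crossprod(Tm, out$fint - out$fext)) + sd * ut
    list(rt = rt, out = out)
  }
  rr <- resid_t(u, FALSE)
  fref <- max(sqrt(sum(rr$out$fext^2)), 1e-6)
  rn <- sqrt(sum(rr$rt[free]^2))
  hist <- rn
  it <- 0L
  while (rn > tol * fref && it < max_iter) {
    it <- it + 1L
    out <- assemble_full(ctx, u, arr, pressure * ramp, TRUE)
    K <- ctx$K0; K@x <- out$xvals
    Kt <- Matrix::crossprod(Tm, K %*% Tm)
    Matrix::diag(Kt) <- Matrix::diag(Kt) + sd
    ut <- as.vector(Matrix::crossprod(Tm, u))
    rt <- as.vector(Matrix::crossprod(Tm, out$fint - out$fext)) + sd * ut
    Kff <- Kt[free, free, drop = FALSE]
    # the tangent is symmetric up to the small follower-load and active-tone
    # terms; by default a symmetrized solve (sparse LDL') is used, which
    # trades textbook-quadratic for fast linear contraction (~ the relative
    # size of the skipped terms).  solver = "lu" requests the exact
    # unsymmetric factorization of the full consistent tangent.
    du <- if (identical(ctx$opts$solver, "lu")) {
      Matrix::solve(Kff, -rt[free])
    } else tryCatch({
      Ks <- methods::as(Matrix::forceSymmetric((Kff + Matrix::t(Kff)) / 2),
                        "CsparseMatrix")
      Matrix::solve(Ks, -rt[free])
    }, error = function(e) Matrix::solve(Kff, -rt[free]))
    ut[free] <- ut[free] + as.vector(du)
    u <- as.vector(Tm %*% ut)
    rr <- resid_t(u, FALSE)
    rn_new <- sqrt(sum(rr$rt[free]^2))
    if (!is.finite(rn_new) || rn_new > 1e6 * (fref + hist[1]))
      stop("Newton divergence")
    rn <- rn_new
    hist <- c(hist, rn)
  }
  list(u = u, converged = rn <= tol * fref, iterations = it,
       residuals = hist, fref = fref)
}

#' Solve quasi-static equilibrium
#'
#' Newton-Raphson with incremental activation of prestretch and pressure
#' (`load_steps` increments from the given starting fraction) and automatic
#' step cutback on divergence.
#'
#' @param ctx solver context.
#' @param state growth state (provides densities, inelastic stretches and
#'   the starting displacement `state$u`).
#' @param pressure luminal pressure (kPa); defaults to the context boundary
#'   spec.
#' @param load_steps number of activation increments (1 = direct solve).
#' @param tol relative residual tolerance.
#' @param max_cutbacks halvings of the activation increment allowed.
#' @return list with displacement `u` and a `report` (converged flag,
#'   Newton iterations and residual history per load step).
#' @export
solve_equilibrium <- function(ctx, state, pressure = ctx$bc$pressure,
                              load_steps = 1, tol = ctx$opts$tol,
                              max_cutbacks = 4) {
  u <- state$u
  report <- list(converged = FALSE, steps = list())
  s_done <- 0
  ds <- 1 / load_steps
  cut <- 0L
  while (s_done < 1 - 1e-12) {
    s_try <- min(1, s_done + ds)
    ok <- tryCatch({
      sol <- newton_solve(ctx, state, u, pressure, ramp = s_try, tol = tol)
      if (!sol$converged) stop("no convergence")
      TRUE
    }, error = function(e) FALSE)
    if (ok) {
      u <- sol$u
      s_done <- s_try
      report$steps[[length(report$steps) + 1L]] <-
        list(ramp = s_try, iterations = sol$iterations,
             residuals = sol$residuals)
      if (cut > 0 && sol$iterations <= 4) { ds <- min(ds * 2, 1 - s_done + 1e-12); cut <- cut - 1L }
    } else {
      cut <- cut + 1L
      if (cut > max_cutbacks)
        stop("equilibrium solve failed after ", cut - 1L,
             " cutbacks at activation ", signif(s_done, 4))
      ds <- ds / 2
    }
  }
  report$converged <- TRUE
  report$iterations <- sum(vapply(report$steps, `[[`, 0L, "iterations"))
  list(u = u, report = report)
}

# per-qp kinematics and stresses at the current displacement
qp_state_fields <- function(ctx, st, u = st$u) {
  arr <- build_arrays(ctx, st)
  qpFields(ctx$mesh$nodes, ctx$elems0, ctx$mesh$pre$dNdX,
           ctx$mesh$pre$dNdX0, u, arr$H6,
           arr$gdet, arr$rmu, arr$rkap, arr$fibA, arr$fibK1, arr$fibK2,
           arr$fibLr2, arr$fibAct, arr$fibTens, arr$fibRho, arr$fibK1spec)
}
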