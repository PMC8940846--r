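#' @useDynLib hcmgr, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats uniroot
#' @importFrom utils read.table write.csv
NULL

abort_geom <- function(msg) {
  stop(structure(class = c("hcmgr_invalid_geometry", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' Hexahedral mesh constructor (internal)
#'
#' Assembles the `hex_mesh` S3 structure shared by all generators and
#' readers: node coordinates in mm, 8-node hexahedral connectivity in the
#' VTK cell-type-12 node ordering, per-element layer labels, node and facet
#' sets, and (once [compute_local_frames()] has run) per-quadrature-point
#' local material frames.
#'
#' @keywords internal
new_hex_mesh <- function(nodes, elems, layer, node_sets, facet_sets, meta) {
  m <- list(nodes = nodes, elems = elems, layer = layer,
            node_sets = node_sets, facet_sets = facet_sets,
            meta = meta, qp_frames = NULL, node_frames = NULL, pre = NULL)
  class(m) <- "hex_mesh"
  m$pre <- hexPrecompute(m$nodes, m$elems - 1L)
  m
}

#' @export
print.hex_mesh <- function(x, ...) {
  cat(sprintf("<hex_mesh> %s: %d nodes, %d hexahedra\n",
              x$meta$type, nrow(x$nodes), nrow(x$elems)))
  cat(sprintf("  layers: %s\n", paste(unique(x$layer), collapse = ", ")))
  cat(sprintf("  node sets: %s\n", paste(names(x$node_sets), collapse = ", ")))
  cat(sprintf("  facet sets: %s\n", paste(names(x$facet_sets), collapse = ", ")))
  invisible(x)
}

# structured-grid helper: node id from (thick k, circ j, axial i) indices
grid_id <- function(k, j, i, ntn, ncn) ((i) * ncn + (j)) * ntn + k + 1L

# VTK hex8 faces as local node indices (1-based), ordered so that the facet
# normal (x_xi x x_eta) points along the local +radial direction for the
# radial faces and +axial for the end faces.
face_rad_min <- c(1L, 4L, 8L, 5L)  # normal +xi (outward through wall)
face_rad_max <- c(2L, 3L, 7L, 6L)
face_ax_min  <- c(1L, 2L, 3L, 4L)
face_ax_max  <- c(5L, 6L, 7L, 8L)

build_structured_tube <- function(radial_breaks, circ_angles, circ_periodic,
                                  axial_param, point_fun, layer_of_k, meta) {
  nt <- length(radial_breaks) - 1L
  nc <- length(circ_angles) - ifelse(circ_periodic, 0L, 1L)
  na <- length(axial_param) - 1L
  ntn <- nt + 1L
  ncn <- if (circ_periodic) nc else nc + 1L
  nan <- na + 1L
  nnode <- ntn * ncn * nan
  nodes <- matrix(0, nnode, 3)
  for (i in 0:na) for (j in 0:(ncn - 1L)) for (k in 0:nt) {
    id <- grid_id(k, j, i, ntn, ncn)
    nodes[id, ] <- point_fun(radial_breaks[k + 1L], circ_angles[j + 1L],
                             axial_param[i + 1L])
  }
  ne <- nt * nc * na
  elems <- matrix(0L, ne, 8)
  layer <- character(ne)
  e <- 0L
  jn <- function(j) if (circ_periodic) j %% nc else j
  for (i in 0:(na - 1L)) for (j in 0:(nc - 1L)) for (k in 0:(nt - 1L)) {
    e <- e + 1L
    j1 <- jn(j + 1L)
    elems[e, ] <- c(grid_id(k, j, i, ntn, ncn),
                    grid_id(k + 1L, j, i, ntn, ncn),
                    grid_id(k + 1L, j1, i, ntn, ncn),
                    grid_id(k, j1, i, ntn, ncn),
                    grid_id(k, j, i + 1L, ntn, ncn),
                    grid_id(k + 1L, j, i + 1L, ntn, ncn),
                    grid_id(k + 1L, j1, i + 1L, ntn, ncn),
                    grid_id(k, j1, i + 1L, ntn, ncn))
    layer[e] <- layer_of_k(k)
  }
  # node sets
  all_kji <- function(k) {
    ids <- integer(0)
    for (i in 0:na) for (j in 0:(ncn - 1L)) ids <- c(ids, grid_id(k, j, i, ntn, ncn))
    ids
  }
  prox <- sort(unique(c(outer(0:nt, 0:(ncn - 1L),
                 function(k, j) grid_id(k, j, 0L, ntn, ncn)))))
  dist <- sort(unique(c(outer(0:nt, 0:(ncn - 1L),
                 function(k, j) grid_id(k, j, na, ntn, ncn)))))
  node_sets <- list(proximal = prox, distal = dist)
  # facet sets: element index of innermost/outermost radial layer
  lum <- matrix(0L, nc * na, 4); out <- matrix(0L, nc * na, 4)
  fidx <- 0L
  e <- 0L
  for (i in 0:(na - 1L)) for (j in 0:(nc - 1L)) for (k in 0:(nt - 1L)) {
    e <- e + 1L
    if (k == 0L) { fidx <- fidx + 1L
      lum[fidx, ] <- elems[e, face_rad_min] }
    if (k == nt - 1L) out[fidx, ] <- elems[e, face_rad_max]
  }
  facet_sets <- list(lumen = lum, outer = out)
  meta$grid <- list(nt = nt, nc = nc, na = na, ntn = ntn, ncn = ncn,
                    periodic = circ_periodic)
  new_hex_mesh(nodes, elems, layer, node_sets, facet_sets, meta)
}

#' Build a hexahedral cylinder mesh
#'
#' Generates a structured trilinear-hex mesh of a straight tube with inner
#' radius `radius`, wall thickness `thickness` and length `length` along the
#' z axis.  With `quarter = TRUE` only the quadrant between the x and y
#' symmetry planes is meshed and the two symmetry node sets are tagged.
#'
#' @param radius inner (luminal) radius in mm.
#' @param length tube length in mm.
#' @param thickness wall thickness in mm.
#' @param n_thick,n_circ,n_axial element divisions through the thickness,
#'   around the circumference and along the axis.
#' @param quarter mesh a quarter cylinder (90 degrees) instead of the full
#'   circumference.
#' @return a `hex_mesh` with node sets `proximal`, `distal` (tube ends) and,
#'   for quarter meshes, `sym_y0`, `sym_x0`; facet sets `lumen` and `outer`.
#' @export
build_cylinder_mesh <- function(radius, length, thickness, n_thick = 2L,
                                n_circ = 15L, n_axial = 60L, quarter = TRUE) {
  if (radius <= 0 || length <= 0 || thickness <= 0)
    abort_geom("cylinder dimensions must be positive")
  if (n_thick < 1 || n_circ < 1 || n_axial < 1)
    abort_geom("element counts must be >= 1")
  theta_max <- if (quarter) pi / 2 else 2 * pi
  circ_angles <- seq(0, theta_max, length.out = n_circ + 1L)
  if (!quarter) circ_angles <- circ_angles[-(n_circ + 1L)]
  rb <- seq(radius, radius + thickness, length.out = n_thick + 1L)
  zz <- seq(0, length, length.out = n_axial + 1L)
  meta <- list(type = "cylinder", radius = radius, length = length,
               thickness = thickness, quarter = quarter)
  m <- build_structured_tube(rb, circ_angles, circ_periodic = !quarter,
                             axial_param = zz,
                             point_fun = function(r, th, z)
                               c(r * cos(th), r * sin(th), z),
                             layer_of_k = function(k) "single", meta)
  if (quarter) {
    tol <- 1e-9 * radius
    m$node_sets$sym_y0 <- which(abs(m$nodes[, 2]) < tol)
    m$node_sets$sym_x0 <- which(abs(m$nodes[, 1]) < tol)
  }
  compute_local_frames(m, "cylinder")
}

#' Build a hexahedral torus-slice mesh
#'
#' Generates a structured mesh of a torus slice (an idealized aortic arch):
#' centerline circle of radius `arch_radius` in the x-y plane, circular
#' cross-section of luminal diameter `lumen_diameter` and wall thickness
#' `thickness`, swept over the toroidal angle `sweep_angle` starting from
#' the positive x axis.  The poloidal angle is measured from the
#' outer-curvature equator.  Elements within `layer_split` of the thickness
#' (from the lumen) are labelled `media`, the remainder `adventitia`; a mesh
#' line is placed exactly at the interface.
#'
#' @param lumen_diameter luminal diameter d in mm.
#' @param arch_radius centerline (arch) radius R in mm.
#' @param thickness wall thickness in mm.
#' @param sweep_angle toroidal extent in radians.
#' @param n_thick,n_circ,n_sweep element divisions (thickness, poloidal,
#'   toroidal).  `n_circ` is the full poloidal circle count.
#' @param layer_split fraction of the wall thickness belonging to the media.
#' @return a `hex_mesh` with layers `media`/`adventitia`, node sets
#'   `proximal` (toroidal angle 0) and `distal`, facet sets `lumen`, `outer`.
#' @export
build_torus_mesh <- function(lumen_diameter, arch_radius, thickness,
                             sweep_angle = pi / 2, n_thick = 2L, n_circ = 16L,
                             n_sweep = 12L, layer_split = 1 / 2) {
  d <- lumen_diameter
  if (d <= 0 || arch_radius <= 0 || thickness <= 0)
    abort_geom("torus dimensions must be positive")
  if (sweep_angle <= 1e-8) abort_geom("degenerate sweep angle")
  if (arch_radius <= d / 2 + thickness)
    abort_geom("self-intersecting torus: arch_radius must exceed lumen radius + thickness")
  if (n_thick < 1 || n_circ < 3 || n_sweep < 1)
    abort_geom("element counts too small")
  # radial breaks with a line exactly at the media/adventitia interface
  if (n_thick >= 2) {
    n_med <- max(1L, min(n_thick - 1L, round(n_thick * layer_split)))
    n_adv <- n_thick - n_med
    rb <- c(seq(0, layer_split * thickness, length.out = n_med + 1L),
            seq(layer_split * thickness, thickness,
                length.out = n_adv + 1L)[-1]) + d / 2
  } else rb <- d / 2 + c(0, thickness)
  # poloidal angle traversed negatively so element jacobians are positive
  th <- -(0:(n_circ - 1L)) * 2 * pi / n_circ
  ph <- seq(0, sweep_angle, length.out = n_sweep + 1L)
  R <- arch_radius
  meta <- list(type = "torus", lumen_diameter = d, arch_radius = R,
               thickness = thickness, sweep_angle = sweep_angle,
               layer_split = layer_split, R_IC = R - d / 2, R_OC = R + d / 2)
  split_r <- d / 2 + layer_split * thickness
  rbm <- 0.5 * (rb[-length(rb)] + rb[-1])
  m <- build_structured_tube(rb, th, circ_periodic = TRUE, axial_param = ph,
    point_fun = function(rho, thv, phv)
      c((R + rho * cos(thv)) * cos(phv), (R + rho * cos(thv)) * sin(phv),
        rho * sin(thv)),
    layer_of_k = function(k) if (rbm[k + 1L] <= split_r + 1e-12) "media" else "adventitia",
    meta)
  compute_local_frames(m, "torus")
}

#' Attach local material frames to a mesh
#'
#' Computes the orthonormal right-handed triad (e_ax, e_R, e_Theta) at every
#' quadrature point and every node: e_ax is tangent to the tube axis
#' (toroidal direction for a torus), e_R points radially outward from the
#' centerline and e_Theta = e_ax x e_R is circumferential.
#'
#' @param mesh a `hex_mesh`.
#' @param geometry one of `"cylinder"`, `"torus"`, `"centerline"`.
#' @param centerline for `"centerline"`, a matrix of polyline points (n x 3).
#' @return the mesh with `qp_frames` (nqp x 9) and `node_frames` (n x 9)
#'   filled; columns are e_ax, e_R, e_Theta.
#' @export
compute_local_frames <- function(mesh, geometry = mesh$meta$type,
                                 centerline = NULL) {
  geometry <- match.arg(geometry, c("cylinder", "torus", "centerline"))
  frame_at <- function(P) {
    if (geometry == "cylinder") {
      r <- sqrt(P[1]^2 + P[2]^2)
      if (r < 1e-12) abort_geom("point on the centerline: radial direction undefined")
      eax <- c(0, 0, 1)
      eR <- c(P[1] / r, P[2] / r, 0)
    } else if (geometry == "torus") {
      phi <- atan2(P[2], P[1])
      eax <- c(-sin(phi), cos(phi), 0)
      cen <- mesh$meta$arch_radius * c(cos(phi), sin(phi), 0)
      v <- P - cen
      nv <- sqrt(sum(v^2))
      if (nv < 1e-12) abort_geom("point on the centerline: radial direction undefined")
      eR <- v / nv
    } else {
      cl <- centerline
      if (is.null(cl) || nrow(cl) < 2)
        abort_geom("centerline mode requires a polyline with >= 2 points")
      # nearest segment projection
      best <- NULL; bd <- Inf
      for (s in 1:(nrow(cl) - 1)) {
        a <- cl[s, ]; b <- cl[s + 1, ]
        ab <- b - a; t <- sum((P - a) * ab) / sum(ab^2)
        t <- min(max(t, 0), 1)
        q <- a + t * ab
        dd <- sum((P - q)^2)
        if (dd < bd) { bd <- dd; best <- list(q = q, tangent = ab / sqrt(sum(ab^2))) }
      }
      if (sqrt(bd) < 1e-12)
        abort_geom("point on the centerline: radial direction undefined")
      eax <- best$tangent
      v <- P - best$q
      v <- v - sum(v * eax) * eax
      eR <- v / sqrt(sum(v^2))
    }
    eth <- c(eax[2] * eR[3] - eax[3] * eR[2],
             eax[3] * eR[1] - eax[1] * eR[3],
             eax[1] * eR[2] - eax[2] * eR[1])
    c(eax, eR, eth)
  }
  qp <- mesh$pre$qp_coords
  mesh$qp_frames <- t(apply(qp, 1, frame_at))
  mesh$node_frames <- t(apply(mesh$nodes, 1, frame_at))
  mesh
}

#' Quadrature volume of a mesh
#'
#' Sum of Gauss-point weighted reference Jacobians over all elements.
#'
#' @param mesh a `hex_mesh`.
#' @return volume in mm^3.
#' @export
mesh_volume <- function(mesh) sum(mesh$pre$detJw)

# quadrature-point coordinates (nqp x 3)
qp_coords <- function(mesh) mesh$pre$qp_coords
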