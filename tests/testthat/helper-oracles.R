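# Shared fixtures and independent oracles: per-unit-mass strain energies
# written directly from their definitions (used to finite-difference stress
# and tangent), small meshes, and a box mesh for patch tests.

KPA_ <- 1e-3
VI6 <- c(1, 2, 3, 1, 2, 1)
VJ6 <- c(1, 2, 3, 2, 3, 3)

rand_rotation <- function() {
  Q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(Q) < 0) Q[, 3] <- -Q[, 3]
  Q
}

# mixture energy per unit reference volume (kPa), written independently of
# the package kernels: neo-Hookean volumetric/isochoric matrix plus
# Fung-exponential fibers (2k2 normalization)
oracle_energy <- function(C, frame, cons, fg = 1) {
  W <- 0
  e_ax <- frame[, 1]; e_R <- frame[, 2]; e_th <- frame[, 3]
  for (cn in cons) {
    if (cn$kind == "matrix") {
      lam <- cn$lambda_h
      if (length(lam) == 1) lam <- rep(lam, 3)
      G <- frame %*% diag(c(lam[1], lam[2] / fg, lam[3])) %*% t(frame)
      Ce <- t(G) %*% C %*% G
      Je <- sqrt(det(Ce))
      W <- W + cn$rho * KPA_ *
        (cn$mu / 2 * (Je^(-2 / 3) * sum(diag(Ce)) - 3) +
         cn$kappa / 2 * (Je - 1)^2)
    } else {
      a <- cos(cn$angle) * e_th + sin(cn$angle) * e_ax
      x <- as.numeric(t(a) %*% C %*% a) * cn$lambda_h^2
      if (x >= 1 || !isTRUE(cn$tension_only))
        W <- W + cn$rho * KPA_ * cn$k1 / (2 * cn$k2) *
          (exp(cn$k2 * (x - 1)^2) - 1)
    }
  }
  W
}

# S = 2 dW/dC by symmetric central differences
oracle_stress_fd <- function(C, frame, cons, fg = 1, h = 1e-6) {
  S <- matrix(0, 3, 3)
  for (i in 1:3) for (j in i:3) {
    Cp <- C; Cp[i, j] <- Cp[i, j] + h; if (i != j) Cp[j, i] <- Cp[j, i] + h
    Cm <- C; Cm[i, j] <- Cm[i, j] - h; if (i != j) Cm[j, i] <- Cm[j, i] - h
    d <- (oracle_energy(Cp, frame, cons, fg) -
          oracle_energy(Cm, frame, cons, fg)) / (2 * h)
    S[i, j] <- S[j, i] <- if (i == j) 2 * d else d
  }
  S
}

# Voigt tangent by central differences of a stress function S(C)
fd_tangent <- function(Sfun, C, h = 1e-6) {
  D <- matrix(0, 6, 6)
  for (q in 1:6) {
    k <- VI6[q]; l <- VJ6[q]
    Cp <- C; Cp[k, l] <- Cp[k, l] + h; if (k != l) Cp[l, k] <- Cp[l, k] + h
    Cm <- C; Cm[k, l] <- Cm[k, l] - h; if (k != l) Cm[l, k] <- Cm[l, k] - h
    dS <- (Sfun(Cp) - Sfun(Cm)) / (2 * h)
    for (p in 1:6)
      D[p, q] <- if (k == l) 2 * dS[VI6[p], VJ6[p]] else dS[VI6[p], VJ6[p]]
  }
  D
}

cyl_frame <- cbind(c(0, 0, 1), c(1, 0, 0), c(0, 1, 0))

bench_constituents <- function() {
  list(
    constituent("matrix", rho = 241.5, mu = 72, kappa = 7200,
                lambda_h = c(1.25, 1 / (1.25 * 1.34), 1.34)),
    constituent("smc", rho = 157.5, k1 = 7.6, k2 = 11.4, angle = 0,
                lambda_h = 1.1),
    constituent("collagen", rho = 65.1, k1 = 568, k2 = 11.2, angle = 0,
                lambda_h = 1.062),
    constituent("collagen", rho = 241.5, k1 = 568, k2 = 11.2, angle = pi / 4,
                lambda_h = 1.062))
}

# small quarter-cylinder solver context with the verification materials
small_cyl_ctx <- function(div = c(1, 4, 6), pressure = 100 * 0.133322,
                          options = list()) {
  cfg <- cylinder_benchmark_scenario(divisions = div, horizon_days = 0)
  mats <- hcmgr:::build_materials(cfg)
  mesh <- build_cylinder_mesh(10, 90, 1.41, div[1], div[2], div[3],
                              quarter = TRUE)
  ctx <- hcmgr:::make_solver_context(mesh, mats,
                                     boundary_spec(pressure = pressure),
                                     options = options)
  lam <- mats$single[[1]]$lambda_h
  ctx$elast_lam <- matrix(lam, ctx$nqp, 3, byrow = TRUE)
  ctx
}

# structured box mesh (nx x ny x nz cube elements on [0,1]^3) with constant
# local frames; optional random interior-node distortion for patch tests
make_box_mesh <- function(n = 2, distort = 0, seed = 1) {
  set.seed(seed)
  xs <- seq(0, 1, length.out = n + 1)
  id <- function(i, j, k) ((k - 1) * (n + 1) + (j - 1)) * (n + 1) + i
  nodes <- as.matrix(expand.grid(x = xs, y = xs, z = xs))[, 1:3]
  if (distort > 0) {
    interior <- nodes[, 1] > 0 & nodes[, 1] < 1 & nodes[, 2] > 0 &
      nodes[, 2] < 1 & nodes[, 3] > 0 & nodes[, 3] < 1
    nodes[interior, ] <- nodes[interior, ] +
      distort / n * matrix(runif(3 * sum(interior), -1, 1), ncol = 3)
  }
  elems <- matrix(0L, n^3, 8)
  e <- 0L
  for (k in 1:n) for (j in 1:n) for (i in 1:n) {
    e <- e + 1L
    elems[e, ] <- c(id(i, j, k), id(i + 1, j, k), id(i + 1, j + 1, k),
                    id(i, j + 1, k), id(i, j, k + 1), id(i + 1, j, k + 1),
                    id(i + 1, j + 1, k + 1), id(i, j + 1, k + 1))
  }
  m <- hcmgr:::new_hex_mesh(nodes, elems, rep("single", n^3),
                            list(proximal = integer(0), distal = integer(0)),
                            list(lumen = matrix(0L, 0, 4)),
                            meta = list(type = "box"))
  fr <- c(0, 0, 1, 1, 0, 0, 0, 1, 0)
  m$qp_frames <- matrix(fr, nrow(elems) * 8, 9, byrow = TRUE)
  m$node_frames <- matrix(fr, nrow(nodes), 9, byrow = TRUE)
  m
}

box_matrix_materials <- function(kappa = 720) {
  list(single = list(
    list(kind = "matrix", rho = 241.5, mu = 72, kappa = kappa, lambda_h = 1)))
}
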