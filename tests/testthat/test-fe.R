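test_that("assembled stiffness matches finite differences of the residual on a 2-element patch", {
  set.seed(3)
  ctx <- small_cyl_ctx(div = c(1, 2, 1), pressure = 100 * 0.133322)
  st <- hcmgr:::init_growth_state(ctx)
  u <- 0.01 * rnorm(ctx$ndof)
  arr <- hcmgr:::build_arrays(ctx, st, 1)
  p <- ctx$bc$pressure
  out <- hcmgr:::assemble_full(ctx, u, arr, p, TRUE)
  K <- ctx$K0; K@x <- out$xvals
  K <- as.matrix(K)
  h <- 1e-6
  Kfd <- matrix(0, ctx$ndof, ctx$ndof)
  for (j in seq_len(ctx$ndof)) {
    up <- u; up[j] <- up[j] + h
    um <- u; um[j] <- um[j] - h
    rp <- hcmgr:::assemble_full(ctx, up, arr, p, FALSE)
    rm_ <- hcmgr:::assemble_full(ctx, um, arr, p, FALSE)
    Kfd[, j] <- ((rp$fint - rp$fext) - (rm_$fint - rm_$fext)) / (2 * h)
  }
  expect_lt(max(abs(K - Kfd)) / max(abs(Kfd)), 1e-5)
})

test_that("a linear displacement field yields constant stress and an equilibrated interior node (patch test)", {
  m <- make_box_mesh(n = 2, distort = 0.15, seed = 5)
  mats <- box_matrix_materials()
  ctx <- hcmgr:::make_solver_context(m, mats, boundary_spec())
  st <- hcmgr:::init_growth_state(ctx)
  A <- matrix(c(0.02, 0.005, 0, 0.003, -0.01, 0.002, 0, 0.004, 0.015), 3)
  u <- as.vector(t(m$nodes %*% t(A)))
  fl <- hcmgr:::qp_state_fields(ctx, st, u)
  # homogeneous deformation: all quadrature-point stresses identical
  for (k in 1:6)
    expect_lt(diff(range(fl$cauchy[, k])), 1e-10 * (1 + max(abs(fl$cauchy))))
  # interior node carries no residual under the constant-stress state
  out <- hcmgr:::assemble_full(ctx, u, hcmgr:::build_arrays(ctx, st), 0, FALSE)
  interior <- which(rowSums(m$nodes > 1e-9 & m$nodes < 1 - 1e-9) == 3)
  expect_length(interior, 1)
  dofs <- 3 * (interior - 1) + 1:3
  expect_lt(max(abs(out$fint[dofs])), 1e-9 * max(abs(out$fint)))
})

test_that("follower pressure integrates to the exact resultant", {
  # single-element box, unit pressure on the unit-square bottom face
  m <- make_box_mesh(n = 1)
  m$facet_sets$lumen <- matrix(c(1L, 2L, 4L, 3L), 1)  # z = 0 face
  mats <- box_matrix_materials()
  ctx <- hcmgr:::make_solver_context(m, mats, boundary_spec(pressure = 1))
  z <- numeric(ctx$ndof)
  pr <- assemble_pressure(ctx, z, 1)
  f <- matrix(pr$f_ext, ncol = 3, byrow = TRUE)
  expect_equal(sum(abs(f[, 1:2])), 0)
  expect_equal(abs(sum(f[, 3])), 1)            # 1 kPa x 1 mm^2
  expect_equal(abs(f[1:4, 3]), rep(0.25, 4))   # split evenly over corners
  expect_equal(assemble_pressure(ctx, z, 0)$f_ext, numeric(ctx$ndof))
  # quarter cylinder: net resultant of p over the lumen is p * projected area
  ctx2 <- small_cyl_ctx(div = c(1, 6, 4))
  p <- ctx2$bc$pressure
  pr2 <- assemble_pressure(ctx2, numeric(ctx2$ndof), p)
  f2 <- colSums(matrix(pr2$f_ext, ncol = 3, byrow = TRUE))
  expect_equal(f2[3], 0, tolerance = 1e-10)
  expect_equal(f2[1], p * 10 * 90, tolerance = 0.01 * p * 900)
  expect_equal(f2[2], p * 10 * 90, tolerance = 0.01 * p * 900)
})

test_that("end rollers with stiff springs pin the in-plane motion", {
  cfg <- cylinder_benchmark_scenario(horizon_days = 0, divisions = c(1, 4, 6))
  mats <- hcmgr:::build_materials(cfg)
  mesh <- build_cylinder_mesh(10, 90, 1.41, 1, 4, 6, quarter = TRUE)
  sol_at <- function(k) {
    ctx <- hcmgr:::make_solver_context(
      mesh, mats, boundary_spec(k_pro = k, k_dis = k,
                                pressure = 100 * 0.133322))
    lam <- mats$single[[1]]$lambda_h
    ctx$elast_lam <- matrix(lam, ctx$nqp, 3, byrow = TRUE)
    st <- hcmgr:::init_growth_state(ctx)
    solve_equilibrium(ctx, st, load_steps = 4)$u
  }
  u_free <- sol_at(0)
  u_stiff <- sol_at(1e15)
  ends <- c(mesh$node_sets$proximal, mesh$node_sets$distal)
  end_dofs <- as.vector(vapply(ends, function(n) 3 * (n - 1) + 1:3,
                               numeric(3)))
  expect_gt(max(abs(u_free[end_dofs])), 1e-3)
  expect_lt(max(abs(u_stiff[end_dofs])), 1e-6 * max(abs(u_free[end_dofs])))
})

test_that("an unloaded natural state solves to zero displacement immediately", {
  m <- make_box_mesh(n = 1)
  mats <- box_matrix_materials()
  ctx <- hcmgr:::make_solver_context(m, mats, boundary_spec(pressure = 0))
  st <- hcmgr:::init_growth_state(ctx)
  sol <- solve_equilibrium(ctx, st, load_steps = 1)
  expect_equal(sol$u, numeric(ctx$ndof))
  expect_equal(sol$report$iterations, 0)
})

test_that("Newton converges quadratically and satisfies global force balance", {
  ctx <- small_cyl_ctx(div = c(2, 6, 8), options = list(solver = "lu"))
  st <- hcmgr:::init_growth_state(ctx)
  sol <- solve_equilibrium(ctx, st, load_steps = 1)
  last <- sol$report$steps[[length(sol$report$steps)]]
  r <- last$residuals
  expect_gte(length(r), 3)
  expect_lte(length(r), 8)             # few iterations to full convergence
  rates <- r[-1] / r[-length(r)]
  # superlinear contraction: some two consecutive iterations together gain
  # more than four orders of magnitude (a linear solver at rate ~0.1 cannot)
  expect_lt(min(rates[-1] * rates[-length(rates)]), 1e-4)
  # equilibrium: internal forces self-equilibrate, free residual vanishes
  st$u <- sol$u
  arr <- hcmgr:::build_arrays(ctx, st)
  out <- hcmgr:::assemble_full(ctx, sol$u, arr, ctx$bc$pressure, FALSE)
  fext_norm <- sqrt(sum(out$fext^2))
  resid <- out$fint - out$fext
  ut <- as.vector(Matrix::crossprod(ctx$Tmat, resid))
  expect_lt(sqrt(sum(ut[ctx$free]^2)), 1e-7 * fext_norm)
  expect_lt(max(abs(colSums(matrix(out$fint, ncol = 3, byrow = TRUE)))),
            1e-8 * fext_norm)
})

test_that("the inflated-cylinder solution converges with mesh refinement", {
  cfg <- cylinder_benchmark_scenario(horizon_days = 0)
  mats <- hcmgr:::build_materials(cfg)
  radial_disp <- function(nc) {
    mesh <- build_cylinder_mesh(10, 9, 1.41, 1, nc, 1, quarter = TRUE)
    ctx <- hcmgr:::make_solver_context(
      mesh, mats, boundary_spec(pressure = 100 * 0.133322))
    lam <- mats$single[[1]]$lambda_h
    ctx$elast_lam <- matrix(lam, ctx$nqp, 3, byrow = TRUE)
    st <- hcmgr:::init_growth_state(ctx)
    u <- solve_equilibrium(ctx, st, load_steps = 2)$u
    mm <- measure_diameter_thickness(mesh, u)
    mm$d
  }
  d <- vapply(c(2, 4, 8, 16), radial_disp, 0)
  err <- abs(d[1:3] - d[4])
  expect_true(all(diff(err) < 0))
  expect_gt(log2(err[1] / err[2]), 1.5)  # ~second order in h
})
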