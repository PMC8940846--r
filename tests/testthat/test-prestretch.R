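test_that("gradient profiles are endpoint-exact and linear", {
  f <- prestretch_field(0.75, 1.3, 1.45, 1.3, lam_iv = 1.3,
                        R_ic = 47, R_oc = 83)
  expect_equal(axial_profile(47, f), 0.75)
  expect_equal(axial_profile(83, f), 1.3)
  expect_equal(axial_profile(65, f), (0.75 + 1.3) / 2)
  expect_equal(circ_profile(47, f), 1.45)
  expect_equal(circ_profile(83, f), 1.3)
  # unit-interval field: the documented midpoint example
  fu <- prestretch_field(0.75, 1.3, 1.45, 1.3)
  expect_equal(axial_profile(0.5, fu), 1.025)
  expect_warning(axial_profile(90, f), "clamp")
  suppressWarnings(expect_equal(axial_profile(90, f), 1.3))
})

test_that("radial closure makes the prestretch triple exactly unimodular", {
  expect_equal(radial_closure(1, 1), 1)
  expect_equal(radial_closure(1.3, 1.3), 1 / 1.69)
  expect_equal(radial_closure(0.75, 1.45), 1 / 1.0875)
  set.seed(21)
  f <- prestretch_field(0.75, 1.3, 1.45, 1.3, R_ic = 47, R_oc = 83)
  R <- runif(20, 47, 83)
  la <- axial_profile(R, f); lt <- circ_profile(R, f)
  expect_equal(la * radial_closure(la, lt) * lt, rep(1, 20),
               tolerance = 1e-14)
})

test_that("straight-tube prestretch calibration balances the pressurized ring", {
  cfg <- cylinder_benchmark_scenario(horizon_days = 0)
  mats <- hcmgr:::build_materials(cfg)
  p <- 100 * 0.133322
  f <- solve_cylinder_prestretch(list(radius = 10, thickness = 1.41),
                                 mats, p, lam_iv = 1.25)
  expect_equal(f$lam_phi_ic, 1.25)          # axial pinned to lam_iv
  expect_equal(f$lam_theta_ic, f$lam_theta_oc)
  # residual of the force balance vanishes at the root
  layers <- list(list(constituents = mats$single, r_in = 10, r_out = 11.41))
  expect_lt(abs(hcmgr:::ring_residual(f$lam_theta_ic, 1.25, layers, p)) / p,
            1e-3)
  # mean circumferential stress close to the thin-wall Laplace estimate
  frame <- cyl_frame
  cons <- mats$single
  cons[[1]]$lambda_h <- c(1.25, radial_closure(1.25, f$lam_theta_ic),
                          f$lam_theta_ic)
  sig <- mixture_stress_and_tangent(list(F = diag(3), frame = frame),
                                    cons)$cauchy
  expect_lt(abs(sig[2, 2] - p * 10 / 1.41) / (p * 10 / 1.41), 0.10)
  # no root in the bracket -> calibration failure
  expect_error(solve_cylinder_prestretch(list(radius = 10, thickness = 1.41),
                                         mats, 500, lam_iv = 1.25),
               "calibration failed")
})

test_that("distortion metrics are zero at rest and scale with uniform inflation", {
  m <- build_cylinder_mesh(10, 30, 1.41, 1, 6, 6, quarter = TRUE)
  rep0 <- distortion_metrics(m, numeric(3 * nrow(m$nodes)))
  expect_equal(rep0$delta_d, 0)
  expect_equal(rep0$delta_t, 0)
  # uniform 1% radial inflation: both distortions are 1%
  u <- t(vapply(seq_len(nrow(m$nodes)), function(n)
    0.01 * c(m$nodes[n, 1], m$nodes[n, 2], 0), numeric(3)))
  rep1 <- distortion_metrics(m, as.vector(t(u)))
  expect_equal(rep1$delta_d, 1, tolerance = 1e-9)
  expect_equal(rep1$delta_t, 1, tolerance = 1e-9)
})

test_that("vacuous tolerances return the initial gradient guess unchanged", {
  cfg <- toric_arch_scenario(horizon_days = 0, divisions = c(1, 8, 4))
  mats <- hcmgr:::build_materials(cfg)
  mesh <- build_torus_mesh(36, 65, 2.38, pi / 2, 1, 8, 4)
  ctx <- hcmgr:::make_solver_context(mesh, mats,
                                     boundary_spec(pressure = 80 * 0.133322))
  init <- prestretch_field(0.8, 1.3, 1.4, 1.35, lam_iv = 1.3,
                           R_ic = 47, R_oc = 83)
  out <- calibrate_prestretch_gradients(ctx, lam_iv = 1.3, eps_t = 100,
                                        eps_d = 100, init = init)
  expect_equal(out$lam_phi_ic, init$lam_phi_ic)
  expect_equal(out$lam_theta_ic, init$lam_theta_ic)
  expect_equal(out$lam_theta_oc, init$lam_theta_oc)
  expect_s3_class(attr(out, "report"), "distortion_report")
})

test_that("a straight cylinder degenerates the calibration to the uniform solve", {
  cfg <- cylinder_benchmark_scenario(horizon_days = 0, divisions = c(1, 4, 6))
  mats <- hcmgr:::build_materials(cfg)
  mesh <- build_cylinder_mesh(10, 90, 1.41, 1, 4, 6, quarter = TRUE)
  ctx <- hcmgr:::make_solver_context(mesh, mats,
                                     boundary_spec(pressure = 100 * 0.133322))
  f <- calibrate_prestretch_gradients(ctx, lam_iv = 1.25)
  ref <- solve_cylinder_prestretch(list(radius = 10, thickness = 1.41),
                                   mats, 100 * 0.133322, lam_iv = 1.25)
  expect_equal(f$lam_theta_ic, ref$lam_theta_ic, tolerance = 1e-10)
})

test_that("the torus prestretch machinery approaches the cylinder limit for a large arch", {
  cfg <- toric_arch_scenario(horizon_days = 0)
  mats <- hcmgr:::build_materials(cfg)
  p <- 80 * 0.133322
  meta <- list(lumen_diameter = 36, arch_radius = 5000, thickness = 2.38,
               layer_split = 0.5, R_IC = 5000 - 18, R_OC = 5000 + 18)
  f0 <- prestretch_field(1.3, 1.3, 1, 1, lam_iv = 1.3,
                         R_ic = meta$R_IC, R_oc = meta$R_OC)
  ep <- hcmgr:::solve_torus_theta_endpoints(meta, mats, p, f0)
  cylref <- solve_cylinder_prestretch(
    list(radius = 18, thickness = 2.38, layer_split = 0.5), mats, p,
    lam_iv = 1.3)
  expect_lt(abs(ep[["ic"]] - cylref$lam_theta_ic) / cylref$lam_theta_ic, 0.01)
  expect_lt(abs(ep[["oc"]] - cylref$lam_theta_ic) / cylref$lam_theta_ic, 0.01)
})
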