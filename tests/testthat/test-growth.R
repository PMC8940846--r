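test_that("elastin aging follows first-order decay", {
  expect_equal(elastin_density_aging(0, 241.5, 101 * 365), 241.5)
  expect_equal(elastin_density_aging(101 * 365, 241.5, 101 * 365),
               241.5 * exp(-1))
  expect_equal(elastin_density_aging(10 * 365, 169, 101 * 365),
               169 * exp(-10 / 101))  # ~153.2 kg/m^3
  t <- seq(0, 50 * 365, by = 365)
  expect_true(all(diff(elastin_density_aging(t, 169, 101 * 365)) < 0))
})

test_that("damage distance separates radial and axial modes", {
  ins <- insult_spec(P0 = c(0, 0, 0), v = c(1, 0, 0))
  expect_equal(damage_distance(c(0, 0, 0), ins, "radial"), 0)
  expect_equal(damage_distance(c(0, 0, 0), ins, "axial"), 0)
  expect_equal(damage_distance(c(0, 4, 3), ins, "axial"), 0)  # orthogonal to v
  expect_equal(damage_distance(c(3, 4, 0), ins, "radial"), 5)
  expect_equal(damage_distance(c(3, 4, 0), ins, "axial"), 3)
})

test_that("the localized insult starts exact, bounds the loss, and reduces to aging far away", {
  ins <- insult_spec(D_max = 0.5, L_dam = 10, t_dam = 40,
                     P0 = c(0, 0, 0), v = c(0, 0, 1))
  expect_equal(elastin_density_insult(c(0, 0, 0), 0, 241.5, ins), 241.5)
  t1 <- 365
  at_centre <- elastin_density_insult(c(0, 0, 0), t1, 241.5, ins)
  aging <- elastin_density_aging(t1, 241.5, ins$T_l)
  expect_lt(at_centre, aging)
  # the exact transient undershoots the naive (1 - D_max) floor by the
  # small ratio t_dam / T_l
  expect_gt(at_centre, (1 - ins$D_max) * aging * (1 - 2 * ins$t_dam / ins$T_l))
  far <- elastin_density_insult(c(0, 0, 10 * ins$L_dam), t1, 241.5, ins)
  expect_lt(abs(far - aging) / aging, 1e-6)
  expect_error(elastin_density_insult(c(0, 0, 0), t1, 241.5,
                 insult_spec(t_dam = 101 * 365, T_l = 101 * 365)),
               "degenerate")
})

test_that("mass production vanishes at homeostasis and is linear in gain and deviation", {
  expect_equal(mass_production_rate(100, 100, 50, 0.05 / 101), 0)
  r <- mass_production_rate(110, 100, 100, 0.05 / 101)
  expect_equal(r, 100 * 0.05 / 101 * 0.1)  # 0.5/T per day
  expect_equal(mass_production_rate(110, 100, 100, 0.10 / 101), 2 * r)
  expect_lt(mass_production_rate(90, 100, 100, 0.05 / 101), 0)
})

test_that("the Euler update is inert without rates and floors densities at zero", {
  st <- structure(list(t = 0,
                       rho = matrix(c(100, 50), 1),
                       rho0 = matrix(c(100, 50), 1),
                       lambda_r = matrix(0.9, 1),
                       fg = 1), class = "growth_state")
  st1 <- update_growth_state(st, 10, list())
  expect_equal(st1$rho, st$rho)
  expect_equal(st1$fg, 1)
  expect_equal(st1$t, 10)
  st2 <- update_growth_state(st, 10, list(rho_dot = matrix(c(0, -20), 1)))
  expect_equal(st2$rho[1, 2], 0)  # floored
  expect_equal(st2$fg, 100 / 150)
  expect_error(update_growth_state(st, 10,
                 list(lambda_r_dot = matrix(-1, 1))), "time step")
})

test_that("elastin-only degradation softens the mixture stress monotonically", {
  cons <- bench_constituents()
  F <- diag(c(1.02, 0.99, 1.05))
  vals <- vapply(seq(1, 0.4, by = -0.1), function(f) {
    c2 <- cons; c2[[1]]$rho <- f * cons[[1]]$rho
    norm(mixture_stress_and_tangent(list(F = F, frame = cyl_frame), c2)$S, "F")
  }, 0)
  expect_true(all(diff(vals) < 0))
})

test_that("remodeling relaxes the fiber stress toward its homeostatic value", {
  # single fiber driven above homeostasis: the inelastic stretch grows and
  # the elastic stretch (and stress) decays back toward target
  k1s <- 2 * 568; k2 <- 11.2; lam_h <- 1.062
  lam <- 1.10       # total stretch held fixed
  lr <- 1 / lam_h   # so x = (lam * lam_h)^2 > lam_h^2: overstressed
  sfun <- function(x) k1s * (x - 1) * exp(k2 * (x - 1)^2) * x
  sh <- sfun(lam_h^2)
  dev0 <- NULL
  for (i in 1:400) {
    x <- lam^2 / lr^2
    s <- sfun(x)
    if (is.null(dev0)) dev0 <- s - sh
    rate <- hcmgr:::remodeling_rate(x, lr, s, sh, k1s, k2, J = 1,
                                    rho_rate_frac = 0, turnover = 101)
    lr <- lr + 1 * rate  # dt = 1 day
  }
  x_end <- lam^2 / lr^2
  expect_gt(dev0, 0)
  expect_lt(abs(sfun(x_end) - sh), 0.05 * abs(dev0))  # >95% relaxed
})
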