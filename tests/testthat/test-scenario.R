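test_that("diameter and thickness metrics reproduce the reference geometries", {
  m <- build_cylinder_mesh(10, 30, 1.41, 1, 6, 6, quarter = TRUE)
  mm <- measure_diameter_thickness(m)
  expect_equal(mm$d, 20)
  expect_equal(mm$t, 1.41, tolerance = 1e-9)
  # uniform 10% inflation scales the diameter to 22 mm
  u <- as.vector(t(0.1 * cbind(m$nodes[, 1], m$nodes[, 2], 0)))
  expect_equal(measure_diameter_thickness(m, u)$d, 22, tolerance = 1e-9)
  mt <- build_torus_mesh(36, 65, 2.38, pi / 2, 2, 16, 12)
  mmt <- measure_diameter_thickness(mt)
  expect_equal(mmt$d, 36, tolerance = 1e-9)
  expect_equal(mmt$t, 2.38, tolerance = 1e-9)
  expect_equal(mmt$d_max, 36, tolerance = 1e-9)
})

test_that("von Mises stress has its closed-form values", {
  expect_equal(von_mises(diag(-5, 3)), 0)
  expect_equal(von_mises(diag(c(7, 0, 0))), 7)
  tau <- 3.2
  sh <- matrix(0, 3, 3); sh[1, 2] <- sh[2, 1] <- tau
  expect_equal(von_mises(sh), sqrt(3) * tau)
  # Voigt row interface agrees with the tensor interface
  v <- matrix(c(7, 0, 0, 0, 0, 0), 1)
  expect_equal(von_mises(v), 7)
  expect_equal(von_mises(matrix(c(0, 0, 0, tau, 0, 0), 1)), sqrt(3) * tau)
})

test_that("normalized collagen density is 1 at the reference and under pure elastin loss", {
  st <- structure(list(
    rho = cbind(100, 50, 10, 20, 20, 10),
    rho0 = cbind(200, 50, 10, 20, 20, 10),  # elastin halved, collagen frozen
    kinds = c("matrix", "smc", "collagen", "collagen", "collagen", "collagen")),
    class = "growth_state")
  expect_equal(normalized_collagen(st), 1)
  st$rho[, 3] <- 15
  expect_equal(normalized_collagen(st), 65 / 60)
  st$kinds <- rep("matrix", 6)
  expect_error(normalized_collagen(st), "collagen")
})

test_that("scenario configs validate, round-trip through YAML, and match the shipped fixtures", {
  cfg <- cylinder_benchmark_scenario()
  f <- tempfile(fileext = ".yml")
  write_scenario_config(cfg, f)
  cfg2 <- read_scenario_config(f)
  expect_equal(unclass(cfg2), unclass(cfg), tolerance = 1e-9)
  expect_error(scenario_config(name = "x",
                               geometry = list(type = "pyramid"),
                               materials = list(single = list()),
                               pressure_mmHg = 100),
               "geometry")
  expect_error(read_scenario_config("missing.yml"),
               class = "hcmgr_file_not_found")
  # shipped fixtures serialize the two benchmark tables field-for-field
  for (pair in list(
    list(file = "cylinder_benchmark.yml", ref = cylinder_benchmark_scenario()),
    list(file = "toric_arch.yml", ref = toric_arch_scenario()))) {
    path <- system.file("extdata", pair$file, package = "hcmgr")
    expect_true(nzchar(path))
    expect_equal(unclass(read_scenario_config(path)), unclass(pair$ref),
                 tolerance = 1e-9)
  }
})

test_that("a zero-horizon run returns only the homeostatic state, deterministically", {
  cfg <- cylinder_benchmark_scenario(horizon_days = 0, divisions = c(1, 4, 8))
  r1 <- run_scenario(cfg)
  expect_equal(nrow(r1$series), 1)
  expect_equal(r1$series$rhoc_max, 1)
  r2 <- run_scenario(cfg)
  expect_identical(r1$series, r2$series)
})

test_that("a localized insult grows the diameter monotonically", {
  cfg <- cylinder_benchmark_scenario(gain_frac = 0.05, horizon_days = 400,
                                     dt_days = 20, divisions = c(1, 6, 16),
                                     insult_mode = "insult")
  cfg$output_every <- 40
  res <- run_scenario(cfg)
  expect_false(res$truncated)
  expect_true(all(diff(res$series$diameter) > 0))
  expect_gt(tail(res$series$rhoc_max, 1), 1)
})

test_that("the command-line interface reports usage errors and writes artifacts", {
  expect_equal(as.integer(cli_main(c("run-config", "no-such-file.yml"))), 2L)
  out <- capture.output(status <- cli_main(character(0)))
  expect_equal(as.integer(status), 2L)
  od <- tempfile("cli")
  status <- suppressWarnings(cli_main(c(
    "verify-cylinder", "--gain", "0.05", "--horizon", "60", "--dt", "20",
    "--mesh-divisions", "1x4x8", "--out-dir", od)))
  expect_equal(as.integer(status), 0L)
  js <- list.files(od, pattern = "_summary\\.json$", full.names = TRUE)
  expect_length(js, 1)
  summ <- jsonlite::read_json(js)
  expect_true(all(c("svm_min_kpa", "svm_max_kpa", "rhoc_max",
                    "final_diameter_mm") %in% names(summ)))
  expect_length(list.files(od, pattern = "_series\\.csv$"), 1)
  expect_length(list.files(od, pattern = "_final\\.vtk$"), 1)
})
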