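test_that("sweep specifications are validated", {
  expect_error(sweep_spec("delta1", family = "delta1",
                          family_values = c(0.1, 0.2)), "distinct")
  expect_error(sweep_spec("delta1", grid = numeric(0)), "non-empty")
  expect_error(sweep_spec("delta1", grid = c(0.2, 0.1)),
               "strictly increasing")
  expect_error(sweep_spec("delta1", family = "M", family_values = NULL),
               "non-empty")
  expect_error(sweep_spec("viscosity"), "arg")
})

test_that("a stenosis-height sweep starts at the unit normalization row", {
  spec <- sweep_spec("delta1", grid = c(0, 0.1, 0.2))
  tab <- run_sweep(spec, stenosis_only_config())
  expect_equal(nrow(tab), 3)
  expect_equal(tab$lambda_bar[1], 1, tolerance = 1e-12)
  expect_equal(tab$tau_bar_w[1], 1, tolerance = 1e-12)
  expect_equal(tab$swept_value, c(0, 0.1, 0.2))
  expect_true(all(diff(tab$lambda_bar) > 0))
})

test_that("family sweeps order impedance by stenosis height at the anchor plug radius", {
  # one curve per stenosis height; at the anchor r0 = 0.2 the taller
  # stenosis always has the larger normalized impedance
  spec <- sweep_spec("r0", grid = c(0.15, 0.2, 0.3, 0.4),
                     family = "delta1", family_values = c(0.05, 0.10, 0.15))
  tab <- run_sweep(spec, stenosis_only_config())
  expect_equal(nrow(tab), 12)
  for (r0 in unique(tab$swept_value)) {
    grp <- tab[tab$swept_value == r0, ]
    grp <- grp[order(grp$family_value), ]
    expect_true(all(diff(grp$lambda_bar) > 0))
  }
})

test_that("sweeps fail loudly when the plug outgrows the lumen", {
  cfg <- stenosis_only_config(height = 0.3)
  spec <- sweep_spec("r0", grid = c(0.2, 0.75))
  expect_error(run_sweep(spec, cfg), "r0 = 0.75")
})

test_that("sweeps are deterministic", {
  spec <- sweep_spec("delta1", grid = c(0, 0.1, 0.2))
  t1 <- run_sweep(spec, stenosis_only_config())
  t2 <- run_sweep(spec, stenosis_only_config())
  expect_identical(t1, t2)
})

test_that("monotonicity report flags reversed trends and degenerate grids", {
  spec <- sweep_spec("delta1", grid = c(0, 0.1, 0.2))
  tab <- run_sweep(spec, stenosis_only_config())
  good <- data.frame(response = "lambda_bar", swept = "delta1",
                     direction = "increasing", source = "self-test")
  expect_equal(monotonicity_report(tab, good)$status, "PASS")

  reversed <- transform(good, direction = "decreasing")
  rep_rev <- monotonicity_report(tab, reversed)
  expect_equal(rep_rev$status, "FAIL")
  expect_gt(rep_rev$worst_violation, 0)

  single <- run_sweep(sweep_spec("delta1", grid = 0.1), stenosis_only_config())
  expect_equal(monotonicity_report(single, good)$status, "NOT-EVALUABLE")

  other <- data.frame(response = "lambda_bar", swept = "M",
                      direction = "increasing", source = "self-test")
  expect_equal(monotonicity_report(tab, other)$status, "NOT-EVALUABLE")
})

test_that("figure suite emits one CSV per catalogued figure", {
  out <- withr::local_tempdir()
  manifest <- figure_suite(out_dir = out, grid_points = 5L, format = "none")
  expect_equal(nrow(manifest), 24)
  expect_equal(manifest$id, sprintf("fig%02d", 2:25))
  expect_true(all(file.exists(manifest$csv)))
  expect_true(any(nzchar(manifest$note)))  # transposed-caption figures flagged
  tab <- utils::read.csv(manifest$csv[1])
  expect_named(tab, c("swept_name", "swept_value", "family_name",
                      "family_value", "lambda_bar", "tau_bar_w",
                      "u_center", "u_at_r"))
})

test_that("configuration files round-trip through YAML and JSON", {
  cfg <- default_config()
  for (ext in c("yaml", "json")) {
    path <- withr::local_tempfile(fileext = paste0(".", ext))
    write_config(cfg, path)
    back <- read_config(path)
    expect_equal(config_plug_radius(back), 0.2)
    expect_equal(config_forces(back)$f, 0.3 * sin(pi / 6))
    expect_equal(config_geometry(back)$domain_length, 1.2)
    # idempotence: a second round trip reproduces the file byte for byte
    path2 <- withr::local_tempfile(fileext = paste0(".", ext))
    write_config(back, path2)
    back2 <- read_config(path2)
    expect_equal(back2, back)
  }
  expect_error(read_config("nope.yaml"), "not found")
})

test_that("angles in configs accept expressions over pi", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("forces:", "  phi: pi/6"), path)
  cfg <- read_config(path)
  expect_equal(cfg$forces$phi, pi / 6)
  expect_error(parse_numeric("system('ls')", "phi"), "cannot interpret")
})

test_that("yield-stress configs convert through the core force balance", {
  cfg <- default_config()
  cfg$casson <- list(yield_stress = 0.1, nominal_pressure_gradient = 1)
  expect_equal(config_plug_radius(cfg), 0.2)
  cfg$casson <- list(yield_stress = 0.1)
  expect_error(config_plug_radius(cfg), "nominal_pressure_gradient")
  cfg$casson <- list()
  expect_error(config_plug_radius(cfg), "plug_radius")
})
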