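test_that("pressure drop over a uniform tube is the constant-integrand value", {
  frc <- caption_forces()
  geom <- vessel_geometry()  # healthy tube, domain length 1
  expect_equal(pressure_drop(0.1, geom, 0.2, frc, "paper"),
               pressure_gradient(0.1, 1, 0.2, frc, "paper"))
  # zero-height lesions are the same expression over the longer domain
  geom0 <- two_lesion_geometry(0, 0)
  expect_equal(pressure_drop(0.1, geom0, 0.2, frc, "paper"),
               pressure_gradient(0.1, 1, 0.2, frc, "paper") * 1.2)
})

test_that("quadrature converges under node doubling", {
  frc <- caption_forces()
  geom <- two_lesion_geometry()
  for (mode in c("paper", "derived")) {
    d1 <- pressure_drop(0.1, geom, 0.2, frc, mode, 2001L)
    d2 <- pressure_drop(0.1, geom, 0.2, frc, mode, 4001L)
    expect_lt(abs(d2 - d1) / abs(d2), 1e-8)
  }
})

test_that("impedance definitions and degenerate cases", {
  frc <- caption_forces()
  geom <- two_lesion_geometry()
  dp <- pressure_drop(0.1, geom, 0.2, frc)
  expect_equal(impedance(0.1, geom, 0.2, frc), 10 * dp)
  expect_error(impedance(0, geom, 0.2, frc), "zero flux")
  # with no body forces the pressure drop is proportional to the flux
  f0 <- force_field(0, 0, 0)
  expect_equal(impedance(0.1, geom, 0.2, f0, "derived"),
               impedance(0.2, geom, 0.2, f0, "derived"))
  # plug wider than the throat lumen is rejected, naming the worst station
  expect_error(pressure_drop(0.1, two_lesion_geometry(delta1 = 0.3), 0.75, frc),
               "z = 0.3")
})

test_that("reference impedance is the healthy-tube value", {
  frc <- caption_forces()
  expect_equal(reference_impedance(0.1, 0.2, frc, "paper", domain_length = 1.2),
               impedance(0.1, two_lesion_geometry(0, 0), 0.2, frc, "paper"))
  # Newtonian, unforced, unit-length tube: lambda_n = 8 exactly
  expect_equal(reference_impedance(1, 0, force_field(0, 0, 0), "derived"), 8)
  # normalization is the plain ratio: lambda_bar * lambda_n == lambda
  geom <- two_lesion_geometry(0.15, 0.05)
  expect_equal(normalized_impedance(0.1, geom, 0.2, frc, "paper") *
                 reference_impedance(0.1, 0.2, frc, "paper", 1.2),
               impedance(0.1, geom, 0.2, frc, "paper"))
})

test_that("normalized quantities equal one for a healthy vessel in both modes", {
  frc <- caption_forces()
  geom0 <- two_lesion_geometry(0, 0)
  for (mode in c("paper", "derived")) {
    expect_equal(normalized_impedance(0.1, geom0, 0.2, frc, mode), 1,
                 tolerance = 1e-12)
    expect_equal(normalized_wss(0.1, geom0, 0.2, frc, mode, station = 0.3), 1,
                 tolerance = 1e-12)
  }
  # station outside all lesions sees the healthy wall
  geom <- two_lesion_geometry(0.15, 0.1)
  expect_equal(normalized_wss(0.1, geom, 0.2, frc, "paper", station = 0.7), 1)
})

test_that("mode antisymmetry without body forces", {
  f0 <- force_field(0, 0, 0)
  geom <- two_lesion_geometry()
  expect_equal(impedance(0.1, geom, 0.2, f0, "paper"),
               -impedance(0.1, geom, 0.2, f0, "derived"))
  expect_equal(normalized_impedance(0.1, geom, 0.2, f0, "paper"),
               normalized_impedance(0.1, geom, 0.2, f0, "derived"))
})

test_that("reference wall shear stress limits", {
  frc <- caption_forces()
  expect_equal(reference_wss(0.1, 0.2, frc, "paper"),
               wall_shear_stress(0.1, 1, 0.2, frc, "paper"))
  expect_equal(reference_wss(0.1, 0, force_field(0, 0, 0), "derived"), 0.4)
})

test_that("axial solution assembles consistent normalized quantities", {
  sol <- solve_config(default_config())
  expect_s3_class(sol, "axial_solution")
  expect_equal(sol$lambda_bar, sol$lambda / sol$lambda_n)
  expect_equal(sol$lambda, sol$delta_p / 0.1)
  expect_equal(sol$station, 0.3)
  expect_true(all(is.finite(sol$profile$tau_w)))
  expect_equal(sol$profile$H[1], 1)
  # wall shear profile reduces to the reference value on healthy wall
  healthy <- sol$profile$H == 1
  expect_equal(sol$profile$tau_w[healthy],
               rep(sol$tau_wn, sum(healthy)))
})
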