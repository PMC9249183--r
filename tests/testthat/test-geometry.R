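test_that("segment bounds accumulate lengths and gaps", {
  g1 <- vessel_geometry(list(abnormal_segment(0.1, 0.2, 0.2, "stenosis")))
  expect_equal(segment_bounds(g1), data.frame(alpha = 0.2, beta = 0.4))

  g2 <- two_lesion_geometry()
  b <- segment_bounds(g2)
  expect_equal(b$alpha, c(0.2, 1.0))
  expect_equal(b$beta, c(0.4, 1.2))

  # ordering identities: alpha_1 = d_1 and beta_{i-1} + d_i = alpha_i
  expect_equal(b$alpha[1], g2$segments[[1]]$gap)
  expect_equal(b$beta[1] + g2$segments[[2]]$gap, b$alpha[2])

  g0 <- vessel_geometry()
  expect_equal(nrow(segment_bounds(g0)), 0)
  expect_equal(g0$domain_length, 1)
})

test_that("wall radius follows the cosine bump with the lesion sign convention", {
  geom <- two_lesion_geometry(delta1 = 0.2, delta2 = 0.1)
  # full height at the midpoints, vanishing at the segment ends
  expect_equal(wall_radius(0.3, geom), 0.8)
  expect_equal(wall_radius(1.1, geom), 1.1)
  expect_equal(wall_radius(c(0.2, 0.4, 1.0, 1.2), geom), rep(1, 4))
  # identity outside all segments
  expect_equal(wall_radius(c(0, 0.1, 0.5, 0.9), geom), rep(1, 4))
  expect_error(wall_radius(1.3, geom), "outside the domain")
  expect_error(wall_radius(-0.1, geom), "outside the domain")
})

test_that("wall profile is vectorized, symmetric and validated", {
  geom <- vessel_geometry(list(abnormal_segment(0.2, 0.2, 0.2, "stenosis")))
  expect_equal(wall_profile(c(0.2, 0.3, 0.4), geom), c(1, 0.8, 1))
  expect_equal(wall_profile(seq(0, 1, 0.1), vessel_geometry()), rep(1, 11))
  # cosine symmetry about the throat
  eps <- seq(0.01, 0.09, 0.01)
  expect_equal(wall_radius(0.3 - eps, geom), wall_radius(0.3 + eps, geom))
  expect_error(wall_profile(c(0.3, 0.2), geom), "strictly increasing")
})

test_that("wall radius is continuous at segment ends and extremal at midpoints", {
  cases <- list(c(0.15, 0.25, 0.1), c(-0.1, 0.3, 0.4), c(0.05, 0.5, 0))
  for (p in cases) {
    kind <- if (p[1] >= 0) "stenosis" else "dilatation"
    geom <- vessel_geometry(list(abnormal_segment(abs(p[1]), p[2], p[3], kind)))
    b <- segment_bounds(geom)
    for (edge in c(b$alpha, b$beta)) {
      expect_lt(abs(wall_radius(min(edge + 1e-9, geom$domain_length), geom) - 1),
                1e-6)
      expect_lt(abs(wall_radius(max(edge - 1e-9, 0), geom) - 1), 1e-6)
    }
    z <- seq(b$alpha, b$beta, length.out = 1001)
    H <- wall_profile(z, geom)
    extremum <- if (p[1] >= 0) min(H) else max(H)
    expect_equal(extremum, 1 - p[1], tolerance = 1e-9)
    expect_equal(z[which(H == extremum)[1]], (b$alpha + b$beta) / 2,
                 tolerance = 1e-3)
  }
})

test_that("segment construction rejects non-physical lesions", {
  expect_error(abnormal_segment(1, 0.2, 0.2, "stenosis"), "height must be < 1")
  expect_error(abnormal_segment(-0.1, 0.2, 0.2, "stenosis"), "magnitude")
  expect_error(abnormal_segment(0.1, 0, 0.2, "stenosis"), "positive")
  expect_error(abnormal_segment(0.1, 0.2, -0.1, "stenosis"), "non-negative")
  expect_error(vessel_geometry(list(abnormal_segment(0.1, 0.2, 0.2, "stenosis")),
                               domain_length = 0.3),
               "ends before the last segment")
  expect_error(vessel_geometry(list("not a segment")), "bad index 1")
})

test_that("mild-stenosis validation reports height ratios", {
  # the anchor lesion height/length ratio exceeds a literal 'much smaller'
  geom <- vessel_geometry(list(abnormal_segment(0.2, 0.2, 0.2, "stenosis")))
  rep1 <- validate_mild_stenosis(geom, tolerance = 0.3)
  expect_equal(rep1$ratio_length, 1.0)
  expect_equal(rep1$ratio_radius, 0.2)
  expect_true(rep1$flagged)
  expect_false(attr(rep1, "pass"))
  expect_error(validate_mild_stenosis(geom, strict = TRUE), "violated")

  geom2 <- vessel_geometry(list(abnormal_segment(0.05, 0.2, 0.2, "stenosis")))
  rep2 <- validate_mild_stenosis(geom2, tolerance = 0.3)
  expect_equal(rep2$ratio_length, 0.25)
  expect_equal(rep2$ratio_radius, 0.05)
  expect_false(rep2$flagged)

  rep0 <- validate_mild_stenosis(vessel_geometry())
  expect_equal(nrow(rep0), 0)
  expect_true(attr(rep0, "pass"))
})

test_that("throat resolves to the first non-zero lesion midpoint", {
  expect_equal(throat_station(two_lesion_geometry()), 0.3)
  expect_equal(throat_station(two_lesion_geometry(delta1 = 0)), 1.1)
  expect_error(throat_station(two_lesion_geometry(0, 0)), "no abnormal segment")
})
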