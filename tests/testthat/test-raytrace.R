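test_that("Snell refraction reproduces textbook angles and signals TIR", {
  # normal incidence: direction unchanged
  expect_equal(refract_snell(c(0, 1), c(0, -1), 1.0, 1.376), c(0, 1))
  # 30 degrees into the cornea -> 21.312 degrees
  d <- c(sin(pi / 6), cos(pi / 6))
  t <- refract_snell(d, c(0, -1), 1.0, 1.376)
  expect_equal(asin(t[1]), asin(0.5 / 1.376), tolerance = 1e-12)
  expect_equal(asin(t[1]) * 180 / pi, 21.3074, tolerance = 1e-4)
  expect_equal(sum(t^2), 1, tolerance = 1e-14)
  # total internal reflection leaving a dense medium at 80 degrees
  d80 <- c(sin(80 * pi / 180), cos(80 * pi / 180))
  expect_error(refract_snell(d80, c(0, -1), 1.376, 1.0),
               class = "corneatrace_tir")
  expect_error(refract_snell(c(0, 2), c(0, -1), 1, 1.376), "unit vectors")
})

test_that("ray fans are uniformly spaced, symmetric and area-weighted", {
  fan <- build_fan(4.408, 1001)
  expect_length(fan$heights, 1001)
  expect_equal(diff(fan$heights)[1], 4.408 / 1000)
  expect_equal(range(fan$heights), c(-2.204, 2.204))
  expect_equal(sum(fan$weights), 1, tolerance = 1e-12)
  expect_identical(fan$heights, -rev(fan$heights))  # exact mirror pairs
  expect_identical(fan$weights, rev(fan$weights))
  expect_equal(fan$heights[501], 0)                 # chief ray, zero weight
  expect_equal(fan$weights[501], 0)

  expect_equal(build_fan(3, 3)$weights, c(0.5, 0, 0.5))
  # fan-weighted mean of r^2 equals the disk average PUP^2/8
  pup <- 4.408
  m2 <- sum(fan$weights * fan$heights^2)
  expect_equal(m2, pup^2 / 8, tolerance = 1e-3 * pup^2 / 8)
  # quadratic weighting variant
  fq <- build_fan(4.408, 1001, weighting = "quadratic")
  expect_equal(fq$weights, fan$heights^2 / sum(fan$heights^2))
  expect_error(build_fan(-1, 101), "positive")
  expect_error(build_fan(4, 2), "at least 3")
})

test_that("the chief ray exits undeviated with OPL = n_cornea * CCT", {
  tf <- trace_eye(mean_cornea(), build_fan(4.408, 101))
  chief <- 51
  expect_equal(tf$y[chief], 0)
  expect_equal(tf$z[chief], 0.547)
  expect_equal(c(tf$dy[chief], tf$dz[chief]), c(0, 1))
  expect_equal(tf$opl[chief], 1.376 * 0.547, tolerance = 1e-12)
})

test_that("paraxial rays follow the Gaussian-optics transfer oracle", {
  tf <- trace_eye(mean_cornea(), build_fan(0.02, 3))  # rays at +/- 0.01 mm
  h <- 0.01
  slope_ref <- paraxial_exit_slope_oracle(h, 7.733, 6.534, 0.547)
  expect_equal(tf$dy[3] / tf$dz[3], slope_ref, tolerance = 1e-6)
})

test_that("traced fans are mirror-symmetric and conserve weights", {
  fan <- build_fan(4.408, 201)
  tf <- trace_eye(mean_cornea(), fan)
  expect_identical(tf$y, -rev(tf$y))
  expect_identical(tf$z, rev(tf$z))
  expect_identical(tf$dy, -rev(tf$dy))
  expect_identical(tf$opl, rev(tf$opl))
  expect_identical(tf$weights, fan$weights)
  expect_true(all(tf$opl > 0))
  expect_equal(sqrt(tf$dy^2 + tf$dz^2), rep(1, 201), tolerance = 1e-12)
})

test_that("OPL at a fixed height is invariant under fan refinement", {
  eye <- mean_cornea()
  t1 <- trace_eye(eye, build_fan(4.408, 101))
  t2 <- trace_eye(eye, build_fan(4.408, 1001))
  # marginal rays at +/- PUP/2 exist in both fans
  expect_equal(t1$opl[c(1, 101)], t2$opl[c(1, 1001)], tolerance = 1e-13)
})

test_that("a single spherical surface focuses small-aperture rays at n2 R/(n2-n1)", {
  R <- 7.733; n2 <- 1.376
  s <- conic_surface(R, 0)
  f_ref <- n2 * R / (n2 - 1)            # paraxial focus of one surface
  for (h in c(1e-3, 5e-4)) {
    p <- ray_surface_intersection(c(h, -1), c(0, 1), s)
    n <- surface_normal(s, p[1])
    d <- refract_snell(c(0, 1), n, 1.0, n2)
    z_cross <- p[2] - p[1] * d[2] / d[1]
    expect_equal(z_cross, f_ref, tolerance = 1e-4)
  }
})

test_that("rays outside the surface extent raise a miss condition", {
  eye <- cornea_model(7.733, 0, 6.534, 0, 0.547)   # spherical, extent 7.733
  expect_error(trace_eye(eye, build_fan(16, 11)), class = "corneatrace_miss")
})
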