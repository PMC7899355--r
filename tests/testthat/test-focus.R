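test_that("the wavefront-circle preset recovers a stigmatic focus exactly", {
  tb <- stigmatic_bundle(z_focus = 30)
  expect_equal(initial_focus_guess(tb), 30, tolerance = 1e-9)
})

test_that("the preset matches the paraxial focus for a narrow fan", {
  tf <- trace_eye(mean_cornea(), build_fan(0.2, 101))
  z_ref <- paraxial_focus_oracle(7.733, 6.534, 0.547)
  expect_equal(initial_focus_guess(tf), z_ref, tolerance = 0.01)
  expect_equal(z_ref, 31.289, tolerance = 1e-3)
})

test_that("an afocal exit bundle raises a no-focus condition", {
  tb <- stigmatic_bundle()
  tb$dy <- rep(0, length(tb$dy)); tb$dz <- rep(1, length(tb$dz))
  tb$opl <- rep(1, length(tb$opl))   # plano wavefront, parallel rays
  expect_error(initial_focus_guess(tb), class = "corneatrace_nofocus")
  one <- stigmatic_bundle(n = 3)   # chief + 2 rays < 3 non-axial
  one$y <- one$y * 1e-14
  expect_error(initial_focus_guess(one), "non-axial")
})

test_that("all four metrics vanish at a stigmatic focus and for degenerate fans", {
  tb <- stigmatic_bundle(z_focus = 30)
  for (cr in c("WF", "RMS", "MA", "TSD"))
    expect_lt(focus_metric(tb, 30, cr), 1e-10)
  # single-ray bundle: no scatter, no wavefront deviation at any plane
  single <- stigmatic_bundle()
  keep <- 11   # one off-axis ray
  for (f in c("y", "z", "dy", "dz", "opl", "weights"))
    single[[f]] <- single[[f]][keep]
  single$weights <- 1
  expect_equal(focus_metric(single, 25, "WF"), 0)
  y25 <- single$y + (25 - single$z) * single$dy / single$dz
  expect_equal(focus_metric(single, 25, "RMS"), abs(y25))
  expect_error(focus_metric(stigmatic_bundle(), 2, "RMS"), "behind")
})

test_that("best focus minimizes its criterion and is bracketed by the preset", {
  eyes <- random_corneas(12, seed = 301)
  for (i in seq_len(nrow(eyes))) {
    e <- eyes[i, ]
    cm <- cornea_model(e$R_f, e$Q_f, e$R_b, e$Q_b, e$CCT)
    tf <- trace_eye(cm, build_fan(e$PUP, 301))
    guess <- initial_focus_guess(tf)
    for (cr in c("WF", "RMS", "MA", "TSD")) {
      zf <- best_focus(tf, cr)
      expect_lt(abs(zf - guess), 2)
      vals <- vapply(seq(zf - 2, zf + 2, length.out = 200),
                     function(z) focus_metric(tf, z, cr), numeric(1))
      expect_lte(focus_metric(tf, zf, cr), min(vals) * (1 + 1e-9))
    }
  }
})

test_that("deterministic and annealing searches agree", {
  tf <- trace_eye(mean_cornea(), build_fan(4.408, 301))
  for (cr in c("WF", "RMS", "MA")) {
    zb <- best_focus(tf, cr, method = "brent")
    za <- best_focus(tf, cr, method = "anneal", seed = 99)
    expect_equal(za, zb, tolerance = 1e-4)
  }
})

test_that("all four criteria converge to the paraxial focus at small aperture", {
  eye <- mean_cornea()
  tf <- trace_eye(eye, build_fan(0.5, 101))
  z_ref <- paraxial_focus_oracle(7.733, 6.534, 0.547)
  cp_ref <- paraxial_power_oracle(7.733, 6.534, 0.547)
  zs <- vapply(c("WF", "RMS", "MA", "TSD"),
               function(cr) best_focus(tf, cr), numeric(1))
  expect_lt(max(zs) - min(zs), 0.02)
  expect_equal(unname(power_from_focus(zs)), rep(cp_ref, 4), tolerance = 0.02 / cp_ref)
  expect_equal(cp_ref, 42.70, tolerance = 2e-4)
})

test_that("power and keratometric conversions are exact and invert", {
  expect_equal(power_from_focus(31.0669), 43.0042, tolerance = 1e-4)
  expect_equal(power_from_focus(31.1353), 42.9097, tolerance = 1e-4)
  expect_equal(power_from_focus(26.72), 50)
  expect_equal(1000 * 1.336 / power_from_focus(28.4), 28.4)  # round trip
  expect_error(power_from_focus(-1), "positive")
  expect_equal(keratometric_power(7.5, 1.3375), 45)
  expect_equal(keratometric_power(7.733, 1.3317), 42.8941, tolerance = 1e-4)
  expect_equal(keratometric_power(7.733, 1.0), 0)
  expect_error(keratometric_power(0), "positive")
})

test_that("the pipeline result satisfies CP * z_F = 1000 n_aqueous per criterion", {
  tf <- trace_eye(mean_cornea(), build_fan(4.408, 301))
  foci <- find_best_foci(tf)
  expect_equal(unname(foci$CP * foci$z_F), rep(1336, 4), tolerance = 1e-9)
  expect_equal(unname(foci$nK), unname(1 + foci$CP * 7.733 / 1000))
  # best planes of the spot criteria are ordered TSD < RMS < MA for
  # positive spherical aberration; the fixed-zone wavefront plane is shortest
  expect_true(foci$z_F["WF"] < foci$z_F["TSD"])
  expect_true(foci$z_F["TSD"] < foci$z_F["RMS"])
  expect_true(foci$z_F["RMS"] < foci$z_F["MA"])
})
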