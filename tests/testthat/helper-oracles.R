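# Independent oracles and shared fixtures for the test suite.

# Population-mean cornea of the cohort (radii/CCT mm, CCT 547 um)
mean_cornea <- function() cornea_model(7.733, -0.3141, 6.534, -0.007, 0.547)

table1_means <- data.frame(R_f = 7.733, Q_f = -0.3141, R_b = 6.534,
                           Q_b = -0.007, CCT = 0.547, PUP = 4.408)

# Paraxial (Gaussian-optics) oracle: vergence propagation through the
# two-surface thick lens; returns back focal point measured from the front
# apex (mm). Independent of the raytracing kernel.
paraxial_focus_oracle <- function(R_f, R_b, CCT, n_c = 1.376, n_a = 1.336) {
  P1 <- 1000 * (n_c - 1) / R_f
  P2 <- 1000 * (n_a - n_c) / R_b
  V <- P1 / (1 - (CCT / 1000 / n_c) * P1)  # vergence at the back surface
  V <- V + P2
  1000 * n_a / V + CCT
}

paraxial_power_oracle <- function(R_f, R_b, CCT, n_c = 1.376, n_a = 1.336) {
  1000 * n_a / paraxial_focus_oracle(R_f, R_b, CCT, n_c, n_a)
}

# Paraxial exit slope (n u' = n u - h P per surface, translation in between)
# for a collimated input ray at height h.
paraxial_exit_slope_oracle <- function(h, R_f, R_b, CCT,
                                       n_c = 1.376, n_a = 1.336) {
  P1 <- 1000 * (n_c - 1) / R_f
  P2 <- 1000 * (n_a - n_c) / R_b
  u1 <- -h * P1 / 1000 / n_c
  h2 <- h + CCT * u1
  (n_c * u1 - h2 * P2 / 1000) / n_a
}

# Brute-force bisection solver for a ray/conic intersection: root of
# z(t) - (z0 + sag(y(t))) on [0, t_hi].
bisect_intersection_oracle <- function(surface, origin, direction,
                                       t_hi = 30, tol = 1e-12) {
  g <- function(t) {
    y <- origin[1] + t * direction[1]
    z <- origin[2] + t * direction[2]
    z - (surface$z0 + conic_sag(surface, y))
  }
  lo <- 0; hi <- t_hi
  if (g(lo) > 0 || g(hi) < 0) stop("oracle: bracket does not straddle root")
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (g(mid) <= 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# Grid-search oracle for the least-squares keratometer index.
grid_nk_oracle <- function(CP, R_f, lo = 1.30, hi = 1.36, step = 1e-6) {
  grid <- seq(lo, hi, by = step)
  x <- 1000 / R_f
  sse <- vapply(grid, function(nk) sum((CP - (nk - 1) * x)^2), numeric(1))
  grid[which.min(sse)]
}

# Hand-held stigmatic exit bundle: rays that all pass through (0, z_focus)
# with identical total optical path; exercises focus metrics and the preset
# without the raytracing kernel.
stigmatic_bundle <- function(z_focus = 30, n = 21, y_max = 2, z_exit = 5,
                             cornea = mean_cornea()) {
  y <- seq(-y_max, y_max, length.out = n)
  dz <- z_focus - z_exit
  len <- sqrt(y^2 + dz^2)
  dyu <- -y / len; dzu <- dz / len
  n_aq <- cornea$constants$n_aqueous
  opl <- 60 - n_aq * len   # equal OPL at the focus by construction
  w <- abs(y); w <- w / sum(w)
  structure(list(y = y, z = rep(z_exit, n), dy = dyu, dz = dzu,
                 opl = opl, weights = w, cornea = cornea,
                 fan = build_fan(2 * y_max, n)),
            class = "traced_fan")
}

# Synthetic OPD map from given radial Zernike coefficients (um), OSA
# normalization, over a 6 mm zone.
synthetic_opd_map <- function(Z00 = 0, Z20 = 0, Z40 = 0, Z60 = 0,
                              n = 101, zone = 6) {
  r <- seq(-zone / 2, zone / 2, length.out = n)
  rho <- abs(r) / (zone / 2)
  opd <- Z00 +
    Z20 * sqrt(3) * (2 * rho^2 - 1) +
    Z40 * sqrt(5) * (6 * rho^4 - 6 * rho^2 + 1) +
    Z60 * sqrt(7) * (20 * rho^6 - 30 * rho^4 + 12 * rho^2 - 1)
  w <- abs(r); w <- w / sum(w)
  structure(list(radii = r, opd = opd, weights = w, focus_plane = 31,
                 zone_diameter = zone),
            class = "opd_map")
}

# Random plausible corneas drawn from the population generator.
random_corneas <- function(n, seed) sample_population(population_spec(n, seed = seed))
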