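test_that("published models evaluate to their frozen hand-computed values", {
  # hand evaluation of the printed equations at the cohort mean covariates
  expect_equal(evaluate_printed_model(1, table1_means), 43.013197,
               tolerance = 1e-6)
  expect_equal(evaluate_printed_model(3, table1_means), 42.815989,
               tolerance = 1e-6)
  # prediction decomposes into keratometric offset + intercept + effects
  set.seed(5)
  eye <- data.frame(R_f = 7.9, Q_f = -0.2, R_b = 6.6, Q_b = 0.05,
                    CCT = 0.52, PUP = 3.7)
  m <- printed_model(2)
  manual <- 1000 * (m$n_K - 1) / eye$R_f + m$b0 + m$bRf * eye$R_f +
    m$bQf * eye$Q_f + m$bRb * eye$R_b + m$bQb * eye$Q_b +
    m$bCCT * eye$CCT + m$bPUP * eye$PUP
  expect_equal(evaluate_printed_model(2, eye), manual)
  expect_error(evaluate_printed_model(5, eye), "model_id")
  expect_identical(vapply(1:4, function(k) printed_model(k)$criterion,
                          character(1)),
                   c("WF", "RMS", "MA", "TSD"))
})

test_that("keratometer index fitting inverts single eyes and matches grid search", {
  # single eye: both modes give the closed-form inversion
  expect_equal(fit_keratometer_index(43.00, 7.720, "least_squares"),
               1.33196, tolerance = 1e-8)
  expect_equal(fit_keratometer_index(43.00, 7.720, "mean_zero"),
               1.33196, tolerance = 1e-8)
  # degenerate population of identical eyes
  expect_equal(fit_keratometer_index(rep(43, 50), rep(7.72, 50)),
               fit_keratometer_index(43, 7.72))
  # least-squares equals a brute-force grid search
  set.seed(21)
  R_f <- runif(200, 7.0, 8.5)
  CP <- 1000 * 0.3315 / R_f + rnorm(200, sd = 0.2)
  nk <- fit_keratometer_index(CP, R_f)
  expect_equal(nk, grid_nk_oracle(CP, R_f), tolerance = 1e-5)
  # mean-zero mode zeroes the mean deviation exactly
  nk0 <- fit_keratometer_index(CP, R_f, "mean_zero")
  expect_equal(mean(CP - keratometric_power(R_f, nk0)), 0, tolerance = 1e-12)
  expect_error(fit_keratometer_index(numeric(0), numeric(0)), "nonempty")
})

test_that("the power-model fit recovers generating coefficients", {
  set.seed(42)
  n <- 400
  eyes <- data.frame(R_f = runif(n, 7, 8.5), Q_f = runif(n, -0.8, 0.2),
                     R_b = runif(n, 5.8, 7.2), Q_b = runif(n, -0.5, 0.4),
                     CCT = runif(n, 0.45, 0.65), PUP = runif(n, 2, 6))
  truth <- printed_model(3)
  CP <- predict_corneal_power(truth, eyes)
  # noise-free: exact linear recovery
  fit <- fit_power_model(eyes, CP, truth$n_K)
  for (b in c("b0", "bRf", "bQf", "bRb", "bQb", "bCCT", "bPUP"))
    expect_equal(fit[[b]], truth[[b]], tolerance = 1e-8)
  expect_lt(fit$rms_error, 1e-10)

  # Gaussian noise: coefficients within 3 standard errors, n = 5000
  set.seed(7)
  n2 <- 5000
  eyes2 <- data.frame(R_f = runif(n2, 7, 8.5), Q_f = runif(n2, -0.8, 0.2),
                      R_b = runif(n2, 5.8, 7.2), Q_b = runif(n2, -0.5, 0.4),
                      CCT = runif(n2, 0.45, 0.65), PUP = runif(n2, 2, 6))
  CP2 <- predict_corneal_power(truth, eyes2) + rnorm(n2, sd = 0.05)
  fit2 <- fit_power_model(eyes2, CP2, truth$n_K)
  y <- CP2 - 1000 * (truth$n_K - 1) / eyes2$R_f
  se <- summary(lm(y ~ R_f + Q_f + R_b + Q_b + CCT + PUP,
                   data = eyes2))$coefficients[, "Std. Error"]
  est <- c(fit2$b0, fit2$bRf, fit2$bQf, fit2$bRb, fit2$bQb, fit2$bCCT,
           fit2$bPUP)
  tru <- c(truth$b0, truth$bRf, truth$bQf, truth$bRb, truth$bQb, truth$bCCT,
           truth$bPUP)
  expect_true(all(abs(est - tru) < 3 * se))
  expect_error(fit_power_model(eyes[1:5, ], CP[1:5], 1.3317), "at least 8")
  dup <- eyes; dup$R_b <- dup$R_f
  dup$Q_b <- dup$Q_f; dup$CCT <- 2 * dup$R_f; dup$PUP <- -dup$R_f
  expect_error(fit_power_model(dup, CP, 1.3317), "rank-deficient")
})

test_that("coefficient recovery is unbiased over repeated noisy fits", {
  truth <- printed_model(3)
  reps <- 100
  err <- matrix(NA_real_, reps, 7)
  for (k in seq_len(reps)) {
    set.seed(1000 + k)
    n <- 300
    eyes <- data.frame(R_f = runif(n, 7, 8.5), Q_f = runif(n, -0.8, 0.2),
                       R_b = runif(n, 5.8, 7.2), Q_b = runif(n, -0.5, 0.4),
                       CCT = runif(n, 0.45, 0.65), PUP = runif(n, 2, 6))
    CP <- predict_corneal_power(truth, eyes) + rnorm(n, sd = 0.05)
    f <- fit_power_model(eyes, CP, truth$n_K)
    err[k, ] <- c(f$b0 - truth$b0, f$bRf - truth$bRf, f$bQf - truth$bQf,
                  f$bRb - truth$bRb, f$bQb - truth$bQb, f$bCCT - truth$bCCT,
                  f$bPUP - truth$bPUP)
  }
  bias <- colMeans(err)
  se_mean <- apply(err, 2, sd) / sqrt(reps)
  expect_true(all(abs(bias) < 4 * se_mean))
})

test_that("model coefficients survive a JSON round trip", {
  m <- printed_model(4)
  path <- withr::local_tempfile(fileext = ".json")
  write_model_coefficients(m, path)
  back <- read_model_coefficients(path)
  for (f in c("n_K", "b0", "bRf", "bQf", "bRb", "bQb", "bCCT", "bPUP"))
    expect_identical(back[[f]], m[[f]])
  expect_identical(back$criterion, "TSD")
})
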