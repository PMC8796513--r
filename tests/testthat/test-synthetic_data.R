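test_that("analytic pulse conserves the dose away from the boundaries", {
  sp <- synthetic_spec(advection_speed = 5, dispersion = 1,
                       injection_site = 38, dose = 0.425)
  truth <- analytic_pulse_matrix(sp)
  dzc <- sp$dz / 1e4
  mass <- colSums(truth$values) * sp$area * dzc / 1000  # umol per column
  # quadrature error below 0.1% while the pulse is clear of the domain ends
  interior <- truth$t_samples <= 60
  expect_true(all(abs(mass[interior] - sp$dose) / sp$dose < 1e-3))
  expect_true(all(truth$values >= 0))
  # t = 0 column is the deposited delta
  expect_equal(sum(truth$values[, 1] > 0), 1L)
})

test_that("limiting cases: pure translation and pure spreading", {
  # D -> 0: the pulse translates at the advection speed
  sp <- synthetic_spec(advection_speed = 10, dispersion = 0,
                       injection_site = 20, n_time = 61)
  tr <- analytic_pulse_matrix(sp)
  peaks <- apply(tr$values, 2, which.max)
  zpk <- tr$z_centers[peaks]
  fit <- lm(zpk ~ tr$t_samples)
  expect_equal(unname(coef(fit)[2]) * 60, 10, tolerance = 0.02)
  # u = 0: symmetric spreading about the release site
  sp0 <- synthetic_spec(advection_speed = 0, dispersion = 2,
                        injection_site = 38)
  sym <- analytic_pulse_matrix(sp0)
  centroids <- apply(sym$values[, -1], 2, function(w)
    sum(sym$z_centers * w) / sum(w))   # t = 0 holds the one-cell delta
  expect_true(all(abs(centroids - 38) < 0.05))
})

test_that("moment recovery returns the generating parameters", {
  sp <- synthetic_spec(advection_speed = 10, dispersion = 1)
  rec <- recover_transport_parameters(analytic_pulse_matrix(sp))
  expect_rel_equal(rec$advection_cm_h, 10, 0.02)
  expect_rel_equal(rec$dispersion_mm2_s, 1, 0.02)
  # with 1%-of-peak measurement noise, recovery holds within 5%
  truth <- analytic_pulse_matrix(sp)
  noisy <- make_pseudo_experiment(truth, 0.01 * max(truth$values[, -1]),
                                  seed = 42)
  recn <- recover_transport_parameters(noisy)
  expect_rel_equal(recn$advection_cm_h, 10, 0.05)
  expect_rel_equal(recn$dispersion_mm2_s, 1, 0.05)
  # a stationary delta recovers (0, 0)
  spd <- synthetic_spec(advection_speed = 0, dispersion = 0)
  recd <- recover_transport_parameters(analytic_pulse_matrix(spd))
  expect_equal(recd$advection_cm_h, 0, tolerance = 1e-8)
  expect_equal(recd$dispersion_mm2_s, 0, tolerance = 1e-8)
})

test_that("front speed on a translating pulse matches the set speed", {
  sp <- synthetic_spec(advection_speed = -31, dispersion = 0.3,
                       injection_site = 60, n_axial = 400, dz = 1900,
                       n_time = 121, dt = 60000)
  # negative speed = cranially directed in this grid convention
  stc <- analytic_pulse_matrix(sp)
  expect_equal(front_speed(stc, 0.05, c(0, 120)), 31, tolerance = 0.02 * 31)
})

test_that("pseudo-experiments are reproducible and clipped at zero", {
  truth <- analytic_pulse_matrix(synthetic_spec(dispersion = 1))
  expect_identical(make_pseudo_experiment(truth, 0, seed = 1)$values,
                   truth$values)
  a <- make_pseudo_experiment(truth, 0.5, seed = 7)
  b <- make_pseudo_experiment(truth, 0.5, seed = 7)
  expect_identical(a$values, b$values)
  d <- make_pseudo_experiment(truth, 0.5, seed = 8)
  expect_false(identical(a$values, d$values))
  expect_true(all(a$values >= 0))
  # the caller RNG stream is untouched
  set.seed(99); x1 <- rnorm(3)
  set.seed(99); invisible(make_pseudo_experiment(truth, 0.5, seed = 7))
  x2 <- rnorm(3)
  expect_identical(x1, x2)
})

test_that("noise level inversion reproduces a requested limit of agreement", {
  truth <- analytic_pulse_matrix(synthetic_spec(dispersion = 1.5,
                                                n_axial = 120, n_time = 121))
  target <- 1.20
  sd0 <- noise_sd_for_loa(truth, target)
  expect_gt(sd0, target / 1.96)   # clipping always inflates the needed sd
  noisy <- make_pseudo_experiment(truth, sd0, seed = 11)
  ba <- bland_altman(pair_matrices(noisy, truth))
  expect_equal(ba$loa_halfwidth, target, tolerance = 0.03 * target)
})

test_that("moment recovery rejects genuinely bimodal fields", {
  z <- seq(0.5, 99.5, by = 1)
  prof <- 5 * gaussian_profile(z, 30, 3) + 5 * gaussian_profile(z, 70, 3)
  vals <- matrix(rep(prof, 5), ncol = 5)
  stc <- stc_matrix(vals, z, seq(0, 40, by = 10))
  expect_error(recover_transport_parameters(stc), "multi-modal")
})
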