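core_to_stc <- function(res, dz_cm, area = 2) {
  n <- nrow(res$conc)
  stc_matrix(res$conc, (seq_len(n) - 0.5) * dz_cm, res$t_s / 60)
}

test_that("closed-domain transport conserves mass and stays positive", {
  n <- 300; dz <- 0.2
  z <- (seq_len(n) - 0.5) * dz
  c0 <- 10 * gaussian_profile(z, 30, 3)
  res <- run_core_uniform(c0, u_cm_s = 2e-3, D_cm2_s = 5e-4, dz_cm = dz,
                          dt = 0.5, t_end_s = 5000, out_every = 1000,
                          absorbing = FALSE)
  m0 <- sum(c0) * 2 * dz
  m1 <- res$mass_in_model_nmol
  expect_lt(abs(m1 - m0) / m0, 1e-6)   # 1e4 steps, reflecting walls
  expect_gte(min(res$conc), -1e-12)
  expect_equal(res$outflow_total_nmol, 0)
})

test_that("advection matches a translated pulse at first order or better", {
  u <- 0.01; t_end <- 1500
  err <- sapply(c(0.2, 0.1), function(dz) {
    n <- round(80 / dz)
    z <- (seq_len(n) - 0.5) * dz
    c0 <- gaussian_profile(z, 20, 2.5)
    dt <- dz / 0.2 * 0.5                       # fixed CFL across levels
    n_steps <- round(t_end / dt)
    res <- run_core_uniform(c0, u, 0, dz, dt = dt, t_end_s = t_end,
                            out_every = n_steps, absorbing = FALSE)
    cT <- res$conc[, 2]                        # final state
    exact <- gaussian_profile(z, 20 + u * t_end, 2.5)
    sqrt(sum((cT - exact)^2) * dz)
  })
  expect_gt(err[1] / err[2], 1.8)   # halving dz at fixed CFL
})

test_that("solver reproduces the analytic advection-dispersion oracle", {
  # uniform coefficients, pulse well inside the domain: the moment
  # estimator applied to the solver output must return the inputs
  n <- 400; dz <- 0.19
  z <- (seq_len(n) - 0.5) * dz
  c0 <- 20 * gaussian_profile(z, 25, 1.5)
  u <- 10 / 3600          # 10 cm/h caudad
  D <- 1.5 / 100          # 1.5 mm^2/s in cm^2/s
  res <- run_core_uniform(c0, u, D, dz, dt = 0.5, t_end_s = 3 * 3600,
                          out_every = 360, absorbing = FALSE)
  stc <- core_to_stc(res, dz)
  rec <- recover_transport_parameters(stc)
  expect_rel_equal(rec$advection_cm_h, 10, 0.05)
  expect_rel_equal(rec$dispersion_mm2_s, 1.5, 0.05)
})

test_that("a tracer-free bolus leaves the system at zero concentration", {
  sc <- scenario_config(name = "water", stock_concentration = 0,
                        duration = 30)
  sim <- simulate_transport(sc, geom = coarse_geom(), dt = 0.2,
                            output_dt = 60)
  expect_equal(max(sim$values), 0)
  expect_equal(injected_dose(sc), 0)
})

test_that("scenario simulations close the mass ledger and start clean", {
  sim <- cached_sim("LP")
  expect_equal(sim$values[, 1], rep(0, nrow(sim$values)))  # pre-injection
  expect_gte(min(sim$values), 0)
  ml <- mass_ledger(sim)
  expect_equal(ml$injected, injected_dose(scenario_from_table("LP")),
               tolerance = 1e-9)
  expect_lt(ml$closure_error, 1e-6)
})

test_that("streaming field obeys its closure and physiologic bounds", {
  g <- reference_geom()
  p <- physiology_params()
  # zero-amplitude flow and zero production: no transport at all
  still <- csftransport:::new_flow_waveform(seq(0, 0.9, length.out = 65),
                                            rep(0, 65), "cardiac", 0.9)
  f0 <- steady_streaming_profile(g, still,
                                 physiology_params(production_rate = 1e-12))
  expect_true(all(abs(f0$mean_velocity) < 1e-9))
  expect_equal(f0$effective_dispersion,
               rep(default_calibration()$D_base, g$n_axial))
  # doubling the waveform amplitude quadruples the dispersion component
  w1 <- cardiac_waveform(1); w2 <- cardiac_waveform(2)
  f1 <- steady_streaming_profile(g, w1, p)
  f2 <- steady_streaming_profile(g, w2, p)
  d1 <- f1$effective_dispersion - default_calibration()$D_base
  d2 <- f2$effective_dispersion - default_calibration()$D_base
  expect_equal(d2, 4 * d1, tolerance = 1e-6)
  # oscillatory amplitudes within the physiologic 0-15 cm/s envelope
  expect_true(all(f1$oscillatory_amplitude >= 0 &
                    f1$oscillatory_amplitude <= 15))
  expect_true(all(f1$effective_dispersion >= 0))
  # cervical streaming within three times the lumbar value
  reg <- region_at(g, g$z_centers)
  ratio <- abs(mean(f1$streaming_velocity[reg == "cervical"])) /
    abs(mean(f1$streaming_velocity[reg == "lumbar"]))
  expect_lte(ratio, 3)
  expect_gt(ratio, 1)   # but clearly elevated
})

test_that("protocol and dispersion responses are monotone", {
  g <- coarse_geom()
  run <- function(sc, cal = default_calibration())
    simulate_transport(sc, geom = g, calibration = cal, dt = 0.2,
                       output_dt = 30)
  # larger bolus at the same tracer concentration cannot lower cranial AUC
  small <- run(scenario_config(duration = 60))
  big <- run(scenario_config(bolus_volume = 15, duration = 60))
  ca <- function(s) compartment_summary(s)$AUC_uMh[1]
  expect_gte(ca(big), ca(small))
  # stronger effective dispersion cannot slow the front
  cal_hi <- default_calibration(alpha = 0.4)
  lo <- run(scenario_config(duration = 120))
  hi <- run(scenario_config(duration = 120), cal_hi)
  expect_gte(front_speed(hi, window = c(0, 120)),
             front_speed(lo, window = c(0, 120)))
})

test_that("ventricular compartments route production and retain ICV dose", {
  lp <- cached_sim("LP")
  expect_equal(ventricular_retention(lp, "lateral_L", 0), 0)
  icv <- cached_sim("ICV")
  # at the end of the bolus most of the dose still sits in the ventricle
  end_bolus <- ventricular_retention(icv, "lateral_L", 1)
  expect_lte(end_bolus, 1)
  expect_gt(end_bolus, 0.5)
  # after 3 h only a few percent remain (production washout)
  expect_lt(ventricular_retention(icv, "lateral_L", 180), 0.10)
  expect_gt(ventricular_retention(icv, "lateral_L", 180), 0.01)
  # the right ventricle never sees tracer (production blocks backflow)
  expect_equal(ventricular_retention(icv, "lateral_R", 180), 0)
  expect_error(ventricular_retention(icv, "pineal", 10), "unknown")
  expect_error(ventricular_retention(icv, "lateral_L", 500), "horizon")
})

test_that("time-step limits are enforced with an informative error", {
  g <- coarse_geom()
  expect_error(
    simulate_transport(scenario_config(bolus_rate = 2000, duration = 10),
                       geom = g, dt = 5, output_dt = 60),
    "dt")
})

test_that("halving grid and step leaves 3-h exposure profiles within 2%", {
  base <- cached_sim("LP")
  fine_geom <- build_neuraxis_geometry(list(dz = 190))
  fine <- simulate_transport("LP", geom = fine_geom, dt = 0.025,
                             output_dt = 9)
  auc_c <- auc_profile(base)
  auc_f <- auc_profile(fine)
  # average refined pairs of cells onto the coarse grid
  auc_f2 <- (auc_f[seq(1, length(auc_f), 2)] +
               auc_f[seq(2, length(auc_f), 2)]) / 2
  sig <- auc_c > 0.01 * max(auc_c)
  rel <- abs(auc_c[sig] - auc_f2[sig]) / max(auc_c)
  expect_lt(max(rel), 0.02)
})
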