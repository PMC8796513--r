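test_that("default geometry discretizes 76 cm at 380 microns into 2000 cells", {
  g <- build_neuraxis_geometry()
  expect_equal(g$total_length, 76)
  expect_equal(g$dz, 0.038)
  expect_equal(g$n_axial, 2000L)
  # scaling: a tenth of the domain at the same spacing
  g10 <- build_neuraxis_geometry(list(total_length = 7.6))
  expect_equal(g10$n_axial, 200L)
})

test_that("geometry regions partition the axial domain and areas are positive", {
  g <- build_neuraxis_geometry()
  rb <- g$region_bounds[order(g$region_bounds$z_from), ]
  expect_equal(rb$z_from[1], 0)
  expect_equal(rb$z_to[nrow(rb)], g$total_length)
  expect_equal(rb$z_from[-1], rb$z_to[-nrow(rb)])   # no gaps, no overlap
  expect_true(all(g$area_profile > 0))
  expect_true(all(g$ventricle_branch$volumes > 0))
  # every cell maps to exactly one region
  expect_false(anyNA(region_at(g, g$z_centers)))
  # ventricle junction lies inside the basal cistern
  bc <- rb[rb$region == "basal_cistern", ]
  expect_gte(g$ventricle_branch$junction_z, bc$z_from)
  expect_lte(g$ventricle_branch$junction_z, bc$z_to)
  # total CSF volume is physiologic
  expect_gt(csf_volume(g), 250)
  expect_lt(csf_volume(g), 400)
})

test_that("invalid geometry parameters are rejected", {
  expect_error(build_neuraxis_geometry(list(total_length = -1)), "positive")
  expect_error(build_neuraxis_geometry(list(dz = 0)), "positive")
  expect_error(build_neuraxis_geometry(list(nonsense = 1)), "unknown")
  expect_error(build_neuraxis_geometry(list(foramen_magnum_z = 100)),
               "inside")
})

test_that("physiology defaults give 576 mL/day production and tile the breath", {
  p <- physiology_params()
  expect_equal(daily_production_volume(p), 576)
  expect_equal(daily_production_volume(physiology_params(production_rate = 1)),
               1440)
  expect_equal(p$cardiac_cycles_per_breath * p$cardiac_period,
               p$respiratory_period)
  expect_error(physiology_params(respiratory_period = 20), "within 2%")
  expect_error(physiology_params(production_rate = -1), "positive")
})

test_that("cardiac waveform hits the requested stroke volume within 0.1%", {
  for (sv in c(1, 2)) {
    w <- cardiac_waveform(sv, 0.9, 256)
    expect_rel_equal(stroke_volume(w), sv, 1e-3)
    expect_lt(abs(net_flow(w)), 1e-9)
  }
  expect_error(cardiac_waveform(1, 0.9, 8), "n_samples")
  expect_error(cardiac_waveform(-1, 0.9), "positive")
})

test_that("stroke volume quadrature matches closed forms", {
  # sinusoid: half-integral of |A sin| over T is A T / pi
  t <- seq(0, 0.9, length.out = 2049)
  a <- pi / 0.9
  w <- csftransport:::new_flow_waveform(t, a * sin(2 * pi * t / 0.9),
                                        "cardiac", 0.9)
  expect_rel_equal(stroke_volume(w), 1, 1e-4)
  # square wave +-1 mL/s, period 2 s -> 1 mL
  tsq <- seq(0, 2, length.out = 4001)
  qsq <- ifelse(tsq %% 2 < 1, 1, -1)
  wsq <- csftransport:::new_flow_waveform(tsq, qsq, "cardiac", 2)
  expect_rel_equal(stroke_volume(wsq), 1, 1e-2)
  # zero waveform
  w0 <- csftransport:::new_flow_waveform(t, 0 * t, "cardiac", 0.9)
  expect_equal(stroke_volume(w0), 0)
  # homogeneity: scaling the flow scales the stroke volume
  w2 <- w; w2$flow <- 3.7 * w$flow
  expect_equal(stroke_volume(w2), 3.7 * stroke_volume(w), tolerance = 1e-12)
})

test_that("deep-respiration composite spans 13 cardiac cycles with zero net flow", {
  comp <- synthesize_deep_respiration_waveform(cardiac_waveform(),
                                               physiology_params())
  expect_equal(max(comp$times), 13 * 0.9, tolerance = 1e-9)
  expect_lt(abs(net_flow(comp)), 1e-9)
  # respiratory peak is 40% of the cardiac peak
  card <- cardiac_waveform()
  expect_rel_equal(max(abs(comp$components$respiratory$flow)),
                   0.4 * max(abs(card$flow)), 1e-6)
  # respiration-induced stroke volume ~6 mL, via stored component and
  # via the moving-average fallback
  expect_equal(respiratory_stroke_volume(comp), 6, tolerance = 0.02)
  stripped <- comp; stripped$components <- NULL
  expect_equal(respiratory_stroke_volume(stripped), 6, tolerance = 0.02)
  # mismatched periods are rejected
  expect_error(
    synthesize_deep_respiration_waveform(cardiac_waveform(period = 1.2),
                                         physiology_params()),
    "tile")
})

test_that("scenario presets reproduce the trial design and share one dose", {
  lp <- scenario_from_table("LP")
  expect_equal(lp$injection_site, 60)
  expect_equal(lp$bolus_rate, 5)
  expect_equal(lp$bolus_volume, 5)
  expect_equal(lp$flush_volume, 0)
  expect_equal(lp$stroke_volume, 1)
  r5 <- scenario_from_table("5X-Bolus rate")
  expect_equal(r5$bolus_rate, 25)
  expect_equal(r5$bolus_volume, 5)
  v3 <- scenario_from_table("3X-Bolus volume")
  expect_equal(v3$bolus_volume, 15)
  expect_equal(v3$tracer_volume_fraction, 1 / 3, tolerance = 0.011)
  fl <- scenario_from_table("5 mL-Flush")
  expect_equal(fl$flush_volume, 5)
  expect_equal(fl$flush_rate, 5)
  expect_true(scenario_from_table("Deep respiration")$deep_respiration)
  expect_equal(scenario_from_table("Deep respiration")$stroke_volume, 1)
  expect_equal(scenario_from_table("CM")$injection_site, 15)
  expect_identical(scenario_from_table("ICV")$injection_site, "lateral_L")
  # equal injected dose across all eight presets (within 1%)
  doses <- vapply(scenario_names(),
                  function(nm) injected_dose(scenario_from_table(nm)),
                  numeric(1))
  expect_lt(diff(range(doses)) / mean(doses), 0.01)
  expect_error(scenario_from_table("epidural"), "valid presets")
})

test_that("injection source switches from bolus to flush to off", {
  fl <- scenario_from_table("5 mL-Flush")
  s <- injection_source(fl, 0.5)     # mid-bolus
  expect_equal(s$rate, 5); expect_equal(s$tracer_fraction, 1)
  s <- injection_source(fl, 1.5)     # mid-flush, tracer-free
  expect_equal(s$rate, 5); expect_equal(s$tracer_fraction, 0)
  s <- injection_source(fl, 100)
  expect_equal(s$rate, 0)
  # without a flush the source simply turns off after the bolus
  lp <- scenario_from_table("LP")
  expect_equal(injection_source(lp, 1.5)$rate, 0)
  expect_error(scenario_config(flush_volume = 5, flush_rate = 0),
               "flush_rate")
})
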