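# Shared fixtures. Full-resolution scenario simulations are expensive
# (~5 s each), so they are computed once per test run and cached.

.sim_cache <- new.env(parent = emptyenv())

reference_geom <- function() {
  if (is.null(.sim_cache$geom)) .sim_cache$geom <- build_neuraxis_geometry()
  .sim_cache$geom
}

cached_sim <- function(name) {
  key <- gsub("[^A-Za-z0-9]", "_", name)
  if (is.null(.sim_cache[[key]])) {
    .sim_cache[[key]] <- simulate_transport(name, geom = reference_geom(),
                                            output_dt = 9)
  }
  .sim_cache[[key]]
}

# coarse geometry for fast solver property tests (same 76 cm domain)
coarse_geom <- function() {
  if (is.null(.sim_cache$coarse)) {
    .sim_cache$coarse <- build_neuraxis_geometry(list(dz = 1900))
  }
  .sim_cache$coarse
}

# direct access to the finite-volume kernel with uniform coefficients on
# a source-free domain (for manufactured-solution and recovery tests)
run_core_uniform <- function(c0, u_cm_s, D_cm2_s, dz_cm, area = 2,
                             dt = 0.5, t_end_s = 3600, out_every = 100,
                             absorbing = FALSE, limiter = TRUE) {
  n <- length(c0)
  core <- utils::getFromNamespace(".fv_transport_core", "csftransport")
  res <- core(
    n = n, dz = dz_cm, V = rep(area * dz_cm, n),
    Aface = rep(area, n + 1), Dface = rep(D_cm2_s, n + 1),
    ussface = rep(u_cm_s, n + 1), absorbing = absorbing,
    junction_cell = 1L, prod_rate = 0, vent_vol = rep(1, 5),
    icv = FALSE, inj_cell = 1L,
    bolus_rate = 0, bolus_conc = 0, bolus_end = 0,
    flush_rate = 0, flush_start = 0, flush_end = 0,
    dt = dt, n_steps = as.integer(round(t_end_s / dt)),
    out_every = as.integer(out_every), limiter = limiter, c0 = c0)
  res
}

gaussian_profile <- function(z, center, sd) {
  exp(-(z - center)^2 / (2 * sd^2))
}

expect_rel_equal <- function(object, expected, tol) {
  expect_lt(abs(object - expected) / abs(expected), tol)
}
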