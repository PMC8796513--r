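#' Injection source schedule of a scenario
#'
#' Piecewise-constant source description at time `t`: during the bolus
#' window `[0, bolus_volume / bolus_rate]` fluid enters at `bolus_rate`
#' carrying tracer at `tracer_volume_fraction`; during the flush window,
#' starting immediately at the end of the bolus, tracer-free fluid enters
#' at `flush_rate`; otherwise the source is off.
#'
#' @param scenario A [scenario_config()].
#' @param t Time since injection start (min).
#' @return List with `site` (axial cm or `"lateral_L"`), `rate` (mL/min)
#'   and `tracer_fraction`.
#' @export
injection_source <- function(scenario, t) {
  stopifnot(inherits(scenario, "scenario_config"), t >= 0)
  t_bolus <- scenario$bolus_volume / scenario$bolus_rate
  t_flush <- t_bolus +
    if (scenario$flush_volume > 0) scenario$flush_volume / scenario$flush_rate
    else 0
  if (t < t_bolus) {
    list(site = scenario$injection_site, rate = scenario$bolus_rate,
         tracer_fraction = scenario$tracer_volume_fraction)
  } else if (t < t_flush) {
    list(site = scenario$injection_site, rate = scenario$flush_rate,
         tracer_fraction = 0)
  } else {
    list(site = scenario$injection_site, rate = 0, tracer_fraction = 0)
  }
}

face_average <- function(x) {
  n <- length(x)
  c(x[1], (x[-n] + x[-1]) / 2, x[n])
}

#' Simulate tracer transport for a scenario
#'
#' Runs the reduced-order finite-volume advection-dispersion solve over
#' the scenario horizon: cycle-averaged steady-streaming drift plus
#' oscillation-induced effective dispersion on the axial grid, transient
#' injected-volume throughflow toward the cranial outlet during the
#' bolus/flush windows, ventricular production routed through the
#' lateral-third-aqueduct-fourth compartment chain into the basal
#' cistern, an advective-outflow (zero-dispersive-gradient) cranial
#' boundary and a closed caudal wall. Intracerebroventricular scenarios
#' inject into the left lateral ventricle compartment; all others into
#' the axial cell at the injection site.
#'
#' @param scenario A [scenario_config()] or preset name.
#' @param geom A [build_neuraxis_geometry()].
#' @param params A [physiology_params()].
#' @param calibration Closure constants, see [default_calibration()].
#' @param dt Internal time step (s). The default 0.05 s is far inside
#'   the advective stability limit at the default grid.
#' @param output_dt Output column spacing (s); 0.9 s reproduces the
#'   standard matrix layout.
#' @param boundary `"absorbing"` (cranial outflow, default) or
#'   `"reflecting"` (closed test domain; requires zero production and is
#'   only valid with a zero-dose source-free configuration or for mass
#'   conservation checks).
#' @param limiter Use the van Leer flux limiter (default TRUE).
#' @param waveform Optional `flow_waveform` override; by default built
#'   from the scenario stroke volume and, when flagged, deep respiration.
#' @param initial_concentration Optional per-cell initial concentration
#'   (uM); defaults to a tracer-free system.
#' @return An [stc_matrix()] whose `meta` carries the scenario, the mass
#'   ledger (`injected`, `in_model`, `outflow`, all umol), ventricular
#'   compartment concentration time courses and the streaming field.
#' @export
simulate_transport <- function(scenario,
                               geom = build_neuraxis_geometry(),
                               params = physiology_params(),
                               calibration = default_calibration(),
                               dt = 0.05,
                               output_dt = 0.9,
                               boundary = c("absorbing", "reflecting"),
                               limiter = TRUE,
                               waveform = NULL,
                               initial_concentration = NULL) {
  if (is.character(scenario)) scenario <- scenario_from_table(scenario)
  stopifnot(inherits(scenario, "scenario_config"),
            inherits(geom, "neuraxis_geometry"))
  boundary <- match.arg(boundary)
  if (is.null(waveform)) {
    waveform <- cardiac_waveform(scenario$stroke_volume,
                                 params$cardiac_period)
    if (scenario$deep_respiration) {
      waveform <- synthesize_deep_respiration_waveform(waveform, params)
    }
  }
  field <- steady_streaming_profile(geom, waveform, params, calibration)

  n <- geom$n_axial
  V <- geom$area_profile * geom$dz
  A_face <- face_average(geom$area_profile)
  D_face <- face_average(field$effective_dispersion) / 100   # mm^2/s -> cm^2/s
  u_face <- face_average(field$streaming_velocity) / 10      # mm/s -> cm/s

  icv <- is.character(scenario$injection_site)
  inj_cell <- if (icv) 0L else cell_at(geom, scenario$injection_site)
  t_bolus <- scenario$bolus_volume / scenario$bolus_rate * 60      # s
  t_flush_end <- t_bolus +
    if (scenario$flush_volume > 0)
      scenario$flush_volume / scenario$flush_rate * 60 else 0

  out_every <- max(1L, as.integer(round(output_dt / dt)))
  n_steps <- as.integer(round(scenario$duration * 60 / dt))
  n_steps <- (n_steps %/% out_every) * out_every

  res <- .fv_transport_core(
    n = n, dz = geom$dz, V = V, Aface = A_face, Dface = D_face,
    ussface = u_face, absorbing = (boundary == "absorbing"),
    junction_cell = geom$ventricle_branch$junction_cell,
    prod_rate = if (boundary == "absorbing") params$production_rate / 60 else 0,
    vent_vol = unname(geom$ventricle_branch$volumes),
    icv = icv, inj_cell = inj_cell,
    bolus_rate = scenario$bolus_rate / 60,
    bolus_conc = scenario$tracer_volume_fraction * scenario$stock_concentration,
    bolus_end = t_bolus,
    flush_rate = scenario$flush_rate / 60,
    flush_start = t_bolus, flush_end = t_flush_end,
    dt = dt, n_steps = n_steps, out_every = out_every,
    limiter = limiter,
    c0 = if (is.null(initial_concentration)) numeric(0)
         else initial_concentration)

  vent <- res$vent_conc
  rownames(vent) <- geom$ventricle_branch$compartments
  initial_nmol <- if (is.null(initial_concentration)) 0 else
    sum(initial_concentration * V)
  ledger <- list(
    injected = res$injected_total_nmol / 1000,
    initial = initial_nmol / 1000,
    in_model = res$mass_in_model_nmol / 1000,
    outflow = res$outflow_total_nmol / 1000)
  ledger$closure_error <- with(ledger,
    abs(in_model + outflow - injected - initial) /
      max(injected + initial, .Machine$double.eps))
  stc_matrix(res$conc, geom$z_centers, res$t_s / 60,
             dose = injected_dose(scenario),
             meta = list(
               scenario = scenario$name,
               scenario_config = scenario,
               grid = "native solver grid",
               mass_ledger = ledger,
               ventricles = vent,
               vent_volumes = geom$ventricle_branch$volumes,
               field = field,
               t_s = res$t_s,
               outflow_nmol = res$outflow_nmol,
               injected_nmol = res$injected_nmol))
}

#' Fraction of the dose resident in a ventricular compartment
#'
#' @param stc A [simulate_transport()] result.
#' @param compartment One of `lateral_L`, `lateral_R`, `third`,
#'   `aqueduct`, `fourth`.
#' @param t Time (min) within the simulated horizon.
#' @return Tracer amount in the compartment divided by the injected dose.
#' @export
ventricular_retention <- function(stc, compartment, t) {
  stopifnot(inherits(stc, "stc_matrix"))
  vent <- stc$meta$ventricles
  if (is.null(vent)) {
    stop("matrix carries no ventricular time courses (not a simulation?)",
         call. = FALSE)
  }
  if (!compartment %in% rownames(vent)) {
    stop("unknown compartment '", compartment, "'; valid: ",
         paste(rownames(vent), collapse = ", "), call. = FALSE)
  }
  if (t < 0 || t > max(stc$t_samples)) {
    stop("t outside the simulated horizon", call. = FALSE)
  }
  j <- which.min(abs(stc$t_samples - t))
  amount_nmol <- vent[compartment, j] *
    stc$meta$vent_volumes[[compartment]]
  unname(amount_nmol / 1000 / stc$dose)
}

#' Mass-conservation ledger of a simulation
#'
#' @param stc A [simulate_transport()] result.
#' @return List with `injected`, `in_model`, `outflow` (umol) and the
#'   relative `closure_error`.
#' @export
mass_ledger <- function(stc) {
  stopifnot(inherits(stc, "stc_matrix"))
  if (is.null(stc$meta$mass_ledger)) {
    stop("matrix carries no mass ledger (not a simulation?)", call. = FALSE)
  }
  stc$meta$mass_ledger
}
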