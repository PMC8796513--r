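#' Physiologic CSF parameters
#'
#' Container for the fluid and flow parameters of the cranio-spinal CSF
#' system used throughout the simulator. Defaults describe a healthy adult:
#' CSF is modelled as water at room temperature, ventricular production is
#' 0.4 mL/min (~576 mL/day), cardiac-driven oscillation has a 1 mL stroke
#' volume at 0.9 s, and deep respiration adds a slow component at 0.085 Hz
#' (11.7 s, i.e. one breath per 13 cardiac cycles) whose peak amplitude is
#' 40% of the cardiac peak.
#'
#' @param density Fluid density (kg/m^3).
#' @param viscosity Dynamic viscosity (mPa s).
#' @param production_rate Total ventricular CSF production (mL/min), split
#'   equally between the two lateral ventricles.
#' @param cardiac_stroke_volume Cardiac-driven CSF stroke volume (mL), one
#'   half the integral of absolute flow over one cardiac cycle.
#' @param cardiac_period Cardiac cycle length (s).
#' @param respiratory_period Deep-respiration cycle length (s).
#' @param respiratory_amplitude_scale Peak respiratory flow amplitude as a
#'   fraction of the cardiac peak.
#' @param cardiac_cycles_per_breath Number of cardiac cycles per breath;
#'   must tile the respiratory period (within 2%).
#' @return An object of class `physiology_params`.
#' @export
#' @examples
#' p <- physiology_params()
#' daily_production_volume(p)
physiology_params <- function(density = 998.3,
                              viscosity = 0.89,
                              production_rate = 0.4,
                              cardiac_stroke_volume = 1.0,
                              cardiac_period = 0.9,
                              respiratory_period = 11.7,
                              respiratory_amplitude_scale = 0.40,
                              cardiac_cycles_per_breath = 13L) {
  p <- list(
    density = density,
    viscosity = viscosity,
    production_rate = production_rate,
    cardiac_stroke_volume = cardiac_stroke_volume,
    cardiac_period = cardiac_period,
    respiratory_period = respiratory_period,
    respiratory_amplitude_scale = respiratory_amplitude_scale,
    cardiac_cycles_per_breath = as.integer(cardiac_cycles_per_breath)
  )
  num <- vapply(p, as.numeric, numeric(1))
  if (any(!is.finite(num)) || any(num <= 0)) {
    stop("all physiology parameters must be finite and strictly positive",
         call. = FALSE)
  }
  tile <- p$cardiac_cycles_per_breath * p$cardiac_period
  if (abs(tile - p$respiratory_period) > 0.02 * p$respiratory_period) {
    stop(sprintf(paste0(
      "cardiac_cycles_per_breath x cardiac_period (%.3f s) must equal ",
      "respiratory_period (%.3f s) within 2%%"), tile, p$respiratory_period),
      call. = FALSE)
  }
  structure(p, class = "physiology_params")
}

#' Daily CSF production volume
#'
#' @param params A [physiology_params()] object.
#' @return Production volume in mL/day (`production_rate` x 1440).
#' @export
daily_production_volume <- function(params) {
  stopifnot(inherits(params, "physiology_params"))
  if (params$production_rate < 0) {
    stop("production_rate must be non-negative", call. = FALSE)
  }
  params$production_rate * 1440
}

#' @export
print.physiology_params <- function(x, ...) {
  cat("CSF physiology parameters\n")
  cat(sprintf("  density            %.1f kg/m^3, viscosity %.2f mPa s\n",
              x$density, x$viscosity))
  cat(sprintf("  production         %.2f mL/min (%.0f mL/day)\n",
              x$production_rate, x$production_rate * 1440))
  cat(sprintf("  cardiac            %.2f mL stroke volume, %.2f s period\n",
              x$cardiac_stroke_volume, x$cardiac_period))
  cat(sprintf("  deep respiration   %.1f s period, %.0f%% of cardiac peak, %d cycles/breath\n",
              x$respiratory_period, 100 * x$respiratory_amplitude_scale,
              x$cardiac_cycles_per_breath))
  invisible(x)
}
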