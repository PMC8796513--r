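#' CSF flow waveforms
#'
#' Analytic surrogates for the oscillatory CSF flow measured at the
#' cervical (C2-C3) level. The cardiac waveform is a skewed two-harmonic
#' sine, `Q(t) = A (sin th + skew sin 2th)`, whose sharper systolic peak
#' mimics PCMRI waveforms; for `|skew| < 1/2` the flow changes sign only
#' twice per cycle so its stroke volume, defined as one half the integral
#' of |Q| over the cycle, is exactly `A T / pi` independent of the skew.
#'
#' @param stroke_volume Target stroke volume (mL), one half the integral
#'   of absolute flow over one cycle.
#' @param period Cycle length (s).
#' @param n_samples Samples per cycle (>= 16).
#' @param skew Second-harmonic fraction (default 1/3; with a 1 mL stroke
#'   volume at 0.9 s this puts the systolic peak at ~4.1 mL/s).
#' @return A `flow_waveform` object: data.frame-like list with `times`
#'   (s), `flow` (mL/s), and `kind`.
#' @export
#' @examples
#' w <- cardiac_waveform(1, 0.9, 256)
#' stroke_volume(w)   # 1 mL
cardiac_waveform <- function(stroke_volume = 1.0, period = 0.9,
                             n_samples = 256L, skew = 1 / 3) {
  if (!is.finite(stroke_volume) || stroke_volume <= 0 ||
      !is.finite(period) || period <= 0) {
    stop("stroke_volume and period must be strictly positive", call. = FALSE)
  }
  if (n_samples < 16) {
    stop("n_samples must be >= 16 to resolve the cycle", call. = FALSE)
  }
  if (abs(skew) >= 0.5) stop("|skew| must be < 0.5", call. = FALSE)
  a <- pi * stroke_volume / period
  t <- seq(0, period, length.out = n_samples + 1L)
  th <- 2 * pi * t / period
  q <- a * (sin(th) + skew * sin(2 * th))
  new_flow_waveform(t, q, kind = "cardiac", period = period)
}

#' @rdname cardiac_waveform
#' @param amplitude Peak flow (mL/s) of the sinusoidal respiratory
#'   component.
#' @export
respiratory_waveform <- function(amplitude, period = 11.7,
                                 n_samples = 256L) {
  if (!is.finite(amplitude) || amplitude <= 0 ||
      !is.finite(period) || period <= 0) {
    stop("amplitude and period must be strictly positive", call. = FALSE)
  }
  if (n_samples < 16) {
    stop("n_samples must be >= 16 to resolve the cycle", call. = FALSE)
  }
  t <- seq(0, period, length.out = n_samples + 1L)
  q <- amplitude * sin(2 * pi * t / period)
  new_flow_waveform(t, q, kind = "respiratory", period = period)
}

new_flow_waveform <- function(times, flow, kind, period,
                              components = NULL) {
  dt <- diff(times)
  if (any(dt <= 0) || diff(range(dt)) > 1e-9 * mean(dt)) {
    stop("waveform times must be strictly increasing and uniform",
         call. = FALSE)
  }
  structure(list(times = times, flow = flow, kind = kind,
                 period = period, components = components),
            class = "flow_waveform")
}

#' Stroke volume of a flow waveform
#'
#' One half of the integrated absolute flow over the full sampled cycle,
#' by trapezoidal quadrature.
#'
#' @param w A `flow_waveform`.
#' @return Stroke volume in mL.
#' @export
stroke_volume <- function(w) {
  stopifnot(inherits(w, "flow_waveform"), length(w$times) >= 2)
  0.5 * trapz(w$times, abs(w$flow))
}

trapz <- function(x, y) sum(diff(x) * (y[-1] + y[-length(y)])) / 2

#' Net flow over the sampled cycle
#'
#' @param w A `flow_waveform`.
#' @return Integral of flow over the cycle (mL); ~0 for zero-net-flow
#'   waveforms.
#' @export
net_flow <- function(w) {
  stopifnot(inherits(w, "flow_waveform"))
  trapz(w$times, w$flow)
}

#' Synthesize the deep-respiration composite waveform
#'
#' Builds one respiratory cycle of combined cardiac and deep-respiration
#' CSF flow: the respiratory component is a sinusoid whose peak amplitude
#' is `respiratory_amplitude_scale` times the cardiac peak, the cardiac
#' cycle is tiled `cardiac_cycles_per_breath` times to span the breath,
#' the two are summed, and the result is shifted by a constant so that
#' net flow over the composite cycle is exactly zero.
#'
#' @param cardiac A single-cycle cardiac `flow_waveform`.
#' @param params A [physiology_params()] object.
#' @return A composite `flow_waveform` spanning one respiratory period,
#'   carrying its cardiac and respiratory components as an attribute used
#'   by [respiratory_stroke_volume()].
#' @export
#' @examples
#' w <- synthesize_deep_respiration_waveform(cardiac_waveform(), physiology_params())
#' abs(net_flow(w)) < 1e-9
#' respiratory_stroke_volume(w)  # ~6 mL
synthesize_deep_respiration_waveform <- function(cardiac,
                                                 params = physiology_params()) {
  stopifnot(inherits(cardiac, "flow_waveform"),
            inherits(params, "physiology_params"))
  ncyc <- params$cardiac_cycles_per_breath
  if (abs(ncyc * cardiac$period - params$respiratory_period) >
      0.02 * params$respiratory_period) {
    stop("cardiac period does not tile the respiratory period ",
         "(cardiac_cycles_per_breath x period must match within 2%)",
         call. = FALSE)
  }
  # tile the cardiac cycle across the breath (drop duplicated cycle ends)
  nc <- length(cardiac$times) - 1L
  t_comp <- seq(0, by = diff(cardiac$times)[1], length.out = ncyc * nc + 1L)
  q_card <- c(rep(cardiac$flow[seq_len(nc)], ncyc), cardiac$flow[nc + 1L])
  t_resp_period <- ncyc * cardiac$period
  amp <- params$respiratory_amplitude_scale * max(abs(cardiac$flow))
  q_resp <- amp * sin(2 * pi * t_comp / t_resp_period)
  q <- q_card + q_resp
  shift <- trapz(t_comp, q) / (t_comp[length(t_comp)] - t_comp[1])
  q <- q - shift
  # the shift is a slow (DC) correction: attribute it to the respiratory band
  new_flow_waveform(
    t_comp, q, kind = "composite", period = t_resp_period,
    components = list(
      cardiac = new_flow_waveform(t_comp, q_card, "cardiac", cardiac$period),
      respiratory = new_flow_waveform(t_comp, q_resp - shift, "respiratory",
                                      t_resp_period)
    )
  )
}

#' Respiration-induced stroke volume of a composite waveform
#'
#' The deep-respiration-induced CSF stroke volume is the stroke volume of
#' the slow (respiratory-band) component of the composite waveform: one
#' half the integral of its absolute flow over the breath. Applying the
#' half-integral to the raw composite instead would count every cardiac
#' back-and-forth (~13 mL per breath for the defaults) rather than the
#' bulk volume displaced by the breath. If the waveform carries its
#' components (as built by [synthesize_deep_respiration_waveform()]) they
#' are used directly; otherwise the cardiac band is removed with a moving
#' average over one cardiac period.
#'
#' @param w A composite `flow_waveform`.
#' @param cardiac_period Cardiac period (s) used for the fallback
#'   moving-average extraction.
#' @return Respiration-induced stroke volume (mL); ~6 mL at defaults.
#' @export
respiratory_stroke_volume <- function(w, cardiac_period = 0.9) {
  stopifnot(inherits(w, "flow_waveform"))
  if (!is.null(w$components$respiratory)) {
    return(stroke_volume(w$components$respiratory))
  }
  dt <- diff(w$times)[1]
  k <- max(1L, as.integer(round(cardiac_period / dt)))
  kern <- rep(1 / k, k)
  # circular moving average over one cardiac period removes the cardiac band
  n <- length(w$flow)
  qq <- stats::filter(c(w$flow[-n], w$flow[-n]), kern, sides = 2, circular = TRUE)
  slow <- as.numeric(qq[seq_len(n - 1L)])
  stroke_volume(new_flow_waveform(w$times, c(slow, slow[1]), "respiratory",
                                  w$period))
}

#' Write a waveform as two-column delimited text
#'
#' @param w A `flow_waveform`.
#' @param path Output file path.
#' @param sep Field delimiter.
#' @return The path, invisibly.
#' @export
write_waveform <- function(w, path, sep = "\t") {
  stopifnot(inherits(w, "flow_waveform"))
  utils::write.table(
    data.frame(time_s = w$times, flow_mL_s = w$flow),
    path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.flow_waveform <- function(x, ...) {
  cat(sprintf("%s flow waveform: period %.2f s, %d samples\n",
              x$kind, x$period, length(x$times)))
  cat(sprintf("  stroke volume %.3f mL, peak %.3f mL/s, net flow %.2e mL\n",
              stroke_volume(x), max(abs(x$flow)), net_flow(x)))
  invisible(x)
}
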