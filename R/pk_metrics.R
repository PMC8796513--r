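#' Per-cell exposure (area under the concentration-time curve)
#'
#' Trapezoidal integration of the concentration time course of every
#' axial cell over the simulated horizon.
#'
#' @param stc An [stc_matrix()] with at least two time samples.
#' @return Numeric vector of AUC values (uM h), one per axial cell.
#' @export
auc_profile <- function(stc) {
  stopifnot(inherits(stc, "stc_matrix"))
  t <- stc$t_samples
  if (length(t) < 2) stop("need >= 2 time samples", call. = FALSE)
  w <- trapezoid_weights(t) / 60   # min -> h
  v <- stc$values
  v[is.na(v)] <- 0
  as.numeric(v %*% w)
}

trapezoid_weights <- function(t) {
  n <- length(t)
  d <- diff(t)
  c(d[1] / 2, (d[-(n - 1)] + d[-1]) / 2, d[n - 1] / 2)
}

#' Per-cell peak concentration and time of peak
#'
#' Row-wise maximum concentration and the time at which it is first
#' attained (ties break to the earliest time).
#'
#' @param stc An [stc_matrix()].
#' @return Data frame with `z` (cm), `cmax` (uM) and `tmax` (min).
#' @export
cmax_tmax_profile <- function(stc) {
  stopifnot(inherits(stc, "stc_matrix"))
  v <- stc$values
  v[is.na(v)] <- -Inf
  idx <- max.col(v, ties.method = "first")
  cmax <- v[cbind(seq_len(nrow(v)), idx)]
  cmax[!is.finite(cmax)] <- NA_real_
  data.frame(z = stc$z_centers, cmax = cmax, tmax = stc$t_samples[idx])
}

#' Regional pharmacokinetic summary
#'
#' For each named anatomical region, averages the concentration over the
#' region's axial cells at every time point and summarizes the resulting
#' regional time course: AUC over the horizon, peak concentration and
#' time of peak. The AUC of the spatial-mean time course equals the
#' spatial mean of per-cell AUCs (integration is linear); the former is
#' what is computed.
#'
#' @param stc An [stc_matrix()].
#' @param geom A [build_neuraxis_geometry()] whose region bounds cover
#'   the matrix rows.
#' @return Data frame with columns `region`, `AUC_uMh`, `Cmax_uM`,
#'   `Tmax_min`, `n_cells`.
#' @export
regional_summary <- function(stc, geom) {
  stopifnot(inherits(stc, "stc_matrix"),
            inherits(geom, "neuraxis_geometry"))
  zmax <- max(stc$z_centers)
  if (zmax > geom$total_length + geom$dz) {
    stop(sprintf("matrix extends to %.1f cm, outside the %.1f cm geometry",
                 zmax, geom$total_length), call. = FALSE)
  }
  reg <- region_at(geom, stc$z_centers)
  if (anyNA(reg)) stop("matrix rows outside all regions", call. = FALSE)
  rb <- geom$region_bounds
  out <- lapply(rb$region, function(rn) {
    rows <- which(reg == rn)
    if (!length(rows)) {
      return(data.frame(region = rn, AUC_uMh = NA_real_, Cmax_uM = NA_real_,
                        Tmax_min = NA_real_, n_cells = 0L))
    }
    course <- colMeans(stc$values[rows, , drop = FALSE], na.rm = TRUE)
    sub <- stc_matrix(matrix(course, 1), stc$z_centers[rows[1]],
                      stc$t_samples)
    pk <- cmax_tmax_profile(sub)
    data.frame(region = rn, AUC_uMh = auc_profile(sub),
               Cmax_uM = pk$cmax, Tmax_min = pk$tmax,
               n_cells = length(rows))
  })
  do.call(rbind, out)
}

#' Cranial/spinal compartment exposure
#'
#' AUC of the spatially averaged concentration time course cranial and
#' caudal of the foramen magnum, plus each compartment's mean peak
#' concentration. The cranial/spinal boundary is a single configurable
#' position (15 cm from the cranial end by default).
#'
#' @param stc An [stc_matrix()].
#' @param boundary_z Cranial/spinal boundary (cm from the cranial end).
#' @return Data frame with one row per compartment (`cranial`, `spinal`):
#'   AUC of the mean time course (uM h), mean and max of per-cell Cmax
#'   (uM).
#' @export
compartment_summary <- function(stc, boundary_z = 15) {
  stopifnot(inherits(stc, "stc_matrix"), boundary_z > 0)
  side <- ifelse(stc$z_centers < boundary_z, "cranial", "spinal")
  pk <- cmax_tmax_profile(stc)
  out <- lapply(c("cranial", "spinal"), function(sn) {
    rows <- which(side == sn)
    if (!length(rows)) {
      return(data.frame(compartment = sn, AUC_uMh = NA_real_,
                        mean_Cmax_uM = NA_real_, max_Cmax_uM = NA_real_,
                        n_cells = 0L))
    }
    course <- colMeans(stc$values[rows, , drop = FALSE], na.rm = TRUE)
    sub <- stc_matrix(matrix(course, 1), stc$z_centers[rows[1]],
                      stc$t_samples)
    data.frame(compartment = sn, AUC_uMh = auc_profile(sub),
               mean_Cmax_uM = mean(pk$cmax[rows], na.rm = TRUE),
               max_Cmax_uM = max(pk$cmax[rows], na.rm = TRUE),
               n_cells = length(rows))
  })
  do.call(rbind, out)
}

#' Cranial-directed tracer front speed
#'
#' At each time in the window, the tracer front is the most cranial row
#' whose concentration reaches `threshold_fraction` of that column's
#' instantaneous maximum; the front speed is the least-squares slope of
#' front position against time, returned as a positive cranial-directed
#' speed in cm/h.
#'
#' @param stc An [stc_matrix()].
#' @param threshold_fraction Fraction of the instantaneous maximum
#'   defining the front (default 0.05).
#' @param window Time interval `c(from, to)` in minutes.
#' @return Front speed (cm/h); positive when the front moves toward the
#'   cranial end.
#' @export
front_speed <- function(stc, threshold_fraction = 0.05,
                        window = c(0, 120)) {
  stopifnot(inherits(stc, "stc_matrix"))
  if (threshold_fraction <= 0 || threshold_fraction >= 1) {
    stop("threshold_fraction must lie in (0, 1)", call. = FALSE)
  }
  jj <- which(stc$t_samples >= window[1] & stc$t_samples <= window[2])
  pos <- tim <- numeric(0)
  for (j in jj) {
    col <- stc$values[, j]
    peak <- suppressWarnings(max(col, na.rm = TRUE))
    if (!is.finite(peak) || peak <= 0) next
    hit <- which(col >= threshold_fraction * peak)
    if (!length(hit)) next
    pos <- c(pos, stc$z_centers[hit[1]])
    tim <- c(tim, stc$t_samples[j])
  }
  if (length(pos) < 2) {
    stop("tracer front never detected in the requested window",
         call. = FALSE)
  }
  slope <- unname(coef(lm(pos ~ tim))[2])   # cm/min, negative = cranial
  -slope * 60
}
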