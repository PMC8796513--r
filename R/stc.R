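#' Spatio-temporal concentration matrix
#'
#' The central data container: cross-sectional-average tracer
#' concentration on an axial-by-time grid. Rows are axial cells ordered
#' cranial-first (z from the cranial end, cm); columns are time samples
#' from injection start (min); values are concentrations in uM.
#'
#' @param values Numeric matrix, rows = axial cells, columns = times.
#' @param z Axial cell-center positions (cm), length `nrow(values)`.
#' @param t Time samples (min), length `ncol(values)`.
#' @param dose Injected tracer amount (umol), if known.
#' @param meta Named list of provenance (scenario name, grid origin, ...).
#' @return An object of class `stc_matrix`.
#' @export
stc_matrix <- function(values, z, t, dose = NA_real_, meta = list()) {
  values <- as.matrix(values)
  if (length(z) != nrow(values) || length(t) != ncol(values)) {
    stop(sprintf("grid/matrix mismatch: %d x %d values vs %d z, %d t",
                 nrow(values), ncol(values), length(z), length(t)),
         call. = FALSE)
  }
  if (is.unsorted(z, strictly = TRUE) || is.unsorted(t, strictly = TRUE)) {
    stop("z and t must be strictly increasing", call. = FALSE)
  }
  if (any(values < 0, na.rm = TRUE)) {
    neg <- min(values, na.rm = TRUE)
    if (neg < -1e-9) {
      stop(sprintf("concentrations must be non-negative (min %.3g)", neg),
           call. = FALSE)
    }
    values[values < 0] <- 0
  }
  structure(list(z_centers = as.numeric(z), t_samples = as.numeric(t),
                 values = values, dose = dose, meta = meta),
            class = "stc_matrix")
}

#' @export
print.stc_matrix <- function(x, ...) {
  cat(sprintf("Spatio-temporal concentration: %d axial x %d time samples\n",
              nrow(x$values), ncol(x$values)))
  cat(sprintf("  z: %.2f-%.2f cm (cranial-first), t: %.1f-%.1f min\n",
              min(x$z_centers), max(x$z_centers),
              min(x$t_samples), max(x$t_samples)))
  cat(sprintf("  peak %.3g uM; dose %.3g umol%s\n",
              max(x$values, na.rm = TRUE), x$dose,
              if (length(x$meta$scenario)) paste0("; scenario ",
                                                 x$meta$scenario) else ""))
  invisible(x)
}

#' @export
dim.stc_matrix <- function(x) dim(x$values)

stc_dz <- function(stc) {
  d <- diff(stc$z_centers)
  if (diff(range(d)) > 1e-6 * mean(d)) return(NA_real_)
  mean(d)
}

stc_dt <- function(stc) {
  d <- diff(stc$t_samples)
  if (diff(range(d)) > 1e-6 * mean(d)) return(NA_real_)
  mean(d)
}
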