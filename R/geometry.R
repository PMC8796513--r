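#' @importFrom stats approx lm coef sd var setNames
#' @importFrom utils count.fields modifyList
NULL

# Default axial extent of the named anatomical regions (cm from the cranial
# end, cranial -> caudal). The cortical band is split into a left and right
# half because a 1D axial model cannot hold two co-located compartments.
default_region_bounds <- function(total_length = 76) {
  scale <- total_length / 76
  data.frame(
    region = c("cortical_SAS_left", "cortical_SAS_right", "basal_cistern",
               "cerebellum", "cervical", "thoracic", "lumbar", "sacral"),
    z_from = c(0, 4.5, 9, 12, 15, 27, 47, 62) * scale,
    z_to   = c(4.5, 9, 12, 15, 27, 47, 62, 76) * scale,
    stringsAsFactors = FALSE
  )
}

# Cross-sectional area control points (cm, cm^2). Piecewise linear between
# points; chosen so the total CSF volume (SAS + ventricles) lands in the
# physiologic 250-400 mL range, with a wide cortical/basal cranial space, a
# constriction at the foramen magnum, a mild lumbar-cistern bulge and a
# sacral taper.
default_area_breakpoints <- function(total_length = 76) {
  scale <- total_length / 76
  data.frame(
    z = c(0, 4.5, 9, 12, 15, 27, 47, 55, 62, 76) * scale,
    area = c(7.5, 13, 14.5, 11, 3.0, 2.5, 1.8, 2.4, 2.0, 0.4)
  )
}

default_ventricle_volumes <- function() {
  c(lateral_L = 11, lateral_R = 11, third = 1.2, aqueduct = 0.1, fourth = 1.4)
}

#' Build the axial discretization of the CSF space
#'
#' Constructs the 1D cranio-spinal geometry: a 76 cm axial domain (cranial
#' end at z = 0, increasing caudally) discretized into cells of 380 microns
#' by default (2000 cells), a piecewise-linear cross-sectional area
#' profile, named anatomical regions, the foramen magnum position
#' separating cranial from spinal CSF, and a ventricular side branch
#' (lateral ventricles, third ventricle, aqueduct, fourth ventricle)
#' joining the axial domain inside the basal cistern.
#'
#' @param overrides Named list of parameter overrides. Recognized keys:
#'   `total_length` (cm), `dz` (micron), `foramen_magnum_z` (cm),
#'   `region_bounds` (data.frame region/z_from/z_to),
#'   `area_breakpoints` (data.frame z/area),
#'   `ventricle_volumes` (named numeric, mL), `ventricle_junction_z` (cm).
#' @return An object of class `neuraxis_geometry` with fields
#'   `total_length`, `dz` (cm), `n_axial`, `z_centers`, `area_profile`
#'   (cm^2 per cell), `foramen_magnum_z`, `region_bounds`,
#'   `ventricle_branch` (compartment volumes and junction cell index).
#' @export
#' @examples
#' g <- build_neuraxis_geometry()
#' g$n_axial    # 2000 cells: 76 cm at 380 micron spacing
build_neuraxis_geometry <- function(overrides = list()) {
  stopifnot(is.list(overrides))
  known <- c("total_length", "dz", "foramen_magnum_z", "region_bounds",
             "area_breakpoints", "ventricle_volumes", "ventricle_junction_z")
  bad <- setdiff(names(overrides), known)
  if (length(bad)) {
    stop("unknown geometry override(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  total_length <- overrides$total_length %||% 76        # cm
  dz_um <- overrides$dz %||% 380                        # micron
  if (!is.finite(total_length) || total_length <= 0 ||
      !is.finite(dz_um) || dz_um <= 0) {
    stop("total_length and dz must be strictly positive", call. = FALSE)
  }
  dz <- dz_um / 1e4                                     # cm
  n_axial <- as.integer(round(total_length / dz))
  if (n_axial < 2) stop("grid must contain at least 2 cells", call. = FALSE)
  if (abs(n_axial * dz - total_length) > dz) {
    stop("total_length must be a whole number of cells within one cell",
         call. = FALSE)
  }
  z_centers <- (seq_len(n_axial) - 0.5) * dz

  rb <- overrides$region_bounds %||% default_region_bounds(total_length)
  validate_region_bounds(rb, total_length, dz)

  ab <- overrides$area_breakpoints %||% default_area_breakpoints(total_length)
  if (any(ab$area <= 0)) {
    stop("cross-sectional areas must be strictly positive", call. = FALSE)
  }
  area_profile <- approx(ab$z, ab$area, xout = z_centers, rule = 2)$y

  fm <- overrides$foramen_magnum_z %||% (15 * total_length / 76)
  if (fm <= 0 || fm >= total_length) {
    stop("foramen_magnum_z must lie inside (0, total_length)", call. = FALSE)
  }

  vv <- overrides$ventricle_volumes %||% default_ventricle_volumes()
  vorder <- c("lateral_L", "lateral_R", "third", "aqueduct", "fourth")
  if (!setequal(names(vv), vorder) || any(vv <= 0)) {
    stop("ventricle_volumes must name lateral_L, lateral_R, third, ",
         "aqueduct, fourth with strictly positive volumes", call. = FALSE)
  }
  vv <- vv[vorder]
  vjz <- overrides$ventricle_junction_z %||% (10.5 * total_length / 76)
  bc <- rb[rb$region == "basal_cistern", ]
  if (nrow(bc) == 1 && !(vjz >= bc$z_from && vjz <= bc$z_to)) {
    stop("ventricle_junction_z must lie within the basal cistern interval",
         call. = FALSE)
  }
  junction_cell <- pmin(pmax(1L, as.integer(ceiling(vjz / dz))), n_axial)

  structure(list(
    total_length = total_length,
    dz = dz,
    n_axial = n_axial,
    z_centers = z_centers,
    area_profile = area_profile,
    area_breakpoints = ab,
    foramen_magnum_z = fm,
    region_bounds = rb,
    ventricle_branch = list(
      compartments = vorder,
      volumes = vv,
      junction_z = vjz,
      junction_cell = junction_cell
    )
  ), class = "neuraxis_geometry")
}

validate_region_bounds <- function(rb, total_length, dz) {
  need <- c("region", "z_from", "z_to")
  if (!is.data.frame(rb) || !all(need %in% names(rb))) {
    stop("region_bounds must be a data.frame with region, z_from, z_to",
         call. = FALSE)
  }
  rb <- rb[order(rb$z_from), ]
  if (any(rb$z_to <= rb$z_from)) {
    stop("region intervals must have z_to > z_from", call. = FALSE)
  }
  gaps <- c(rb$z_from[1], rb$z_from[-1] - rb$z_to[-nrow(rb)],
            total_length - rb$z_to[nrow(rb)])
  if (any(abs(gaps) > dz / 2 + 1e-9)) {
    stop("region intervals must be disjoint and cover [0, total_length]",
         call. = FALSE)
  }
  invisible(rb)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Map axial positions to region labels
#'
#' @param geom A [build_neuraxis_geometry()] object.
#' @param z Axial positions (cm from the cranial end).
#' @return Character vector of region names.
#' @export
region_at <- function(geom, z) {
  stopifnot(inherits(geom, "neuraxis_geometry"))
  rb <- geom$region_bounds
  idx <- findInterval(z, c(rb$z_from, geom$total_length),
                      rightmost.closed = TRUE)
  idx[z < 0 | z > geom$total_length] <- NA_integer_
  rb$region[idx]
}

#' Cell index containing an axial position
#'
#' @param geom A [build_neuraxis_geometry()] object.
#' @param z Axial position (cm from the cranial end).
#' @return Integer cell index (1 = most cranial cell).
#' @export
cell_at <- function(geom, z) {
  stopifnot(inherits(geom, "neuraxis_geometry"))
  if (any(z < 0 | z > geom$total_length)) {
    stop("z outside [0, total_length]", call. = FALSE)
  }
  pmin(pmax(1L, as.integer(ceiling(z / geom$dz))), geom$n_axial)
}

#' Total modelled CSF volume
#'
#' @param geom A [build_neuraxis_geometry()] object.
#' @return Volume (mL) of the axial domain plus ventricular compartments.
#' @export
csf_volume <- function(geom) {
  stopifnot(inherits(geom, "neuraxis_geometry"))
  sum(geom$area_profile) * geom$dz + sum(geom$ventricle_branch$volumes)
}

#' @export
print.neuraxis_geometry <- function(x, ...) {
  cat(sprintf("Neuraxis geometry: %.1f cm, %d cells of %.0f um\n",
              x$total_length, x$n_axial, x$dz * 1e4))
  cat(sprintf("  foramen magnum at %.1f cm; total CSF volume %.0f mL\n",
              x$foramen_magnum_z, csf_volume(x)))
  cat(sprintf("  ventricles (lateral L+R > third > aqueduct > fourth) join at z = %.1f cm\n",
              x$ventricle_branch$junction_z))
  invisible(x)
}
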