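#' Matrix file layout specification
#'
#' Describes the delimited-text layout used for spatio-temporal
#' concentration matrices: header-less rectangular numeric matrices whose
#' rows step down the neuraxis (380 micron spacing by default, top row =
#' cranial end) and whose columns step through time (900 ms per column by
#' default, left column = time 0). Blank cells, "NaN" or negative
#' sentinels are treated as missing.
#'
#' @param delimiter Field delimiter; `NULL` auto-detects among comma, tab
#'   and semicolon on the first line.
#' @param row_convention `"cranial_first"` (default) or `"caudal_first"`.
#' @param dz Axial spacing (micron).
#' @param dt Time resolution (ms).
#' @param origin_time Time of the first column (min).
#' @return A `matrix_file_spec` object.
#' @export
matrix_file_spec <- function(delimiter = NULL,
                             row_convention = c("cranial_first",
                                                "caudal_first"),
                             dz = 380, dt = 900, origin_time = 0) {
  row_convention <- match.arg(row_convention)
  if (!is.null(delimiter) && !delimiter %in% c(",", "\t", ";")) {
    stop("delimiter must be one of ',', tab, ';'", call. = FALSE)
  }
  if (dz <= 0 || dt <= 0) stop("dz and dt must be positive", call. = FALSE)
  structure(list(delimiter = delimiter, row_convention = row_convention,
                 dz = dz, dt = dt, origin_time = origin_time, units = "uM"),
            class = "matrix_file_spec")
}

detect_delimiter <- function(path) {
  line1 <- readLines(path, n = 1L, warn = FALSE)
  counts <- vapply(c(",", "\t", ";"), function(d)
    lengths(regmatches(line1, gregexpr(d, line1, fixed = TRUE))), integer(1))
  if (all(counts == 0)) return(",")  # single-column file
  c(",", "\t", ";")[which.max(counts)]
}

#' Read a spatio-temporal concentration matrix
#'
#' Reads a header-less delimited-text matrix in the layout described by
#' `spec` and attaches grid coordinates: row `i` maps to
#' `z = (i - 1/2) dz` from the cranial end and column `j` to
#' `t = origin_time + (j - 1) dt`. Ragged input is rejected with the
#' offending row number; non-numeric cells are reported with their
#' coordinates. Blank and "NaN" cells become missing values.
#'
#' @param path Path to the matrix file.
#' @param spec A [matrix_file_spec()]; when `NULL`, a `<path>.meta.yaml`
#'   sidecar written by [write_stc_matrix()] is used if present,
#'   otherwise the default layout.
#' @param dose Injected dose (umol) to record on the result, if known.
#' @return An [stc_matrix()].
#' @export
read_stc_matrix <- function(path, spec = NULL, dose = NA_real_) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (is.null(spec)) {
    sidecar <- paste0(path, ".meta.yaml")
    spec <- if (file.exists(sidecar)) {
      do.call(matrix_file_spec, yaml::read_yaml(sidecar))
    } else {
      matrix_file_spec()
    }
  }
  stopifnot(inherits(spec, "matrix_file_spec"))
  delim <- spec$delimiter %||% detect_delimiter(path)
  nf <- count.fields(path, sep = delim, blank.lines.skip = FALSE,
                     comment.char = "")
  if (length(nf) == 0) stop("empty matrix file: ", path, call. = FALSE)
  if (any(nf != nf[1])) {
    bad <- which(nf != nf[1])[1]
    stop(sprintf("ragged matrix: row %d has %d fields, expected %d",
                 bad, nf[bad], nf[1]), call. = FALSE)
  }
  dt_tab <- data.table::fread(path, sep = delim, header = FALSE,
                              colClasses = "character", na.strings = NULL,
                              data.table = FALSE)
  raw <- as.matrix(dt_tab)
  vals <- suppressWarnings(array(as.numeric(raw), dim = dim(raw)))
  blank <- raw == "" | toupper(raw) == "NAN" | toupper(raw) == "NA"
  badcell <- which(is.na(vals) & !blank, arr.ind = TRUE)
  if (nrow(badcell)) {
    stop(sprintf("non-numeric cell '%s' at row %d, column %d",
                 raw[badcell[1, 1], badcell[1, 2]],
                 badcell[1, 1], badcell[1, 2]), call. = FALSE)
  }
  vals[blank] <- NA_real_
  vals[!is.na(vals) & vals < 0] <- NA_real_   # negative sentinels
  if (spec$row_convention == "caudal_first") {
    vals <- vals[rev(seq_len(nrow(vals))), , drop = FALSE]
  }
  dz_cm <- spec$dz / 1e4
  z <- (seq_len(nrow(vals)) - 0.5) * dz_cm
  t <- spec$origin_time + (seq_len(ncol(vals)) - 1L) * spec$dt / 6e4
  stc_matrix(vals, z, t, dose = dose,
             meta = list(source = path, spec = spec))
}

#' Write a spatio-temporal concentration matrix
#'
#' Writes the matrix as header-less delimited text in the layout of
#' `spec` (values formatted with 7 significant digits; missing values as
#' blanks). The grid must be uniform and match the declared spacing.
#'
#' @param stc An [stc_matrix()] with a uniform grid.
#' @param path Output path.
#' @param spec A [matrix_file_spec()]; by default derived from the
#'   matrix grid.
#' @param sidecar Also write a `<path>.meta.yaml` sidecar carrying the
#'   layout fields, so the file can be re-read without guessing the grid.
#' @return `path`, invisibly.
#' @export
write_stc_matrix <- function(stc, path, spec = NULL, sidecar = TRUE) {
  stopifnot(inherits(stc, "stc_matrix"))
  dz <- stc_dz(stc); dt <- stc_dt(stc)
  if (is.na(dz) || is.na(dt)) {
    stop("matrix grid must be uniform; resample before writing",
         call. = FALSE)
  }
  if (is.null(spec)) {
    spec <- matrix_file_spec(delimiter = ",", dz = dz * 1e4, dt = dt * 6e4,
                             origin_time = stc$t_samples[1])
  }
  stopifnot(inherits(spec, "matrix_file_spec"))
  vals <- stc$values
  if (spec$row_convention == "caudal_first") {
    vals <- vals[rev(seq_len(nrow(vals))), , drop = FALSE]
  }
  txt <- array(sprintf("%.7g", vals), dim = dim(vals))
  txt[is.na(vals)] <- ""
  delim <- spec$delimiter %||% ","
  data.table::fwrite(as.data.frame(txt), path, sep = delim,
                     col.names = FALSE, quote = FALSE)
  if (sidecar) {
    yaml::write_yaml(
      list(delimiter = delim, row_convention = spec$row_convention,
           dz = spec$dz, dt = spec$dt, origin_time = spec$origin_time),
      paste0(path, ".meta.yaml"))
  }
  invisible(path)
}

#' Load a scenario configuration file
#'
#' Reads a flat YAML configuration naming a scenario preset and optional
#' overrides for the scenario, geometry and physiology, and returns the
#' fully resolved objects. Unknown keys are rejected. An empty file
#' resolves to the baseline lumbar-puncture defaults.
#'
#' Layout:
#' ```yaml
#' preset: "LP"            # optional, defaults to LP
#' scenario:               # optional per-field overrides
#'   bolus_rate: 10
#' geometry:
#'   total_length: 76
#' physiology:
#'   production_rate: 0.4
#' ```
#'
#' @param path Path to the YAML file.
#' @param quiet Suppress the resolved-parameter echo.
#' @return List with elements `scenario`, `geometry`, `physiology`.
#' @export
load_scenario_config <- function(path, quiet = FALSE) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  known <- c("preset", "scenario", "geometry", "physiology")
  bad <- setdiff(names(cfg), known)
  if (length(bad)) {
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  preset <- cfg$preset %||% "LP"
  base <- scenario_presets()
  if (!preset %in% names(base)) {
    stop("unknown preset '", preset, "'; valid presets: ",
         paste(names(base), collapse = ", "), call. = FALSE)
  }
  sc_args <- modifyList(base[[preset]], as.list(cfg$scenario %||% list()))
  bad_sc <- setdiff(names(sc_args), names(formals(scenario_config)))
  if (length(bad_sc)) {
    stop("unknown scenario key(s): ", paste(bad_sc, collapse = ", "),
         call. = FALSE)
  }
  scenario <- do.call(scenario_config, sc_args)
  geometry <- build_neuraxis_geometry(as.list(cfg$geometry %||% list()))
  ph_args <- as.list(cfg$physiology %||% list())
  bad_ph <- setdiff(names(ph_args), names(formals(physiology_params)))
  if (length(bad_ph)) {
    stop("unknown physiology key(s): ", paste(bad_ph, collapse = ", "),
         call. = FALSE)
  }
  physiology <- do.call(physiology_params, ph_args)
  if (!quiet) {
    message("resolved configuration from ", path)
    print(scenario); print(geometry); print(physiology)
  }
  list(scenario = scenario, geometry = geometry, physiology = physiology)
}
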