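#' Pair two spatio-temporal matrices cell by cell
#'
#' Aligns two matrices on a common grid (identical grids, or grids whose
#' coordinates match to within half a cell / half a time step by nearest
#' neighbor) and returns the co-located, co-timed value pairs with
#' non-finite entries dropped. By convention the first argument is the
#' numerical (simulated) field and the second the reference
#' (experimental) field.
#'
#' @param numerical,reference [stc_matrix()] objects.
#' @return Data frame with columns `reference`, `numerical`, `z`, `t`;
#'   attribute `n_dropped` counts discarded non-finite pairs.
#' @export
pair_matrices <- function(numerical, reference) {
  stopifnot(inherits(numerical, "stc_matrix"),
            inherits(reference, "stc_matrix"))
  a <- numerical; b <- reference
  if (!isTRUE(all.equal(dim(a$values), dim(b$values))) &&
      (nrow(a$values) != nrow(b$values) || ncol(a$values) != ncol(b$values))) {
    stop(sprintf("incompatible grids: %d x %d vs %d x %d",
                 nrow(a$values), ncol(a$values),
                 nrow(b$values), ncol(b$values)), call. = FALSE)
  }
  hz <- stc_dz(a) / 2; ht <- stc_dt(a) / 2
  if (max(abs(a$z_centers - b$z_centers)) > hz ||
      max(abs(a$t_samples - b$t_samples)) > ht) {
    stop("grids not alignable within half a cell / half a time step",
         call. = FALSE)
  }
  av <- as.numeric(a$values); bv <- as.numeric(b$values)
  keep <- is.finite(av) & is.finite(bv)
  out <- data.frame(
    reference = bv[keep], numerical = av[keep],
    z = rep(a$z_centers, times = ncol(a$values))[keep],
    t = rep(a$t_samples, each = nrow(a$values))[keep])
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Linear agreement of paired measurements
#'
#' Ordinary least squares of the numerical value on the reference value,
#' with R^2 the squared Pearson correlation.
#'
#' @param pairs Data frame from [pair_matrices()] (columns `reference`,
#'   `numerical`).
#' @return List with `slope`, `intercept` (uM), `r_squared`, `n_pairs`.
#' @export
linear_agreement <- function(pairs) {
  x <- pairs$reference; y <- pairs$numerical
  if (length(x) < 3) stop("need >= 3 pairs", call. = FALSE)
  if (var(x) <= 0) {
    stop("degenerate reference values (zero variance)", call. = FALSE)
  }
  fit <- lm(y ~ x)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared = stats::cor(x, y)^2, n_pairs = length(x))
}

#' Bland-Altman limits of agreement
#'
#' Mean difference (numerical minus reference) and the 95% limits of
#' agreement, `1.96 x SD` of the differences, also expressed as a
#' percentage of the dataset's dynamic range.
#'
#' @param pairs Data frame from [pair_matrices()].
#' @param dynamic_range Concentration span (uM) used for the percentage;
#'   defaults to the pooled range (max - min) over both matrices.
#' @param sd_type `"population"` (divide by n, default) or `"sample"`;
#'   the difference is negligible at the usual pair counts.
#' @return List with `mean_difference`, `loa_halfwidth` (uM),
#'   `loa_percent_dynamic_range`, `dynamic_range`, `n_pairs`.
#' @export
bland_altman <- function(pairs, dynamic_range = NULL,
                         sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  d <- pairs$numerical - pairs$reference
  n <- length(d)
  if (n < 3) stop("need >= 3 pairs", call. = FALSE)
  if (is.null(dynamic_range)) {
    pool <- c(pairs$numerical, pairs$reference)
    dynamic_range <- max(pool) - min(pool)
  }
  if (!is.finite(dynamic_range) || dynamic_range <= 0) {
    stop("dynamic_range must be strictly positive", call. = FALSE)
  }
  s <- sd(d)
  if (sd_type == "population") s <- s * sqrt((n - 1) / n)
  loa <- 1.96 * s
  list(mean_difference = mean(d), loa_halfwidth = loa,
       loa_percent_dynamic_range = 100 * loa / dynamic_range,
       dynamic_range = dynamic_range, n_pairs = n)
}

#' Full method-agreement report for two matrices
#'
#' Convenience wrapper running [pair_matrices()], [linear_agreement()]
#' and [bland_altman()].
#'
#' @inheritParams pair_matrices
#' @inheritParams bland_altman
#' @return An `agreement_stats` list combining both analyses.
#' @export
agreement_stats <- function(numerical, reference, dynamic_range = NULL,
                            sd_type = "population") {
  pairs <- pair_matrices(numerical, reference)
  out <- c(linear_agreement(pairs),
           bland_altman(pairs, dynamic_range, sd_type),
           list(n_dropped = attr(pairs, "n_dropped")))
  structure(out, class = "agreement_stats")
}

#' @export
print.agreement_stats <- function(x, ...) {
  cat("Method agreement (numerical vs reference)\n")
  cat(sprintf("  n = %d pairs (%d dropped)\n", x$n_pairs, x$n_dropped))
  cat(sprintf("  regression: slope %.3f, intercept %.4g uM, R^2 %.3f\n",
              x$slope, x$intercept, x$r_squared))
  cat(sprintf("  Bland-Altman: mean diff %.4g uM, LoA +/- %.3g uM (%.3g%% of %.3g uM range)\n",
              x$mean_difference, x$loa_halfwidth,
              x$loa_percent_dynamic_range, x$dynamic_range))
  invisible(x)
}
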