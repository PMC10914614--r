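# Absolute quantitation arithmetic: ribosomes per cell from A260, cells
# loaded per gel lane, and protein copies per cell via a purified-protein
# standard curve (least squares through the origin).

#' Avogadro constant (SI exact), molecules per mole
#' @export
AVOGADRO <- 6.02214076e23

#' Ribosomes per cell from an A260 measurement
#'
#' Converts the 260 nm absorbance of a ribosome-containing sample into a
#' molar concentration with the 70S extinction coefficient, scales by the
#' sample volume and Avogadro's number, and divides by the number of cells
#' lysed:
#' `(a260 / (epsilon * path_cm)) * volume_l * N_A / n_cells`.
#'
#' @param a260 Absorbance at 260 nm (dimensionless).
#' @param volume_l Sample volume in litres.
#' @param n_cells Number of cells lysed into the sample.
#' @param epsilon Molar extinction coefficient of the particle,
#'   1/(M cm); default `3.84e7` for bacterial 70S ribosomes.
#' @param path_cm Optical path length, cm (default 1).
#' @return Ribosomes per cell.
#' @export
ribosomes_per_cell <- function(a260, volume_l, n_cells,
                               epsilon = 3.84e7, path_cm = 1.0) {
  check_scalar_positive(a260, "a260")
  check_scalar_positive(volume_l, "volume_l")
  check_scalar_positive(n_cells, "n_cells")
  check_scalar_positive(epsilon, "epsilon")
  check_scalar_positive(path_cm, "path_cm")
  molar <- a260 / (epsilon * path_cm)
  molar * volume_l * AVOGADRO / n_cells
}

#' Cells loaded per gel lane
#'
#' `cfu_per_ml * culture_ml * lane_fraction`: the culture's colony count
#' scaled by the fraction of the culture loaded on one lane.
#'
#' @param cfu_per_ml Colony-forming units per ml of culture.
#' @param culture_ml Culture volume in ml.
#' @param lane_fraction Fraction of the culture loaded (0 < f <= 1).
#' @return Cell count.
#' @export
cells_loaded <- function(cfu_per_ml, culture_ml, lane_fraction) {
  check_scalar_positive(cfu_per_ml, "cfu_per_ml")
  check_scalar_positive(culture_ml, "culture_ml")
  check_scalar_positive(lane_fraction, "lane_fraction")
  if (lane_fraction > 1)
    gs_parameter_error("'lane_fraction' cannot exceed 1")
  cfu_per_ml * culture_ml * lane_fraction
}

#' Fit a standard curve through the origin
#'
#' Least squares fit of `signal = slope * molecules` with no intercept
#' (zero protein must give zero signal on a blot). Residuals are kept so a
#' nonlinear blot can be rejected by inspection.
#'
#' @param molecules Molecules loaded per standard point (> 0).
#' @param signal Measured signal per point (>= 0).
#' @return An object of class `"standard_curve"`: list with `points`
#'   (data.frame), `slope` (signal per molecule), `residuals` and
#'   `r_squared` (about the origin fit).
#' @export
fit_standard_curve <- function(molecules, signal) {
  molecules <- as.numeric(molecules); signal <- as.numeric(signal)
  if (length(molecules) < 1L || length(molecules) != length(signal))
    gs_parameter_error("'molecules' and 'signal' must be equal-length, non-empty")
  if (any(!is.finite(molecules)) || any(molecules <= 0))
    gs_parameter_error("'molecules' must be positive and finite")
  if (any(!is.finite(signal)) || any(signal < 0))
    gs_parameter_error("'signal' must be non-negative and finite")
  slope <- sum(molecules * signal) / sum(molecules^2)
  if (slope <= 0)
    gs_error("standard curve has non-positive slope; cannot quantify",
             "gradsift_degenerate_curve")
  fitted <- slope * molecules
  res <- signal - fitted
  ss_tot <- sum(signal^2)  # about the origin, consistent with the fit
  structure(list(points = data.frame(molecules = molecules, signal = signal),
                 slope = slope,
                 residuals = res,
                 r_squared = if (ss_tot > 0) 1 - sum(res^2) / ss_tot else NA_real_),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("<standard_curve> %d points, slope %.4g signal/molecule, R^2 (origin) %.4f\n",
              nrow(x$points), x$slope, x$r_squared))
  invisible(x)
}

#' Protein copies per cell from a blot signal and a standard curve
#'
#' `(sample_signal / slope) / n_cells`: the sample signal converted to
#' molecules via the standard slope, divided by the number of cells loaded
#' on the lane.
#'
#' @param sample_signal Measured signal of the sample band (>= 0).
#' @param curve A `"standard_curve"` from [fit_standard_curve()].
#' @param n_cells Cells loaded on the sample lane, e.g. from
#'   [cells_loaded()].
#' @return Copies per cell.
#' @export
copies_per_cell <- function(sample_signal, curve, n_cells) {
  stopifnot(inherits(curve, "standard_curve"))
  if (!is.numeric(sample_signal) || sample_signal < 0 || !is.finite(sample_signal))
    gs_parameter_error("'sample_signal' must be non-negative and finite")
  check_scalar_positive(n_cells, "n_cells")
  (sample_signal / curve$slope) / n_cells
}
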