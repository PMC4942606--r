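#' Construct a SNOM transmission image
#'
#' A transmission image is one real-valued pixel matrix recorded for one cell
#' at one fixed biomarker wavelength. Rows are slow-scan lines, columns are
#' fast-scan positions; the pixel pitch along the fast axis is
#' `scan_size_um / ncol(pixels)`.
#'
#' @param pixels numeric matrix (>= 2 rows and columns, all finite).
#' @param wavelength_um illumination wavelength in micrometres.
#' @param biomarker one of `"lipids"`, `"amide_I"`, `"amide_II"`, `"dna"`.
#' @param cell_id identifier of the imaged cell.
#' @param class_label cytology class of the cell.
#' @param scan_size_um physical scan extent in micrometres.
#' @return An object of class `transmission_image`.
#' @export
transmission_image <- function(pixels, wavelength_um, biomarker,
                               cell_id = NA_character_,
                               class_label = NA_character_,
                               scan_size_um = 400) {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    stop_validation("`pixels` must be a numeric matrix")
  }
  if (nrow(pixels) < 2L || ncol(pixels) < 2L) {
    stop_validation("`pixels` must have at least 2 rows and 2 columns")
  }
  if (!all(is.finite(pixels))) {
    stop_validation("`pixels` must contain only finite values")
  }
  assert_scalar_number(scan_size_um, "scan_size_um", 0, strict = TRUE)
  biomarker <- match.arg(biomarker, snom_biomarkers())
  structure(
    list(
      pixels = unname(pixels),
      wavelength_um = wavelength_um,
      biomarker = biomarker,
      cell_id = cell_id,
      class_label = class_label,
      scan_size_um = scan_size_um
    ),
    class = "transmission_image"
  )
}

#' @export
print.transmission_image <- function(x, ...) {
  cat(sprintf(
    "<transmission_image> %dx%d px, %s (%.2f um), cell %s [%s], scan %g um\n",
    nrow(x$pixels), ncol(x$pixels), x$biomarker, x$wavelength_um,
    x$cell_id, x$class_label, x$scan_size_um
  ))
  invisible(x)
}

# Internal constructor for spectrum-like signals (the 1 x c row vector
# obtained by column-averaging a transmission image).
new_signal <- function(values, spatial_axis_um, biomarker,
                       source_cell_id = NA_character_,
                       class_label = NA_character_,
                       normalized = FALSE) {
  if (length(values) != length(spatial_axis_um)) {
    stop_validation("signal values and spatial axis must have equal length")
  }
  if (any(diff(spatial_axis_um) <= 0)) {
    stop_validation("spatial axis must be strictly increasing")
  }
  if (normalized && any(values < 0)) {
    stop_validation("a normalized signal must be non-negative")
  }
  structure(
    list(
      values = as.numeric(values),
      spatial_axis_um = as.numeric(spatial_axis_um),
      biomarker = biomarker,
      source_cell_id = source_cell_id,
      class_label = class_label,
      normalized = isTRUE(normalized)
    ),
    class = "spectrum_signal"
  )
}

#' @export
print.spectrum_signal <- function(x, ...) {
  cat(sprintf(
    "<spectrum_signal> %d points, %s, cell %s%s\n",
    length(x$values), x$biomarker, x$source_cell_id,
    if (x$normalized) " (normalized)" else ""
  ))
  invisible(x)
}

#' Construct a spectral dataset
#'
#' The common carrier for multivariate analysis: an `n x p` intensity matrix
#' over a strictly increasing variable axis (wavenumber in cm^-1 for ATR-FTIR
#' spectra, or spatial position in micrometres for stacked spectrum-like
#' signals), with one class label per sample.
#'
#' @param variables_axis strictly increasing numeric vector of length `p`.
#' @param intensities numeric `n x p` matrix of finite intensities.
#' @param class_labels character vector of length `n`.
#' @param sample_ids optional sample identifiers (defaults to `s1..sn`).
#' @return An object of class `spectral_dataset`.
#' @export
spectral_dataset <- function(variables_axis, intensities, class_labels,
                             sample_ids = NULL) {
  intensities <- as.matrix(intensities)
  n <- nrow(intensities)
  p <- ncol(intensities)
  if (n < 2L || p < 2L) {
    stop_validation("a spectral dataset needs >= 2 samples and >= 2 variables")
  }
  if (length(variables_axis) != p) {
    stop_validation("`variables_axis` length must equal ncol(intensities)")
  }
  if (any(diff(variables_axis) <= 0)) {
    stop_validation("`variables_axis` must be strictly increasing")
  }
  if (!all(is.finite(intensities))) {
    stop_validation("`intensities` must be finite")
  }
  if (length(class_labels) != n) {
    stop_validation("`class_labels` length must equal nrow(intensities)")
  }
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(n))
  if (length(sample_ids) != n || anyDuplicated(sample_ids)) {
    stop_validation("`sample_ids` must be unique and of length n")
  }
  structure(
    list(
      variables_axis = as.numeric(variables_axis),
      intensities = unname(intensities),
      class_labels = as.character(class_labels),
      sample_ids = as.character(sample_ids)
    ),
    class = "spectral_dataset"
  )
}

#' @export
print.spectral_dataset <- function(x, ...) {
  cat(sprintf(
    "<spectral_dataset> %d samples x %d variables, axis [%g, %g], %d classes\n",
    nrow(x$intensities), ncol(x$intensities),
    min(x$variables_axis), max(x$variables_axis),
    length(unique(x$class_labels))
  ))
  invisible(x)
}
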