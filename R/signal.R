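#' Reduce a transmission image to its spectrum-like signal
#'
#' Collapses the pixel matrix to a row vector by averaging over the slow-scan
#' direction: `s_j = (1/m) * sum_i x_ij`, one value per fast-scan column
#' (for a 150 x 150 image, a 1 x 150 signal). The spatial axis assigns column
#' `j` the position `(j - 1) * scan_size_um / c`, spanning `[0, scan_size)`.
#'
#' @param image a [transmission_image()].
#' @return An unnormalized `spectrum_signal`.
#' @export
image_to_signal <- function(image) {
  stopifnot(inherits(image, "transmission_image"))
  px <- image$pixels
  if (length(px) == 0L) stop_validation("empty image matrix")
  values <- colMeans(px)
  axis <- (seq_len(ncol(px)) - 1) * image$scan_size_um / ncol(px)
  new_signal(values, axis, image$biomarker,
             source_cell_id = image$cell_id,
             class_label = image$class_label,
             normalized = FALSE)
}

#' Normalize a spectrum-like signal
#'
#' Mean-centres the signal and takes the absolute value:
#' `|s - mean(s)|` elementwise. The centred vector has mean zero by
#' construction; the output is non-negative, which is what makes the
#' downstream area integrals well-defined. Normalizing twice is a contract
#' error — the second pass would silently measure deviations of deviations.
#'
#' @param signal an unnormalized `spectrum_signal`.
#' @return The normalized signal (`normalized` flag set).
#' @export
normalize_signal <- function(signal) {
  stopifnot(inherits(signal, "spectrum_signal"))
  if (signal$normalized) {
    stop_validation("signal is already normalized; double normalization is forbidden")
  }
  centred <- signal$values - mean(signal$values)
  out <- signal
  out$values <- abs(centred)
  out$normalized <- TRUE
  out
}

#' Average replicate signals pointwise
#'
#' @param signals list of `spectrum_signal`s of identical length, biomarker
#'   and normalization state.
#' @return A single `spectrum_signal`, metadata inherited from the first.
#' @export
average_replicates <- function(signals) {
  if (!is.list(signals) || length(signals) < 1L) {
    stop_validation("`signals` must be a non-empty list of spectrum signals")
  }
  stopifnot(all(vapply(signals, inherits, logical(1), "spectrum_signal")))
  lens <- vapply(signals, function(s) length(s$values), integer(1))
  if (length(unique(lens)) != 1L) {
    stop_validation("replicate signals must all have the same length")
  }
  bms <- unique(vapply(signals, function(s) s$biomarker, character(1)))
  if (length(bms) != 1L) {
    stop_validation("replicate signals must share one biomarker, got: ",
                    paste(bms, collapse = ", "))
  }
  norm <- unique(vapply(signals, function(s) s$normalized, logical(1)))
  if (length(norm) != 1L) {
    stop_validation("replicate signals must share one normalization state")
  }
  out <- signals[[1]]
  out$values <- rowMeans(vapply(signals, function(s) s$values,
                                numeric(lens[1])))
  out
}

# Snap an interval to the nearest axis points; returns the snapped index
# range and positions.
snap_interval <- function(axis, interval) {
  if (length(interval) != 2L || !all(is.finite(interval)) ||
      interval[1] >= interval[2]) {
    stop_validation("interval must be (lo, hi) with lo < hi")
  }
  if (interval[1] < min(axis) - 1e-9 || interval[2] > max(axis) + 1e-9) {
    stop_validation("interval must lie within the spatial axis range [",
                    min(axis), ", ", max(axis), "]")
  }
  i_lo <- which.min(abs(axis - interval[1]))
  i_hi <- which.min(abs(axis - interval[2]))
  if (i_lo >= i_hi) {
    stop_validation("interval collapses to fewer than two axis points after snapping")
  }
  list(idx = i_lo:i_hi, lo = axis[i_lo], hi = axis[i_hi])
}

#' Integrate a normalized signal over a spatial interval
#'
#' Trapezoidal quadrature of the signal over `[lo, hi]`, after snapping the
#' endpoints to the nearest axis points (the snapped endpoints are reported
#' as attributes `interval_lo` / `interval_hi`).
#'
#' @param signal a normalized `spectrum_signal`.
#' @param interval_um numeric `(lo, hi)` in micrometres, within the axis.
#' @return Non-negative area, with snapped-interval attributes.
#' @export
signal_area <- function(signal, interval_um) {
  stopifnot(inherits(signal, "spectrum_signal"))
  if (!signal$normalized) {
    stop_validation("areas are defined on normalized signals; call normalize_signal() first")
  }
  sn <- snap_interval(signal$spatial_axis_um, interval_um)
  x <- signal$spatial_axis_um[sn$idx]
  y <- signal$values[sn$idx]
  area <- sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
  structure(area, interval_lo = sn$lo, interval_hi = sn$hi)
}

#' Percentage area change relative to the normal class
#'
#' `100 * (area - area_normal) / area_normal`.
#'
#' @param area biomarker area for the class under comparison.
#' @param area_normal biomarker area for the normal class (must be > 0).
#' @return Signed percentage.
#' @export
delta_area_percent <- function(area, area_normal) {
  assert_scalar_number(area, "area", 0)
  if (!is.numeric(area_normal) || length(area_normal) != 1L ||
      !is.finite(area_normal) || area_normal <= 0) {
    stop_validation("`area_normal` must be > 0 (degenerate normal reference)")
  }
  100 * (area - area_normal) / area_normal
}

#' Automatic integration interval for a normalized signal
#'
#' Fallback used when no hand-picked interval is supplied: the smallest
#' interval containing every axis point where the signal exceeds half its
#' maximum, padded by 10% of the axis span and clipped to the axis.
#'
#' @param signal a normalized `spectrum_signal`.
#' @param threshold fraction of the maximum defining the support (default 0.5).
#' @param pad_fraction padding as a fraction of the full axis span.
#' @return Numeric `(lo, hi)`.
#' @export
auto_interval <- function(signal, threshold = 0.5, pad_fraction = 0.1) {
  stopifnot(inherits(signal, "spectrum_signal"))
  ax <- signal$spatial_axis_um
  v <- signal$values
  top <- max(v)
  if (top <= 0) return(c(min(ax), max(ax)))
  idx <- which(v >= threshold * top)
  pad <- pad_fraction * (max(ax) - min(ax))
  c(max(min(ax), ax[min(idx)] - pad), min(max(ax), ax[max(idx)] + pad))
}

#' Build the biomarker area / delta-area table
#'
#' For every (class, biomarker) group: normalize and replicate-average the
#' spectrum-like signals, integrate over the integration interval, and
#' express each class's area as a percentage change from the normal class
#' (absent for normal itself). The default replicate order is
#' normalize-then-average; `"average_then_normalize"` is also available since
#' the two orders differ on noisy data.
#'
#' @param signals list of unnormalized `spectrum_signal`s (one per image),
#'   each carrying `class_label` and `biomarker` metadata.
#' @param intervals optional named list mapping class labels to `(lo, hi)`
#'   intervals in micrometres; groups without an entry use [auto_interval()].
#' @param order replicate combination order.
#' @param normal_class label of the reference class (default `"normal"`).
#' @return A data frame with columns `class_label`, `biomarker`,
#'   `interval_lo_um`, `interval_hi_um`, `area`, `delta_area_pct` (`NA` for
#'   the normal class), ordered by (class appearance, biomarker order).
#' @export
build_area_table <- function(signals, intervals = NULL,
                             order = c("normalize_then_average",
                                       "average_then_normalize"),
                             normal_class = "normal") {
  order <- match.arg(order)
  stopifnot(all(vapply(signals, inherits, logical(1), "spectrum_signal")))
  classes <- unique(vapply(signals, function(s) s$class_label, character(1)))
  if (!normal_class %in% classes) {
    stop_validation("no '", normal_class, "' class among the signals; ",
                    "a normal reference is required")
  }
  bms <- intersect(snom_biomarkers(),
                   unique(vapply(signals, function(s) s$biomarker, character(1))))
  key <- function(s) paste(s$class_label, s$biomarker, sep = "\r")
  groups <- split(signals, vapply(signals, key, character(1)))
  combined <- list()
  for (cl in classes) {
    for (bm in bms) {
      g <- groups[[paste(cl, bm, sep = "\r")]]
      if (is.null(g)) {
        stop_validation("class '", cl, "' is missing biomarker '", bm, "'")
      }
      combined[[paste(cl, bm, sep = "\r")]] <- if (order == "normalize_then_average") {
        average_replicates(lapply(g, normalize_signal))
      } else {
        normalize_signal(average_replicates(g))
      }
    }
  }
  rows <- vector("list", length(classes) * length(bms))
  k <- 1L
  areas_normal <- numeric(0)
  for (cl in c(normal_class, setdiff(classes, normal_class))) {
    for (bm in bms) {
      sig <- combined[[paste(cl, bm, sep = "\r")]]
      iv <- if (!is.null(intervals) && !is.null(intervals[[cl]])) {
        intervals[[cl]]
      } else {
        auto_interval(sig)
      }
      a <- signal_area(sig, iv)
      rows[[k]] <- data.frame(
        class_label = cl, biomarker = bm,
        interval_lo_um = attr(a, "interval_lo"),
        interval_hi_um = attr(a, "interval_hi"),
        area = as.numeric(a),
        stringsAsFactors = FALSE
      )
      if (cl == normal_class) areas_normal[bm] <- as.numeric(a)
      k <- k + 1L
    }
  }
  tab <- do.call(rbind, rows)
  tab$delta_area_pct <- NA_real_
  non_normal <- tab$class_label != normal_class
  tab$delta_area_pct[non_normal] <- mapply(
    delta_area_percent,
    tab$area[non_normal],
    areas_normal[tab$biomarker[non_normal]]
  )
  # restore original class order (normal was computed first for reference)
  tab <- tab[order(match(tab$class_label, classes),
                   match(tab$biomarker, bms)), ]
  rownames(tab) <- NULL
  tab
}

#' Presentation-only image enhancement
#'
#' Mirrors the visual clean-up applied to published SNOM images: (1) subtract
#' each fast-scan row's median (line correction), then (2) remove high
#' spatial frequencies by zeroing all 2-D Fourier components with radial
#' frequency above `cutoff_fraction` of Nyquist and inverse-transforming.
#' The result is flagged `enhanced` and is for display only — quantitative
#' analysis runs on raw pixels.
#'
#' @param image a [transmission_image()].
#' @param cutoff_fraction radial frequency cutoff in (0, 1]; 1 keeps the full
#'   band (identity for step 2).
#' @return The enhanced [transmission_image()], with attribute
#'   `presentation_only = TRUE`.
#' @export
enhance_image <- function(image, cutoff_fraction = 0.5) {
  stopifnot(inherits(image, "transmission_image"))
  if (!is.numeric(cutoff_fraction) || length(cutoff_fraction) != 1L ||
      !is.finite(cutoff_fraction) ||
      cutoff_fraction <= 0 || cutoff_fraction > 1) {
    stop_validation("`cutoff_fraction` must be in (0, 1]")
  }
  px <- image$pixels
  # step 1: row-median line correction (fast-scan axis)
  px <- px - apply(px, 1L, stats::median)
  # step 2: radial low-pass in the 2-D frequency domain
  nr <- nrow(px)
  nc <- ncol(px)
  fr <- ifelse(seq_len(nr) - 1 <= nr / 2, seq_len(nr) - 1, seq_len(nr) - 1 - nr) / nr
  fc <- ifelse(seq_len(nc) - 1 <= nc / 2, seq_len(nc) - 1, seq_len(nc) - 1 - nc) / nc
  # radial frequency normalized so that 1 = the largest representable radius
  # (the grid corner, sqrt(2) x Nyquist); cutoff_fraction = 1 keeps everything
  rho <- sqrt(outer((fr / 0.5)^2, (fc / 0.5)^2, `+`)) / sqrt(2)
  keep <- rho <= cutoff_fraction + 1e-12
  ft <- stats::fft(px)
  ft[!keep] <- 0
  px2 <- Re(stats::fft(ft, inverse = TRUE)) / (nr * nc)
  out <- image
  out$pixels <- px2
  attr(out, "presentation_only") <- TRUE
  out
}
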