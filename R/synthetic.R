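#' Class/biomarker effect table
#'
#' Encodes, per cytology class and biomarker, the absorption amplitude of the
#' simulated cell relative to the normal class (normal is defined as 1). The
#' default table is derived from the published percentage area variations of
#' the four biomarkers relative to normal cells: a multiplier `1 + dA/100`
#' reproduces those percentage changes exactly in a noise-free simulation,
#' because the downstream signal extraction is linear in the absorption
#' amplitude.
#'
#' @param effect numeric matrix with one row per class and one column per
#'   biomarker, strictly positive, `effect["normal", ] == 1`.
#' @param classes,biomarkers row/column labels; defaults to the study's five
#'   cytology classes and four biomarkers.
#' @return An object of class `class_effect_table`.
#' @examples
#' eff <- default_effect_table()
#' eff$effect["CIN2_HGCGIN", ]  # all > 1: every biomarker elevated
#' @export
class_effect_table <- function(effect,
                               classes = rownames(effect),
                               biomarkers = colnames(effect)) {
  effect <- as.matrix(effect)
  if (is.null(classes) || is.null(biomarkers)) {
    stop_validation("`effect` needs class row names and biomarker column names")
  }
  rownames(effect) <- classes
  colnames(effect) <- biomarkers
  if (!"normal" %in% classes) {
    stop_validation("the effect table must contain a 'normal' class row")
  }
  if (!all(is.finite(effect)) || any(effect <= 0)) {
    stop_validation("all effect multipliers must be finite and strictly positive")
  }
  if (any(abs(effect["normal", ] - 1) > 1e-12)) {
    stop_validation("effect('normal', b) must equal 1 for every biomarker")
  }
  structure(
    list(classes = classes, biomarkers = biomarkers, effect = effect),
    class = "class_effect_table"
  )
}

#' @rdname class_effect_table
#' @export
default_effect_table <- function() {
  bm <- snom_biomarkers()
  cl <- snom_classes()
  # Relative amplitude vs normal, biomarker order (lipids, amide_I, amide_II,
  # dna). Signs of (multiplier - 1) follow the published area-change pattern:
  # dyskaryosis loses Amide I and lipids while Amide II and DNA rise; the
  # pre-invasive CIN2/HGCGIN cell is elevated in all four; adenocarcinoma 1B1
  # is depressed in all but DNA.
  eff <- rbind(
    normal                 = c(1.00, 1.00, 1.00, 1.00),
    low_grade_dyskaryosis  = c(0.69, 0.27, 2.43, 2.11),
    high_grade_dyskaryosis = c(0.22, 0.06, 1.40, 2.32),
    CIN2_HGCGIN            = c(1.93, 1.38, 6.09, 13.72),
    adenocarcinoma_1B1     = c(0.53, 0.34, 0.54, 6.85)
  )
  colnames(eff) <- bm
  class_effect_table(eff, classes = cl, biomarkers = bm)
}

#' Simulation configuration for SNOM transmission images
#'
#' Defaults mirror the acquisition geometry of the study: 150 x 150 pixel
#' matrices covering a 400 um x 400 um scan, imaged at the four fixed
#' biomarker wavelengths (lipids 5.71 um, Amide I 6.06 um, Amide II 6.46 um,
#' DNA 8.16 um), three replicate images per biomarker. The simulated cell is
#' a filled ellipse with a cosine-tapered rim on a uniform background;
#' absorption adds a class- and biomarker-dependent amplitude inside the
#' cell. The lipid channel receives extra pixel noise
#' (`lipid_noise_multiplier`) to emulate its lower signal-to-noise ratio.
#'
#' @param image_rows,image_cols pixel counts (>= 2).
#' @param scan_size_um physical scan extent (um).
#' @param wavelengths_um named vector of per-biomarker wavelengths (um).
#' @param cell_center_px ellipse centre `(row, col)`; `NULL` = image centre.
#' @param cell_radii_px ellipse semi-axes `(row, col)` in pixels.
#' @param taper_fraction rim width as a fraction of the radius; the mask is 1
#'   inside the ellipse and decays smoothly to 0 over the rim.
#' @param baseline_level uniform background level.
#' @param base_amplitude absorption amplitude of the normal class.
#' @param noise_sd pixel noise standard deviation.
#' @param lipid_noise_multiplier (>= 1) noise inflation for the lipid channel.
#' @param line_offset_sd standard deviation of per-row additive offsets
#'   (slow-scan line artifacts).
#' @param replicates images per (cell, biomarker).
#' @param polarity `"absorption"` (cell brighter than background, default) or
#'   `"transmission"` (cell darker).
#' @param seed default RNG seed used when a generator is called without one.
#' @return An object of class `snom_sim_config`.
#' @export
snom_sim_config <- function(image_rows = 150L, image_cols = 150L,
                            scan_size_um = 400,
                            wavelengths_um = c(lipids = 5.71, amide_I = 6.06,
                                               amide_II = 6.46, dna = 8.16),
                            cell_center_px = NULL,
                            cell_radii_px = c(45, 50),
                            taper_fraction = 0.15,
                            baseline_level = 0.2,
                            base_amplitude = 1,
                            noise_sd = 0.02,
                            lipid_noise_multiplier = 3,
                            line_offset_sd = 0.01,
                            replicates = 3L,
                            polarity = c("absorption", "transmission"),
                            seed = 1L) {
  polarity <- match.arg(polarity)
  if (image_rows < 2L || image_cols < 2L) {
    stop_validation("`image_rows` and `image_cols` must both be >= 2")
  }
  assert_scalar_number(scan_size_um, "scan_size_um", 0, strict = TRUE)
  assert_scalar_number(noise_sd, "noise_sd", 0)
  assert_scalar_number(line_offset_sd, "line_offset_sd", 0)
  assert_scalar_number(lipid_noise_multiplier, "lipid_noise_multiplier", 1)
  assert_scalar_number(taper_fraction, "taper_fraction", 0)
  if (replicates < 1L) stop_validation("`replicates` must be >= 1")
  if (is.null(names(wavelengths_um)) ||
      !all(snom_biomarkers() %in% names(wavelengths_um))) {
    stop_validation("`wavelengths_um` must be named for all four biomarkers")
  }
  if (is.null(cell_center_px)) {
    cell_center_px <- c((image_rows + 1) / 2, (image_cols + 1) / 2)
  }
  if (length(cell_center_px) != 2L || length(cell_radii_px) != 2L ||
      any(cell_radii_px <= 0)) {
    stop_validation("`cell_center_px` and `cell_radii_px` must be length-2, radii > 0")
  }
  outer_r <- cell_radii_px * (1 + taper_fraction)
  if (cell_center_px[1] - outer_r[1] < 1 ||
      cell_center_px[1] + outer_r[1] > image_rows ||
      cell_center_px[2] - outer_r[2] < 1 ||
      cell_center_px[2] + outer_r[2] > image_cols) {
    stop_validation("the cell ellipse (including its tapered rim) must fit inside the image")
  }
  structure(
    list(
      image_rows = as.integer(image_rows), image_cols = as.integer(image_cols),
      scan_size_um = scan_size_um, wavelengths_um = wavelengths_um,
      cell_center_px = cell_center_px, cell_radii_px = cell_radii_px,
      taper_fraction = taper_fraction, baseline_level = baseline_level,
      base_amplitude = base_amplitude, noise_sd = noise_sd,
      lipid_noise_multiplier = lipid_noise_multiplier,
      line_offset_sd = line_offset_sd, replicates = as.integer(replicates),
      polarity = polarity, seed = seed
    ),
    class = "snom_sim_config"
  )
}

# Smooth elliptical cell footprint: 1 inside the unit ellipse, cosine decay
# to 0 across the rim (normalized radius 1 .. 1 + taper), 0 beyond.
ellipse_mask <- function(rows, cols, center, radii, taper) {
  r <- (seq_len(rows) - center[1]) / radii[1]
  c_ <- (seq_len(cols) - center[2]) / radii[2]
  rho <- sqrt(outer(r^2, c_^2, `+`))
  m <- matrix(0, rows, cols)
  m[rho <= 1] <- 1
  if (taper > 0) {
    rim <- rho > 1 & rho < 1 + taper
    m[rim] <- 0.5 * (1 + cos(pi * (rho[rim] - 1) / taper))
  }
  m
}

#' Generate one synthetic SNOM transmission image
#'
#' The pixel model is `baseline + sign * amplitude * effect(class, biomarker)
#' * mask + row offsets + noise`, where `mask` is the tapered ellipse
#' footprint, `sign` is +1 for absorption-positive polarity, row offsets are
#' i.i.d. Gaussian per slow-scan line, and pixel noise is i.i.d. Gaussian
#' (scaled by `lipid_noise_multiplier` on the lipid channel).
#'
#' @param class_label,biomarker class and biomarker; must be present in
#'   `effects`.
#' @param config a [snom_sim_config()].
#' @param effects a [class_effect_table()].
#' @param seed RNG seed (defaults to `config$seed`).
#' @param cell_id identifier stored in the image metadata.
#' @return A [transmission_image()].
#' @export
generate_snom_image <- function(class_label, biomarker,
                                config = snom_sim_config(),
                                effects = default_effect_table(),
                                seed = config$seed,
                                cell_id = paste0("cell_", class_label)) {
  if (!class_label %in% effects$classes) {
    stop_validation("unknown class '", class_label, "'; expected one of: ",
                    paste(effects$classes, collapse = ", "))
  }
  if (!biomarker %in% effects$biomarkers) {
    stop_validation("unknown biomarker '", biomarker, "'; expected one of: ",
                    paste(effects$biomarkers, collapse = ", "))
  }
  eff <- effects$effect[class_label, biomarker]
  sgn <- if (config$polarity == "absorption") 1 else -1
  mask <- ellipse_mask(config$image_rows, config$image_cols,
                       config$cell_center_px, config$cell_radii_px,
                       config$taper_fraction)
  nsd <- config$noise_sd *
    if (biomarker == "lipids") config$lipid_noise_multiplier else 1
  px <- with_seed(seed, {
    base <- config$baseline_level + sgn * config$base_amplitude * eff * mask
    offs <- if (config$line_offset_sd > 0) {
      stats::rnorm(config$image_rows, 0, config$line_offset_sd)
    } else {
      numeric(config$image_rows)
    }
    noise <- if (nsd > 0) {
      matrix(stats::rnorm(length(base), 0, nsd), nrow(base), ncol(base))
    } else {
      0
    }
    base + offs + noise
  })
  transmission_image(px, config$wavelengths_um[[biomarker]], biomarker,
                     cell_id = cell_id, class_label = class_label,
                     scan_size_um = config$scan_size_um)
}

#' Generate a full synthetic SNOM image dataset
#'
#' One image per (class, biomarker, replicate): with the defaults, 5 classes
#' x 4 biomarkers x 3 replicates = 60 images, emulating one imaged cell per
#' cytology class measured in triplicate at each biomarker wavelength.
#'
#' @inheritParams generate_snom_image
#' @param dir optional output directory; when given, each image is written as
#'   a whitespace-delimited ASCII matrix file and the manifest as
#'   `manifest.csv`.
#' @return A list with `images` (list of [transmission_image()]) and
#'   `manifest` (data frame with columns `file_path`, `cell_id`,
#'   `class_label`, `biomarker`, `wavelength_um`, `replicate_id`).
#' @export
generate_snom_dataset <- function(config = snom_sim_config(),
                                  effects = default_effect_table(),
                                  seed = config$seed,
                                  dir = NULL) {
  if (config$replicates < 1L) stop_validation("`replicates` must be >= 1")
  grid <- expand.grid(
    replicate_id = seq_len(config$replicates),
    biomarker = effects$biomarkers,
    class_label = effects$classes,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )[, c("class_label", "biomarker", "replicate_id")]
  # one derived sub-seed per image keeps images independent yet reproducible
  sub_seeds <- with_seed(seed, sample.int(.Machine$integer.max, nrow(grid)))
  images <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    images[[i]] <- generate_snom_image(
      grid$class_label[i], grid$biomarker[i], config, effects,
      seed = sub_seeds[i]
    )
  }
  manifest <- data.frame(
    file_path = sprintf("%s_%s_rep%d.txt", grid$class_label, grid$biomarker,
                        grid$replicate_id),
    cell_id = paste0("cell_", grid$class_label),
    class_label = grid$class_label,
    biomarker = grid$biomarker,
    wavelength_um = as.numeric(config$wavelengths_um[grid$biomarker]),
    replicate_id = grid$replicate_id,
    stringsAsFactors = FALSE
  )
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    for (i in seq_along(images)) {
      write_matrix_text(images[[i]]$pixels, file.path(dir, manifest$file_path[i]))
    }
    utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  }
  list(images = images, manifest = manifest)
}

#' Simulation configuration for ATR-FTIR-like spectra
#'
#' Defaults follow the study's acquisition and findings: a 900-3100 cm^-1
#' axis at 8 cm^-1 spacing (276 points), Gaussian bands at the ten
#' discriminant wavenumbers reported for cervical cytology (1022, 1157, 1184,
#' 1234, 1331, 1512, 1566, 1662, 2345, 2939 cm^-1), and ten spectra per
#' class. Per-class band amplitudes are free parameters; the defaults give
#' each class a distinct profile at several fingerprint bands (elevated
#' phosphate/nucleic-acid bands in dyskaryotic and neoplastic classes,
#' depressed glycogen and Amide I), well above the noise floor.
#'
#' @param wavenumber_start,wavenumber_end,spacing_cm1 axis definition (cm^-1).
#' @param band_centers_cm1 Gaussian band centres (cm^-1), all within the axis.
#' @param band_width_cm1 Gaussian band standard deviation (cm^-1).
#' @param class_amplitudes numeric matrix, one row per class, one column per
#'   band centre.
#' @param baseline_level constant baseline offset.
#' @param noise_sd i.i.d. Gaussian noise standard deviation.
#' @param n_per_class spectra per class.
#' @param seed default RNG seed.
#' @return An object of class `atr_sim_config`.
#' @export
atr_sim_config <- function(wavenumber_start = 900, wavenumber_end = 3100,
                           spacing_cm1 = 8,
                           band_centers_cm1 = c(1022, 1157, 1184, 1234, 1331,
                                                1512, 1566, 1662, 2345, 2939),
                           band_width_cm1 = 16,
                           class_amplitudes = NULL,
                           baseline_level = 0.05,
                           noise_sd = 0.01,
                           n_per_class = 10L,
                           seed = 1L) {
  assert_scalar_number(spacing_cm1, "spacing_cm1", 0, strict = TRUE)
  assert_scalar_number(band_width_cm1, "band_width_cm1", 0, strict = TRUE)
  assert_scalar_number(noise_sd, "noise_sd", 0)
  if (wavenumber_end <= wavenumber_start) {
    stop_validation("`wavenumber_end` must exceed `wavenumber_start`")
  }
  if (n_per_class < 1L) stop_validation("`n_per_class` must be >= 1")
  if (any(band_centers_cm1 < wavenumber_start) ||
      any(band_centers_cm1 > wavenumber_end)) {
    stop_validation("all band centers must lie within the wavenumber axis")
  }
  if (is.null(class_amplitudes)) {
    class_amplitudes <- rbind(
      normal                 = c(0.50, 0.40, 0.35, 0.55, 0.30, 0.40, 0.65, 0.90, 0.25, 0.45),
      low_grade_dyskaryosis  = c(0.35, 0.45, 0.50, 0.80, 0.45, 0.40, 0.90, 0.60, 0.25, 0.40),
      high_grade_dyskaryosis = c(0.25, 0.50, 0.60, 0.95, 0.55, 0.35, 0.75, 0.40, 0.30, 0.35),
      CIN2_HGCGIN            = c(0.60, 0.60, 0.70, 1.10, 0.70, 0.55, 1.10, 1.00, 0.35, 0.55),
      adenocarcinoma_1B1     = c(0.40, 0.35, 0.55, 0.90, 0.60, 0.30, 0.45, 0.55, 0.20, 0.30)
    )
  }
  class_amplitudes <- as.matrix(class_amplitudes)
  if (is.null(rownames(class_amplitudes))) {
    stop_validation("`class_amplitudes` must have class row names")
  }
  if (ncol(class_amplitudes) != length(band_centers_cm1)) {
    stop_validation("each class amplitude vector must match the number of band centers")
  }
  structure(
    list(
      wavenumber_start = wavenumber_start, wavenumber_end = wavenumber_end,
      spacing_cm1 = spacing_cm1, band_centers_cm1 = band_centers_cm1,
      band_width_cm1 = band_width_cm1, class_amplitudes = class_amplitudes,
      baseline_level = baseline_level, noise_sd = noise_sd,
      n_per_class = as.integer(n_per_class), seed = seed
    ),
    class = "atr_sim_config"
  )
}

#' Generate a synthetic ATR-FTIR spectral dataset
#'
#' Each spectrum is `baseline + sum of Gaussian bands + noise`, with band
#' amplitudes drawn from the per-class row of `config$class_amplitudes`.
#'
#' @param config an [atr_sim_config()].
#' @param seed RNG seed (defaults to `config$seed`).
#' @return A [spectral_dataset()] with `n_per_class` spectra per class.
#' @export
generate_atr_dataset <- function(config = atr_sim_config(),
                                 seed = config$seed) {
  axis <- seq(config$wavenumber_start, config$wavenumber_end,
              by = config$spacing_cm1)
  classes <- rownames(config$class_amplitudes)
  # p x n_bands Gaussian band profiles, shared across classes
  profiles <- vapply(
    config$band_centers_cm1,
    function(c0) exp(-(axis - c0)^2 / (2 * config$band_width_cm1^2)),
    numeric(length(axis))
  )
  n <- length(classes) * config$n_per_class
  X <- with_seed(seed, {
    out <- matrix(NA_real_, n, length(axis))
    row <- 1L
    for (cl in classes) {
      clean <- config$baseline_level +
        as.numeric(profiles %*% config$class_amplitudes[cl, ])
      for (k in seq_len(config$n_per_class)) {
        noise <- if (config$noise_sd > 0) {
          stats::rnorm(length(axis), 0, config$noise_sd)
        } else {
          0
        }
        out[row, ] <- clean + noise
        row <- row + 1L
      }
    }
    out
  })
  labels <- rep(classes, each = config$n_per_class)
  ids <- paste0(labels, "_", rep(seq_len(config$n_per_class), length(classes)))
  spectral_dataset(axis, X, labels, ids)
}
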