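test_that("default effect table encodes the published area-change sign pattern", {
  eff <- default_effect_table()
  expect_equal(unname(eff$effect["normal", ]), rep(1, 4))
  expect_true(all(eff$effect > 0))
  # signs of (multiplier - 1), biomarker order (lipids, amide_I, amide_II, dna)
  expected_signs <- rbind(
    low_grade_dyskaryosis  = c(-1, -1, +1, +1),
    high_grade_dyskaryosis = c(-1, -1, +1, +1),
    CIN2_HGCGIN            = c(+1, +1, +1, +1),
    adenocarcinoma_1B1     = c(-1, -1, -1, +1)
  )
  for (cl in rownames(expected_signs)) {
    expect_equal(unname(sign(eff$effect[cl, ] - 1)), expected_signs[cl, ],
                 info = cl)
  }
})

test_that("effect table constructor validates its invariants", {
  bad <- default_effect_table()$effect
  bad["normal", 1] <- 1.5
  expect_error(class_effect_table(bad), "normal")
  bad2 <- default_effect_table()$effect
  bad2[2, 2] <- -0.1
  expect_error(class_effect_table(bad2), "positive")
})

test_that("noise-free image construction is exact inside and outside the cell", {
  cfg <- snom_sim_config(image_rows = 40, image_cols = 40, noise_sd = 0,
                         line_offset_sd = 0, baseline_level = 0,
                         base_amplitude = 1, cell_radii_px = c(10, 12),
                         taper_fraction = 0)
  img <- generate_snom_image("normal", "dna", cfg, seed = 1)
  ctr <- cfg$cell_center_px
  rho <- sqrt(outer(((1:40) - ctr[1]) / 10, rep(1, 40))^2 +
              outer(rep(1, 40), ((1:40) - ctr[2]) / 12)^2)
  expect_true(all(img$pixels[rho <= 1] == 1))
  expect_true(all(img$pixels[rho > 1] == 0))
})

test_that("image generation is deterministic per seed and varies across seeds", {
  cfg <- snom_sim_config(image_rows = 30, image_cols = 30,
                         cell_radii_px = c(8, 8))
  a <- generate_snom_image("normal", "lipids", cfg, seed = 11)
  b <- generate_snom_image("normal", "lipids", cfg, seed = 11)
  c <- generate_snom_image("normal", "lipids", cfg, seed = 12)
  expect_identical(a$pixels, b$pixels)
  expect_false(identical(a$pixels, c$pixels))
})

test_that("unknown class or biomarker gives a labelled lookup error", {
  expect_error(generate_snom_image("mystery", "dna"), "unknown class")
  expect_error(generate_snom_image("normal", "amideI"), "unknown biomarker")
})

test_that("an ellipse that does not fit the image is a configuration error", {
  expect_error(
    snom_sim_config(image_rows = 20, image_cols = 20, cell_radii_px = c(15, 15)),
    "fit inside"
  )
})

test_that("noise-free class/normal in-ellipse mean ratio equals the effect multiplier", {
  cfg <- snom_sim_config(image_rows = 50, image_cols = 50, noise_sd = 0,
                         line_offset_sd = 0, baseline_level = 0,
                         cell_radii_px = c(14, 16))
  eff <- default_effect_table()
  mask_pos <- {
    ctr <- cfg$cell_center_px
    rho <- sqrt(outer(((1:50) - ctr[1]) / 14, rep(1, 50))^2 +
                outer(rep(1, 50), ((1:50) - ctr[2]) / 16)^2)
    rho <= 1
  }
  for (bm in c("lipids", "amide_I", "amide_II", "dna")) {
    base <- generate_snom_image("normal", bm, cfg, eff, seed = 1)
    for (cl in c("low_grade_dyskaryosis", "CIN2_HGCGIN")) {
      img <- generate_snom_image(cl, bm, cfg, eff, seed = 1)
      ratio <- mean(img$pixels[mask_pos]) / mean(base$pixels[mask_pos])
      expect_equal(ratio, unname(eff$effect[cl, bm]), tolerance = 1e-12)
    }
  }
})

test_that("pre-invasive CIN2/HGCGIN exceeds normal at all four biomarkers", {
  cfg <- snom_sim_config(image_rows = 50, image_cols = 50, noise_sd = 0,
                         line_offset_sd = 0, cell_radii_px = c(14, 16))
  for (bm in c("lipids", "amide_I", "amide_II", "dna")) {
    nrm <- generate_snom_image("normal", bm, cfg, seed = 1)
    cin <- generate_snom_image("CIN2_HGCGIN", bm, cfg, seed = 1)
    expect_gt(mean(cin$pixels), mean(nrm$pixels))
  }
})

test_that("dataset generation counts images and writes a coherent manifest", {
  cfg <- snom_sim_config(image_rows = 20, image_cols = 20,
                         cell_radii_px = c(5, 6), replicates = 3)
  ds <- generate_snom_dataset(cfg, seed = 1)
  expect_length(ds$images, 5 * 4 * 3)
  expect_equal(nrow(ds$manifest), 60)
  cfg1 <- snom_sim_config(image_rows = 20, image_cols = 20,
                          cell_radii_px = c(5, 6), replicates = 1)
  expect_length(generate_snom_dataset(cfg1, seed = 1)$images, 20)
  # distinct seeds: identical manifests, different pixels
  ds2 <- generate_snom_dataset(cfg, seed = 2)
  expect_identical(ds$manifest, ds2$manifest)
  expect_false(identical(ds$images[[1]]$pixels, ds2$images[[1]]$pixels))
})

test_that("ATR axis and sample counts follow the configuration", {
  ds <- generate_atr_dataset(atr_sim_config(), seed = 1)
  expect_length(ds$variables_axis, 276)  # floor((3100-900)/8) + 1
  expect_equal(nrow(ds$intensities), 50)
  expect_equal(as.vector(table(ds$class_labels)), rep(10L, 5))
})

test_that("a single noise-free band peaks at the axis point nearest its center", {
  amp <- matrix(1, 1, 1, dimnames = list("only", NULL))
  cfg <- atr_sim_config(band_centers_cm1 = 1333, class_amplitudes = amp,
                        noise_sd = 0, n_per_class = 2)
  ds <- generate_atr_dataset(cfg, seed = 1)
  peak <- ds$variables_axis[which.max(ds$intensities[1, ])]
  expect_equal(peak, ds$variables_axis[which.min(abs(ds$variables_axis - 1333))])
})

test_that("band centers outside the axis are a configuration error", {
  expect_error(atr_sim_config(band_centers_cm1 = c(1022, 5000)), "within")
})

test_that("ATR generation is a pure function of (config, seed)", {
  cfg <- atr_sim_config(n_per_class = 3)
  a <- generate_atr_dataset(cfg, seed = 5)
  b <- generate_atr_dataset(cfg, seed = 5)
  expect_identical(a$intensities, b$intensities)
})

test_that("stronger class separation never degrades SPA-LDA test accuracy", {
  base <- atr_sim_config()$class_amplitudes
  delta <- sweep(base, 2L, base["normal", ])  # class contrasts vs normal
  acc <- vapply(c(0.2, 0.6, 1.0), function(s) {
    amps <- sweep(delta * s, 2L, base["normal", ], `+`)
    cfg <- atr_sim_config(class_amplitudes = amps, noise_sd = 0.08)
    ds <- generate_atr_dataset(cfg, seed = 31)
    rep <- run_atr_pipeline(ds, max_A = 6, max_len = 6)
    rep$spa_lda_accuracy
  }, numeric(1))
  expect_true(all(diff(acc) >= 0))
})
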