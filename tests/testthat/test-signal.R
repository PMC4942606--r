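test_that("image reduction equals the explicit double-loop column mean", {
  img <- transmission_image(matrix(1, 150, 150), 8.16, "dna")
  expect_equal(image_to_signal(img)$values, rep(1, 150))

  m <- matrix(1:12, 4, 3, byrow = TRUE)
  sig <- image_to_signal(transmission_image(m, 8.16, "dna", scan_size_um = 3))
  expect_equal(sig$values, c(5.5, 6.5, 7.5))  # frozen from the loop oracle
  expect_equal(sig$values, oracle_column_mean(m))

  set.seed(3)
  for (i in 1:50) {
    nr <- sample(2:20, 1); nc <- sample(2:20, 1)
    m <- matrix(rnorm(nr * nc), nr, nc)
    got <- image_to_signal(transmission_image(m, 5.71, "lipids"))$values
    expect_equal(got, oracle_column_mean(m), tolerance = 1e-12)
  }
})

test_that("image reduction is linear and respects row/column permutations", {
  set.seed(4)
  X <- matrix(rnorm(48), 6, 8)
  Y <- matrix(rnorm(48), 6, 8)
  sig <- function(m) image_to_signal(transmission_image(m, 6.06, "amide_I"))$values
  expect_equal(sig(2 * X + 3 * Y), 2 * sig(X) + 3 * sig(Y), tolerance = 1e-12)
  expect_equal(sig(X[sample(6), ]), sig(X), tolerance = 1e-12)
  perm <- sample(8)
  expect_equal(sig(X[, perm]), sig(X)[perm], tolerance = 1e-12)
})

test_that("normalization mean-centres then takes absolute values", {
  expect_equal(normalize_signal(toy_signal(c(1, 1, 1)))$values, c(0, 0, 0))
  expect_equal(normalize_signal(toy_signal(c(0, 2)))$values, c(1, 1))
  expect_equal(normalize_signal(toy_signal(c(1, 2, 6)))$values, c(2, 1, 3))
  set.seed(5)
  v <- rnorm(40)
  expect_lt(abs(mean(v - mean(v))), 1e-12)  # the centred stage has mean zero
  out <- normalize_signal(toy_signal(v))
  expect_true(all(out$values >= 0))
  expect_true(out$normalized)
})

test_that("double normalization is rejected", {
  once <- normalize_signal(toy_signal(c(1, 2, 6)))
  expect_error(normalize_signal(once), "already normalized")
})

test_that("replicate averaging is pointwise and validates its inputs", {
  s <- toy_signal(c(1, 2, 3))
  expect_equal(average_replicates(list(s, s, s))$values, s$values)
  expect_equal(average_replicates(list(s))$values, s$values)
  expect_equal(
    average_replicates(list(toy_signal(c(0, 0)), toy_signal(c(2, 4))))$values,
    c(1, 2)
  )
  expect_error(
    average_replicates(list(s, toy_signal(c(1, 2, 3), biomarker = "lipids"))),
    "biomarker"
  )
  expect_error(average_replicates(list(s, toy_signal(c(1, 2)))), "length")
})

test_that("areas follow trapezoidal quadrature with endpoint snapping", {
  rect <- toy_signal(c(1, 1), axis = c(0, 1), normalized = TRUE)
  expect_equal(as.numeric(signal_area(rect, c(0, 1))), 1.0)
  tri <- toy_signal(c(0, 1, 0), axis = c(0, 1, 2), normalized = TRUE)
  expect_equal(as.numeric(signal_area(tri, c(0, 2))), 1.0)
  expect_equal(as.numeric(signal_area(tri, c(0, 1))), 0.5)
  # endpoints snap to the nearest axis points
  a <- signal_area(tri, c(0.1, 1.9))
  expect_equal(attr(a, "interval_lo"), 0)
  expect_equal(attr(a, "interval_hi"), 2)
  expect_error(signal_area(tri, c(1, 1)), "lo < hi")
  expect_error(signal_area(toy_signal(c(0, 1, 0), axis = c(0, 1, 2)),
                           c(0, 2)), "normalized")
})

test_that("enlarging the interval never decreases the area", {
  set.seed(6)
  for (i in 1:25) {
    v <- abs(rnorm(30))
    sig <- toy_signal(v, axis = 0:29, normalized = TRUE)
    lo <- sort(sample(0:28, 2))
    inner <- c(lo[1] + 0.4, lo[2] + 0.6)
    outer_iv <- c(max(0, inner[1] - sample(0:5, 1)),
                  min(29, inner[2] + sample(0:5, 1)))
    if (inner[1] >= inner[2]) next
    expect_gte(as.numeric(signal_area(sig, outer_iv)) + 1e-12,
               as.numeric(signal_area(sig, inner)))
  }
})

test_that("delta area percent follows 100 * (A - A_ref) / A_ref", {
  expect_equal(delta_area_percent(2, 2), 0)
  expect_equal(delta_area_percent(4, 2), 100)
  expect_equal(delta_area_percent(1, 2), -50)
  expect_error(delta_area_percent(1, 0), "degenerate")
})

test_that("the area table recovers the generating sign pattern, counts and zeros", {
  cfg <- snom_sim_config(image_rows = 40, image_cols = 40, noise_sd = 0,
                         line_offset_sd = 0, cell_radii_px = c(10, 12),
                         replicates = 2)
  eff <- default_effect_table()
  ds <- generate_snom_dataset(cfg, eff, seed = 1)
  signals <- lapply(ds$images, image_to_signal)
  tab <- build_area_table(signals)
  expect_equal(nrow(tab), 20)
  expect_equal(sum(is.na(tab$delta_area_pct)), 4)
  non_normal <- tab[tab$class_label != "normal", ]
  for (i in seq_len(nrow(non_normal))) {
    want <- sign(eff$effect[non_normal$class_label[i], non_normal$biomarker[i]] - 1)
    expect_equal(sign(non_normal$delta_area_pct[i]), unname(want))
  }
  # all-equal effects: every delta is zero
  flat <- class_effect_table(matrix(1, 5, 4, dimnames = dimnames(eff$effect)))
  ds0 <- generate_snom_dataset(cfg, flat, seed = 1)
  tab0 <- build_area_table(lapply(ds0$images, image_to_signal))
  expect_equal(tab0$delta_area_pct[!is.na(tab0$delta_area_pct)],
               rep(0, 16), tolerance = 1e-9)
})

test_that("area table validation names missing classes and biomarkers", {
  cfg <- snom_sim_config(image_rows = 20, image_cols = 20, replicates = 1,
                         cell_radii_px = c(5, 6))
  ds <- generate_snom_dataset(cfg, seed = 1)
  signals <- lapply(ds$images, image_to_signal)
  no_normal <- Filter(function(s) s$class_label != "normal", signals)
  expect_error(build_area_table(no_normal), "normal")
  gap <- Filter(function(s) !(s$class_label == "CIN2_HGCGIN" &&
                                s$biomarker == "dna"), signals)
  expect_error(build_area_table(gap), "CIN2_HGCGIN.*dna")
})

test_that("image enhancement fixes constants, levels rows and passes full band", {
  cfg <- snom_sim_config(image_rows = 32, image_cols = 32, noise_sd = 0.01,
                         cell_radii_px = c(8, 8))
  img <- generate_snom_image("normal", "dna", cfg, seed = 3)

  const <- transmission_image(matrix(5, 16, 16), 8.16, "dna")
  enh <- enhance_image(const, 0.5)
  expect_equal(enh$pixels, matrix(0, 16, 16), tolerance = 1e-10)  # median removed

  # one row offset by +5: after line correction its median matches the rest
  px <- img$pixels
  px[7, ] <- px[7, ] + 5
  shifted <- transmission_image(px, 8.16, "dna")
  corrected <- shifted$pixels - apply(shifted$pixels, 1, stats::median)
  expect_equal(stats::median(corrected[7, ]), stats::median(corrected[8, ]),
               tolerance = 1e-12)

  # full-band cutoff leaves the (line-corrected) image untouched
  enh_full <- enhance_image(img, 1)
  manual <- img$pixels - apply(img$pixels, 1, stats::median)
  expect_equal(enh_full$pixels, manual, tolerance = 1e-10)
  expect_true(isTRUE(attr(enh_full, "presentation_only")))
  expect_error(enhance_image(img, 0), "cutoff_fraction")
})
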