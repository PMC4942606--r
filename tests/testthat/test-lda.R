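test_that("queries are assigned to the nearest class under the pooled metric", {
  set.seed(30)
  X <- rbind(matrix(rnorm(20, 0), 10, 2), matrix(rnorm(20, 10), 10, 2))
  y <- rep(c("a", "b"), each = 10)
  m <- fit_lda(X, y)
  expect_equal(lda_predict(m, matrix(c(1, 1), 1)), "a")
  expect_equal(lda_predict(m, matrix(c(9, 9), 1)), "b")
})

test_that("exact ties go to the lowest class index, with a message", {
  X <- rbind(c(-2, 0), c(-2, 1), c(-2, -1), c(2, 0), c(2, 1), c(2, -1))
  y <- rep(c("a", "b"), each = 3)
  m <- fit_lda(X, y)  # zero within-class spread on x: exercises the ridge
  # the midpoint of the two class means is equidistant from both
  mid <- matrix(colMeans(m$class_means), 1)
  expect_message(p <- lda_predict(m, mid), "tie")
  expect_equal(p, "a")
})

test_that("discriminant scores match the brute-force Mahalanobis oracle", {
  set.seed(31)
  X <- matrix(rnorm(12), 6, 2) + rep(c(0, 4), each = 3)
  y <- rep(c("a", "b"), each = 3)
  m <- fit_lda(X, y)
  Q <- matrix(rnorm(10), 5, 2)
  expect_equal(discriminant_scores(m, Q),
               oracle_mahalanobis(X, y, Q), tolerance = 1e-10)
  expect_equal(lda_predict(m, Q),
               colnames(oracle_mahalanobis(X, y, Q))[
                 apply(oracle_mahalanobis(X, y, Q), 1, which.min)])
})

test_that("a sample at a class mean scores zero for that class", {
  set.seed(32)
  X <- matrix(rnorm(30), 10, 3) + rep(c(0, 3), each = 5)
  y <- rep(c("a", "b"), each = 5)
  m <- fit_lda(X, y)
  sc <- discriminant_scores(m, m$class_means)
  expect_equal(diag(sc), c(0, 0), tolerance = 1e-10)
})

test_that("scores are invariant under a common affine shift", {
  set.seed(33)
  X <- matrix(rnorm(40), 10, 4) + rep(c(0, 2), each = 5)
  y <- rep(c("a", "b"), each = 5)
  Q <- matrix(rnorm(12), 3, 4)
  shift <- rnorm(4)
  m0 <- fit_lda(X, y)
  m1 <- fit_lda(sweep(X, 2, shift, `+`), y)
  expect_equal(discriminant_scores(m0, Q),
               discriminant_scores(m1, sweep(Q, 2, shift, `+`)),
               tolerance = 1e-8)
})

test_that("classes with fewer than two samples are rejected", {
  X <- matrix(rnorm(8), 4, 2)
  expect_error(fit_lda(X, c("a", "a", "a", "b")), ">= 2")
})

test_that("G cost matches its brute-force loop and is zero at class means", {
  set.seed(34)
  X <- matrix(rnorm(24), 8, 3) + rep(c(0, 3), each = 4)
  y <- rep(c("a", "b"), each = 4)
  m <- fit_lda(X, y)
  # samples exactly at their own class means
  expect_equal(g_cost(m, m$class_means, m$class_order), 0, tolerance = 1e-12)
  # equidistant sample: its ratio of equal distances is exactly 1
  mid <- matrix(colMeans(m$class_means), 1)
  expect_equal(g_cost(m, mid, "a"), 1, tolerance = 1e-10)
  # brute-force equivalence on a fuzzed validation set
  Xv <- matrix(rnorm(15), 5, 3)
  yv <- c("a", "b", "a", "b", "a")
  expect_equal(g_cost(m, Xv, yv), oracle_g_cost(X, y, Xv, yv),
               tolerance = 1e-10)
  expect_error(g_cost(m, Xv, c("a", "b", "c", "a", "b")), "absent")
})

test_that("label permutation drives prediction accuracy to chance", {
  set.seed(35)
  n <- 40
  X <- matrix(rnorm(n * 3), n, 3)  # pure noise features
  train <- 1:30
  test <- 31:40
  accs <- replicate(200, {
    y <- sample(rep(c("a", "b"), each = n / 2))
    m <- fit_lda(X[train, ], y[train])
    mean(lda_predict(m, X[test, ]) == y[test])
  })
  n_total <- 200 * length(test)
  half_width <- 1.96 * sqrt(0.25 / n_total)
  expect_lt(abs(mean(accs) - 0.5), half_width + 0.01)
})

test_that("PCA-LDA picks a small model when the structure is low-dimensional", {
  # class structure confined to a 2-D subspace, near-zero noise
  set.seed(36)
  centers <- rbind(c(0, 0), c(4, 0), c(0, 4), c(4, 4), c(2, 2))
  B <- qr.Q(qr(matrix(rnorm(20 * 2), 20, 2)))  # embed into 20 variables
  n_per <- 8
  X <- do.call(rbind, lapply(1:5, function(k) {
    matrix(centers[k, ], n_per, 2, byrow = TRUE) %*% t(B) +
      matrix(rnorm(n_per * 20, sd = 1e-3), n_per, 20)
  }))
  y <- rep(paste0("c", 1:5), each = n_per)
  ds <- spectral_dataset(1:20, X, y)
  sp <- kennard_stone_split(ds$intensities)
  fit <- pca_lda_train(ds, sp, max_A = 6)
  expect_lte(fit$chosen_A, 3)
  pred <- predict(fit, ds$intensities[sp$prediction_idx, ])
  expect_equal(mean(pred == y[sp$prediction_idx]), 1)
  # single candidate: chosen_A is forced to 1
  expect_equal(pca_lda_train(ds, sp, max_A = 1)$chosen_A, 1L)
  expect_error(pca_lda_train(ds, sp, max_A = 0), "max_A")
})

test_that("PCA-LDA on permuted labels predicts at chance level", {
  set.seed(37)
  ds0 <- generate_atr_dataset(atr_sim_config(noise_sd = 0.05), seed = 40)
  perm <- sample(length(ds0$class_labels))
  ds <- spectral_dataset(ds0$variables_axis, ds0$intensities,
                         ds0$class_labels[perm], ds0$sample_ids)
  sp <- kennard_stone_split(ds$intensities)
  fit <- pca_lda_train(ds, sp, max_A = 6)
  acc <- mean(predict(fit, ds$intensities[sp$prediction_idx, ]) ==
                ds$class_labels[sp$prediction_idx])
  # chance is 1/5; binomial 95% upper bound for 7 prediction samples
  expect_lte(acc, 0.2 + 1.96 * sqrt(0.2 * 0.8 / length(sp$prediction_idx)))
})
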