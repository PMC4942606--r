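# Independent brute-force oracles used to cross-check the implementation.
# These deliberately use explicit loops and direct matrix inversion, not the
# package's own code paths.

# explicit double-loop column mean (the image-to-signal reduction)
oracle_column_mean <- function(m) {
  out <- numeric(ncol(m))
  for (j in seq_len(ncol(m))) {
    acc <- 0
    for (i in seq_len(nrow(m))) acc <- acc + m[i, j]
    out[j] <- acc / nrow(m)
  }
  out
}

# squared Mahalanobis distances to each class mean, by direct inversion
oracle_mahalanobis <- function(X_train, y_train, X_query) {
  classes <- sort(unique(y_train))
  d <- ncol(X_train)
  means <- lapply(classes, function(k) colMeans(X_train[y_train == k, , drop = FALSE]))
  Sw <- matrix(0, d, d)
  for (k in seq_along(classes)) {
    rows <- which(y_train == classes[k])
    for (i in rows) {
      v <- X_train[i, ] - means[[k]]
      Sw <- Sw + outer(v, v)
    }
  }
  Sw <- Sw / (nrow(X_train) - length(classes))
  Sinv <- solve(Sw)
  out <- matrix(NA_real_, nrow(X_query), length(classes),
                dimnames = list(NULL, classes))
  for (i in seq_len(nrow(X_query))) {
    for (k in seq_along(classes)) {
      v <- X_query[i, ] - means[[k]]
      out[i, k] <- drop(t(v) %*% Sinv %*% v)
    }
  }
  out
}

# G cost by explicit loops over validation samples and rival classes
oracle_g_cost <- function(X_train, y_train, X_val, y_val) {
  sc <- oracle_mahalanobis(X_train, y_train, X_val)
  classes <- colnames(sc)
  total <- 0
  for (i in seq_len(nrow(sc))) {
    own <- sc[i, y_val[i]]
    rival <- min(sc[i, setdiff(classes, y_val[i])])
    total <- total + own / rival
  }
  as.numeric(total / nrow(sc))
}

# a small signal with metadata, for unit tests
toy_signal <- function(values, axis = seq_along(values) - 1,
                       biomarker = "dna", class_label = "normal",
                       normalized = FALSE) {
  snomchemo:::new_signal(values, axis, biomarker,
                         source_cell_id = paste0("cell_", class_label),
                         class_label = class_label, normalized = normalized)
}

# dataset with exactly 3 informative variables out of p, 5 classes; the
# class means in the informative subspace are chosen so that no 2-variable
# projection separates all classes (two classes coincide in every pair)
make_three_informative_dataset <- function(p = 30, n_per = 12, sd = 0.05,
                                           informative = c(4, 11, 23),
                                           seed = 7) {
  classes <- paste0("c", 1:5)
  means3 <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(1, 1, 1))
  set.seed(seed)
  X <- matrix(rnorm(5 * n_per * p, sd = sd), 5 * n_per, p)
  lab <- rep(classes, each = n_per)
  for (k in 1:5) {
    X[lab == classes[k], informative] <-
      X[lab == classes[k], informative] +
      matrix(means3[k, ], n_per, 3, byrow = TRUE)
  }
  list(dataset = spectral_dataset(seq_len(p), X, lab),
       informative = informative)
}
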