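#' Kennard-Stone train/validation/prediction split
#'
#' The classic uniform-coverage sampling algorithm: start from the pair of
#' samples with the largest Euclidean distance, then repeatedly add the
#' sample whose minimum distance to the already-selected set is largest
#' (max-min criterion). The first `round(f_train * n)` samples in selection
#' order form the training set, the next `round(f_val * n)` the validation
#' set, and the remainder the prediction set. Fully deterministic; ties are
#' broken by the lowest sample index.
#'
#' @param X numeric `n x p` matrix.
#' @param fractions length-3 positive vector summing to 1
#'   (default `c(0.70, 0.15, 0.15)`).
#' @return An object of class `ks_split` with `train_idx`, `validation_idx`,
#'   `prediction_idx` (in selection order) and `order` (the full KS ordering).
#' @export
kennard_stone_split <- function(X, fractions = c(0.70, 0.15, 0.15)) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 3L) stop_validation("Kennard-Stone needs at least 3 samples")
  if (length(fractions) != 3L || any(fractions <= 0) ||
      abs(sum(fractions) - 1) > 1e-8) {
    stop_validation("`fractions` must be 3 positive numbers summing to 1")
  }
  D <- as.matrix(stats::dist(X))
  if (max(D) == 0) {
    warning("all pairwise distances are zero; Kennard-Stone order is by index")
  }
  # initial pair: maximal distance, ties -> lowest (i, j)
  flat <- which(D == max(D), arr.ind = TRUE)
  flat <- flat[flat[, 1] < flat[, 2], , drop = FALSE]
  if (nrow(flat) == 0L) flat <- matrix(c(1L, 2L), 1L)
  first <- flat[order(flat[, 1], flat[, 2])[1], ]
  selected <- as.integer(first)
  remaining <- setdiff(seq_len(n), selected)
  min_d <- pmin(D[, selected[1]], D[, selected[2]])
  while (length(remaining) > 0L) {
    cand <- remaining[which.max(min_d[remaining])]  # which.max: lowest index on ties
    selected <- c(selected, cand)
    remaining <- setdiff(remaining, cand)
    min_d <- pmin(min_d, D[, cand])
  }
  n_train <- round(fractions[1] * n)
  n_val <- round(fractions[2] * n)
  n_train <- max(1L, min(n_train, n - 2L))
  n_val <- max(1L, min(n_val, n - n_train - 1L))
  structure(
    list(
      train_idx = selected[seq_len(n_train)],
      validation_idx = selected[n_train + seq_len(n_val)],
      prediction_idx = selected[(n_train + n_val + 1):n],
      order = selected,
      fractions = fractions
    ),
    class = "ks_split"
  )
}

#' @export
print.ks_split <- function(x, ...) {
  cat(sprintf("<ks_split> train %d / validation %d / prediction %d\n",
              length(x$train_idx), length(x$validation_idx),
              length(x$prediction_idx)))
  invisible(x)
}
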