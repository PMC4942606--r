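#' Fit a principal component model
#'
#' Mean-centred singular value decomposition. Loadings carry a deterministic
#' sign convention (the largest-magnitude element of each loading column is
#' made positive) so repeated fits are bit-identical across platforms.
#' Explained variance for component `a` is `100 * sigma_a^2 / sum(sigma^2)`.
#'
#' @param X numeric `n x p` matrix (rows = samples).
#' @param A number of components, `1 <= A <= min(n - 1, p)`.
#' @return An object of class `pca_model` with elements `mean_vector`,
#'   `loadings` (`p x A`, orthonormal), `scores` (`n x A`),
#'   `explained_variance_pct` (length `A`), `eigenvalues` (all
#'   `min(n - 1, p)` score variances, for diagnostics), `n_components`, `n`.
#' @export
fit_pca <- function(X, A) {
  X <- as.matrix(X)
  n <- nrow(X)
  p <- ncol(X)
  if (!all(is.finite(X))) stop_validation("`X` must be finite")
  rank_bound <- min(n - 1L, p)
  if (!is.numeric(A) || length(A) != 1L || A < 1 || A > rank_bound) {
    stop_validation("`A` must satisfy 1 <= A <= min(n - 1, p) = ", rank_bound)
  }
  A <- as.integer(A)
  mu <- colMeans(X)
  Xc <- sweep(X, 2L, mu)
  sv <- svd(Xc, nu = 0, nv = rank_bound)
  d <- sv$d[seq_len(rank_bound)]
  V <- sv$v
  # sign convention: largest-|.| element of each loading column positive
  for (a in seq_len(ncol(V))) {
    piv <- which.max(abs(V[, a]))
    if (V[piv, a] < 0) V[, a] <- -V[, a]
  }
  loadings <- V[, seq_len(A), drop = FALSE]
  scores <- Xc %*% loadings
  tot <- sum(d^2)
  explained <- if (tot > 0) 100 * d^2 / tot else rep(0, rank_bound)
  structure(
    list(
      mean_vector = mu,
      loadings = loadings,
      scores = scores,
      explained_variance_pct = explained[seq_len(A)],
      explained_variance_all_pct = explained,
      eigenvalues = d^2 / (n - 1),
      n_components = A,
      n = n
    ),
    class = "pca_model"
  )
}

#' @export
print.pca_model <- function(x, ...) {
  cat(sprintf("<pca_model> %d components (n = %d)\n", x$n_components, x$n))
  cat("  explained variance (%):",
      paste(sprintf("%.2f", x$explained_variance_pct), collapse = ", "), "\n")
  invisible(x)
}

#' Project new samples onto a fitted PCA model
#'
#' @param model a `pca_model`.
#' @param X matrix in the model's variable space.
#' @return `n x A` score matrix.
#' @export
pca_project <- function(model, X) {
  X <- as.matrix(X)
  if (ncol(X) != length(model$mean_vector)) {
    stop_validation("variable dimension mismatch: model has ",
                    length(model$mean_vector), ", data has ", ncol(X))
  }
  sweep(X, 2L, model$mean_vector) %*% model$loadings
}

#' Hotelling T-squared and Q-residual diagnostics
#'
#' Per sample: `T2 = sum_a t_a^2 / lambda_a` (`lambda_a` = variance of the
#' a-th training score) measures distance within the model plane; `Q` is the
#' squared norm of the residual after projection onto the `A` loadings and
#' measures variation outside the model. The 95% T2 limit is the F-based
#' limit `A (n - 1) / (n - A) * F_0.95(A, n - A)`; the 95% Q limit uses the
#' Jackson-Mudholkar approximation from the residual eigenvalues (reported as
#' 0 when the model is full rank and no residual space exists).
#'
#' @param model a fitted `pca_model`.
#' @param X the samples to diagnose (the training matrix, typically).
#' @return An object of class `pca_diagnostics`: `t2_values`, `q_values`,
#'   `t2_limit_95`, `q_limit_95`, `outlier` (logical, outside either limit).
#' @export
pca_diagnostics <- function(model, X) {
  stopifnot(inherits(model, "pca_model"))
  A <- model$n_components
  n <- model$n
  if (n <= A) {
    stop_validation("T2 limit undefined: need n > A (n = ", n, ", A = ", A, ")")
  }
  X <- as.matrix(X)
  scores <- pca_project(model, X)
  lambda <- model$eigenvalues[seq_len(A)]
  if (any(lambda <= 0)) {
    stop_validation("degenerate component with zero variance; reduce A")
  }
  t2 <- rowSums(sweep(scores^2, 2L, lambda, `/`))
  resid <- sweep(X, 2L, model$mean_vector) - scores %*% t(model$loadings)
  q <- rowSums(resid^2)
  t2_lim <- A * (n - 1) / (n - A) * stats::qf(0.95, A, n - A)
  resid_eig <- model$eigenvalues[-seq_len(A)]
  resid_eig <- resid_eig[resid_eig > 1e-12 * sum(model$eigenvalues)]
  q_lim <- if (length(resid_eig) == 0L) {
    0
  } else {
    th1 <- sum(resid_eig)
    th2 <- sum(resid_eig^2)
    th3 <- sum(resid_eig^3)
    h0 <- 1 - 2 * th1 * th3 / (3 * th2^2)
    if (h0 < 0.001) h0 <- 0.001
    z <- stats::qnorm(0.95)
    th1 * (z * sqrt(2 * th2 * h0^2) / th1 + 1 +
             th2 * h0 * (h0 - 1) / th1^2)^(1 / h0)
  }
  structure(
    list(
      t2_values = t2, q_values = q,
      t2_limit_95 = t2_lim, q_limit_95 = q_lim,
      outlier = t2 > t2_lim | (q_lim > 0 & q > q_lim)
    ),
    class = "pca_diagnostics"
  )
}

#' @export
print.pca_diagnostics <- function(x, ...) {
  cat(sprintf(
    "<pca_diagnostics> %d samples, T2 limit %.3f, Q limit %.3g, %d outlier(s)\n",
    length(x$t2_values), x$t2_limit_95, x$q_limit_95, sum(x$outlier)
  ))
  invisible(x)
}
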