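#' Fit a Mahalanobis linear discriminant model
#'
#' Nearest-class-mean classification under the pooled within-class
#' covariance: class means are estimated per class, the pooled covariance
#' uses divisor `n - K`, and a sample is assigned to the class minimizing the
#' squared Mahalanobis distance to its mean. If the pooled covariance is
#' near-singular (smallest eigenvalue < `1e-10 * trace/d`), a ridge of
#' `1e-8 * trace/d` is added to the diagonal (reported in the model).
#'
#' @param X numeric `n x d` feature matrix (selected variables or PC scores).
#' @param labels class label per row; every class needs >= 2 samples.
#' @param feature_idx optional indices recording which original variables the
#'   columns of `X` correspond to.
#' @return An object of class `lda_model`: `class_means` (`K x d`),
#'   `pooled_covariance`, `pooled_inverse`, `class_order`, `feature_idx`,
#'   `ridge` (0 when no regularization was needed).
#' @export
fit_lda <- function(X, labels, feature_idx = seq_len(ncol(as.matrix(X)))) {
  X <- as.matrix(X)
  n <- nrow(X)
  d <- ncol(X)
  if (length(labels) != n) stop_validation("`labels` length must equal nrow(X)")
  class_order <- if (is.factor(labels)) {
    levels(droplevels(labels))
  } else {
    sort(unique(as.character(labels)))
  }
  labels <- as.character(labels)
  K <- length(class_order)
  if (K < 2L) stop_validation("LDA needs at least 2 classes")
  counts <- table(factor(labels, levels = class_order))
  if (any(counts < 2L)) {
    stop_validation("every class needs >= 2 training samples; short: ",
                    paste(names(counts)[counts < 2], collapse = ", "))
  }
  means <- do.call(rbind, lapply(class_order, function(k) {
    colMeans(X[labels == k, , drop = FALSE])
  }))
  rownames(means) <- class_order
  Sw <- matrix(0, d, d)
  for (k in class_order) {
    Xk <- X[labels == k, , drop = FALSE]
    Xk <- sweep(Xk, 2L, colMeans(Xk))
    Sw <- Sw + crossprod(Xk)
  }
  Sw <- Sw / (n - K)
  tr_d <- sum(diag(Sw)) / d
  ev_min <- min(eigen(Sw, symmetric = TRUE, only.values = TRUE)$values)
  ridge <- 0
  if (tr_d <= 0 || ev_min < 1e-10 * tr_d) {
    ridge <- if (tr_d > 0) 1e-8 * tr_d else 1e-8
    Sw <- Sw + diag(ridge, d)
  }
  structure(
    list(
      class_means = means,
      pooled_covariance = Sw,
      pooled_inverse = solve(Sw),
      class_order = class_order,
      feature_idx = feature_idx,
      ridge = ridge
    ),
    class = "lda_model"
  )
}

#' @export
print.lda_model <- function(x, ...) {
  cat(sprintf("<lda_model> %d classes, %d features%s\n",
              length(x$class_order), ncol(x$class_means),
              if (x$ridge > 0) sprintf(" (ridge %.3g)", x$ridge) else ""))
  invisible(x)
}

#' Per-class squared Mahalanobis distances
#'
#' The discriminant scores underlying DF plots: entry `(i, k)` is the squared
#' Mahalanobis distance of sample `i` to the mean of class `k` under the
#' pooled covariance. The predicted class is the argmin per row.
#'
#' @param model an `lda_model`.
#' @param X feature matrix matching the model's dimension.
#' @return `n x K` matrix with classes as columns.
#' @export
discriminant_scores <- function(model, X) {
  stopifnot(inherits(model, "lda_model"))
  X <- as.matrix(X)
  if (ncol(X) != ncol(model$class_means)) {
    stop_validation("feature dimension mismatch: model has ",
                    ncol(model$class_means), ", data has ", ncol(X))
  }
  K <- length(model$class_order)
  out <- matrix(NA_real_, nrow(X), K, dimnames = list(NULL, model$class_order))
  for (k in seq_len(K)) {
    Y <- sweep(X, 2L, model$class_means[k, ])
    out[, k] <- rowSums((Y %*% model$pooled_inverse) * Y)
  }
  out
}

#' Classify samples with a fitted LDA model
#'
#' @param model an `lda_model`.
#' @param X feature matrix.
#' @return Character vector of predicted classes (ties go to the
#'   lowest-index class, with a message).
#' @export
lda_predict <- function(model, X) {
  sc <- discriminant_scores(model, X)
  pick <- apply(sc, 1L, function(r) {
    hits <- which(r == min(r))
    if (length(hits) > 1L) message("discriminant tie; assigning lowest class index")
    hits[1]
  })
  model$class_order[pick]
}

#' G cost of an LDA model on a validation set
#'
#' The validation cost used to guide model selection in SPA-LDA and PCA-LDA:
#' `G = mean over validation samples of r2(x, m_own) / min_rival r2(x, m_J)`,
#' where `r2` is the squared Mahalanobis distance under the training pooled
#' covariance, `m_own` is the sample's true class mean and the denominator is
#' the distance to the nearest rival class mean. Zero when every sample sits
#' exactly at its own class mean; below 1 on average for well-separated data.
#'
#' @param model an `lda_model` fitted on training data.
#' @param X_val validation feature matrix.
#' @param val_labels true classes of the validation samples; all must be
#'   present in the training model.
#' @return Non-negative scalar.
#' @export
g_cost <- function(model, X_val, val_labels) {
  stopifnot(inherits(model, "lda_model"))
  val_labels <- as.character(val_labels)
  unknown <- setdiff(unique(val_labels), model$class_order)
  if (length(unknown) > 0) {
    stop_validation("validation class(es) absent from training: ",
                    paste(unknown, collapse = ", "))
  }
  sc <- discriminant_scores(model, X_val)
  own_col <- match(val_labels, model$class_order)
  own <- sc[cbind(seq_len(nrow(sc)), own_col)]
  rival <- vapply(seq_len(nrow(sc)), function(i) min(sc[i, -own_col[i]]),
                  numeric(1))
  mean(own / rival)
}

#' Train a PCA-LDA classifier with validation-chosen dimensionality
#'
#' For each candidate number of components `A = 1..max_A`: fit PCA on the
#' training rows, fit LDA on the training scores, and evaluate the model on
#' the validation scores. The chosen `A` minimizes the selection criterion
#' (the G cost by default; validation error rate optionally), with ties going
#' to the smallest model.
#'
#' @param dataset a [spectral_dataset()].
#' @param split a [kennard_stone_split()] of the dataset's rows.
#' @param max_A largest candidate component count (capped by the training
#'   rank and by the LDA sample-size requirement).
#' @param criterion `"g"` (default) or `"accuracy"` (1 - validation accuracy).
#' @return A list of class `pca_lda_model`: `pca`, `lda`, `chosen_A`,
#'   `cost_curve` (data frame of A vs cost), `criterion`.
#' @export
pca_lda_train <- function(dataset, split, max_A = 10L,
                          criterion = c("g", "accuracy")) {
  criterion <- match.arg(criterion)
  stopifnot(inherits(dataset, "spectral_dataset"), inherits(split, "ks_split"))
  if (max_A < 1) stop_validation("`max_A` must be >= 1")
  Xtr <- dataset$intensities[split$train_idx, , drop = FALSE]
  ytr <- dataset$class_labels[split$train_idx]
  Xval <- dataset$intensities[split$validation_idx, , drop = FALSE]
  yval <- dataset$class_labels[split$validation_idx]
  K <- length(unique(ytr))
  bound <- min(nrow(Xtr) - 1L, ncol(Xtr), nrow(Xtr) - K - 1L)
  if (max_A > bound) {
    stop_validation("`max_A` exceeds the usable rank bound ", bound)
  }
  costs <- numeric(max_A)
  for (A in seq_len(max_A)) {
    pca <- fit_pca(Xtr, A)
    lda <- fit_lda(pca$scores, ytr)
    val_scores <- pca_project(pca, Xval)
    costs[A] <- if (criterion == "g") {
      g_cost(lda, val_scores, yval)
    } else {
      mean(lda_predict(lda, val_scores) != yval)
    }
  }
  chosen_A <- which.min(costs)  # which.min takes the smallest A on ties
  pca <- fit_pca(Xtr, chosen_A)
  lda <- fit_lda(pca$scores, ytr)
  structure(
    list(
      pca = pca, lda = lda, chosen_A = as.integer(chosen_A),
      cost_curve = data.frame(A = seq_len(max_A), cost = costs),
      criterion = criterion
    ),
    class = "pca_lda_model"
  )
}

#' Predict classes with a fitted PCA-LDA model
#'
#' @param object a `pca_lda_model`.
#' @param newdata matrix in the original variable space.
#' @param ... unused.
#' @return Character vector of predicted classes.
#' @export
predict.pca_lda_model <- function(object, newdata, ...) {
  lda_predict(object$lda, pca_project(object$pca, as.matrix(newdata)))
}
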