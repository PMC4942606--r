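#' Successive projections algorithm variable chains
#'
#' Forward variable selection by orthogonal projections, designed to minimize
#' collinearity among the selected variables. For each starting variable `k`,
#' the chain is grown by repeatedly appending the variable whose
#' (mean-centred) training column has the largest norm after orthogonal
#' projection onto the complement of the span of the columns already in the
#' chain. Chains stop at `max_len` or when every remaining projected norm is
#' numerically zero.
#'
#' @param X_train numeric `n x p` training matrix.
#' @param max_len maximum chain length, `<= min(p, n - 1)`.
#' @param tol relative tolerance below which a projected norm counts as zero.
#' @return A list of integer chains, one per usable starting variable, named
#'   by starting column. Zero-variance starting columns are skipped with a
#'   message.
#' @export
spa_chains <- function(X_train, max_len, tol = 1e-10) {
  X <- as.matrix(X_train)
  n <- nrow(X)
  p <- ncol(X)
  if (max_len < 1 || max_len > min(p, n - 1L)) {
    stop_validation("`max_len` must satisfy 1 <= max_len <= min(p, n - 1) = ",
                    min(p, n - 1L))
  }
  Xc <- sweep(X, 2L, colMeans(X))
  norms0 <- sqrt(colSums(Xc^2))
  scale0 <- max(norms0)
  if (scale0 == 0) stop_validation("all columns have zero variance")
  chains <- list()
  for (k in seq_len(p)) {
    if (norms0[k] <= tol * scale0) {
      message("skipping zero-variance starting column ", k)
      next
    }
    chain <- k
    R <- Xc  # residual columns after projecting out the selected span
    q <- Xc[, k] / norms0[k]
    R <- R - q %*% crossprod(q, R)
    while (length(chain) < max_len) {
      rn <- sqrt(colSums(R^2))
      rn[chain] <- -1
      nxt <- which.max(rn)  # lowest index on ties
      if (rn[nxt] <= tol * scale0) break
      chain <- c(chain, nxt)
      q <- R[, nxt] / rn[nxt]
      R <- R - q %*% crossprod(q, R)
    }
    chains[[as.character(k)]] <- chain
  }
  if (length(chains) == 0L) stop_validation("no usable SPA chains")
  chains
}

#' SPA-LDA variable selection
#'
#' Evaluates every prefix of every SPA chain by fitting an LDA model on the
#' training rows restricted to the prefix and scoring it with the [g_cost()]
#' on the validation set. The selected variable subset is the global cost
#' minimizer; exact ties go first to the smaller subset, then to the
#' lexicographically smallest sorted index set. The final LDA model is refit
#' on the training set at the selection.
#'
#' @param dataset a [spectral_dataset()].
#' @param split a [kennard_stone_split()] of the dataset's rows.
#' @param max_len maximum variables per chain (capped as in [spa_chains()]
#'   and by the LDA sample-size requirement `n_train - K - 1`).
#' @return An object of class `spa_result`: `chains`, `cost_curve` (data
#'   frame: chain start, subset size, G), `selected_variables` (sorted),
#'   `selected_wavenumbers`, `lda`, `g_selected`.
#' @export
spa_lda_select <- function(dataset, split, max_len = 10L) {
  stopifnot(inherits(dataset, "spectral_dataset"), inherits(split, "ks_split"))
  Xtr <- dataset$intensities[split$train_idx, , drop = FALSE]
  ytr <- dataset$class_labels[split$train_idx]
  Xval <- dataset$intensities[split$validation_idx, , drop = FALSE]
  yval <- dataset$class_labels[split$validation_idx]
  K <- length(unique(ytr))
  cap <- min(ncol(Xtr), nrow(Xtr) - 1L, nrow(Xtr) - K - 1L)
  if (max_len > cap) {
    stop_validation("`max_len` exceeds the usable bound ", cap)
  }
  chains <- spa_chains(Xtr, max_len)
  cache <- new.env(parent = emptyenv())
  eval_subset <- function(vars) {
    key <- paste(sort(vars), collapse = ",")
    if (!is.null(cache[[key]])) return(cache[[key]])
    g <- tryCatch({
      m <- fit_lda(Xtr[, vars, drop = FALSE], ytr, feature_idx = vars)
      g_cost(m, Xval[, vars, drop = FALSE], yval)
    }, error = function(e) Inf)
    cache[[key]] <- g
    g
  }
  curve <- list()
  best <- list(g = Inf, vars = NULL)
  better <- function(g, vars, cur) {
    if (!is.finite(g)) return(FALSE)
    if (is.null(cur$vars)) return(TRUE)
    if (g != cur$g) return(g < cur$g)
    if (length(vars) != length(cur$vars)) return(length(vars) < length(cur$vars))
    # lexicographic comparison of sorted index sets
    a <- sort(vars)
    b <- cur$vars
    diffpos <- which(a != b)
    length(diffpos) > 0 && a[diffpos[1]] < b[diffpos[1]]
  }
  i <- 1L
  for (start in names(chains)) {
    chain <- chains[[start]]
    for (len in seq_along(chain)) {
      vars <- chain[seq_len(len)]
      g <- eval_subset(vars)
      curve[[i]] <- data.frame(chain_start = as.integer(start), size = len,
                               g = g)
      i <- i + 1L
      if (is.finite(g) && better(g, vars, best)) {
        best <- list(g = g, vars = sort(vars))
      }
    }
  }
  if (is.null(best$vars)) stop_validation("all SPA chain prefixes were degenerate")
  lda <- fit_lda(Xtr[, best$vars, drop = FALSE], ytr, feature_idx = best$vars)
  structure(
    list(
      chains = chains,
      cost_curve = do.call(rbind, curve),
      selected_variables = best$vars,
      selected_wavenumbers = dataset$variables_axis[best$vars],
      lda = lda,
      g_selected = best$g
    ),
    class = "spa_result"
  )
}

#' @export
print.spa_result <- function(x, ...) {
  cat(sprintf("<spa_result> %d variables selected (G = %.4g):\n",
              length(x$selected_variables), x$g_selected))
  cat(" ", paste(format(x$selected_wavenumbers), collapse = ", "), "\n")
  invisible(x)
}

#' Predict classes with an SPA-LDA selection
#'
#' @param object a `spa_result`.
#' @param newdata matrix in the original variable space.
#' @param ... unused.
#' @return Character vector of predicted classes.
#' @export
predict.spa_result <- function(object, newdata, ...) {
  lda_predict(object$lda,
              as.matrix(newdata)[, object$selected_variables, drop = FALSE])
}
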