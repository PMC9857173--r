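# Kernel principal component analysis with a radial-basis-function kernel,
# written out from first principles: K_ij = exp(-gamma ||x_i - x_j||^2),
# double-centering K~ = (I - 11'/n) K (I - 11'/n), eigendecomposition, and
# projection of (training or new) rows onto the top eigenvectors scaled by
# 1/sqrt(eigenvalue). Out-of-sample rows are centered with the *training*
# kernel statistics, so the reduction can be fit inside a cross-validation
# training fold without touching test rows.

#' Fit an RBF kernel PCA model
#'
#' @param X Numeric matrix, rows = observations.
#' @param n_components Number of components to retain (default 38, the
#'   dimensionality used for the phonetic feature set).
#' @param gamma Kernel width; default `1 / (ncol(X) * var(as.vector(X)))`
#'   (inverse of dimension times total variance). `gamma = "median"` uses the
#'   median-heuristic `1 / median(||x_i - x_j||^2)`.
#' @return A `kpca_rbf` model: retained eigenvalues (non-increasing, positive),
#'   dual coefficients, training rows and kernel centering statistics, plus
#'   `scores` (the n x n_components training projection). Component signs are
#'   fixed by making each eigenvector's largest-magnitude loading positive.
#' @export
kpca_rbf <- function(X, n_components = 38L, gamma = NULL) {
  X <- as.matrix(X)
  stopifnot(is.numeric(X), all(is.finite(X)), nrow(X) >= 2L)
  n <- nrow(X)
  if (n_components < 1L || n_components > n)
    stop_idscreen("idscreen_contract_error",
                  "n_components must be in 1..%d, got %s", n, n_components)
  D2 <- as.matrix(dist(X))^2
  if (identical(gamma, "median")) {
    med <- stats::median(D2[upper.tri(D2)])
    if (!is.finite(med) || med <= 0)
      stop_idscreen("idscreen_degenerate_error",
                    "median heuristic failed: all rows coincide")
    gamma <- 1 / med
  } else if (is.null(gamma)) {
    v <- var(as.vector(X))
    if (!is.finite(v) || v <= 0)
      stop_idscreen("idscreen_degenerate_error",
                    "default gamma undefined: zero total variance")
    gamma <- 1 / (ncol(X) * v)
  }
  assert_number(gamma, "gamma", lower = .Machine$double.xmin)

  K <- exp(-gamma * D2)
  km <- colMeans(K)           # symmetric: row means == column means
  kmm <- mean(K)
  Kc <- K - outer(rep(1, n), km) - outer(km, rep(1, n)) + kmm

  eig <- eigen(Kc, symmetric = TRUE)
  pos <- eig$values > max(eig$values[1], 0) * 1e-12
  rank <- sum(pos)
  if (n_components > rank)
    stop_idscreen("idscreen_rank_error",
                  "requested %d components but the centered kernel has only %d positive eigenvalues",
                  n_components, rank)
  lambda <- eig$values[seq_len(n_components)]
  V <- eig$vectors[, seq_len(n_components), drop = FALSE]
  # deterministic sign: largest-|loading| entry of each eigenvector positive
  for (j in seq_len(n_components)) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  alpha <- sweep(V, 2, sqrt(lambda), "/")
  scores <- sweep(V, 2, sqrt(lambda), "*")
  colnames(scores) <- sprintf("KPC%02d", seq_len(n_components))
  rownames(scores) <- rownames(X)
  structure(list(X_train = X, gamma = gamma, n_components = as.integer(n_components),
                 eigenvalues = lambda, alpha = alpha,
                 k_col_means = km, k_mean = kmm,
                 centered_trace = sum(pmax(eig$values, 0)), scores = scores),
            class = "kpca_rbf")
}

#' @export
print.kpca_rbf <- function(x, ...) {
  cat(sprintf("<kpca_rbf> %d components over %d training rows (gamma = %.3g)\n",
              x$n_components, nrow(x$X_train), x$gamma))
  invisible(x)
}

#' Project new rows with a fitted kernel PCA model
#'
#' Computes the RBF kernel between the new rows and the training rows, centers
#' it with the training-kernel statistics, and projects onto the retained
#' components. Applied to the training rows themselves it reproduces the
#' fitted `scores`.
#'
#' @param object A `kpca_rbf` model.
#' @param newdata Numeric matrix with the training column count.
#' @param ... Unused.
#' @return Numeric matrix, `nrow(newdata)` x `n_components`.
#' @export
predict.kpca_rbf <- function(object, newdata, ...) {
  Xn <- as.matrix(newdata)
  if (ncol(Xn) != ncol(object$X_train))
    stop_idscreen("idscreen_schema_error",
                  "newdata has %d columns, model was trained on %d",
                  ncol(Xn), ncol(object$X_train))
  stopifnot(all(is.finite(Xn)))
  D2 <- outer(rowSums(Xn^2), rowSums(object$X_train^2), "+") -
    2 * tcrossprod(Xn, object$X_train)
  D2[D2 < 0] <- 0
  Kn <- exp(-object$gamma * D2)
  Knc <- Kn - rowMeans(Kn) -
    matrix(object$k_col_means, nrow(Kn), ncol(Kn), byrow = TRUE) + object$k_mean
  out <- Knc %*% object$alpha
  colnames(out) <- colnames(object$scores)
  rownames(out) <- rownames(Xn)
  out
}

#' Reduce a phonetic matrix to its kernel principal components
#'
#' Convenience wrapper: fit [kpca_rbf()] on `X` and return the projected
#' matrix with the model attached as attribute `"model"`.
#'
#' @inheritParams kpca_rbf
#' @return The n x n_components score matrix.
#' @export
kpca_reduce <- function(X, n_components = 38L, gamma = NULL) {
  model <- kpca_rbf(X, n_components = n_components, gamma = gamma)
  structure(model$scores, model = model)
}
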