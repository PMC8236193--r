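#' Principal component analysis with explained-variance accounting
#'
#' Eigendecomposition of the correlation matrix (`standardize = TRUE`,
#' default) or covariance matrix of the columns, with the same divisor
#' `n` convention as [fit_mcpca()] so that PCA's top-`q` eigenvalue sum
#' on standardized data is directly comparable to (and bounded above
#' by) the MCPCA objective on the same discretized input.
#'
#' @param X numeric matrix (samples x features), e.g. a
#'   [dosage_matrix].
#' @param q number of components.
#' @param standardize scale columns to unit variance (correlation PCA);
#'   constant columns are dropped with a warning.
#' @return An object of class `embedding`: list with `method = "pca"`,
#'   `scores` (n x q), `eigenvalues`, `explained_fraction`
#'   (top-q eigenvalue sum over total), `sample_ids`.
#' @export
pca <- function(X, q, standardize = TRUE) {
  X <- as.matrix(unclass(X))
  n <- nrow(X); if (n < 2L) stop_usage("need at least 2 samples")
  sds <- sqrt(colMeans(X^2) - colMeans(X)^2)
  if (standardize && any(sds == 0)) {
    warning(sum(sds == 0), " constant column(s) dropped")
    X <- X[, sds > 0, drop = FALSE]
    sds <- sds[sds > 0]
  }
  p <- ncol(X)
  Xc <- sweep(X, 2, colMeans(X))
  if (standardize) Xc <- sweep(Xc, 2, sds, `/`)
  r <- min(n - 1L, p)
  if (q > r) {
    warning("q = ", q, " exceeds rank bound ", r, "; truncated")
    q <- r
  }
  sv <- svd(Xc, nu = 0, nv = q)
  ev <- sv$d^2 / n                       # eigenvalues of X'X / n
  total <- if (standardize) p else sum(colMeans(Xc^2))
  scores <- Xc %*% sv$v
  rownames(scores) <- rownames(X)
  structure(list(method = "pca", scores = scores,
                 eigenvalues = ev,
                 explained_fraction = sum(ev[seq_len(q)]) / total,
                 q = q, sample_ids = rownames(X)),
            class = "embedding")
}

#' Polynomial-kernel kernel PCA
#'
#' Gram matrix `G[i, k] = (scale <x_i, x_k> + offset)^degree`, double
#' centered in feature space and eigendecomposed.  The explained
#' fraction is the top-`q` eigenvalue sum over the trace of the
#' centered Gram matrix (the total variance in feature space — the
#' standard kernel-variance accounting).  Scores are the eigenvectors
#' scaled by the square root of their eigenvalues.  With
#' `degree = 1, scale = 1, offset = 0` KPCA reduces to covariance PCA.
#'
#' @param X numeric matrix (samples x features).
#' @param q number of components (`<= n - 1`, the centered Gram rank
#'   bound).
#' @param degree polynomial degree (default 2).
#' @param scale inner-product scale; default `1/ncol(X)` keeps kernel
#'   values O(1) regardless of dimension.
#' @param offset kernel offset (default 1).
#' @return An object of class `embedding` with `method = "kpca"` and
#'   `kernel = list(degree, scale, offset)`.
#' @export
kpca <- function(X, q, degree = 2, scale = NULL, offset = 1) {
  X <- as.matrix(unclass(X))
  n <- nrow(X); if (n < 2L) stop_usage("need at least 2 samples")
  if (is.null(scale)) scale <- 1 / ncol(X)
  if (q > n - 1L) {
    warning("q = ", q, " exceeds centered Gram rank bound ", n - 1L,
            "; truncated")
    q <- n - 1L
  }
  G <- (scale * tcrossprod(X) + offset)^degree
  rm <- rowMeans(G); gm <- mean(G)
  Gc <- sweep(sweep(G, 1, rm), 2, rm) + gm
  ee <- eigen(Gc, symmetric = TRUE)
  ev <- ee$values
  if (any(ev < -1e-8 * max(abs(ev))))
    warning("centered Gram has negative eigenvalues beyond tolerance; clipped")
  ev <- pmax(ev, 0)
  scores <- ee$vectors[, seq_len(q), drop = FALSE] %*%
    diag(sqrt(ev[seq_len(q)]), q)
  scores <- fix_signs_scores(scores)
  rownames(scores) <- rownames(X)
  structure(list(method = "kpca", scores = scores,
                 eigenvalues = ev,
                 explained_fraction = sum(ev[seq_len(q)]) / sum(ev),
                 q = q, kernel = list(degree = degree, scale = scale,
                                      offset = offset),
                 sample_ids = rownames(X)),
            class = "embedding")
}

# sign convention on score columns for reproducibility
fix_signs_scores <- function(S) {
  for (k in seq_len(ncol(S))) {
    i <- which.max(abs(S[, k]))
    if (S[i, k] < 0) S[, k] <- -S[, k]
  }
  S
}

#' @export
print.embedding <- function(x, ...) {
  cat(sprintf("embedding (%s): %d samples, q = %d, explained fraction %.4f\n",
              x$method, nrow(x$scores), x$q, x$explained_fraction))
  invisible(x)
}
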