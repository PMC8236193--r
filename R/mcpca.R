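#' Standardize a per-feature transform
#'
#' Rescales a category-to-value map to weighted mean 0 and weighted
#' variance 1 under the empirical category frequencies (the sample-mean
#' substitution for the population constraints `E[phi] = 0`,
#' `E[phi^2] = 1`; divisor `n`, not `n - 1`).
#'
#' @param phi numeric vector, one value per category.
#' @param counts category counts (same length; sum is the sample size).
#' @return standardized `phi`.  A transform that is constant over the
#'   observed categories has no standardization; this raises a classed
#'   error (`mcpca_degenerate`) that callers such as [fit_mcpca()]
#'   catch to keep the previous transform.
#' @export
standardize_transform <- function(phi, counts) {
  if (length(phi) != length(counts))
    stop_usage("phi and counts must have equal length")
  if (sum(counts > 0) < 2L)
    stop_usage("need at least 2 categories with nonzero count")
  n <- sum(counts)
  w <- counts / n
  mu <- sum(w * phi)
  v <- sum(w * (phi - mu)^2)
  if (v < 1e-12)
    stop(errorCondition("degenerate transform: zero variance over observed categories",
                        class = c("mcpca_degenerate", "error")))
  (phi - mu) / sqrt(v)
}

# n x p matrix of transformed values Phi[i, j] = phi_j(D[i, j])
transform_values <- function(D, transforms) {
  D <- unclass(D)
  p <- ncol(D)
  Phi <- matrix(0, nrow(D), p)
  for (j in seq_len(p)) Phi[, j] <- transforms[[j]][D[, j] + 1L]
  Phi
}

#' Covariance of transformed features
#'
#' `K(j, j') = (1/n) sum_i phi_j(D[i,j]) phi_{j'}(D[i,j'])` for
#' standardized transforms: symmetric with unit diagonal (a correlation
#' matrix of the transformed features).
#'
#' @param D a [discrete_matrix].
#' @param transforms list of per-feature transform vectors (category ->
#'   value), each standardized as by [standardize_transform()].
#' @return `p x p` covariance matrix.
#' @export
transformed_covariance <- function(D, transforms) {
  n <- nrow(D)
  Phi <- transform_values(D, transforms)
  mu <- colMeans(Phi)
  s2 <- colMeans(Phi^2)
  if (any(abs(mu) > 1e-6) || any(abs(s2 - 1) > 1e-6))
    stop_usage("transforms are not standardized (mean 0, second moment 1)")
  crossprod(Phi) / n
}

#' Ky Fan q-norm of a symmetric matrix
#'
#' Sum of the `q` largest eigenvalues.
#'
#' @param K symmetric (PSD up to roundoff) matrix.
#' @param q number of leading eigenvalues, `1 <= q <= p`.
#' @return numeric scalar.
#' @export
kyfan <- function(K, q) {
  p <- ncol(K)
  if (q < 1 || q > p) stop_usage("q must lie in [1, ", p, "]")
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  sum(ev[seq_len(q)])
}

# deterministic sign convention: largest-|.| loading of each column > 0
fix_signs <- function(U) {
  for (k in seq_len(ncol(U))) {
    i <- which.max(abs(U[, k]))
    if (U[i, k] < 0) U[, k] <- -U[, k]
  }
  U
}

#' Fit maximally correlated PCA by block coordinate descent
#'
#' Finds per-feature standardized transformations `phi_j` of the
#' category labels maximizing the Ky Fan q-norm (sum of the top `q`
#' eigenvalues) of the transformed covariance matrix `K_phi`.
#'
#' Each sweep (1) eigendecomposes the current `K` and forms the
#' projector `W = U U'` onto its top-`q` eigenspace, then (2) updates
#' features sequentially (Gauss-Seidel, fixed index order): the new
#' `phi_j(c)` is the mean over samples in category `c` of
#' `g_j(i) = sum_{j' != j} W(j, j') phi_{j'}(D[i, j'])`, re-standardized;
#' a zero-variance update keeps the previous transform.  Each feature
#' update maximizes the surrogate `trace(U' K U)` with `U` fixed, and
#' refreshing `U` cannot decrease the sum of the top `q` eigenvalues, so
#' the objective trajectory is non-decreasing.  Iteration stops when the
#' objective improves by less than `tol` or after `max_sweeps` sweeps.
#'
#' With identity initialization the sweep-0 objective equals the Ky Fan
#' value of the correlation matrix of the raw labels, i.e. PCA's
#' explained-variance numerator on the same data, so MCPCA's final
#' objective always dominates PCA's.
#'
#' @param D a [discrete_matrix] with no degenerate (single-category)
#'   features — drop those first (see attribute `degenerate`).
#' @param q embedding dimension, `1 <= q <= p`.
#' @param tol absolute objective-improvement convergence threshold.
#' @param max_sweeps sweep cap; hitting it sets `converged = FALSE`
#'   (not an error).
#' @param init `"identity"` (standardized raw labels; default) or
#'   `"random"` (standard normal category values, standardized).
#' @param seed integer seed used for random initialization and recorded
#'   in the result.
#' @return An object of class `mcpca_fit`: list with `transforms`
#'   (per-feature category value vectors), `K` (final transformed
#'   covariance), `eigenvalues`, `q`, `objective_trace` (one entry per
#'   sweep, starting at initialization), `scores` (n x q MCPCs,
#'   `Phi %*% U_final`), `explained_fraction` (objective / p),
#'   `converged`, `sweeps`, `seed`, `sample_ids`.
#' @export
fit_mcpca <- function(D, q, tol = 1e-6, max_sweeps = 100L,
                      init = c("identity", "random"), seed = NULL) {
  init <- match.arg(init)
  if (!inherits(D, "discrete_matrix")) D <- as_discrete_matrix(D)
  n <- nrow(D); p <- ncol(D)
  if (n < 2L) stop_usage("need at least 2 samples")
  if (q < 1 || q > p) stop_usage("q must lie in [1, p = ", p, "]")
  m <- attr(D, "m")
  if (any(m == 1L))
    stop_usage(sum(m == 1L), " degenerate single-category feature(s); ",
               "drop them before fitting (see attr(D, 'degenerate'))")
  lab <- unclass(D)
  attributes(lab) <- list(dim = dim(D))
  if (!is.null(seed)) set.seed(seed)
  transforms <- vector("list", p)
  for (j in seq_len(p)) {
    counts <- tabulate(lab[, j] + 1L, nbins = m[j])
    raw <- if (init == "identity") as.numeric(seq_len(m[j]) - 1L)
           else rnorm(m[j])
    phi <- tryCatch(standardize_transform(raw, counts),
                    mcpca_degenerate = function(e) NULL)
    while (is.null(phi)) {  # random draw happened to be constant
      phi <- tryCatch(standardize_transform(rnorm(m[j]), counts),
                      mcpca_degenerate = function(e) NULL)
    }
    transforms[[j]] <- phi
  }
  Phi <- transform_values(lab, transforms)
  K <- crossprod(Phi) / n
  ee <- eigen(K, symmetric = TRUE)
  obj <- sum(ee$values[seq_len(q)])
  trace <- obj
  converged <- FALSE
  sweeps <- 0L
  while (sweeps < max_sweeps) {
    sweeps <- sweeps + 1L
    U <- fix_signs(ee$vectors[, seq_len(q), drop = FALSE])
    W <- tcrossprod(U)
    sw <- bcd_sweep(Phi, W, lab, m)
    Phi <- sw$Phi
    K <- crossprod(Phi) / n
    ee <- eigen(K, symmetric = TRUE)
    obj_new <- sum(ee$values[seq_len(q)])
    trace <- c(trace, obj_new)
    improved <- obj_new - obj
    obj <- obj_new
    if (improved < tol) { converged <- TRUE; break }
  }
  # read the final per-category values back off Phi
  for (j in seq_len(p)) {
    phi_j <- rep(NA_real_, m[j])
    phi_j[lab[, j] + 1L] <- Phi[, j]
    transforms[[j]] <- phi_j
  }
  U_final <- fix_signs(ee$vectors[, seq_len(q), drop = FALSE])
  scores <- Phi %*% U_final
  rownames(scores) <- rownames(D)
  structure(list(transforms = transforms, K = K,
                 eigenvalues = ee$values, q = q,
                 objective_trace = trace, scores = scores,
                 explained_fraction = obj / p,
                 converged = converged, sweeps = sweeps, seed = seed,
                 method = "mcpca", sample_ids = rownames(D)),
            class = "mcpca_fit")
}

#' @export
print.mcpca_fit <- function(x, ...) {
  cat(sprintf(paste0(
    "mcpca_fit: p = %d features, q = %d, objective = %.4f ",
    "(explained fraction %.4f)\n%d sweep(s), %sconverged\n"),
    ncol(x$K), x$q, x$objective_trace[length(x$objective_trace)],
    x$explained_fraction, x$sweeps, if (x$converged) "" else "NOT "))
  invisible(x)
}

#' Fraction of total variance captured by the fit
#'
#' `kyfan(K, q) / trace(K)`; for standardized transforms the trace is
#' `p`, so this is `objective / p`.
#'
#' @param result an `mcpca_fit` (or `embedding`) object.
#' @return numeric fraction in `(0, 1]`.
#' @export
explained_fraction <- function(result) {
  result$explained_fraction
}
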