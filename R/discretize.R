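#' Freedman-Diaconis bin count
#'
#' Bin width `h = 2 IQR(x) n^(-1/3)`; the number of bins is
#' `ceiling(range(x) / h)`, clamped to `[m_min, m_max]`.  Degenerate
#' inputs (zero interquartile range or zero range) return `m_min`.
#'
#' @param x numeric vector, `length(x) >= 2`.
#' @param m_min,m_max clamp bounds for the bin count; the defaults
#'   (2, 20) keep dosage features away from both a single bin and the
#'   overfitting seen with effectively continuous category structures.
#' @return integer bin count.
#' @export
fd_bin_count <- function(x, m_min = 2L, m_max = 20L) {
  n <- length(x)
  if (n < 2L) stop_usage("fd_bin_count needs at least 2 values")
  iqr <- stats::IQR(x)
  rng <- diff(range(x))
  if (iqr <= 0 || rng <= 0) return(as.integer(m_min))
  h <- 2 * iqr * n^(-1 / 3)
  m <- ceiling(rng / h)
  as.integer(min(max(m, m_min), m_max))
}

# compact labels to 0..k-1 preserving order; returns list(labels, map)
compact_labels <- function(lab) {
  used <- sort(unique(lab))
  list(labels = match(lab, used) - 1L, map = used)
}

#' Equal-width binning
#'
#' Divides the range of `x` into `m` intervals of equal length.  Bins
#' are half-open `[a, b)` with the last bin closed, so a value exactly
#' on an interior edge is assigned to the bin on its right.  Empty bins
#' are allowed; the returned labels are compacted to `0..k-1` (the
#' original bin index of each label is kept in attribute `bin_map`, the
#' interval edges in attribute `edges`).
#'
#' @param x numeric vector.
#' @param m number of bins (`>= 1`).
#' @return integer labels in `0..k-1` with attributes `edges`, `bin_map`.
#' @export
equal_width <- function(x, m) {
  m <- as.integer(m)
  if (m < 1L) stop_usage("m must be >= 1")
  lo <- min(x); hi <- max(x)
  edges <- lo + (0:m) * (hi - lo) / m
  if (hi == lo) {
    raw <- rep(0L, length(x))
  } else {
    raw <- pmin(as.integer(floor((x - lo) / ((hi - lo) / m))), m - 1L)
  }
  cl <- compact_labels(raw)
  structure(cl$labels, edges = edges, bin_map = cl$map)
}

#' Equal-frequency binning
#'
#' Cuts at sample quantiles so each bin holds (as nearly as possible)
#' the same number of observations.  Ties are never split: every
#' duplicate of a value shares one label, so bins can be unequal when
#' the data contain repeated values.  With all-distinct values bin
#' sizes differ by at most one.
#'
#' @param x numeric vector.
#' @param m number of bins (`>= 1`).
#' @return integer labels in `0..k-1`, ordered by value, with attribute
#'   `bin_values` (list of the distinct values in each bin).
#' @export
equal_frequency <- function(x, m) {
  m <- as.integer(m)
  if (m < 1L) stop_usage("m must be >= 1")
  vals <- sort(unique(x))
  cnt <- tabulate(match(x, vals), nbins = length(vals))
  d <- length(vals)
  lab_of_val <- integer(d)
  # greedy: fill bins in value order, never splitting a tie group; each
  # bin targets (remaining n) / (remaining bins) members and always
  # leaves one distinct value for every bin still to come
  b <- 0L; i <- 1L; n_r <- length(x); m_r <- min(m, d)
  while (i <= d) {
    target <- ceiling(n_r / m_r)
    size <- 0L
    repeat {
      lab_of_val[i] <- b
      size <- size + cnt[i]
      n_r <- n_r - cnt[i]
      i <- i + 1L
      if (i > d) break
      if (m_r > 1L && (size >= target || d - i + 1L <= m_r - 1L)) break
    }
    b <- b + 1L
    m_r <- max(m_r - 1L, 1L)
  }
  lab <- lab_of_val[match(x, vals)]
  cl <- compact_labels(lab)
  structure(cl$labels, bin_values = unname(split(vals, lab_of_val)))
}

#' Jenks natural-breaks binning
#'
#' Exact 1-D optimal partition into `m` classes minimizing the total
#' within-class sum of squares (Fisher/Jenks dynamic programming over
#' classes contiguous in sorted order, which is optimal for 1-D
#' k-means).  Labels `0..m-1` are assigned in increasing order of class
#' mean; contiguity makes this automatic and side-steps any label
#' switching.
#'
#' @param x numeric vector.
#' @param m number of classes; if `m` exceeds the number of distinct
#'   values it is reduced with a warning.
#' @return integer labels in `0..m-1` with attribute `class_means`.
#' @export
jenks <- function(x, m) {
  m <- as.integer(m)
  if (m < 1L) stop_usage("m must be >= 1")
  vals <- sort(unique(x))
  cnt <- as.numeric(tabulate(match(x, vals), nbins = length(vals)))
  d <- length(vals)
  if (m > d) {
    warning("m = ", m, " exceeds ", d, " distinct values; reduced to ", d)
    m <- d
  }
  lab_of_val <- if (m == 1L) rep(0L, d) else
    as.integer(jenks_dp(vals, cnt, m))
  lab <- lab_of_val[match(x, vals)]
  means <- vapply(split(seq_len(d), lab_of_val),
                  function(ix) sum(vals[ix] * cnt[ix]) / sum(cnt[ix]),
                  numeric(1))
  structure(lab, class_means = unname(means))
}

#' Discrete (categorical) matrix container
#'
#' Integer category labels per sample and feature, `0..m_j - 1` for
#' feature `j`, as consumed by [fit_mcpca()].
#'
#' @param labels integer `n x p` matrix of 0-based labels.
#' @param m per-feature category counts (defaults to observed).
#' @param method tag: `"intv"`, `"freq"`, `"jenks"` or `"raw"`.
#' @param bins optional per-feature bin metadata (edges / class means).
#' @return An integer matrix of class `discrete_matrix` with attributes
#'   `m`, `method`, `bins`, `degenerate` (logical, `m_j == 1`).
#' @export
discrete_matrix <- function(labels, m = NULL, method = "raw", bins = NULL) {
  labels <- as.matrix(labels)
  storage.mode(labels) <- "integer"
  if (any(labels < 0L)) stop_data("labels must be >= 0")
  if (is.null(m)) m <- apply(labels, 2, function(col) max(col) + 1L)
  m <- as.integer(m)
  for (j in seq_len(ncol(labels))) {
    u <- sort(unique(labels[, j]))
    if (!identical(u, seq_len(length(u)) - 1L))
      stop_data("feature ", j, " has label gaps; compact labels first")
    if (m[j] < length(u)) stop_data("feature ", j, " has labels beyond m")
  }
  structure(labels, m = m, method = method, bins = bins,
            degenerate = m == 1L,
            class = c("discrete_matrix", "matrix", "array"))
}

#' @export
print.discrete_matrix <- function(x, ...) {
  cat(sprintf(
    "discrete_matrix: %d samples x %d features (%s), m in [%d, %d]%s\n",
    nrow(x), ncol(x), attr(x, "method"), min(attr(x, "m")),
    max(attr(x, "m")),
    if (any(attr(x, "degenerate")))
      sprintf(", %d degenerate", sum(attr(x, "degenerate"))) else ""))
  invisible(x)
}

#' Coerce a matrix to a discrete_matrix without binning
#'
#' Each column's distinct values become its categories (labels compacted
#' to `0..m_j - 1` in value order).  For true-genotype matrices the
#' three genotypes are the categories; applied to continuous dosages
#' this is the "raw dosage" route, where every distinct dosage value is
#' its own category (prone to overfitting — prefer
#' [discretize_matrix()]).
#'
#' @param X numeric matrix (e.g. a genotype or dosage [dosage_matrix]).
#' @return A [discrete_matrix] with method tag `"raw"`.
#' @export
as_discrete_matrix <- function(X) {
  X <- as.matrix(unclass(X))
  lab <- matrix(0L, nrow(X), ncol(X), dimnames = dimnames(X))
  for (j in seq_len(ncol(X))) {
    u <- sort(unique(X[, j]))
    lab[, j] <- match(X[, j], u) - 1L
  }
  discrete_matrix(lab, method = "raw")
}

#' Discretize a dosage matrix per SNP
#'
#' Applies one of the three binning schemes to every column
#' independently; with `m = "auto"` the per-SNP bin count comes from
#' the Freedman-Diaconis rule ([fd_bin_count()]), clamped to
#' `[m_min, m_max]`.  Constant columns get a single category and are
#' flagged degenerate (attribute `degenerate`); [fit_mcpca()] requires
#' the caller to drop them.
#'
#' @param X a [dosage_matrix] or numeric matrix.
#' @param method `"intv"` (equal width), `"freq"` (equal frequency) or
#'   `"jenks"`.
#' @param m `"auto"` or a fixed integer bin count.
#' @param m_min,m_max clamp bounds for the automatic bin count.
#' @return A [discrete_matrix].
#' @export
discretize_matrix <- function(X, method = c("intv", "freq", "jenks"),
                              m = "auto", m_min = 2L, m_max = 20L) {
  method <- match.arg(method)
  X <- as.matrix(unclass(X))
  if (any(!is.finite(X))) stop_data("dosage matrix contains non-finite values")
  n <- nrow(X); p <- ncol(X)
  lab <- matrix(0L, n, p)
  bins <- vector("list", p)
  binfun <- switch(method, intv = equal_width, freq = equal_frequency,
                   jenks = jenks)
  for (j in seq_len(p)) {
    x <- X[, j]
    if (length(unique(x)) == 1L) {
      lab[, j] <- 0L
      bins[[j]] <- list(m = 1L)
      next
    }
    mj <- if (identical(m, "auto")) fd_bin_count(x, m_min, m_max)
          else as.integer(m)
    lj <- suppressWarnings(binfun(x, mj))
    lab[, j] <- as.integer(lj)
    bins[[j]] <- attributes(lj)
  }
  dimnames(lab) <- dimnames(X)
  discrete_matrix(lab, method = method, bins = bins)
}
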