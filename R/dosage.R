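#' Dosage matrix container
#'
#' An `n x p` matrix of genotype values in `[0, 2]` under additive
#' minor-allele coding.  `provenance` records what the values are:
#' hard true genotypes (`true_genotype`, values in \{0, 1, 2\}),
#' perturbed hard calls (`observed_genotype`) or posterior-mean dosages
#' (`posterior_dosage`, `DS = Pr(1 | Data) + 2 Pr(2 | Data)`).
#'
#' @param values numeric `n x p` matrix with entries in `[0, 2]`.
#' @param markers optional marker data frame (or marker id vector).
#' @param sample_ids optional sample id vector.
#' @param provenance one of `"true_genotype"`, `"observed_genotype"`,
#'   `"posterior_dosage"`.
#' @return A numeric matrix of class `dosage_matrix` with attributes
#'   `markers`, `provenance`; row names are sample ids, column names
#'   marker ids.
#' @export
dosage_matrix <- function(values, markers = NULL, sample_ids = NULL,
                          provenance = c("posterior_dosage",
                                         "true_genotype",
                                         "observed_genotype")) {
  provenance <- match.arg(provenance)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (any(values < 0 | values > 2, na.rm = TRUE))
    stop_data("dosage values must lie in [0, 2]")
  if (provenance == "true_genotype" && any(values != round(values)))
    stop_data("true_genotype provenance requires values in {0, 1, 2}")
  if (is.null(markers)) {
    ids <- colnames(values)
    if (is.null(ids)) ids <- paste0("snp", seq_len(ncol(values)))
    markers <- data.frame(id = ids, allele_major = "A", allele_minor = "B")
  } else if (!is.data.frame(markers)) {
    markers <- data.frame(id = as.character(markers),
                          allele_major = "A", allele_minor = "B")
  }
  if (nrow(markers) != ncol(values))
    stop_usage("markers do not match number of columns")
  if (is.null(sample_ids)) {
    sample_ids <- rownames(values)
    if (is.null(sample_ids)) sample_ids <- paste0("Ind", seq_len(nrow(values)))
  }
  dimnames(values) <- list(sample_ids, markers$id)
  structure(values, markers = markers, provenance = provenance,
            class = c("dosage_matrix", "matrix", "array"))
}

#' @export
print.dosage_matrix <- function(x, ...) {
  cat(sprintf("dosage_matrix: %d samples x %d sites (%s)\n",
              nrow(x), ncol(x), attr(x, "provenance")))
  invisible(x)
}

#' Convert genotype likelihoods to posterior probabilities
#'
#' Applies Bayes' rule per site and individual:
#' `posterior(g) \eqn{\propto} L(g) prior(g)`.  The Hardy-Weinberg prior for
#' minor-allele frequency `f` is `((1-f)^2, 2f(1-f), f^2)`; when `af` is
#' not supplied it is estimated per site as half the mean dosage of the
#' normalized likelihoods (ANGSD-style allele-frequency prior).  A set
#' already flagged `is_posterior` is returned unchanged.
#'
#' @param gl a [gl_set] of likelihoods.
#' @param prior `"hwe"` (default) or `"uniform"`.
#' @param af optional per-site minor-allele frequencies in `(0, 1)`
#'   (recycled if scalar); only used with the HWE prior.
#' @return A [gl_set] with `is_posterior = TRUE`.
#' @export
posteriors_from_likelihoods <- function(gl, prior = c("hwe", "uniform"),
                                        af = NULL) {
  stopifnot(inherits(gl, "gl_set"))
  prior <- match.arg(prior)
  if (gl$is_posterior) return(gl)
  v <- gl$values
  n <- dim(v)[1]; p <- dim(v)[2]
  slab <- function(g) matrix(v[, , g], n, p)  # dims survive n = 1 / p = 1
  tot <- slab(1) + slab(2) + slab(3)
  if (any(tot <= 0)) {
    ij <- which(tot <= 0, arr.ind = TRUE)[1, ]
    stop_data("all-zero likelihood triplet at sample '",
              gl$sample_ids[ij[1]], "', marker '",
              gl$markers$id[ij[2]], "'")
  }
  if (prior == "hwe") {
    if (is.null(af)) {
      # normalized-likelihood mean dosage / 2 as the frequency estimate
      af <- colMeans((slab(2) + 2 * slab(3)) / tot) / 2
      af <- pmin(pmax(af, 1e-6), 1 - 1e-6)
    } else {
      if (any(af <= 0 | af >= 1))
        stop_usage("HWE prior frequencies must lie in (0, 1)")
      af <- rep_len(af, p)
    }
    pri <- rbind((1 - af)^2, 2 * af * (1 - af), af^2)  # 3 x p
  } else {
    pri <- matrix(1 / 3, nrow = 3, ncol = p)
  }
  post <- v
  for (g in 1:3)
    post[, , g] <- slab(g) * matrix(pri[g, ], n, p, byrow = TRUE)
  tot <- matrix(post[, , 1], n, p) + matrix(post[, , 2], n, p) +
    matrix(post[, , 3], n, p)
  for (g in 1:3) post[, , g] <- matrix(post[, , g], n, p) / tot
  gl_set(post, gl$markers, gl$sample_ids, is_posterior = TRUE)
}

#' Posterior-mean genotype dosage
#'
#' `DS = Pr(1 | Data) + 2 Pr(2 | Data)`, the posterior mean of the
#' minor-allele count under additive coding; continuous in `[0, 2]`.
#'
#' @param post a [gl_set] with `is_posterior = TRUE`.
#' @param tol maximum tolerated deviation of triplet sums from 1.
#' @return A [dosage_matrix] with provenance `posterior_dosage`.
#' @export
dosage_from_posteriors <- function(post, tol = 1e-6) {
  stopifnot(inherits(post, "gl_set"))
  if (!post$is_posterior)
    stop_usage("input is not flagged as posteriors; ",
               "run posteriors_from_likelihoods() first")
  sums <- post$values[, , 1] + post$values[, , 2] + post$values[, , 3]
  if (any(abs(sums - 1) > tol))
    stop_data("posterior triplets deviate from sum 1 beyond tol = ", tol)
  ds <- post$values[, , 2] + 2 * post$values[, , 3]
  ds <- pmin(pmax(ds, 0), 2)
  dim(ds) <- dim(post$values)[1:2]  # keep n x p even when n = 1
  dosage_matrix(ds, markers = post$markers, sample_ids = post$sample_ids,
                provenance = "posterior_dosage")
}

#' Filter sites on minor allele frequency
#'
#' The per-site allele frequency is `f = mean(value) / 2`, folded to
#' `min(f, 1 - f)`; sites with folded frequency below `threshold` are
#' removed.  Computing MAF from dosages (rather than hard calls) keeps
#' the filter meaningful at low coverage.  The index of kept sites is
#' attached as attribute `kept_sites`.
#'
#' @param X a [dosage_matrix] or plain numeric genotype matrix.
#' @param threshold folded-frequency cutoff in `[0, 0.5]` (default 0.05).
#' @return The filtered matrix (same class as `X`) with attribute
#'   `kept_sites`.
#' @export
maf_filter <- function(X, threshold = 0.05) {
  if (threshold < 0 || threshold > 0.5)
    stop_usage("MAF threshold must lie in [0, 0.5]")
  f <- unname(colMeans(as.matrix(X))) / 2
  folded <- pmin(f, 1 - f)
  keep <- which(folded >= threshold & folded > 0 | threshold == 0)
  if (threshold == 0) keep <- seq_len(ncol(X))
  if (length(keep) == 0L)
    stop_data("all ", ncol(X), " sites filtered at MAF threshold ",
              threshold, "; lower the threshold")
  out <- X[, keep, drop = FALSE]
  if (inherits(X, "dosage_matrix")) {
    out <- dosage_matrix(out,
                         markers = attr(X, "markers")[keep, , drop = FALSE],
                         sample_ids = rownames(X),
                         provenance = attr(X, "provenance"))
  }
  attr(out, "kept_sites") <- keep
  out
}
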