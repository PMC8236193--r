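#' Genotype likelihood/posterior container
#'
#' Holds per-individual, per-site triplets of genotype likelihoods or
#' posterior probabilities for the three diploid genotypes (0, 1, 2
#' copies of the minor allele), together with marker metadata.
#'
#' @param values numeric array of dimension `n x p x 3` (samples x
#'   markers x genotypes), all entries non-negative.
#' @param markers data frame with columns `id`, `allele_major`,
#'   `allele_minor` (one row per marker).
#' @param sample_ids character vector of length `n`.
#' @param is_posterior logical; `TRUE` when each triplet is a normalized
#'   posterior distribution (sums to 1 within `1e-6`).
#'
#' @return An object of class `gl_set`.
#' @export
gl_set <- function(values, markers, sample_ids = NULL, is_posterior = FALSE) {
  if (length(dim(values)) != 3L || dim(values)[3] != 3L)
    stop_usage("'values' must be an n x p x 3 array")
  n <- dim(values)[1]; p <- dim(values)[2]
  if (is.null(sample_ids)) sample_ids <- paste0("Ind", seq_len(n))
  if (nrow(markers) != p)
    stop_usage("markers (", nrow(markers), ") do not match p = ", p)
  if (length(sample_ids) != n)
    stop_usage("sample_ids (", length(sample_ids), ") do not match n = ", n)
  if (any(values < 0, na.rm = TRUE))
    stop_data("genotype likelihoods must be non-negative")
  if (is_posterior) {
    sums <- apply(values, c(1, 2), sum)
    if (any(abs(sums - 1) > 1e-6))
      stop_data("is_posterior = TRUE but some triplets do not sum to 1")
  }
  structure(list(values = values, markers = markers,
                 sample_ids = sample_ids, is_posterior = is_posterior),
            class = "gl_set")
}

#' @export
print.gl_set <- function(x, ...) {
  cat(sprintf("gl_set: %d samples x %d markers (%s)\n",
              length(x$sample_ids), nrow(x$markers),
              if (x$is_posterior) "posteriors" else "likelihoods"))
  invisible(x)
}

#' @export
dim.gl_set <- function(x) dim(x$values)[1:2]

#' Read Beagle genotype-likelihood text files
#'
#' Parses the whitespace-delimited Beagle GL dialect written by ANGSD
#' (`-doGlf 2`): a header line `marker allele1 allele2` followed by one
#' row per marker with three columns (genotypes 0/1/2) per individual.
#' Whether the triplets are posteriors is inferred: if every triplet
#' sums to 1 within `1e-6` the set is flagged `is_posterior`.
#'
#' @param path path to the text file (may be gzipped).
#' @return A [gl_set].
#' @seealso [write_beagle_gl()]
#' @export
read_beagle_gl <- function(path) {
  if (!file.exists(path)) stop_usage("no such file: ", path)
  nf <- tryCatch(count.fields(path, comment.char = ""),
                 error = function(e) stop_data("cannot parse ", path, ": ",
                                               conditionMessage(e)))
  if (length(nf) == 0L) stop_data("empty Beagle-GL file: ", path)
  bad <- which(nf != nf[1])
  if (length(bad))
    stop_data("Beagle-GL format error: line ", bad[1] + 0L,
              " has ", nf[bad[1]], " fields, expected ", nf[1])
  if (nf[1] < 6L || (nf[1] - 3L) %% 3L != 0L)
    stop_data("Beagle-GL format error: ", nf[1],
              " columns is not 3 + 3k for k >= 1 individuals")
  tab <- read.table(path, header = TRUE, check.names = FALSE,
                    colClasses = c(rep("character", 3),
                                   rep("numeric", nf[1] - 3L)))
  if (nrow(tab) == 0L) stop_data("Beagle-GL file has a header but no markers")
  n <- (nf[1] - 3L) %/% 3L
  p <- nrow(tab)
  vals <- as.matrix(tab[, -(1:3), drop = FALSE])
  if (any(!is.finite(vals))) stop_data("non-numeric genotype likelihood value")
  if (any(vals < 0)) {
    ij <- which(vals < 0, arr.ind = TRUE)[1, ]
    stop_data("negative genotype likelihood at marker line ", ij[1])
  }
  sample_ids <- unique(sub("(\\.\\d+)?$", "", colnames(tab)[-(1:3)]))
  if (length(sample_ids) != n) sample_ids <- paste0("Ind", seq_len(n))
  arr <- array(NA_real_, dim = c(n, p, 3))
  for (g in 1:3) arr[, , g] <- t(vals[, seq(g, by = 3, length.out = n),
                                      drop = FALSE])
  markers <- data.frame(id = tab[[1]], allele_major = tab[[2]],
                        allele_minor = tab[[3]])
  sums <- apply(arr, c(1, 2), sum)
  gl_set(arr, markers, sample_ids,
         is_posterior = all(abs(sums - 1) <= 1e-6))
}

#' Write a gl_set in Beagle genotype-likelihood format
#'
#' @param gl a [gl_set].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_beagle_gl <- function(gl, path) {
  stopifnot(inherits(gl, "gl_set"))
  n <- length(gl$sample_ids); p <- nrow(gl$markers)
  out <- matrix("", nrow = p, ncol = 3L + 3L * n)
  out[, 1] <- as.character(gl$markers$id)
  out[, 2] <- as.character(gl$markers$allele_major)
  out[, 3] <- as.character(gl$markers$allele_minor)
  for (g in 1:3)
    out[, seq(3L + g, by = 3L, length.out = n)] <-
      format(t(gl$values[, , g]), digits = 15, trim = TRUE,
             scientific = FALSE)
  header <- c("marker", "allele1", "allele2", rep(gl$sample_ids, each = 3))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(header, collapse = "\t"), con)
  write.table(out, con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Convert a Phred quality score to an error probability
#'
#' `Q` Phred units correspond to an error probability of
#' `10^(-Q/10)`: Q = 10 is 1 error in 10 bases, Q = 30 is 1 in 1000.
#'
#' @param Q numeric vector of Phred scores, all `>= 0`.
#' @return numeric vector of error probabilities in `(0, 1]`.
#' @export
phred_to_error <- function(Q) {
  if (any(Q < 0)) stop_usage("Phred quality scores must be >= 0")
  10^(-Q / 10)
}

#' Read genotype probabilities or dosages from a VCF
#'
#' Extracts one of the FORMAT fields `GP` (genotype posterior
#' probabilities), `PL` (Phred-scaled genotype likelihoods, converted
#' via `p` proportional to `10^(-PL/10)` and renormalized) or `DS`
#' (dosage).  Only biallelic records are used; multiallelic records are
#' skipped with a warning.  Missing calls become uniform triplets
#' (1/3, 1/3, 1/3) — maximal uncertainty, so the downstream dosage falls
#' back to the prior mean — and their count is reported in a message.
#'
#' Requires the `VariantAnnotation` package.
#'
#' @param path path to a VCF file.
#' @param field one of `"GP"`, `"PL"`, `"DS"`.
#' @return A [gl_set] for `GP`/`PL`, a [dosage_matrix] for `DS`.
#' @export
read_vcf_genotype_probs <- function(path, field = c("GP", "PL", "DS")) {
  field <- match.arg(field)
  if (!requireNamespace("VariantAnnotation", quietly = TRUE))
    stop_usage("read_vcf_genotype_probs requires the VariantAnnotation package")
  vcf <- VariantAnnotation::readVcf(path)
  if (!field %in% names(VariantAnnotation::geno(vcf)))
    stop_data("FORMAT field '", field, "' absent from ", path)
  nalt <- lengths(VariantAnnotation::alt(vcf))
  if (any(nalt != 1L)) {
    warning(sum(nalt != 1L), " multiallelic record(s) skipped")
    vcf <- vcf[nalt == 1L]
  }
  if (nrow(vcf) == 0L) stop_data("no biallelic records in ", path)
  ref <- as.character(VariantAnnotation::ref(vcf))
  alt <- as.character(unlist(VariantAnnotation::alt(vcf)))
  markers <- data.frame(id = rownames(vcf), allele_major = ref,
                        allele_minor = alt)
  samples <- colnames(vcf)
  dat <- VariantAnnotation::geno(vcf)[[field]]
  if (field == "DS") {
    ds <- t(matrix(as.numeric(dat), nrow = nrow(vcf)))
    nmiss <- sum(is.na(ds))
    if (nmiss) {
      message(nmiss, " missing DS call(s) set to 1 (prior mean)")
      ds[is.na(ds)] <- 1
    }
    return(dosage_matrix(ds, markers = markers, sample_ids = samples,
                         provenance = "posterior_dosage"))
  }
  # GP / PL arrive as a variant x sample x genotype array, or as a
  # list-matrix when the genotype count varied across (pre-filter)
  # records; normalize to the array form
  if (is.list(dat)) {
    cube <- array(NA_real_, dim = c(nrow(dat), ncol(dat), 3))
    for (g in 1:3)
      cube[, , g] <- matrix(vapply(dat, function(x)
        if (length(x) >= g) as.numeric(x[g]) else NA_real_,
        numeric(1)), nrow(dat), ncol(dat))
    dat <- cube
  }
  if (length(dim(dat)) != 3L || dim(dat)[3] != 3L)
    stop_data("field '", field, "' is not a 3-genotype array; ",
              "only biallelic diploid VCFs are supported")
  arr <- aperm(dat, c(2, 1, 3))  # -> sample x variant x genotype
  storage.mode(arr) <- "double"
  miss <- is.na(arr[, , 1]) | is.na(arr[, , 2]) | is.na(arr[, , 3])
  if (field == "PL") arr <- 10^(-arr / 10)
  tot <- arr[, , 1] + arr[, , 2] + arr[, , 3]
  for (g in 1:3) arr[, , g] <- arr[, , g] / tot
  if (any(miss)) {
    message(sum(miss), " missing ", field,
            " call(s) set to uniform (1/3, 1/3, 1/3)")
    for (g in 1:3) { slab <- arr[, , g]; slab[miss] <- 1 / 3; arr[, , g] <- slab }
  }
  gl_set(arr, markers, samples, is_posterior = (field == "GP"))
}

#' Write sample scores and a JSON run report
#'
#' Writes a TSV with one row per sample (`sample_id` plus `q` score
#' columns) and a companion JSON report (same path with extension
#' `.json`) carrying the eigenvalues, the objective trajectory (for
#' MCPCA fits), the explained-variance fraction, the configuration echo
#' and the seed, so every run can be reproduced from its report.
#'
#' @param result an `mcpca_fit` or `embedding` object, or any list with
#'   elements `scores` (n x q matrix) and optionally `sample_ids`,
#'   `eigenvalues`, `objective_trace`, `q`, `seed`, `explained_fraction`,
#'   `config`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_scores <- function(result, path) {
  scores <- result$scores
  if (is.null(scores)) stop_usage("'result' has no scores; fit it first")
  q <- ncol(scores)
  ids <- result$sample_ids
  if (is.null(ids)) ids <- rownames(scores)
  if (is.null(ids)) ids <- paste0("Ind", seq_len(nrow(scores)))
  df <- data.frame(sample_id = ids, scores, check.names = FALSE)
  colnames(df) <- c("sample_id", paste0("MCPC", seq_len(q)))
  ok <- tryCatch({
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop_data("cannot write scores to ", path)
  report <- list(
    q = q,
    eigenvalues = as.numeric(result$eigenvalues),
    objective_trace = as.numeric(result$objective_trace),
    explained_fraction = result$explained_fraction,
    method = if (!is.null(result$method)) result$method else class(result)[1],
    seed = result$seed,
    config = result$config
  )
  jsonlite::write_json(report,
                       paste0(tools::file_path_sans_ext(path), ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a score TSV written by [write_scores()]
#'
#' @param path TSV path.
#' @return data frame with `sample_id` and score columns.
#' @export
read_scores <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  df$sample_id <- as.character(df$sample_id)
  df
}
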