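#' Simulation configuration
#'
#' Bundles the parameters of the low-coverage genotype simulation
#' pipeline: admixed multi-population true genotypes, per-site read
#' depths from a Gamma model, Phred-quality-driven genotype errors and
#' read-level genotype likelihoods.
#'
#' Defaults describe the reference scenario used throughout the
#' package's tests: 3 populations of 50 individuals (n = 150), moderate
#' admixture (80% own-population ancestry), Gamma read depths with
#' shape 6.3 and scale `mean_depth / 6.3`, and a synthetic quality
#' model with mean Phred score about 3 per unit of depth (so 1x reads
#' average Q ~ 3, 10x reads Q ~ 30).  Rare variants below 5% folded
#' MAF are removed.  The default `fst = 0.55` is an *effective*
#' differentiation for independent sites: with no linkage
#' disequilibrium between simulated sites it reproduces the
#' top-eigenvalue share that coalescent simulations of three
#' continental populations (where linked sites reinforce each other)
#' show at much lower nominal Fst; linear PCA with q = 10 then
#' explains about 0.38 of the variance at n = 150, p ~ 1500.
#'
#' @param n_per_pop individuals per population.
#' @param n_pops number of populations.
#' @param admix_main ancestry proportion each individual keeps from its
#'   own population; the remainder is split evenly over the others.
#' @param p_sites candidate sites simulated before the MAF filter.
#' @param fst Balding-Nichols differentiation coefficient.
#' @param mean_depth mean sequencing depth (reads per site).
#' @param depth_shape Gamma shape for the depth model (default 6.3;
#'   scale is `mean_depth / depth_shape`).
#' @param qual_slope,qual_sd,qual_max synthetic quality model:
#'   `Q = clamp(qual_slope * depth + N(0, qual_sd), 0, qual_max)`.
#' @param maf_threshold folded-MAF filter cutoff.
#' @param seed integer seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_per_pop = 50L, n_pops = 3L, admix_main = 0.8,
                       p_sites = 2000L, fst = 0.55, mean_depth = 5,
                       depth_shape = 6.3, qual_slope = 3, qual_sd = 2,
                       qual_max = 40, maf_threshold = 0.05, seed = 1L) {
  cfg <- list(n_per_pop = as.integer(n_per_pop),
              n_pops = as.integer(n_pops), admix_main = admix_main,
              p_sites = as.integer(p_sites), fst = fst,
              mean_depth = mean_depth, depth_shape = depth_shape,
              qual_slope = qual_slope, qual_sd = qual_sd,
              qual_max = qual_max, maf_threshold = maf_threshold,
              seed = as.integer(seed))
  if (cfg$n_per_pop < 1L || cfg$n_pops < 1L || cfg$p_sites < 1L)
    stop_usage("sample and site counts must be positive")
  if (cfg$admix_main < 0 || cfg$admix_main > 1)
    stop_usage("admix_main must lie in [0, 1]")
  if (cfg$fst <= 0 || cfg$fst >= 1)
    stop_usage("fst must lie in (0, 1)")
  if (cfg$mean_depth <= 0) stop_usage("mean_depth must be positive")
  if (cfg$depth_shape <= 0) stop_usage("depth_shape must be positive")
  if (cfg$maf_threshold < 0 || cfg$maf_threshold > 0.5)
    stop_usage("maf_threshold must lie in [0, 0.5]")
  structure(cfg, class = "sim_config")
}

#' Parse ms-style coalescent simulator output
#'
#' Reads the standard `ms` text stream: replicates separated by `//`,
#' each with a `segsites:` count, a `positions:` line and one 0/1
#' haplotype string per chromosome.
#'
#' @param text character vector of lines, a single string with
#'   newlines, or a file path.
#' @return list with one element per replicate, each a list of
#'   `positions` (numeric) and `haplotypes` (haplotype x site 0/1
#'   integer matrix).
#' @seealso [genotypes_from_haplotypes()]
#' @export
parse_ms_output <- function(text) {
  if (length(text) == 1L && !grepl("\n", text) && file.exists(text))
    text <- readLines(text)
  else if (length(text) == 1L)
    text <- strsplit(text, "\n", fixed = TRUE)[[1]]
  starts <- which(trimws(text) == "//")
  if (length(starts) == 0L) stop_data("no '//' replicate separator found")
  bounds <- c(starts, length(text) + 1L)
  lapply(seq_along(starts), function(r) {
    block <- text[(bounds[r] + 1L):(bounds[r + 1L] - 1L)]
    block <- block[nzchar(trimws(block))]
    segline <- grep("^segsites:", trimws(block), value = TRUE)
    if (length(segline) != 1L) stop_data("replicate ", r, ": missing segsites")
    s <- as.integer(sub("^segsites:\\s*", "", trimws(segline)))
    if (s == 0L)
      return(list(positions = numeric(0),
                  haplotypes = matrix(0L, 0, 0)))
    posline <- grep("^positions:", trimws(block), value = TRUE)
    positions <- if (length(posline))
      as.numeric(strsplit(sub("^positions:\\s*", "", trimws(posline[1])),
                          "\\s+")[[1]]) else numeric(0)
    hap_lines <- block[grepl("^[01]+$", trimws(block))]
    if (length(hap_lines) == 0L) stop_data("replicate ", r, ": no haplotypes")
    bad <- which(nchar(trimws(hap_lines)) != s)
    if (length(bad))
      stop_data("replicate ", r, ": haplotype ", bad[1], " has ",
                nchar(trimws(hap_lines[bad[1]])),
                " sites but segsites: ", s)
    haps <- do.call(rbind, lapply(trimws(hap_lines), function(h)
      as.integer(strsplit(h, "")[[1]])))
    list(positions = positions, haplotypes = haps)
  })
}

#' Pair haplotypes into diploid genotypes
#'
#' Consecutive haplotypes (rows 1-2, 3-4, ...) form one diploid
#' individual; the genotype is the haplotype sum.
#'
#' @param haps haplotype x site 0/1 matrix with an even number of rows.
#' @return individual x site genotype matrix with values in
#'   \{0, 1, 2\}.
#' @export
genotypes_from_haplotypes <- function(haps) {
  if (nrow(haps) %% 2L != 0L)
    stop_data("odd number of haplotypes cannot be paired into diploids")
  haps[seq(1, nrow(haps), by = 2), , drop = FALSE] +
    haps[seq(2, nrow(haps), by = 2), , drop = FALSE]
}

#' Simulate admixed multi-population genotypes
#'
#' Built-in substitute for coalescent (ms) input: the Balding-Nichols
#' model.  Ancestral allele frequencies are Uniform(0.05, 0.95); each
#' population's frequency is Beta(f (1-F)/F, (1-f)(1-F)/F) around the
#' ancestral `f` with differentiation `F = cfg$fst`; each individual
#' mixes population frequencies with its ancestry proportions
#' (`admix_main` on its own population, the rest split evenly); the
#' genotype is Binomial(2, individual frequency).  Sites are then
#' MAF-filtered at `cfg$maf_threshold`.
#'
#' @param cfg a [sim_config].
#' @param n_keep optionally subsample (the first) `n_keep` post-filter
#'   sites for a fixed-size design.
#' @return list with `G` (a [dosage_matrix] with provenance
#'   `true_genotype`), `pop` (integer population labels) and `freq`
#'   (population x site allele-frequency matrix of the kept sites).
#' @export
sim_admixed_genotypes <- function(cfg, n_keep = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  K <- cfg$n_pops
  n <- cfg$n_per_pop * K
  p <- cfg$p_sites
  f0 <- runif(p, 0.05, 0.95)
  Fst <- cfg$fst
  a <- f0 * (1 - Fst) / Fst
  b <- (1 - f0) * (1 - Fst) / Fst
  freq <- matrix(rbeta(K * p, rep(a, each = K), rep(b, each = K)),
                 nrow = K)  # pop x site
  pop <- rep(seq_len(K), each = cfg$n_per_pop)
  if (K > 1L) {
    anc <- matrix((1 - cfg$admix_main) / (K - 1), n, K)
    anc[cbind(seq_len(n), pop)] <- cfg$admix_main
  } else {
    anc <- matrix(1, n, 1)
  }
  pind <- anc %*% freq                   # individual x site frequency
  G <- matrix(rbinom(n * p, 2L, pind), n, p)
  Gd <- dosage_matrix(G, provenance = "true_genotype")
  Gf <- maf_filter(Gd, cfg$maf_threshold)
  kept <- attr(Gf, "kept_sites")
  if (!is.null(n_keep)) {
    if (length(kept) < n_keep)
      stop_data("only ", length(kept), " sites survive the MAF filter; ",
                "raise p_sites to keep ", n_keep)
    idx <- seq_len(n_keep)
    Gf <- dosage_matrix(unclass(Gf)[, idx, drop = FALSE],
                        provenance = "true_genotype")
    kept <- kept[idx]
  }
  list(G = Gf, pop = pop, freq = freq[, kept, drop = FALSE])
}

#' Simulate per-site read depths
#'
#' Depths are `round(Gamma(shape, scale = mean_depth / shape))` draws,
#' shape 6.3 by default, giving mean `mean_depth` and variance
#' `mean_depth^2 / shape` before rounding.
#'
#' @param cfg a [sim_config] (supplies `mean_depth`, `depth_shape`).
#' @param n,p matrix dimensions.
#' @return `n x p` integer matrix of depths.
#' @export
sim_depths <- function(cfg, n, p) {
  stopifnot(inherits(cfg, "sim_config"))
  d <- rgamma(n * p, shape = cfg$depth_shape,
              scale = cfg$mean_depth / cfg$depth_shape)
  matrix(as.integer(round(d)), n, p)
}

#' Simulate Phred quality scores for given depths
#'
#' Synthetic mode (default): `Q = clamp(slope * depth + N(0, sd), 0,
#' qmax)`; the default slope 3 reproduces the depth-to-quality scaling
#' of typical low-coverage calling (about Q 3 at 1x, Q 15 at 5x, Q 30
#' at 10x) and makes mean quality monotone in depth.  Table mode: a
#' user-supplied list mapping read counts to pools of observed quality
#' scores (e.g. drawn from a reference sequencing project); each cell
#' samples from the pool whose depth is closest to its own.
#'
#' @param depths integer matrix of read depths.
#' @param cfg a [sim_config] (synthetic-model parameters).
#' @param model `"synthetic"` or `"table"`.
#' @param table for table mode: named list, names = depths, values =
#'   numeric vectors of quality scores to sample from.
#' @return numeric matrix of Phred scores, same shape as `depths`.
#' @export
sim_quality <- function(depths, cfg = sim_config(),
                        model = c("synthetic", "table"), table = NULL) {
  model <- match.arg(model)
  if (model == "synthetic") {
    Q <- cfg$qual_slope * depths +
      rnorm(length(depths), 0, cfg$qual_sd)
    Q <- pmin(pmax(Q, 0), cfg$qual_max)
    return(matrix(Q, nrow(depths), ncol(depths)))
  }
  if (is.null(table) || length(table) == 0L)
    stop_usage("table mode requires a nonempty depth -> quality table")
  avail <- as.integer(names(table))
  Q <- matrix(0, nrow(depths), ncol(depths))
  warned <- FALSE
  for (d in sort(unique(as.vector(depths)))) {
    idx <- which(depths == d)
    j <- which.min(abs(avail - d))
    if (avail[j] != d && !warned) {
      warning("no quality pool for some depth(s); nearest pool used")
      warned <- TRUE
    }
    pool <- table[[j]]
    Q[idx] <- if (length(pool) == 1L) pool else sample(pool, length(idx),
                                                       replace = TRUE)
  }
  Q
}

#' Perturb genotypes with quality-driven errors
#'
#' Each genotype is miscalled with probability
#' `eps = 10^(-Q/10)`; a miscalled genotype is replaced by one of the
#' other two values in \{0, 1, 2\} (equally likely, the default) or,
#' with `mode = "allele_flip"`, by flipping one of its two alleles.
#'
#' @param G genotype matrix (values 0/1/2).
#' @param Q Phred quality matrix, same shape.
#' @param mode `"uniform_other"` (default) or `"allele_flip"`.
#' @param seed optional seed.
#' @return list with `G_obs` (a [dosage_matrix] with provenance
#'   `observed_genotype`) and `error_mask` (logical matrix of realized
#'   miscalls).
#' @export
perturb_genotypes <- function(G, Q, mode = c("uniform_other", "allele_flip"),
                              seed = NULL) {
  mode <- match.arg(mode)
  G <- as.matrix(unclass(G))
  if (!all(dim(G) == dim(Q))) stop_usage("G and Q shapes differ")
  if (!is.null(seed)) set.seed(seed)
  eps <- phred_to_error(Q)
  err <- matrix(runif(length(G)) < eps, nrow(G), ncol(G))
  Gt <- G
  idx <- which(err)
  if (length(idx)) {
    g <- G[idx]
    if (mode == "uniform_other") {
      # pick uniformly between the two other genotype values
      u <- runif(length(idx)) < 0.5
      other1 <- ifelse(g == 0, 1, ifelse(g == 1, 0, 0))
      other2 <- ifelse(g == 0, 2, ifelse(g == 1, 2, 1))
      Gt[idx] <- ifelse(u, other1, other2)
    } else {
      # flip one random allele: 0 -> 1, 2 -> 1, 1 -> 0 or 2
      u <- runif(length(idx)) < 0.5
      Gt[idx] <- ifelse(g == 1, ifelse(u, 0, 2), 1)
    }
  }
  list(G_obs = dosage_matrix(Gt, provenance = "observed_genotype"),
       error_mask = err)
}

#' Simulate minor-allele read counts
#'
#' Given true genotypes and per-cell depths, the number of reads
#' supporting the minor allele is Binomial(depth, pi_g) with per-read
#' minor-allele probability `pi_g = (g/2)(1 - eps) + (1 - g/2) eps`.
#'
#' @param G genotype matrix (0/1/2).
#' @param depths integer depth matrix, same shape.
#' @param eps per-read base error probability (scalar or matrix).
#' @return list of class `read_counts`: `depths`, `minor` (matrices).
#' @export
sim_reads <- function(G, depths, eps) {
  G <- as.matrix(unclass(G))
  if (!all(dim(G) == dim(depths))) stop_usage("G and depths shapes differ")
  if (any(eps <= 0 | eps >= 1)) stop_usage("eps must lie in (0, 1)")
  pi_g <- (G / 2) * (1 - eps) + (1 - G / 2) * eps
  minor <- matrix(rbinom(length(G), as.vector(depths), as.vector(pi_g)),
                  nrow(G), ncol(G))
  structure(list(depths = depths, minor = minor), class = "read_counts")
}

#' Genotype likelihoods from read counts
#'
#' Standard biallelic read-pileup likelihood: with `a` minor-allele
#' reads out of `d` and per-read error `eps`,
#' `L(g) = pi_g^a (1 - pi_g)^(d - a)` where
#' `pi_g = (g/2)(1 - eps) + (1 - g/2) eps`.  Zero-depth cells get the
#' flat likelihood (1, 1, 1), so their dosage falls back to the prior
#' mean downstream.
#'
#' @param reads a `read_counts` object (see [sim_reads()]).
#' @param eps per-read error probability in `(0, 1)` (scalar or matrix).
#' @return A [gl_set] of likelihoods (`is_posterior = FALSE`).
#' @export
likelihoods_from_reads <- function(reads, eps) {
  if (any(eps <= 0 | eps >= 1)) stop_usage("eps must lie in (0, 1)")
  d <- reads$depths; a <- reads$minor
  if (any(a > d | a < 0)) stop_data("minor counts exceed depths")
  n <- nrow(d); p <- ncol(d)
  if (length(eps) == 1L) eps <- matrix(eps, n, p)
  arr <- array(NA_real_, dim = c(n, p, 3))
  for (g in 0:2) {
    pi_g <- (g / 2) * (1 - eps) + (1 - g / 2) * eps
    arr[, , g + 1L] <- pi_g^a * (1 - pi_g)^(d - a)
  }
  # flat likelihood at zero depth (0^0 already yields 1, kept explicit)
  zero <- d == 0L
  if (any(zero)) for (g in 1:3) {
    slab <- arr[, , g]; slab[zero] <- 1; arr[, , g] <- slab
  }
  markers <- data.frame(id = paste0("snp", seq_len(p)),
                        allele_major = "A", allele_minor = "B")
  gl_set(arr, markers, is_posterior = FALSE)
}

#' Two-group nonlinear classification scenario
#'
#' Two groups separated by a smooth nonlinear boundary in the first two
#' coordinates — concentric annuli (group 1 at radius 1, group 2 at
#' radius 2.5, uniform angle, Gaussian radial noise) — plus `p - 2`
#' pure-noise standard-normal features.  No linear function of
#' `(x1, x2)` separates the groups, but the radius does, which is the
#' structure a nonlinear embedding should recover.
#'
#' @param n1,n2 group sizes (defaults 200 and 100).
#' @param p total number of features (`>= 2`).
#' @param radius1,radius2 group radii.
#' @param sigma radial noise standard deviation.
#' @param seed integer seed.
#' @return list with `X` (n x p matrix), `labels` (1/2), `radius`
#'   (the generating radii, before noise-free classification).
#' @export
sim_two_group_nonlinear <- function(n1 = 200L, n2 = 100L, p = 1000L,
                                    radius1 = 1, radius2 = 2.5,
                                    sigma = 0.15, seed = 1L) {
  if (n1 < 1L || n2 < 1L) stop_usage("group sizes must be >= 1")
  if (p < 2L) stop_usage("p must be >= 2")
  set.seed(seed)
  n <- n1 + n2
  labels <- rep(c(1L, 2L), c(n1, n2))
  r <- ifelse(labels == 1L, radius1, radius2) + rnorm(n, 0, sigma)
  theta <- runif(n, 0, 2 * pi)
  X <- matrix(rnorm(n * p), n, p)
  X[, 1] <- r * cos(theta)
  X[, 2] <- r * sin(theta)
  list(X = X, labels = labels, radius = r)
}

#' Full low-coverage simulation pipeline
#'
#' Runs the three genotype regimes end to end for one replicate: true
#' genotypes (admixed multi-population), observed genotypes (hard calls
#' perturbed by quality-driven errors) and dosages (posterior-mean
#' genotypes from read-level likelihoods under the HWE prior).
#'
#' @param cfg a [sim_config].
#' @param n_keep optional fixed number of post-filter sites.
#' @return list with `G` (true), `G_obs` (observed), `DS` (dosage),
#'   `gl` (likelihood [gl_set]), `pop`, `depths`, `Q`, `error_mask`.
#' @export
sim_low_coverage <- function(cfg, n_keep = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  sim <- sim_admixed_genotypes(cfg, n_keep = n_keep)
  G <- sim$G
  n <- nrow(G); p <- ncol(G)
  depths <- sim_depths(cfg, n, p)
  Q <- sim_quality(depths, cfg)
  pert <- perturb_genotypes(G, Q)
  # read-level error: per-read base error from the same quality model,
  # floored away from 0/1 for likelihood validity
  eps_read <- pmin(pmax(phred_to_error(Q), 1e-6), 1 - 1e-6)
  reads <- sim_reads(unclass(G), depths, eps_read)
  gl <- likelihoods_from_reads(reads, eps_read)
  post <- posteriors_from_likelihoods(gl, prior = "hwe")
  DS <- dosage_from_posteriors(post)
  list(G = G, G_obs = pert$G_obs, DS = DS, gl = gl, pop = sim$pop,
       depths = depths, Q = Q, error_mask = pert$error_mask)
}
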