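# Independent oracles and fixture builders shared across test files.

# Hirschfeld-Gebelein-Renyi maximal correlation of a discrete pair:
# second singular value of Q(a, b) = P(a, b) / sqrt(P(a) P(b)),
# computed from the empirical joint table.
hgr_maximal_correlation <- function(a, b) {
  tab <- table(a, b) / length(a)
  Q <- tab / sqrt(outer(rowSums(tab), colSums(tab)))
  svd(Q)$d[2]
}

# Brute-force optimal 1-D partition: enumerate all placements of m - 1
# breaks between the d sorted distinct values and minimize the total
# within-class SS over the original observations.
brute_force_jenks_ss <- function(x, m) {
  vals <- sort(unique(x))
  d <- length(vals)
  stopifnot(m <= d)
  class_ss <- function(v) sum((v - mean(v))^2)
  if (m == 1) return(class_ss(x))
  best <- Inf
  for (cut in as.data.frame(utils::combn(d - 1, m - 1))) {
    edges <- c(0, cut, d)
    ss <- 0
    for (k in seq_len(m)) {
      members <- x[x %in% vals[(edges[k] + 1):edges[k + 1]]]
      ss <- ss + class_ss(members)
    }
    best <- min(best, ss)
  }
  best
}

# total within-class SS realized by a labelling
labelling_ss <- function(x, lab) {
  sum(vapply(split(x, lab), function(v) sum((v - mean(v))^2), numeric(1)))
}

# best-permutation agreement between a clustering and true labels
label_agreement <- function(cluster, truth) {
  ks <- sort(unique(truth))
  perms <- all_permutations(seq_along(ks))
  best <- 0
  for (p in perms) {
    mapped <- ks[p][match(cluster, sort(unique(cluster)))]
    best <- max(best, mean(mapped == truth))
  }
  best
}

all_permutations <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (rest in all_permutations(v[-i]))
      out[[length(out) + 1L]] <- c(v[i], rest)
  out
}

# random discrete matrix: n samples, p features, 2-4 categories each,
# mild cross-feature dependence through a shared latent group
random_discrete_matrix <- function(n, p, seed) {
  set.seed(seed)
  grp <- sample(2L, n, replace = TRUE)
  lab <- matrix(0L, n, p)
  for (j in seq_len(p)) {
    mj <- sample(2:4, 1)
    repeat {
      pr1 <- rgamma(mj, 1); pr2 <- rgamma(mj, 1)
      col <- ifelse(grp == 1L,
                    sample(mj, n, replace = TRUE, prob = pr1),
                    sample(mj, n, replace = TRUE, prob = pr2)) - 1L
      if (length(unique(col)) >= 2L) break
    }
    lab[, j] <- match(col, sort(unique(col))) - 1L
  }
  discrete_matrix(lab)
}

# small gl_set fixture
toy_gl <- function(values, is_posterior = FALSE) {
  p <- dim(values)[2]
  gl_set(values,
         markers = data.frame(id = paste0("m", seq_len(p)),
                              allele_major = "A", allele_minor = "G"),
         is_posterior = is_posterior)
}

final_objective <- function(fit) fit$objective_trace[length(fit$objective_trace)]
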