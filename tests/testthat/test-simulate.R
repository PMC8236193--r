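test_that("parse_ms_output reads replicates, positions, haplotypes", {
  txt <- c("ms 4 2 -t 5", "1234 5678", "",
           "//", "segsites: 2", "positions: 0.25 0.75",
           "01", "11", "10", "00",
           "//", "segsites: 0")
  reps <- parse_ms_output(txt)
  expect_length(reps, 2)
  expect_equal(reps[[1]]$positions, c(0.25, 0.75))
  expect_equal(dim(reps[[1]]$haplotypes), c(4L, 2L))
  expect_equal(reps[[2]]$positions, numeric(0))
  expect_equal(ncol(reps[[2]]$haplotypes), 0L)

  # diploid pairing: "01" + "11" -> (1, 2)
  G <- genotypes_from_haplotypes(reps[[1]]$haplotypes)
  expect_equal(G[1, ], c(1L, 2L))
  expect_equal(G[2, ], c(1L, 0L))

  bad <- c("//", "segsites: 3", "positions: 0.1 0.5 0.9", "01", "111")
  expect_error(parse_ms_output(bad), "segsites", class = "mcpca_data_error")
  expect_error(parse_ms_output("no separator here"), "//")
  expect_error(genotypes_from_haplotypes(matrix(0L, 3, 2)), "odd")
})

test_that("sim_admixed_genotypes obeys the Balding-Nichols construction", {
  cfg <- sim_config(n_per_pop = 30, p_sites = 400, seed = 42)
  sim <- sim_admixed_genotypes(cfg)
  expect_equal(attr(sim$G, "provenance"), "true_genotype")
  expect_equal(nrow(sim$G), 90)
  expect_equal(length(sim$pop), 90)
  expect_true(all(unclass(sim$G) %in% 0:2))
  # MAF filter postcondition
  f <- colMeans(unclass(sim$G)) / 2
  expect_true(all(pmin(f, 1 - f) >= cfg$maf_threshold))
  # seed reproducibility
  sim2 <- sim_admixed_genotypes(cfg)
  expect_identical(unclass(sim$G)[, ], unclass(sim2$G)[, ])

  # F -> 0 limit: population frequencies collapse to the ancestral one
  cfg0 <- sim_config(n_per_pop = 10, p_sites = 3000, fst = 1e-4, seed = 3)
  s0 <- sim_admixed_genotypes(cfg0)
  expect_gt(cor(s0$freq[1, ], s0$freq[2, ]), 0.99)

  expect_error(sim_config(fst = 0), "\\(0, 1\\)")
  expect_error(sim_config(mean_depth = -1), "positive")
})

test_that("sim_depths matches the Gamma depth model moments", {
  cfg <- sim_config(mean_depth = 5, seed = 10)
  set.seed(10)
  d <- sim_depths(cfg, 200, 500)   # 1e5 draws
  expect_true(all(d >= 0))
  se_mean <- 5 / sqrt(6.3) / sqrt(length(d))
  expect_lt(abs(mean(d) - 5), 3 * se_mean + 0.15)  # + rounding slack
  # continuous-draw variance shape * scale^2 = 25 / 6.3 ~ 3.968
  expect_lt(abs(var(as.vector(d)) - 25 / 6.3), 0.5)
  set.seed(99); d1 <- sim_depths(cfg, 10, 10)
  set.seed(99); d2 <- sim_depths(cfg, 10, 10)
  expect_identical(d1, d2)
})

test_that("sim_quality is monotone in depth; table mode reproduces pools", {
  cfg <- sim_config(seed = 1)
  set.seed(2)
  dep <- matrix(rep(c(0L, 1L, 10L), each = 4000), ncol = 3)
  Q <- sim_quality(dep, cfg)
  expect_true(all(Q >= 0 & Q <= cfg$qual_max))
  expect_lt(mean(Q[, 1]), mean(Q[, 2]) + 1e-9)
  expect_gt(mean(Q[, 3]), mean(Q[, 2]))
  # depth 0 sits at the low clamp on average
  expect_lt(mean(Q[, 1]), 1.5)

  tabQ <- list(`1` = 5, `10` = 30)
  Qt <- sim_quality(matrix(c(1L, 10L), 1), cfg, model = "table", table = tabQ)
  expect_equal(as.vector(Qt), c(5, 30))
  expect_warning(sim_quality(matrix(3L, 1, 1), cfg, model = "table",
                             table = tabQ), "nearest")
  expect_error(sim_quality(dep, cfg, model = "table"), "nonempty")
})

test_that("perturb_genotypes realizes the Bernoulli error model", {
  set.seed(5)
  G <- matrix(sample(0:2, 1e5, replace = TRUE), 100)
  # Q = 60: essentially no errors
  out60 <- perturb_genotypes(G, matrix(60, 100, 1000), seed = 1)
  expect_lte(mean(out60$error_mask), 1e-4)
  # Q = 0: eps = 1, every genotype changed
  out0 <- perturb_genotypes(G, matrix(0, 100, 1000), seed = 1)
  expect_equal(mean(out0$error_mask), 1)
  expect_true(all(unclass(out0$G_obs) != G))
  # realized error rate tracks mean(eps) within 3 s.e.
  Q <- matrix(7, 100, 1000)
  eps <- phred_to_error(7)
  outQ <- perturb_genotypes(G, Q, seed = 2)
  se <- sqrt(eps * (1 - eps) / length(G))
  expect_lt(abs(mean(outQ$error_mask) - eps), 3 * se)
  # perturbed values stay genotypes, and errors always change the value
  expect_true(all(unclass(outQ$G_obs) %in% 0:2))
  expect_true(all((unclass(outQ$G_obs) != G) == outQ$error_mask))
  # allele-flip mode: heterozygotes leave 1, homozygotes become 1
  outF <- perturb_genotypes(G, matrix(0, 100, 1000), mode = "allele_flip",
                            seed = 3)
  expect_true(all(unclass(outF$G_obs)[G != 1] == 1))
  expect_true(all(unclass(outF$G_obs)[G == 1] %in% c(0L, 2L)))
})

test_that("likelihoods_from_reads implements the pileup likelihood", {
  # d = 1 minor read, eps -> 0: posteriors (0, 1/3, 2/3), DS = 5/3
  reads <- structure(list(depths = matrix(1L, 1, 1),
                          minor = matrix(1L, 1, 1)), class = "read_counts")
  gl <- likelihoods_from_reads(reads, eps = 1e-12)
  post <- posteriors_from_likelihoods(gl, prior = "uniform")
  expect_equal(post$values[1, 1, ], c(0, 1 / 3, 2 / 3), tolerance = 1e-9)
  ds <- dosage_from_posteriors(post)
  expect_equal(unclass(ds)[1, 1], 5 / 3, ignore_attr = TRUE,
               tolerance = 1e-9)

  # zero depth: flat likelihood, dosage = prior mean
  reads0 <- structure(list(depths = matrix(0L, 1, 1),
                           minor = matrix(0L, 1, 1)), class = "read_counts")
  gl0 <- likelihoods_from_reads(reads0, eps = 0.01)
  expect_equal(gl0$values[1, 1, ], c(1, 1, 1))
  ds0 <- dosage_from_posteriors(
    posteriors_from_likelihoods(gl0, prior = "hwe", af = 0.3))
  expect_equal(unclass(ds0)[1, 1], 0.6, ignore_attr = TRUE)  # 2 * 0.3

  # eps = 0.5 is uninformative
  readsN <- structure(list(depths = matrix(6L, 1, 1),
                           minor = matrix(2L, 1, 1)), class = "read_counts")
  glN <- likelihoods_from_reads(readsN, eps = 0.5 - 1e-15)
  expect_equal(glN$values[1, 1, 1], glN$values[1, 1, 3], tolerance = 1e-9)
  expect_error(likelihoods_from_reads(readsN, eps = 0), "\\(0, 1\\)")
})

test_that("dosage converges to the truth with deep accurate reads", {
  set.seed(12)
  G <- matrix(sample(0:2, 50 * 40, replace = TRUE,
                     prob = c(0.45, 0.35, 0.2)), 50)
  reads <- sim_reads(G, matrix(100L, 50, 40), eps = 1e-4)
  ds <- dosage_from_posteriors(
    posteriors_from_likelihoods(likelihoods_from_reads(reads, 1e-4)))
  expect_lt(max(abs(unclass(ds) - G)), 0.01)
})

test_that("sim_two_group_nonlinear builds a radius-separable annulus", {
  sim <- sim_two_group_nonlinear(n1 = 200, n2 = 100, p = 50, seed = 4)
  expect_equal(dim(sim$X), c(300L, 50L))
  expect_equal(as.integer(table(sim$labels)), c(200L, 100L))
  # radius threshold classifies nearly perfectly
  r <- sqrt(sim$X[, 1]^2 + sim$X[, 2]^2)
  acc <- mean((r > 1.75) + 1 == sim$labels)
  expect_gte(acc, 0.99)
  # no linear separation in (x1, x2): group means nearly coincide
  expect_lt(abs(mean(sim$X[sim$labels == 1, 1]) -
                mean(sim$X[sim$labels == 2, 1])), 0.3)
  # noise features uncorrelated with labels
  cors <- abs(cor(sim$X[, 3:50], sim$labels))
  expect_lt(mean(cors), 3 / sqrt(300))
  expect_identical(sim_two_group_nonlinear(seed = 4, p = 10)$X,
                   sim_two_group_nonlinear(seed = 4, p = 10)$X)
})
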