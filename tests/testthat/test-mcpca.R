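test_that("standardize_transform enforces weighted mean 0 / variance 1", {
  # phi = (0,1,2) with frequencies (1/4, 1/2, 1/4): mean 1, var 1/2
  out <- standardize_transform(c(0, 1, 2), c(25, 50, 25))
  expect_equal(out, c(-sqrt(2), 0, sqrt(2)))
  # idempotence
  expect_equal(standardize_transform(out, c(25, 50, 25)), out)
  # weighted moments with divisor n
  set.seed(9)
  phi <- rnorm(5); cnt <- c(3, 7, 2, 5, 3)
  s <- standardize_transform(phi, cnt)
  w <- cnt / sum(cnt)
  expect_equal(sum(w * s), 0, tolerance = 1e-12)
  expect_equal(sum(w * s^2), 1, tolerance = 1e-12)

  expect_error(standardize_transform(c(5, 5), c(10, 10)),
               class = "mcpca_degenerate")
  expect_error(standardize_transform(c(1, 2), c(10, 0)), "at least 2")
})

test_that("transformed_covariance matches its definition", {
  # two identical features -> off-diagonal exactly 1
  lab <- cbind(c(0L, 1L, 1L, 0L), c(0L, 1L, 1L, 0L))
  tr <- list(standardize_transform(c(0, 1), c(2, 2)),
             standardize_transform(c(0, 1), c(2, 2)))
  K <- transformed_covariance(discrete_matrix(lab), tr)
  expect_equal(K, matrix(1, 2, 2))

  # p = 1
  K1 <- transformed_covariance(discrete_matrix(lab[, 1, drop = FALSE]),
                               tr[1])
  expect_equal(K1, matrix(1, 1, 1))

  # independent features: off-diagonal small (LLN bound 3/sqrt(n))
  set.seed(21)
  n <- 4000
  lab2 <- cbind(sample(0:2, n, TRUE), sample(0:1, n, TRUE))
  D2 <- discrete_matrix(lab2)
  tr2 <- list(standardize_transform(0:2, tabulate(lab2[, 1] + 1, 3)),
              standardize_transform(0:1, tabulate(lab2[, 2] + 1, 2)))
  expect_lt(abs(transformed_covariance(D2, tr2)[1, 2]), 3 / sqrt(n))

  expect_error(transformed_covariance(D2, list(c(0, 1, 2), c(0, 1))),
               "not standardized")
})

test_that("kyfan sums the top-q eigenvalues", {
  expect_equal(kyfan(diag(3), 2), 2)
  K <- crossprod(matrix(rnorm(30), 10, 3)) / 10
  expect_equal(kyfan(K, 3), sum(diag(K)))
  v <- c(1, -1, 1, 1) / sqrt(4) * 2   # ||v||^2 = p = 4
  expect_equal(kyfan(tcrossprod(v), 1), 4)
  expect_error(kyfan(diag(3), 4), class = "mcpca_usage_error")
  expect_error(kyfan(diag(3), 0), class = "mcpca_usage_error")
})

test_that("fit_mcpca validates inputs", {
  D <- random_discrete_matrix(20, 3, seed = 2)
  expect_error(fit_mcpca(D, q = 4), "q must lie")
  expect_error(fit_mcpca(D[1, , drop = FALSE], q = 1), "at least 2")
  Ddeg <- discrete_matrix(cbind(c(0L, 1L, 0L), c(0L, 0L, 0L)))
  expect_error(fit_mcpca(Ddeg, q = 1), "degenerate")
})

test_that("q = p conserves the trace: objective p, unit diagonal", {
  for (s in 1:3) {
    D <- random_discrete_matrix(40, 4, seed = s)
    fit <- fit_mcpca(D, q = 4)
    expect_equal(final_objective(fit), 4, tolerance = 1e-6)
    expect_equal(diag(fit$K), rep(1, 4), tolerance = 1e-8)
    expect_equal(sum(diag(fit$K)), 4, tolerance = 1e-6)
  }
})

test_that("p = 2, q = 1 objective equals 1 + HGR maximal correlation", {
  set.seed(33)
  for (rep in 1:5) {
    P <- matrix(rgamma(9, 1), 3); P <- P / sum(P)
    idx <- sample(9, 300, TRUE, prob = as.vector(P))
    a <- (idx - 1) %% 3; b <- (idx - 1) %/% 3
    if (length(unique(a)) < 2 || length(unique(b)) < 2) next
    D <- discrete_matrix(cbind(match(a, sort(unique(a))) - 1L,
                               match(b, sort(unique(b))) - 1L))
    fit <- fit_mcpca(D, q = 1, tol = 1e-12, max_sweeps = 5000)
    expect_equal(final_objective(fit), 1 + hgr_maximal_correlation(a, b),
                 tolerance = 1e-7)
  }
})

test_that("a feature duplicated p times reaches the rank-1 optimum", {
  set.seed(5)
  col <- sample(0:2, 60, replace = TRUE)
  D <- discrete_matrix(matrix(col, 60, 5))
  fit <- fit_mcpca(D, q = 1)
  expect_equal(final_objective(fit), 5, tolerance = 1e-8)
  expect_equal(fit$K, matrix(1, 5, 5), tolerance = 1e-8)
})

test_that("objective is monotone, dominates PCA, and respects invariances", {
  set.seed(77)
  for (s in 1:6) {
    D <- random_discrete_matrix(sample(30:80, 1), sample(3:8, 1), seed = s)
    q <- sample(seq_len(min(3, ncol(D))), 1)
    fit <- fit_mcpca(D, q = q)
    # monotone trajectory
    expect_true(all(diff(fit$objective_trace) >= -1e-10))
    # Ky Fan dominance over correlation-matrix PCA on the raw labels
    expect_gte(final_objective(fit) + 1e-10,
               kyfan(stats::cor(unclass(D)), q))
    # explained fraction in (0, 1]
    expect_gt(fit$explained_fraction, 0)
    expect_lte(fit$explained_fraction, 1 + 1e-12)

    # invariance: permuting category labels (with the transform) and
    # flipping transform signs leave the objective unchanged
    lab <- unclass(D)
    perm <- sample(max(lab[, 1]) + 1) - 1L
    lab2 <- lab; lab2[, 1] <- perm[lab[, 1] + 1L]
    lab2[, 1] <- match(lab2[, 1], sort(unique(lab2[, 1]))) - 1L
    fit2 <- fit_mcpca(discrete_matrix(lab2), q = q)
    expect_equal(final_objective(fit2), final_objective(fit),
                 tolerance = 1e-6)
  }
})

test_that("identity init is deterministic; scores have q columns", {
  D <- random_discrete_matrix(50, 6, seed = 13)
  f1 <- fit_mcpca(D, q = 2, seed = 1)
  f2 <- fit_mcpca(D, q = 2, seed = 99)   # identity init ignores the seed
  expect_identical(f1$objective_trace, f2$objective_trace)
  expect_identical(f1$scores, f2$scores)
  expect_equal(dim(f1$scores), c(50L, 2L))
  # random init with the same seed reproduces
  r1 <- fit_mcpca(D, q = 2, init = "random", seed = 7)
  r2 <- fit_mcpca(D, q = 2, init = "random", seed = 7)
  expect_identical(r1$objective_trace, r2$objective_trace)
})

test_that("explained_fraction is objective/p and monotone in q", {
  D <- random_discrete_matrix(60, 5, seed = 19)
  fr <- vapply(1:5, function(q) fit_mcpca(D, q = q)$explained_fraction,
               numeric(1))
  expect_true(all(diff(fr) > -1e-10))
  expect_equal(fr[5], 1, tolerance = 1e-6)
  fit <- fit_mcpca(D, q = 2)
  expect_equal(explained_fraction(fit), final_objective(fit) / 5)
})
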