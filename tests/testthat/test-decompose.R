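test_that("flattening follows the documented row-major parameter order", {
  sig <- deamination_signature()
  v <- flatten(sig)
  expect_identical(length(v), 24L)
  expect_equal(v[1:3], c(0.004, 0.006, 0.928))
  expect_equal(v[7:10], unname(sig$matrix["-2", 1:4]))
  expect_equal(v[23:24], unname(sig$matrix["strand", 1:2]))

  a <- random_signature_set(1, alex_spec, seed = 1)[[1]]
  expect_identical(flatten(a), unname(a$probs))
})

test_that("mixed context specs cannot be stacked", {
  s1 <- random_signature_set(1, triplet_spec, seed = 1)
  s2 <- random_signature_set(1, quintet_strand_spec, seed = 1)
  expect_error(signature_matrix(c(s1, s2)), "mixed")
})

test_that("nearest_positive_definite perturbs minimally and only when needed", {
  I <- diag(3)
  expect_identical(nearest_positive_definite(I), I)

  # eigenvalue clipping: diag(1, 0) needs only a floor on the zero eigenvalue
  M <- diag(c(1, 0))
  M2 <- nearest_positive_definite(M)
  ev <- eigen(M2, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > 0))
  expect_lt(max(abs(M2 - M)), 1e-6)

  # a rank-deficient Gram matrix (duplicated signature) becomes PD
  S <- matrix(runif(12), 6, 2)
  S <- cbind(S, S[, 1])
  G <- crossprod(S)
  G2 <- nearest_positive_definite(G)
  expect_true(all(eigen(G2, symmetric = TRUE)$values > 0))

  expect_error(nearest_positive_definite(matrix(1:6, 2, 3)), "square")
  expect_error(nearest_positive_definite(matrix(c(1, 2, 3, 4), 2, 2)),
               "symmetric")
})

test_that("the Gram matrix of a full-rank signature set is left untouched", {
  sigs <- random_signature_set(15, quintet_strand_spec, seed = 17,
                               min_separation = 0.4)
  G <- crossprod(signature_matrix(sigs))
  G2 <- nearest_positive_definite(G)
  expect_lt(max(abs(G2 - G) / abs(G)), 3e-15)
})

test_that("solve_exposures handles the elementary cases exactly", {
  # K = 1: the constraint forces w = 1
  expect_identical(unname(solve_exposures(runif(5), matrix(runif(5)))$weights), 1)

  # orthonormal columns spanning g: exact interpolation, zero residual
  S <- cbind(c(1, 0), c(0, 1))
  fit <- solve_exposures(c(0.3, 0.7), S)
  expect_equal(unname(fit$weights), c(0.3, 0.7), tolerance = 1e-10)
  expect_equal(fit$rss, 0, tolerance = 1e-15)

  # boundary solution: best fit pins all weight on one signature
  S <- cbind(c(0.8, 0.2), c(0.2, 0.8))
  fit <- solve_exposures(c(0.9, 0.1), S)
  expect_equal(unname(fit$weights), c(1, 0), tolerance = 1e-8)
  expect_equal(fit$rss, 0.02, tolerance = 1e-10)
  # agrees with the brute-force grid oracle
  expect_equal(unname(fit$weights), grid_simplex_fit(c(0.9, 0.1), S, 1e-4),
               tolerance = 2e-4)
})

test_that("the QP solution matches an established solver on random problems", {
  set.seed(90)
  for (i in 1:40) {
    K <- sample(2:8, 1)
    P <- sample(c(5, 10, 14, 24), 1)
    S <- matrix(stats::rgamma(P * K, 0.5), P, K)
    S <- sweep(S, 2, colSums(S), "/")
    g <- stats::rgamma(P, 0.5); g <- g / sum(g)
    expect_equal(unname(solve_exposures(g, S)$weights),
                 pracma_simplex_fit(g, S), tolerance = 1e-6)
  }
})

test_that("exact mixtures are recovered to machine precision", {
  set.seed(12)
  for (i in 1:10) {
    sigs <- random_signature_set(8, quintet_strand_spec,
                                 min_separation = 0.3)
    S <- signature_matrix(sigs)
    w_true <- stats::rgamma(8, 1); w_true <- w_true / sum(w_true)
    fit <- solve_exposures(as.numeric(S %*% w_true), S)
    expect_lt(max(abs(fit$weights - w_true)), 1e-6)
  }
})

test_that("exposures are invariant to signature order", {
  set.seed(7)
  sigs <- random_signature_set(6, triplet_spec, min_separation = 0.2)
  g <- simulate_genome(sigs, make_exposures(6, 2, 0.7), 500, seed = 3)
  w <- solve_exposures(g, signature_matrix(sigs))$weights
  perm <- c(4, 1, 6, 2, 5, 3)
  wp <- solve_exposures(g, signature_matrix(sigs[perm]))$weights
  expect_equal(unname(wp), unname(w[perm]), tolerance = 1e-8)
})

test_that("explained variance uses the model-appropriate baseline", {
  sigs <- random_signature_set(3, triplet_spec, seed = 41,
                               min_separation = 0.3)
  S <- signature_matrix(sigs)
  g <- as.numeric(S %*% c(0.5, 0.3, 0.2))
  spec <- triplet_spec
  # perfect reconstruction
  expect_equal(explained_variance(g, g, spec), 1)
  # predicting the flat baseline explains nothing
  gflat <- flatten(flat_genome(spec))
  expect_equal(explained_variance(g, gflat, spec), 0)
  # direct formula evaluation oracle
  ghat <- as.numeric(S %*% c(0.6, 0.2, 0.2))
  expect_equal(explained_variance(g, ghat, spec),
               1 - sum((g - ghat)^2) / sum((g - gflat)^2))
  # alexandrov baseline is the mean frequency
  ga <- flatten(random_signature_set(1, alex_spec, seed = 5)[[1]])
  gh <- rep(1 / 96, 96)
  expect_equal(explained_variance(ga, gh, alex_spec),
               1 - sum((ga - gh)^2) / sum((ga - mean(ga))^2))
  # degenerate input: the flat genome itself has no variance to explain
  expect_error(explained_variance(gflat, gflat, spec), "degenerate")
})

test_that("subset search returns the generating subset on clean mixtures", {
  sigs <- random_signature_set(4, quintet_strand_spec, seed = 23,
                               min_separation = 0.5)
  g <- simulate_genome(sigs, make_exposures(4, c(2, 4), c(0.6, 0.4)),
                       n_mutations = 50000, seed = 6)
  fit <- decompose_tumor(g, sigs, min_explained_variance = 0.95)
  expect_setequal(fit$subset, c("sig2", "sig4"))
  expect_true(fit$threshold_reached)
  expect_equal(unname(fit$exposures[c("sig2", "sig4")]), c(0.6, 0.4),
               tolerance = 0.02)
  expect_equal(sum(fit$exposures), 1, tolerance = 1e-8)
})

test_that("threshold-free decomposition equals the full-set fit", {
  sigs <- random_signature_set(5, triplet_spec, seed = 3,
                               min_separation = 0.2)
  g <- simulate_genome(sigs, rep(0.2, 5), 2000, seed = 8)
  fit <- decompose_tumor(g, sigs)
  direct <- solve_exposures(g, signature_matrix(sigs))
  expect_equal(fit$exposures, direct$weights)
  expect_equal(fit$rss, direct$rss)
  # a zero threshold is met at the smallest allowed subset size whenever the
  # fit beats the flat baseline, so a driver-dominated genome stops at k = 2
  gd <- simulate_genome(sigs, make_exposures(5, 1, 0.8), 2000, seed = 8)
  fit0 <- decompose_tumor(gd, sigs, min_explained_variance = 0,
                          min_num_signatures = 2)
  expect_identical(length(fit0$subset), 2L)
  expect_true(fit0$threshold_reached)
})

test_that("an unreachable threshold returns the best fit, flagged", {
  sigs <- random_signature_set(3, triplet_spec, seed = 19,
                               min_separation = 0.3)
  # a genome unrelated to the signatures cannot reach R^2 = 0.999
  g <- simulate_genome(random_signature_set(1, triplet_spec, seed = 99),
                       1, 200, seed = 1)
  fit <- decompose_tumor(g, sigs, min_explained_variance = 0.9999)
  expect_false(fit$threshold_reached)
  expect_identical(length(fit$subset), 3L)  # falls back to the best (full) set
})

test_that("the explained-variance curve is monotone and ends at the full fit", {
  sigs <- random_signature_set(4, triplet_spec, seed = 13,
                               min_separation = 0.2)
  g <- simulate_genome(sigs, make_exposures(4, 1, 0.5), 2000, seed = 4)
  curve <- explained_variance_curve(g, sigs)
  expect_identical(curve$k, 1:4)
  expect_true(all(diff(curve$explained_variance) >= -1e-10))
  full <- decompose_tumor(g, sigs)
  expect_equal(curve$explained_variance[4], full$explained_variance)

  # duplicating a signature creates a plateau: k = 2 already achieves k = 3
  dup <- c(sigs[1:2], list(sigs[[2]]))
  dup[[3]]$name <- "sig2dup"
  g2 <- simulate_genome(dup, c(0.5, 0.3, 0.2), 5000, seed = 5)
  c2 <- explained_variance_curve(g2, dup)
  expect_equal(c2$explained_variance[2], c2$explained_variance[3],
               tolerance = 1e-10)
})

test_that("greedy forward selection approximates the exhaustive search", {
  sigs <- random_signature_set(6, triplet_spec, seed = 29,
                               min_separation = 0.25)
  g <- simulate_genome(sigs, make_exposures(6, c(1, 5), c(0.6, 0.3)),
                       20000, seed = 2)
  ex <- decompose_tumor(g, sigs, min_explained_variance = 0.9)
  gr <- decompose_tumor(g, sigs, min_explained_variance = 0.9, greedy = TRUE)
  expect_true(gr$threshold_reached)
  expect_gte(gr$explained_variance, 0.9)
  expect_lte(length(gr$subset), length(ex$subset) + 1L)
})

test_that("fitted-model methods are mutually consistent", {
  sigs <- random_signature_set(4, quintet_strand_spec, seed = 37,
                               min_separation = 0.4)
  g <- simulate_genome(sigs, make_exposures(4, 1, 0.8), 1000, seed = 11)
  fit <- decompose_tumor(g, sigs)
  expect_s3_class(fit, "tumor_decomposition")
  expect_equal(sum(coef(fit)), 1, tolerance = 1e-8)
  expect_equal(fitted(fit) + residuals(fit), flatten(g))
  expect_equal(sum(residuals(fit)^2), fit$rss)
  pred <- predict(fit)
  expect_s3_class(pred, "genome_profile")
  expect_equal(flatten(pred), fitted(fit), tolerance = 1e-9)
  sims <- simulate(fit, nsim = 2, seed = 21, n_mutations = 500)
  expect_identical(length(sims), 2L)
  expect_identical(sims[[1]]$n_mutations, 500L)
  expect_output(print(fit), "explained variance")
  expect_output(print(summary(fit)), "non-zero exposure")
})
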