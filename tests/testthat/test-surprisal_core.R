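# SVD decomposition, orientation conventions, reconstruction, balance state.

random_log_matrix <- function(n, ns, seed = 1) {
  set.seed(seed)
  matrix(stats::rnorm(n * ns, mean = 2), n, ns,
         dimnames = list(sprintf("g%04d", seq_len(n)), sprintf("s%02d", seq_len(ns))))
}

test_that("a rank-1 matrix is decomposed analytically", {
  set.seed(11)
  g <- stats::rnorm(30); g <- g / sqrt(sum(g^2))
  l <- stats::rnorm(5) * 10
  Y <- g %o% l
  dimnames(Y) <- list(sprintf("g%02d", 1:30), sprintf("s%d", 1:5))
  d <- surprisal_decompose(Y)
  expect_equal(d$omega[1], sqrt(sum(l^2)), tolerance = 1e-12)
  expect_lt(max(d$omega[-1]), 1e-10)
  expect_equal(abs(sum(d$G[, 1] * g)), 1, tolerance = 1e-12)
  # n_terms = 1 recovers a rank-1 input exactly
  expect_lt(max(abs(reconstruct(d, 1) - Y)), 1e-10)
})

test_that("full reconstruction is exact and G columns are orthonormal", {
  for (dims in list(c(6, 4), c(50, 10), c(400, 25))) {
    Y <- random_log_matrix(dims[1], dims[2], seed = dims[1])
    d <- surprisal_decompose(Y)
    expect_lt(max(abs(reconstruct(d) - Y)), 1e-8)
    gram <- crossprod(d$G)
    expect_lt(max(abs(gram - diag(dims[2]))), 1e-10)
    expect_true(all(diff(d$omega) <= 1e-12))   # non-increasing
  }
})

test_that("lambda rows agree with a brute-force eigendecomposition of Y'Y", {
  for (seed in c(2, 9)) {
    Y <- random_log_matrix(50, 10, seed = seed)
    d <- surprisal_decompose(Y)
    eig <- eigen(crossprod(Y), symmetric = TRUE)   # independent oracle
    for (a in 1:10) {
      oracle <- sqrt(eig$values[a]) * eig$vectors[, a]
      got <- d$lambda[a, ]
      if (sum(oracle * got) < 0) oracle <- -oracle
      expect_lt(max(abs(got - oracle)), 1e-8)
    }
  }
})

test_that("permuting sample columns permutes lambda columns and fixes G up to sign", {
  Y <- random_log_matrix(40, 6, seed = 5)
  perm <- c(3, 1, 6, 2, 5, 4)
  d1 <- surprisal_decompose(Y)
  d2 <- surprisal_decompose(Y[, perm])
  for (a in 1:6) {
    s <- sign(sum(d1$G[, a] * d2$G[, a]))
    expect_equal(d2$G[, a], s * d1$G[, a], tolerance = 1e-8)
    expect_equal(unname(d2$lambda[a, ]), unname(s * d1$lambda[a, perm]),
                 tolerance = 1e-8)
  }
})

test_that("group orientation flips jointly, is idempotent, and rejects bad rules", {
  Y <- random_log_matrix(30, 5, seed = 4)
  d <- surprisal_decompose(Y)
  recon_before <- reconstruct(d)
  grp <- colnames(Y)[1:3]
  rule <- orientation_rule(1, grp, +1)
  d1 <- orient_by_groups(d, list(rule))
  expect_gt(mean(d1$lambda[2, grp]), 0)
  # reconstruction is unchanged by any joint flip
  expect_lt(max(abs(reconstruct(d1) - recon_before)), 1e-12)
  # idempotent
  d2 <- orient_by_groups(d1, list(rule))
  expect_equal(d2$G, d1$G)
  expect_equal(d2$lambda, d1$lambda)
  expect_error(orient_by_groups(d, list(rule, orientation_rule(1, grp, -1))),
               "conflicting")
  expect_error(orientation_rule(1, character(0), +1), "empty")
  expect_error(orient_by_groups(d, list(orientation_rule(1, "ghost", +1))),
               "ghost")
})

test_that("anchor-gene orientation flips jointly and is an involution", {
  Y <- random_log_matrix(30, 5, seed = 8)
  d <- surprisal_decompose(Y)
  gene <- d$gene_ids[which.max(abs(d$G[, 2]))]
  w <- d$G[gene, 2]
  d_pos <- orient_by_anchor_gene(d, 1, gene, +1)
  expect_gt(d_pos$G[gene, 2], 0)
  if (w < 0) {
    expect_equal(d_pos$lambda[2, ], -d$lambda[2, ])
  } else {
    expect_equal(d_pos$lambda[2, ], d$lambda[2, ])
  }
  # applying opposite signs in sequence returns the original
  back <- orient_by_anchor_gene(orient_by_anchor_gene(d, 1, gene, +1),
                                1, gene, sign(w))
  expect_equal(back$G, d$G)
  expect_equal(back$lambda, d$lambda)
  d0 <- d; d0$G[gene, 2] <- 0
  expect_error(orient_by_anchor_gene(d0, 1, gene, +1), "zero")
})

test_that("truncated reconstruction error is non-increasing in n_terms", {
  Y <- random_log_matrix(60, 8, seed = 13)
  d <- surprisal_decompose(Y)
  res <- vapply(1:8, function(k) sqrt(sum((Y - reconstruct(d, k))^2)), numeric(1))
  expect_true(all(diff(res) <= 1e-9))
  # Eckart-Young oracle: the residual equals the tail singular-value norm
  expect_equal(res[1:7], vapply(1:7, function(k) sqrt(sum(d$omega[(k + 1):8]^2)),
                                numeric(1)), tolerance = 1e-8)
  expect_error(reconstruct(d, 0), "n_terms")
  expect_error(reconstruct(d, 9), "n_terms")
})

test_that("balance state of a positive matrix is sign-constant with free energy = -stability", {
  Y <- abs(random_log_matrix(80, 6, seed = 21)) + 0.5   # strictly positive
  d <- surprisal_decompose(Y)
  d <- orient_by_groups(d, list(orientation_rule(0, colnames(Y), +1)))
  b <- balance_state(d)
  # leading singular vector of a positive matrix has one sign
  expect_true(all(b$genes$G0 >= 0))
  expect_true(all(b$genes$stability >= 0))
  expect_equal(b$genes$free_energy, -b$genes$stability)
  expect_equal(b$lambda0_bar, mean(d$lambda[1, ]))
})

test_that("planted structure is recovered from noisy synthetic data", {
  for (seed in c(1, 5, 9)) {
    ds <- generate_dataset(mini_config(seed = seed, noise_sd = 0.1))
    d <- surprisal_decompose(synthetic_log_matrix(ds))
    rec <- recovery_report(ds$truth, d)
    expect_true(all(rec$g_correlation[2:3] >= 0.95))
    expect_true(all(rec$sign_concordance == 1))
  }
})

test_that("degenerate and invalid inputs are rejected", {
  expect_error(surprisal_decompose(matrix(1, 5, 1)), "2 samples")
  Y <- random_log_matrix(6, 4)
  Y[2, 2] <- NA
  expect_error(surprisal_decompose(Y), "finite")
  # exact ties in omega must not crash
  expect_silent(surprisal_decompose(diag(4) * 2))
})
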