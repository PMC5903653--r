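# The generator: determinism, planted structure, recovery, noise monotonicity.

test_that("generation is deterministic under a seed and strictly positive", {
  a <- generate_dataset(mini_config(seed = 5))
  b <- generate_dataset(mini_config(seed = 5))
  expect_equal(SummarizedExperiment::assay(a$data, "fpkm"),
               SummarizedExperiment::assay(b$data, "fpkm"))
  expect_identical(a$gene_sets, b$gene_sets)
  c <- generate_dataset(mini_config(seed = 6))
  expect_false(identical(SummarizedExperiment::assay(a$data, "fpkm"),
                         SummarizedExperiment::assay(c$data, "fpkm")))
  expect_true(all(SummarizedExperiment::assay(a$data, "fpkm") > 0))
  # planted factors are orthonormal / orthogonal
  expect_lt(max(abs(crossprod(a$truth$G) - diag(3))), 1e-10)
  lam <- a$truth$lambda
  expect_lt(abs(sum(lam[1, ] * lam[2, ])) / sqrt(sum(lam[1, ]^2) * sum(lam[2, ]^2)),
            1e-10)
})

test_that("without noise the matrix is exactly rank 3 and fully recoverable", {
  ds <- generate_dataset(mini_config(seed = 2, noise_sd = 0))
  Y <- synthetic_log_matrix(ds)
  d <- surprisal_decompose(Y)
  expect_lt(d$omega[4] / d$omega[1], 1e-10)
  rec <- recovery_report(ds$truth, d)
  expect_equal(unname(rec$g_correlation), rep(1, 3), tolerance = 1e-8)
  expect_equal(unname(rec$lambda_correlation), rep(1, 3), tolerance = 1e-8)
  expect_equal(unname(rec$sign_concordance), c(1, 1))
  # planted multiplier rows are recovered exactly up to sign
  for (j in 1:3) {
    s <- sign(sum(d$lambda[j, ] * ds$truth$lambda[j, ]))
    expect_equal(s * d$lambda[j, ], ds$truth$lambda[j, ], tolerance = 1e-6)
  }
})

test_that("planted multiplier signs and ranges match the configuration", {
  cfg <- mini_config(seed = 31)
  ds <- generate_dataset(cfg)
  md <- ds$truth$metadata
  lam <- ds$truth$lambda
  expect_true(all(lam[1, ] > 0))
  expect_true(all(sign(lam[2, ]) == ifelse(md$medium == "liquid", 1, -1)))
  expect_true(all(sign(lam[3, ]) == ifelse(md$light == "light", 1, -1)))
  expect_equal(max(lam[1, ]) - min(lam[1, ]), cfg$lambda0_range)
  expect_equal(max(lam[2, ]) - min(lam[2, ]), cfg$lambda1_range)
  expect_equal(max(lam[3, ]) - min(lam[3, ]), cfg$lambda2_range)
})

test_that("configured discordant samples carry small opposite-sign multipliers", {
  ds <- generate_dataset(mini_config(seed = 3, discordant_medium = "AD2",
                                     discordant_light = "AL1"))
  lam <- ds$truth$lambda
  expect_gt(lam["lambda_1", "AD2"], 0)
  expect_lt(lam["lambda_1", "AD2"], 0.05 * lambda_range(lam["lambda_1", ]))
  expect_lt(lam["lambda_2", "AL1"], 0)
  expect_error(generate_dataset(mini_config(discordant_medium = "XX9")),
               "XX9")
})

test_that("recovery correlation does not improve as noise grows", {
  mean_cor <- vapply(c(0.05, 0.5, 2), function(ns) {
    mean(vapply(1:3, function(seed) {
      ds <- generate_dataset(mini_config(seed = seed, noise_sd = ns))
      d <- surprisal_decompose(synthetic_log_matrix(ds))
      mean(recovery_report(ds$truth, d)$g_correlation[2:3])
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_cor) <= 1e-6))
})

test_that("truth compared with a noise-free decomposition recovers everything", {
  ds <- generate_dataset(mini_config(seed = 8, noise_sd = 0))
  d <- orient_study(surprisal_decompose(to_log(ds$data)))
  sets <- suppressMessages(pathway_sets(ds$gene_sets, d$gene_ids, min_size = 5))
  rec <- recovery_report(ds$truth, d, sets = sets, top_k = 8)
  expect_equal(unname(rec$g_correlation), rep(1, 3), tolerance = 1e-8)
  expect_equal(unname(rec$pathway_recovery), rep(1, 4))
  # axis mismatch is an error
  d_bad <- d; d_bad$gene_ids <- rev(d$gene_ids)
  expect_error(recovery_report(ds$truth, d_bad), "universe")
})

test_that("infeasible configurations are rejected up front", {
  expect_error(synthetic_config(n_genes = 100, n_markers_per_phenotype = 30),
               "marker")
  expect_error(synthetic_config(n_pathways = 4, n_enriched_per_phenotype = 2),
               "enriched")
  expect_error(synthetic_config(noise_sd = -1), "noise_sd")
})

test_that("the filter-pass guarantee lifts low baselines above the threshold", {
  cfg <- mini_config(seed = 12, ensure_filter_pass = TRUE,
                     filter_threshold = 50)
  ds <- generate_dataset(cfg)
  fpkm <- SummarizedExperiment::assay(ds$data, "fpkm")
  md <- ds$truth$metadata
  agar <- md$sample_id[md$medium == "agar"]
  expect_true(all(rowMeans(fpkm[, agar]) >= 50))
  expect_gt(ds$truth$n_baseline_lifted, 0)
  filtered <- suppressMessages(filter_low_expression(ds$data, agar, 50))
  expect_equal(nrow(filtered), nrow(fpkm))
})

test_that("written datasets round-trip through the loaders", {
  dir <- withr::local_tempdir()
  # at 60 genes the mean balance weight is larger, so the balance level must
  # rise with it to keep the balance component dominant
  ds <- generate_dataset(mini_config(seed = 14, n_genes = 60,
                                     n_markers_per_phenotype = 10,
                                     pathway_size = 8, balance_level = 12))
  paths <- write_synthetic_dataset(ds, dir)
  se <- load_expression(paths["matrix"], paths["metadata"])
  expect_equal(SummarizedExperiment::assay(se, "fpkm"),
               SummarizedExperiment::assay(ds$data, "fpkm"),
               tolerance = 1e-12)
  sets <- suppressMessages(load_gene_sets(paths["gene_sets"], rownames(se),
                                          min_size = 2))
  expect_setequal(unique(ds$gene_sets$pathway_id), names(sets))
})
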