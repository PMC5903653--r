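# Set-ratio enrichment: P/N arithmetic, ranking rules, conservation.

# A decomposition-like object with a prescribed weight column for alpha = 1.
fake_decomposition <- function(weights, gene_ids = names(weights)) {
  G <- cbind(G_0 = rep(1 / sqrt(length(weights)), length(weights)),
             G_1 = unname(weights))
  rownames(G) <- gene_ids
  structure(list(G = G,
                 lambda = matrix(0, 2, 2,
                                 dimnames = list(c("lambda_0", "lambda_1"),
                                                 c("s1", "s2"))),
                 omega = c(2, 1), gene_ids = gene_ids, sample_ids = c("s1", "s2"),
                 metadata = NULL,
                 orientation = data.frame(alpha = 0:1, flipped = FALSE,
                                          rule = NA_character_)),
            class = "surprisal_decomposition")
}

make_sets <- function(members) {
  mapping <- do.call(rbind, lapply(names(members), function(p) {
    data.frame(gene_id = members[[p]], pathway_id = p, stringsAsFactors = FALSE)
  }))
  suppressMessages(pathway_sets(mapping, unique(mapping$gene_id), min_size = 1))
}

test_that("P, N and SR reproduce hand-computed values exactly", {
  w <- c(gA = 0.01, gB = -0.02, gC = 0.03)
  d <- fake_decomposition(w)
  sets <- make_sets(list(path1 = c("gA", "gB", "gC")))
  sc <- pathway_weights(d, sets, 1)
  expect_equal(sc$P, 0.0010)
  expect_equal(sc$N, 0.0004)
  expect_equal(sc$SR, 2.5)

  # all-positive members give N = 0 and an infinite set ratio
  sets2 <- make_sets(list(pos = c("gA", "gC")))
  sc2 <- pathway_weights(d, sets2, 1)
  expect_equal(sc2$N, 0)
  expect_identical(sc2$SR, Inf)

  # zero-weight genes contribute to neither sum
  w3 <- c(w, gZ = 0)
  d3 <- fake_decomposition(w3)
  sc3 <- pathway_weights(d3, make_sets(list(path1 = names(w3))), 1)
  expect_equal(sc3$P, 0.0010)
  expect_equal(sc3$N, 0.0004)
})

test_that("set_ratio handles the degenerate cases", {
  expect_equal(set_ratio(0.001, 0.0004), 2.5)
  expect_equal(set_ratio(1, 1), 1)
  expect_identical(set_ratio(0.5, 0), Inf)
  expect_identical(set_ratio(0, 0), NA_real_)
  expect_equal(set_ratio(0, 0.2), 0)
  expect_error(set_ratio(-1, 1), "non-negative")
})

test_that("P + N over a disjoint partition of all genes sums to 1", {
  ds <- generate_dataset(mini_config(seed = 2))
  d <- surprisal_decompose(synthetic_log_matrix(ds))
  ids <- d$gene_ids
  members <- split(ids, rep(1:10, length.out = length(ids)))
  names(members) <- paste0("part", 1:10)
  sets <- make_sets(members)
  for (a in c(0, 1, 3)) {
    sc <- pathway_weights(d, sets, a)
    expect_equal(sum(sc$P) + sum(sc$N), 1, tolerance = 1e-10)
  }
})

test_that("pathways below the minimum size are dropped", {
  mapping <- data.frame(
    gene_id = c(sprintf("g%02d", 1:9), sprintf("g%02d", 1:10)),
    pathway_id = c(rep("small", 9), rep("big", 10)),
    stringsAsFactors = FALSE
  )
  analyzed <- sprintf("g%02d", 1:10)
  sets <- suppressMessages(pathway_sets(mapping, analyzed, min_size = 10))
  expect_identical(names(sets), "big")
  expect_equal(sets$big$n_genes, 10)
  # min_size 1 drops nothing
  sets1 <- suppressMessages(pathway_sets(mapping, analyzed, min_size = 1))
  expect_setequal(names(sets1), c("small", "big"))
  # membership counts only analyzed genes
  sets2 <- suppressMessages(pathway_sets(mapping, sprintf("g%02d", 1:5), min_size = 1))
  expect_equal(sets2$small$n_genes, 5)
  expect_error(suppressMessages(pathway_sets(mapping[0, ], analyzed)), "empty")
})

test_that("orientation flips swap P and N and invert finite set ratios", {
  ds <- generate_dataset(mini_config(seed = 4))
  d <- surprisal_decompose(synthetic_log_matrix(ds))
  sets <- suppressMessages(pathway_sets(ds$gene_sets, d$gene_ids, min_size = 5))
  before <- pathway_weights(d, sets, 1)
  flipped <- orient_by_anchor_gene(
    d, 1, d$gene_ids[which.max(abs(d$G[, 2]))], -sign(d$G[which.max(abs(d$G[, 2])), 2]))
  after <- pathway_weights(flipped, sets, 1)
  expect_equal(after$P, before$N)
  expect_equal(after$N, before$P)
  fin <- is.finite(before$SR) & before$SR > 0
  expect_equal(after$SR[fin], 1 / before$SR[fin])
})

test_that("ranking follows the set-ratio ordering rules", {
  scores <- data.frame(
    pathway_id = c("oxo", "mid", "auto", "allpos", "allneg", "dead"),
    name = c("oxo", "mid", "auto", "allpos", "allneg", "dead"),
    alpha = 1, n_genes = 10,
    P = c(9.41e-5, 1e-5, 1.03e-6, 2e-6, 0, 0),
    N = c(1.99e-6, 1e-5, 6.42e-5, 0, 3e-6, 0),
    stringsAsFactors = FALSE
  )
  scores$SR <- set_ratio(scores$P, scores$N)
  expect_equal(round(scores$SR[1], 2), 47.29)

  hi <- suppressMessages(rank_pathways(scores, "high_SR", top_k = 3))
  # all-positive sets outrank finite ratios; then decreasing SR
  expect_identical(hi$pathway_id, c("allpos", "oxo", "mid"))
  lo <- suppressMessages(rank_pathways(scores, "low_SR", top_k = 3))
  expect_identical(lo$pathway_id, c("allneg", "auto", "mid"))
  # all-zero pathways are dropped, never ranked
  expect_false("dead" %in% c(hi$pathway_id, lo$pathway_id))

  # exact ties break lexicographically by pathway id
  tied <- data.frame(pathway_id = c("b", "a", "c"), name = "x", alpha = 1,
                     n_genes = 10, P = 0.002, N = 0.001, stringsAsFactors = FALSE)
  tied$SR <- set_ratio(tied$P, tied$N)
  expect_identical(rank_pathways(tied, "high_SR", 3)$pathway_id, c("a", "b", "c"))

  # balance-state convention: rank on max(P, N)
  mag <- rank_pathways(scores[1:3, ], "magnitude", 2)
  expect_identical(mag$pathway_id, c("oxo", "auto"))
  expect_error(rank_pathways(scores[0, ], "high_SR"), "empty")
})

test_that("planted enriched pathways dominate the set-ratio rankings", {
  ds <- generate_dataset(mini_config(seed = 6, n_enriched_per_phenotype = 3))
  d <- orient_study(surprisal_decompose(to_log(ds$data)))
  sets <- suppressMessages(pathway_sets(ds$gene_sets, d$gene_ids, min_size = 5))
  rec <- recovery_report(ds$truth, d, sets = sets, top_k = 5)
  expect_true(all(rec$pathway_recovery >= 0.8))
})

test_that("gene-set files round-trip in tabular and GMT formats", {
  dir <- withr::local_tempdir()
  mapping <- data.frame(gene_id = sprintf("g%02d", 1:12),
                        pathway_id = rep(c("p1", "p2"), 6),
                        pathway_name = rep(c("first", "second"), 6),
                        stringsAsFactors = FALSE)
  tsv <- file.path(dir, "sets.tsv")
  utils::write.table(mapping, tsv, sep = "\t", row.names = FALSE, quote = FALSE)
  sets <- suppressMessages(load_gene_sets(tsv, mapping$gene_id, min_size = 2))
  expect_setequal(names(sets), c("p1", "p2"))
  expect_equal(sets$p1$n_genes, 6)
  expect_equal(sets$p1$name, "first")

  gmt <- file.path(dir, "sets.gmt")
  writeLines(c(paste(c("p1", "first", mapping$gene_id[mapping$pathway_id == "p1"]),
                     collapse = "\t"),
               paste(c("p2", "second", mapping$gene_id[mapping$pathway_id == "p2"]),
                     collapse = "\t")), gmt)
  sets_gmt <- suppressMessages(load_gene_sets(gmt, mapping$gene_id, min_size = 2,
                                              format = "gmt"))
  expect_equal(sets_gmt$p1$gene_ids, sets$p1$gene_ids)
})
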