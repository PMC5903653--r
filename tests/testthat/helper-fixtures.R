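# Shared fixture builders: everything is generated in code at test time.

# A small expression dataset over the 2x2 design (2 samples per series).
toy_metadata <- function(sizes = c(AL = 2, AD = 2, LL = 2, LD = 2)) {
  series <- rep(names(sizes), sizes)
  info <- data.frame(
    series = c("AL", "AD", "LL", "LD"),
    medium = c("agar", "agar", "liquid", "liquid"),
    light = c("light", "dark", "light", "dark"),
    stringsAsFactors = FALSE
  )
  idx <- match(series, info$series)
  data.frame(
    sample_id = paste0(series, unlist(lapply(sizes, seq_len))),
    medium = info$medium[idx],
    light = info$light[idx],
    series = series,
    strain = "toy",
    source_lab = "toy_lab",
    stringsAsFactors = FALSE
  )
}

toy_dataset <- function(n_genes = 12, sizes = c(AL = 2, AD = 2, LL = 2, LD = 2),
                        seed = 1) {
  md <- toy_metadata(sizes)
  set.seed(seed)
  vals <- matrix(stats::rexp(n_genes * nrow(md), rate = 0.2),
                 nrow = n_genes,
                 dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                                 md$sample_id))
  expression_dataset(vals, md)
}

# A down-scaled synthetic configuration for fast end-to-end tests. With few
# genes the balance multiplier must be larger so the balance component keeps
# the largest singular value (its norm scales with balance_level / sqrt(N)).
mini_config <- function(seed = 1, ...) {
  args <- list(n_genes = 300, n_markers_per_phenotype = 40,
               n_pathways = 12, pathway_size = 10,
               n_enriched_per_phenotype = 2, balance_level = 4.5,
               seed = seed)
  args[names(list(...))] <- list(...)
  do.call(synthetic_config, args)
}

# ln-matrix of a synthetic dataset, bypassing filtering/flooring.
synthetic_log_matrix <- function(ds) {
  log(SummarizedExperiment::assay(ds$data, "fpkm"))
}
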