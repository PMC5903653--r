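# Stratified-subsampling robustness analysis with per-draw sign reattribution.

#' Specification of a randomization run
#'
#' The study configuration draws 6 AL, 3 AD and 3 LL samples per draw and
#' always includes the two LD samples, for subsets of 14 of the 38 samples,
#' repeated 1000 times.
#'
#' @param draws_per_series named integer vector: samples to draw (without
#'   replacement) from each series.
#' @param always_include sample ids included in every draw.
#' @param n_draws number of independent draws (default 1000).
#' @param seed master seed; per-draw substream seeds are spawned from it so
#'   individual draws are reproducible in isolation.
#' @param anchor_genes optional named list `alpha -> list(gene_id, sign)`
#'   used for per-draw sign reattribution; when `NULL`, anchors default to
#'   the top-weight gene of each constraint in a full-data run.
#' @param separation_threshold p-value threshold for the per-draw Wilcoxon
#'   separation flag (default 0.05).
#' @return an object of class `randomization_spec`.
#' @export
randomization_spec <- function(draws_per_series = c(AL = 6, AD = 3, LL = 3),
                               always_include = c("LD1", "LD2"),
                               n_draws = 1000, seed = 1,
                               anchor_genes = NULL,
                               separation_threshold = 0.05) {
  if (is.null(names(draws_per_series)) || any(!nzchar(names(draws_per_series)))) {
    stop("draws_per_series must be a named vector of series counts")
  }
  if (any(draws_per_series < 1)) stop("draws_per_series counts must be >= 1")
  if (n_draws < 1) stop("n_draws must be >= 1")
  structure(list(draws_per_series = draws_per_series,
                 always_include = always_include,
                 n_draws = as.integer(n_draws), seed = as.integer(seed),
                 anchor_genes = anchor_genes,
                 separation_threshold = separation_threshold),
            class = "randomization_spec")
}

#' Draw stratified sample subsets
#'
#' Each draw takes the configured number of samples from each series without
#' replacement, plus the always-included samples. Draws are independent of
#' one another (the same subset may recur by chance).
#'
#' @param metadata sample metadata `data.frame` (columns `sample_id`, `series`).
#' @param spec a `randomization_spec`.
#' @return list of character vectors of sample ids; attribute `draw_seeds`
#'   records the per-draw substream seeds.
#' @export
draw_subsets <- function(metadata, spec) {
  absent <- setdiff(spec$always_include, metadata$sample_id)
  if (length(absent) > 0) {
    stop("always_include names unknown sample(s): ", paste(absent, collapse = ", "))
  }
  pools <- lapply(names(spec$draws_per_series), function(s) {
    setdiff(metadata$sample_id[metadata$series == s], spec$always_include)
  })
  names(pools) <- names(spec$draws_per_series)
  for (s in names(pools)) {
    if (spec$draws_per_series[[s]] > length(pools[[s]])) {
      stop(sprintf("series %s: requested %d samples but only %d available",
                   s, spec$draws_per_series[[s]], length(pools[[s]])))
    }
  }
  set.seed(spec$seed)
  draw_seeds <- sample.int(.Machine$integer.max - 1L, spec$n_draws)
  subsets <- lapply(draw_seeds, function(ds) {
    set.seed(ds)
    drawn <- unlist(lapply(names(pools), function(s) {
      sample(pools[[s]], spec$draws_per_series[[s]])
    }), use.names = FALSE)
    c(drawn, spec$always_include)
  })
  attr(subsets, "draw_seeds") <- draw_seeds
  subsets
}

# Default anchors: the top-|weight| gene of each of the first three
# components in a full-data study-oriented run, with its full-data sign.
.default_anchors <- function(y, metadata = NULL) {
  d <- surprisal_decompose(y)
  if (!is.null(metadata)) d$metadata <- metadata
  d <- orient_study(d)
  anchors <- lapply(0:2, function(a) {
    w <- d$G[, a + 1L]
    i <- order(-abs(w), d$gene_ids)[1]
    list(gene_id = d$gene_ids[i], sign = sign(w[i]))
  })
  names(anchors) <- as.character(0:2)
  anchors
}

#' Analyze a single subsample draw
#'
#' Re-runs the full surprisal decomposition on the column subset,
#' reattributes component signs via the anchor genes, tests the Wilcoxon
#' separation of lambda_1 (agar vs liquid) and lambda_2 (dark vs light)
#' within the subset, and computes pathway weights for components 0..2.
#'
#' @param subset character vector of sample ids (>= 3).
#' @param y log-expression `SummarizedExperiment` (assay `ln_fpkm`) or matrix
#'   (already filtered/floored/logged; filtering is not recomputed per draw).
#' @param gene_sets optional `pathway_sets` object; when supplied, pathway
#'   scores are computed per draw.
#' @param spec a `randomization_spec` whose `anchor_genes` are set.
#' @param metadata sample metadata (needed when `y` is a plain matrix).
#' @return list with `subset`, `lambda` (3 x subset matrix for alpha 0..2),
#'   `medium`/`light` (`group_separation`), and `scores` (data.frame or NULL).
#' @export
analyze_draw <- function(subset, y, gene_sets = NULL, spec, metadata = NULL) {
  if (length(subset) < 3) stop("subset must contain at least 3 samples")
  md <- if (is.null(metadata)) .sample_metadata(y) else metadata
  if (is.null(md)) stop("sample metadata required")
  if (is.null(spec$anchor_genes)) stop("spec$anchor_genes must be set (see run_randomization)")
  Y <- .as_log_matrix(y)[, subset, drop = FALSE]
  d <- surprisal_decompose(Y)
  for (a_chr in names(spec$anchor_genes)) {
    anc <- spec$anchor_genes[[a_chr]]
    d <- orient_by_anchor_gene(d, as.integer(a_chr), anc$gene_id, anc$sign)
  }
  md_sub <- md[md$sample_id %in% subset, , drop = FALSE]
  medium <- group_separation_test(
    d$lambda[2, ],
    md_sub$sample_id[md_sub$medium == "agar"],
    md_sub$sample_id[md_sub$medium == "liquid"],
    spec$separation_threshold, labels = c("agar", "liquid"))
  light <- group_separation_test(
    d$lambda[3, ],
    md_sub$sample_id[md_sub$light == "dark"],
    md_sub$sample_id[md_sub$light == "light"],
    spec$separation_threshold, labels = c("dark", "light"))
  scores <- NULL
  if (!is.null(gene_sets)) {
    scores <- do.call(rbind, lapply(0:2, function(a) pathway_weights(d, gene_sets, a)))
  }
  list(subset = subset, lambda = d$lambda[1:3, , drop = FALSE],
       anchor_weights = vapply(names(spec$anchor_genes), function(a_chr) {
         d$G[spec$anchor_genes[[a_chr]]$gene_id, as.integer(a_chr) + 1L]
       }, numeric(1)),
       medium = medium, light = light, scores = scores)
}

#' Aggregate per-draw results
#'
#' @param results list of [analyze_draw()] results.
#' @return an object of class `randomization_summary`: per-sample mean/SD of
#'   lambda_0..2 over the draws containing each sample, per-pathway mean/SD
#'   of P, N and SR per component, per-draw p-values, and the fraction of
#'   draws whose Wilcoxon separations pass.
#' @export
aggregate_draws <- function(results) {
  if (length(results) == 0) stop("no draw results to aggregate")
  all_samples <- sort(unique(unlist(lapply(results, function(r) r$subset))))
  lambda_stats <- lapply(1:3, function(j) {
    mat <- matrix(NA_real_, nrow = length(results), ncol = length(all_samples),
                  dimnames = list(NULL, all_samples))
    for (i in seq_along(results)) {
      mat[i, colnames(results[[i]]$lambda)] <- results[[i]]$lambda[j, ]
    }
    n_obs <- colSums(!is.na(mat))
    m <- colMeans(mat, na.rm = TRUE)
    s <- apply(mat, 2, stats::sd, na.rm = TRUE)
    s[n_obs <= 1] <- 0   # a sample seen in a single draw has no spread
    data.frame(sample_id = all_samples, alpha = j - 1L, n_draws = n_obs,
               mean = m, sd = s, row.names = NULL, stringsAsFactors = FALSE)
  })
  lambda_summary <- do.call(rbind, lambda_stats)

  pathway_summary <- NULL
  if (!is.null(results[[1]]$scores)) {
    sc <- do.call(rbind, lapply(results, function(r) r$scores))
    grp <- split(seq_len(nrow(sc)), paste(sc$alpha, sc$pathway_id, sep = "\r"))
    sd0 <- function(v) if (length(v) > 1) stats::sd(v) else 0
    pathway_summary <- do.call(rbind, lapply(grp, function(ix) {
      sr <- sc$SR[ix]
      data.frame(pathway_id = sc$pathway_id[ix[1]], alpha = sc$alpha[ix[1]],
                 n_draws = length(ix),
                 mean_P = mean(sc$P[ix]), sd_P = sd0(sc$P[ix]),
                 mean_N = mean(sc$N[ix]), sd_N = sd0(sc$N[ix]),
                 mean_SR = mean(sr),
                 sd_SR = sd0(sr[is.finite(sr)]),
                 stringsAsFactors = FALSE)
    }))
    rownames(pathway_summary) <- NULL
  }

  p_medium <- vapply(results, function(r) r$medium$p_value, numeric(1))
  p_light <- vapply(results, function(r) r$light$p_value, numeric(1))
  sep_medium <- vapply(results, function(r) r$medium$separated, logical(1))
  sep_light <- vapply(results, function(r) r$light$separated, logical(1))
  structure(
    list(lambda = lambda_summary, pathways = pathway_summary,
         p_medium = p_medium, p_light = p_light,
         separation_fraction = c(medium = mean(sep_medium),
                                 light = mean(sep_light)),
         n_draws_effective = length(results)),
    class = "randomization_summary"
  )
}

#' @export
print.randomization_summary <- function(x, ...) {
  cat(sprintf("Randomization summary over %d draws\n", x$n_draws_effective))
  cat(sprintf("  Wilcoxon separation pass fraction: medium %.3f, light %.3f\n",
              x$separation_fraction["medium"], x$separation_fraction["light"]))
  cat(sprintf("  median p: medium %.3g, light %.3g\n",
              stats::median(x$p_medium), stats::median(x$p_light)))
  invisible(x)
}

#' Run the full randomization analysis
#'
#' Draws stratified subsets, re-decomposes each, reattributes signs via the
#' anchor genes (defaulting to the strongest-weight gene per component from a
#' full-data run), and aggregates. Deterministic given the spec's seed.
#'
#' @param y log-expression `SummarizedExperiment` or matrix.
#' @param spec a `randomization_spec`.
#' @param gene_sets optional `pathway_sets` for per-draw pathway scores.
#' @param metadata sample metadata (needed when `y` is a plain matrix).
#' @return list with `spec` (anchors filled in), `subsets`, `results`
#'   (per-draw) and `summary` (a `randomization_summary`).
#' @export
run_randomization <- function(y, spec, gene_sets = NULL, metadata = NULL) {
  md <- if (is.null(metadata)) .sample_metadata(y) else metadata
  if (is.null(md)) stop("sample metadata required")
  if (is.null(spec$anchor_genes)) {
    spec$anchor_genes <- .default_anchors(.as_log_matrix(y), md)
  }
  subsets <- draw_subsets(md, spec)
  results <- lapply(subsets, analyze_draw, y = y, gene_sets = gene_sets,
                    spec = spec, metadata = md)
  list(spec = spec, subsets = subsets, results = results,
       summary = aggregate_draws(results))
}
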