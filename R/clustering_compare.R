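# K-means with Pearson-correlation distance and the figure-of-merit
# cross-validation of cluster count; overlap with surprisal top-gene lists.

#' Mean-center a log-expression matrix at the gene level
#'
#' @param y `SummarizedExperiment` with assay `ln_fpkm` or numeric matrix.
#' @return numeric matrix with every gene row centered to mean zero.
#' @export
mean_center <- function(y) {
  Y <- .as_log_matrix(y)
  Y - rowMeans(Y)
}

# Row-standardize to unit vectors: centered rows divided by their L2 norm.
# Pearson correlation between rows then equals the dot product of the
# standardized rows. Zero-variance rows become all-zero (correlation 0 with
# everything; they land deterministically in the first cluster).
.standardize_rows <- function(X) {
  Xc <- X - rowMeans(X)
  nrm <- sqrt(rowSums(Xc^2))
  nrm[nrm == 0] <- 1
  Xc / nrm
}

#' K-means clustering with Pearson-correlation distance
#'
#' Clusters gene profiles using distance `1 - cor(gene, centroid)`. Gene rows
#' are centered and scaled to unit norm, so the correlation is a dot product;
#' the centroid update is the normalized mean of the member unit profiles,
#' which makes the total distance objective non-increasing across iterations
#' (asserted at run time). The best of `n_init` random restarts by total
#' within-cluster distance is returned. An empty cluster is re-seeded from
#' the gene currently least correlated with its centroid.
#'
#' @param x numeric matrix of mean-centered ln expression (genes x samples);
#'   a `SummarizedExperiment` is centered automatically.
#' @param k number of clusters (>= 2).
#' @param seed integer seed for the restarts.
#' @param n_init random restarts (default 10).
#' @param max_iter iteration cap per restart (default 300); convergence is
#'   declared when assignments stop changing.
#' @param metadata optional sample metadata; when supplied (or carried by
#'   `x`), clusters are labelled with the phenotype (agar/liquid/dark/light)
#'   whose samples have the highest centroid mean.
#' @return an object of class `pearson_kmeans`: `labels` (named integer
#'   vector), `centroids` (k x samples matrix, mean of member centered rows),
#'   `objective` (total 1 - cor), `k`, `n_iter`, and `phenotype_of_cluster`
#'   when metadata is available.
#' @export
kmeans_pearson <- function(x, k, seed = 1, n_init = 10, max_iter = 300,
                           metadata = NULL) {
  if (is.null(metadata)) metadata <- .sample_metadata(x)
  X <- mean_center(x)
  if (k < 2) stop("k must be >= 2")
  if (k > nrow(X)) stop("k exceeds the number of genes")
  Z <- .standardize_rows(X)
  n <- nrow(Z)
  set.seed(seed)
  best <- NULL
  for (init in seq_len(n_init)) {
    centers <- Z[sample.int(n, k), , drop = FALSE]
    # guard against zero rows picked as seeds
    while (any(rowSums(centers^2) == 0)) {
      centers <- Z[sample.int(n, k), , drop = FALSE]
    }
    centers <- centers / sqrt(rowSums(centers^2))
    labels <- rep(0L, n)
    prev_obj <- Inf
    iter <- 0L
    repeat {
      iter <- iter + 1L
      sim <- Z %*% t(centers)                    # cosine = Pearson on rows
      new_labels <- max.col(sim, ties.method = "first")
      obj <- sum(1 - sim[cbind(seq_len(n), new_labels)])
      stopifnot(obj <= prev_obj + 1e-8)          # objective never increases
      prev_obj <- obj
      if (identical(new_labels, labels) || iter >= max_iter) {
        labels <- new_labels
        break
      }
      labels <- new_labels
      for (j in seq_len(k)) {
        members <- which(labels == j)
        if (length(members) == 0) {
          # re-seed from the gene least correlated with its centroid
          worst <- which.min(sim[cbind(seq_len(n), labels)])
          centers[j, ] <- Z[worst, ]
          labels[worst] <- j
        } else {
          m <- colMeans(Z[members, , drop = FALSE])
          nm <- sqrt(sum(m^2))
          if (nm > 0) centers[j, ] <- m / nm
        }
      }
    }
    if (is.null(best) || prev_obj < best$objective) {
      best <- list(labels = labels, objective = prev_obj, n_iter = iter)
    }
  }
  labels <- stats::setNames(best$labels, rownames(X))
  centroids <- do.call(rbind, lapply(seq_len(k), function(j) {
    members <- which(labels == j)
    if (length(members) == 0) rep(NA_real_, ncol(X))
    else colMeans(X[members, , drop = FALSE])
  }))
  colnames(centroids) <- colnames(X)
  rownames(centroids) <- paste0("cluster_", seq_len(k))
  res <- structure(list(labels = labels, centroids = centroids,
                        objective = best$objective, k = k,
                        n_iter = best$n_iter),
                   class = "pearson_kmeans")
  if (!is.null(metadata)) {
    res$phenotype_of_cluster <- assign_cluster_phenotypes(res, metadata)
  }
  res
}

#' @export
print.pearson_kmeans <- function(x, ...) {
  cat(sprintf("Pearson-distance k-means: k = %d, %d genes, objective %.2f\n",
              x$k, length(x$labels), x$objective))
  print(table(cluster = x$labels))
  if (!is.null(x$phenotype_of_cluster)) {
    cat("Cluster phenotypes:",
        paste(sprintf("%d=%s", seq_len(x$k), x$phenotype_of_cluster),
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' Label clusters with the phenotype of their highest centroid group mean
#'
#' For each cluster, the centroid (mean-centered ln units) is averaged over
#' the agar, liquid, dark and light sample groups; the cluster is labelled
#' with the group of the largest mean (genes upregulated in that condition).
#'
#' @param result a `pearson_kmeans` object.
#' @param metadata sample metadata with `medium` and `light` columns.
#' @return character vector of phenotype labels, one per cluster.
#' @export
assign_cluster_phenotypes <- function(result, metadata) {
  groups <- list(agar = metadata$sample_id[metadata$medium == "agar"],
                 liquid = metadata$sample_id[metadata$medium == "liquid"],
                 dark = metadata$sample_id[metadata$light == "dark"],
                 light = metadata$sample_id[metadata$light == "light"])
  vapply(seq_len(result$k), function(j) {
    means <- vapply(groups, function(g) {
      mean(result$centroids[j, intersect(g, colnames(result$centroids))])
    }, numeric(1))
    names(means)[which.max(means)]
  }, character(1))
}

#' Figure-of-merit estimate of the cluster count
#'
#' Leave-one-sample-out cross-validation: for each candidate k and each
#' left-out sample, genes are clustered on the remaining samples and the
#' root-mean-square deviation of the left-out column from its cluster means
#' is computed, adjusted by `sqrt((N - k) / N)`. The per-k curve is the sum
#' over left-out samples; the recommended k is the smallest whose relative
#' improvement when moving to k + 1 falls below `elbow_frac`.
#'
#' @param x mean-centered matrix or `SummarizedExperiment`.
#' @param k_range candidate cluster counts (within 2..Ns).
#' @param seed integer seed.
#' @param n_init restarts per clustering (default 3; the FOM curve is an
#'   estimate, not a final clustering).
#' @param elbow_frac relative-improvement threshold (default 0.1).
#' @return list with `fom` (named numeric per k) and `recommended_k`.
#' @export
estimate_k_fom <- function(x, k_range = 2:8, seed = 1, n_init = 3,
                           elbow_frac = 0.1) {
  X <- mean_center(x)
  if (length(k_range) == 0) stop("k_range is empty")
  k_range <- sort(unique(as.integer(k_range)))
  if (min(k_range) < 2 || max(k_range) > ncol(X)) {
    stop("k_range must lie within 2..", ncol(X))
  }
  n <- nrow(X)
  fom <- vapply(k_range, function(k) {
    total <- 0
    for (e in seq_len(ncol(X))) {
      cl <- kmeans_pearson(X[, -e, drop = FALSE], k,
                           seed = seed + e, n_init = n_init)
      pred <- stats::ave(X[, e], cl$labels)      # cluster means in column e
      total <- total + sqrt(mean((X[, e] - pred)^2)) / sqrt((n - k) / n)
    }
    total
  }, numeric(1))
  names(fom) <- k_range
  recommended <- k_range[length(k_range)]
  if (length(k_range) > 1) {
    for (i in seq_len(length(k_range) - 1)) {
      improvement <- (fom[i] - fom[i + 1]) / fom[i]
      if (improvement < elbow_frac) {
        recommended <- k_range[i]
        break
      }
    }
  }
  list(fom = fom, recommended_k = recommended)
}

#' Cross-tabulate surprisal top-gene lists against clusters
#'
#' Counts how many of each phenotype's top-n surprisal genes fall in each
#' cluster, and the fraction landing in the cluster(s) labelled with the
#' matching phenotype.
#'
#' @param result a `pearson_kmeans` with `phenotype_of_cluster` (cluster the
#'   matrix with metadata, or call [assign_cluster_phenotypes()]).
#' @param lists named list of data.frames (or character vectors) of gene ids
#'   per phenotype, e.g. from [phenotype_gene_table()].
#' @return an object of class `overlap_table`: `counts` (phenotype x cluster
#'   matrix, rows summing to the list lengths), `matched_fraction` per
#'   phenotype, and `pooled_fraction`.
#' @export
overlap_table <- function(result, lists) {
  if (is.null(result$phenotype_of_cluster)) {
    stop("clusters carry no phenotype labels; supply metadata to kmeans_pearson()")
  }
  ids <- lapply(lists, function(l) if (is.data.frame(l)) l$gene_id else as.character(l))
  absent <- setdiff(unlist(ids), names(result$labels))
  if (length(absent) > 0) {
    stop("gene(s) in the lists were not clustered: ",
         paste(utils::head(absent, 5), collapse = ", "))
  }
  counts <- do.call(rbind, lapply(ids, function(g) {
    tabulate(result$labels[g], nbins = result$k)
  }))
  rownames(counts) <- names(lists)
  colnames(counts) <- paste0("cluster_", seq_len(result$k))
  matched <- vapply(names(lists), function(ph) {
    match_clusters <- which(result$phenotype_of_cluster == ph)
    if (length(match_clusters) == 0) return(0)
    sum(counts[ph, match_clusters]) / sum(counts[ph, ])
  }, numeric(1))
  pooled <- sum(vapply(names(lists), function(ph) {
    match_clusters <- which(result$phenotype_of_cluster == ph)
    sum(counts[ph, match_clusters])
  }, numeric(1))) / sum(counts)
  structure(list(counts = counts, matched_fraction = matched,
                 pooled_fraction = pooled,
                 phenotype_of_cluster = result$phenotype_of_cluster),
            class = "overlap_table")
}

#' @export
print.overlap_table <- function(x, ...) {
  print(x$counts)
  cat("Matched fraction per phenotype:",
      paste(sprintf("%s %.1f%%", names(x$matched_fraction),
                    100 * x$matched_fraction), collapse = ", "), "\n")
  cat(sprintf("Pooled matched fraction: %.1f%%\n", 100 * x$pooled_fraction))
  invisible(x)
}
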