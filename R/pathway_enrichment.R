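# Set-ratio pathway enrichment on constraint weight vectors.

#' Build pathway sets from a gene-to-pathway mapping
#'
#' Restricts each pathway to the analyzed gene universe and drops pathways
#' with fewer than `min_size` remaining genes. A gene may belong to several
#' pathways.
#'
#' @param mapping data.frame with columns `gene_id`, `pathway_id` and
#'   optionally `pathway_name`.
#' @param analyzed_genes character vector of gene ids present in the matrix.
#' @param min_size minimum member count (default 10).
#' @return an object of class `pathway_sets`: a named list of lists with
#'   elements `pathway_id`, `name`, `gene_ids`, `n_genes`.
#' @export
pathway_sets <- function(mapping, analyzed_genes, min_size = 10) {
  if (!all(c("gene_id", "pathway_id") %in% names(mapping))) {
    stop("mapping must have columns gene_id and pathway_id")
  }
  if (nrow(mapping) == 0) stop("empty gene-to-pathway mapping")
  if (min_size < 1) stop("min_size must be >= 1")
  unmapped <- setdiff(analyzed_genes, unique(mapping$gene_id))
  if (length(unmapped) > 0) {
    message(sprintf("pathway_sets: %d of %d analyzed genes map to no pathway",
                    length(unmapped), length(analyzed_genes)))
  }
  mapping <- mapping[mapping$gene_id %in% analyzed_genes, , drop = FALSE]
  names_by_id <- if ("pathway_name" %in% names(mapping)) {
    tapply(mapping$pathway_name, mapping$pathway_id, function(v) v[1])
  } else NULL
  members <- split(mapping$gene_id, mapping$pathway_id)
  sets <- lapply(names(members), function(pid) {
    genes <- unique(members[[pid]])
    list(pathway_id = pid,
         name = if (is.null(names_by_id)) pid else unname(names_by_id[pid]),
         gene_ids = genes, n_genes = length(genes))
  })
  names(sets) <- names(members)
  keep <- vapply(sets, function(s) s$n_genes >= min_size, logical(1))
  if (sum(!keep) > 0) {
    message(sprintf("pathway_sets: dropped %d pathway(s) with fewer than %d analyzed genes",
                    sum(!keep), min_size))
  }
  structure(sets[keep], class = "pathway_sets")
}

#' Read a gene-to-pathway mapping file
#'
#' Supports a two/three-column delimited table (`gene_id`, `pathway_id`,
#' optional `pathway_name`) or GMT (one pathway per line:
#' id, description, member genes, tab-separated).
#'
#' @param path file path.
#' @param analyzed_genes gene ids present in the analyzed matrix.
#' @param min_size minimum member count after restriction (default 10).
#' @param format `"tsv"` (default; comma also accepted via `sep`) or `"gmt"`.
#' @param sep field separator for tabular input (default tab).
#' @return a `pathway_sets` object.
#' @export
load_gene_sets <- function(path, analyzed_genes, min_size = 10,
                           format = c("tsv", "gmt"), sep = "\t") {
  format <- match.arg(format)
  if (format == "gmt") {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    if (length(lines) == 0) stop("empty gene-set file: ", path)
    parts <- strsplit(lines, "\t", fixed = TRUE)
    mapping <- do.call(rbind, lapply(parts, function(p) {
      if (length(p) < 3) return(NULL)
      data.frame(gene_id = p[-(1:2)], pathway_id = p[1], pathway_name = p[2],
                 stringsAsFactors = FALSE)
    }))
    if (is.null(mapping)) stop("no parsable pathway lines in ", path)
  } else {
    mapping <- utils::read.table(path, sep = sep, header = TRUE,
                                 stringsAsFactors = FALSE, check.names = FALSE)
  }
  pathway_sets(mapping, analyzed_genes, min_size)
}

#' Positive/negative pathway weights and set ratios for one constraint
#'
#' For each pathway J and constraint alpha, the positive weight is
#' `P = sum(G[i, alpha]^2)` over member genes with positive weight, the
#' negative weight `N = sum(G[i, alpha]^2)` over members with negative
#' weight, and the set ratio `SR = P / N`. Because each G column is a unit
#' vector, P + N partitions of the pathway's share of 1. Genes with weight
#' exactly zero contribute to neither sum.
#'
#' @param d a `surprisal_decomposition`.
#' @param sets a `pathway_sets` object.
#' @param alpha constraint index (0 = balance state).
#' @return data.frame with columns `pathway_id`, `name`, `alpha`, `n_genes`,
#'   `P`, `N`, `SR` (`Inf` when all member weights are positive, `NA` when
#'   the pathway has no nonzero member weight).
#' @export
pathway_weights <- function(d, sets, alpha) {
  a <- .check_alpha(d, alpha)
  g <- d$G[, a + 1L]
  # one shared lookup over all member lists (genes absent from the matrix
  # are silently excluded; membership was already restricted at load time)
  sizes <- vapply(sets, function(s) length(s$gene_ids), integer(1))
  pos <- match(unlist(lapply(sets, `[[`, "gene_ids"), use.names = FALSE),
               d$gene_ids)
  set_of <- rep(seq_along(sets), sizes)
  ok <- !is.na(pos)
  w <- g[pos[ok]]
  f <- factor(set_of[ok], levels = seq_along(sets))
  sum_by <- function(v) {
    out <- vapply(split(v, f), sum, numeric(1))
    out
  }
  P <- unname(sum_by(ifelse(w > 0, w^2, 0)))
  N <- unname(sum_by(ifelse(w < 0, w^2, 0)))
  out <- data.frame(
    pathway_id = vapply(sets, `[[`, character(1), "pathway_id"),
    name = vapply(sets, `[[`, character(1), "name"),
    alpha = a,
    n_genes = vapply(sets, `[[`, integer(1), "n_genes"),
    P = P, N = N, SR = set_ratio(P, N),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Set ratio SR = P / N
#'
#' @param P,N non-negative positive/negative pathway weights (vectorized).
#' @return `P / N`; `Inf` when `N == 0` and `P > 0` (all-positive set);
#'   `NA` when both are zero.
#' @export
set_ratio <- function(P, N) {
  if (any(P < 0) || any(N < 0)) stop("P and N must be non-negative")
  ifelse(N > 0, P / N, ifelse(P > 0, Inf, NA_real_))
}

#' Rank pathways by set ratio
#'
#' `high_SR` ranks enrichment in the positively-signed phenotype: sets whose
#' member weights are all positive (SR undefined as a finite number) are
#' placed above the finite ratios and ordered by P; finite ratios follow in
#' decreasing order. `low_SR` mirrors this: all-negative sets first, ordered
#' by N, then finite ratios increasing. `magnitude` ranks by `max(P, N)`
#' (the balance-state convention, where the orientation makes one sign
#' dominant). Ties break lexicographically by pathway id; pathways with no
#' nonzero member weight are dropped with a message.
#'
#' @param scores data.frame from [pathway_weights()] (one constraint).
#' @param direction `"high_SR"`, `"low_SR"` or `"magnitude"`.
#' @param top_k number of pathways to return (default 10).
#' @return the top rows of `scores`, with a `rank` column prepended.
#' @export
rank_pathways <- function(scores, direction = c("high_SR", "low_SR", "magnitude"),
                          top_k = 10) {
  direction <- match.arg(direction)
  if (nrow(scores) == 0) stop("empty pathway score table")
  if (top_k < 1) stop("top_k must be >= 1")
  undefined <- scores$P == 0 & scores$N == 0
  if (any(undefined)) {
    message(sprintf("rank_pathways: dropped %d pathway(s) with all-zero weights",
                    sum(undefined)))
    scores <- scores[!undefined, , drop = FALSE]
  }
  if (nrow(scores) == 0) stop("no pathway has a nonzero weight")
  if (direction == "high_SR") {
    one_signed <- scores$N == 0            # all weights positive
    top <- scores[one_signed, , drop = FALSE]
    top <- top[order(-top$P, top$pathway_id), , drop = FALSE]
    rest <- scores[!one_signed, , drop = FALSE]
    rest <- rest[order(-rest$SR, rest$pathway_id), , drop = FALSE]
    out <- rbind(top, rest)
  } else if (direction == "low_SR") {
    one_signed <- scores$P == 0            # all weights negative
    top <- scores[one_signed, , drop = FALSE]
    top <- top[order(-top$N, top$pathway_id), , drop = FALSE]
    rest <- scores[!one_signed, , drop = FALSE]
    rest <- rest[order(rest$SR, rest$pathway_id), , drop = FALSE]
    out <- rbind(top, rest)
  } else {
    out <- scores[order(-pmax(scores$P, scores$N), scores$pathway_id), ,
                  drop = FALSE]
  }
  out <- utils::head(out, top_k)
  out <- cbind(rank = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}
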