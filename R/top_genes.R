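# Per-gene constraint-weight rankings.

#' Top-contributing genes of a constraint
#'
#' Ranks genes by their weight `G[i, alpha]` and returns the `n` largest or
#' smallest. Ties break lexicographically by gene id. These lists are the
#' ranking notion of differential expression used throughout: no statistical
#' test is attached.
#'
#' @param d a `surprisal_decomposition`.
#' @param alpha constraint index.
#' @param n list length (default 100). If `n` exceeds the number of genes,
#'   all genes are returned with a warning.
#' @param direction `"largest"` (descending weight) or `"smallest"`.
#' @return data.frame with columns `rank`, `gene_id`, `weight`.
#' @export
top_contributing_genes <- function(d, alpha, n = 100,
                                   direction = c("largest", "smallest")) {
  direction <- match.arg(direction)
  a <- .check_alpha(d, alpha)
  if (n < 1) stop("n must be >= 1")
  w <- d$G[, a + 1L]
  ids <- d$gene_ids
  if (n > length(ids)) {
    warning("n exceeds the number of genes; returning all ", length(ids))
    n <- length(ids)
  }
  ord <- if (direction == "largest") order(-w, ids) else order(w, ids)
  sel <- ord[seq_len(n)]
  data.frame(rank = seq_len(n), gene_id = ids[sel], weight = unname(w[sel]),
             stringsAsFactors = FALSE)
}

#' Per-phenotype top-gene lists
#'
#' Under the study orientation (lambda_1 positive for liquid samples,
#' lambda_2 positive for light samples), genes with `G[i,1] > 0` are
#' overexpressed in liquid and underexpressed on agar, and genes with
#' `G[i,2] > 0` are overexpressed in light. The liquid and light lists are
#' therefore the largest-weight lists of constraints 1 and 2, and the agar
#' and dark lists the smallest-weight lists.
#'
#' @param d an oriented `surprisal_decomposition` (components 1 and 2 must
#'   carry an orientation record; see [orient_study()] /
#'   [orient_by_anchor_gene()]).
#' @param n genes per list (default 100).
#' @return named list of data.frames: `agar`, `liquid`, `dark`, `light`.
#' @export
phenotype_gene_table <- function(d, n = 100) {
  oriented <- !is.na(d$orientation$rule)
  if (!all(oriented[2:3])) {
    stop("constraints 1 and 2 must be oriented before building phenotype lists")
  }
  list(
    agar = top_contributing_genes(d, 1, n, "smallest"),
    liquid = top_contributing_genes(d, 1, n, "largest"),
    dark = top_contributing_genes(d, 2, n, "smallest"),
    light = top_contributing_genes(d, 2, n, "largest")
  )
}
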