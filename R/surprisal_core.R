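# SVD-based surprisal decomposition: balance state + constraints.

#' Surprisal decomposition of a log-expression matrix
#'
#' Factorizes the N x Ns natural-log expression matrix Y by economy-size
#' singular value decomposition, Y = U diag(omega) V'. The per-gene phenotype
#' weights are G[i, alpha] = U[i, alpha] and the per-sample Lagrange
#' multipliers are lambda[alpha, s] = omega[alpha] * V[s, alpha]. Component
#' alpha = 0 (largest singular value) is the balance state; alpha = 1 ..
#' Ns - 1 are the constraints in decreasing-omega order. Keeping all Ns terms
#' reconstructs Y exactly.
#'
#' @param y a `SummarizedExperiment` with assay `ln_fpkm` (see [to_log()]) or
#'   a finite numeric matrix of ln expression values (genes x samples).
#' @return an object of class `surprisal_decomposition` with elements `G`
#'   (N x Ns, columns `G_0` ...), `lambda` (Ns x Ns, rows `lambda_0` ...),
#'   `omega` (non-increasing singular values), `gene_ids`, `sample_ids`,
#'   `metadata` (sample metadata when `y` carries it) and `orientation`
#'   (record of sign conventions applied).
#' @export
surprisal_decompose <- function(y) {
  metadata <- .sample_metadata(y)
  Y <- .as_log_matrix(y)
  if (!all(is.finite(Y))) stop("log-expression matrix contains non-finite entries")
  n_s <- ncol(Y)
  if (n_s < 2) stop("at least 2 samples are required")
  if (nrow(Y) < n_s) stop("expected at least as many genes as samples")
  sv <- svd(Y)   # economy size: u is N x Ns, v is Ns x Ns
  G <- sv$u
  lambda <- sv$d * t(sv$v)   # lambda[alpha, s] = omega_alpha * V[s, alpha]
  alpha_names <- paste0("G_", seq_len(n_s) - 1)
  colnames(G) <- alpha_names
  rownames(G) <- rownames(Y)
  rownames(lambda) <- paste0("lambda_", seq_len(n_s) - 1)
  colnames(lambda) <- colnames(Y)
  structure(
    list(G = G, lambda = lambda, omega = sv$d,
         gene_ids = rownames(Y), sample_ids = colnames(Y),
         metadata = metadata,
         orientation = data.frame(alpha = seq_len(n_s) - 1, flipped = FALSE,
                                  rule = NA_character_,
                                  stringsAsFactors = FALSE)),
    class = "surprisal_decomposition"
  )
}

#' @export
print.surprisal_decomposition <- function(x, ...) {
  cat(sprintf("Surprisal decomposition: %d genes x %d samples\n",
              length(x$gene_ids), length(x$sample_ids)))
  cat("Leading singular values (omega):",
      paste(signif(utils::head(x$omega, 5), 4), collapse = ", "),
      if (length(x$omega) > 5) "..." else "", "\n")
  oriented <- x$orientation$alpha[!is.na(x$orientation$rule)]
  if (length(oriented) > 0) {
    cat("Oriented components:", paste(oriented, collapse = ", "), "\n")
  } else {
    cat("No orientation convention applied yet.\n")
  }
  invisible(x)
}

.check_alpha <- function(d, alpha) {
  if (length(alpha) != 1 || alpha < 0 || alpha > length(d$omega) - 1) {
    stop("alpha must be a single index in 0..", length(d$omega) - 1)
  }
  as.integer(alpha)
}

# Jointly negate G column alpha and lambda row alpha; reconstruction invariant.
.flip_component <- function(d, alpha, rule) {
  j <- alpha + 1L
  d$G[, j] <- -d$G[, j]
  d$lambda[j, ] <- -d$lambda[j, ]
  d$orientation$flipped[j] <- !d$orientation$flipped[j]
  d$orientation$rule[j] <- rule
  d
}

.mark_oriented <- function(d, alpha, rule) {
  d$orientation$rule[alpha + 1L] <- rule
  d
}

#' Build an orientation rule
#'
#' @param alpha component index (0 = balance state).
#' @param samples non-empty character vector of sample ids defining the group.
#' @param sign desired sign (+1 or -1) of the mean of `lambda[alpha, ]` over
#'   the group.
#' @return a rule usable with [orient_by_groups()].
#' @export
orientation_rule <- function(alpha, samples, sign = 1) {
  if (!sign %in% c(-1, 1)) stop("sign must be +1 or -1")
  if (length(samples) == 0) stop("orientation rule names an empty sample group")
  list(alpha = as.integer(alpha), samples = as.character(samples), sign = sign)
}

#' Orient components by sample-group mean sign
#'
#' SVD fixes component signs only up to a convention. For each rule, if the
#' mean of `lambda[alpha, ]` over the named sample group has the wrong sign,
#' the G column and lambda row of that component are negated jointly, leaving
#' the reconstruction unchanged.
#'
#' @param d a `surprisal_decomposition`.
#' @param rules list of rules from [orientation_rule()]; at most one per
#'   component.
#' @return the oriented decomposition (orientation record updated even when
#'   no flip was needed).
#' @export
orient_by_groups <- function(d, rules) {
  alphas <- vapply(rules, function(r) r$alpha, integer(1))
  if (anyDuplicated(alphas)) stop("conflicting orientation rules for the same component")
  for (r in rules) {
    a <- .check_alpha(d, r$alpha)
    absent <- setdiff(r$samples, d$sample_ids)
    if (length(absent) > 0) {
      stop("orientation rule names unknown sample(s): ",
           paste(absent, collapse = ", "))
    }
    m <- mean(d$lambda[a + 1L, r$samples])
    if (m == 0) stop("group mean of lambda_", a, " is exactly zero; orientation undefined")
    rule_txt <- sprintf("group(%d samples) mean sign %+d", length(r$samples), r$sign)
    if (sign(m) != r$sign) {
      d <- .flip_component(d, a, rule_txt)
    } else {
      d <- .mark_oriented(d, a, rule_txt)
    }
  }
  d
}

#' Apply the study orientation convention
#'
#' Orients the balance state so its mean multiplier over all samples is
#' positive, constraint 1 so liquid-grown samples have positive lambda_1, and
#' constraint 2 so light-grown samples have positive lambda_2. Requires
#' sample metadata (columns `medium`, `light`).
#'
#' @param d a `surprisal_decomposition` carrying metadata, or supply
#'   `metadata` explicitly.
#' @param metadata optional sample metadata `data.frame`.
#' @return the oriented decomposition.
#' @export
orient_study <- function(d, metadata = NULL) {
  md <- if (is.null(metadata)) d$metadata else metadata
  if (is.null(md)) stop("sample metadata required for the study orientation")
  rules <- list(
    orientation_rule(0, d$sample_ids, +1),
    orientation_rule(1, md$sample_id[md$medium == "liquid"], +1),
    orientation_rule(2, md$sample_id[md$light == "light"], +1)
  )
  orient_by_groups(d, rules)
}

#' Orient a component by an anchor gene
#'
#' Flips the (G column, lambda row) pair of component `alpha` so the anchor
#' gene's weight `G[gene, alpha]` has the desired sign. This is the sign
#' reattribution convention used to aggregate subsample draws coherently.
#'
#' @param d a `surprisal_decomposition`.
#' @param alpha component index.
#' @param gene_id anchor gene (must have a nonzero weight in the component).
#' @param sign desired sign (+1 or -1).
#' @return the oriented decomposition.
#' @export
orient_by_anchor_gene <- function(d, alpha, gene_id, sign = 1) {
  a <- .check_alpha(d, alpha)
  if (!sign %in% c(-1, 1)) stop("sign must be +1 or -1")
  if (!gene_id %in% d$gene_ids) stop("anchor gene not found: ", gene_id)
  w <- d$G[gene_id, a + 1L]
  if (w == 0) stop("anchor gene has weight exactly zero in component ", a,
                   "; orientation undefined")
  rule_txt <- sprintf("anchor(%s) sign %+d", gene_id, sign)
  if (sign(w) != sign) {
    .flip_component(d, a, rule_txt)
  } else {
    .mark_oriented(d, a, rule_txt)
  }
}

#' Reconstruct the log-expression matrix from leading components
#'
#' Returns `sum_{alpha < n_terms} G[, alpha] %o% lambda[alpha, ]`. With
#' `n_terms` equal to the number of samples the input is recovered exactly
#' (within numerical precision).
#'
#' @param d a `surprisal_decomposition`.
#' @param n_terms number of components to keep (1 .. Ns).
#' @return numeric matrix (genes x samples) in ln units.
#' @export
reconstruct <- function(d, n_terms = length(d$omega)) {
  n_s <- length(d$omega)
  if (length(n_terms) != 1 || n_terms < 1 || n_terms > n_s) {
    stop("n_terms must be in 1..", n_s)
  }
  idx <- seq_len(n_terms)
  d$G[, idx, drop = FALSE] %*% d$lambda[idx, , drop = FALSE]
}

#' Balance-state summary
#'
#' The balance state is the dominant component (alpha = 0). Its per-gene term
#' `G[i, 0] * mean(lambda_0)` is the prior thermodynamic weight of gene i:
#' genes with a positive term are stable (low free energy,
#' `-G[i, 0] * mean(lambda_0)`), genes with a negative term unstable. Because
#' lambda_0 is only approximately constant across samples, the scalar used is
#' its across-sample mean; the per-sample values are returned as well.
#'
#' @param d a `surprisal_decomposition`.
#' @return an object of class `balance_state`: a list with `lambda0`
#'   (per-sample), `lambda0_bar`, and `genes`, a data.frame with columns
#'   `gene_id`, `G0`, `stability` and `free_energy` (= -stability).
#' @export
balance_state <- function(d) {
  lam0 <- d$lambda[1, ]
  lam0_bar <- mean(lam0)
  genes <- data.frame(
    gene_id = d$gene_ids,
    G0 = d$G[, 1],
    stability = d$G[, 1] * lam0_bar,
    stringsAsFactors = FALSE
  )
  genes$free_energy <- -genes$stability
  genes$stable <- genes$stability > 0
  structure(list(lambda0 = lam0, lambda0_bar = lam0_bar, genes = genes),
            class = "balance_state")
}

#' @export
print.balance_state <- function(x, ...) {
  cat(sprintf("Balance state: lambda_0 mean %.3f, range %.3f over %d samples\n",
              x$lambda0_bar, max(x$lambda0) - min(x$lambda0), length(x$lambda0)))
  cat(sprintf("%d / %d genes stable (positive prior thermodynamic weight)\n",
              sum(x$genes$stable), nrow(x$genes)))
  invisible(x)
}
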