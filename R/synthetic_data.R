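# Synthetic expression matrices with planted surprisal structure:
# balance state + two constraints + Gaussian noise, plus planted pathway
# enrichment, so every pipeline stage can be validated against known truth.

#' Configuration for the synthetic-data generator
#'
#' The generated ln-expression matrix is
#' `ln X = G0 lambda0 + G1 lambda1 + G2 lambda2 + noise`, with orthonormal
#' planted gene weight columns and mutually orthogonal planted multiplier
#' rows, so the planted factors are exactly the leading SVD components of the
#' noise-free matrix. lambda_0 is near-constant and positive (the balance
#' state); lambda_1's sign follows the growth medium (liquid positive),
#' lambda_2's the light regime (light positive). Each phenotype direction
#' gets a block of marker genes with strong one-signed weights, and enriched
#' pathways are drawn predominantly from those markers.
#'
#' @param n_genes number of genes (default 2000).
#' @param series_sizes named sizes of the AL, AD, LL, LD series (default
#'   23/5/8/2, the 38-sample unbalanced 2x2 design).
#' @param balance_level mean ln-FPKM of the balance term (default 2).
#' @param lambda0_range sample-to-sample spread (max - min) of the balance
#'   multiplier, in ln units (default 41).
#' @param lambda1_range,lambda2_range spread of the constraint multipliers
#'   (defaults 152 and 133), chosen so group separation dwarfs the noise.
#' @param noise_sd Gaussian noise sd on the ln scale (default 0.1).
#' @param marker_strength ratio of marker to background raw weight magnitude
#'   (default 4).
#' @param n_markers_per_phenotype marker genes per phenotype direction
#'   (default 120).
#' @param n_pathways total pathways in the mapping (default 40).
#' @param pathway_size genes per pathway (default 15).
#' @param n_enriched_per_phenotype enriched pathways planted per phenotype
#'   (default 4).
#' @param marker_fraction fraction of an enriched pathway's genes drawn from
#'   its phenotype's markers (default 0.8).
#' @param discordant_medium,discordant_light sample ids planted with a small
#'   opposite-sign multiplier (default none, so planted signs match the
#'   group labels exactly).
#' @param ensure_filter_pass lift baselines so every gene passes the
#'   low-expression filter computed on the agar samples (default FALSE).
#' @param filter_threshold FPKM threshold used by that guarantee (default 1).
#' @param seed integer seed.
#' @return an object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_genes = 2000,
                             series_sizes = c(AL = 23, AD = 5, LL = 8, LD = 2),
                             balance_level = 2,
                             lambda0_range = 41,
                             lambda1_range = 152,
                             lambda2_range = 133,
                             noise_sd = 0.1,
                             marker_strength = 4,
                             n_markers_per_phenotype = 120,
                             n_pathways = 40,
                             pathway_size = 15,
                             n_enriched_per_phenotype = 4,
                             marker_fraction = 0.8,
                             discordant_medium = character(0),
                             discordant_light = character(0),
                             ensure_filter_pass = FALSE,
                             filter_threshold = 1,
                             seed = 1) {
  cfg <- list(n_genes = as.integer(n_genes), series_sizes = series_sizes,
              balance_level = balance_level, lambda0_range = lambda0_range,
              lambda1_range = lambda1_range, lambda2_range = lambda2_range,
              noise_sd = noise_sd, marker_strength = marker_strength,
              n_markers_per_phenotype = as.integer(n_markers_per_phenotype),
              n_pathways = as.integer(n_pathways),
              pathway_size = as.integer(pathway_size),
              n_enriched_per_phenotype = as.integer(n_enriched_per_phenotype),
              marker_fraction = marker_fraction,
              discordant_medium = discordant_medium,
              discordant_light = discordant_light,
              ensure_filter_pass = isTRUE(ensure_filter_pass),
              filter_threshold = filter_threshold,
              seed = as.integer(seed))
  if (cfg$n_genes < 10) stop("n_genes must be >= 10")
  if (!all(c("AL", "AD", "LL", "LD") %in% names(cfg$series_sizes))) {
    stop("series_sizes must name AL, AD, LL and LD")
  }
  if (any(cfg$series_sizes < 1)) stop("series sizes must be positive")
  if (cfg$noise_sd < 0) stop("noise_sd must be >= 0")
  if (4 * cfg$n_markers_per_phenotype > cfg$n_genes) {
    stop("more marker genes requested than genes available")
  }
  if (4 * cfg$n_enriched_per_phenotype > cfg$n_pathways) {
    stop("more enriched pathways requested than pathways available")
  }
  if (cfg$pathway_size > cfg$n_genes) stop("pathway_size exceeds n_genes")
  n_marker_in_path <- round(cfg$marker_fraction * cfg$pathway_size)
  if (n_marker_in_path > cfg$n_markers_per_phenotype) {
    stop("enriched pathways need more marker genes than are planted per phenotype")
  }
  structure(cfg, class = "synthetic_config")
}

#' Study-scale synthetic configuration
#'
#' A preset emulating the published study conditions: 12774 genes, the
#' 23/5/8/2 sample design, multiplier spreads of 41/152/133 ln units, one
#' discordant agar sample (AD4, slightly positive lambda_1) and one
#' discordant light sample (AL3, slightly negative lambda_2), 113 pathways,
#' and baselines guaranteed to pass the 1-FPKM agar filter (the emulated
#' matrix is the post-filter gene universe).
#'
#' @param seed integer seed.
#' @param ... overrides passed to [synthetic_config()].
#' @return a `synthetic_config`.
#' @export
synthetic_study_config <- function(seed = 1, ...) {
  args <- list(n_genes = 12774, balance_level = 3,
               n_markers_per_phenotype = 300,
               n_pathways = 113, pathway_size = 20,
               n_enriched_per_phenotype = 5,
               discordant_medium = "AD4", discordant_light = "AL3",
               ensure_filter_pass = TRUE, seed = seed)
  args[names(list(...))] <- list(...)
  do.call(synthetic_config, args)
}

# Sample metadata matching the series sizes; AL/AD/LL use the resident lab's
# wild-type strain, LD the dark-adapted strain from the second lab.
.synthetic_metadata <- function(series_sizes) {
  rows <- lapply(c("AL", "AD", "LL", "LD"), function(s) {
    n <- series_sizes[[s]]
    info <- .SERIES_TABLE[.SERIES_TABLE$series == s, ]
    data.frame(sample_id = paste0(s, seq_len(n)),
               medium = info$medium, light = info$light, series = s,
               strain = if (s == "LD") "4A+" else "137C",
               source_lab = if (s == "LD") "lab_B" else "lab_A",
               stringsAsFactors = FALSE)
  })
  md <- do.call(rbind, rows)
  rownames(md) <- md$sample_id
  md
}

# Remove the components of v along each row of basis (rows assumed nonzero).
.project_out <- function(v, basis) {
  for (j in seq_len(nrow(basis))) {
    b <- basis[j, ]
    v <- v - sum(v * b) / sum(b * b) * b
  }
  v
}

# Adjust only the non-fixed coordinates of v so that sum(v) = 0 and
# v is orthogonal to `partner` (if given), leaving v[fixed] untouched.
# Corrections are exact (closed form), so planted discordant samples can
# coexist with an exactly orthogonal multiplier basis.
.constrain_row <- function(v, fixed = integer(0), partner = NULL) {
  u <- rep(1, length(v)); u[fixed] <- 0
  v <- v - u * (sum(v) / sum(u))
  if (!is.null(partner)) {
    w <- partner; w[fixed] <- 0
    w <- w - u * (sum(w) / sum(u))       # keeps the zero-sum correction space
    denom <- sum(w * partner)
    if (abs(denom) > 1e-12) {
      v <- v - w * (sum(v * partner) / denom)
    }
  }
  v
}

# Scale a vector so max - min equals target (pure scaling preserves
# orthogonality).
.scale_to_range <- function(v, target) {
  r <- max(v) - min(v)
  if (r == 0) stop("cannot scale a constant vector to a nonzero range")
  v * target / r
}

#' Generate a synthetic expression dataset with known truth
#'
#' @param cfg a [synthetic_config()].
#' @return an object of class `synthetic_dataset`: a list with `data` (a
#'   `SummarizedExperiment`, assay `fpkm`), `gene_sets` (gene-to-pathway
#'   mapping data.frame) and `truth` (planted `G` N x 3, `lambda` 3 x Ns,
#'   `metadata`, marker and enriched-pathway ids per phenotype, and the
#'   config).
#' @export
generate_dataset <- function(cfg) {
  if (!inherits(cfg, "synthetic_config")) stop("cfg must be a synthetic_config")
  set.seed(cfg$seed)
  md <- .synthetic_metadata(cfg$series_sizes)
  n <- cfg$n_genes
  n_s <- nrow(md)
  gene_ids <- sprintf("gene_%05d", seq_len(n))

  bad_disc <- setdiff(c(cfg$discordant_medium, cfg$discordant_light), md$sample_id)
  if (length(bad_disc) > 0) {
    stop("discordant sample(s) not in the design: ", paste(bad_disc, collapse = ", "))
  }

  ## --- planted gene weights -------------------------------------------------
  phenotypes <- c("agar", "liquid", "dark", "light")
  marker_idx <- split(sample.int(n, 4 * cfg$n_markers_per_phenotype),
                      rep(phenotypes, each = cfg$n_markers_per_phenotype))
  mu <- cfg$marker_strength
  strong <- function(m) abs(stats::rnorm(m, mean = mu, sd = 0.25 * mu)) + 0.5 * mu
  g0_raw <- stats::runif(n, 1, 2)
  g1_raw <- stats::rnorm(n)
  g1_raw[marker_idx$liquid] <- strong(cfg$n_markers_per_phenotype)
  g1_raw[marker_idx$agar] <- -strong(cfg$n_markers_per_phenotype)
  g2_raw <- stats::rnorm(n)
  g2_raw[marker_idx$light] <- strong(cfg$n_markers_per_phenotype)
  g2_raw[marker_idx$dark] <- -strong(cfg$n_markers_per_phenotype)
  qr_fit <- qr(cbind(g0_raw, g1_raw, g2_raw))
  G <- qr.Q(qr_fit)
  # align each orthonormal column with its raw direction
  for (j in 1:3) {
    raw <- list(g0_raw, g1_raw, g2_raw)[[j]]
    if (sum(G[, j] * raw) < 0) G[, j] <- -G[, j]
  }
  dimnames(G) <- list(gene_ids, paste0("G_", 0:2))

  ## --- planted multipliers --------------------------------------------------
  # lam1 and lam2 are built exactly mean-zero and mutually orthogonal, so the
  # near-constant balance row is orthogonal to both by construction and the
  # planted factors are the exact SVD components of the noise-free matrix.
  is_agar <- md$medium == "agar"
  is_dark <- md$light == "dark"
  disc_m <- which(md$sample_id %in% cfg$discordant_medium)
  disc_l <- which(md$sample_id %in% cfg$discordant_light)
  jit <- function(m) 1 + stats::runif(m, -0.1, 0.1)
  # constraint 1: agar negative, liquid positive; discordant samples get a
  # small opposite-sign value; remaining coordinates absorb the zero-mean
  # correction so the row stays orthogonal to the constant balance direction
  lam1 <- numeric(n_s)
  lam1[is_agar] <- -jit(sum(is_agar))
  lam1[!is_agar] <- (sum(is_agar) / sum(!is_agar)) * jit(sum(!is_agar))
  lam1[disc_m] <- 0.01 * (max(lam1) - min(lam1))
  lam1 <- .constrain_row(lam1, fixed = disc_m)
  lam1 <- .scale_to_range(lam1, cfg$lambda1_range)
  # constraint 2: dark negative, light positive; zero mean and exactly
  # orthogonal to lam1, again without touching its discordant samples
  lam2 <- numeric(n_s)
  lam2[is_dark] <- -jit(sum(is_dark))
  lam2[!is_dark] <- (sum(is_dark) / sum(!is_dark)) * jit(sum(!is_dark))
  lam2[disc_l] <- -0.015 * (max(lam2) - min(lam2))
  lam2 <- .constrain_row(lam2, fixed = disc_l, partner = lam1)
  lam2 <- .scale_to_range(lam2, cfg$lambda2_range)
  # balance state: a positive constant (orthogonal to the mean-zero
  # constraints) plus a small jitter projected into their orthocomplement;
  # only the jitter is scaled, so the range is exact and the mean stable
  lam0_bar <- cfg$balance_level / mean(G[, 1])
  jitter0 <- stats::runif(n_s, -1, 1)
  jitter0 <- .project_out(jitter0 - mean(jitter0), rbind(lam1, lam2))
  lam0 <- lam0_bar + .scale_to_range(jitter0, cfg$lambda0_range)
  lambda <- rbind(lambda_0 = lam0, lambda_1 = lam1, lambda_2 = lam2)
  colnames(lambda) <- md$sample_id
  if (any(lam0 <= 0)) stop("internal error: balance multiplier not positive")
  omegas <- sqrt(rowSums(lambda^2))
  if (!(omegas[1] > omegas[2] && omegas[2] > omegas[3])) {
    stop("planted component norms must decrease with alpha; adjust the ranges")
  }

  ## --- assemble matrix ------------------------------------------------------
  ln_x <- G %*% lambda
  if (cfg$noise_sd > 0) {
    ln_x <- ln_x + matrix(stats::rnorm(n * n_s, sd = cfg$noise_sd), n, n_s)
  }
  fpkm <- exp(ln_x)
  n_lifted <- 0L
  if (cfg$ensure_filter_pass) {
    agar_ids <- md$sample_id[is_agar]
    m_ref <- rowMeans(fpkm[, agar_ids, drop = FALSE])
    lift_to <- 1.05 * cfg$filter_threshold
    low <- m_ref < lift_to
    n_lifted <- sum(low)
    if (n_lifted > 0) {
      fpkm[low, ] <- fpkm[low, ] * (lift_to / m_ref[low])
    }
  }

  ## --- pathway planting -----------------------------------------------------
  pathway_ids <- sprintf("path_%03d", seq_len(cfg$n_pathways))
  enriched <- split(pathway_ids[seq_len(4 * cfg$n_enriched_per_phenotype)],
                    rep(phenotypes, each = cfg$n_enriched_per_phenotype))
  background_pool <- setdiff(seq_len(n), unlist(marker_idx))
  n_from_markers <- round(cfg$marker_fraction * cfg$pathway_size)
  mapping <- do.call(rbind, lapply(pathway_ids, function(pid) {
    ph <- names(enriched)[vapply(enriched, function(e) pid %in% e, logical(1))]
    if (length(ph) == 1) {
      genes <- c(sample(marker_idx[[ph]], n_from_markers),
                 sample(background_pool, cfg$pathway_size - n_from_markers))
    } else {
      genes <- sample.int(n, cfg$pathway_size)
    }
    data.frame(gene_id = gene_ids[genes], pathway_id = pid,
               pathway_name = paste0("synthetic pathway ", pid),
               stringsAsFactors = FALSE)
  }))

  se <- expression_dataset(fpkm, md)
  truth <- list(G = G, lambda = lambda, metadata = md,
                markers = lapply(marker_idx, function(ix) gene_ids[ix]),
                enriched_pathways = enriched,
                n_baseline_lifted = n_lifted,
                noise_sd = cfg$noise_sd, seed = cfg$seed, config = cfg)
  structure(list(data = se, gene_sets = mapping, truth = truth),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("Synthetic dataset: %d genes x %d samples, noise sd %g, seed %d\n",
              nrow(x$data), ncol(x$data), x$truth$noise_sd, x$truth$seed))
  cat(sprintf("  %d pathways (%d enriched), %d marker genes per phenotype\n",
              x$truth$config$n_pathways, 4 * x$truth$config$n_enriched_per_phenotype,
              x$truth$config$n_markers_per_phenotype))
  invisible(x)
}

#' Compare a decomposition (and optional rankings) against planted truth
#'
#' @param truth the `truth` element of a `synthetic_dataset`.
#' @param d a `surprisal_decomposition` of the same gene/sample universe.
#' @param sets optional `pathway_sets` built from the dataset's mapping; when
#'   supplied, the fraction of planted enriched pathways recovered in the
#'   top-k set-ratio rankings is reported.
#' @param top_k ranking depth for pathway recovery (default 10).
#' @return list with `g_correlation` and `lambda_correlation` (absolute
#'   Pearson correlation per component after sign alignment),
#'   `sign_concordance` (fraction of samples whose lambda_1/lambda_2 sign
#'   matches the planted sign, orientation-free) and `pathway_recovery`
#'   (per-phenotype fractions, or NULL).
#' @export
recovery_report <- function(truth, d, sets = NULL, top_k = 10) {
  if (!identical(rownames(truth$G), d$gene_ids) ||
      !identical(colnames(truth$lambda), d$sample_ids)) {
    stop("gene/sample universe of the decomposition does not match the truth")
  }
  g_cor <- vapply(1:3, function(j) abs(stats::cor(truth$G[, j], d$G[, j])),
                  numeric(1))
  l_cor <- vapply(1:3, function(j) abs(stats::cor(truth$lambda[j, ], d$lambda[j, ])),
                  numeric(1))
  names(g_cor) <- names(l_cor) <- paste0("alpha_", 0:2)
  conc <- vapply(2:3, function(j) {
    agree <- mean(sign(truth$lambda[j, ]) == sign(d$lambda[j, ]))
    max(agree, 1 - agree)     # orientation-free
  }, numeric(1))
  names(conc) <- c("medium", "light")
  pathway_recovery <- NULL
  if (!is.null(sets)) {
    sc1 <- pathway_weights(d, sets, 1)
    sc2 <- pathway_weights(d, sets, 2)
    top <- list(
      liquid = rank_pathways(sc1, "high_SR", top_k)$pathway_id,
      agar = rank_pathways(sc1, "low_SR", top_k)$pathway_id,
      light = rank_pathways(sc2, "high_SR", top_k)$pathway_id,
      dark = rank_pathways(sc2, "low_SR", top_k)$pathway_id
    )
    pathway_recovery <- vapply(names(top), function(ph) {
      planted <- truth$enriched_pathways[[ph]]
      mean(planted %in% top[[ph]])
    }, numeric(1))
  }
  list(g_correlation = g_cor, lambda_correlation = l_cor,
       sign_concordance = conc, pathway_recovery = pathway_recovery)
}

#' Write a synthetic dataset to delimited text files
#'
#' Writes `matrix.csv`, `metadata.csv`, `gene_sets.tsv` and
#' `truth_lambda.csv` / `truth_g.csv` to a directory, in the formats
#' [load_expression()] and [load_gene_sets()] read back.
#'
#' @param ds a `synthetic_dataset`.
#' @param dir output directory (created if needed).
#' @return invisibly, the file paths.
#' @export
write_synthetic_dataset <- function(ds, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fpkm <- SummarizedExperiment::assay(ds$data, "fpkm")
  paths <- c(matrix = file.path(dir, "matrix.csv"),
             metadata = file.path(dir, "metadata.csv"),
             gene_sets = file.path(dir, "gene_sets.tsv"),
             truth_lambda = file.path(dir, "truth_lambda.csv"),
             truth_g = file.path(dir, "truth_g.csv"))
  utils::write.csv(data.frame(gene_id = rownames(fpkm), fpkm,
                              check.names = FALSE),
                   paths["matrix"], row.names = FALSE)
  utils::write.csv(ds$truth$metadata, paths["metadata"], row.names = FALSE)
  utils::write.table(ds$gene_sets, paths["gene_sets"], sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.csv(data.frame(sample_id = colnames(ds$truth$lambda),
                              t(ds$truth$lambda)),
                   paths["truth_lambda"], row.names = FALSE)
  utils::write.csv(data.frame(gene_id = rownames(ds$truth$G), ds$truth$G),
                   paths["truth_g"], row.names = FALSE)
  invisible(paths)
}
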