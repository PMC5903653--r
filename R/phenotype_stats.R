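# Quantifying how a constraint's Lagrange multipliers separate sample groups.

#' Sign partition of multipliers by sample group
#'
#' Tallies, per group, how many lambda values are negative, positive or
#' exactly zero, and lists discordant samples (minority sign within a group).
#'
#' @param lam named numeric vector of lambda values (names = sample ids).
#' @param labels character vector of group labels, parallel to `lam` (or
#'   named by sample id).
#' @return a data.frame with one row per group (`group`, `n`, `n_negative`,
#'   `n_positive`, `n_zero`, `discordant` as a comma-separated id list).
#' @export
sign_partition <- function(lam, labels) {
  if (length(labels) != length(lam)) {
    stop("every sample needs a group label")
  }
  if (!is.null(names(labels)) && !is.null(names(lam))) {
    if (!all(names(lam) %in% names(labels))) {
      stop("label missing for sample(s): ",
           paste(setdiff(names(lam), names(labels)), collapse = ", "))
    }
    labels <- labels[names(lam)]
  }
  if (anyNA(labels)) stop("label missing for one or more samples")
  groups <- split(lam, labels)
  out <- do.call(rbind, lapply(names(groups), function(g) {
    v <- groups[[g]]
    n_neg <- sum(v < 0); n_pos <- sum(v > 0); n_zero <- sum(v == 0)
    # minority sign within the group marks discordant samples
    disc <- character(0)
    if (n_neg > 0 && n_pos > 0) {
      minority_sign <- if (n_neg < n_pos) -1 else 1
      disc <- names(v)[sign(v) == minority_sign]
    }
    data.frame(group = g, n = length(v), n_negative = n_neg,
               n_positive = n_pos, n_zero = n_zero,
               discordant = paste(disc, collapse = ","),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- out$group
  out
}

#' Spread of a multiplier row
#'
#' @param lam numeric vector of lambda values.
#' @return `max(lam) - min(lam)` in natural-log units.
#' @export
lambda_range <- function(lam) {
  if (length(lam) == 0) stop("empty lambda vector")
  if (anyNA(lam)) stop("lambda vector contains missing values")
  max(lam) - min(lam)
}

#' Rank-based group separation test
#'
#' Two-sided Wilcoxon rank-sum (Mann-Whitney) test of the lambda values of
#' two disjoint sample groups. The exact distribution is used for combined
#' n <= 20 without ties; otherwise the normal approximation with continuity
#' correction. Also reports the sign tallies, the overall spread, and the gap
#' between the two groups' value ranges (positive iff the groups separate
#' completely).
#'
#' @param lam named numeric vector of lambda values.
#' @param group_a,group_b disjoint non-empty character vectors of sample ids.
#' @param threshold significance level for the `separated` flag (default 0.05).
#' @param labels optional pair of group names for printing.
#' @return an object of class `group_separation`.
#' @export
group_separation_test <- function(lam, group_a, group_b, threshold = 0.05,
                                  labels = c("group_a", "group_b")) {
  if (length(group_a) == 0 || length(group_b) == 0) {
    stop("both groups must be non-empty")
  }
  if (length(intersect(group_a, group_b)) > 0) {
    stop("groups overlap: ", paste(intersect(group_a, group_b), collapse = ", "))
  }
  absent <- setdiff(c(group_a, group_b), names(lam))
  if (length(absent) > 0) stop("no lambda value for sample(s): ",
                               paste(absent, collapse = ", "))
  va <- lam[group_a]; vb <- lam[group_b]
  n_total <- length(va) + length(vb)
  has_ties <- anyDuplicated(c(va, vb)) > 0
  use_exact <- n_total <= 20 && !has_ties
  p <- suppressWarnings(
    stats::wilcox.test(va, vb, alternative = "two.sided",
                       exact = use_exact, correct = TRUE)$p.value
  )
  gap <- max(min(va) - max(vb), min(vb) - max(va))
  structure(
    list(labels = labels,
         group_a = group_a, group_b = group_b,
         counts = sign_partition(c(va, vb),
                                 c(rep(labels[1], length(va)),
                                   rep(labels[2], length(vb)))),
         range_all = lambda_range(c(va, vb)),
         gap = gap,
         p_value = p,
         threshold = threshold,
         separated = p < threshold,
         exact = use_exact),
    class = "group_separation"
  )
}

#' @export
print.group_separation <- function(x, ...) {
  cat(sprintf("Wilcoxon rank-sum: %s (n=%d) vs %s (n=%d)\n",
              x$labels[1], length(x$group_a), x$labels[2], length(x$group_b)))
  cat(sprintf("  p = %.3g (%s), separated at %g: %s\n",
              x$p_value, if (x$exact) "exact" else "normal approx.",
              x$threshold, x$separated))
  cat(sprintf("  overall range = %.2f, inter-group gap = %.2f\n",
              x$range_all, x$gap))
  invisible(x)
}

#' Phenotype separation summary for an oriented decomposition
#'
#' Runs [group_separation_test()] for constraint 1 (agar vs liquid) and
#' constraint 2 (dark vs light), and reports the spreads of lambda_0,
#' lambda_1 and lambda_2.
#'
#' @param d an oriented `surprisal_decomposition` carrying metadata.
#' @param metadata optional metadata `data.frame` overriding `d$metadata`.
#' @param threshold significance level (default 0.05).
#' @return a list with `medium` and `light` (`group_separation` objects),
#'   `ranges` (named vector for alpha 0..2) and `partitions` (sign tallies).
#' @export
phenotype_separation <- function(d, metadata = NULL, threshold = 0.05) {
  md <- if (is.null(metadata)) d$metadata else metadata
  if (is.null(md)) stop("sample metadata required")
  agar <- md$sample_id[md$medium == "agar"]
  liquid <- md$sample_id[md$medium == "liquid"]
  dark <- md$sample_id[md$light == "dark"]
  light <- md$sample_id[md$light == "light"]
  medium_sep <- group_separation_test(d$lambda[2, ], agar, liquid, threshold,
                                      labels = c("agar", "liquid"))
  light_sep <- group_separation_test(d$lambda[3, ], dark, light, threshold,
                                     labels = c("dark", "light"))
  ranges <- c(lambda_0 = lambda_range(d$lambda[1, ]),
              lambda_1 = lambda_range(d$lambda[2, ]),
              lambda_2 = lambda_range(d$lambda[3, ]))
  partitions <- list(
    medium = sign_partition(d$lambda[2, ], stats::setNames(md$medium, md$sample_id)),
    light = sign_partition(d$lambda[3, ], stats::setNames(md$light, md$sample_id))
  )
  list(medium = medium_sep, light = light_sep, ranges = ranges,
       partitions = partitions)
}
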