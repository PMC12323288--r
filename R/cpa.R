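#' Per-bin paired t statistics and observed clusters
#'
#' For one group, compares participant-level trial-averaged fixation
#' proportions between a condition and the unrelated distractor with a
#' two-sided paired t-test in every 50-ms bin, then forms clusters as
#' maximal runs of two or more adjacent supra-threshold bins with effects
#' in the same direction. The cluster statistic is the sum of the member
#' bins' t values (sum-t).
#'
#' @param tensor Occupancy tensor.
#' @param comparison Condition compared against `unrelated` (`"target"`,
#'   `"agent_related"` or `"action_related"`).
#' @param group Group label.
#' @param alpha Cluster-forming threshold (two-sided), default 0.05.
#' @param bin_width_ms Bin width.
#' @return List with `bins` (tibble `bin`, `time_ms`, `t`, `df`, `supra`,
#'   `sign`) and `clusters` (tibble `comparison`, `group`, `start_ms`,
#'   `end_ms` — bin centres of the first/last member — `n_bins`, `sum_t`).
#'   Bins with zero within-pair variance get `NA` t and are excluded from
#'   clustering with a warning.
#' @export
cluster_stats <- function(tensor, comparison = "target", group,
                          alpha = 0.05, bin_width_ms = 50) {
  pc <- prop_matrix(tensor, comparison, group)
  pu <- prop_matrix(tensor, "unrelated", group)
  n <- nrow(pc)
  if (n < 3) stop("cluster_stats needs at least 3 participants, got ", n)
  d <- pc - pu
  tt <- paired_t_by_bin(d)
  if (anyNA(tt)) {
    warning(sum(is.na(tt)), " bin(s) with zero within-pair variance ",
            "excluded from clustering")
  }
  crit <- stats::qt(1 - alpha / 2, df = n - 1)
  supra <- !is.na(tt) & abs(tt) > crit
  bins <- as.integer(colnames(pc))
  bin_tbl <- tibble::tibble(
    bin = bins, time_ms = bins * bin_width_ms + bin_width_ms / 2,
    t = unname(tt), df = n - 1, supra = unname(supra),
    sign = sign(unname(tt))
  )
  clusters <- find_clusters(tt, supra, bins, bin_width_ms)
  clusters$comparison <- comparison
  clusters$group <- group
  list(bins = bin_tbl,
       clusters = clusters[, c("comparison", "group", "start_ms", "end_ms",
                               "n_bins", "sum_t")])
}

# Column-wise one-sample t statistics of a participants x bins difference
# matrix; NA where the column SD is zero.
paired_t_by_bin <- function(d) {
  n <- nrow(d)
  mu <- colMeans(d)
  sdv <- sqrt(pmax(colSums(d^2) - n * mu^2, 0) / (n - 1))
  t <- mu / (sdv / sqrt(n))
  t[sdv < 1e-12] <- NA_real_
  t
}

# Largest |sum of t| over runs of >= 2 adjacent supra-threshold same-sign
# bins; 0 when no cluster forms. Lean path for the permutation loop.
max_cluster_sum <- function(tt, crit) {
  lab <- ifelse(abs(tt) > crit, sign(tt), 0)
  r <- rle(lab)
  keep <- r$values != 0 & r$lengths >= 2
  if (!any(keep)) return(0)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  max(vapply(which(keep),
             function(i) abs(sum(tt[starts[i]:ends[i]])), 0))
}

# Maximal runs of >= 2 adjacent supra-threshold same-sign bins.
find_clusters <- function(tt, supra, bins, bin_width_ms) {
  lab <- ifelse(supra, sign(tt), 0)
  lab[is.na(lab)] <- 0
  r <- rle(lab)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- which(r$values != 0 & r$lengths >= 2)
  tibble::tibble(
    start_ms = bins[starts[keep]] * bin_width_ms + bin_width_ms / 2,
    end_ms = bins[ends[keep]] * bin_width_ms + bin_width_ms / 2,
    n_bins = r$lengths[keep],
    sum_t = unname(vapply(keep, function(i) sum(tt[starts[i]:ends[i]]), 0))
  )
}

#' Cluster-based permutation test
#'
#' Attaches permutation p-values to the observed clusters of
#' [cluster_stats()]. The null distribution is built by independently
#' flipping the sign of each participant's whole difference series
#' (condition minus unrelated) — the exact permutation scheme for a paired,
#' within-participant comparison — recomputing the clusters, and recording
#' the maximal absolute sum-t per permutation (family-wise max-statistic
#' construction). Each observed cluster's p-value is
#' `(1 + #\{perm max >= |sum_t|\}) / (n_perm + 1)`.
#'
#' @inheritParams cluster_stats
#' @param n_perm Number of permutations, default 1000.
#' @param seed Integer seed.
#' @return Tibble of clusters with `p` and `n_perm` columns appended,
#'   plus attributes `bins` (the per-bin test series) and `perm_max`
#'   (the null distribution).
#' @export
permutation_test <- function(tensor, comparison = "target", group,
                             n_perm = 1000, seed = 1, alpha = 0.05,
                             bin_width_ms = 50) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  obs <- cluster_stats(tensor, comparison, group, alpha, bin_width_ms)
  pc <- prop_matrix(tensor, comparison, group)
  pu <- prop_matrix(tensor, "unrelated", group)
  d <- pc - pu
  n <- nrow(d)
  crit <- stats::qt(1 - alpha / 2, df = n - 1)
  zero_var <- is.na(paired_t_by_bin(d))
  sumsq <- colSums(d^2)
  perm_max <- withr::with_seed(as.integer(seed), {
    signs <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), n_perm, n)
    m <- (signs %*% d) / n
    varm <- sweep(-n * m^2, 2, sumsq, "+") / (n - 1)
    tmat <- m / sqrt(varm / n)
    tmat[!is.finite(tmat)] <- 0
    tmat[, zero_var] <- 0
    apply(tmat, 1, max_cluster_sum, crit = crit)
  })
  out <- obs$clusters
  out$p <- vapply(out$sum_t, function(s) {
    (1 + sum(perm_max >= abs(s))) / (n_perm + 1)
  }, 0)
  out$n_perm <- n_perm
  attr(out, "bins") <- obs$bins
  attr(out, "perm_max") <- perm_max
  out
}

#' Run the cluster permutation analysis for all comparisons and groups
#'
#' @param tensor Occupancy tensor.
#' @param comparisons Conditions compared against `unrelated`.
#' @param groups Group labels (default: all in the tensor).
#' @inheritParams permutation_test
#' @return Tibble of all clusters across comparisons and groups.
#' @export
cpa_analysis <- function(tensor,
                         comparisons = c("target", "agent_related",
                                         "action_related"),
                         groups = NULL, n_perm = 1000, seed = 1,
                         alpha = 0.05) {
  if (is.null(groups)) groups <- unique(tensor$group)
  res <- list()
  for (g in groups) {
    for (cmp in comparisons) {
      r <- permutation_test(tensor, cmp, g, n_perm = n_perm,
                            seed = seed + match(cmp, comparisons),
                            alpha = alpha)
      attr(r, "bins") <- NULL
      attr(r, "perm_max") <- NULL
      res[[length(res) + 1]] <- r
    }
  }
  dplyr::bind_rows(res)
}
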