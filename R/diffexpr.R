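#' Pairwise Wilcoxon differential expression
#'
#' Per gene, a two-sided Wilcoxon rank-sum test between two cell groups
#' on log-space expression, Bonferroni-adjusted across the genes tested.
#' The log2 fold change is the difference of group means in
#' log2((TPM/10)+1) space. A gene is significantly up in A when the
#' adjusted p is below `alpha` and the fold change strictly exceeds
#' `lfc_min`.
#'
#' @param m log-space [expr_matrix()].
#' @param group_a,group_b cell ids of the two groups (>= 3 cells each).
#' @param lfc_min minimum log2 fold change, strict (default 0.5).
#' @param alpha adjusted-p threshold (default 0.05).
#' @param comparison label stored with the results.
#' @return Tibble with `gene_id`, `log2_fold_change`, `raw_p`,
#'   `adjusted_p`, `direction`, `significant_up`, `comparison`.
#' @export
pairwise_de_wilcoxon <- function(m, group_a, group_b, lfc_min = 0.5,
                                 alpha = 0.05,
                                 comparison = "A_vs_B") {
  assert_space(m, "log", "pairwise_de_wilcoxon()")
  if (length(group_a) < 3 || length(group_b) < 3) {
    abort("Each group needs at least 3 cells.")
  }
  va <- unclass(m)[group_a, , drop = FALSE]
  vb <- unclass(m)[group_b, , drop = FALSE]
  raw_p <- vapply(seq_len(ncol(va)), function(j) {
    suppressWarnings(wilcox.test(va[, j], vb[, j])$p.value)
  }, numeric(1))
  raw_p[is.na(raw_p)] <- 1 # constant genes carry no evidence
  lfc <- colMeans(va) - colMeans(vb)
  adj <- p.adjust(raw_p, method = "bonferroni")
  tibble(
    gene_id = gene_ids(m),
    log2_fold_change = unname(lfc),
    raw_p = raw_p,
    adjusted_p = adj,
    direction = ifelse(lfc >= 0, "up", "down"),
    significant_up = adj < alpha & lfc > lfc_min,
    comparison = comparison
  )
}

#' Cluster-specific genes by pairwise intersection
#'
#' A gene is specific to the focal cluster when it is significantly
#' upregulated (Bonferroni-adjusted Wilcoxon p < `alpha`, log2 fold
#' change > `lfc_min`) in the focal cluster versus EVERY other cluster.
#'
#' @param m log-space [expr_matrix()].
#' @param cluster_labels named vector, cell id -> cluster.
#' @param focal_cluster the cluster whose specific genes are sought.
#' @param lfc_min,alpha as in [pairwise_de_wilcoxon()].
#' @return Tibble of specific genes with their weakest fold change and
#'   largest adjusted p across comparisons; the full per-comparison
#'   table is attached as attribute `"comparisons"`.
#' @export
specific_degs <- function(m, cluster_labels, focal_cluster, lfc_min = 0.5,
                          alpha = 0.05) {
  clusters <- unique(cluster_labels)
  if (length(clusters) < 2) abort("Need at least 2 clusters.")
  if (!focal_cluster %in% clusters) abort("Unknown focal cluster.")
  focal_cells <- names(cluster_labels)[cluster_labels == focal_cluster]
  others <- setdiff(clusters, focal_cluster)
  per_comp <- purrr::map_dfr(others, function(cl) {
    pairwise_de_wilcoxon(
      m, focal_cells, names(cluster_labels)[cluster_labels == cl],
      lfc_min = lfc_min, alpha = alpha,
      comparison = paste0(focal_cluster, "_vs_", cl)
    )
  })
  specific <- per_comp |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(
      min_log2_fold_change = min(.data$log2_fold_change),
      max_adjusted_p = max(.data$adjusted_p),
      in_all = all(.data$significant_up)
    ) |>
    dplyr::filter(.data$in_all) |>
    dplyr::select(-"in_all")
  attr(specific, "comparisons") <- per_comp
  specific
}

#' Recurrently differential genes against every other sample
#'
#' For each gene and each non-focal sample, a two-sided Welch t-test and
#' a log2 fold change (focal minus other, in log space). A gene is
#' returned when, in ALL pairwise comparisons, the unadjusted p is below
#' `alpha` and the fold change is at least `lfc_min` (direction
#' `"up"`) or at most `-lfc_min` (direction `"down"`).
#'
#' @param m log-space [expr_matrix()].
#' @param sample_labels named vector, cell id -> sample.
#' @param focal_sample the sample of interest.
#' @param lfc_min minimum absolute log2 fold change, inclusive
#'   (default 1).
#' @param alpha unadjusted-p threshold (default 0.05).
#' @param direction `"up"` (default) or `"down"`.
#' @return Tibble of recurrent genes with their weakest fold change and
#'   largest p across the comparisons.
#' @export
recurrent_pairwise_de <- function(m, sample_labels, focal_sample,
                                  lfc_min = 1, alpha = 0.05,
                                  direction = c("up", "down")) {
  direction <- match.arg(direction)
  samples <- unique(sample_labels)
  if (length(samples) < 2) abort("Need at least 2 samples.")
  if (!focal_sample %in% samples) abort("Unknown focal sample.")
  focal_cells <- names(sample_labels)[sample_labels == focal_sample]
  if (length(focal_cells) < 3) abort("Focal sample needs >= 3 cells.")
  vf <- unclass(m)[focal_cells, , drop = FALSE]
  per_comp <- purrr::map_dfr(setdiff(samples, focal_sample), function(s) {
    cells <- names(sample_labels)[sample_labels == s]
    if (length(cells) < 3) abort(sprintf("Sample %s needs >= 3 cells.", s))
    vo <- unclass(m)[cells, , drop = FALSE]
    p <- vapply(seq_len(ncol(vf)), function(j) {
      if (sd(vf[, j]) == 0 && sd(vo[, j]) == 0) return(1)
      t.test(vf[, j], vo[, j])$p.value
    }, numeric(1))
    tibble(
      gene_id = gene_ids(m),
      log2_fold_change = unname(colMeans(vf) - colMeans(vo)),
      raw_p = p, other_sample = s
    )
  })
  passes <- if (direction == "up") {
    per_comp$log2_fold_change >= lfc_min & per_comp$raw_p < alpha
  } else {
    per_comp$log2_fold_change <= -lfc_min & per_comp$raw_p < alpha
  }
  per_comp |>
    dplyr::mutate(pass = passes) |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(
      min_abs_log2_fold_change = min(abs(.data$log2_fold_change)),
      max_raw_p = max(.data$raw_p),
      in_all = all(.data$pass)
    ) |>
    dplyr::filter(.data$in_all) |>
    dplyr::select(-"in_all")
}
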