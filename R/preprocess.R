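#' Quality-control filter on a raw expression matrix
#'
#' Keeps cells detecting at least `min_genes` genes (value > 0) AND with a
#' mitochondrial read fraction strictly below `max_mito`, AND not listed in
#' `exclude`. Mitochondrial genes are identified by a gene-name prefix.
#' An exclusion list reproduces curation steps (e.g. doublet clusters)
#' that are outside the scope of automatic QC.
#'
#' @param m raw-space [expr_matrix()].
#' @param min_genes minimum detected genes per cell (default 1000).
#' @param max_mito maximum mitochondrial fraction, exclusive (default 0.30).
#' @param mito_prefix gene-name prefix marking mitochondrial genes
#'   (default `"MT-"`).
#' @param exclude optional character vector of cell ids to drop.
#' @return List with `expr` (filtered matrix) and `report` (tibble of
#'   per-criterion removal counts; criteria are not mutually exclusive).
#' @export
qc_filter <- function(m, min_genes = 1000, max_mito = 0.30,
                      mito_prefix = "MT-", exclude = NULL) {
  assert_space(m, "raw", "qc_filter()")
  stopifnot(min_genes >= 0, max_mito >= 0, max_mito <= 1)
  detected <- rowSums(m > 0)
  mito <- startsWith(gene_ids(m), mito_prefix)
  total <- rowSums(m)
  mito_frac <- if (any(mito)) {
    ifelse(total > 0, rowSums(m[, mito, drop = FALSE]) / total, 0)
  } else {
    rep(0, nrow(m))
  }
  excluded <- cell_ids(m) %in% (exclude %||% character())
  fail_genes <- detected < min_genes
  fail_mito <- mito_frac >= max_mito
  keep <- !excluded & !fail_genes & !fail_mito
  if (!any(keep)) abort("No cells pass QC.")
  report <- tibble(
    criterion = c("input", "excluded", "min_genes", "mito_fraction", "kept"),
    cells = c(nrow(m), sum(excluded), sum(fail_genes), sum(fail_mito),
              sum(keep))
  )
  list(expr = m[keep, , drop = FALSE], report = report)
}

#' Log-transform TPM-like values
#'
#' Applies `v -> log2(v/10 + 1)`, the transform under which all downstream
#' filtering, centering and CNA smoothing operate.
#'
#' @param m raw-space [expr_matrix()].
#' @return Log-space [expr_matrix()].
#' @examples
#' m <- expr_matrix(matrix(c(0, 10, 30, 70), 2, 2,
#'   dimnames = list(c("a", "b"), c("g1", "g2"))), "raw")
#' log_transform(m)[, ]
#' @export
log_transform <- function(m) {
  assert_space(m, "raw", "log_transform()")
  expr_matrix(log2(unclass(m) / 10 + 1), "log")
}

#' Invert the log transform
#' @param m log-space [expr_matrix()].
#' @return Raw-space [expr_matrix()].
#' @export
unlog_transform <- function(m) {
  assert_space(m, "log", "unlog_transform()")
  expr_matrix((2^unclass(m) - 1) * 10, "raw")
}

#' Keep genes expressed above a mean log threshold
#'
#' Retains genes whose mean log2 value across all cells of this matrix is
#' strictly greater than `cutoff`. The filter is applied per constructed
#' analysis matrix (e.g. patient cells plus pooled reference together),
#' not once globally.
#'
#' @param m log-space [expr_matrix()].
#' @param cutoff mean-log2 threshold (default 4.5).
#' @return Filtered matrix, gene order preserved.
#' @export
filter_genes <- function(m, cutoff = 4.5) {
  assert_space(m, "log", "filter_genes()")
  keep <- colMeans(m) > cutoff
  if (!any(keep)) abort("No genes exceed the expression cutoff.")
  m[, keep, drop = FALSE]
}

#' Mean-centre each gene
#'
#' Subtracts every gene's mean across the matrix's cells, so each column
#' averages zero. Centred relative expression is the input to genome
#' smoothing.
#'
#' @param m log-space [expr_matrix()].
#' @return Centered-space [expr_matrix()].
#' @export
center_genes <- function(m) {
  assert_space(m, "log", "center_genes()")
  v <- unclass(m)
  expr_matrix(sweep(v, 2, colMeans(v)), "centered")
}
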