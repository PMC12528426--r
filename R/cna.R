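#' Relative copy-number matrix
#'
#' Cells by genome-ordered positions of inferred relative copy-number
#' values; positions align with the annotation rows carried alongside.
#' Values strictly inside the noise band are exactly zero.
#'
#' @param values numeric matrix, cells x ordered positions, column names
#'   equal to the annotation's gene ids.
#' @param annotation annotation tibble restricted to the matrix's
#'   positions, in genome order.
#' @param params list of the parameters used (`clip_bound`, `window`,
#'   `noise_floor`, `gene_cutoff`).
#' @param reference description of the reference used (character or
#'   tibble).
#' @return A `cna_matrix` object.
#' @export
cna_matrix <- function(values, annotation, params = list(),
                       reference = NULL) {
  stopifnot(is.matrix(values), ncol(values) == nrow(annotation))
  if (!identical(colnames(values), annotation$gene_id)) {
    abort("Column names must match the annotation's gene ids, in order.")
  }
  structure(
    list(values = values, annotation = as_tibble(annotation),
         params = params, reference = reference),
    class = "cna_matrix"
  )
}

#' @export
print.cna_matrix <- function(x, ...) {
  cat(sprintf(
    "<cna_matrix> %d cells x %d positions (%d arms); %.1f%% nonzero\n",
    nrow(x$values), ncol(x$values), length(unique(x$annotation$arm)),
    100 * mean(x$values != 0)
  ))
  invisible(x)
}

#' @export
dim.cna_matrix <- function(x) dim(x$values)

#' Order matrix columns by genomic position
#'
#' Sorts genes by the annotation's genome-wide `order_index`
#' (chromosome, then start; coordinate ties broken by gene id). Genes
#' absent from the annotation are dropped with a warning; if fewer than
#' half the genes are annotated the call errors.
#'
#' @param m centered-space [expr_matrix()].
#' @param ann annotation tibble.
#' @return List with `expr` (genome-ordered matrix) and `annotation`
#'   (rows aligned to its columns).
#' @export
order_genes <- function(m, ann) {
  assert_space(m, "centered", "order_genes()")
  hit <- gene_ids(m) %in% ann$gene_id
  if (mean(hit) < 0.5) {
    abort("Fewer than 50% of matrix genes are annotated.")
  }
  if (!all(hit)) {
    warn(sprintf("%d unannotated gene(s) dropped.", sum(!hit)))
    m <- m[, hit, drop = FALSE]
  }
  sub <- ann[match(gene_ids(m), ann$gene_id), , drop = FALSE]
  ord <- order(sub$order_index)
  list(expr = m[, ord, drop = FALSE], annotation = as_tibble(sub[ord, ]))
}

#' Clip centred expression values
#'
#' Limits extreme relative-expression values to `[-clip_bound,
#' clip_bound]` so single outlier genes cannot dominate a smoothing
#' window.
#'
#' @param m numeric matrix (or [expr_matrix()]) of centred values.
#' @param clip_bound positive bound (default 3).
#' @return Matrix of the same shape.
#' @export
clip_values <- function(m, clip_bound = 3) {
  stopifnot(clip_bound > 0)
  pmin(pmax(unclass(m), -clip_bound), clip_bound)
}

#' Moving average along the genome
#'
#' For each cell, replaces the value at every position with the mean over
#' a centred window of up to `window` consecutive genes on the same
#' chromosome; windows are truncated at chromosome boundaries and never
#' span chromosomes. `window = 1` is the identity.
#'
#' @param m numeric matrix, cells x genome-ordered positions.
#' @param ann annotation aligned to the matrix columns (used for
#'   chromosome boundaries).
#' @param window window size in genes (default 100).
#' @return Smoothed matrix of identical shape.
#' @examples
#' ann <- build_genome_model(5, data.frame(arm = "1p", genes = 5))
#' m <- matrix(c(0, 3, 0, 3, 0), 1, dimnames = list("c", ann$gene_id))
#' moving_average(m, ann, window = 3) # 1.5 1 2 1 1.5
#' @export
moving_average <- function(m, ann, window = 100) {
  stopifnot(window >= 1)
  m <- unclass(m)
  if (nrow(ann) != ncol(m)) {
    abort("Annotation rows must align with matrix columns.")
  }
  left <- (window - 1L) %/% 2L
  right <- window %/% 2L
  out <- m
  for (cols in split(seq_len(ncol(m)), factor(ann$chromosome,
                                              unique(ann$chromosome)))) {
    L <- length(cols)
    if (L == 1) next # a single gene is its own window
    block <- m[, cols, drop = FALSE]
    cs <- cbind(0, t(apply(block, 1, cumsum)))
    j <- seq_len(L)
    lo <- pmax(1L, j - left)
    hi <- pmin(L, j + right)
    sums <- cs[, hi + 1L, drop = FALSE] - cs[, lo, drop = FALSE]
    out[, cols] <- sweep(sums, 2, hi - lo + 1L, "/")
  }
  out
}

#' Subtract the reference envelope
#'
#' Given per-reference-type mean smoothed profiles, subtracts at each
#' position the highest type mean from positive values and the lowest
#' from negative values. A value whose sign would flip is set to zero: a
#' deviation smaller than the reference envelope carries no copy-number
#' evidence.
#'
#' @param m smoothed matrix, cells x positions.
#' @param ref_profiles matrix of per-type mean smoothed profiles, types x
#'   positions (at least one row).
#' @return Reference-calibrated matrix.
#' @export
subtract_reference <- function(m, ref_profiles) {
  m <- unclass(m)
  if (is.null(dim(ref_profiles))) {
    ref_profiles <- matrix(ref_profiles, 1)
  }
  if (nrow(ref_profiles) < 1) abort("At least one reference type required.")
  if (ncol(ref_profiles) != ncol(m)) {
    abort("Reference profiles must cover the same positions.")
  }
  ref_max <- apply(ref_profiles, 2, max)
  ref_min <- apply(ref_profiles, 2, min)
  out <- matrix(0, nrow(m), ncol(m), dimnames = dimnames(m))
  pos <- m > 0
  neg <- m < 0
  shift_pos <- sweep(m, 2, ref_max)
  shift_neg <- sweep(m, 2, ref_min)
  out[pos] <- pmax(shift_pos[pos], 0)
  out[neg] <- pmin(shift_neg[neg], 0)
  out
}

#' Zero out sub-threshold values
#'
#' Values strictly between `-noise_floor` and `noise_floor` are assumed
#' to reflect noise and set to exactly zero; boundary values are kept.
#'
#' @param m reference-calibrated matrix.
#' @param noise_floor half-width of the open noise band (default 0.15).
#' @return Matrix with the noise band zeroed.
#' @export
apply_noise_floor <- function(m, noise_floor = 0.15) {
  stopifnot(noise_floor > 0)
  m <- unclass(m)
  m[abs(m) < noise_floor] <- 0
  m
}

#' Infer per-cell relative copy-number profiles
#'
#' Full pipeline on an assembled analysis matrix (target cells plus
#' reference): log transform if needed, gene filter, per-gene centering,
#' genome ordering, clipping, moving-average smoothing, subtraction of
#' the per-reference-type mean envelope, and noise flooring. The returned
#' matrix covers all cells, reference included.
#'
#' @param expr raw- or log-space [expr_matrix()] of the assembled matrix.
#' @param ann gene annotation tibble.
#' @param reference tibble (`cell_id`, `cell_type`) from
#'   [build_pooled_reference()], or a character vector of reference cell
#'   ids (treated as one type).
#' @param gene_cutoff mean-log2 expression filter (default 4.5).
#' @param clip_bound clipping bound on centred values (default 3).
#' @param window moving-average window in genes (default 100).
#' @param noise_floor half-width of the zeroed noise band (default 0.15).
#' @return A [cna_matrix()].
#' @export
infer_cna <- function(expr, ann, reference, gene_cutoff = 4.5,
                      clip_bound = 3, window = 100, noise_floor = 0.15) {
  ref_tbl <- if (is.character(reference)) {
    tibble(cell_id = reference, cell_type = "reference")
  } else {
    as_tibble(reference)[, c("cell_id", "cell_type")]
  }
  if (!nrow(ref_tbl)) abort("Empty reference.")
  missing <- setdiff(ref_tbl$cell_id, cell_ids(expr))
  if (length(missing)) {
    abort(sprintf("%d reference cell(s) absent from the matrix.",
                  length(missing)))
  }
  if (expr_space(expr) == "raw") expr <- log_transform(expr)
  m <- expr |>
    filter_genes(cutoff = gene_cutoff) |>
    center_genes()
  ordered <- order_genes(m, ann)
  v <- clip_values(ordered$expr, clip_bound)
  smoothed <- moving_average(v, ordered$annotation, window)
  ref_profiles <- do.call(rbind, lapply(
    split(ref_tbl$cell_id, ref_tbl$cell_type),
    function(ids) colMeans(smoothed[ids, , drop = FALSE])
  ))
  calibrated <- subtract_reference(smoothed, ref_profiles)
  floored <- apply_noise_floor(calibrated, noise_floor)
  cna_matrix(
    floored, ordered$annotation,
    params = list(
      gene_cutoff = gene_cutoff, clip_bound = clip_bound,
      window = window, noise_floor = noise_floor
    ),
    reference = ref_tbl
  )
}
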