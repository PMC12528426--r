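#' Expression matrix with an explicit value-space tag
#'
#' A thin matrix container used throughout the pipeline. Rows are cells,
#' columns are genes. The `space` tag records which transformations have
#' been applied so that each stage can assert its precondition:
#'
#' * `"raw"` — TPM-like non-negative values,
#' * `"log"` — `log2(v/10 + 1)` transformed,
#' * `"centered"` — log values mean-centred per gene.
#'
#' @param values numeric matrix, cells x genes, with unique row (cell) and
#'   column (gene) names.
#' @param space one of `"raw"`, `"log"`, `"centered"`.
#' @return An object of class `expr_matrix`.
#' @examples
#' m <- expr_matrix(matrix(1:6, 2, 3,
#'   dimnames = list(c("c1", "c2"), c("g1", "g2", "g3"))), "raw")
#' dim(m)
#' @export
expr_matrix <- function(values, space = c("raw", "log", "centered")) {
  space <- match.arg(space)
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("`values` must be a numeric matrix (cells x genes).")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    abort("`values` must carry cell (row) and gene (column) names.")
  }
  if (anyDuplicated(rownames(values))) abort("Duplicate cell ids.")
  if (anyDuplicated(colnames(values))) abort("Duplicate gene ids.")
  if (any(!is.finite(values))) abort("Expression values must be finite.")
  if (space == "raw" && any(values < 0)) {
    abort("Raw expression values must be non-negative.")
  }
  structure(values, space = space, class = c("expr_matrix", "matrix", "array"))
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf(
    "<expr_matrix> %d cells x %d genes, space = '%s'\n",
    nrow(x), ncol(x), expr_space(x)
  ))
  invisible(x)
}

#' Value space of an expression matrix
#' @param m an [expr_matrix()].
#' @return `"raw"`, `"log"` or `"centered"`.
#' @export
expr_space <- function(m) attr(m, "space") %||% "raw"

#' @export
`[.expr_matrix` <- function(x, i, j, ..., drop = FALSE) {
  out <- NextMethod(drop = drop)
  if (is.matrix(out)) {
    structure(out,
      space = expr_space(x),
      class = c("expr_matrix", "matrix", "array")
    )
  } else {
    out
  }
}

cell_ids <- function(m) rownames(m)
gene_ids <- function(m) colnames(m)

assert_space <- function(m, space, what) {
  if (!inherits(m, "expr_matrix")) {
    abort(sprintf("%s expects an `expr_matrix`.", what))
  }
  if (!expr_space(m) %in% space) {
    abort(sprintf(
      "%s expects a matrix in %s space, got '%s'.",
      what, paste(sprintf("'%s'", space), collapse = "/"), expr_space(m)
    ))
  }
  invisible(m)
}
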