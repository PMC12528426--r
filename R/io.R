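#' Read an expression matrix
#'
#' Two on-disk layouts are supported:
#'
#' * **mtx** — Matrix Market triplet (genes x cells, the field's usual
#'   orientation) plus one-column `genes.tsv` / `cells.tsv` sidecars;
#' * **tsv** — dense table, cells as rows, first column `cell_id`,
#'   remaining columns one per gene.
#'
#' Duplicate ids and dimension mismatches are rejected.
#'
#' @param path path to the `.mtx` file, the dense `.tsv`, or a directory
#'   containing `matrix.mtx`, `genes.tsv`, `cells.tsv`.
#' @param format `"auto"` (by extension), `"mtx"` or `"tsv"`.
#' @param space value space tag of the stored matrix (default `"raw"`).
#' @return An [expr_matrix()], cells x genes.
#' @export
read_expression <- function(path, format = c("auto", "mtx", "tsv"),
                            space = "raw") {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (dir.exists(path) || grepl("\\.mtx$", path)) "mtx" else "tsv"
  }
  if (format == "mtx") {
    if (dir.exists(path)) {
      mtx <- file.path(path, "matrix.mtx")
      genes <- file.path(path, "genes.tsv")
      cells <- file.path(path, "cells.tsv")
    } else {
      mtx <- path
      genes <- file.path(dirname(path), "genes.tsv")
      cells <- file.path(dirname(path), "cells.tsv")
    }
    m <- tryCatch(
      as.matrix(Matrix::readMM(mtx)),
      warning = function(w) {
        abort(sprintf("Malformed MTX file: %s", conditionMessage(w)))
      }
    )
    gene_ids <- readLines(genes)
    cell_ids <- readLines(cells)
    if (nrow(m) != length(gene_ids) || ncol(m) != length(cell_ids)) {
      abort("MTX dimensions do not match the gene/cell sidecars.")
    }
    dimnames(m) <- list(gene_ids, cell_ids)
    expr_matrix(t(m), space)
  } else {
    tab <- utils::read.table(path, sep = "\t", header = TRUE,
                             check.names = FALSE)
    if (names(tab)[1] != "cell_id") {
      abort("Dense TSV must have `cell_id` as its first column.")
    }
    ids <- as.character(tab$cell_id)
    m <- as.matrix(tab[, -1, drop = FALSE])
    if (!is.numeric(m)) abort("Non-numeric expression entries.")
    rownames(m) <- ids
    expr_matrix(m, space)
  }
}

#' Write an expression matrix
#'
#' @param m an [expr_matrix()].
#' @param path output directory (mtx layout) or `.tsv` file path.
#' @param format `"mtx"` (Matrix Market triplet + sidecars) or `"tsv"`
#'   (dense).
#' @return The path, invisibly.
#' @export
write_expression <- function(m, path, format = c("mtx", "tsv")) {
  format <- match.arg(format)
  if (format == "mtx") {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    Matrix::writeMM(
      Matrix::Matrix(t(unclass(m)), sparse = TRUE),
      file.path(path, "matrix.mtx")
    )
    writeLines(gene_ids(m), file.path(path, "genes.tsv"))
    writeLines(cell_ids(m), file.path(path, "cells.tsv"))
  } else {
    tab <- data.frame(cell_id = cell_ids(m), unclass(m),
                      check.names = FALSE)
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Write a gene annotation as BED-like + arm-table files
#'
#' @param ann annotation tibble with an arm table attribute (e.g. from
#'   [build_genome_model()]).
#' @param genes_bed,arms_tsv output paths.
#' @param gene_span interval length written per gene (default 1).
#' @return `genes_bed`, invisibly.
#' @export
write_annotation <- function(ann, genes_bed, arms_tsv, gene_span = 1) {
  bed <- data.frame(
    chrom = ann$chromosome, start = ann$start,
    end = ann$start + gene_span, gene_id = ann$gene_id
  )
  utils::write.table(bed, genes_bed, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  arms <- genome_arm_table(ann)
  utils::write.table(
    data.frame(chrom = arms$chromosome, arm = arms$arm,
               start = arms$start, end = arms$end),
    arms_tsv, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(genes_bed)
}

#' Write a simulated cohort to disk
#'
#' Emits the expression matrix (MTX triplet layout), cell metadata and
#' ground-truth labels (carried events collapsed as
#' `"arm:direction;arm:direction"`).
#'
#' @param sim result of [simulate_expression()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression(sim$expr, dir, "mtx")
  readr::write_tsv(sim$meta, file.path(dir, "metadata.tsv"))
  truth <- sim$truth |>
    dplyr::mutate(events = purrr::map_chr(.data$events, paste,
                                          collapse = ";"))
  readr::write_tsv(truth, file.path(dir, "truth.tsv"))
  invisible(dir)
}

#' Read ground-truth labels written by [write_cohort()]
#' @param path path to `truth.tsv`.
#' @return Truth tibble with the `events` list-column restored.
#' @export
read_truth <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE) |>
    dplyr::mutate(events = purrr::map(.data$events, function(e) {
      if (is.na(e) || e == "") character() else strsplit(e, ";")[[1]]
    }))
}

#' Write a CNA matrix as dense TSV plus a positions sidecar
#'
#' @param cna a [cna_matrix()].
#' @param dir output directory; writes `cna.tsv` and `positions.tsv`.
#' @return `dir`, invisibly.
#' @export
write_cna <- function(cna, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tab <- data.frame(cell_id = rownames(cna$values), cna$values,
                    check.names = FALSE)
  utils::write.table(tab, file.path(dir, "cna.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  readr::write_tsv(cna$annotation, file.path(dir, "positions.tsv"))
  invisible(dir)
}

#' Read a CNA matrix written by [write_cna()]
#' @param dir directory holding `cna.tsv` and `positions.tsv`.
#' @return A [cna_matrix()].
#' @export
read_cna <- function(dir) {
  tab <- utils::read.table(file.path(dir, "cna.tsv"), sep = "\t",
                           header = TRUE, check.names = FALSE)
  ann <- readr::read_tsv(file.path(dir, "positions.tsv"),
                         show_col_types = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab$cell_id
  cna_matrix(m, ann)
}
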