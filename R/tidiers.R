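#' Tidy a subclone result
#'
#' One row per (cluster, arm) with the mean CNA value and called event.
#'
#' @param x a `subclone_result` from [detect_subclones()].
#' @param ... unused.
#' @return A tibble.
#' @method tidy subclone_result
#' @export
tidy.subclone_result <- function(x, ...) {
  sizes <- dplyr::count(x$assignments, .data$cluster, name = "n_cells")
  dplyr::left_join(x$profiles, sizes, by = "cluster")
}

#' One-row summary of a subclone result
#' @param x a `subclone_result`.
#' @param ... unused.
#' @return A one-row tibble: cells, initial and final cluster counts,
#'   merge rounds, total events called.
#' @method glance subclone_result
#' @export
glance.subclone_result <- function(x, ...) {
  tibble(
    n_cells = nrow(x$assignments),
    initial_clusters = x$initial_clusters,
    final_clusters = length(unique(x$assignments$cluster)),
    merge_rounds = x$n_rounds,
    n_events = sum(x$profiles$event != "none")
  )
}

#' Per-cell classification records
#' @param x a `cna_classification` from [classify_cells()].
#' @param ... unused.
#' @return The records tibble.
#' @method tidy cna_classification
#' @export
tidy.cna_classification <- function(x, ...) x$records

#' One-row summary of a classification
#' @param x a `cna_classification`.
#' @param ... unused.
#' @return A one-row tibble with cutoffs and malignant counts.
#' @method glance cna_classification
#' @export
glance.cna_classification <- function(x, ...) {
  r <- x$records
  tibble(
    n_cells = nrow(r),
    n_reference = sum(r$is_reference),
    n_malignant = sum(r$malignant),
    malignant_fraction = mean(r$malignant[!r$is_reference]),
    signal_cutoff = x$cutoffs$signal_cutoff,
    correlation_cutoff = x$cutoffs$correlation_cutoff
  )
}

#' Tidy a CNA matrix into long form
#'
#' @param x a [cna_matrix()].
#' @param ... unused.
#' @return Long tibble: `cell_id`, `gene_id`, `arm`, `order_index`,
#'   `cna`.
#' @method tidy cna_matrix
#' @export
tidy.cna_matrix <- function(x, ...) {
  tibble(
    cell_id = rep(rownames(x$values), times = ncol(x$values)),
    gene_id = rep(x$annotation$gene_id, each = nrow(x$values)),
    arm = rep(x$annotation$arm, each = nrow(x$values)),
    order_index = rep(x$annotation$order_index, each = nrow(x$values)),
    cna = as.vector(x$values)
  )
}
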