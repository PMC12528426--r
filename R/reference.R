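#' Build a donor-balanced pooled stromal reference
#'
#' From each donor holding at least `min_cells_per_donor` cells of an
#' eligible (presumed-diploid) cell type, exactly `sample_per_donor` cells
#' of that type are sampled uniformly without replacement. Pooling equal
#' numbers per donor avoids the reference being dominated by any one
#' patient's batch. Donors and types are visited in sorted order so the
#' draw is reproducible under a fixed seed.
#'
#' @param meta cell metadata tibble with columns `cell_id`, `donor_id`,
#'   `cell_type`.
#' @param eligible_types cell types allowed into the reference (default
#'   fibroblast, endothelial, adrenocortical).
#' @param min_cells_per_donor minimum count for a (donor, type) pair to
#'   contribute (default 15).
#' @param sample_per_donor cells sampled per contributing pair
#'   (default 15); must not exceed `min_cells_per_donor`.
#' @param seed integer seed for the sampling.
#' @return Tibble of reference cells (`cell_id`, `donor_id`, `cell_type`)
#'   with a `"composition"` attribute giving per-type totals.
#' @examples
#' meta <- tibble::tibble(
#'   cell_id = sprintf("c%02d", 1:40),
#'   donor_id = rep(c("D1", "D2"), each = 20),
#'   cell_type = "fibroblast"
#' )
#' nrow(build_pooled_reference(meta)) # 15 per donor
#' @export
build_pooled_reference <- function(meta,
                                   eligible_types = c(
                                     "fibroblast", "endothelial",
                                     "adrenocortical"
                                   ),
                                   min_cells_per_donor = 15,
                                   sample_per_donor = 15, seed = 1L) {
  if (!all(c("cell_id", "donor_id", "cell_type") %in% names(meta))) {
    abort("`meta` needs columns cell_id, donor_id, cell_type.")
  }
  if (sample_per_donor > min_cells_per_donor) {
    abort("`sample_per_donor` must be <= `min_cells_per_donor`.")
  }
  set.seed(seed)
  picks <- list()
  for (donor in sort(unique(meta$donor_id))) {
    for (type in sort(eligible_types)) {
      ids <- meta$cell_id[meta$donor_id == donor & meta$cell_type == type]
      if (length(ids) < min_cells_per_donor) next
      ids <- sort(ids)
      chosen <- ids[sample.int(length(ids), sample_per_donor)]
      picks[[paste(donor, type)]] <- tibble(
        cell_id = chosen, donor_id = donor, cell_type = type
      )
    }
  }
  if (!length(picks)) {
    abort("Empty reference: no (donor, cell type) pair reaches the minimum count.")
  }
  ref <- dplyr::bind_rows(picks)
  composition <- ref |>
    dplyr::count(.data$cell_type, name = "cells") |>
    dplyr::arrange(.data$cell_type)
  attr(ref, "composition") <- composition
  ref
}

#' Per-type composition of a pooled reference
#' @param reference tibble from [build_pooled_reference()].
#' @return Tibble with `cell_type` and `cells`.
#' @export
reference_composition <- function(reference) {
  attr(reference, "composition") %||%
    dplyr::count(reference, .data$cell_type, name = "cells")
}

#' Assemble one patient's CNA analysis matrix
#'
#' Combines the patient's target-compartment cells (by default
#' neuroendocrine and Schwann) with the reference cells into one matrix.
#' Downstream gene filtering and centering are applied to this combined
#' matrix, so the reference calibrates each gene's zero point. Reference
#' cells also present among the patient's target cells are dropped from
#' the reference side with a warning.
#'
#' @param expr raw- or log-space [expr_matrix()] covering all cells.
#' @param meta metadata tibble (`cell_id`, `donor_id`, `cell_type`).
#' @param patient donor id whose cells are analysed.
#' @param target_types compartments to profile (default neuroendocrine +
#'   schwann).
#' @param reference reference tibble from [build_pooled_reference()] or a
#'   character vector of reference cell ids.
#' @return List with `expr` (combined matrix, target cells first) and
#'   `meta` (matching rows with logical `is_reference`).
#' @export
assemble_patient_matrix <- function(expr, meta, patient,
                                    target_types = c(
                                      "neuroendocrine", "schwann"
                                    ),
                                    reference) {
  if (!patient %in% meta$donor_id) {
    abort(sprintf("Patient '%s' absent from metadata.", patient))
  }
  ref_ids <- if (is.character(reference)) reference else reference$cell_id
  target_ids <- meta$cell_id[
    meta$donor_id == patient & meta$cell_type %in% target_types
  ]
  if (!length(target_ids)) {
    abort(sprintf("Patient '%s' has no cells of the target types.", patient))
  }
  overlap <- intersect(ref_ids, target_ids)
  if (length(overlap)) {
    warn(sprintf(
      "%d reference cell(s) overlap the patient's target cells; removed from the reference.",
      length(overlap)
    ))
    ref_ids <- setdiff(ref_ids, overlap)
  }
  missing <- setdiff(c(target_ids, ref_ids), cell_ids(expr))
  if (length(missing)) {
    abort(sprintf("%d cell id(s) absent from the expression matrix.",
                  length(missing)))
  }
  ids <- c(target_ids, ref_ids)
  sub <- meta[match(ids, meta$cell_id), , drop = FALSE]
  sub$is_reference <- sub$cell_id %in% ref_ids
  list(expr = expr[ids, , drop = FALSE], meta = as_tibble(sub))
}
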