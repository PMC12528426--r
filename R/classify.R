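#' CNA signal of a single cell
#'
#' Mean of the absolute CNA values over the cell's own top
#' `ceiling(top_fraction * n)` positions ranked by absolute CNA value
#' (ties broken by genome order). High signal means the cell deviates
#' strongly from the diploid baseline somewhere in its genome.
#'
#' @param profile numeric CNA vector for one cell.
#' @param top_fraction fraction of positions used (default 0.2).
#' @return Non-negative scalar.
#' @examples
#' cna_signal(c(0.9, 0.7, rep(0.1, 8))) # mean(0.9, 0.7) = 0.8
#' @export
cna_signal <- function(profile, top_fraction = 0.2) {
  n <- length(profile)
  if (!n) abort("Empty CNA profile.")
  k <- ceiling(top_fraction * n)
  a <- abs(profile)
  mean(a[order(-a, seq_len(n))[seq_len(k)]])
}

cna_signal_cells <- function(cna, cells = NULL, top_fraction = 0.2) {
  v <- cna$values[cells %||% rownames(cna$values), , drop = FALSE]
  apply(v, 1, cna_signal, top_fraction = top_fraction)
}

#' Average CNA profile of the strongest tumour cells
#'
#' Ranks the candidate cells by [cna_signal()] (ties broken by cell id)
#' and averages the CNA profiles of the top `ceiling(top_cell_fraction *
#' n)` cells. This is the template against which every cell's CNA
#' correlation is computed.
#'
#' @param cna a [cna_matrix()].
#' @param cells candidate tumour cell ids (at least 5).
#' @param top_cell_fraction fraction of cells averaged (default 0.2).
#' @param top_gene_fraction passed to [cna_signal()] (default 0.2).
#' @return Named numeric vector over the matrix positions.
#' @export
tumor_profile <- function(cna, cells, top_cell_fraction = 0.2,
                          top_gene_fraction = 0.2) {
  stopifnot(inherits(cna, "cna_matrix"))
  if (length(cells) < 5) abort("Need at least 5 candidate tumour cells.")
  sig <- cna_signal_cells(cna, cells, top_gene_fraction)
  k <- ceiling(top_cell_fraction * length(cells))
  top <- cells[order(-sig, cells)[seq_len(k)]]
  colMeans(cna$values[top, , drop = FALSE])
}

#' CNA correlation between a cell and the tumour profile
#'
#' Product-moment (Pearson) correlation between the cell's CNA vector
#' and the average tumour profile; Spearman rank correlation is offered
#' as an option. If either vector is constant the correlation is
#' undefined and 0 is returned with a warning.
#'
#' @param profile the cell's CNA vector.
#' @param reference_profile the tumour profile from [tumor_profile()].
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return Correlation in \[-1, 1\].
#' @export
cna_correlation <- function(profile, reference_profile,
                            method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(profile) != length(reference_profile)) {
    abort("Profiles must have equal length.")
  }
  if (sd(profile) == 0 || sd(reference_profile) == 0) {
    warn("Constant CNA profile: correlation undefined, returning 0.")
    return(0)
  }
  cor(profile, reference_profile, method = method)
}

#' Median + k*SD cutoffs from reference cells
#'
#' For each metric the cutoff is the reference cells' median plus
#' `sd_multiplier` sample standard deviations (n-1 denominator), so a
#' cell must exceed what essentially all diploid reference cells show.
#'
#' @param signal CNA-signal values of the reference cells (>= 3).
#' @param correlation CNA-correlation values of the reference cells.
#' @param sd_multiplier number of SDs above the median (default 2).
#' @return List with `signal_cutoff` and `correlation_cutoff`.
#' @examples
#' compute_cutoffs(0:4, rep(0.1, 5))$signal_cutoff # 2 + 2*sqrt(2.5)
#' @export
compute_cutoffs <- function(signal, correlation, sd_multiplier = 2) {
  if (length(signal) < 3 || length(correlation) < 3) {
    abort("Need at least 3 reference cells to set cutoffs.")
  }
  list(
    signal_cutoff = median(signal) + sd_multiplier * sd(signal),
    correlation_cutoff = median(correlation) + sd_multiplier * sd(correlation)
  )
}

#' Classify cells as neoplastic from CNA signal and correlation
#'
#' Computes, for every cell in the matrix, the CNA signal and the CNA
#' correlation against the average profile of the strongest candidate
#' tumour cells; sets cutoffs at median + `sd_multiplier` SD of the
#' reference cells' metrics; and flags as malignant exactly the cells
#' strictly above both cutoffs. Metrics, not labels, decide: a reference
#' cell resembling the tumour profile is flagged.
#'
#' @param cna a [cna_matrix()].
#' @param reference reference cell ids (character) or tibble with
#'   `cell_id`; defaults to the reference recorded in the matrix.
#' @param candidates candidate tumour cells for the profile (default:
#'   all non-reference cells).
#' @param top_gene_frac per-cell fraction of positions for the signal
#'   (default 0.2).
#' @param top_cell_frac fraction of cells averaged into the tumour
#'   profile (default 0.2).
#' @param sd_multiplier cutoff stringency (default 2).
#' @param method correlation type (default `"pearson"`).
#' @return A `cna_classification`: list with `records` (tibble:
#'   `cell_id`, `cna_signal`, `cna_correlation`, `is_reference`,
#'   `malignant`), `cutoffs`, and `profile` (the tumour template).
#' @export
classify_cells <- function(cna, reference = NULL, candidates = NULL,
                           top_gene_frac = 0.2, top_cell_frac = 0.2,
                           sd_multiplier = 2,
                           method = c("pearson", "spearman")) {
  stopifnot(inherits(cna, "cna_matrix"))
  method <- match.arg(method)
  reference <- reference %||% cna$reference
  ref_ids <- if (is.character(reference)) reference else reference$cell_id
  all_cells <- rownames(cna$values)
  if (!all(ref_ids %in% all_cells)) {
    abort("Reference cells absent from the CNA matrix.")
  }
  candidates <- candidates %||% setdiff(all_cells, ref_ids)
  profile <- tumor_profile(cna, candidates, top_cell_frac, top_gene_frac)
  sig <- cna_signal_cells(cna, all_cells, top_gene_frac)
  corr <- if (sd(profile) == 0) {
    warn("Constant tumour profile: all CNA correlations set to 0.")
    setNames(rep(0, length(all_cells)), all_cells)
  } else {
    apply(cna$values, 1, function(v) {
      if (sd(v) == 0) 0 else cor(v, profile, method = method)
    })
  }
  cuts <- compute_cutoffs(sig[ref_ids], corr[ref_ids], sd_multiplier)
  records <- tibble(
    cell_id = all_cells,
    cna_signal = unname(sig),
    cna_correlation = unname(corr),
    signal_cutoff = cuts$signal_cutoff,
    correlation_cutoff = cuts$correlation_cutoff,
    is_reference = all_cells %in% ref_ids,
    malignant = unname(sig > cuts$signal_cutoff &
                       corr > cuts$correlation_cutoff)
  )
  structure(
    list(records = records, cutoffs = cuts, profile = profile,
         params = list(top_gene_frac = top_gene_frac,
                       top_cell_frac = top_cell_frac,
                       sd_multiplier = sd_multiplier, method = method)),
    class = "cna_classification"
  )
}

#' @export
print.cna_classification <- function(x, ...) {
  r <- x$records
  cat(sprintf(
    "<cna_classification> %d cells (%d reference); %d malignant\n  cutoffs: signal > %.3f, correlation > %.3f\n",
    nrow(r), sum(r$is_reference), sum(r$malignant),
    x$cutoffs$signal_cutoff, x$cutoffs$correlation_cutoff
  ))
  invisible(x)
}

#' Clonal status of glial cells against the tumour event profile
#'
#' A glial cell shares an event when its own per-cell arm call matches a
#' tumour event in both arm and direction. Cells sharing no tumour event
#' are non-neoplastic; cells sharing every tumour event are full
#' matches; cells sharing a nonempty proper subset — typically the
#' initiating deletion only — are pre-neoplastic.
#'
#' @param glial_events long tibble from [cell_arm_events()] (`cell_id`,
#'   `arm`, `event`) for the glial cells.
#' @param tumor_events arm-event tibble from [call_arm_events()] on the
#'   neoplastic tumour cells.
#' @return Tibble with `cell_id`, `n_shared`, `n_tumor_events`,
#'   `glial_status` in {non_neoplastic, pre_neoplastic, full_match}.
#' @export
classify_glial <- function(glial_events, tumor_events) {
  tum <- tumor_events[tumor_events$event != "none", c("arm", "event")]
  cells <- unique(glial_events$cell_id)
  if (!nrow(tum)) {
    warn("Tumour event set is empty: all glial cells non-neoplastic.")
    return(tibble(
      cell_id = cells, n_shared = 0L, n_tumor_events = 0L,
      glial_status = "non_neoplastic"
    ))
  }
  shared <- glial_events |>
    dplyr::semi_join(tum, by = c("arm", "event")) |>
    dplyr::count(.data$cell_id, name = "n_shared")
  tibble(cell_id = cells) |>
    dplyr::left_join(shared, by = "cell_id") |>
    dplyr::mutate(
      n_shared = dplyr::coalesce(.data$n_shared, 0L),
      n_tumor_events = nrow(tum),
      glial_status = dplyr::case_when(
        .data$n_shared == 0L ~ "non_neoplastic",
        .data$n_shared == nrow(tum) ~ "full_match",
        .default = "pre_neoplastic"
      )
    )
}
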