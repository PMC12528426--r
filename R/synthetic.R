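#' Declare a planted chromosome-arm event
#'
#' Describes a clonal copy-number event injected by the simulator: an
#' arm-level deletion or amplification realised as an additive shift of
#' `effect` log2 units (negative for deletions) on every gene of the arm,
#' in a stated fraction of each carrier cell type.
#'
#' @param arm arm id present in the genome model (e.g. `"3p"`).
#' @param direction `"deletion"` or `"amplification"`.
#' @param effect per-gene shift in log2 units, > 0; the sign is applied
#'   from `direction`.
#' @param carriers named numeric vector, cell type -> fraction in \[0, 1\]
#'   of that type carrying the event.
#' @return A `planted_event` list.
#' @examples
#' planted_event("3p", "deletion", 0.6,
#'   carriers = c(neuroendocrine = 1, schwann = 0.1))
#' @export
planted_event <- function(arm, direction = c("deletion", "amplification"),
                          effect, carriers) {
  direction <- match.arg(direction)
  if (!is.numeric(effect) || length(effect) != 1 || effect <= 0) {
    abort("`effect` must be a single positive log2 shift.")
  }
  if (is.null(names(carriers)) || any(carriers < 0) || any(carriers > 1)) {
    abort("`carriers` must be a named vector of fractions in [0, 1].")
  }
  structure(
    list(arm = arm, direction = direction, effect = effect,
         carriers = carriers),
    class = "planted_event"
  )
}

#' Known cell types and their tissue compartments
#' @keywords internal
.cell_types <- c(
  neuroendocrine = "neuroendocrine",
  schwann = "glial",
  fibroblast = "stromal",
  endothelial = "stromal",
  adrenocortical = "stromal"
)

#' Default synthetic genome: five chromosomes, 150 genes per arm
#'
#' Ten arms (1p..5q) of 150 genes each, 1500 genes total. Arm sizes are of
#' the order seen after expression filtering of a deep Smart-seq2 matrix,
#' and chromosome 3p carries 150 genes so arm-level events are well
#' supported by the default 100-gene smoothing window.
#'
#' @return Annotation tibble from [build_genome_model()].
#' @export
default_genome <- function() {
  arms <- paste0(rep(1:5, each = 2), c("p", "q"))
  build_genome_model(1500, data.frame(arm = arms, genes = 150))
}

#' Specify a synthetic multi-donor cohort
#'
#' Collects everything the simulator needs: donor layout, per-type cell
#' counts, genome model, planted events and noise settings. Baseline gene
#' means are lognormal (log2 mean drawn Normal(5, 2), scaled so roughly
#' half the genes clear the downstream 4.5 expression filter); noise is
#' Gaussian in log2 space; per-cell depth factors are lognormal residuals
#' (TPM-like units are already depth-normalised, so the default is small);
#' dropout is optional Bernoulli zeroing.
#'
#' @param cells tibble/data.frame with columns `donor`, `cell_type`, `n`,
#'   or a named vector (cell type -> count) replicated for each donor in
#'   `donors`.
#' @param donors donor ids; required only when `cells` is a named vector.
#' @param genome annotation tibble (default [default_genome()]).
#' @param events list of [planted_event()]s.
#' @param noise_sd log2-space noise standard deviation (default 0.5).
#' @param depth_sd per-cell depth-factor log2 sd (default 0.05).
#' @param dropout_rate Bernoulli zeroing probability in \[0, 1\] (default 0).
#' @param baseline_mean,baseline_sd,baseline_scale parameters of the
#'   lognormal gene baseline (log2 mean ~ `baseline_scale` *
#'   Normal(`baseline_mean`, `baseline_sd`)).
#' @param seed integer seed; the same spec (including seed) reproduces the
#'   cohort bit for bit.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(cells, donors = NULL, genome = default_genome(),
                        events = list(), noise_sd = 0.5, depth_sd = 0.05,
                        dropout_rate = 0, baseline_mean = 5,
                        baseline_sd = 2, baseline_scale = 1.6, seed = 1L) {
  if (!is.data.frame(cells)) {
    if (is.null(names(cells)) || is.null(donors)) {
      abort("Vector `cells` needs names (cell types) and `donors`.")
    }
    cells <- tidyr::expand_grid(donor = donors, cell_type = names(cells)) |>
      dplyr::mutate(n = unname(cells[.data$cell_type]))
  }
  cells <- as_tibble(cells)
  if (!all(c("donor", "cell_type", "n") %in% names(cells))) {
    abort("`cells` needs columns donor, cell_type, n.")
  }
  if (any(cells$n < 0)) abort("Cell counts must be >= 0.")
  bad <- setdiff(unique(cells$cell_type), names(.cell_types))
  if (length(bad)) {
    abort(sprintf(
      "Unknown cell type(s): %s. Known: %s.",
      paste(bad, collapse = ", "), paste(names(.cell_types), collapse = ", ")
    ))
  }
  if (inherits(events, "planted_event")) events <- list(events)
  arms <- unique(genome$arm)
  for (ev in events) {
    if (!inherits(ev, "planted_event")) abort("`events` must be planted_event objects.")
    if (!ev$arm %in% arms) {
      abort(sprintf("Event arm '%s' absent from the genome model.", ev$arm))
    }
  }
  stopifnot(noise_sd >= 0, depth_sd >= 0,
            dropout_rate >= 0, dropout_rate <= 1)
  structure(
    list(cells = cells, genome = genome, events = events,
         noise_sd = noise_sd, depth_sd = depth_sd,
         dropout_rate = dropout_rate, baseline_mean = baseline_mean,
         baseline_sd = baseline_sd, baseline_scale = baseline_scale,
         seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

event_label <- function(ev) paste0(ev$arm, ":", ev$direction)

#' Simulate a synthetic expression cohort with planted CNA events
#'
#' Draws lognormal gene baselines, applies each planted event as an
#' additive log2 shift to its carrier cells (deletions negative,
#' amplifications positive), adds Gaussian log2 noise and a per-cell depth
#' factor, back-transforms to TPM-like linear units and optionally zeroes
#' entries at the dropout rate. Carrier counts per (donor, cell type) are
#' `round(fraction * n)`. Fully deterministic given the spec's seed.
#'
#' @param spec a [cohort_spec()].
#' @return A list with `expr` (raw-space [expr_matrix()]), `meta` (tibble:
#'   `cell_id`, `donor_id`, `cell_type`, `compartment`) and `truth`
#'   (tibble: one row per cell with a list-column `events` of carried
#'   `"arm:direction"` labels).
#' @examples
#' spec <- cohort_spec(c(neuroendocrine = 20, fibroblast = 20),
#'   donors = "D1", seed = 7)
#' sim <- simulate_expression(spec)
#' sim$expr
#' @export
simulate_expression <- function(spec) {
  if (!inherits(spec, "cohort_spec")) abort("`spec` must be a cohort_spec.")
  set.seed(spec$seed)
  ann <- spec$genome
  n_genes <- nrow(ann)
  cells <- spec$cells[order(spec$cells$donor, spec$cells$cell_type), ]
  cells <- cells[cells$n > 0, , drop = FALSE]
  if (!nrow(cells)) abort("Cohort holds no cells.")

  baseline <- spec$baseline_scale *
    rnorm(n_genes, spec$baseline_mean, spec$baseline_sd)

  meta <- purrr::pmap_dfr(cells, function(donor, cell_type, n) {
    tibble(
      cell_id = sprintf("%s_%s_%04d", donor, cell_type, seq_len(n)),
      donor_id = donor, cell_type = cell_type,
      compartment = unname(.cell_types[cell_type])
    )
  })
  n_cells <- nrow(meta)

  # carrier assignment: round(fraction * n) carriers per (donor, type)
  carried <- matrix(FALSE, n_cells, length(spec$events))
  for (j in seq_along(spec$events)) {
    ev <- spec$events[[j]]
    for (g in split(seq_len(n_cells),
                    paste(meta$donor_id, meta$cell_type))) {
      type <- meta$cell_type[g[1]]
      frac <- ev$carriers[type]
      if (is.na(frac) || frac == 0) next
      k <- round(frac * length(g))
      if (k > 0) carried[g[sample.int(length(g), k)], j] <- TRUE
    }
  }

  log2_expr <- matrix(rep(baseline, each = n_cells), n_cells, n_genes)
  for (j in seq_along(spec$events)) {
    ev <- spec$events[[j]]
    shift <- if (ev$direction == "deletion") -ev$effect else ev$effect
    cols <- which(ann$arm == ev$arm)
    rows <- which(carried[, j])
    if (length(rows)) log2_expr[rows, cols] <- log2_expr[rows, cols] + shift
  }
  if (spec$noise_sd > 0) {
    log2_expr <- log2_expr + matrix(
      rnorm(n_cells * n_genes, 0, spec$noise_sd), n_cells, n_genes
    )
  }
  if (spec$depth_sd > 0) {
    log2_expr <- log2_expr + rnorm(n_cells, 0, spec$depth_sd)
  }
  values <- 2^log2_expr
  if (spec$dropout_rate > 0) {
    keep <- matrix(
      rbinom(n_cells * n_genes, 1, 1 - spec$dropout_rate), n_cells, n_genes
    )
    values <- values * keep
  }
  dimnames(values) <- list(meta$cell_id, ann$gene_id)

  labels <- vapply(spec$events, event_label, character(1))
  truth <- meta |>
    dplyr::mutate(events = purrr::map(seq_len(n_cells), function(i) {
      labels[carried[i, ]]
    }))

  list(expr = expr_matrix(values, "raw"), meta = meta, truth = truth)
}

#' Canonical VHL-like clone-recovery cohort
#'
#' Three donors; donor `D1` carries the tumour: 300 neuroendocrine cells
#' and 200 Schwann (sustentacular-like) cells. Stromal cells are spread so
#' that donor-balanced 15-cell sampling yields a pooled reference of 30
#' fibroblasts, 45 endothelial and 30 adrenocortical cells. Two planted
#' deletions of 0.6 log2 units on 150-gene arms: 3p in 100% of tumour
#' cells and 10% of Schwann cells (the shared initiating VHL second hit),
#' and a tumour-private 1p deletion (a recurrent secondary PPGL event) —
#' so 3p-only Schwann carriers are genuinely pre-neoplastic. Noise sd 1.0.
#'
#' @param seed integer seed.
#' @param noise_sd log2 noise sd (default 1.0).
#' @param effect event size in log2 units (default 0.6).
#' @param glial_carrier_frac fraction of Schwann cells carrying 3p
#'   (default 0.1).
#' @return A [cohort_spec()].
#' @export
clone_recovery_cohort <- function(seed = 1L, noise_sd = 1.0, effect = 0.6,
                                  glial_carrier_frac = 0.1) {
  cells <- tibble(
    donor = c("D1", "D1", "D1", "D2", "D1", "D2", "D3", "D2", "D3"),
    cell_type = c(
      "neuroendocrine", "schwann",
      "fibroblast", "fibroblast",
      "endothelial", "endothelial", "endothelial",
      "adrenocortical", "adrenocortical"
    ),
    n = c(300, 200, 20, 20, 20, 20, 20, 20, 20)
  )
  cohort_spec(
    cells,
    events = list(
      planted_event("3p", "deletion", effect,
        carriers = c(neuroendocrine = 1, schwann = glial_carrier_frac)),
      planted_event("1p", "deletion", effect,
        carriers = c(neuroendocrine = 1))
    ),
    noise_sd = noise_sd, seed = seed
  )
}

#' Event-free cohort from the reference distribution
#'
#' Same donor/stromal layout as [clone_recovery_cohort()] but with no
#' planted events and default noise; used for null calibration of the
#' CNA pipeline and the neoplastic cutoffs.
#'
#' @param seed integer seed.
#' @param n_target cells per target type (neuroendocrine, schwann) on
#'   donor D1 (default 100).
#' @return A [cohort_spec()].
#' @export
null_cohort <- function(seed = 1L, n_target = 100) {
  cells <- tibble(
    donor = c("D1", "D1", "D1", "D2", "D1", "D2", "D3", "D2", "D3"),
    cell_type = c(
      "neuroendocrine", "schwann",
      "fibroblast", "fibroblast",
      "endothelial", "endothelial", "endothelial",
      "adrenocortical", "adrenocortical"
    ),
    n = c(n_target, n_target, 20, 20, 20, 20, 20, 20, 20)
  )
  cohort_spec(cells, seed = seed)
}
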