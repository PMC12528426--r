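#' Pipeline configuration with study defaults
#'
#' Collects every tunable of the pipeline under its default value;
#' unknown names and out-of-range values are rejected. The defaults are
#' the study conditions: QC at 1000 genes/cell and mitochondrial
#' fraction < 0.30, gene filter at mean log2 > 4.5, clipping at |3|,
#' 100-gene smoothing window, +/-0.15 noise floor and arm-event
#' threshold, 15-cell donor-balanced reference sampling, top-2/3
#' position selection with k = 15 overclustering, top-20% signal and
#' profile fractions, median + 2 SD cutoffs, and the two DE thresholds.
#'
#' @param ... name = value overrides of the defaults.
#' @return A validated `pipeline_config` list with a `hash` attribute
#'   that changes iff any tunable changes.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    qc_min_genes = 1000, qc_max_mito = 0.30, mito_prefix = "MT-",
    gene_expr_cutoff = 4.5, clip_bound = 3, window = 100,
    noise_floor = 0.15, ref_min_cells = 15, ref_sample_n = 15,
    subclone_fraction = 2 / 3, k_neighbors = 15, arm_threshold = 0.15,
    top_gene_frac = 0.2, top_cell_frac = 0.2, sd_multiplier = 2,
    de_lfc_min = 0.5, de_alpha = 0.05, recurrent_lfc_min = 1,
    recurrent_alpha = 0.05, seed = 1L
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown)) {
    abort(sprintf("Unknown config key(s): %s.",
                  paste(unknown, collapse = ", ")))
  }
  config <- utils::modifyList(defaults, overrides)
  with(config, {
    stopifnot(
      qc_min_genes >= 0, qc_max_mito >= 0, qc_max_mito <= 1,
      clip_bound > 0, window >= 1, noise_floor > 0,
      ref_sample_n <= ref_min_cells, subclone_fraction > 0,
      subclone_fraction <= 1, k_neighbors >= 1, arm_threshold > 0,
      top_gene_frac > 0, top_gene_frac <= 1, top_cell_frac > 0,
      top_cell_frac <= 1, sd_multiplier >= 0, de_alpha > 0,
      recurrent_alpha > 0
    )
  })
  config$seed <- as.integer(config$seed)
  structure(config, class = "pipeline_config",
            hash = rlang::hash(config))
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  for (n in names(x)) cat(sprintf("  %s = %s\n", n, format(x[[n]])))
  cat(sprintf("  hash: %s\n", attr(x, "hash")))
  invisible(x)
}

# Per-stage seed derived from the global seed and the stage name, so a
# stage's draws do not depend on how many stages ran before it.
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  (as.integer(seed) * 1009L + h) %% .Machine$integer.max
}

#' Run the full analysis pipeline on one cohort
#'
#' Chains the stages end to end: optional QC, donor-balanced pooled
#' reference, then per patient an assembled matrix, CNA inference,
#' subclone detection, neoplastic classification and glial clonal-status
#' calls. Every random stage draws from a seed derived from the global
#' seed and the stage name, so results are reproducible and independent
#' of stage order.
#'
#' @param expr raw-space [expr_matrix()] for the whole cohort.
#' @param meta metadata tibble (`cell_id`, `donor_id`, `cell_type`).
#' @param ann gene annotation tibble.
#' @param config a [pipeline_config()].
#' @param patients donor ids to analyse (default: donors holding any
#'   neuroendocrine or schwann cells).
#' @param qc apply [qc_filter()] first (default FALSE: simulated TPM
#'   matrices are already clean).
#' @param exclude cell ids removed at QC.
#' @return List with `reference`, per-patient `results` (each holding
#'   `cna`, `subclones`, `classification`, `glial`) and a `manifest`
#'   (config hash, seed, package version) enabling exact re-runs.
#' @export
run_pipeline <- function(expr, meta, ann, config = pipeline_config(),
                         patients = NULL, qc = FALSE, exclude = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!all(c("cell_id", "donor_id", "cell_type") %in% names(meta))) {
    abort("run_pipeline: metadata lacks cell_id/donor_id/cell_type.")
  }
  if (qc) {
    filtered <- qc_filter(expr, config$qc_min_genes, config$qc_max_mito,
                          config$mito_prefix, exclude)
    expr <- filtered$expr
    meta <- meta[meta$cell_id %in% cell_ids(expr), , drop = FALSE]
    qc_report <- filtered$report
  } else {
    qc_report <- NULL
  }
  reference <- build_pooled_reference(
    meta,
    min_cells_per_donor = config$ref_min_cells,
    sample_per_donor = config$ref_sample_n,
    seed = stage_seed(config$seed, "reference")
  )
  target_types <- c("neuroendocrine", "schwann")
  patients <- patients %||% sort(unique(
    meta$donor_id[meta$cell_type %in% target_types]
  ))
  results <- lapply(patients, function(patient) {
    assembled <- assemble_patient_matrix(expr, meta, patient,
                                         target_types, reference)
    cna <- infer_cna(
      assembled$expr, ann, reference,
      gene_cutoff = config$gene_expr_cutoff,
      clip_bound = config$clip_bound, window = config$window,
      noise_floor = config$noise_floor
    )
    tumor_cells <- assembled$meta$cell_id[
      assembled$meta$cell_type == "neuroendocrine"
    ]
    glial_cells <- assembled$meta$cell_id[
      assembled$meta$cell_type == "schwann"
    ]
    sub <- detect_subclones(
      cna, cells = tumor_cells,
      fraction = config$subclone_fraction,
      k_neighbors = config$k_neighbors,
      threshold = config$arm_threshold,
      seed = stage_seed(config$seed, paste0("subclones_", patient))
    )
    classification <- classify_cells(
      cna, reference = reference, candidates = tumor_cells,
      top_gene_frac = config$top_gene_frac,
      top_cell_frac = config$top_cell_frac,
      sd_multiplier = config$sd_multiplier
    )
    malignant_ne <- intersect(
      tumor_cells,
      classification$records$cell_id[classification$records$malignant]
    )
    tumor_events <- call_arm_events(
      cna, if (length(malignant_ne)) malignant_ne else tumor_cells,
      config$arm_threshold
    )
    glial <- if (length(glial_cells)) {
      classify_glial(
        cell_arm_events(cna, glial_cells, config$arm_threshold),
        tumor_events
      )
    } else {
      NULL
    }
    list(patient = patient, cna = cna, subclones = sub,
         classification = classification, tumor_events = tumor_events,
         glial = glial)
  })
  names(results) <- patients
  list(
    reference = reference,
    results = results,
    qc_report = qc_report,
    manifest = list(
      package = "cnaclone",
      version = as.character(utils::packageVersion("cnaclone")),
      config_hash = attr(config, "hash"),
      seed = config$seed,
      patients = patients,
      n_cells = nrow(meta)
    )
  )
}
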