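toy_cna <- function(values, ann = NULL) {
  n <- ncol(values)
  ann <- ann %||% build_genome_model(n, data.frame(arm = "1p", genes = n))
  colnames(values) <- ann$gene_id
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("c%03d", seq_len(nrow(values)))
  }
  cna_matrix(values, ann, params = list(clip_bound = 3, noise_floor = 0.15))
}

test_that("top-position selection keeps the highest mean |CNA| in genome order", {
  v <- matrix(rep(9:1, each = 2), 2, 9)
  v[, 4] <- -v[, 4] # sign must not matter
  cna <- toy_cna(v)
  red <- select_top_positions(cna, 2 / 3)
  expect_equal(ncol(red$values), 6)
  expect_identical(red$annotation$gene_id, cna$annotation$gene_id[1:6])
  # fraction 1 is the identity
  expect_identical(select_top_positions(cna, 1)$values, cna$values)
  # all-zero: deterministic tie-break keeps the first ceil(2n/3) positions
  zero <- toy_cna(matrix(0, 2, 9))
  expect_identical(select_top_positions(zero, 2 / 3)$annotation$gene_id,
                   zero$annotation$gene_id[1:6])
})

test_that("arm event calls use strict thresholds on the arm mean", {
  ann <- build_genome_model(4, data.frame(arm = c("1p", "1q", "2p", "2q"),
                                          genes = c(1, 1, 1, 1)))
  v <- matrix(c(-0.16, 0.15, 0.151, 0), 1)
  cna <- toy_cna(v, ann)
  ev <- call_arm_events(cna)
  expect_equal(ev$event, c("deletion", "none", "amplification", "none"))
  zeroes <- call_arm_events(toy_cna(matrix(0, 3, 4), ann))
  expect_true(all(zeroes$event == "none"))
  expect_error(call_arm_events(cna, cells = character()), "nonempty")
})

test_that("merging collapses identical profiles and records history", {
  ann <- build_genome_model(2, data.frame(arm = c("3p", "5q"), genes = c(1, 1)))
  v <- rbind(
    matrix(rep(c(-0.5, 0), 4), 4, 2, byrow = TRUE),  # cluster A: 3p del
    matrix(rep(c(-0.5, 0), 4), 4, 2, byrow = TRUE),  # cluster B: 3p del
    matrix(0, 4, 2)                                   # cluster C: none
  )
  cna <- toy_cna(v, ann)
  labels <- setNames(rep(1:3, each = 4), rownames(cna$values))
  res <- merge_identical_clusters(cna, labels)
  expect_equal(length(unique(res$assignments$cluster)), 2)
  expect_equal(res$n_rounds, 1)
  expect_equal(nrow(res$history[[1]]), 1)
  # all identical -> one cluster
  all_same <- merge_identical_clusters(toy_cna(matrix(0, 9, 2), ann),
                                       setNames(rep(1:3, each = 3),
                                                sprintf("c%03d", 1:9)))
  expect_equal(length(unique(all_same$assignments$cluster)), 1)
  # already distinct -> identity in zero rounds
  v2 <- rbind(matrix(rep(c(-0.5, 0), 3), 3, 2, byrow = TRUE),
              matrix(rep(c(0, 0.5), 3), 3, 2, byrow = TRUE))
  distinct <- merge_identical_clusters(toy_cna(v2, ann),
                                       setNames(rep(1:2, each = 3),
                                                sprintf("c%03d", 1:6)))
  expect_equal(distinct$n_rounds, 0)
  expect_equal(length(unique(distinct$assignments$cluster)), 2)
})

test_that("final profiles are pairwise distinct and partitions stay valid", {
  spec <- clone_recovery_cohort(seed = 21)
  sim <- simulate_expression(spec)
  ref <- build_pooled_reference(sim$meta, seed = 4)
  asm <- assemble_patient_matrix(sim$expr, sim$meta, "D1", reference = ref)
  cna <- infer_cna(asm$expr, spec$genome, ref)
  tumor <- sim$meta$cell_id[sim$meta$cell_type == "neuroendocrine"]
  res <- detect_subclones(cna, cells = tumor, seed = 5)
  expect_equal(sort(res$assignments$cell_id), sort(tumor))
  sigs <- tapply(res$profiles$event, res$profiles$cluster, paste,
                 collapse = "|")
  expect_equal(anyDuplicated(sigs), 0)
  expect_lte(res$n_rounds, res$initial_clusters - 1)
})

test_that("two planted clones with disjoint events are recovered exactly", {
  cells <- tibble::tibble(
    donor = c("D1", "D1", "D1", "D2", "D1", "D2", "D3", "D2", "D3"),
    cell_type = c("neuroendocrine", "schwann", "fibroblast", "fibroblast",
                  "endothelial", "endothelial", "endothelial",
                  "adrenocortical", "adrenocortical"),
    n = c(200, 0, 20, 20, 20, 20, 20, 20, 20)
  )
  spec <- cohort_spec(
    cells,
    events = list(
      planted_event("3p", "deletion", 0.6,
                    carriers = c(neuroendocrine = 0.5)),
      planted_event("5q", "amplification", 0.6,
                    carriers = c(neuroendocrine = 1))
    ),
    noise_sd = 0.8, seed = 22
  )
  sim <- simulate_expression(spec)
  ref <- build_pooled_reference(sim$meta, seed = 6)
  asm <- assemble_patient_matrix(sim$expr, sim$meta, "D1", reference = ref)
  cna <- infer_cna(asm$expr, spec$genome, ref)
  tumor <- sim$meta$cell_id[sim$meta$cell_type == "neuroendocrine"]
  res <- detect_subclones(cna, cells = tumor, seed = 7)
  truth_clone <- ifelse(
    carrier_of(sim$truth, "3p:deletion")[match(res$assignments$cell_id,
                                               sim$truth$cell_id)],
    "del3p", "wt3p"
  )
  expect_gte(adjusted_rand(res$assignments$cluster, truth_clone), 0.9)
  # the 3p clone's profile carries the deletion, the other does not
  prof <- tidy(res)
  del3p_clusters <- unique(prof$cluster[prof$arm == "3p" &
                                        prof$event == "deletion"])
  expect_equal(length(del3p_clusters), 1)
})

test_that("overclustering is seeded and needs enough cells", {
  v <- matrix(rnorm(40 * 6), 40, 6)
  cna <- toy_cna(v)
  l1 <- overcluster_cells(cna, k_neighbors = 5, seed = 3)
  l2 <- overcluster_cells(cna, k_neighbors = 5, seed = 3)
  expect_identical(l1, l2)
  expect_error(overcluster_cells(toy_cna(matrix(0, 5, 6)), k_neighbors = 15),
               "at least")
})
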