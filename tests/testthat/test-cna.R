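test_that("gene ordering sorts columns by chromosome and start", {
  ann <- build_genome_model(5, data.frame(arm = c("1p", "2p"),
                                          genes = c(2, 3)))
  # feed genes in reversed order: chr2 genes first
  rev_ids <- rev(ann$gene_id)
  m <- make_expr(matrix(seq_len(10), 2, 5), space = "centered",
                 genes = rev_ids)
  ordered <- order_genes(m, ann)
  expect_identical(colnames(ordered$expr), ann$gene_id)
  expect_equal(ordered$annotation$order_index, 0:4)
  already <- make_expr(matrix(1:10, 2, 5), space = "centered",
                       genes = ann$gene_id)
  expect_identical(colnames(order_genes(already, ann)$expr), ann$gene_id)
})

test_that("unannotated genes are dropped, too few annotated errors", {
  ann <- tiny_genome(3, c("1p", "1q"))
  m <- make_expr(matrix(0, 2, 8), space = "centered",
                 genes = c(ann$gene_id[1:5], "alien1", "alien2", "alien3"))
  expect_warning(res <- order_genes(m, ann), "unannotated")
  expect_equal(ncol(res$expr), 5)
  mostly_alien <- make_expr(matrix(0, 2, 8), space = "centered",
                            genes = c(ann$gene_id[1:3], sprintf("x%d", 1:5)))
  expect_error(order_genes(mostly_alien, ann), "50%")
})

test_that("clipping limits values symmetrically", {
  m <- matrix(c(3.7, -5, 2, 0, -3, 3), 2, 3)
  expect_equal(as.vector(clip_values(m, 3)), c(3, -3, 2, 0, -3, 3))
})

test_that("moving average reproduces the worked single-chromosome example", {
  ann <- build_genome_model(5, data.frame(arm = "1p", genes = 5))
  m <- matrix(c(0, 3, 0, 3, 0), 1, dimnames = list("c", ann$gene_id))
  expect_equal(as.vector(moving_average(m, ann, 3)), c(1.5, 1, 2, 1, 1.5))
})

test_that("windows never span chromosomes and window=1 is the identity", {
  ann <- build_genome_model(10, data.frame(arm = c("1p", "2p"),
                                           genes = c(5, 5)))
  m <- matrix(c(rep(0, 5), rep(6, 5)), 1, dimnames = list("c", ann$gene_id))
  sm <- moving_average(m, ann, 3)
  expect_equal(as.vector(sm), c(rep(0, 5), rep(6, 5)))
  set.seed(5)
  r <- matrix(rnorm(30), 3, 10, dimnames = list(letters[1:3], ann$gene_id))
  expect_equal(moving_average(r, ann, 1), r)
  const <- matrix(2, 2, 10, dimnames = list(c("a", "b"), ann$gene_id))
  expect_equal(moving_average(const, ann, 100), const)
})

test_that("moving average matches the brute-force oracle on random input", {
  set.seed(6)
  for (rep in 1:10) {
    n_chrom <- sample(1:3, 1)
    genes <- sample(3:12, n_chrom, replace = TRUE)
    ann <- build_genome_model(sum(genes), data.frame(
      arm = paste0(seq_len(n_chrom), "p"), genes = genes
    ))
    m <- matrix(rnorm(4 * sum(genes)), 4, sum(genes),
                dimnames = list(sprintf("c%d", 1:4), ann$gene_id))
    for (w in c(1, 2, 3, 5, 7)) {
      expect_equal(moving_average(m, ann, w),
                   oracle_moving_average(m, ann, w))
    }
  }
})

test_that("adding a constant to one chromosome shifts its smoothed values by it", {
  ann <- build_genome_model(12, data.frame(arm = c("1p", "2p"),
                                           genes = c(6, 6)))
  set.seed(7)
  m <- matrix(rnorm(24), 2, 12, dimnames = list(c("a", "b"), ann$gene_id))
  shifted <- m
  shifted[1, ann$chromosome == "1"] <- shifted[1, ann$chromosome == "1"] + 0.7
  base <- moving_average(m, ann, 4)
  out <- moving_average(shifted, ann, 4)
  expect_equal(out[1, ann$chromosome == "1"],
               base[1, ann$chromosome == "1"] + 0.7)
  expect_equal(out[1, ann$chromosome == "2"], base[1, ann$chromosome == "2"])
  expect_equal(out[2, ], base[2, ])
})

test_that("reference subtraction follows the max/min rule with sign clamp", {
  m <- matrix(c(0.5, -0.5, 0.25, 0), 1)
  ref <- rbind(c(0.1, -0.2, 0.3, 0.1),
               c(0.2, 0.0, 0.1, 0.0),
               c(0.3, 0.1, 0.2, -0.1))
  out <- subtract_reference(m, ref)
  expect_equal(as.vector(out), c(0.5 - 0.3, -0.5 - (-0.2), 0, 0))
  expect_error(subtract_reference(m, matrix(numeric(0), 0, 4)),
               "reference type")
})

test_that("noise floor zeroes the open band and keeps the boundary", {
  m <- matrix(c(0.149, -0.151, 0, 0.15, -0.15, 0.3), 1)
  out <- apply_noise_floor(m, 0.15)
  expect_equal(as.vector(out), c(0, -0.151, 0, 0.15, -0.15, 0.3))
})

test_that("event-free cohort yields a mostly-zero CNA matrix", {
  spec <- null_cohort(seed = 10, n_target = 40)
  sim <- simulate_expression(spec)
  ref <- build_pooled_reference(sim$meta, seed = 2)
  asm <- assemble_patient_matrix(sim$expr, sim$meta, "D1", reference = ref)
  cna <- infer_cna(asm$expr, spec$genome, ref)
  expect_gte(mean(cna$values[ref$cell_id, ] == 0), 0.95)
  expect_gte(mean(cna$values == 0), 0.9)
  expect_true(all(abs(cna$values) <= 2 * cna$params$clip_bound))
})

test_that("a noiseless cohort with no events gives an identically zero matrix", {
  spec <- null_cohort(seed = 11, n_target = 20)
  spec$noise_sd <- 0
  spec$depth_sd <- 0
  sim <- simulate_expression(spec)
  ref <- build_pooled_reference(sim$meta, seed = 1)
  asm <- assemble_patient_matrix(sim$expr, sim$meta, "D1", reference = ref)
  cna <- infer_cna(asm$expr, spec$genome, ref)
  expect_true(all(cna$values == 0))
})

test_that("a planted 3p deletion depresses 3p positions of carriers only", {
  spec <- clone_recovery_cohort(seed = 12, noise_sd = 0.5)
  sim <- simulate_expression(spec)
  ref <- build_pooled_reference(sim$meta, seed = 3)
  asm <- assemble_patient_matrix(sim$expr, sim$meta, "D1", reference = ref)
  cna <- infer_cna(asm$expr, spec$genome, ref)
  p3 <- cna$annotation$arm == "3p"
  tumor <- sim$meta$cell_id[sim$meta$cell_type == "neuroendocrine"]
  glia_noncarrier <- setdiff(
    sim$meta$cell_id[sim$meta$cell_type == "schwann"],
    sim$truth$cell_id[carrier_of(sim$truth, "3p:deletion")]
  )
  expect_lt(mean(cna$values[tumor, p3]), -cna$params$noise_floor)
  expect_lt(abs(mean(cna$values[glia_noncarrier, p3])), 0.1)
})
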