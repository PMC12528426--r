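de_matrix <- function(a, b, extra_genes = 0, seed = 1) {
  # one contrast gene + `extra_genes` null genes; groups stacked A then B
  set.seed(seed)
  na <- length(a)
  nb <- length(b)
  v <- cbind(c(a, b),
             matrix(rnorm((na + nb) * extra_genes, 5), na + nb))
  make_expr(v, space = "log",
            cells = c(sprintf("a%02d", seq_len(na)),
                      sprintf("b%02d", seq_len(nb))))
}

test_that("complete separation at n=m=10 gives the exact enumeration p", {
  m <- de_matrix(rep(8, 10) + (1:10) * 1e-6, rep(0, 10) + (1:10) * 1e-6)
  res <- pairwise_de_wilcoxon(m, sprintf("a%02d", 1:10), sprintf("b%02d", 1:10))
  expect_equal(res$raw_p[1], 2 / choose(20, 10), tolerance = 1e-12)
  expect_true(res$significant_up[1])
})

test_that("rank-sum p matches the enumeration oracle for small groups", {
  set.seed(11)
  for (rep in 1:8) {
    na <- sample(3:6, 1)
    nb <- sample(3:6, 1)
    x <- rnorm(na)
    y <- rnorm(nb, 0.5)
    m <- de_matrix(c(x, y), numeric(0), extra_genes = 0)
    # build the matrix manually: one gene, two groups
    v <- matrix(c(x, y), ncol = 1)
    mm <- make_expr(v, space = "log",
                    cells = c(sprintf("a%02d", seq_len(na)),
                              sprintf("b%02d", seq_len(nb))))
    res <- pairwise_de_wilcoxon(mm, sprintf("a%02d", seq_len(na)),
                                sprintf("b%02d", seq_len(nb)))
    expect_equal(res$raw_p, oracle_ranksum_p(x, y), tolerance = 1e-12)
  }
})

test_that("Bonferroni adjustment is min(1, p * n_tested)", {
  m <- de_matrix(rep(8, 10) + (1:10) * 1e-6, rep(0, 10) + (1:10) * 1e-6,
                 extra_genes = 49)
  res <- pairwise_de_wilcoxon(m, sprintf("a%02d", 1:10), sprintf("b%02d", 1:10))
  expect_equal(res$adjusted_p, pmin(1, res$raw_p * 50))
  expect_true(all(res$adjusted_p >= res$raw_p))
  expect_true(all(res$adjusted_p <= 1))
})

test_that("identical groups yield no significant genes; lfc threshold is strict", {
  set.seed(12)
  v <- matrix(rnorm(120, 5), 12, 10)
  m <- make_expr(v, space = "log")
  cells <- rownames(m)
  res <- pairwise_de_wilcoxon(m, cells[1:6], cells[1:6])
  expect_false(any(res$significant_up))
  # log2FC exactly at the threshold must not pass
  sep <- make_expr(
    cbind(c(rep(1.5, 6) + (1:6) * 1e-9, rep(1, 6) + (1:6) * 1e-9)),
    space = "log"
  )
  r2 <- pairwise_de_wilcoxon(sep, rownames(sep)[1:6], rownames(sep)[7:12],
                             lfc_min = 0.5)
  expect_equal(r2$log2_fold_change, 0.5, tolerance = 1e-8)
  expect_false(any(r2$significant_up))
  expect_error(pairwise_de_wilcoxon(m, cells[1:2], cells[3:12]), "3 cells")
})

test_that("cluster-specific genes are the intersection across all pairwise tests", {
  set.seed(13)
  n <- 8
  base <- matrix(rnorm(3 * n * 20, 5, 0.3), 3 * n, 20)
  # gene 1 up in cluster 1 vs both others; gene 2 up only vs cluster 2
  base[1:n, 1] <- base[1:n, 1] + 3
  base[1:n, 2] <- base[1:n, 2] + 3
  base[(2 * n + 1):(3 * n), 2] <- base[(2 * n + 1):(3 * n), 2] + 3
  m <- make_expr(base, space = "log")
  labels <- setNames(rep(1:3, each = n), rownames(m))
  spec1 <- specific_degs(m, labels, 1)
  expect_true("gene001" %in% spec1$gene_id)
  expect_false("gene002" %in% spec1$gene_id)
  # the specific set is contained in every pairwise up-list
  comps <- attr(spec1, "comparisons")
  for (cmp in unique(comps$comparison)) {
    up <- comps$gene_id[comps$comparison == cmp & comps$significant_up]
    expect_true(all(spec1$gene_id %in% up))
  }
  # with 2 clusters the specific set equals the single pairwise up-list
  two <- specific_degs(m, labels[labels != 3], 1)
  single <- pairwise_de_wilcoxon(m, names(labels)[labels == 1],
                                 names(labels)[labels == 2])
  expect_setequal(two$gene_id, single$gene_id[single$significant_up])
  expect_error(specific_degs(m, labels[labels == 1], 1), "2 clusters")
})

test_that("recurrent DE requires the gene to pass against every other sample", {
  set.seed(14)
  n <- 6
  n_samples <- 5
  v <- matrix(rnorm(n_samples * n * 12, 5, 0.2), n_samples * n, 12)
  labels <- setNames(rep(sprintf("S%d", 1:n_samples), each = n),
                     sprintf("cell%03d", seq_len(n_samples * n)))
  # gene 1: up in focal S1 only; gene 2: up in S1 and equally in S2
  v[labels == "S1", 1] <- v[labels == "S1", 1] + 2
  v[labels == "S1", 2] <- v[labels == "S1", 2] + 2
  v[labels == "S2", 2] <- v[labels == "S2", 2] + 2
  m <- make_expr(v, space = "log", cells = names(labels))
  res <- recurrent_pairwise_de(m, labels, "S1")
  expect_true("gene001" %in% res$gene_id)
  expect_false("gene002" %in% res$gene_id)
  # focal identical to all -> empty
  null_m <- make_expr(matrix(rnorm(n_samples * n * 5, 5, 0.2),
                             n_samples * n, 5),
                      space = "log", cells = names(labels))
  expect_equal(nrow(recurrent_pairwise_de(null_m, labels, "S1")), 0)
})

test_that("raising the fold-change threshold never adds genes", {
  set.seed(15)
  n <- 8
  v <- matrix(rnorm(2 * n * 30, 5, 0.5), 2 * n, 30)
  v[1:n, 1:10] <- v[1:n, 1:10] + matrix(rep(seq(0.4, 2.2, length.out = 10),
                                            each = n), n, 10)
  m <- make_expr(v, space = "log")
  labels <- setNames(rep(c("S1", "S2"), each = n), rownames(m))
  loose <- recurrent_pairwise_de(m, labels, "S1", lfc_min = 0.5)
  strict <- recurrent_pairwise_de(m, labels, "S1", lfc_min = 1.5)
  expect_true(all(strict$gene_id %in% loose$gene_id))
})
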