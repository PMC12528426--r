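# Shared fixtures and independent oracles used across the suite.

make_expr <- function(values, space = "raw", cells = NULL, genes = NULL) {
  values <- as.matrix(values)
  rownames(values) <- cells %||% sprintf("cell%03d", seq_len(nrow(values)))
  colnames(values) <- genes %||% sprintf("gene%03d", seq_len(ncol(values)))
  expr_matrix(values, space)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

tiny_genome <- function(genes_per_arm = 5, arms = c("1p", "1q", "2p", "2q")) {
  build_genome_model(
    genes_per_arm * length(arms),
    data.frame(arm = arms, genes = genes_per_arm)
  )
}

# Brute-force moving-average oracle: explicit window enumeration per
# chromosome, independent of the cumulative-sum implementation.
oracle_moving_average <- function(m, ann, window) {
  left <- (window - 1) %/% 2
  right <- window %/% 2
  out <- m
  for (i in seq_len(nrow(m))) {
    for (j in seq_len(ncol(m))) {
      same <- which(ann$chromosome == ann$chromosome[j])
      win <- intersect(same, (j - left):(j + right))
      out[i, j] <- mean(m[i, win])
    }
  }
  out
}

# Exact two-sided rank-sum p by full enumeration of group assignments.
oracle_ranksum_p <- function(x, y) {
  n <- length(x)
  pooled <- c(x, y)
  r <- rank(pooled)
  obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  combs <- utils::combn(length(pooled), n)
  u <- apply(combs, 2, function(idx) sum(r[idx]) - n * (n + 1) / 2)
  p_le <- mean(u <= obs)
  p_ge <- mean(u >= obs)
  min(1, 2 * min(p_le, p_ge))
}

# Adjusted Rand index from the contingency-table closed form.
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(1)
  (sum_ij - expected) / (max_idx - expected)
}

carrier_of <- function(truth, label) {
  vapply(truth$events, function(e) label %in% e, logical(1))
}
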