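#' Keep the most informative genome positions
#'
#' Ranks positions by mean absolute CNA value across cells and keeps the
#' top `ceiling(fraction * n)` of them, ties broken by genome order, with
#' the kept positions returned in genome order. All cells remain, so the
#' reduction only concentrates the clustering on informative loci.
#'
#' @param cna a [cna_matrix()].
#' @param fraction fraction of positions kept (default 2/3).
#' @return A reduced [cna_matrix()].
#' @export
select_top_positions <- function(cna, fraction = 2 / 3) {
  stopifnot(inherits(cna, "cna_matrix"), fraction > 0, fraction <= 1)
  n <- ncol(cna$values)
  if (!n) abort("Empty CNA matrix.")
  k <- ceiling(fraction * n)
  score <- colMeans(abs(cna$values))
  keep <- sort(order(-score, seq_len(n))[seq_len(k)])
  cna_matrix(
    cna$values[, keep, drop = FALSE],
    cna$annotation[keep, , drop = FALSE],
    params = cna$params, reference = cna$reference
  )
}

#' Overcluster cells on their CNA profiles
#'
#' Embeds the (reduced) CNA matrix in a low-dimensional principal
#' component space, builds a k-nearest-neighbour graph and partitions it
#' with Louvain modularity optimisation. With a small neighbourhood
#' (default k = 15) this deliberately over-partitions, which the
#' profile-merging step then collapses. Deterministic given `seed`.
#'
#' @param cna a [cna_matrix()] (typically from [select_top_positions()]).
#' @param cells optional cell ids to cluster (default: all non-reference
#'   cells if the matrix records a reference, else all cells).
#' @param k_neighbors neighbourhood size (default 15).
#' @param n_pcs number of principal components for the embedding
#'   (default 10, capped by the data).
#' @param seed integer seed.
#' @return Named integer vector of initial cluster labels.
#' @export
overcluster_cells <- function(cna, cells = NULL, k_neighbors = 15,
                              n_pcs = 10, seed = 1L) {
  stopifnot(inherits(cna, "cna_matrix"))
  v <- cna$values
  if (is.null(cells)) {
    cells <- rownames(v)
    if (is.data.frame(cna$reference)) {
      cells <- setdiff(cells, cna$reference$cell_id)
    }
  }
  v <- v[cells, , drop = FALSE]
  n <- nrow(v)
  if (n < k_neighbors + 1) {
    abort(sprintf("Need at least %d cells to cluster.", k_neighbors + 1))
  }
  rank <- min(n_pcs, n - 1L, ncol(v))
  emb <- tryCatch(
    prcomp(v, rank. = rank, center = TRUE, scale. = FALSE)$x,
    error = function(e) v
  )
  d <- as.matrix(dist(emb))
  diag(d) <- Inf
  edges <- do.call(rbind, lapply(seq_len(n), function(i) {
    nn <- order(d[i, ])[seq_len(k_neighbors)]
    cbind(i, nn)
  }))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::simplify(g)
  set.seed(seed)
  comm <- igraph::cluster_louvain(g)
  labels <- as.integer(igraph::membership(comm))
  names(labels) <- rownames(v)
  labels
}

#' Call chromosome-arm events for a set of cells
#'
#' Averages CNA values over the given cells and each arm's positions; an
#' arm is a deletion if the mean is below `-threshold`, an amplification
#' if above `threshold`, else none. Arms of the annotation with no
#' positions in the matrix yield `"none"` with a warning.
#'
#' @param cna a [cna_matrix()].
#' @param cells cell ids to average over (default: all rows).
#' @param threshold event threshold on the arm mean (default 0.15).
#' @param arms arms to report (default: all arms in the annotation).
#' @return Tibble with `arm`, `mean_cna`, `event`.
#' @export
call_arm_events <- function(cna, cells = NULL, threshold = 0.15,
                            arms = NULL) {
  stopifnot(inherits(cna, "cna_matrix"))
  cells <- cells %||% rownames(cna$values)
  if (!length(cells)) abort("`cells` must be nonempty.")
  arms <- arms %||% unique(cna$annotation$arm)
  v <- cna$values[cells, , drop = FALSE]
  means <- vapply(arms, function(a) {
    idx <- which(cna$annotation$arm == a)
    if (!length(idx)) {
      warn(sprintf("Arm %s has no positions in the matrix.", a))
      return(NA_real_)
    }
    mean(v[, idx])
  }, numeric(1))
  tibble(
    arm = arms,
    mean_cna = unname(means),
    event = dplyr::case_when(
      is.na(means) ~ "none",
      means < -threshold ~ "deletion",
      means > threshold ~ "amplification",
      .default = "none"
    )
  )
}

#' Per-cell chromosome-arm events
#'
#' Vectorised [call_arm_events()] applied to each cell separately.
#'
#' @inheritParams call_arm_events
#' @return Long tibble with `cell_id`, `arm`, `mean_cna`, `event`.
#' @export
cell_arm_events <- function(cna, cells = NULL, threshold = 0.15) {
  stopifnot(inherits(cna, "cna_matrix"))
  cells <- cells %||% rownames(cna$values)
  arms <- unique(cna$annotation$arm)
  v <- cna$values[cells, , drop = FALSE]
  arm_means <- vapply(arms, function(a) {
    rowMeans(v[, cna$annotation$arm == a, drop = FALSE])
  }, numeric(length(cells)))
  if (length(cells) == 1) arm_means <- matrix(arm_means, 1)
  tibble(
    cell_id = rep(cells, times = length(arms)),
    arm = rep(arms, each = length(cells)),
    mean_cna = as.vector(arm_means)
  ) |>
    dplyr::mutate(event = dplyr::case_when(
      .data$mean_cna < -threshold ~ "deletion",
      .data$mean_cna > threshold ~ "amplification",
      .default = "none"
    ))
}

profile_signature <- function(profile) {
  paste(profile$event, collapse = "|")
}

#' Merge clusters with identical arm-event profiles
#'
#' Iteratively computes each cluster's arm-event profile on the full CNA
#' matrix, merges all clusters sharing an identical profile, recomputes
#' on the merged clusters and repeats until every remaining pair of
#' clusters differs on at least one arm. The cluster count strictly
#' decreases each merging round, so the loop terminates in at most
#' (initial clusters - 1) rounds.
#'
#' @param cna a [cna_matrix()] (full, not position-reduced).
#' @param labels named integer vector of initial labels from
#'   [overcluster_cells()].
#' @param threshold arm-event threshold (default 0.15).
#' @return A `subclone_result`: list with `assignments` (tibble
#'   `cell_id`, `cluster`), `profiles` (long tibble `cluster`, `arm`,
#'   `mean_cna`, `event`), `history` (one tibble per merge round) and
#'   `n_rounds`.
#' @export
merge_identical_clusters <- function(cna, labels, threshold = 0.15) {
  stopifnot(inherits(cna, "cna_matrix"))
  current <- labels
  history <- list()
  initial_k <- length(unique(current))
  repeat {
    clusters <- sort(unique(current))
    profs <- lapply(clusters, function(cl) {
      call_arm_events(cna, names(current)[current == cl], threshold)
    })
    names(profs) <- clusters
    sigs <- vapply(profs, profile_signature, character(1))
    dup_groups <- split(clusters, sigs)
    dup_groups <- dup_groups[lengths(dup_groups) > 1]
    if (!length(dup_groups)) {
      profiles <- dplyr::bind_rows(
        purrr::imap(profs, ~ dplyr::mutate(.x, cluster = as.integer(.y)))
      )[, c("cluster", "arm", "mean_cna", "event")]
      return(structure(
        list(
          assignments = tibble(
            cell_id = names(current), cluster = unname(current)
          ),
          profiles = profiles,
          history = history,
          n_rounds = length(history),
          initial_clusters = initial_k
        ),
        class = "subclone_result"
      ))
    }
    merges <- purrr::map_dfr(dup_groups, function(g) {
      tibble(from = g[-1], into = g[1])
    })
    history[[length(history) + 1]] <- merges
    for (i in seq_len(nrow(merges))) {
      current[current == merges$from[i]] <- merges$into[i]
    }
  }
}

#' Detect genetic subclones from a CNA matrix
#'
#' Composition of [select_top_positions()], [overcluster_cells()] and
#' [merge_identical_clusters()]: cluster cells on the most informative
#' positions, then collapse clusters until every remaining cluster's
#' chromosome-arm event profile is unique. Arm events are always called
#' on the full matrix.
#'
#' @param cna a [cna_matrix()].
#' @param cells cells to cluster (default: non-reference cells).
#' @param fraction fraction of positions used for clustering
#'   (default 2/3).
#' @param k_neighbors neighbourhood size (default 15).
#' @param threshold arm-event threshold (default 0.15).
#' @param seed integer seed.
#' @return A `subclone_result` (see [merge_identical_clusters()]).
#' @export
detect_subclones <- function(cna, cells = NULL, fraction = 2 / 3,
                             k_neighbors = 15, threshold = 0.15,
                             seed = 1L) {
  reduced <- select_top_positions(cna, fraction)
  labels <- overcluster_cells(reduced, cells = cells,
                              k_neighbors = k_neighbors, seed = seed)
  merge_identical_clusters(cna, labels, threshold)
}

#' @export
print.subclone_result <- function(x, ...) {
  k <- length(unique(x$assignments$cluster))
  cat(sprintf(
    "<subclone_result> %d cells, %d cluster(s) after %d merge round(s) (from %d)\n",
    nrow(x$assignments), k, x$n_rounds, x$initial_clusters
  ))
  ev <- dplyr::filter(x$profiles, .data$event != "none")
  if (nrow(ev)) {
    for (cl in unique(ev$cluster)) {
      e <- ev[ev$cluster == cl, ]
      cat(sprintf(
        "  cluster %d: %s\n", cl,
        paste(e$arm, substr(e$event, 1, 3), collapse = ", ")
      ))
    }
  } else {
    cat("  no arm events called\n")
  }
  invisible(x)
}
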