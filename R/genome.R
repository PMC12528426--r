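#' @section Coordinate conventions:
#' All genomic files and tables use 0-based half-open intervals (BED
#' convention); `order_index` is a 0-based genome-wide rank.
#' @name cnaclone-conventions
#' @keywords internal
NULL

# Natural chromosome order: 1..22 numerically, then X, Y, MT, then others.
chrom_rank <- function(chrom) {
  base <- sub("^chr", "", chrom)
  n <- suppressWarnings(as.numeric(base))
  special <- match(base, c("X", "Y", "M", "MT"))
  ifelse(!is.na(n), n,
    ifelse(!is.na(special), 100 + special,
      200 + as.numeric(factor(base))
    )
  )
}

arm_to_chrom <- function(arm) sub("[pq]$", "", arm)

finalize_annotation <- function(ann) {
  ord <- order(chrom_rank(ann$chromosome), ann$start, ann$gene_id)
  ann <- ann[ord, , drop = FALSE]
  ann$order_index <- seq_len(nrow(ann)) - 1L
  as_tibble(ann)
}

#' Build a synthetic genome model from an arm layout
#'
#' Lays `n_genes` genes out on the chromosome arms given in `arm_table`,
#' assigning unique gene ids, strictly increasing start coordinates within
#' each chromosome, one arm per gene, and a genome-wide `order_index`.
#' Deterministic: no randomness is involved.
#'
#' @param n_genes total number of genes; must equal the sum of
#'   `arm_table$genes`.
#' @param arm_table data frame with columns `arm` (e.g. `"3p"`) and `genes`
#'   (count per arm, all >= 1).
#' @param gene_spacing distance in bp between consecutive gene starts
#'   (default 1e4).
#' @return A tibble with columns `gene_id`, `chromosome`, `start`, `arm`,
#'   `order_index`, plus an `"arm_table"` attribute holding the 0-based
#'   half-open arm intervals.
#' @examples
#' ann <- build_genome_model(100, data.frame(
#'   arm = c("1p", "1q"),
#'   genes = c(50, 50)
#' ))
#' table(ann$arm)
#' @export
build_genome_model <- function(n_genes, arm_table, gene_spacing = 1e4) {
  arm_table <- as.data.frame(arm_table)
  if (!all(c("arm", "genes") %in% names(arm_table))) {
    abort("`arm_table` needs columns `arm` and `genes`.")
  }
  if (anyDuplicated(arm_table$arm)) abort("Duplicate arms in `arm_table`.")
  if (any(arm_table$genes < 1)) {
    abort("Every declared arm must hold at least one gene.")
  }
  if (sum(arm_table$genes) != n_genes) {
    abort(sprintf(
      "`n_genes` (%d) != sum of arm gene counts (%d).",
      n_genes, sum(arm_table$genes)
    ))
  }
  arm_table$chromosome <- arm_to_chrom(arm_table$arm)
  # p arms precede q arms on a chromosome regardless of listing order
  arm_table <- arm_table[order(
    chrom_rank(arm_table$chromosome),
    substring(arm_table$arm, nchar(arm_table$arm))
  ), , drop = FALSE]

  pieces <- vector("list", nrow(arm_table))
  offsets <- ave(arm_table$genes, arm_table$chromosome,
    FUN = function(g) cumsum(c(0, head(g, -1)))
  )
  for (i in seq_len(nrow(arm_table))) {
    k <- arm_table$genes[i]
    within <- offsets[i] + seq_len(k) - 1L
    pieces[[i]] <- data.frame(
      chromosome = arm_table$chromosome[i],
      start = within * gene_spacing,
      arm = arm_table$arm[i]
    )
  }
  ann <- do.call(rbind, pieces)
  ann$gene_id <- sprintf("G%05d", seq_len(nrow(ann)))
  ann <- finalize_annotation(ann[, c("gene_id", "chromosome", "start", "arm")])

  bounds <- do.call(rbind, lapply(split(ann, ann$arm), function(a) {
    data.frame(
      chromosome = a$chromosome[1], arm = a$arm[1],
      start = min(a$start), end = max(a$start) + gene_spacing
    )
  }))
  bounds <- bounds[order(chrom_rank(bounds$chromosome), bounds$start), ]
  attr(ann, "arm_table") <- as_tibble(bounds)
  ann
}

#' Read gene annotation from a BED-like file plus an arm table
#'
#' Genes come from a BED-like TSV (`chrom start end gene_id`, no header,
#' 0-based half-open). Arms come from a cytoband-like TSV with header
#' columns `chrom`, `arm`, `start`, `end`; `arm` may be `"p"`/`"q"` or the
#' full label (`"3p"`). A gene is assigned the arm whose interval contains
#' its start; genes falling outside every arm are dropped with a warning.
#'
#' @param genes_bed path to the BED-like gene file.
#' @param arms_tsv path to the arm interval table.
#' @return Annotation tibble as from [build_genome_model()].
#' @export
read_annotation <- function(genes_bed, arms_tsv) {
  genes <- utils::read.table(genes_bed,
    sep = "\t", header = FALSE,
    col.names = c("chromosome", "start", "end", "gene_id"),
    colClasses = c("character", "integer", "integer", "character")
  )
  if (anyDuplicated(genes$gene_id)) abort("Duplicate gene ids in BED file.")
  if (any(genes$end <= genes$start)) abort("Malformed BED interval (end <= start).")
  arms <- utils::read.table(arms_tsv, sep = "\t", header = TRUE)
  if (!all(c("chrom", "arm", "start", "end") %in% names(arms))) {
    abort("Arm table needs columns chrom, arm, start, end.")
  }
  arms$chrom <- as.character(arms$chrom)
  arms$arm <- ifelse(grepl("^[pq]$", arms$arm),
    paste0(sub("^chr", "", arms$chrom), arms$arm), as.character(arms$arm)
  )
  # reject overlapping arm intervals on one chromosome
  for (ch in unique(arms$chrom)) {
    a <- arms[arms$chrom == ch, ]
    a <- a[order(a$start), ]
    if (nrow(a) > 1 && any(a$start[-1] < a$end[-nrow(a)])) {
      abort(sprintf("Overlapping arm intervals on chromosome %s.", ch))
    }
  }
  idx <- mapply(function(ch, s) {
    hit <- which(arms$chrom == ch & arms$start <= s & s < arms$end)
    if (length(hit)) hit[1] else NA_integer_
  }, genes$chromosome, genes$start)
  if (anyNA(idx)) {
    warn(sprintf(
      "%d gene(s) fall outside every arm interval and were dropped.",
      sum(is.na(idx))
    ))
    genes <- genes[!is.na(idx), , drop = FALSE]
    idx <- idx[!is.na(idx)]
  }
  if (!nrow(genes)) abort("No genes left after arm assignment.")
  genes$arm <- arms$arm[idx]
  finalize_annotation(genes[, c("gene_id", "chromosome", "start", "arm")])
}

#' Arm intervals attached to a synthetic genome model
#' @param ann annotation from [build_genome_model()].
#' @return Tibble with `chromosome`, `arm`, `start`, `end`.
#' @export
genome_arm_table <- function(ann) {
  tab <- attr(ann, "arm_table")
  if (is.null(tab)) abort("Annotation carries no arm table attribute.")
  tab
}
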