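# Single-cell expression summarization: TPM normalization of a count
# matrix, gene-set aggregation, and the per-cluster dot-plot statistics
# (percent expressed, z-scored cluster means).

#' Transcripts-per-million normalization
#'
#' Per cell: TPM_g = (count_g / length_g) / sum_j(count_j / length_j) * 1e6.
#' Cells with zero total counts keep an all-zero row (reported via message).
#'
#' @param counts nonnegative count matrix, cells x genes
#' @param effective_length positive per-gene effective lengths
#' @return TPM matrix, same shape as `counts`
#' @export
compute_tpm <- function(counts, effective_length) {
  stopifnot(ncol(counts) == length(effective_length))
  if (any(effective_length <= 0))
    stop("effective lengths must be positive", call. = FALSE)
  rate <- sweep(counts, 2, effective_length, "/")
  tot <- rowSums(rate)
  empty <- tot == 0
  if (any(empty))
    message(sprintf("%d cell(s) with zero counts left as all-zero rows",
                    sum(empty)))
  tot[empty] <- 1
  rate / tot * 1e6
}

#' Aggregate expression over a gene set
#'
#' Per-cell sum of TPM over the member genes; used to summarize a gene
#' module as one expression profile.
#'
#' @param tpm TPM matrix, cells x genes, with gene colnames
#' @param gene_set nonempty character vector of member genes
#' @return numeric vector, one value per cell
#' @export
aggregate_gene_set <- function(tpm, gene_set) {
  if (length(gene_set) == 0) stop("gene set is empty", call. = FALSE)
  missing <- setdiff(gene_set, colnames(tpm))
  if (length(missing))
    stop("unknown gene(s): ", paste(missing, collapse = ", "), call. = FALSE)
  rowSums(tpm[, gene_set, drop = FALSE])
}

#' Cluster dot-plot statistics
#'
#' For each gene and cluster: the fraction of the cluster's cells with
#' expression above `detect_min` (Exp%), and the cluster mean z-scored
#' across clusters (population standard deviation).  With a single cluster
#' or zero variance across cluster means, the z-score is reported as 0 with
#' `degenerate = TRUE`.
#'
#' @param expr expression matrix (cells x genes), typically TPM
#' @param clusters per-cell cluster labels
#' @param detect_min detection threshold for Exp% (default 0: "> 0")
#' @return data.frame with `cluster`, `gene`, `exp_pct`, `mean_expr`,
#'   `z_mean`, `degenerate`
#' @export
cluster_dot_stats <- function(expr, clusters, detect_min = 0) {
  stopifnot(nrow(expr) == length(clusters))
  labs <- sort(unique(as.character(clusters)))
  counts <- table(factor(clusters, levels = labs))
  if (any(counts == 0)) stop("empty cluster", call. = FALSE)
  genes <- colnames(expr) %||% as.character(seq_len(ncol(expr)))
  out <- lapply(seq_along(genes), function(j) {
    v <- expr[, j]
    m <- vapply(labs, function(cl) mean(v[clusters == cl]), numeric(1))
    pct <- vapply(labs, function(cl) mean(v[clusters == cl] > detect_min),
                  numeric(1))
    sd_pop <- sqrt(mean((m - mean(m))^2))
    degen <- length(labs) < 2 || sd_pop == 0
    z <- if (degen) rep(0, length(labs)) else (m - mean(m)) / sd_pop
    data.frame(cluster = labs, gene = genes[j], exp_pct = pct,
               mean_expr = m, z_mean = z, degenerate = degen,
               stringsAsFactors = FALSE, row.names = NULL)
  })
  do.call(rbind, out)
}
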