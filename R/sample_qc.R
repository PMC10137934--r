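# Sample-level quality control: contamination and call-rate filters, a
# robust variant-count outlier rule, kinship pruning, and principal-component
# ancestry filtering.  Filters are applied in a fixed order and each sample
# receives exactly one qc_status: the first rule it fails.

#' Sample-level QC thresholds
#'
#' Defaults follow standard exome-cohort practice: FREEMIX contamination
#' above 0.075 fails (strict), call missingness above 0.10 fails (strict),
#' variant-count outliers beyond `outlier_k` scaled MADs from the median
#' fail, kinship above 0.09375 (second-degree bound) flags a pair, samples in
#' `relationship_hub_min` or more flagged pairs are dropped outright, and
#' ancestry is assessed on common variants (AF > `pca_common_af_min`).
#'
#' @param freemix_max maximum tolerated contamination fraction
#' @param sample_missingness_max maximum tolerated call missingness
#' @param outlier_k multiplier on the scaled MAD (constant 1.4826) for the
#'   variant-count outlier rule; `Inf` disables it
#' @param kinship_cutoff KING-robust kinship threshold for relatedness
#' @param relationship_hub_min flagged-pair count at which a sample is
#'   removed as a relationship hub
#' @param pca_common_af_min minimum allele frequency for PCA sites
#' @param pca_n_components number of principal components examined
#' @param pca_sd_multiple per-component outlier bound in reference-cohort
#'   standard deviations
#' @return list of thresholds
#' @export
qc_thresholds <- function(freemix_max = 0.075,
                          sample_missingness_max = 0.10,
                          outlier_k = 4,
                          kinship_cutoff = 0.09375,
                          relationship_hub_min = 5,
                          pca_common_af_min = 0.05,
                          pca_n_components = 10,
                          pca_sd_multiple = 6) {
  th <- list(freemix_max = freemix_max,
             sample_missingness_max = sample_missingness_max,
             outlier_k = outlier_k,
             kinship_cutoff = kinship_cutoff,
             relationship_hub_min = relationship_hub_min,
             pca_common_af_min = pca_common_af_min,
             pca_n_components = pca_n_components,
             pca_sd_multiple = pca_sd_multiple)
  stopifnot(all(vapply(th, function(x) is.numeric(x) && length(x) == 1 && !is.na(x),
                       logical(1))))
  th
}

#' Contamination, missingness and variant-count outlier filters
#'
#' Applies the per-sample metric filters in order: contamination
#' (freemix > `freemix_max`, strict), call missingness
#' (> `sample_missingness_max`, strict), then variant-count outliers
#' (|count - median| > `outlier_k` * scaled MAD, computed over samples that
#' passed the first two rules).  The first failing rule sets `qc_status`.
#'
#' @param samples data.frame with at least `sample_id`, `freemix`,
#'   `call_missingness`, `variant_count`
#' @param thresholds a [qc_thresholds()] list
#' @return `samples` with a `qc_status` column (`pass`, `fail_contamination`,
#'   `fail_missingness`, `fail_outlier`)
#' @export
filter_sample_metrics <- function(samples, thresholds = qc_thresholds()) {
  need <- c("freemix", "call_missingness", "variant_count")
  for (f in need) {
    bad <- is.na(samples[[f]])
    if (is.null(samples[[f]]) || any(bad))
      stop(sprintf("missing metric '%s' for sample(s): %s", f,
                   paste(samples$sample_id[bad], collapse = ", ")), call. = FALSE)
  }
  status <- rep("pass", nrow(samples))
  status[samples$freemix > thresholds$freemix_max] <- "fail_contamination"
  miss <- status == "pass" &
    samples$call_missingness > thresholds$sample_missingness_max
  status[miss] <- "fail_missingness"
  ok <- status == "pass"
  if (any(ok) && is.finite(thresholds$outlier_k)) {
    vc <- samples$variant_count[ok]
    med <- stats::median(vc)
    smad <- stats::mad(vc, constant = 1.4826)
    out <- abs(samples$variant_count - med) > thresholds$outlier_k * smad
    status[ok & out] <- "fail_outlier"
  }
  samples$qc_status <- status
  samples
}

#' Prune related samples
#'
#' Two passes over pairs with kinship above the cutoff: first, any sample
#' participating in `relationship_hub_min` or more flagged pairs is removed
#' (relationship hub); then each remaining flagged pair loses exactly one
#' member.  The member removed is the one with higher call missingness, with
#' ties broken by removing the control rather than the case (preserving case
#' power) and then the lexicographically larger sample id.  The result does
#' not depend on input row order.
#'
#' @param samples data.frame with `sample_id`, `cohort`, `call_missingness`,
#'   and a `qc_status` column; only `pass` samples participate
#' @param pairs data.frame of flagged pairs (`sample_i`, `sample_j`, `phi`)
#'   from [king_related_pairs()], possibly augmented with known pedigree
#'   pairs
#' @param thresholds a [qc_thresholds()] list
#' @return `samples` with `qc_status` set to `fail_related` for removed rows
#' @export
prune_related <- function(samples, pairs, thresholds = qc_thresholds()) {
  if (is.null(samples$qc_status)) samples$qc_status <- "pass"
  if (nrow(pairs) == 0) return(samples)
  active <- samples$sample_id[samples$qc_status == "pass"]
  pairs <- pairs[pairs$phi > thresholds$kinship_cutoff &
                   pairs$sample_i %in% active & pairs$sample_j %in% active, ,
                 drop = FALSE]
  if (nrow(pairs) == 0) return(samples)
  # canonical pair order for determinism
  lo <- pmin(pairs$sample_i, pairs$sample_j)
  hi <- pmax(pairs$sample_i, pairs$sample_j)
  ord <- order(lo, hi)
  pairs <- data.frame(sample_i = lo[ord], sample_j = hi[ord],
                      phi = pairs$phi[ord], stringsAsFactors = FALSE)
  removed <- character()
  deg <- table(c(pairs$sample_i, pairs$sample_j))
  hubs <- sort(names(deg)[deg >= thresholds$relationship_hub_min])
  removed <- c(removed, hubs)
  keep_pair <- !(pairs$sample_i %in% hubs | pairs$sample_j %in% hubs)
  pairs <- pairs[keep_pair, , drop = FALSE]
  miss <- stats::setNames(samples$call_missingness, samples$sample_id)
  coh <- stats::setNames(samples$cohort, samples$sample_id)
  for (k in seq_len(nrow(pairs))) {
    i <- pairs$sample_i[k]
    j <- pairs$sample_j[k]
    if (i %in% removed || j %in% removed) next
    victim <- if (miss[i] > miss[j]) i
    else if (miss[j] > miss[i]) j
    else if (coh[i] != coh[j]) {
      if (coh[i] == "control") i else j
    } else max(i, j)
    removed <- c(removed, victim)
  }
  samples$qc_status[samples$sample_id %in% removed &
                      samples$qc_status == "pass"] <- "fail_related"
  samples
}

#' Principal-component ancestry filter
#'
#' Standardizes common-variant dosages per site (center 2*AF, scale
#' sqrt(2*AF*(1-AF)), missing dosages imputed to the site mean), extracts the
#' top principal components, and fails any sample whose score on a retained
#' component lies outside mean +/- `pca_sd_multiple` standard deviations of
#' the reference cohort's scores.  Monomorphic or non-common sites are
#' dropped.
#'
#' @param geno dosage matrix (samples x sites); only rows of `pass` samples
#'   are used
#' @param samples data.frame with `sample_id`, `cohort`, optional `qc_status`
#' @param reference_cohort cohort label defining the reference score
#'   distribution (default `"control"`)
#' @param thresholds a [qc_thresholds()] list
#' @return list with updated `samples` (`fail_ancestry` set), the score
#'   matrix `scores`, and `n_sites_used`
#' @export
pca_ancestry_filter <- function(geno, samples, reference_cohort = "control",
                                thresholds = qc_thresholds()) {
  if (is.null(samples$qc_status)) samples$qc_status <- "pass"
  k <- thresholds$pca_n_components
  if (k == 0) return(list(samples = samples, scores = NULL, n_sites_used = 0L))
  act <- samples$qc_status == "pass"
  ids <- samples$sample_id[act]
  G <- geno[ids, , drop = FALSE]
  af <- colMeans(G, na.rm = TRUE) / 2
  common <- !is.na(af) & pmin(af, 1 - af) > thresholds$pca_common_af_min
  if (sum(common) < k)
    stop("fewer common polymorphic sites than requested components", call. = FALSE)
  if (sum(samples$cohort[act] == reference_cohort) < 2)
    stop("need at least 2 reference-cohort samples for ancestry filtering",
         call. = FALSE)
  G <- G[, common, drop = FALSE]
  af <- af[common]
  X <- sweep(G, 2, 2 * af, "-")
  X[is.na(G)] <- 0                      # impute to site mean, i.e. 0 after centering
  X <- sweep(X, 2, sqrt(2 * af * (1 - af)), "/")
  # exact PCA via the smaller Gram matrix
  if (ncol(X) <= nrow(X)) {
    ev <- eigen(crossprod(X), symmetric = TRUE)
    scores <- X %*% ev$vectors[, seq_len(k), drop = FALSE]
  } else {
    ev <- eigen(tcrossprod(X), symmetric = TRUE)
    scores <- ev$vectors[, seq_len(k), drop = FALSE] %*%
      diag(sqrt(pmax(ev$values[seq_len(k)], 0)), k)
  }
  rownames(scores) <- ids
  ref <- samples$cohort[act] == reference_cohort
  mu <- colMeans(scores[ref, , drop = FALSE])
  sdv <- apply(scores[ref, , drop = FALSE], 2, stats::sd)
  dev <- sweep(abs(sweep(scores, 2, mu, "-")), 2,
               pmax(sdv, .Machine$double.eps), "/")
  fail <- apply(dev > thresholds$pca_sd_multiple, 1, any)
  samples$qc_status[match(ids[fail], samples$sample_id)] <- "fail_ancestry"
  list(samples = samples, scores = scores, n_sites_used = sum(common))
}
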