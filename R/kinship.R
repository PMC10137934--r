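# KING-robust pairwise kinship from biallelic genotype dosages.
#
# The between-family robust estimator:
#   phi = (n_het_het - 2 * n_opp_hom) / (n_het_i + n_het_j)
# with all counts taken over sites non-missing in both samples.  Expected
# values: 0.5 for duplicates/MZ twins, ~0.25 for parent-offspring, 0 for
# unrelated pairs; 0.09375 is the conventional second-degree lower bound.

#' Estimate KING-robust kinship for one sample pair
#'
#' @param geno integer matrix of allele dosages (samples x sites, values
#'   0/1/2 or NA), rownames are sample ids
#' @param i,j row indices or sample ids of the pair
#' @return list with `sample_i`, `sample_j`, `n_het_het`, `n_opp_hom`,
#'   `n_het_i`, `n_het_j`, and `phi` (NA when the denominator is zero,
#'   in which case the pair is uninformative)
#' @export
estimate_kinship <- function(geno, i, j) {
  gi <- geno[i, ]
  gj <- geno[j, ]
  obs <- !is.na(gi) & !is.na(gj)
  gi <- gi[obs]
  gj <- gj[obs]
  n_het_het <- sum(gi == 1 & gj == 1)
  n_opp_hom <- sum((gi == 0 & gj == 2) | (gi == 2 & gj == 0))
  n_het_i <- sum(gi == 1)
  n_het_j <- sum(gj == 1)
  den <- n_het_i + n_het_j
  phi <- if (den > 0) (n_het_het - 2 * n_opp_hom) / den else NA_real_
  ids <- rownames(geno)
  list(sample_i = if (!is.null(ids) && is.numeric(i)) ids[i] else as.character(i),
       sample_j = if (!is.null(ids) && is.numeric(j)) ids[j] else as.character(j),
       n_het_het = n_het_het, n_opp_hom = n_opp_hom,
       n_het_i = n_het_i, n_het_j = n_het_j, phi = phi)
}

#' All pairs exceeding a kinship cutoff
#'
#' Computes the KING-robust estimate for every sample pair via matrix
#' cross-products (feasible for thousands of samples when the site panel is a
#' few thousand markers) and returns the pairs above `cutoff`.
#'
#' @inheritParams estimate_kinship
#' @param cutoff kinship threshold; pairs with `phi > cutoff` are returned
#'   (default 0.09375, the second-degree bound)
#' @return data.frame with columns `sample_i`, `sample_j`, `phi`; pairs with
#'   zero denominator are excluded (uninformative)
#' @export
king_related_pairs <- function(geno, cutoff = 0.09375) {
  n <- nrow(geno)
  if (n < 2) return(data.frame(sample_i = character(), sample_j = character(),
                               phi = numeric()))
  obs <- !is.na(geno)
  H <- matrix(0, n, ncol(geno))
  H[which(obs & geno == 1)] <- 1
  A0 <- matrix(0, n, ncol(geno))
  A0[which(obs & geno == 0)] <- 1
  A2 <- matrix(0, n, ncol(geno))
  A2[which(obs & geno == 2)] <- 1
  M <- matrix(0, n, ncol(geno))
  M[which(obs)] <- 1
  n11 <- tcrossprod(H)
  opp <- tcrossprod(A0, A2)
  opp <- opp + t(opp)
  hm <- tcrossprod(H, M)       # sites het in i and observed in both
  den <- hm + t(hm)
  num <- n11 - 2 * opp
  ut <- upper.tri(den)
  hit <- which(ut & den > 0 & num / pmax(den, 1) > cutoff)
  idx_i <- ((hit - 1) %% n) + 1
  idx_j <- ((hit - 1) %/% n) + 1
  ids <- rownames(geno) %||% as.character(seq_len(n))
  out <- data.frame(sample_i = ids[idx_i], sample_j = ids[idx_j],
                    phi = num[hit] / den[hit], stringsAsFactors = FALSE)
  out[order(out$sample_i, out$sample_j), , drop = FALSE]
}
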