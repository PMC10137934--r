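# Site-level quality control for a jointly called variant set: per-genotype
# GQ masking, indel-proximity exclusion, and the numbered site filters
# (excess heterozygosity, VQSR tranche, missing rate, differential
# missingness, control HWE).  Each removed site carries exactly one tag, the
# first criterion it fails.

#' Site-level QC thresholds
#'
#' @param exc_het_p_min sites pass only with excess-heterozygosity p
#'   strictly above this (default 3.4e-6)
#' @param gq_min_snv,gq_min_indel minimum genotype quality retained at SNVs
#'   (20) and indels (60); lower calls are masked to missing
#' @param indel_window_snv,indel_window_indel exclusion windows in bp around
#'   indels for SNVs (10) and for other indels (5); the boundary is
#'   inclusive ("within" includes the window edge)
#' @param missing_rate_max sites fail at pooled missing rate >= this
#'   (strict "< 0.10" pass rule)
#' @param diff_missingness_p_min sites pass only with case/control
#'   differential-missingness p strictly above this (1e-6)
#' @param control_hwe_p_min sites pass only with control HWE p strictly
#'   above this (1e-6)
#' @return list of thresholds
#' @export
site_thresholds <- function(exc_het_p_min = 3.4e-6,
                            gq_min_snv = 20,
                            gq_min_indel = 60,
                            indel_window_snv = 10,
                            indel_window_indel = 5,
                            missing_rate_max = 0.10,
                            diff_missingness_p_min = 1e-6,
                            control_hwe_p_min = 1e-6) {
  list(exc_het_p_min = exc_het_p_min,
       gq_min_snv = gq_min_snv,
       gq_min_indel = gq_min_indel,
       indel_window_snv = indel_window_snv,
       indel_window_indel = indel_window_indel,
       missing_rate_max = missing_rate_max,
       diff_missingness_p_min = diff_missingness_p_min,
       control_hwe_p_min = control_hwe_p_min)
}

#' Mask low-quality genotype calls
#'
#' GQ is a genotype-level field, so quality filtering masks individual calls
#' rather than whole sites: a genotype at an SNV with GQ below `gq_min_snv`
#' (20), or at an indel below `gq_min_indel` (60), becomes missing.  The
#' boundary is inclusive (GQ = 20 at an SNV is retained).  Site-level
#' missingness is recomputed downstream from the masked matrix.
#'
#' @param geno dosage matrix (samples x sites)
#' @param gq genotype-quality matrix, same shape
#' @param variant_type per-site `"SNV"`/`"indel"` vector
#' @param thresholds a [site_thresholds()] list
#' @return masked dosage matrix
#' @export
mask_low_gq_genotypes <- function(geno, gq, variant_type,
                                  thresholds = site_thresholds()) {
  stopifnot(identical(dim(geno), dim(gq)),
            length(variant_type) == ncol(geno))
  gq_min <- ifelse(variant_type == "indel",
                   thresholds$gq_min_indel, thresholds$gq_min_snv)
  mask <- sweep(gq, 2, gq_min, "<")
  geno[mask] <- NA
  geno
}

#' Distance from each site to the nearest other indel
#'
#' Positions are 1-based; distance is the absolute position difference to
#' the closest indel site on the same chromosome, excluding the site itself.
#' Sites on chromosomes without any (other) indel get NA.
#'
#' @param sites data.frame with `chrom`, `pos`, `variant_type`
#' @return numeric vector of distances, one per row of `sites`
#' @export
compute_indel_proximity <- function(sites) {
  out <- rep(NA_real_, nrow(sites))
  for (ch in unique(sites$chrom)) {
    on <- which(sites$chrom == ch)
    ind <- on[sites$variant_type[on] == "indel"]
    if (length(ind) == 0) next
    ipos <- sites$pos[ind]
    for (s in on) {
      dd <- abs(sites$pos[s] - ipos)
      if (s %in% ind) dd <- dd[ind != s]   # a site is never its own neighbor
      if (length(dd)) out[s] <- min(dd)
    }
  }
  out
}

#' Apply the site-level filters
#'
#' Evaluates, in order: (1) excess-heterozygosity p (input annotation,
#' strict ">"), (2) VQSR tranche pass flag (input annotation), (4) indel
#' proximity (SNVs within 10 bp or indels within 5 bp of another indel,
#' boundary inclusive), (5) pooled missing rate (strict "< 0.10") and
#' case/control differential missingness (two-sided Fisher exact test on
#' missing vs non-missing calls, strict ">"), and (6) exact HWE on control
#' genotype counts (strict ">").  GQ-based masking (criterion 3) must be
#' applied to `geno` beforehand; its effect enters through the recomputed
#' missing rate.  The first failed criterion tags the site.
#'
#' @param geno masked dosage matrix (samples x sites), colnames = site ids
#' @param sites data.frame with `site_id`, `chrom`, `pos`, `variant_type`,
#'   `exc_het_p`, `vqsr_pass_99_95`
#' @param case_ids,control_ids sample id vectors defining the two cohorts
#' @param thresholds a [site_thresholds()] list
#' @return `sites` with computed columns `nearest_indel_distance`,
#'   `missing_rate`, `diff_missingness_p`, `control_hwe_p`, `site_status`
#' @export
apply_site_filters <- function(geno, sites, case_ids, control_ids,
                               thresholds = site_thresholds()) {
  for (f in c("exc_het_p", "vqsr_pass_99_95")) {
    bad <- is.na(sites[[f]])
    if (is.null(sites[[f]]) || any(bad))
      stop(sprintf("missing site annotation '%s' for site(s): %s", f,
                   paste(sites$site_id[bad], collapse = ", ")), call. = FALSE)
  }
  stopifnot(identical(colnames(geno), sites$site_id))
  gc_all <- geno[c(case_ids, control_ids), , drop = FALSE]
  gcase <- geno[case_ids, , drop = FALSE]
  gctrl <- geno[control_ids, , drop = FALSE]
  n_all <- nrow(gc_all)
  miss_case <- colSums(is.na(gcase))
  miss_ctrl <- colSums(is.na(gctrl))
  sites$nearest_indel_distance <- compute_indel_proximity(sites)
  sites$missing_rate <- (miss_case + miss_ctrl) / n_all
  sites$diff_missingness_p <- vapply(seq_len(ncol(geno)), function(j) {
    fisher_exact_two_sided(miss_case[j], length(case_ids) - miss_case[j],
                           miss_ctrl[j], length(control_ids) - miss_ctrl[j])
  }, numeric(1))
  sites$control_hwe_p <- vapply(seq_len(ncol(geno)), function(j) {
    g <- gctrl[, j]
    hwe_exact_test(sum(g == 0, na.rm = TRUE), sum(g == 1, na.rm = TRUE),
                   sum(g == 2, na.rm = TRUE))
  }, numeric(1))
  win <- ifelse(sites$variant_type == "indel",
                thresholds$indel_window_indel, thresholds$indel_window_snv)
  near_indel <- !is.na(sites$nearest_indel_distance) &
    sites$nearest_indel_distance <= win
  status <- rep("pass", nrow(sites))
  status[sites$control_hwe_p <= thresholds$control_hwe_p_min] <- "fail_hwe"
  status[sites$diff_missingness_p <= thresholds$diff_missingness_p_min] <-
    "fail_diff_missingness"
  status[sites$missing_rate >= thresholds$missing_rate_max] <- "fail_missing_rate"
  status[near_indel] <- "fail_indel_proximity"
  status[!sites$vqsr_pass_99_95] <- "fail_vqsr"
  status[sites$exc_het_p <= thresholds$exc_het_p_min] <- "fail_exc_het"
  sites$site_status <- status
  sites
}
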