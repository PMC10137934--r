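# Carrier collapsing and phenotype-stratified case-control burden testing,
# including the public-reference (allele-count) control mode, the synonymous
# negative control, and compound-heterozygote detection.

#' Collapse qualifying variants to per-sample carrier status
#'
#' A sample is a carrier when it holds at least one non-reference genotype
#' at at least one qualifying site; several qualifying variants still count
#' once (collapsing).
#'
#' @param geno dosage matrix (samples x sites) with site ids as colnames
#' @param qualifying_sites character vector of qualifying site ids
#' @return data.frame with `sample_id`, `carrier`, `n_carrier_variants`,
#'   and `carrier_variants` (semicolon-joined site ids)
#' @export
collect_carriers <- function(geno, qualifying_sites) {
  qs <- intersect(colnames(geno), qualifying_sites)
  G <- geno[, qs, drop = FALSE]
  hit <- !is.na(G) & G >= 1
  data.frame(
    sample_id = rownames(geno),
    carrier = rowSums(hit) > 0,
    n_carrier_variants = rowSums(hit),
    carrier_variants = apply(hit, 1, function(r) paste(qs[r], collapse = ";")),
    stringsAsFactors = FALSE)
}

qualifying_site_sets <- function(classified) {
  list(
    all_PDV = classified$site_id[classified$pdv],
    D_Mis_only = classified$site_id[classified$rare &
                                      classified$variant_class == "damaging_missense"],
    LoF_only = classified$site_id[classified$rare &
                                    classified$variant_class == "lof"],
    synonymous = classified$site_id[classified$rare &
                                      classified$variant_class == "synonymous"])
}

burden_row <- function(phenotype, variant_set, a, b, c, d, alpha, m) {
  p <- fisher_exact_two_sided(a, b, c, d)
  orr <- odds_ratio_ci(a, b, c, d)
  data.frame(phenotype = phenotype, variant_set = variant_set,
             a = a, b = b, c = c, d = d,
             or = orr$or, ci_low = orr$ci[1], ci_high = orr$ci[2],
             p = p, bonferroni_m = m, significant = p < alpha / m,
             stringsAsFactors = FALSE)
}

#' Phenotype-stratified gene burden tests
#'
#' For every (phenotype, variant set) combination, builds the 2x2 carrier
#' table of the phenotype's cases against the shared controls, computes the
#' two-sided Fisher exact p, the cross-product odds ratio with its Woolf 95%
#' interval, and applies a Bonferroni correction whose family is all tests
#' performed in this invocation (significant iff p < alpha / m).
#'
#' @param geno dosage matrix restricted to QC-passing samples and sites
#' @param classified classified annotation table from [classify_variants()]
#'   with a `site_id` column
#' @param samples sample table (`sample_id`, `cohort`, `phenotypes`);
#'   only rows present in `geno` are used
#' @param phenotypes phenotype labels to stratify cases by
#' @param variant_sets subset of
#'   `c("all_PDV", "D_Mis_only", "LoF_only", "synonymous")`
#' @param alpha family-wise significance level
#' @return data.frame, one row per test (phenotypes without cases are
#'   skipped with a message)
#' @export
run_burden <- function(geno, classified, samples,
                       phenotypes = c("CHD", "CTD", "LVOTO", "AVSD"),
                       variant_sets = c("all_PDV", "D_Mis_only", "LoF_only"),
                       alpha = 0.05) {
  samples <- samples[samples$sample_id %in% rownames(geno), , drop = FALSE]
  sets <- qualifying_site_sets(classified)[variant_sets]
  controls <- samples$sample_id[samples$cohort == "control"]
  grid <- expand.grid(phenotype = phenotypes, variant_set = variant_sets,
                      stringsAsFactors = FALSE)
  case_sets <- lapply(phenotypes, function(ph)
    samples$sample_id[samples$cohort == "case" &
                        has_phenotype(samples$phenotypes, ph)])
  names(case_sets) <- phenotypes
  empty <- vapply(case_sets, length, integer(1)) == 0
  if (any(empty)) {
    message("skipping phenotype(s) with zero cases: ",
            paste(names(case_sets)[empty], collapse = ", "))
    grid <- grid[!grid$phenotype %in% names(case_sets)[empty], , drop = FALSE]
  }
  m <- nrow(grid)
  if (m == 0) stop("no cases remain", call. = FALSE)
  out <- lapply(seq_len(m), function(k) {
    ph <- grid$phenotype[k]
    vs <- grid$variant_set[k]
    carr <- collect_carriers(geno, sets[[vs]])
    flag <- stats::setNames(carr$carrier, carr$sample_id)
    a <- sum(flag[case_sets[[ph]]])
    c_ <- sum(flag[controls])
    burden_row(ph, vs, a, length(case_sets[[ph]]) - a,
               c_, length(controls) - c_, alpha, m)
  })
  do.call(rbind, out)
}

#' Burden test against a public reference-population control
#'
#' When the control arm is a reference summary (per-variant allele counts
#' and allele numbers, e.g. a public exome aggregate) rather than genotypes,
#' the test is built on alleles.  Only reference records with a PASS filter
#' and >10x coverage in more than 90% of samples qualify.  The control
#' denominator is the median of the qualifying allele numbers (even count:
#' mean of the two central values, rounded down); the control numerator is
#' the summed allele count.  The case side counts alleles symmetrically
#' (2 * n_cases total).
#'
#' @param case_alt_alleles total alternate alleles observed in cases over
#'   the qualifying variants (scalar or per-variant vector)
#' @param reference data.frame with `variant_key`, `allele_count`,
#'   `allele_number`, `pass_filter`, `covered_10x_fraction`
#' @param n_cases number of case subjects
#' @param min_coverage_fraction coverage qualification bound (default 0.90,
#'   strict ">")
#' @param alpha significance level (single test, m = 1)
#' @return a one-row burden data.frame, or a not-evaluable row (NA
#'   statistics) when no reference variant qualifies
#' @export
reference_control_burden <- function(case_alt_alleles, reference, n_cases,
                                     min_coverage_fraction = 0.90,
                                     alpha = 0.05) {
  ok <- reference$pass_filter &
    reference$covered_10x_fraction > min_coverage_fraction
  ref <- reference[ok, , drop = FALSE]
  if (nrow(ref) == 0) {
    message("no qualifying reference variants; burden not evaluable")
    return(data.frame(phenotype = "CHD", variant_set = "all_PDV",
                      a = NA_integer_, b = NA_integer_, c = NA_integer_,
                      d = NA_integer_, or = NA_real_, ci_low = NA_real_,
                      ci_high = NA_real_, p = NA_real_, bonferroni_m = 1L,
                      significant = NA, evaluable = FALSE,
                      stringsAsFactors = FALSE))
  }
  stopifnot(all(ref$allele_count <= ref$allele_number))
  an_med <- floor(stats::median(ref$allele_number))
  a <- sum(case_alt_alleles)
  b <- 2 * n_cases - a
  c_ <- sum(ref$allele_count)
  d <- an_med - c_
  row <- burden_row("CHD", "all_PDV", a, b, c_, d, alpha, 1L)
  row$evaluable <- TRUE
  row
}

#' Synonymous-variant negative control burden
#'
#' Runs the identical collapsing pipeline on rare synonymous variants, which
#' carry no consensus-predictor requirement and are not expected to be
#' disease related; reported without asserting a direction.
#'
#' @inheritParams run_burden
#' @return one-row burden data.frame, or a not-evaluable row when no rare
#'   synonymous variant exists
#' @export
synonymous_control <- function(geno, classified, samples, alpha = 0.05) {
  syn <- qualifying_site_sets(classified)$synonymous
  if (length(syn) == 0) {
    message("no rare synonymous variants; control not evaluable")
    return(data.frame(phenotype = "CHD", variant_set = "synonymous",
                      a = NA_integer_, b = NA_integer_, c = NA_integer_,
                      d = NA_integer_, or = NA_real_, ci_low = NA_real_,
                      ci_high = NA_real_, p = NA_real_, bonferroni_m = 1L,
                      significant = NA, evaluable = FALSE,
                      stringsAsFactors = FALSE))
  }
  row <- run_burden(geno, classified, samples, phenotypes = "CHD",
                    variant_sets = "synonymous", alpha = alpha)
  row$evaluable <- TRUE
  row
}

#' Detect compound-heterozygous and homozygous carriers
#'
#' A sample is compound heterozygous in a gene when it carries heterozygous
#' genotypes at two or more distinct qualifying sites of that gene (no
#' phasing required).  Homozygous non-reference genotypes at a single
#' qualifying site are reported separately as `homozygous`.  Qualification
#' uses the relaxed rarity tier (AF < `af_threshold`, default 0.01) on the
#' damaging classes.
#'
#' @param geno dosage matrix (samples x sites)
#' @param annotations annotation table with `site_id`, `gene_symbol`,
#'   `consequence`, `gnomad_af`, predictor columns
#' @param af_threshold rarity threshold for this tier (default 0.01)
#' @param min_damaging consensus threshold for damaging missense
#' @return data.frame with `sample_id`, `gene`, `type`
#'   (`compound_het` / `homozygous`), `variants`, `n_variants`
#' @export
find_compound_hets <- function(geno, annotations, af_threshold = 0.01,
                               min_damaging = 4) {
  qual <- select_pdvs(annotations, af_threshold, min_damaging)
  qual <- qual[qual$site_id %in% colnames(geno), , drop = FALSE]
  out <- list()
  for (gene in unique(qual$gene_symbol)) {
    sid <- qual$site_id[qual$gene_symbol == gene]
    G <- geno[, sid, drop = FALSE]
    het <- !is.na(G) & G == 1
    hom <- !is.na(G) & G == 2
    ch <- which(rowSums(het) >= 2)
    for (s in ch)
      out[[length(out) + 1]] <- data.frame(
        sample_id = rownames(geno)[s], gene = gene, type = "compound_het",
        variants = paste(sid[het[s, ]], collapse = ";"),
        n_variants = sum(het[s, ]), stringsAsFactors = FALSE)
    hz <- which(rowSums(hom) >= 1 & rowSums(het) < 2)
    for (s in hz)
      out[[length(out) + 1]] <- data.frame(
        sample_id = rownames(geno)[s], gene = gene, type = "homozygous",
        variants = paste(sid[hom[s, ]], collapse = ";"),
        n_variants = sum(hom[s, ]), stringsAsFactors = FALSE)
  }
  if (length(out) == 0)
    return(data.frame(sample_id = character(), gene = character(),
                      type = character(), variants = character(),
                      n_variants = integer(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res[order(res$sample_id), , drop = FALSE]
}
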