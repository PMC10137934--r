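# End-to-end orchestration: simulate (or load) -> sample QC -> site QC ->
# kinship and ancestry pruning -> classification -> burden testing, with a
# manifest recording thresholds and per-stage bookkeeping.

#' Run the full burden pipeline
#'
#' Stages, in order: (1) per-sample metric filters (contamination,
#' missingness, variant-count outliers); (2) site QC on the metric-passing
#' samples (GQ masking, indel proximity, missing-rate / differential
#' missingness / control-HWE filters); (3) KING kinship pruning and (4)
#' principal-component ancestry filtering, both on the common-variant
#' background panel when one is present (falling back to QC-passing gene
#' sites otherwise); (5) variant classification; (6) carrier collapsing and
#' phenotype-stratified burden tests plus the synonymous negative control
#' and compound-heterozygote scan.  Re-running with the same configuration
#' reproduces identical output.
#'
#' @param config a [sim_config()]; ignored when `fixture` is supplied
#' @param fixture an existing `cohort_fixture` (e.g. from [read_cohort()])
#' @param qc sample-level thresholds ([qc_thresholds()])
#' @param site site-level thresholds ([site_thresholds()])
#' @param af_threshold PDV rarity threshold (default 1e-4)
#' @param comphet_af_threshold relaxed rarity tier for the
#'   compound-heterozygote scan (default 0.01)
#' @param min_damaging consensus threshold for damaging missense
#' @param phenotypes case strata to test
#' @param variant_sets qualifying-variant sets to test
#' @param alpha family-wise significance level
#' @param known_pairs optional data.frame of pedigree-known related pairs
#'   (`sample_i`, `sample_j`), merged with kinship flags before pruning
#' @param out_dir optional directory; when given, the manifest (JSON) and
#'   per-stage report TSVs are written there
#' @return manifest list: `counts` (per-stage sample/site bookkeeping),
#'   `thresholds`, `burden`, `synonymous`, `compound_hets`, `sample_qc`,
#'   `site_qc`, `kinship_pairs`
#' @export
run_pipeline <- function(config = NULL, fixture = NULL,
                         qc = qc_thresholds(), site = site_thresholds(),
                         af_threshold = 1e-4, comphet_af_threshold = 0.01,
                         min_damaging = 4,
                         phenotypes = c("CHD", "CTD", "LVOTO", "AVSD"),
                         variant_sets = c("all_PDV", "D_Mis_only", "LoF_only"),
                         alpha = 0.05, known_pairs = NULL, out_dir = NULL) {
  if (is.null(fixture)) {
    if (is.null(config)) stop("supply a config or a fixture", call. = FALSE)
    fixture <- generate_cohort(config)
  }
  samples <- fixture$samples
  n_in <- nrow(samples)

  # stage 1: per-sample metrics
  samples <- filter_sample_metrics(samples, qc)
  pass1 <- samples$sample_id[samples$qc_status == "pass"]

  # stage 2: site QC on metric-passing samples
  geno <- mask_low_gq_genotypes(fixture$geno, fixture$gq,
                                fixture$sites$variant_type, site)
  case_ids <- intersect(pass1, samples$sample_id[samples$cohort == "case"])
  ctrl_ids <- intersect(pass1, samples$sample_id[samples$cohort == "control"])
  if (length(case_ids) == 0) stop("no cases remain", call. = FALSE)
  if (length(ctrl_ids) == 0) stop("no controls remain", call. = FALSE)
  sites <- apply_site_filters(geno[pass1, , drop = FALSE], fixture$sites,
                              case_ids, ctrl_ids, site)
  pass_sites <- sites$site_id[sites$site_status == "pass"]

  # stage 3: kinship pruning on the background panel (or passing gene sites)
  panel <- if (!is.null(fixture$background)) fixture$background$geno
  else geno[, pass_sites, drop = FALSE]
  pairs <- king_related_pairs(panel[pass1, , drop = FALSE],
                              cutoff = qc$kinship_cutoff)
  if (!is.null(known_pairs) && nrow(known_pairs) > 0)
    pairs <- rbind(pairs, data.frame(sample_i = known_pairs$sample_i,
                                     sample_j = known_pairs$sample_j,
                                     phi = Inf, stringsAsFactors = FALSE))
  samples <- prune_related(samples, pairs, qc)

  # stage 4: ancestry filter
  pca <- pca_ancestry_filter(panel, samples, reference_cohort = "control",
                             thresholds = qc)
  samples <- pca$samples
  retained <- samples$sample_id[samples$qc_status == "pass"]
  cases_ret <- samples$sample_id[samples$qc_status == "pass" &
                                   samples$cohort == "case"]
  if (length(cases_ret) == 0) stop("no cases remain", call. = FALSE)

  # stage 5: classification
  classified <- classify_variants(sites[sites$site_status == "pass", ,
                                        drop = FALSE],
                                  af_threshold, min_damaging)

  # stage 6: burden
  geno_final <- geno[retained, pass_sites, drop = FALSE]
  burden <- run_burden(geno_final, classified, samples,
                       phenotypes = phenotypes, variant_sets = variant_sets,
                       alpha = alpha)
  synon <- synonymous_control(geno_final, classified, samples, alpha = alpha)
  comphet <- find_compound_hets(geno_final, classified,
                                af_threshold = comphet_af_threshold,
                                min_damaging = min_damaging)

  status_tab <- function(x) as.list(table(x))
  manifest <- list(
    seed = fixture$config$seed %||% NA,
    thresholds = list(sample = qc, site = site, af_threshold = af_threshold,
                      comphet_af_threshold = comphet_af_threshold,
                      min_damaging = min_damaging, alpha = alpha),
    counts = list(
      samples_in = n_in,
      samples_removed = sum(samples$qc_status != "pass"),
      samples_out = length(retained),
      cases_retained = length(cases_ret),
      controls_retained = length(retained) - length(cases_ret),
      sample_status = status_tab(samples$qc_status),
      sites_in = nrow(sites),
      sites_removed = sum(sites$site_status != "pass"),
      sites_out = length(pass_sites),
      site_status = status_tab(sites$site_status),
      pdv_sites = sum(classified$pdv),
      pca_sites_used = pca$n_sites_used),
    burden = burden,
    synonymous = synon,
    compound_hets = comphet,
    sample_qc = samples,
    site_qc = sites[, c("site_id", "chrom", "pos", "variant_type",
                        "exc_het_p", "vqsr_pass_99_95",
                        "nearest_indel_distance", "missing_rate",
                        "diff_missingness_p", "control_hwe_p",
                        "site_status")],
    kinship_pairs = pairs)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(
      manifest[c("seed", "thresholds", "counts", "burden", "synonymous")],
      file.path(out_dir, "manifest.json"),
      auto_unbox = TRUE, digits = NA, dataframe = "rows")
    utils::write.table(burden, file.path(out_dir, "burden.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(samples, file.path(out_dir, "sample_qc.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(manifest$site_qc, file.path(out_dir, "site_qc.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(comphet, file.path(out_dir, "compound_hets.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  manifest
}

#' Run the pipeline from a YAML configuration file
#'
#' The YAML file holds one block per concern: `simulation` (fields of
#' [sim_config()]), optional `thresholds$sample` / `thresholds$site`
#' overrides, and optional `analysis` settings (`af_threshold`, `alpha`,
#' `phenotypes`, `variant_sets`), plus an optional `out_dir`.
#'
#' @param path YAML file path
#' @return the pipeline manifest
#' @export
run_pipeline_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  sim <- do.call(sim_config, cfg$simulation %||% list())
  qc <- do.call(qc_thresholds, cfg$thresholds$sample %||% list())
  site <- do.call(site_thresholds, cfg$thresholds$site %||% list())
  an <- cfg$analysis %||% list()
  run_pipeline(config = sim, qc = qc, site = site,
               af_threshold = an$af_threshold %||% 1e-4,
               comphet_af_threshold = an$comphet_af_threshold %||% 0.01,
               min_damaging = an$min_damaging %||% 4,
               phenotypes = unlist(an$phenotypes) %||% c("CHD", "CTD", "LVOTO", "AVSD"),
               variant_sets = unlist(an$variant_sets) %||%
                 c("all_PDV", "D_Mis_only", "LoF_only"),
               alpha = an$alpha %||% 0.05,
               out_dir = cfg$out_dir)
}
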