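# Synthetic cohort generation with a ground-truth ledger.  The generator
# emulates the statistical structure of a case-control exome study of one
# gene: phenotype subgroups among cases, carrier enrichment at configurable
# odds ratios, planted related pairs and contaminated samples, sites
# violating each site-QC criterion, and a genome-wide-like background panel
# of common variants for kinship and ancestry analysis.

PDV_CLASSES <- c("LoF", "damaging_missense", "inframe_indel")
SITE_CLASSES <- c("LoF", "damaging_missense", "benign_missense",
                  "synonymous", "inframe_indel")
FAILURE_KINDS <- c("exc_het", "vqsr", "low_gq", "indel_proximity",
                   "missing_rate", "diff_missingness", "hwe")
# a site planted with uniformly low GQ is removed through the recomputed
# missing rate, so that is the status the pipeline is expected to assign
EXPECTED_STATUS <- c(exc_het = "fail_exc_het", vqsr = "fail_vqsr",
                     low_gq = "fail_missing_rate",
                     indel_proximity = "fail_indel_proximity",
                     missing_rate = "fail_missing_rate",
                     diff_missingness = "fail_diff_missingness",
                     hwe = "fail_hwe")

#' Simulation configuration
#'
#' Defaults reproduce the dimensions of the motivating study design: 1922
#' cases (with AVSD and DORV subgroup fractions at their published counts,
#' 142/1922 and 111/1922) against 2602 controls, a control carrier frequency
#' of 36/2602 for putative damaging variants, and published subgroup odds
#' ratios.  Clean-sample QC metrics are drawn from bounded supports so that
#' exactly the planted entities violate each threshold.
#'
#' @param n_cases,n_controls cohort sizes
#' @param phenotype_fractions named fractions of cases per subgroup label
#'   (each case receives one subgroup plus the CHD umbrella label; the
#'   remainder is labeled `other`)
#' @param n_sites number of gene sites
#' @param site_class_mix named fractions over
#'   `LoF, damaging_missense, benign_missense, synonymous, inframe_indel`
#'   (must sum to 1)
#' @param carrier_freq_control probability that a control carries a
#'   qualifying damaging variant
#' @param carrier_or named target odds ratios per phenotype; a case uses its
#'   subgroup's entry, falling back to `CHD`, then 1
#' @param n_compound_het cases planted with two heterozygous damaging
#'   variants
#' @param n_planted_duplicates,n_planted_parent_offspring related pairs to
#'   plant
#' @param n_contaminated samples planted with FREEMIX above threshold
#' @param n_failing_sites_per_criterion sites planted to fail each QC
#'   criterion flavor (excess het, VQSR, low GQ, indel proximity, missing
#'   rate, differential missingness, control HWE)
#' @param m_background number of common background-panel SNVs used for
#'   kinship and ancestry (0 disables the panel)
#' @param seed integer; identical configurations yield identical fixtures
#' @return validated configuration object
#' @export
sim_config <- function(n_cases = 1922, n_controls = 2602,
                       phenotype_fractions = c(CTD = 0.35, LVOTO = 0.25,
                                               AVSD = 142 / 1922,
                                               DORV = 111 / 1922),
                       n_sites = 120,
                       site_class_mix = c(LoF = 0.10, damaging_missense = 0.25,
                                          benign_missense = 0.30,
                                          synonymous = 0.30,
                                          inframe_indel = 0.05),
                       carrier_freq_control = 36 / 2602,
                       carrier_or = c(CHD = 2.22, CTD = 2.37,
                                      LVOTO = 1.86, AVSD = 3.14),
                       n_compound_het = 0L,
                       n_planted_duplicates = 0L,
                       n_planted_parent_offspring = 0L,
                       n_contaminated = 0L,
                       n_failing_sites_per_criterion = 0L,
                       m_background = 4000L,
                       seed = 1L) {
  for (nm in c("n_cases", "n_controls", "n_sites", "n_compound_het",
               "n_planted_duplicates", "n_planted_parent_offspring",
               "n_contaminated", "n_failing_sites_per_criterion",
               "m_background", "seed"))
    check_count(get(nm), nm)
  if (any(phenotype_fractions < 0) || any(phenotype_fractions > 1) ||
      sum(phenotype_fractions) > 1 + 1e-9)
    stop("phenotype fractions must lie in [0,1] and sum to at most 1",
         call. = FALSE)
  if (!setequal(names(site_class_mix), SITE_CLASSES) ||
      abs(sum(site_class_mix) - 1) > 1e-9 || any(site_class_mix < 0))
    stop("site_class_mix must be nonnegative fractions over the five site classes summing to 1",
         call. = FALSE)
  if (carrier_freq_control < 0 || carrier_freq_control >= 1)
    stop("carrier_freq_control must lie in [0, 1)", call. = FALSE)
  if (any(carrier_or < 0) || any(!is.finite(carrier_or)))
    stop("carrier odds ratios must be finite and nonnegative", call. = FALSE)
  odds0 <- carrier_freq_control / (1 - carrier_freq_control)
  p1 <- (odds0 * carrier_or) / (1 + odds0 * carrier_or)
  if (any(p1 >= 1))
    stop("carrier_or and carrier_freq_control imply a case carrier probability >= 1",
         call. = FALSE)
  structure(as.list(environment())[c(
    "n_cases", "n_controls", "phenotype_fractions", "n_sites",
    "site_class_mix", "carrier_freq_control", "carrier_or",
    "n_compound_het", "n_planted_duplicates", "n_planted_parent_offspring",
    "n_contaminated", "n_failing_sites_per_criterion", "m_background",
    "seed")], class = "sim_config")
}

case_carrier_prob <- function(config, subgroup) {
  p0 <- config$carrier_freq_control
  odds0 <- p0 / (1 - p0)
  co <- config$carrier_or
  orv <- vapply(subgroup, function(g) {
    if (g %in% names(co)) co[[g]]
    else if ("CHD" %in% names(co)) co[["CHD"]]
    else 1
  }, numeric(1))
  (odds0 * orv) / (1 + odds0 * orv)
}

gen_samples <- function(config) {
  n <- config$n_cases + config$n_controls
  sample_id <- sprintf("S%05d", seq_len(n))
  cohort <- rep(c("case", "control"), c(config$n_cases, config$n_controls))
  pf <- config$phenotype_fractions
  probs <- c(pf, other = 1 - sum(pf))
  subgroup <- c(sample(names(probs), config$n_cases, TRUE, probs),
                rep(NA_character_, config$n_controls))
  phenotypes <- ifelse(cohort == "case", paste("CHD", subgroup, sep = ","), "")
  data.frame(sample_id = sample_id, cohort = cohort,
             phenotypes = phenotypes, subgroup = subgroup,
             freemix = stats::runif(n, 0, 0.05),
             call_missingness = stats::runif(n, 0, 0.05),
             variant_count = round(stats::runif(n, 19000, 21000)),
             stringsAsFactors = FALSE)
}

random_seq <- function(len) paste(sample(c("A", "C", "G", "T"), len, TRUE),
                                  collapse = "")

gen_sites <- function(config) {
  m <- config$n_sites
  counts <- diff(c(0, round(cumsum(config$site_class_mix) * m)))
  sim_class <- sample(rep(names(config$site_class_mix), counts))
  consequence <- vapply(sim_class, function(cl) switch(cl,
    LoF = sample(LOF_CONSEQUENCES, 1),
    damaging_missense = "missense",
    benign_missense = "missense",
    synonymous = "synonymous",
    inframe_indel = "inframe_indel"), character(1))
  variant_type <- ifelse(consequence %in% c("frameshift_indel", "inframe_indel"),
                         "indel", "SNV")
  pos <- 57522276 + (seq_len(m) - 1L) * 500L
  ref <- vapply(seq_len(m), function(i) {
    if (variant_type[i] == "SNV") random_seq(1)
    else if (consequence[i] == "inframe_indel") random_seq(4)
    else random_seq(2)
  }, character(1))
  alt <- vapply(seq_len(m), function(i) {
    if (variant_type[i] == "SNV") sample(setdiff(c("A", "C", "G", "T"),
                                                 ref[i]), 1)
    else substr(ref[i], 1, 1)
  }, character(1))
  is_pdv_class <- sim_class %in% PDV_CLASSES
  gnomad_af <- numeric(m)
  gnomad_af[is_pdv_class] <- stats::runif(sum(is_pdv_class), 0, 5e-5)
  gnomad_af[is_pdv_class][stats::runif(sum(is_pdv_class)) < 0.3] <- NA
  neut <- which(!is_pdv_class)
  common <- neut[seq_along(neut) %% 2 == 0]
  rare_neut <- setdiff(neut, common)
  gnomad_af[common] <- stats::runif(length(common), 0.05, 0.5)
  gnomad_af[rare_neut] <- stats::runif(length(rare_neut), 0, 8e-5)
  verdicts <- matrix("absent", m, length(PREDICTORS),
                     dimnames = list(NULL, PREDICTORS))
  for (i in which(sim_class == "damaging_missense")) {
    nd <- sample(4:9, 1)
    verdicts[i, sample(PREDICTORS, nd)] <- "damaging"
    verdicts[i, verdicts[i, ] == "absent"][
      stats::runif(9 - nd) < 0.7] <- "tolerated"
  }
  for (i in which(sim_class == "benign_missense")) {
    nd <- sample(0:3, 1)
    if (nd > 0) verdicts[i, sample(PREDICTORS, nd)] <- "damaging"
    verdicts[i, verdicts[i, ] == "absent"][
      stats::runif(9 - nd) < 0.7] <- "tolerated"
  }
  protein_position <- rep(NA_integer_, m)
  paff <- consequence %in% c("missense", "inframe_indel", "synonymous",
                             LOF_CONSEQUENCES)
  protein_position[paff] <- as.integer(
    round((pos[paff] - min(pos)) / max(1L, diff(range(pos))) * 4543) + 1L)
  sites <- data.frame(site_id = sprintf("V%04d", seq_len(m)),
                      chrom = "12", pos = pos, ref = ref, alt = alt,
                      variant_type = variant_type, gene_symbol = "LRP1",
                      consequence = consequence, gnomad_af = gnomad_af,
                      protein_position = protein_position,
                      cadd_phred = round(stats::runif(m, 0, 40), 1),
                      exc_het_p = stats::runif(m, 0.05, 1),
                      vqsr_pass_99_95 = TRUE,
                      stringsAsFactors = FALSE)
  sites <- cbind(sites, as.data.frame(verdicts, stringsAsFactors = FALSE))
  # allele frequency used to draw cohort genotypes; damaging-class sites
  # carry planted carriers only, so their background frequency is 0
  sites$sim_af <- ifelse(is_pdv_class, 0,
                         ifelse(is.na(sites$gnomad_af), 0, sites$gnomad_af))
  sites$sim_class <- sim_class
  sites
}

gen_genotypes <- function(config, samples, sites) {
  n <- nrow(samples)
  m <- nrow(sites)
  geno <- matrix(0L, n, m, dimnames = list(samples$sample_id, sites$site_id))
  poly <- which(sites$sim_af > 0)
  if (length(poly))
    geno[, poly] <- matrix(
      stats::rbinom(n * length(poly), 2, rep(sites$sim_af[poly], each = n)),
      n, length(poly))
  pdv_sites <- which(sites$sim_class %in% PDV_CLASSES)
  p <- c(case_carrier_prob(config, samples$subgroup[samples$cohort == "case"]),
         rep(config$carrier_freq_control, config$n_controls))
  carrier <- stats::rbinom(n, 1, p) == 1
  if (any(carrier) && length(pdv_sites) == 0)
    stop("no damaging-class sites available to plant carriers", call. = FALSE)
  for (i in which(carrier))
    geno[i, sample(pdv_sites, 1)] <- 1L
  comp_ids <- character(0)
  if (config$n_compound_het > 0) {
    if (length(pdv_sites) < 2)
      stop("need at least two damaging-class sites for compound heterozygotes",
           call. = FALSE)
    cases <- which(samples$cohort == "case")
    picked <- sample(cases, config$n_compound_het)
    for (i in picked) {
      geno[i, pdv_sites] <- 0L
      geno[i, sample(pdv_sites, 2)] <- 1L
    }
    comp_ids <- samples$sample_id[picked]
  }
  gq <- matrix(sample(60:99, n * m, TRUE), n, m,
               dimnames = dimnames(geno))
  list(geno = geno, gq = gq, compound_het = comp_ids)
}

plant_site_failures <- function(config, samples, sites, geno, gq) {
  k <- config$n_failing_sites_per_criterion
  ledger <- data.frame(site_id = character(), planted = character(),
                       expected_status = character(), stringsAsFactors = FALSE)
  if (k == 0)
    return(list(sites = sites, geno = geno, gq = gq, ledger = ledger))
  pool <- which(sites$sim_class %in% c("benign_missense", "synonymous") &
                  sites$variant_type == "SNV")
  need <- k * (length(FAILURE_KINDS) + 1)  # proximity consumes a companion
  if (length(pool) < need)
    stop("not enough neutral SNV sites to plant the requested failures",
         call. = FALSE)
  pool <- sample(pool)
  take <- function(nk) { v <- pool[seq_len(nk)]; pool <<- pool[-seq_len(nk)]; v }
  n <- nrow(samples)
  cases <- which(samples$cohort == "case")
  controls <- which(samples$cohort == "control")
  add <- function(idx, kind) {
    ledger <<- rbind(ledger, data.frame(
      site_id = sites$site_id[idx], planted = kind,
      expected_status = unname(EXPECTED_STATUS[kind]),
      stringsAsFactors = FALSE))
  }
  v <- take(k); sites$exc_het_p[v] <- 1e-8; add(v, "exc_het")
  v <- take(k); sites$vqsr_pass_99_95[v] <- FALSE; add(v, "vqsr")
  v <- take(k); gq[, v] <- 10L; add(v, "low_gq")
  for (i in seq_len(k)) {             # proximity: victim SNV + companion indel
    v <- take(1); w <- take(1)
    sites$variant_type[w] <- "indel"
    sites$consequence[w] <- "inframe_indel"
    sites$sim_class[w] <- "inframe_indel"
    sites$gnomad_af[w] <- 0.02        # common, hence never a qualifying PDV
    sites$ref[w] <- random_seq(4)
    sites$alt[w] <- substr(sites$ref[w], 1, 1)
    sites$pos[w] <- sites$pos[v] + 10L
    add(v, "indel_proximity")
  }
  v <- take(k)
  for (s in v) geno[sample(n, ceiling(0.2 * n)), s] <- NA
  add(v, "missing_rate")
  v <- take(k)
  for (s in v) geno[sample(cases, ceiling(0.15 * length(cases))), s] <- NA
  add(v, "diff_missingness")
  v <- take(k)
  for (s in v) {
    sites$gnomad_af[s] <- 0.3
    sites$sim_af[s] <- 0.3
    geno[controls, s] <- sample(c(0L, 2L), length(controls), TRUE, c(0.7, 0.3))
    geno[cases, s] <- stats::rbinom(length(cases), 2, 0.3)
  }
  add(v, "hwe")
  list(sites = sites, geno = geno, gq = gq, ledger = ledger)
}

recompute_truth_carriers <- function(fixture) {
  sites <- fixture$sites
  pdv <- sites$site_id[sites$sim_class %in% PDV_CLASSES &
                         is_rare(sites$gnomad_af, 1e-4)]
  carr <- collect_carriers(fixture$geno, pdv)
  fixture$truth$carriers <- carr[, c("sample_id", "carrier",
                                     "carrier_variants")]
  fixture$truth$pdv_sites <- pdv
  fixture
}

#' Generate a synthetic cohort fixture
#'
#' Draws a complete cohort under the configured study conditions: sample
#' metadata and QC metrics, gene sites with annotations and deleteriousness
#' verdicts, genotypes with planted carriers at the configured odds ratios,
#' a common-variant background panel, planted related pairs, contaminated
#' samples, and sites violating each QC criterion.  Everything is recorded
#' in a ground-truth ledger; identical configurations give identical
#' fixtures.
#'
#' @param config a [sim_config()] object
#' @return a `cohort_fixture` list: `samples`, `sites`, `geno`, `gq`,
#'   `background` (list with `geno`, `af`, or NULL), `truth`, `config`
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  samples <- with_seed(substream_seed(config$seed, "samples"),
                       gen_samples(config))
  sites <- with_seed(substream_seed(config$seed, "sites"), gen_sites(config))
  gg <- with_seed(substream_seed(config$seed, "genotypes"),
                  gen_genotypes(config, samples, sites))
  pf <- with_seed(substream_seed(config$seed, "site_failures"),
                  plant_site_failures(config, samples, sites, gg$geno, gg$gq))
  contaminated <- character(0)
  if (config$n_contaminated > 0) {
    samples <- with_seed(substream_seed(config$seed, "contamination"), {
      idx <- sample(nrow(samples), config$n_contaminated)
      samples$freemix[idx] <- stats::runif(config$n_contaminated, 0.08, 0.2)
      samples
    })
    contaminated <- samples$sample_id[samples$freemix > 0.075]
  }
  background <- NULL
  if (config$m_background > 0) {
    background <- with_seed(substream_seed(config$seed, "background"), {
      af <- stats::runif(config$m_background, 0.1, 0.9)
      g <- matrix(stats::rbinom(nrow(samples) * config$m_background, 2,
                                rep(af, each = nrow(samples))),
                  nrow(samples), config$m_background,
                  dimnames = list(samples$sample_id,
                                  sprintf("B%05d", seq_len(config$m_background))))
      list(geno = g, af = af)
    })
  }
  fixture <- structure(list(
    samples = samples, sites = pf$sites, geno = pf$geno, gq = pf$gq,
    background = background,
    truth = list(carriers = NULL, pdv_sites = NULL,
                 related_pairs = data.frame(sample_i = character(),
                                            sample_j = character(),
                                            kind = character(),
                                            stringsAsFactors = FALSE),
                 contaminated = contaminated,
                 compound_het = gg$compound_het,
                 site_failures = pf$ledger,
                 carrier_model = list(
                   carrier_freq_control = config$carrier_freq_control,
                   carrier_or = config$carrier_or)),
    config = config), class = "cohort_fixture")
  if (config$n_planted_duplicates > 0)
    fixture <- plant_relatives(fixture, "duplicate",
                               config$n_planted_duplicates)
  if (config$n_planted_parent_offspring > 0)
    fixture <- plant_relatives(fixture, "parent_offspring",
                               config$n_planted_parent_offspring)
  recompute_truth_carriers(fixture)
}

#' Plant related sample pairs into a fixture
#'
#' Duplicates copy gene and background genotype rows exactly; for
#' parent-offspring pairs the second member's genotypes are redrawn with one
#' allele transmitted from the parent by Mendelian inheritance and the other
#' drawn from the site's population frequency.  The truth ledger is updated
#' and carrier status is recomputed from the modified genotypes.
#'
#' @param fixture a `cohort_fixture`
#' @param kind `"duplicate"` or `"parent_offspring"`
#' @param pair_count number of disjoint pairs to plant
#' @return the modified fixture
#' @export
plant_relatives <- function(fixture, kind, pair_count) {
  if (!kind %in% c("duplicate", "parent_offspring"))
    stop("unknown relative kind: ", kind, call. = FALSE)
  check_count(pair_count, "pair_count")
  if (pair_count == 0) return(fixture)
  used <- unique(c(fixture$truth$related_pairs$sample_i,
                   fixture$truth$related_pairs$sample_j,
                   fixture$truth$contaminated, fixture$truth$compound_het))
  pool <- setdiff(fixture$samples$sample_id, used)
  if (length(pool) < 2 * pair_count)
    stop("pair_count exceeds available samples / 2", call. = FALSE)
  seed <- substream_seed(fixture$config$seed,
                         paste0("relatives_", kind, "_",
                                nrow(fixture$truth$related_pairs)))
  fixture <- with_seed(seed, {
    picked <- sample(pool, 2 * pair_count)
    src <- picked[seq_len(pair_count)]
    dst <- picked[pair_count + seq_len(pair_count)]
    for (k in seq_len(pair_count)) {
      if (kind == "duplicate") {
        fixture$geno[dst[k], ] <- fixture$geno[src[k], ]
        fixture$gq[dst[k], ] <- fixture$gq[src[k], ]
        if (!is.null(fixture$background))
          fixture$background$geno[dst[k], ] <- fixture$background$geno[src[k], ]
      } else {
        fixture$geno[dst[k], ] <- mendelian_child(fixture$geno[src[k], ],
                                                  fixture$sites$sim_af)
        if (!is.null(fixture$background))
          fixture$background$geno[dst[k], ] <- mendelian_child(
            fixture$background$geno[src[k], ], fixture$background$af)
      }
    }
    fixture$truth$related_pairs <- rbind(
      fixture$truth$related_pairs,
      data.frame(sample_i = src, sample_j = dst, kind = kind,
                 stringsAsFactors = FALSE))
    fixture
  })
  recompute_truth_carriers(fixture)
}

mendelian_child <- function(parent, af) {
  transmitted <- stats::rbinom(length(parent), 1,
                               ifelse(is.na(parent), af, parent / 2))
  other <- stats::rbinom(length(parent), 1, af)
  as.integer(transmitted + other)
}

#' Generate a synthetic single-cell expression fixture
#'
#' Negative-binomial counts with cluster-specific means: marker genes of a
#' cluster have their mean multiplied by `marker_fold` (default 5) in that
#' cluster, so the marker cluster attains the maximal z-scored mean.
#'
#' @param n_cells,n_genes positive dimensions
#' @param clusters character vector of cluster labels; cells are assigned
#'   round-robin (every cluster nonempty) and shuffled
#' @param marker_spec named list: cluster label -> character vector of
#'   marker gene ids (`g0001`, ...)
#' @param seed integer seed
#' @param marker_fold mean multiplier for markers in their cluster
#' @param dispersion negative-binomial size parameter
#' @return list with `counts` (cells x genes), `effective_length`,
#'   `clusters` (per-cell labels), `marker_spec`
#' @export
generate_expression <- function(n_cells, n_genes,
                                clusters = c("OFT", "AVC", "ventricle"),
                                marker_spec = NULL, seed = 1,
                                marker_fold = 5, dispersion = 2) {
  if (n_cells < 1 || n_genes < 1)
    stop("n_cells and n_genes must be positive", call. = FALSE)
  genes <- sprintf("g%04d", seq_len(n_genes))
  bad <- setdiff(unlist(marker_spec), genes)
  if (length(bad))
    stop("unknown marker gene(s): ", paste(bad, collapse = ", "), call. = FALSE)
  if (!all(names(marker_spec) %in% clusters))
    stop("marker_spec names must be cluster labels", call. = FALSE)
  with_seed(substream_seed(seed, "expression"), {
    cell_cluster <- sample(rep(clusters, length.out = n_cells))
    base_mu <- stats::rlnorm(n_genes, meanlog = 1, sdlog = 1)
    mu <- matrix(rep(base_mu, each = length(clusters)),
                 length(clusters), n_genes,
                 dimnames = list(clusters, genes))
    for (cl in names(marker_spec))
      mu[cl, marker_spec[[cl]]] <- mu[cl, marker_spec[[cl]]] * marker_fold
    counts <- matrix(0L, n_cells, n_genes,
                     dimnames = list(sprintf("cell%05d", seq_len(n_cells)),
                                     genes))
    for (cl in clusters) {
      rows <- which(cell_cluster == cl)
      counts[rows, ] <- matrix(
        stats::rnbinom(length(rows) * n_genes,
                       mu = rep(mu[cl, ], each = length(rows)),
                       size = dispersion),
        length(rows), n_genes)
    }
    list(counts = counts,
         effective_length = stats::setNames(
           round(stats::runif(n_genes, 200, 3000)), genes),
         clusters = cell_cluster, marker_spec = marker_spec)
  })
}
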