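# Consequence-based variant classification with a consensus missense
# deleteriousness rule, rarity thresholds, and protein-domain mapping.

#' The nine missense deleteriousness predictors
#'
#' Column names expected on the annotation table; each holds a verdict in
#' `{"damaging", "tolerated", "absent"}` (NA is treated as absent).
#' @export
PREDICTORS <- c("SIFT", "Polyphen2_HDIV", "LRT", "MutationTaster",
                "MutationAssessor", "FATHMM", "PROVEAN", "MetaSVM", "M_CAP")

LOF_CONSEQUENCES <- c("nonsense", "canonical_splice_site", "frameshift_indel",
                      "start_loss")

#' Consensus damaging-missense call
#'
#' A missense variant is damaging when at least `min_damaging` of the nine
#' predictors call it damaging.  Absent verdicts never count toward the
#' threshold, so variants scored by fewer than `min_damaging` predictors can
#' never be classified damaging.
#'
#' @param verdicts character vector of nine verdicts for one variant, or a
#'   matrix / data.frame with one row per variant and the nine predictor
#'   columns
#' @param min_damaging consensus threshold, default 4
#' @return logical: damaging missense?
#' @export
consensus_dmis <- function(verdicts, min_damaging = 4) {
  if (is.null(dim(verdicts))) {
    if (length(verdicts) != length(PREDICTORS))
      stop(sprintf("expected %d predictor verdicts", length(PREDICTORS)),
           call. = FALSE)
    return(sum(verdicts == "damaging", na.rm = TRUE) >= min_damaging)
  }
  v <- as.matrix(verdicts[, PREDICTORS, drop = FALSE])
  rowSums(v == "damaging", na.rm = TRUE) >= min_damaging
}

#' Rarity test against a reference allele frequency
#'
#' Strictly below the threshold counts as rare; a variant absent from the
#' frequency database (NA) is treated as unobserved, AF 0, hence rare.
#'
#' @param gnomad_af numeric allele frequencies (NA = absent)
#' @param af_threshold frequency threshold in (0, 1]
#' @return logical vector
#' @export
is_rare <- function(gnomad_af, af_threshold = 1e-4) {
  stopifnot(af_threshold > 0, af_threshold <= 1)
  is.na(gnomad_af) | gnomad_af < af_threshold
}

#' Classify variant consequences
#'
#' Maps annotated consequences to analysis classes: loss-of-function
#' (nonsense, canonical splice site, frameshift indel, start loss), damaging
#' or benign missense (consensus rule), inframe indel, synonymous (kept as
#' the negative-control class), and `other` for everything else.
#'
#' @param annotations data.frame with `consequence` and the nine predictor
#'   verdict columns
#' @param min_damaging consensus threshold for damaging missense
#' @return character vector of classes
#' @export
classify_consequence <- function(annotations, min_damaging = 4) {
  cons <- annotations$consequence
  cls <- rep("other", nrow(annotations))
  cls[cons %in% LOF_CONSEQUENCES] <- "lof"
  cls[cons == "inframe_indel"] <- "inframe_indel"
  cls[cons == "synonymous"] <- "synonymous"
  mis <- cons == "missense"
  if (any(mis)) {
    dm <- consensus_dmis(annotations[mis, , drop = FALSE], min_damaging)
    cls[mis] <- ifelse(dm, "damaging_missense", "benign_missense")
  }
  unknown <- !cons %in% c(LOF_CONSEQUENCES, "inframe_indel", "synonymous",
                          "missense", "other")
  if (any(unknown))
    message(sprintf("%d variant(s) with unrecognized consequence kept as 'other'",
                    sum(unknown)))
  cls
}

#' Classify variants and flag putative damaging variants (PDVs)
#'
#' Adds `variant_class`, `rare`, and `pdv` columns.  A PDV is a rare variant
#' (AF below `af_threshold`, absent counts as rare) whose class is
#' loss-of-function, damaging missense, or inframe indel.  Synonymous and
#' benign missense variants are never PDVs; rare synonymous variants serve
#' as the negative control.
#'
#' @param annotations data.frame with `consequence`, `gnomad_af`, and the
#'   nine predictor verdict columns
#' @param af_threshold rarity threshold (default 1e-4)
#' @param min_damaging consensus threshold for damaging missense
#' @return `annotations` with classification columns appended
#' @export
classify_variants <- function(annotations, af_threshold = 1e-4,
                              min_damaging = 4) {
  annotations$variant_class <- classify_consequence(annotations, min_damaging)
  annotations$rare <- is_rare(annotations$gnomad_af, af_threshold)
  annotations$pdv <- annotations$rare &
    annotations$variant_class %in% c("lof", "damaging_missense", "inframe_indel")
  annotations
}

#' Select putative damaging variants
#'
#' @inheritParams classify_variants
#' @return the PDV subset of `annotations`, classified
#' @export
select_pdvs <- function(annotations, af_threshold = 1e-4, min_damaging = 4) {
  cl <- classify_variants(annotations, af_threshold, min_damaging)
  cl[cl$pdv, , drop = FALSE]
}

#' Map a protein position to a domain and membrane region
#'
#' Intervals are 1-based and inclusive on both ends.  A residue between
#' annotated domains gets domain NA but still receives its region class
#' (extracellular / transmembrane / cytoplasmic), which must tile the
#' protein.
#'
#' @param protein_position 1-based residue index
#' @param domain_map data.frame of domain intervals: `domain`, `start`,
#'   `end`, plus region rows flagged by `track == "region"` vs
#'   `track == "domain"` (see [lrp1_domain_map()])
#' @return list with `domain` (or NA) and `region`
#' @export
map_to_domain <- function(protein_position, domain_map) {
  stopifnot(length(protein_position) == 1, !is.na(protein_position))
  reg <- domain_map[domain_map$track == "region", , drop = FALSE]
  if (protein_position < 1 || protein_position > max(reg$end))
    stop(sprintf("protein position %d outside protein length %d",
                 protein_position, max(reg$end)), call. = FALSE)
  in_iv <- function(df) df$domain[df$start <= protein_position &
                                    df$end >= protein_position]
  region <- in_iv(reg)
  dom <- domain_map[domain_map$track == "domain", , drop = FALSE]
  hit <- in_iv(dom)
  list(domain = if (length(hit)) hit[1] else NA_character_,
       region = region[1])
}

#' Illustrative LRP1 domain map
#'
#' A coarse residue map of the 4544-residue LRP1 receptor used for fixture
#' construction and examples: the large extracellular ligand-binding region
#' (alpha-chain plus extracellular beta-chain, residues 1-4400 here), a
#' single transmembrane helix, and the short cytoplasmic tail carrying the
#' NPxY internalization motifs.  Boundaries are illustrative round numbers,
#' not curated annotations.
#'
#' @return data.frame usable with [map_to_domain()]
#' @export
lrp1_domain_map <- function() {
  data.frame(
    track = c("region", "region", "region", "domain", "domain", "domain"),
    domain = c("extracellular", "transmembrane", "cytoplasmic",
               "ligand_binding_II", "EGF_repeat", "NPxY_tail"),
    start = c(1, 4401, 4426, 850, 4200, 4460),
    end = c(4400, 4425, 4544, 1200, 4400, 4544),
    stringsAsFactors = FALSE)
}
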