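# Fixture serialization: VCF 4.2 for genotypes (GT and GQ FORMAT fields),
# tab-separated tables for annotations and sample metadata, JSON for the
# ground-truth ledger.

geno_to_gt <- function(g) {
  out <- rep("./.", length(g))
  out[!is.na(g) & g == 0] <- "0/0"
  out[!is.na(g) & g == 1] <- "0/1"
  out[!is.na(g) & g == 2] <- "1/1"
  out
}

gt_to_geno <- function(gt) {
  alleles <- strsplit(gsub("\\|", "/", gt), "/", fixed = FALSE)
  vapply(alleles, function(a) {
    if (length(a) != 2 || any(a == ".")) NA_integer_
    else sum(as.integer(a) > 0)
  }, integer(1))
}

#' Write a cohort fixture to disk
#'
#' Emits `cohort.vcf` (VCF 4.2, GT:GQ), `annotations.tsv`, `samples.tsv`,
#' and `truth.json` under `dir`.  The background panel is omitted by default
#' (it is bulky and regenerable from the configuration).
#'
#' @param fixture a `cohort_fixture`
#' @param dir output directory (created if needed)
#' @param include_background also write `background.vcf`
#' @return `dir`, invisibly
#' @export
write_cohort <- function(fixture, dir, include_background = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_vcf(fixture$geno, fixture$gq, fixture$sites,
            file.path(dir, "cohort.vcf"))
  utils::write.table(fixture$sites, file.path(dir, "annotations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(fixture$samples, file.path(dir, "samples.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(fixture$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  if (include_background && !is.null(fixture$background)) {
    bg_sites <- data.frame(
      site_id = colnames(fixture$background$geno),
      chrom = "1",
      pos = seq_len(ncol(fixture$background$geno)) * 1000L,
      ref = "A", alt = "G", stringsAsFactors = FALSE)
    write_vcf(fixture$background$geno, NULL, bg_sites,
              file.path(dir, "background.vcf"))
  }
  invisible(dir)
}

write_vcf <- function(geno, gq, sites, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype Quality\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", rownames(geno)), collapse = "\t")), con)
  ord <- order(sites$chrom, sites$pos)
  for (j in ord) {
    gt <- geno_to_gt(geno[, j])
    cell <- if (is.null(gq)) gt else paste(gt, gq[, j], sep = ":")
    writeLines(paste(c(sites$chrom[j], sites$pos[j], sites$site_id[j],
                       sites$ref[j], sites$alt[j], ".", "PASS", ".",
                       if (is.null(gq)) "GT" else "GT:GQ", cell),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a cohort fixture from disk
#'
#' Restores the tables written by [write_cohort()]; the VCF is parsed with
#' vcfR.  The background panel and configuration are not restored.
#'
#' @param dir directory written by [write_cohort()]
#' @return a `cohort_fixture` (without `background`/`config`)
#' @export
read_cohort <- function(dir) {
  sites <- utils::read.delim(file.path(dir, "annotations.tsv"),
                             stringsAsFactors = FALSE,
                             colClasses = c(chrom = "character"))
  samples <- utils::read.delim(file.path(dir, "samples.tsv"),
                               stringsAsFactors = FALSE)
  samples$phenotypes[is.na(samples$phenotypes)] <- ""
  vcf <- vcfR::read.vcfR(file.path(dir, "cohort.vcf"), verbose = FALSE)
  ids <- vcfR::getID(vcf)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  gqm <- suppressWarnings(vcfR::extract.gt(vcf, element = "GQ", as.numeric = TRUE))
  geno <- apply(gt, 2, gt_to_geno)
  rownames(geno) <- ids
  rownames(gqm) <- ids
  # back to samples x sites, in annotation order
  geno <- t(geno)[, sites$site_id, drop = FALSE]
  gqm <- t(gqm)[, sites$site_id, drop = FALSE]
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  structure(list(samples = samples, sites = sites, geno = geno,
                 gq = gqm, background = NULL, truth = truth, config = NULL),
            class = "cohort_fixture")
}
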