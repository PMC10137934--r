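test_that("carrier collapsing counts a sample once regardless of variant count", {
  geno <- matrix(0L, 3, 4, dimnames = list(c("A", "B", "C"),
                                           sprintf("V%02d", 1:4)))
  geno["A", 1:3] <- 1L
  geno["B", 2] <- NA
  out <- collect_carriers(geno, sprintf("V%02d", 1:4))
  expect_identical(out$carrier, c(TRUE, FALSE, FALSE))
  expect_identical(out$n_carrier_variants, c(3, 0, 0))
  expect_identical(out$carrier_variants[1], "V01;V02;V03")
  # non-qualifying sites are ignored
  out2 <- collect_carriers(geno, "V04")
  expect_false(any(out2$carrier))
})

test_that("collapsed carriers reproduce the generator's truth ledger", {
  cfg <- sim_config(n_cases = 400, n_controls = 400, n_sites = 60,
                    carrier_freq_control = 0.03, m_background = 0, seed = 31)
  fx <- generate_cohort(cfg)
  carr <- collect_carriers(fx$geno, fx$truth$pdv_sites)
  expect_identical(carr$carrier, fx$truth$carriers$carrier)
  # and via the classification route rather than the truth ledger
  pdv <- select_pdvs(fx$sites)$site_id
  expect_setequal(pdv, fx$truth$pdv_sites)
})

test_that("burden rows are internally consistent and Bonferroni-corrected", {
  cfg <- sim_config(n_cases = 500, n_controls = 600, n_sites = 60,
                    carrier_freq_control = 0.05,
                    carrier_or = c(CHD = 3), m_background = 0, seed = 32)
  fx <- generate_cohort(cfg)
  cl <- classify_variants(fx$sites)
  res <- run_burden(fx$geno, cl, fx$samples,
                    phenotypes = c("CHD", "AVSD"),
                    variant_sets = c("all_PDV", "D_Mis_only"))
  expect_identical(nrow(res), 4L)
  expect_true(all(res$bonferroni_m == 4))
  for (k in seq_len(nrow(res))) {
    expect_equal(res$p[k], fisher_exact_two_sided(res$a[k], res$b[k],
                                                  res$c[k], res$d[k]))
    expect_equal(res$significant[k], res$p[k] < 0.05 / 4)
    n_ph <- sum(fx$samples$cohort == "case" &
                  grepl(res$phenotype[k], fx$samples$phenotypes))
    expect_identical(res$a[k] + res$b[k], n_ph)
    expect_identical(res$c[k] + res$d[k], 600L)
  }
  single <- run_burden(fx$geno, cl, fx$samples, phenotypes = "CHD",
                       variant_sets = "all_PDV")
  expect_identical(single$bonferroni_m, 1L)
  expect_identical(single$significant, single$p < 0.05)
})

test_that("phenotypes without cases are skipped with a message", {
  cfg <- sim_config(n_cases = 50, n_controls = 50, n_sites = 40,
                    phenotype_fractions = c(AVSD = 0),
                    carrier_freq_control = 0.05, m_background = 0, seed = 33)
  fx <- generate_cohort(cfg)
  cl <- classify_variants(fx$sites)
  expect_message(res <- run_burden(fx$geno, cl, fx$samples,
                                   phenotypes = c("CHD", "AVSD"),
                                   variant_sets = "all_PDV"),
                 "AVSD")
  expect_identical(res$phenotype, "CHD")
  expect_identical(res$bonferroni_m, 1L)
})

test_that("reference-control mode builds the allele table from the median AN", {
  ref <- data.frame(variant_key = c("a", "b", "c"),
                    allele_count = c(5, 10, 5),
                    allele_number = c(250000, 251000, 249000),
                    pass_filter = TRUE, covered_10x_fraction = 0.99)
  out <- reference_control_burden(case_alt_alleles = 10, ref, n_cases = 1000)
  expect_identical(out$c, 20)
  expect_identical(out$d, 250000 - 20)
  # worked toy example: OR = (10/1990) / (20/99980)
  ref2 <- data.frame(variant_key = "x", allele_count = 20,
                     allele_number = 100000, pass_filter = TRUE,
                     covered_10x_fraction = 0.95)
  out2 <- reference_control_burden(10, ref2, n_cases = 1000)
  expect_equal(out2$or, (10 * 99980) / (1990 * 20), tolerance = 1e-12)
  expect_equal(round(out2$or, 1), 25.1)
  # even AN count: mean of central values, rounded down
  ref3 <- data.frame(variant_key = c("x", "y"), allele_count = c(0, 1),
                     allele_number = c(100, 201), pass_filter = TRUE,
                     covered_10x_fraction = 0.95)
  out3 <- reference_control_burden(2, ref3, n_cases = 50)
  expect_identical(out3$d, 150 - 1)
  # zero reference carriers engage the Haldane path with a finite OR
  ref4 <- data.frame(variant_key = "x", allele_count = 0,
                     allele_number = 10000, pass_filter = TRUE,
                     covered_10x_fraction = 0.95)
  out4 <- reference_control_burden(3, ref4, n_cases = 100)
  expect_true(is.finite(out4$or) && out4$or > 1)
})

test_that("low-coverage and non-PASS reference records are excluded", {
  ref <- data.frame(variant_key = c("a", "b", "c"),
                    allele_count = c(5, 10, 7),
                    allele_number = c(250000, 251000, 100),
                    pass_filter = c(TRUE, FALSE, TRUE),
                    covered_10x_fraction = c(0.99, 0.99, 0.50))
  out <- reference_control_burden(10, ref, n_cases = 1000)
  expect_identical(out$c, 5)             # only record "a" qualifies
  none <- ref[ref$pass_filter == FALSE, ]
  expect_message(bad <- reference_control_burden(10, none, 1000), "not evaluable")
  expect_false(bad$evaluable)
  expect_true(is.na(bad$p))
})

test_that("synonymous control runs the identical pipeline on rare synonymous sites", {
  ann <- mini_annotations(c("syn1", "syn2", "common_syn"),
                          rep("synonymous", 3),
                          gnomad_af = c(NA, 2e-5, 0.5))
  cl <- classify_variants(ann)
  n <- 200
  ids <- sprintf("S%03d", 1:(2 * n))
  geno <- matrix(0L, 2 * n, 3, dimnames = list(ids, ann$site_id))
  geno[c(1:10, n + (1:10)), 1] <- 1L
  geno[, 3] <- 2L                        # common synonymous must be excluded
  samples <- data.frame(sample_id = ids,
                        cohort = rep(c("case", "control"), each = n),
                        phenotypes = rep(c("CHD", ""), each = n),
                        stringsAsFactors = FALSE)
  out <- synonymous_control(geno, cl, samples)
  expect_identical(c(out$a, out$b, out$c, out$d), c(10L, 190L, 10L, 190L))
  expect_equal(out$or, 1)
  expect_equal(out$p, 1)
})

test_that("the synonymous null distribution is centered at OR 1", {
  set.seed(77)
  ann <- mini_annotations("syn1", "synonymous", NA_real_)
  cl <- classify_variants(ann)
  n <- 400
  ids <- sprintf("S%04d", 1:(2 * n))
  samples <- data.frame(sample_id = ids,
                        cohort = rep(c("case", "control"), each = n),
                        phenotypes = rep(c("CHD", ""), each = n),
                        stringsAsFactors = FALSE)
  lors <- ps <- numeric(300)
  for (r in 1:300) {
    geno <- matrix(rbinom(2 * n, 1, 0.05), 2 * n, 1,
                   dimnames = list(ids, "syn1"))
    out <- synonymous_control(geno, cl, samples)
    lors[r] <- log(out$or)
    ps[r] <- out$p
  }
  expect_lt(abs(mean(lors)), 0.1)
  expect_gt(median(ps), 0.2)
})

test_that("planted compound heterozygotes are recovered exactly", {
  cfg <- sim_config(n_cases = 200, n_controls = 200, n_sites = 80,
                    carrier_freq_control = 0.02, n_compound_het = 5,
                    m_background = 0, seed = 35)
  fx <- generate_cohort(cfg)
  ch <- find_compound_hets(fx$geno, fx$sites)
  expect_setequal(ch$sample_id[ch$type == "compound_het"],
                  fx$truth$compound_het)
  expect_true(all(ch$n_variants[ch$type == "compound_het"] == 2))
})

test_that("homozygotes are reported separately and singles not flagged", {
  ann <- mini_annotations(c("p1", "p2"), c("nonsense", "missense"),
                          gnomad_af = c(1e-5, 1e-4), n_damaging = c(0, 6))
  ids <- c("hom", "single", "comp")
  geno <- matrix(0L, 3, 2, dimnames = list(ids, c("p1", "p2")))
  geno["hom", 1] <- 2L
  geno["single", 1] <- 1L
  geno["comp", ] <- 1L
  out <- find_compound_hets(geno, ann, af_threshold = 0.01)
  expect_identical(out$type[out$sample_id == "hom"], "homozygous")
  expect_identical(out$type[out$sample_id == "comp"], "compound_het")
  expect_false("single" %in% out$sample_id)
})
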