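test_that("identical configurations produce identical fixtures", {
  cfg <- sim_config(n_cases = 80, n_controls = 80, n_sites = 50,
                    n_planted_duplicates = 2, n_contaminated = 2,
                    n_failing_sites_per_criterion = 1,
                    m_background = 200, seed = 41)
  fx1 <- generate_cohort(cfg)
  fx2 <- generate_cohort(cfg)
  expect_identical(fx1, fx2)
  fx3 <- generate_cohort(sim_config(n_cases = 80, n_controls = 80,
                                    n_sites = 50, n_planted_duplicates = 2,
                                    n_contaminated = 2,
                                    n_failing_sites_per_criterion = 1,
                                    m_background = 200, seed = 42))
  expect_false(identical(fx1$geno, fx3$geno))
})

test_that("configuration invariants are enforced", {
  expect_error(sim_config(carrier_freq_control = 1), "\\[0, 1\\)")
  expect_error(sim_config(site_class_mix = c(LoF = 0.5, damaging_missense = 0.2,
                                             benign_missense = 0.1,
                                             synonymous = 0.1,
                                             inframe_indel = 0.2)),
               "summing to 1")
  expect_error(sim_config(n_cases = -1), "nonnegative")
  expect_error(sim_config(phenotype_fractions = c(CTD = 0.9, AVSD = 0.3)),
               "sum to at most 1")
  expect_error(sim_config(carrier_or = c(CHD = Inf)), "finite")
})

test_that("null configurations produce an odds ratio distribution centered at 1", {
  lors <- vapply(1:200, function(s) {
    fx <- generate_cohort(sim_config(n_cases = 500, n_controls = 500,
                                     n_sites = 12,
                                     carrier_freq_control = 0.05,
                                     carrier_or = c(CHD = 1),
                                     m_background = 0, seed = 1000 + s))
    carr <- collect_carriers(fx$geno, fx$truth$pdv_sites)$carrier
    case <- fx$samples$cohort == "case"
    log(odds_ratio_ci(sum(carr[case]), sum(case) - sum(carr[case]),
                      sum(carr[!case]), sum(!case) - sum(carr[!case]))$or)
  }, numeric(1))
  expect_lt(abs(mean(lors)), 0.1)
})

test_that("planted duplicates have identical rows and are listed in truth", {
  cfg <- sim_config(n_cases = 60, n_controls = 60, n_sites = 40,
                    n_planted_duplicates = 3, m_background = 300, seed = 43)
  fx <- generate_cohort(cfg)
  pairs <- fx$truth$related_pairs
  expect_identical(nrow(pairs), 3L)
  for (k in 1:3) {
    i <- pairs$sample_i[k]; j <- pairs$sample_j[k]
    expect_identical(fx$geno[i, ], fx$geno[j, ])
    expect_identical(fx$background$geno[i, ], fx$background$geno[j, ])
    expect_identical(estimate_kinship(fx$background$geno, i, j)$phi, 0.5)
  }
})

test_that("planted parent-offspring pairs estimate kinship near 0.25", {
  cfg <- sim_config(n_cases = 30, n_controls = 30, n_sites = 20,
                    n_planted_parent_offspring = 2, m_background = 4000,
                    seed = 44)
  fx <- generate_cohort(cfg)
  pairs <- fx$truth$related_pairs
  expect_identical(unique(pairs$kind), "parent_offspring")
  for (k in seq_len(nrow(pairs))) {
    phi <- estimate_kinship(fx$background$geno,
                            pairs$sample_i[k], pairs$sample_j[k])$phi
    expect_gt(phi, 0.20); expect_lt(phi, 0.30)
  }
})

test_that("planting zero pairs leaves the fixture unchanged; unknown kinds error", {
  cfg <- sim_config(n_cases = 20, n_controls = 20, n_sites = 20,
                    m_background = 50, seed = 45)
  fx <- generate_cohort(cfg)
  expect_identical(plant_relatives(fx, "duplicate", 0), fx)
  expect_error(plant_relatives(fx, "sibling", 1), "unknown relative kind")
  expect_error(plant_relatives(fx, "duplicate", 100), "available samples")
})

test_that("truth carrier ledger matches an independent recount from genotypes", {
  cfg <- sim_config(n_cases = 150, n_controls = 150, n_sites = 50,
                    carrier_freq_control = 0.04, n_planted_duplicates = 2,
                    m_background = 100, seed = 46)
  fx <- generate_cohort(cfg)
  for (i in seq_len(nrow(fx$samples))) {
    g <- fx$geno[fx$samples$sample_id[i], fx$truth$pdv_sites]
    expect_identical(any(!is.na(g) & g >= 1),
                     fx$truth$carriers$carrier[i])
  }
})

test_that("planted QC metric violations hit exactly the planted entities", {
  cfg <- sim_config(n_cases = 100, n_controls = 100, n_sites = 60,
                    n_contaminated = 4, m_background = 0, seed = 47)
  fx <- generate_cohort(cfg)
  expect_identical(length(fx$truth$contaminated), 4L)
  expect_identical(sum(fx$samples$freemix > 0.075), 4L)
  expect_identical(sum(fx$samples$call_missingness > 0.10), 0L)
})

test_that("expression fixture gives marker clusters the maximal z-score", {
  hits <- 0L
  for (s in 1:10) {
    ex <- generate_expression(240, 40, clusters = c("A", "B", "C"),
                              marker_spec = list(A = c("g0001", "g0002")),
                              seed = s)
    tpm <- compute_tpm(ex$counts, ex$effective_length)
    st <- cluster_dot_stats(tpm, ex$clusters)
    for (g in c("g0001", "g0002")) {
      sg <- st[st$gene == g, ]
      hits <- hits + (sg$cluster[which.max(sg$z_mean)] == "A")
    }
  }
  expect_identical(hits, 20L)
})

test_that("expression generator validates inputs and flags degenerate cases", {
  expect_error(generate_expression(0, 10), "positive")
  expect_error(generate_expression(10, 5, marker_spec = list(A = "g9999")),
               "unknown marker gene")
  ex <- generate_expression(50, 8, clusters = "only", seed = 2)
  st <- cluster_dot_stats(compute_tpm(ex$counts, ex$effective_length),
                          ex$clusters)
  expect_true(all(st$degenerate))
  expect_true(all(st$z_mean == 0))
})

test_that("exchangeable clusters show only sampling-noise differences", {
  ex <- generate_expression(600, 20, clusters = c("A", "B"), seed = 3)
  st <- cluster_dot_stats(compute_tpm(ex$counts, ex$effective_length),
                          ex$clusters)
  d <- tapply(st$exp_pct, st$gene, function(x) abs(diff(x)))
  expect_lt(max(d), 0.15)
})
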