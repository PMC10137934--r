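mk_samples <- function(n, cohort = "control", freemix = 0.01,
                       miss = 0.01, vc = 20000) {
  data.frame(sample_id = sprintf("X%03d", seq_len(n)),
             cohort = rep(cohort, length.out = n),
             phenotypes = ifelse(rep(cohort, length.out = n) == "case", "CHD", ""),
             freemix = rep(freemix, length.out = n),
             call_missingness = rep(miss, length.out = n),
             variant_count = rep(vc, length.out = n),
             stringsAsFactors = FALSE)
}

test_that("contamination and missingness boundaries are strict", {
  s <- mk_samples(4)
  s$freemix <- c(0.075, 0.0751, 0.01, 0.01)
  s$call_missingness <- c(0.01, 0.01, 0.10, 0.101)
  out <- filter_sample_metrics(s)
  expect_identical(out$qc_status,
                   c("pass", "fail_contamination", "pass", "fail_missingness"))
})

test_that("contamination takes precedence over missingness", {
  s <- mk_samples(1, freemix = 0.2, miss = 0.5)
  expect_identical(filter_sample_metrics(s)$qc_status, "fail_contamination")
})

test_that("variant-count outlier rule flags exactly the planted outlier", {
  set.seed(11)
  s <- mk_samples(101)
  s$variant_count <- c(100 + sample(-5:5, 100, TRUE), 400)
  out <- filter_sample_metrics(s)
  expect_identical(sum(out$qc_status == "fail_outlier"), 1L)
  expect_identical(out$qc_status[101], "fail_outlier")
  # direct computation of the rule on the constructed vector
  med <- median(s$variant_count[1:100])
  smad <- mad(s$variant_count[1:100], constant = 1.4826)
  expect_true(abs(400 - med) > 4 * smad)
  expect_true(all(abs(s$variant_count[1:100] - med) <= 4 * smad))
})

test_that("a missing metric is an error naming the sample", {
  s <- mk_samples(3)
  s$freemix[2] <- NA
  expect_error(filter_sample_metrics(s), "X002")
})

test_that("one sample is removed per related pair", {
  s <- mk_samples(4)
  s$qc_status <- "pass"
  pairs <- data.frame(sample_i = "X001", sample_j = "X002", phi = 0.5)
  out <- prune_related(s, pairs)
  expect_identical(sum(out$qc_status == "fail_related"), 1L)
  expect_true(out$qc_status[1] == "pass" || out$qc_status[2] == "pass")
})

test_that("relationship hubs are removed and their partners kept", {
  s <- mk_samples(7)
  s$qc_status <- "pass"
  pairs <- data.frame(sample_i = rep("X001", 5),
                      sample_j = sprintf("X%03d", 2:6),
                      phi = rep(0.2, 5))
  out <- prune_related(s, pairs)
  expect_identical(out$qc_status[1], "fail_related")
  expect_identical(sum(out$qc_status == "fail_related"), 1L)
})

test_that("pair resolution prefers higher missingness, then controls", {
  s <- mk_samples(4, cohort = c("case", "control", "case", "control"))
  s$qc_status <- "pass"
  s$call_missingness <- c(0.04, 0.01, 0.02, 0.02)
  pairs <- data.frame(sample_i = c("X001", "X003"),
                      sample_j = c("X002", "X004"),
                      phi = c(0.3, 0.3))
  out <- prune_related(s, pairs)
  expect_identical(out$qc_status[1], "fail_related")  # higher missingness
  expect_identical(out$qc_status[4], "fail_related")  # tie: drop the control
})

test_that("pruning is invariant to input order and to sub-threshold pairs", {
  s <- mk_samples(6)
  s$qc_status <- "pass"
  s$call_missingness <- seq(0.01, 0.06, by = 0.01)
  pairs <- data.frame(sample_i = c("X001", "X003", "X002"),
                      sample_j = c("X004", "X005", "X006"),
                      phi = c(0.3, 0.05, 0.2))
  ref <- prune_related(s, pairs)
  perm <- sample(nrow(s))
  out <- prune_related(s[perm, ], pairs[c(3, 1, 2), ])
  out <- out[order(out$sample_id), ]
  expect_identical(out$qc_status, ref$qc_status)
  expect_identical(ref$qc_status[3], "pass")   # phi below cutoff: untouched
  s2 <- prune_related(s, pairs[pairs$phi > 0.5, ])
  expect_true(all(s2$qc_status == "pass"))
})

test_that("single-population cohorts are essentially never ancestry-flagged", {
  removed <- 0L
  total <- 0L
  for (seed in 1:100) {
    set.seed(seed)
    af <- runif(200, 0.1, 0.9)
    g <- matrix(rbinom(100 * 200, 2, rep(af, each = 100)), 100, 200)
    s <- mk_samples(100, cohort = rep(c("case", "control"), 50))
    rownames(g) <- s$sample_id
    s$qc_status <- "pass"
    out <- pca_ancestry_filter(g, s, thresholds = qc_thresholds(pca_n_components = 5))
    removed <- removed + sum(out$samples$qc_status == "fail_ancestry")
    total <- total + 100L
  }
  expect_lt(removed / total, 0.01)
})

test_that("a diverged population is fully removed against the reference", {
  set.seed(21)
  af1 <- runif(300, 0.05, 0.55)
  af2 <- af1 + 0.4
  g1 <- matrix(rbinom(80 * 300, 2, rep(af1, each = 80)), 80, 300)
  g2 <- matrix(rbinom(20 * 300, 2, rep(af2, each = 20)), 20, 300)
  g <- rbind(g1, g2)
  s <- mk_samples(100, cohort = c(rep("control", 80), rep("case", 20)))
  rownames(g) <- s$sample_id
  s$qc_status <- "pass"
  out <- pca_ancestry_filter(g, s, reference_cohort = "control",
                             thresholds = qc_thresholds(pca_n_components = 5))
  expect_true(all(out$samples$qc_status[81:100] == "fail_ancestry"))
  expect_true(mean(out$samples$qc_status[1:80] == "pass") > 0.95)
})

test_that("zero requested components is the identity filter", {
  s <- mk_samples(10)
  s$qc_status <- "pass"
  g <- matrix(1L, 10, 5, dimnames = list(s$sample_id, NULL))
  out <- pca_ancestry_filter(g, s, thresholds = qc_thresholds(pca_n_components = 0))
  expect_true(all(out$samples$qc_status == "pass"))
})
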