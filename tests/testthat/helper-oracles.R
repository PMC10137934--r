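# Independent oracles used across tests.

# Two-sided Fisher p by direct hypergeometric enumeration with stats::dhyper
# (independent of the package's log-factorial implementation).
enum_fisher <- function(a, b, c, d) {
  r1 <- a + b
  c1 <- a + c
  n <- a + b + c + d
  if (n == 0 || r1 == 0 || c1 == 0 || r1 == n || c1 == n) return(1)
  lo <- max(0, r1 + c1 - n)
  hi <- min(r1, c1)
  pr <- stats::dhyper(lo:hi, c1, n - c1, r1)
  min(1, sum(pr[pr <= pr[a - lo + 1] * (1 + 1e-7)]))
}

# Exact HWE p by brute-force evaluation of the conditional distribution of
# heterozygote counts (raw probabilities; no renormalization trick).
enum_hwe <- function(n_hom_ref, n_het, n_hom_alt) {
  n <- n_hom_ref + n_het + n_hom_alt
  nalt <- 2 * n_hom_alt + n_het
  na <- min(nalt, 2 * n - nalt)
  if (n == 0 || na == 0) return(1)
  hs <- seq(na %% 2, na, by = 2)
  p <- vapply(hs, function(h) {
    hm <- (na - h) / 2
    hM <- n - h - hm
    exp(lfactorial(n) - lfactorial(h) - lfactorial(hm) - lfactorial(hM) +
          h * log(2) + lfactorial(na) + lfactorial(2 * n - na) -
          lfactorial(2 * n))
  }, numeric(1))
  min(1, sum(p[p <= p[match(n_het, hs)] * (1 + 1e-7)]))
}

# random 2x2 tables for property tests
random_tables <- function(n_tables, max_cell = 40, seed = 1) {
  set.seed(seed)
  matrix(sample(0:max_cell, 4 * n_tables, TRUE), ncol = 4)
}

# minimal classified annotation table for burden tests
mini_annotations <- function(site_id, consequence, gnomad_af,
                             gene = "LRP1", n_damaging = 0) {
  m <- length(site_id)
  verd <- matrix("absent", m, length(PREDICTORS),
                 dimnames = list(NULL, PREDICTORS))
  for (i in seq_len(m))
    if (n_damaging[min(i, length(n_damaging))] > 0)
      verd[i, seq_len(n_damaging[min(i, length(n_damaging))])] <- "damaging"
  cbind(data.frame(site_id = site_id, gene_symbol = gene,
                   consequence = consequence, gnomad_af = gnomad_af,
                   stringsAsFactors = FALSE),
        as.data.frame(verd, stringsAsFactors = FALSE))
}
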