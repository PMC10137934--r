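# Exact small-sample statistics used throughout the pipeline: the two-sided
# Fisher test on 2x2 tables, odds ratios with confidence intervals, and the
# exact Hardy-Weinberg test.  These are written from first principles with
# log-factorial accumulation so that every consumer (burden testing, site
# differential missingness, HWE) shares one verified core.

check_cells <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(is.na(cells)) || any(cells < 0) || any(cells != round(cells)))
    stop("table cells must be nonnegative integers", call. = FALSE)
  invisible(cells)
}

# log point probabilities of the hypergeometric support for fixed margins
# (row1 total r1, col1 total c1, grand total n)
hyper_log_probs <- function(r1, c1, n) {
  lo <- max(0, r1 + c1 - n)
  hi <- min(r1, c1)
  k <- lo:hi
  lfactorial(r1) + lfactorial(n - r1) + lfactorial(c1) + lfactorial(n - c1) -
    lfactorial(n) - lfactorial(k) - lfactorial(r1 - k) -
    lfactorial(c1 - k) - lfactorial(n - r1 - c1 + k)
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact conditional test on both margins.  The two-sided p-value follows the
#' minimum-likelihood convention: the sum of hypergeometric point
#' probabilities not exceeding that of the observed table (within relative
#' tolerance 1e-7), the definition used by most statistical software.
#'
#' Cell layout for burden testing: `a` carrier cases, `b` non-carrier cases,
#' `c` carrier controls, `d` non-carrier controls.  A degenerate margin
#' (all-zero row or column) returns p = 1 by convention.
#'
#' @param a,b,c,d nonnegative integer cell counts
#' @return two-sided p-value in \[0, 1\]
#' @examples
#' fisher_exact_two_sided(58, 1864, 36, 2566)
#' @export
fisher_exact_two_sided <- function(a, b, c, d) {
  check_cells(a, b, c, d)
  r1 <- a + b
  c1 <- a + c
  n <- a + b + c + d
  if (n == 0 || r1 == 0 || c1 == 0 || r1 == n || c1 == n) return(1)
  lp <- hyper_log_probs(r1, c1, n)
  lo <- max(0, r1 + c1 - n)
  lp_obs <- lp[a - lo + 1]
  min(1, sum(exp(lp[lp <= lp_obs + log1p(1e-7)])))
}

#' One-sided (enrichment) Fisher exact p-value
#'
#' Upper-tail probability of observing at least `a` carrier cases given both
#' margins; used for monotonicity diagnostics.
#'
#' @inheritParams fisher_exact_two_sided
#' @return one-sided p-value
#' @export
fisher_exact_greater <- function(a, b, c, d) {
  check_cells(a, b, c, d)
  r1 <- a + b
  c1 <- a + c
  n <- a + b + c + d
  if (n == 0 || r1 == 0 || c1 == 0 || r1 == n || c1 == n) return(1)
  lp <- hyper_log_probs(r1, c1, n)
  lo <- max(0, r1 + c1 - n)
  min(1, sum(exp(lp[(a - lo + 1):length(lp)])))
}

#' Odds ratio with 95% confidence interval for a 2x2 table
#'
#' Point estimate is the cross-product ratio a*d/(b*c).  When any cell is
#' zero, the Haldane-Anscombe correction (0.5 added to every cell) is used
#' for both the point estimate and the interval.  The default interval is the
#' Woolf log method, exp(log OR +/- z * sqrt(1/a + 1/b + 1/c + 1/d)); the
#' conditional maximum-likelihood exact interval (as produced by
#' [stats::fisher.test()]) is available as `method = "cmle"`.
#'
#' @inheritParams fisher_exact_two_sided
#' @param method `"woolf"` (default) or `"cmle"`
#' @param conf_level confidence level, default 0.95
#' @return list with `or`, `ci` (length-2 vector), `method`, and
#'   `corrected` (whether the 0.5 correction was applied)
#' @examples
#' odds_ratio_ci(58, 1864, 36, 2566)
#' @export
odds_ratio_ci <- function(a, b, c, d, method = c("woolf", "cmle"),
                          conf_level = 0.95) {
  method <- match.arg(method)
  check_cells(a, b, c, d)
  corrected <- any(c(a, b, c, d) == 0)
  cc <- if (corrected) c(a, b, c, d) + 0.5 else c(a, b, c, d)
  or <- cc[1] * cc[4] / (cc[2] * cc[3])
  if (method == "woolf") {
    z <- stats::qnorm(1 - (1 - conf_level) / 2)
    se <- sqrt(sum(1 / cc))
    ci <- exp(log(or) + c(-1, 1) * z * se)
  } else {
    ft <- stats::fisher.test(matrix(c(a, c, b, d), 2), conf.level = conf_level)
    ci <- as.numeric(ft$conf.int)
  }
  list(or = or, ci = ci, method = method, corrected = corrected)
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Conditional-on-allele-counts exact test: enumerates all heterozygote
#' counts compatible with the observed allele counts and sums the
#' probabilities of configurations no more likely than the observed one
#' (within relative tolerance 1e-7).
#'
#' @param n_hom_ref,n_het,n_hom_alt genotype counts
#' @return exact p-value; 1 for monomorphic or empty input
#' @examples
#' hwe_exact_test(25, 50, 25)
#' @export
hwe_exact_test <- function(n_hom_ref, n_het, n_hom_alt) {
  cnt <- c(n_hom_ref, n_het, n_hom_alt)
  if (any(is.na(cnt)) || any(cnt < 0) || any(cnt != round(cnt)))
    stop("genotype counts must be nonnegative integers", call. = FALSE)
  n <- sum(cnt)
  if (n == 0) return(1)
  n_alt <- 2 * n_hom_alt + n_het
  na <- min(n_alt, 2 * n - n_alt)     # minor allele count
  if (na == 0) return(1)
  h_obs <- n_het
  h <- seq(na %% 2, na, by = 2)       # feasible het counts share parity
  hom_minor <- (na - h) / 2
  hom_major <- n - h - hom_minor
  lp <- lfactorial(n) - lfactorial(h) - lfactorial(hom_minor) -
    lfactorial(hom_major) + h * log(2) +
    lfactorial(na) + lfactorial(2 * n - na) - lfactorial(2 * n)
  lp <- lp - max(lp)                  # stabilize, renormalize below
  p <- exp(lp) / sum(exp(lp))
  p_obs <- p[match(h_obs, h)]
  if (is.na(p_obs))
    stop("observed heterozygote count incompatible with allele counts", call. = FALSE)
  min(1, sum(p[p <= p_obs * (1 + 1e-7)]))
}
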