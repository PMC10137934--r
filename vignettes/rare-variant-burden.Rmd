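---
title: "Rare-variant gene burden testing with cohort quality control"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rare-variant gene burden testing with cohort quality control}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The analysis

rvburden implements a single-gene, case-control collapsing burden analysis
for rare putative damaging variants (PDVs), of the kind used to ask whether
damaging variation in one candidate gene — here motivated by *LRP1* and
congenital heart disease (CHD) — is enriched in affected individuals.  The
chain is:

1. **Sample QC** — remove contaminated samples (FREEMIX > 0.075), samples
   with call missingness > 10%, variant-count outliers, one member of every
   cryptically related pair (KING-robust kinship > 0.09375, the
   second-degree bound), relationship hubs (5 or more flagged pairs), and
   ancestry outliers (principal-component scores beyond 6 reference SDs).
2. **Site QC** — six criteria applied with first-failure tagging: excess
   heterozygosity p > 3.4e-6 (input annotation), VQSR 99.95% tranche pass
   (input annotation), genotype quality (GQ >= 20 for SNVs, >= 60 for
   indels, applied as per-genotype masking), indel proximity (SNVs within
   10 bp or indels within 5 bp of another indel are removed; "within" is
   read inclusively), pooled missing rate < 10% together with differential
   missingness p > 1e-6 (a two-sided Fisher exact test of missing calls in
   cases vs controls), and control Hardy-Weinberg exact p > 1e-6.
3. **Classification** — loss of function (nonsense, canonical splice site,
   frameshift indel, start loss), damaging missense by consensus (at least
   4 of 9 predictors: SIFT, Polyphen2_HDIV, LRT, MutationTaster,
   MutationAssessor, FATHMM, PROVEAN, MetaSVM, M_CAP), inframe indel,
   benign missense, synonymous.  A PDV is a LoF, damaging-missense, or
   inframe-indel variant with reference allele frequency below 1e-4
   (absent = rare).
4. **Burden testing** — carriers are collapsed per sample (any qualifying
   non-reference genotype counts once) and each phenotype stratum (CHD,
   CTD, LVOTO, AVSD, ...) is compared with the shared controls by a
   two-sided Fisher exact test; the odds ratio is the cross-product
   a·d/(b·c) with a Woolf log-interval, and Bonferroni correction uses all
   tests of the invocation as the family.

Ancillary results: a synonymous-variant negative control run through the
identical machinery, a compound-heterozygote scan at the relaxed AF < 0.01
tier, an allele-count mode for public reference controls, and single-cell
expression summaries (TPM, per-cluster percent-expressed and z-scored
cluster means) of the kind shown in developmental-heart dot plots.

## Statistical conventions and numerical choices

**Fisher exact test.**  Written from first principles with log-factorial
accumulation over the hypergeometric support.  The two-sided p-value is the
minimum-likelihood definition — the sum of point probabilities not
exceeding the observed one — with a relative tolerance of 1e-7 on the
comparison, matching the convention of common statistical software.
Degenerate margins return p = 1.  The implementation is validated in the
test suite against exhaustive enumeration for *every* 2×2 table with total
at most 60 (agreement to 1e-12) and against `stats::fisher.test` on random
tables.

**Odds ratios.**  The point estimate is the cross-product ratio, the
convention that reproduces published table-derived ORs; when any cell is
zero the Haldane–Anscombe 0.5 correction is applied to all cells for both
the point and the interval.  The default interval is the Woolf log method;
the conditional-MLE exact interval (via `stats::fisher.test`) is available
as an option.

**Exact HWE test.**  Conditional on allele counts, summing configurations
no more likely than the one observed, computed with a max-shifted
renormalized log-probability vector; checked against brute-force
enumeration for n ≤ 50.

**KING-robust kinship.**  phi = (n_het_het − 2·n_opp_hom) / (n_het_i +
n_het_j), counted over sites non-missing in both samples; a pair with no
heterozygous informative sites has undefined kinship and is excluded from
pruning.  All-pairs screening is done with dense cross-products, which
handles ~4,500 samples against a few thousand markers in well under a
minute.

**Relatedness resolution.**  The threshold graph is resolved
deterministically: hubs (degree ≥ 5) first, then one member per remaining
pair — the higher-missingness member, ties broken by removing the control
(preserving case power), then the lexicographically larger id.  The
retained set is invariant to input order.

**PCA ancestry.**  Dosages at common sites (AF > 0.05) are standardized to
unit Hardy–Weinberg variance with mean-imputed missing calls; exact
components come from the smaller Gram matrix.  Defaults (10 components,
6 SD) are deliberately permissive: they flag cross-population outliers
while essentially never flagging members of a homogeneous cohort.

## What the synthetic cohort emulates — and what it does not

`sim_config()` defaults *are* the study conditions: 1922 cases versus 2602
controls, control carrier frequency 36/2602, and subgroup odds ratios (CHD
2.22, CTD 2.37, LVOTO 1.86, AVSD 3.14).  The control carrier count 36 is
not printed in the source tables; it is implied uniquely by the printed
pair (OR 2.22, p = 1.92e-4), which the reconstruction in
`scripts/acceptance.R` recovers by enumeration.  AVSD (142/1922) and DORV
(111/1922) subgroup fractions are published counts; CTD (0.35) and LVOTO
(0.25) fractions are this package's own realistic choices for a CHD cohort,
as the corresponding counts appear only in a figure.

Carrier status is drawn per sample as a Bernoulli with the control
probability p0 for controls and, for a case in subgroup g, the probability
whose odds equal OR_g times the control odds.  Carriers are planted
heterozygous at a single damaging site (most such variants are observed
heterozygous); compound heterozygotes are planted explicitly when
requested.  Damaging-class sites carry *only* planted carriers, so the
truth ledger matches the genotype matrix exactly and recovery tests are
sharp.

Two generator choices deserve emphasis:

* **Bounded clean metrics.**  Clean samples draw FREEMIX from U(0, 0.05),
  missingness from U(0, 0.05) and exome-wide variant counts from
  U(19000, 21000).  With bounded supports the median ± 4·MAD outlier rule
  has a *zero* nominal false-positive rate, so the generator's contract —
  exactly the planted entities violate each threshold — holds by
  construction, and QC-recovery tests are deterministic.
* **A background marker panel.**  Kinship and ancestry estimation are
  meaningless on the ~10² sites of a single gene: the KING estimator's
  standard error on unrelated pairs scales like 0.9/sqrt(m), so at m ≈ 100
  the second-degree threshold would be crossed constantly by noise.  Real
  pipelines estimate kinship and PCA genome-wide; the generator therefore
  also emits a panel of m = 4000 common biallelic SNVs (AF ~ U(0.1, 0.9),
  Hardy–Weinberg, no LD), giving sd(phi) ≈ 0.014 and an expected count of
  false second-degree flags below 1e-3 across all ~10⁷ pairs of the
  full-size cohort.  Duplicates and parent-offspring pairs are planted in
  both the gene matrix and the panel (offspring by Mendelian transmission
  of one parental allele, the other drawn from the site frequency).

The generator does **not** model linkage disequilibrium, sequencing-read
error processes, population substructure within a cohort (unless planted),
per-site coverage profiles, or annotation errors.  Passing tests therefore
demonstrate the correctness and calibration of the statistical machinery
under the stated model, not robustness of the method to real-data
pathologies such as batch-confounded coverage or predictor disagreement
structure.

One deliberate coupling: a site planted with uniformly low GQ is removed by
the pipeline under the *missing-rate* tag, because GQ filtering masks
genotypes and the site then fails recomputed missingness.  The truth ledger
records that expected status so recovery tests compare like with like.

**Randomness.**  One user seed is forked into named substreams per
component (samples, sites, genotypes, background, relatives, ...), so
adding a component does not perturb the draws of the others; identical
configurations yield byte-identical fixtures.

## Problem sizes used for verification

The shipped checks use sizes chosen to make Monte-Carlo error small while
keeping a full run comfortable on a laptop: 2000 replicate null cohorts of
500/500 for type-I calibration (99% binomial band around 0.05, with the
exact test's conservatism accepted below it); 500 replicates at the full
1922/2602 dimensions for odds-ratio recovery (mean within 10% of 2.22, CI
coverage ≥ 90%); exhaustive exact-test validation over all tables with
total ≤ 60; a full-size clean cohort for the 1922-case accounting check;
and 100 seeds for expression marker recovery.  Replicated fixtures for the
calibration studies disable the background panel (m_background = 0), which
only kinship/PCA consume.

## Interpreting the synonymous control

Rare synonymous variants run through the identical pipeline serve as the
negative control; with equal carrier frequencies the odds-ratio
distribution is centered at 1.  The package reports this result without
asserting a direction — it is a diagnostic for cryptic stratification or
differential calling, not a hypothesis test.

## Reference-control mode

When controls are a public reference summary rather than genotypes, the
comparison is built on alleles: qualifying reference variants (PASS filter,
>10× coverage in >90% of samples) contribute their summed allele count
against a denominator equal to the floor of the median allele number across
qualifying variants; cases contribute summed alternate alleles against
2·n_cases.  Median-of-AN is robust to per-variant call-rate variation in
the reference; the corresponding carrier-approximation is deliberately not
the default since the reference reports alleles, not carriers.

## Known limitations

* Single-gene focus: the Bonferroni family is the invocation's tests, not
  an exome-wide scan.
* No covariate adjustment (no logistic/Firth regression) and no
  variance-component tests; the contrast is purely the collapsed 2×2 table.
* Phenotype subgroup labels are taken from the sample table as given;
  non-exclusive labels are supported but the generator assigns one
  subgroup per case.
* VQSR tranche membership and excess-heterozygosity p are consumed as
  input annotations — they require the raw joint-calling context and are
  fabricated by the generator.
* Transcript selection ("most severe consequence") is assumed done by the
  annotation source; CADD scores are carried but unused, as no threshold
  on them is part of the analysis.
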