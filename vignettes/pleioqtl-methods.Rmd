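---
title: "Methods: multi-trait GWAS, eQTL mapping and SMR in pleioqtl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-trait GWAS, eQTL mapping and SMR in pleioqtl}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Fertility traits in cattle (days to calving, age at first calving, pregnancy
status, weeks pregnant) are heritable but noisy, so single-trait GWAS at
moderate sample sizes finds few genome-wide significant variants, and the
ones it finds rarely explain mechanism. `pleioqtl` implements a pipeline
that attacks this from three sides: (i) a conditional multi-trait statistic
that pools evidence across correlated traits, (ii) cis/trans eQTL mapping in
whole blood with a hierarchical multiple-testing correction, and (iii)
summary-data-based Mendelian randomisation (SMR) linking the two, so that a
variant associated with both a trait and a gene's expression flags the gene
as a candidate mediator. A synthetic-data generator with planted truth makes
every stage testable end to end.

# Models

## Single-trait mixed model

Each trait is analysed with

$$y = 1_n\mu + X\beta + W_i\alpha_i + g + e,\qquad
  g \sim N(0, G\sigma_g^2),\quad e \sim N(0, \sigma_e^2 I),$$

where $G$ is the allele-frequency-standardized genomic relationship matrix
(GRM), $G_{jk} = \tfrac1m\sum_i (x_{ij}-2p_i)(x_{ik}-2p_i)/(2p_i(1-p_i))$,
built from variants with folded MAF above 0.01. Variance components are
estimated once per trait by REML under the null (no variant term) and held
fixed across variants; each variant is then tested by generalized least
squares with $V = \sigma_g^2 G + \sigma_e^2 I$. This "estimate once, scan
fast" strategy is the standard large-cohort approximation; the residual
scale is re-profiled per variant, so in the $\sigma_g^2 = 0$ limit every
record is exactly the OLS regression t-test (a property the test suite
asserts at 1e-8). p-values use the standard-normal reference on
$t = \hat\alpha/\mathrm{SE}$; at the tiny n used by the REML grid-oracle
test the Student-t reference would differ, which is why that oracle checks
the restricted likelihood itself rather than p-values.

REML is computed through a single eigendecomposition of the (complete-case
subsetted) GRM: rotating $y$ and $X$ by the eigenvectors diagonalizes $V$,
and the restricted likelihood is profiled over the variance ratio with a
univariate optimizer (interior optimum compared against the
$\sigma_g^2 = 0$ boundary). Binary traits (pregnancy status) are analysed
on the 0/1 scale with the same linear model, as is standard in livestock
genetics.

## Conditional multi-trait statistic

For variant $i$ with signed t-values $t_i$ across the $k$ traits,

$$X^2_i = t_i^\top V^{-1} t_i, \qquad X^2_i \sim \chi^2_k \text{ under the null},$$

where $V$ is the $k \times k$ correlation matrix of signed t-values across
all scanned variants. Under the null $V$ approximates the phenotypic
correlation of the traits on shared samples, and the statistic gains the
most power when effects oppose the residual correlation structure. The
solve uses a Cholesky factorization, never an explicit inverse.

The stepwise conditional selection cycles between (a) single-trait scans
conditioning on the current putative causal set (fitted jointly as fixed
covariates) and (b) the multi-trait statistic. Within a cycle, per
chromosome, the most significant variant with $p < 5\times10^{-6}$ is
selected, every significant same-chromosome variant with LD $r^2 > 0.1$ to
a selected variant is set aside as tagging the same QTL, and selection
repeats until no significant variant remains; cycles stop when nothing new
is selected (cap: 10 cycles). Design choices the procedure's description
leaves open, resolved here:

* **V is estimated once** from the unconditional scans and held fixed across
  cycles. Re-estimating V after conditioning would change the statistic's
  null reference mid-run.
* Variance components are likewise not re-fitted per cycle.
* Ties in significance break by (smaller p, lower chromosome, lower
  position) for reproducibility.
* Cross-chromosome LD is not checked; the $r^2$ rule applies within a
  chromosome only.
* The same-chromosome $r^2 \le 0.1$ invariant over the selected set is
  asserted programmatically on every run.

## Closed-form FDR

For a threshold $P$, with $A$ of $T$ tested variants significant,

$$\mathrm{FDR} = \frac{P\,(1 - A/T)}{(A/T)\,(1 - P)},$$

capped at 1, with $A=0$ reported as 1 by convention. Reports truncate
rather than round (0.5190 prints as 0.51; 3.898% prints as 3.8%), which is
what `truncate_decimals()` is for.

## cis/trans eQTL mapping

Genes pass the inclusion filter unless CPM < 3 in at least 25% of samples
(inclusive at the boundary). The model per gene mirrors the trait model
with log-CPM as the phenotype, fixed covariates (contemporary group,
lactation, weeks pregnant) plus the first four expression PCs (computed
after the CPM filter, before any genotype enters, with a deterministic
sign convention), and the GRM random effect with per-gene REML components.
The cis window is $\pm 2$ Mb around the annotated TSS and closed (a variant
at exactly the boundary is tested); windows are symmetric, so strand only
orients the sign of the reported TSS distance. Trans pairs require the same
chromosome and a TSS distance strictly above 5 Mb, so a trans association
cannot tag a cis effect; cross-chromosome testing is deliberately off. The
trans test set is the deduplicated union of lead cis-eQTLs, genome-wide
significant GWAS variants ($p \le 5\times10^{-8}$ from single-trait and
multi-trait scans), and panel variants within 100 bp of any of these; flank
variants come from the already-MAF-filtered panel.

The hierarchical correction is two nested Bonferroni steps: locally,
$p_{\mathrm{local}} = \min(1, p \times m_g)$ with $m_g$ the gene's tested
variant count; globally, a gene is an eGene iff
$\min p_{\mathrm{local}} \times n_{\mathrm{genes}} < \alpha$ (0.01), and
its significant eQTLs are the variants passing the same product threshold.
The two phrasings "$\alpha/n$ applied to $p_{\mathrm{local}}$" and
"$\alpha$ applied to $\min p_{\mathrm{local}} \times n$" are algebraically
identical, and identical here by construction. Output labels keep the
conventional name "global FDR" for the Step-2 quantity even though the
procedure is Bonferroni-style. Lead ties break by smallest
$|$TSS distance$|$, then position.

## SMR

With $z_g = b_{\mathrm{GWAS}}/\mathrm{SE}$ and
$z_e = b_{\mathrm{eQTL}}/\mathrm{SE}$,

$$T_{\mathrm{SMR}} = \frac{z_g^2 z_e^2}{z_g^2 + z_e^2} \sim \chi^2_1,
  \qquad \hat b_{xy} = b_{\mathrm{GWAS}} / b_{\mathrm{eQTL}}.$$

Instruments are each eGene's lead cis-eQTL at $p < 5\times10^{-8}$, tested
per trait where the variant's GWAS $p < 5\times10^{-3}$; alleles are
harmonized by (chrom, pos) with sign flips for swapped effect alleles, and
unalignable pairs are skipped. The statistic is symmetric in the two
z-scores and bounded by $\min(z_g^2, z_e^2)$. The Bonferroni threshold is
$\alpha$ over the pooled count of genes tested across traits (the per-trait
count is also reported); the HEIDI heterogeneity test and multi-instrument
SMR are out of scope.

## Enrichment and validation

Interval membership is a 1-based point query against BED intervals
converted at the boundary (BED `10 20` covers 1-based 11..20). Enrichment
of lead eQTLs in a category uses the upper-tail hypergeometric test against
the background of all variants tested in the corresponding scan
(configurable); category definitions come from user-supplied interval
files, never hard-coded windows. Gene-set overlap uses Fisher's exact test
(two-sided by default, the sidedness being unstated in common practice)
over an explicit universe argument — the right universe is a scientific
choice the package refuses to guess. The Haldane 0.5 correction is applied
to the odds ratio (flagged) when a margin cell is zero. Variance explained
by a variant subset builds a GRM from those variants alone, fits REML, and
contrasts against the mean of five equally sized random subsets;
`validation_retest()` counts discovery hits below p = 0.002 in a second
cohort's summary statistics and attaches the closed-form FDR.

# The synthetic-data generator

The generator emulates the statistical structure the stages assume, not the
biology that produced it:

* **Genotypes**: two haplotypes per animal; within a chromosome each
  haplotype is a first-order Markov chain — the allele at site $i{+}1$ is
  copied from site $i$ with probability `ld_rho` (default 0.9), else drawn
  fresh at that site's target frequency (uniform in [0.05, 0.5]). Adjacent
  dosage correlation is therefore $\approx$ `ld_rho` and decays
  geometrically, which is exactly enough LD to exercise clumping and
  proxy-recovery; realized MAF is recorded from the data. With
  heterogeneous frequencies the copy mechanism lets marginals drift
  slightly toward upstream sites — accepted, since realized frequencies are
  what downstream code uses. A `template` argument reuses a panel's
  positions and frequencies with fresh haplotypes, giving an independent
  cohort genotyped on the same variants (the validation population).
* **Traits**: fixed covariate effects (birth year, contemporary group, age
  at joining) + planted causal effects + GRM-structured polygenic term +
  residual noise with exchangeable correlation 0.5 across the four traits.
  Genetic variance splits between planted causals (share `prop_h2_causal`,
  default 0.2) and polygenic background, each rescaled to its realized
  target so per-trait h2 matches the configuration. Traits are
  standardized; no implemented statistic depends on trait units. One trait
  is binarised at the 0.3 liability quantile (a ~70% pregnancy success
  rate, typical of the recorded herds). An `effects` argument plants exact
  per-allele effects for calibrated power experiments.
* **Expression**: negative-binomial counts whose log-mean combines a gene
  baseline, planted cis effects (within ±2 Mb of the TSS) and trans
  effects (>5 Mb, same chromosome), latent batch factors, Gaussian
  log-scale noise (SD 0.5), covariate effects and log-normal library-size
  variation. Planted effect sizes are in log units per allele; "an effect
  of 1.5 SD" in the validation suites means 1.5 × the log-scale noise SD.
  Dispersion is small (mean 0.05) so the Gaussian term dominates the
  residual, making planted effect sizes interpretable.

What it does **not** emulate: realistic demography or recombination maps,
rare-variant site frequency spectra, imputation error correlated with
frequency, read-level RNA-seq artefacts, or expression networks. Passing
tests therefore demonstrate the estimators' statistical correctness under
the assumed model, not robustness to everything real data can do.

# Numerical choices

* GRM eigenvalues are clipped at zero; a GRM is rejected if materially
  non-PSD. Monomorphic variants are excluded with a warning.
* The REML search runs on $h^2 \in [0, 0.9999]$ with the boundary checked
  explicitly; the reported log-likelihood includes its constants so it is
  directly comparable to a brute-force evaluation of the restricted
  likelihood (the suite requires 1e-6 agreement at n = 8).
* Monomorphic test variants yield a flagged record with beta 0 and p 1;
  variants conditioned on are flagged the same way (self-collinearity).
* V matrices that fail a positive-definiteness check are ridge-shrunk
  toward the identity in logged steps of at least 1e-6.
* All randomness flows from one integer seed; stage-level generators derive
  sub-streams as `seed + 1000003 * offset (mod 2^31 - 19)`.

# Validation-suite problem sizes

The calibration and recovery suites use sizes chosen to make the tested
property measurable at desk scale: null calibration at n = 1000 samples x
50,000 independent variants (genomic-control lambda in [0.95, 1.05], KS
agreement of the multi-trait statistic with chi-squared(4)); stepwise
recovery with three planted pleiotropic QTLs (marginal z about 4.5,
alternating signs against residual correlation 0.5) at n = 2000 over three
chromosomes; hierarchical-correction control with 200 null replicates of
500 genes x 200 cis variants at n = 200 via the fixed-effects path (no
relatedness is simulated there, and OLS is the exact sigma_g^2 = 0 limit of
the engine); planted-effect recovery at n = 489 over 20 replicates with the
mixed-model path; REML recovery with 50 replicates at n = 1000; and the
bundled demo at 500 samples, 5 x 2000 variants, 300 genes.

# Known limitations

* The dense GRM is always used; sparse-GRM thresholding (offered by some
  large-cohort tools) is not implemented, which matters only for n far
  beyond the target designs.
* Exact per-variant REML is intentionally not performed; with components
  held fixed, SEs at very small n are approximate.
* Conditionally independent secondary cis signals per gene, interaction
  eQTLs and colocalization posteriors are out of scope.
* Ortholog mapping between species is an input table, never inferred.
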