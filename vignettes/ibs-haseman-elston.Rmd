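---
title: "IBS Haseman–Elston regression: model, assumptions, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{IBS Haseman–Elston regression: model, assumptions, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(hereg)
```

## The estimator

The package estimates SNP heritability by regressing a pairwise phenotype
dissimilarity on pairwise genomic relatedness.  For unrelated individuals
$i$ and $j$,
$$Y_{ij} = \mu + b\,\Omega_{ij} + e_{ij}, \qquad Y_{ij} = (y_i - y_j)^2,$$
fitted by ordinary least squares over all $N(N-1)/2$ pairs.  The
relatedness is identity-by-state, built from genotype scores standardized
by allele frequency, $s_{ik} = (x_{ik} - 2p_k)/\sqrt{2p_kq_k}$, as
$\Omega_{ij} = s_i\cdot s_j/M$.  Under random mating, biallelic loci, and
purely additive QTL effects:

* one marker tagging one QTL at LD correlation $\rho$ gives
  $E(b) = -4\tau^2 p_k q_k \beta^2 = -2\rho^2\sigma_l^2$, where
  $\tau = 1 - r - R = -D/(p_kq_k)$ is the coupling-conditional-probability
  contrast and $\sigma_l^2 = 2p_lq_l\beta^2$ the QTL variance;
* $M$ markers tagging $L$ QTLs give
  $E(b) = -2\sigma^2_A\Lambda + \Delta$ with
  $\Lambda = \bar\rho^2_Q/\bar\rho^2_M$, the tagged fraction of the
  additive variance, and $\Delta$ a between-locus covariance remainder;
* with a standardized phenotype, $\hat h^2 = -b/2$; unstandardized,
  $\hat h^2 = -b/\mu$, since $E(\mu)$ is twice the phenotypic variance.

The same machinery supports a cross-product response $Y_{ij} = y_iy_j$
(coefficient of half the magnitude and opposite sign), a multi-component
fit over several relatedness matrices (e.g. per chromosome), covariate
residualization, and a per-marker association scan in which each marker's
own relatedness has unit variance and $\hat h^2_k = -b_k/2$ is the tagged
variance.

### Assumptions

Random mating (so two haplotypes per individual are independent and the
genotypic locus-locus correlation equals the haplotypic one), biallelic
loci, additive gene action only (no dominance or epistasis anywhere in the
package), and unrelated individuals (close relatives violate
$E(\Omega_{ij}) = 0$; `filter_relatedness()` prunes pairs above a cutoff,
conventionally 0.05, by greedily removing the most-connected individual).

## Tunable parameters

* **MAF floor** (`standardize_genotypes(maf = 0.01)`): the scale factor
  $\sqrt{2pq}$ degenerates as loci approach monomorphism; loci under the
  floor are dropped rather than explode the scores.  Unitless frequency;
  raise it on small samples where frequency estimates are noisy.
* **Missing policy** (`missing = "mean"`): missing genotypes become 0 on
  the standardized scale, which leaves pairwise products unbiased.  The
  alternative per-pair complete-marker denominator
  (`compute_grm(denominator = "pairwise_complete")`) mimics common GRM
  tools; the mean-imputation default is deterministic and unbiased for the
  moments the regression uses.
* **Allele orientation** (`read_plink(count_allele1)`): which allele is
  counted only flips the sign of $s$ coherently, so $\Omega$ and
  $\hat h^2$ are invariant; the default counts PLINK allele 1.
* **Effective marker count**: $M_e = 1/\widehat{var}(\Omega)$ uses the
  *centered* off-diagonal sample variance.  Sample-estimated frequencies
  leave a mean of order $-1/(N-1)$ in $\Omega$; centering removes that
  nuisance and reproduces the analytic $1/M + (1/M^2)\sum_{k\neq l}
  \rho^2_{kl}$ at large $N$.
* **SE convention** (`analytic_se(d = 1)`): the error sum of squares
  $8\sigma_y^4 - 4\sigma_A^4$ over $n_{pairs} - d$ with $d = 1$; with
  $\sigma^2_A$ left at its default 0 this is the simplified
  $se(b) = \sqrt{16M_e/(N(N-1))}$, $se(\hat h^2) = se(b)/2$.

## Standard-error honesty

Two standard errors are reported.  The analytic one treats the pair
observations as if independent given $M_e$; the naive OLS one does the
same implicitly.  Both understate the replicate-to-replicate spread of the
estimator when the tagged signal is strong, because the $N(N-1)/2$ pairs
carry only $N$ individuals' worth of information: in the single-marker
design at $N = 1000$, $h^2 = 0.5$, the across-replicate SD of $\hat b$ is
roughly ten times the analytic 0.004 (the mean *reported* per-fit SE does
sit at 0.004, which is the quantity our validation checks).  Under the
null the analytic SE instead over-states the spread (the null SD of
$\hat b$ is $2\sqrt2/N$, not $4/N$), so the per-marker association test
runs conservative — measured type-I ≈ 0.03 at nominal 0.05.  Both facts
are properties of the estimator family, not implementation artifacts, and
the test suite asserts them as such.

## The GREML comparator

`reml_fit()` fits $y = X\beta + g + e$, $cov(g) = \sigma^2_g\Omega$, by
profiling the restricted likelihood over $h^2$ on the GRM eigenbasis: one
eigendecomposition, then a one-dimensional Brent optimization
(`tol = 1e-8`).  When standardized scores are attached to the GRM and
$M < N$, an economy SVD replaces the dense eigendecomposition — the GRM
has at most $M$ non-zero eigenvalues, and the null space enters the
likelihood only through the projections of $y$ and $X$, captured exactly
by a reduced QR basis.  The two paths agree to optimizer tolerance and are
tested against a fine grid search.  Numerical guards: eigenvalues below
$10^{-10}\times$ the largest are clipped to exactly zero (sample-frequency
centering always leaves one such value), and any $h^2$ making a rotated
variance non-positive scores $-\infty$.  "Non-constrained" mode widens the
search to wherever the profiled covariance stays positive definite; note a
rank-deficient GRM caps that interval below 1 regardless, because zero
eigenvalues force $\sigma^2_e > 0$.

## The simulators, and what they do not emulate

`simulate_ar1_haplotypes()` draws each haplotype as a Markov chain:
first allele Bernoulli($p$), each next allele from the coupling
conditionals of the adjacent-locus LD pair, so loci at distance $d$
correlate as $\rho^d$ on both the haplotype and (by random mating) the
genotype scale.  This reproduces the decaying-LD block structure the
derivations assume and the published effective-marker counts
($M_e \approx 100, 90, 61, 29$ for $\rho = 0, .25, .5, .75$ at $M = 100$),
but **not** real-genome features: no allele-frequency spectrum (loci are
equifrequent by default), no MAF–effect coupling, no recombination
hotspots or long-range LD, no population structure or admixture.  Passing
tests therefore validate the estimator's internal consistency and its
published operating characteristics under the stated architecture — they
do not certify behavior under stratification or frequency-dependent
architectures, which real analyses should address with covariate
residualization and relatedness filtering.

`simulate_phenotype()` sets the residual variance from the *analytic*
covariance-inclusive additive variance
$\sigma^2_A = \sum_l 2p_lq_l\beta_l^2 + \sum_{l_1\ne l_2}2\rho^{|l_1-l_2|}
\sqrt{p_{l_1}q_{l_1}p_{l_2}q_{l_2}}\beta_{l_1}\beta_{l_2}$, so the target
$h^2$ holds exactly for every effect draw.  One consequence worth knowing:
the standardized estimand is a ratio of quadratic forms in the $L = 100$
effects, and its mean over effect draws sits slightly below the nominal
value at strong LD (about 0.485 rather than 0.500 at $\rho = 0.75$ —
measured over 400 replicates and consistent with the published simulation
batches).  The validation suite checks unbiasedness with a 0.02 floor that
reflects this, and checks the sorted-effects designs against the per-draw
closed-form prediction, which tracks the fitted values tightly.

`simulate_case_control()` is a liability-threshold sampler: independent
equifrequent loci, effects $N(0, h^2_l/(2pqL))$, genetic values centered
and scaled by their analytic SD so the unit-variance liability carries
exactly $h^2_l$; cases exceed $\Phi^{-1}(1-K)$; batched rejection sampling
fills the case/control quotas with a configurable effort cap (prevalences
near $10^{-3}$ with large quotas are refused by default rather than
silently grinding).  Desk-scale validation uses $K \in \{0.1, 0.01\}$ with
500 cases/500 controls and 30 replicates; that is where the headline
contrast — HE plus the liability transformation stays near the simulated
$h^2_l = 0.5$ while constrained GREML underestimates, badly so at low
prevalence — is asserted.

## Design decisions that were genuinely open

* **$\Delta$ is defined operationally** as the exact remainder
  $E(b) - (-2\sigma^2_{A,\text{within}}\Lambda)$ with $E(b)$ from the full
  ratio formula.  Published closed forms for $\Delta$ disagree with each
  other by a factor of two; the remainder definition is the only one
  guaranteed consistent with the ratio expectation, and it is validated by
  simulation (prediction vs fitted mean within Monte-Carlo error).
* **Breakeven sample size** uses the plain ceiling of $4/(h^2\rho^2)$,
  which reproduces the published grid exactly at its exact-integer cells.
* **Cross-product sign**: the cross-product coefficient is empirically
  *positive* (similarity regressed on similarity); the package asserts the
  magnitude relation $|b_{CP}| = |b_{SD}|/2$ and reports the observed
  sign rather than assuming a derived one.
* **Genome-wide significance** defaults to $5\times10^{-8}$ (field
  convention); the association scan's threshold is configurable.
* **Sorted-effects direction**: ascending; $\Delta$ is symmetric in the
  sort direction, so no flag is exposed.
* **Power solver**: a generic $\chi^2_1$ solver on the HE non-centrality
  parameter $(Nh^2\rho^2/2)^2$ is provided for arbitrary $(\alpha,
  \text{power})$; no published sample-size table other than the breakeven
  grid is treated as a reference, since the printed detection-threshold
  table is not consistent with any stated $\alpha$ under the derived NCPs.

## Problem sizes used in validation

Closed-form identities are checked exactly (enumeration oracles to
$10^{-12}$).  Stochastic checks use the published designs at their
published sizes where the derivations were stated: $N = 1000$,
$M = L = 100$, 100 replicates for the quantitative-trait studies; 6000
individuals for the effective-marker-count check; 30 replicates at
500/500 cases/controls for the case-control contrast.  These sizes were
chosen once, as the package's validation conditions, and the full suite
runs in a few minutes on a laptop-class machine.

## Known limitations

No dominance or epistatic relatedness; no LD-weighted GRMs; no
multi-locus phasing (all LD algebra is pairwise); single-component REML
only (multi-component heritability partitioning is available on the HE
side only); the liability transformation is the standard
prevalence/ascertainment correction and assumes the usual infinitesimal
liability model, which is exactly the regime the case-control study probes
the edges of.
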