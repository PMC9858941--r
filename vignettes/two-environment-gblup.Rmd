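---
title: "Comparing SNP effects and genomic breeding values between two environments"
author: "gxeblup"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing SNP effects and genomic breeding values between two environments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gxeblup)
```

## Scientific setting

Heat stress changes the physiology and the milk production of dairy cows.
The temperature–humidity index (THI),

$$\mathrm{THI} = (1.8\,t + 32) - (0.55 - 0.0055\,rh)(1.8\,t - 26),$$

with temperature $t$ in °C and relative humidity $rh$ in percent
(`compute_thi()`), summarises the thermal environment; values around 72 and
above are conventionally treated as the heat-stress zone. When a random
regression evaluation has produced breeding values for the same animals
*along* a THI gradient, the values at a comfort level and at a stress level
can be taken as two pseudo-phenotypes of the same animal and analysed as two
traits of a bivariate genomic model. The questions this package answers are
then:

* how similar are the per-SNP contributions to the additive variance in the
  two environments (top-k overlap, truncation-point quadrants)?
* do animals rerank between the environments when selected on direct
  genomic breeding values (Spearman correlations of the top fractions)?

## The model and its assumptions

With pseudo-phenotypes $y_1$, $y_2$ on the same genotyped animals,

$$\begin{pmatrix} y_1 \\ y_2\end{pmatrix} =
  \begin{pmatrix} \mathbf{1}\mu_1 \\ \mathbf{1}\mu_2 \end{pmatrix} +
  \begin{pmatrix} Z_1 & 0 \\ 0 & Z_2 \end{pmatrix}
  \begin{pmatrix} a_1 \\ a_2 \end{pmatrix} +
  \begin{pmatrix} e_1 \\ e_2 \end{pmatrix},
  \qquad a \sim N(0,\, G_0 \otimes G), \quad e \sim N(0,\, R_0 \otimes I).$$

Only the environment means are fixed effects: pseudo-phenotypes are already
adjusted breeding values, so no further systematic effects belong in the
model. $G$ is the VanRaden method 1 genomic relationship matrix,
$G = ZZ'/(2\sum_j p_j(1-p_j))$ with $Z = M - 2P$ the dosage matrix centered
at twice the allele frequencies. The frequencies used for centering and for
the denominator are the observed post-QC frequencies; base-population
frequencies are rarely available and the package does not try to infer
them. A ridge `blend_epsilon` (default $10^{-6}$) is added to the diagonal
so that $G$ is invertible for REML.

Assumptions worth keeping in mind:

* both environments are measured on the *same* genotyped animals (the REML
  step uses the animals with records in both environments; the BLUP step
  accepts any incidence pattern and predicts all animals in $G$);
* the residuals of the two environments are correlated within animal
  (estimated, not assumed zero), independent across animals;
* marker effects are implicitly infinitesimal — GBLUP shrinks every SNP, so
  per-SNP explained variances are comparative quantities, not significance
  tests. No significance testing of SNP effects is provided by design.

## Restricted maximum likelihood

`fit_greml()` estimates $G_0$ and $R_0$ (six free parameters; four when
`estimate_covariance = FALSE` fixes both covariances at zero, which makes
the bivariate fit decouple exactly into two single-trait fits). Numerically
it:

1. eigendecomposes $G = U D U'$ once and rotates the data by $U'$
   (the canonical transformation), after which the restricted likelihood,
   its gradient, the average-information matrix and the EM updates are sums
   of $2\times2$ computations over the $n$ eigen-blocks $V_m = d_m G_0 + R_0$
   — every iteration is $O(n)$;
2. proposes an average-information (AI) Newton step; candidates outside the
   positive-definite cone or that do not improve the restricted likelihood
   are step-halved, and if no AI candidate is accepted the
   expectation–maximization (EM) update is taken instead. EM ascent is
   guaranteed, so the log-likelihood trace is non-decreasing by
   construction (`loglik_trace` in the returned object, asserted in the
   test suite);
3. keeps iterates strictly inside the parameter space. Rejecting (rather
   than projecting) non-PD candidates matters: eigenvalue-clipping an
   overshooting AI step onto the boundary produces a singular $G_0$ from
   which the sandwich-form EM update $G_0 + G_0(\cdot)G_0/n$ cannot escape.
   Estimated matrices are still projected onto the PSD cone by eigenvalue
   clipping at $10^{-10}$ of the trace as a final safeguard;
4. starts from half the phenotypic (co)variance assigned to each of $G_0$
   and $R_0$ (with a slightly larger eigenvalue floor on the start so that
   degenerate inputs, e.g. identical phenotypes in both environments,
   begin strictly inside the cone);
5. declares convergence when the largest absolute change of any free
   parameter drops below `tol` (default $10^{-8}$); hitting `max_iter`
   (default 200) flags `converged = FALSE` instead of raising an error.

**Identifiability.** The genetic and residual covariances are separated
only through the spread of the eigenvalues of $G$. With linkage-equilibrium
markers that spread narrows as the marker/animal ratio grows, the restricted
likelihood develops a flat ridge along "more $G_0$ covariance, less $R_0$
covariance", and the maximum can sit at the genetic-correlation boundary
$|r_g| = 1$ even when the generating correlation was 0.9–0.95. This is a
property of the likelihood, not a defect of the optimizer: in validation
runs at 500 animals × 1000 markers the mean estimated correlation across
ten replicates is within 0.03 of the generating 0.9, but individual
replicates do reach 1.0. Downstream code therefore never inverts $G_0$
(next section).

## BLUP solutions

`solve_mme()` returns the solutions of Henderson's mixed-model equations,
computed through the equivalent generalized-least-squares form

$$\hat\mu = (X'V^{-1}X)^{-1}X'V^{-1}y, \qquad
  \hat a = \mathrm{Cov}(a, y)\,V^{-1}(y - X\hat\mu), \qquad
  V = Z (G_0 \otimes G) Z' + R.$$

For positive-definite components this is algebraically identical to solving
the MME, but it never forms $G_0^{-1}$ or $G^{-1}$, so a positive
*semi*-definite $G_0$ — a genetic correlation estimated at the $\pm1$
boundary — is handled exactly: the two environments' GEBVs simply become
proportional. Animals present in $G$ but without records still receive
GEBVs through their genomic relationships. An error is raised only when $V$
itself is singular (no genetic variance and a singular residual block).

## SNP effects and explained variance

`backsolve_snp_effects()` recovers per-environment marker effects from the
GEBVs,

$$\hat u = D Z'(Z D Z')^{-1}\hat a,$$

with $Z$ the *centered* dosage matrix — the same centering as the GRM, which
makes $ZDZ'$ proportional to the unblended $G$ and the back-solve consistent
with the model that produced $\hat a$. $D$ is a diagonal SNP-weight matrix,
identity by default; the package performs a single pass and no iterative
reweighting. Because centering at observed frequencies zeroes every column
sum, $ZZ'$ is always singular by one dimension; the `ridge` argument
(recommended: `G$scale * G$epsilon`, which reproduces the blended-G
factorization already used in the model) keeps the solve regular, and
without it the Moore–Penrose pseudoinverse is used and flagged
(`pseudo_inverse` attribute plus a warning).

`explained_variance()` computes per SNP $\hat\sigma^2_{u,i} = 2 p_i (1-p_i)
\hat u_i^2$ and expresses it as a percentage of the environment's *summed
per-SNP variance*, so percentages sum to 100 within each environment and are
directly comparable across environments. The REML additive variance would
be an alternative denominator; the summed-SNP convention was chosen because
it is self-contained (no dependence on the REML step) and scale-free.

## Comparing the environments

`top_k()` selects the $k$ (default 50) SNPs with the largest percentage per
environment; the truncation point $T$ is the percentage of the $k$-th SNP.
Every marker falls into one of four quadrants — above both truncation
points (`both`), above only one (`only_env1` / `only_env2`), or below both
(`neither`). Ties at the $k$-th value are broken deterministically by
(percentage descending, chromosome ascending, position ascending) with a
warning. `annotate_markers()` reports, for any marker subset, the containing
gene or the nearest gene within a window (default 600 kb, covering the
largest distances usually discussed for regulatory context); without strand
information "upstream" means before the interval start and "downstream"
after its end on the forward axis.

`compute_dbv()` reconstructs direct genomic breeding values $DBV = Z\hat u$
per environment — when $ZZ'$ is invertible these reproduce the GEBVs
exactly, and they can be computed for any new genotyped animal without
re-solving the model. `rank_correlations()` selects the top 10%, top 40%
and all animals by DBV in one environment, reports the Spearman correlation
with the other environment's DBVs in that selected set, and counts how many
selected animals the other environment would not retain. Selection is based
on environment 1 (the comfort zone) to answer "would the animals chosen in
comfort still be the best under stress?"; the symmetric environment-2-based
rows are also returned since the choice of basis is a convention.

## The synthetic-data generator

`sim_config()` / `simulate_genotypes()` / `simulate_pseudo_phenotypes()`
emulate the study design the pipeline targets:

* ~1000 genotyped cows (default 1013) typed on a mid-density chip, scaled
  down to 5000 autosomal SNPs over 29 chromosomes to keep simulation cheap;
* per-marker allele frequencies uniform on \[0.05, 0.50\], dosages in
  Hardy–Weinberg proportions, markers in linkage equilibrium, 1% of calls
  missing completely at random;
* per-marker effect pairs from a bivariate normal with correlation
  `genetic_corr` (default 0.95, a high between-environment correlation;
  exact rank-1 construction at $\pm1$), rescaled so the realised additive
  variance matches `env_variances` exactly;
* pseudo-phenotypes = mean + genetic value + independent Gaussian noise.
  The default means and total variances reproduce the milk-yield
  pseudo-phenotype scale (mean 1.13, SD 2.13 kg/day in comfort; 1.00 and
  2.01 under stress), split evenly between additive and residual variance —
  pseudo-phenotypes from a prior evaluation carry roughly reliability-0.5
  information for a cow population of this size.

What the generator does **not** emulate: linkage disequilibrium and chip
ascertainment, pedigree and family structure, selection, non-Gaussian or
heteroscedastic EBV errors, and informative missingness. Passing tests
therefore validate the estimation and comparison machinery under the
model's own assumptions; they do not certify behaviour on real cattle data,
where LD between markers and family structure change the effective
dimensionality of $G$.

Determinism: `simulate_genotypes()` seeds the RNG with `seed` and
`simulate_pseudo_phenotypes()` with `seed + 1`, so the effect and noise
draws never reuse the stream that produced the genotypes, and identical
configurations give identical data.

## Quality control conventions

`qc_genotypes()` applies, in order: animal call rate (< 0.90 removed,
boundary kept), then per marker — sex-chromosome removal, call rate < 0.90,
minor allele frequency < 0.02, and Hardy–Weinberg deviation
$|\,\hat{\mathrm{het}} - 2\hat p(1-\hat p)\,| > 0.15$. Each marker is
counted under the first rule that removes it. Three conventions are worth
stating because chip-QC phrasing is often ambiguous:

* *all* sex-chromosome markers are removed, not only low-call-rate ones —
  the standard GWAS convention;
* the HWE rule is an absolute deviation of observed heterozygosity from its
  expectation, the only scale on which 0.15 is a standard chip cutoff
  (not an exact test, by design);
* marker frequencies for MAF/HWE are computed on observed calls of the
  surviving animals, before imputation.

`impute_missing()` replaces missing dosages by the marker mean (2$\hat p$),
fractional on purpose: downstream algebra needs a numeric $M$, and rounding
would bias allele frequencies. Haplotype-based imputation is out of scope.

## Numerical choices and degenerate inputs

* GRM blending: $\varepsilon = 10^{-6}$ on the diagonal (configurable,
  0 allowed for exact algebra on full-rank toys).
* REML: `tol` $10^{-8}$ on parameter changes, `max_iter` 200, AI step
  halving up to 10 times, eigenvalue floor $10^{-10}$ of trace.
* Back-solve: ridge `G$scale * G$epsilon` recommended; pseudoinverse
  fallback flagged, never silent.
* Ties in top-k selection and in DBV ranking are broken by genome order and
  animal id respectively, so results are reproducible to the byte.
* Constant DBVs make Spearman correlations undefined; they are reported as
  `NA` with a warning rather than an error.
* All-missing markers, all-zero SNP effects, empty QC survivors and
  mismatched marker sets raise immediate, specific errors.

## Validation strategy and problem sizes

The test suite validates the pipeline against independent oracles rather
than against itself: a dense REML likelihood evaluated from the full
$2n \times 2n$ covariance (block computations must match it to $10^{-8}$,
and the fitted parameters must beat 200 random PSD draws of the surface); a
hand-assembled dense mixed-model system at $n = 5$; the exact
GBLUP–SNP-BLUP equivalence (ridge regression at $\lambda = 2\Sigma p(1-p)
\cdot \sigma^2_e/\sigma^2_a$) at 50 animals × 200 markers; the back-solve
round trip $Z\hat u = \hat a$ on full-rank instances; the classical
rank-difference Spearman formula; and exact enumeration of planted QC
fixtures. Statistical properties use fixed-seed replicates at sizes chosen
to keep the full suite under a minute of compute: variance-component
recovery at 500 animals × 1000 markers × 10 seeds (mean genetic correlation
within ±0.1 of the generating 0.9, components within ±15%), and top-50
overlap across generating correlations 0.2/0.6/0.9/1.0 (monotone in the
mean, with >80% overlap in at least 8 of 10 seeds at correlations ≥ 0.95 —
the qualitative signature of two environments that share most of their
genetic architecture).

One property is demonstrably unattainable at an arbitrary marker/animal
ratio: the rank coupling between |true effect| and estimated explained
variance. With more markers than animals the back-solve can only recover
the projection of the effect vector onto the row space of $Z$, and the
coupling plateaus near Spearman 0.3 regardless of heritability; the test
asserts it (>0.5) at 500 animals × 150 markers, where the effects are
individually estimable.

## Known limitations

* Two environments (traits) at most in the REML engine; the containers
  generalize, the likelihood code does not (by design — the comparison is
  pairwise).
* No pedigree information: blending is a diagonal ridge, not a pedigree
  $A$-matrix, and single-step evaluation is out of scope.
* Single-pass SNP back-solving ($D = I$); no iterative reweighting toward
  sparse architectures.
* Mean imputation only; with high missingness the shrinkage of imputed
  dosages toward $2p$ deflates relationships.
* The explained-variance percentage uses the summed-SNP denominator;
  analyses that need shares of the REML additive variance can rescale by
  `sum(var_env) / G0[j, j]`.
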