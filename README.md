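# gxeblup

Genotype-by-environment comparison of SNP effects and genomic breeding
values with bivariate GBLUP.

## The problem

Dairy cattle perform differently in heat-comfort and heat-stress
conditions, conventionally separated by a temperature–humidity index (THI)
threshold of 72, where

```
THI = (1.8 t + 32) − (0.55 − 0.0055 rh)(1.8 t − 26)
```

with `t` the air temperature (°C) and `rh` the relative humidity (%). A
practical question for selection programs is whether the *same* animals and
the *same* genome regions would be picked in both conditions. `gxeblup`
answers this by treating an animal's breeding values at two environmental
levels (for example THI 59, comfort, and THI 74, stress) as two traits of a
bivariate genomic model, and then comparing the per-SNP explained variance
and the reconstructed breeding values between the two environments.

The package is aimed at animal-breeding researchers who have allele-dosage
genotypes and per-animal pseudo-phenotypes (deregressed proofs or breeding
values from an earlier evaluation) for the same animals in two environments.
Because such data are usually proprietary, the package also ships a
synthetic-data module that generates genotypes and two-environment
pseudo-phenotypes with a controlled genetic correlation, so the entire
pipeline is testable and demonstrable without any download.

## The model

Pseudo-phenotypes `y1`, `y2` at the two levels follow the bi-trait GBLUP
model

```
[y1]   [1 mu1]   [Z1 0 ] [a1]   [e1]
[y2] = [1 mu2] + [0  Z2] [a2] + [e2]
```

with `a ~ N(0, G0 ⊗ G)` and `e ~ N(0, R0 ⊗ I)`, where `G0` and `R0` are the
2×2 additive and residual covariance matrices between the environments and
`G` is the VanRaden (method 1) genomic relationship matrix
`G = ZZ' / (2 Σ p(1−p))` built from column-centered dosages `Z = M − 2P`.
The package estimates `G0`, `R0` by restricted maximum likelihood (EM steps
with average-information acceleration), solves the mixed-model equations for
GEBVs, back-solves per-SNP effects

```
u = D M' (M D M')⁻¹ a      (D = I, single pass)
```

computes each SNP's explained additive variance `2 p (1−p) u²` (reported as
a percentage of the environment's summed SNP variance), selects the top-k
SNPs per environment with their truncation points `T` for the quadrant
dispersion plot, annotates markers against user-supplied gene intervals,
reconstructs direct genomic breeding values `DBV = M u`, and reports the
Spearman rank correlation of the top 10% / top 40% / all animals between the
environments together with how many selected animals are not retained when
the other environment does the ranking.

## Worked example

```r
library(gxeblup)
cfg <- sim_config(seed = 7)        # 1013 animals x 5000 SNPs, two THI levels
g   <- simulate_genotypes(cfg)
sim <- simulate_pseudo_phenotypes(g, cfg)

qc <- qc_genotypes(g)              # call rate, sex chromosomes, MAF, HWE
g  <- impute_missing(qc$genotypes)
p  <- allele_frequencies(g)
G  <- vanraden_g(g, p)

vc  <- fit_greml(sim$phenotypes, G, tol = 1e-6)
print(vc)
#> GREML fit: 1013 animals, 6 iteration(s), converged
#> additive covariance G0:
#>          THI59    THI74
#> THI59 2.413981 1.825479
#> THI74 1.825479 2.191754
#> residual covariance R0:
#>          THI59    THI74
#> THI59 2.178654 0.320673
#> THI74 0.320673 1.739939
#> genetic correlation: 0.7936
#> REML log-likelihood: -4164.151892

fit <- solve_mme(sim$phenotypes, G, vc)
eff <- explained_variance(
  backsolve_snp_effects(fit, g, p, ridge = G$scale * G$epsilon)
)
cmp <- top_k(eff, k = 50)
print(cmp)
#> top-50 SNP comparison (THI59 vs THI74)
#>   truncation points: 0.1713% / 0.163%
#>   SNPs in common: 34; in one environment only: 32

dbv <- compute_dbv(g, eff, p)
rc  <- rank_correlations(dbv)
subset(rc, basis == "env1")
#>  basis fraction n_selected spearman_rho n_not_retained
#>   env1      0.1        102    0.6844688             28
#>   env1      0.4        406    0.7415716             68
#>   env1      1.0       1013    0.9092144              0
```

Reading the output: the two environments share an estimated genetic
correlation of 0.79 in this replicate, 34 of the top-50 SNPs (by percentage
of explained additive variance) coincide, and ranking all 1013 animals on
their direct genomic breeding values in one environment agrees with the
other at Spearman rho 0.91 — but among the top 10% (102 animals) the
agreement drops to 0.68 and 28 of them would not be selected in the other
environment. Higher simulated genetic correlations move the overlap towards
50/50 and the correlations towards 1.

See `vignettes/two-environment-gblup.Rmd` for the model, algorithmic and
design details.

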