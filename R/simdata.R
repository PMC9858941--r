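#' Configuration for the synthetic two-environment data generator
#'
#' Bundles and validates the parameters of the genotype and pseudo-phenotype
#' simulator. The defaults emulate the kind of data the pipeline was designed
#' for: roughly one thousand genotyped dairy cows whose estimated breeding
#' values at two temperature-humidity-index (THI) levels serve as
#' pseudo-phenotypes of a bi-trait model. Trait means and total variances
#' default to the milk-yield pseudo-phenotype scale (mean 1.13, SD 2.13
#' kg/day in the comfort environment; mean 1.00, SD 2.01 in the stress
#' environment), split evenly between additive and residual variance. The
#' marker panel is scaled down from a 50k chip to keep simulation cheap;
#' markers are in linkage equilibrium.
#'
#' @param n_animals number of genotyped animals (>= 2).
#' @param n_markers number of autosomal SNPs (>= 1).
#' @param n_chromosomes number of chromosomes markers are assigned to,
#'   round-robin (default 29, the bovine autosomes).
#' @param maf_low,maf_high bounds of the uniform distribution the per-marker
#'   allele frequency of the counted allele is drawn from; both in (0, 0.5].
#' @param missing_rate fraction of calls set to missing, completely at
#'   random; in \[0, 1).
#' @param genetic_corr correlation between the two environments' true marker
#'   effects, in \[-1, 1\].
#' @param env_variances length-2 vector of additive-genetic variance targets
#'   per environment (trait units squared).
#' @param noise_variances length-2 vector of residual variance targets.
#' @param trait_mean length-2 vector of environment means.
#' @param trait trait label written to phenotype tables (default `"MY"`,
#'   milk yield).
#' @param envs length-2 character vector of environment labels
#'   (default `c("THI59", "THI74")`).
#' @param seed integer seed; identical configurations give identical data.
#' @return an object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(n_animals = 100, n_markers = 500, seed = 42)
#' g <- simulate_genotypes(cfg)
#' @export
sim_config <- function(n_animals = 1013,
                       n_markers = 5000,
                       n_chromosomes = 29,
                       maf_low = 0.05,
                       maf_high = 0.50,
                       missing_rate = 0.01,
                       genetic_corr = 0.95,
                       env_variances = c(2.13, 2.01)^2 / 2,
                       noise_variances = c(2.13, 2.01)^2 / 2,
                       trait_mean = c(1.13, 1.00),
                       trait = "MY",
                       envs = c("THI59", "THI74"),
                       seed = 1L) {
  stopifnot(
    length(n_animals) == 1, n_animals >= 2,
    length(n_markers) == 1, n_markers >= 1,
    length(n_chromosomes) == 1, n_chromosomes >= 1
  )
  if (!(maf_low > 0 && maf_high <= 0.5 && maf_low <= maf_high)) {
    stop("need 0 < maf_low <= maf_high <= 0.5", call. = FALSE)
  }
  if (!(missing_rate >= 0 && missing_rate < 1)) {
    stop("missing_rate must lie in [0, 1)", call. = FALSE)
  }
  if (abs(genetic_corr) > 1) {
    stop("genetic_corr must lie in [-1, 1]", call. = FALSE)
  }
  if (length(env_variances) != 2 || any(env_variances < 0) ||
      length(noise_variances) != 2 || any(noise_variances < 0)) {
    stop("env_variances and noise_variances must be length-2, >= 0",
         call. = FALSE)
  }
  if (length(trait_mean) != 2) stop("trait_mean must be length 2", call. = FALSE)
  if (length(envs) != 2 || anyDuplicated(envs)) {
    stop("envs must be two distinct labels", call. = FALSE)
  }
  structure(list(
    n_animals = as.integer(n_animals),
    n_markers = as.integer(n_markers),
    n_chromosomes = as.integer(n_chromosomes),
    maf_low = maf_low, maf_high = maf_high,
    missing_rate = missing_rate,
    genetic_corr = genetic_corr,
    env_variances = as.numeric(env_variances),
    noise_variances = as.numeric(noise_variances),
    trait_mean = as.numeric(trait_mean),
    trait = as.character(trait),
    envs = as.character(envs),
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Simulate an allele-dosage genotype matrix
#'
#' Draws, for each marker, an allele frequency p ~ Uniform(maf_low, maf_high)
#' and dosages Binomial(2, p) per animal (Hardy-Weinberg proportions, linkage
#' equilibrium). Missing calls are inserted completely at random at
#' `missing_rate`. Markers are assigned round-robin to chromosomes
#' `"1" ... "n_chromosomes"` with strictly increasing positions at a fixed
#' 50 kb stride within each chromosome.
#'
#' @param cfg a [sim_config()].
#' @return a [geno_matrix()] with attribute `"allele_freq_true"` holding the
#'   generating allele frequencies.
#' @export
simulate_genotypes <- function(cfg) {
  if (!inherits(cfg, "sim_config")) stop("`cfg` must be a sim_config", call. = FALSE)
  set.seed(cfg$seed)
  n <- cfg$n_animals
  m <- cfg$n_markers
  p <- runif(m, cfg$maf_low, cfg$maf_high)
  d <- matrix(rbinom(n * m, 2L, rep(p, each = n)), nrow = n, ncol = m)
  if (cfg$missing_rate > 0) {
    d[runif(n * m) < cfg$missing_rate] <- NA_integer_
  }
  mode(d) <- "numeric"
  rownames(d) <- sprintf("A%04d", seq_len(n))
  colnames(d) <- sprintf("SNP%06d", seq_len(m))
  chrom_idx <- ((seq_len(m) - 1L) %% cfg$n_chromosomes) + 1L
  within_idx <- ((seq_len(m) - 1L) %/% cfg$n_chromosomes) + 1L
  map <- data.frame(
    marker_id = colnames(d),
    chrom = as.character(chrom_idx),
    pos = within_idx * 50000,
    stringsAsFactors = FALSE
  )
  g <- geno_matrix(d, map)
  attr(g, "allele_freq_true") <- p
  g
}

#' Simulate two-environment pseudo-phenotypes and true marker effects
#'
#' Draws one pair of marker effects per SNP from a bivariate normal with
#' correlation `genetic_corr` (exact rank-1 construction when the correlation
#' is +/-1), rescales each environment's effect vector so the realised
#' additive variance (sample variance of centered-genotype times effects)
#' equals `env_variances`, and returns pseudo-phenotypes
#' `trait_mean + genetic value + Gaussian noise` with independent residuals of
#' variance `noise_variances`. Missing dosages are mean-imputed internally
#' before computing genetic values; the returned genotypes are untouched.
#'
#' The RNG is seeded with `cfg$seed + 1` so effect and noise draws do not
#' reuse the stream that generated the genotypes.
#'
#' @param g a [geno_matrix()], typically from [simulate_genotypes()].
#' @param cfg the [sim_config()] used to generate `g` (or compatible).
#' @return list with elements
#'   * `phenotypes`: data.frame `animal_id`, `trait`, `env`, `value` (long
#'     format, one row per animal and environment);
#'   * `true_effects`: data.frame `marker_id`, `u_env1`, `u_env2` of the
#'     generating per-allele effects (trait units per allele copy);
#'   * `genetic_values`: animals x 2 matrix of simulated breeding values.
#' @export
simulate_pseudo_phenotypes <- function(g, cfg) {
  stopifnot_geno(g)
  if (!inherits(cfg, "sim_config")) stop("`cfg` must be a sim_config", call. = FALSE)
  d <- g$dosages
  if (any(colSums(!is.na(d)) == 0)) {
    stop("genotype matrix has all-missing markers", call. = FALSE)
  }
  set.seed(cfg$seed + 1L)
  n <- nrow(d)
  m <- ncol(d)
  rg <- cfg$genetic_corr

  # raw effect pairs with the requested correlation
  if (abs(rg) == 1) {
    u1 <- rnorm(m)
    u <- cbind(u1, sign(rg) * u1)
  } else {
    z1 <- rnorm(m)
    z2 <- rnorm(m)
    u <- cbind(z1, rg * z1 + sqrt(1 - rg^2) * z2)
  }

  # center dosages on observed frequencies (mean-impute missing)
  p_obs <- colSums(d, na.rm = TRUE) / (2 * colSums(!is.na(d)))
  dimp <- d
  if (anyNA(dimp)) {
    na_idx <- which(is.na(dimp), arr.ind = TRUE)
    dimp[na_idx] <- (2 * p_obs)[na_idx[, 2]]
  }
  zc <- sweep(dimp, 2, 2 * p_obs, "-")

  gv <- zc %*% u
  for (j in 1:2) {
    target <- cfg$env_variances[j]
    if (target == 0) {
      u[, j] <- 0
      gv[, j] <- 0
    } else {
      s <- sd(gv[, j])
      if (s == 0) {
        stop("cannot scale genetic values: zero variance (monomorphic panel?)",
             call. = FALSE)
      }
      u[, j] <- u[, j] * sqrt(target) / s
      gv[, j] <- gv[, j] * sqrt(target) / s
    }
  }

  noise <- cbind(rnorm(n, 0, sqrt(cfg$noise_variances[1])),
                 rnorm(n, 0, sqrt(cfg$noise_variances[2])))
  y <- sweep(gv + noise, 2, cfg$trait_mean, "+")

  phen <- data.frame(
    animal_id = rep(rownames(d), 2),
    trait = cfg$trait,
    env = rep(cfg$envs, each = n),
    value = c(y[, 1], y[, 2]),
    stringsAsFactors = FALSE
  )
  eff <- data.frame(
    marker_id = colnames(d),
    u_env1 = u[, 1],
    u_env2 = u[, 2],
    stringsAsFactors = FALSE
  )
  colnames(gv) <- cfg$envs
  list(phenotypes = phen, true_effects = eff, genetic_values = gv)
}
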