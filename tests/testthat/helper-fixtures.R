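# shared fixtures and independent oracles, all built in code

# wrap a plain dosage matrix into a geno_matrix with generated ids/map
toy_geno <- function(d, chrom = NULL, pos = NULL) {
  n <- nrow(d)
  m <- ncol(d)
  rownames(d) <- sprintf("A%03d", seq_len(n))
  colnames(d) <- sprintf("M%03d", seq_len(m))
  if (is.null(chrom)) chrom <- rep("1", m)
  if (is.null(pos)) pos <- seq_len(m) * 1000
  geno_matrix(d, data.frame(marker_id = colnames(d), chrom = chrom, pos = pos,
                            stringsAsFactors = FALSE))
}

# 5 animals x 10 markers with exactly one planted violation per QC rule:
# animal A3 at 80% call rate; M1 on X; M2 below marker call rate (after A3
# is gone); M3 monomorphic (MAF 0); M4 all heterozygous (HWE deviation 0.5);
# M5-M10 clean with dosages (0,1,1,2) among survivors.
qc_fixture <- function() {
  clean <- c(0, 1, 1, 1, 2) # rows A1,A2,A3,A4,A5
  d <- cbind(
    M01 = clean,                   # sex chromosome
    M02 = c(NA, 1, 0, 1, 2),       # marker call rate 3/4 after A3 removed
    M03 = c(0, 0, 0, 0, 0),        # MAF 0
    M04 = c(1, 1, 1, 1, 1),        # HWE deviation |1 - 0.5| = 0.5
    M05 = c(0, 1, NA, 1, 2),       # A3 missing here (animal call-rate plant)
    M06 = c(0, 1, NA, 1, 2),       # and here
    M07 = clean, M08 = clean, M09 = clean, M10 = clean
  )
  rownames(d) <- paste0("A", 1:5)
  map <- data.frame(
    marker_id = colnames(d),
    chrom = c("X", rep("1", 9)),
    pos = seq_len(10) * 1000,
    stringsAsFactors = FALSE
  )
  geno_matrix(d, map)
}

# simulate a full small dataset ready for the genomic model; markers that
# come out monomorphic at small n are dropped before the phenotypes are built
sim_dataset <- function(n = 100, m = 400, rg = 0.9, h2_split = c(1, 1),
                        noise = c(1, 1), seed = 1, missing_rate = 0,
                        blend = 1e-6, use_true_p = FALSE) {
  cfg <- sim_config(n_animals = n, n_markers = m, missing_rate = missing_rate,
                    genetic_corr = rg, env_variances = h2_split,
                    noise_variances = noise, trait_mean = c(0, 0), seed = seed)
  g <- simulate_genotypes(cfg)
  p_true <- attr(g, "allele_freq_true")
  if (!use_true_p) {
    p_obs <- allele_frequencies(g)
    keep <- which(p_obs > 0 & p_obs < 1)
    if (length(keep) < ncol(g$dosages)) {
      g <- subset_geno_test(g, keep)
      p_true <- p_true[keep]
    }
  }
  sim <- simulate_pseudo_phenotypes(g, cfg)
  if (missing_rate > 0) g <- impute_missing(g)
  p <- if (use_true_p) p_true else allele_frequencies(g)
  G <- vanraden_g(g, p, blend_epsilon = blend)
  list(cfg = cfg, g = g, sim = sim, p = p, G = G)
}

# marker subset of a geno_matrix (test-side helper)
subset_geno_test <- function(g, markers) {
  map <- g$map[markers, , drop = FALSE]
  rownames(map) <- NULL
  geno_matrix(g$dosages[, markers, drop = FALSE], map)
}

# independent dense REML log-likelihood for the bi-trait model with trait
# means as the only fixed effects (same constant convention as the package)
dense_reml_loglik <- function(G0, R0, Gmat, Y) {
  n <- nrow(Y)
  t_n <- ncol(Y)
  V <- kronecker(G0, Gmat) + kronecker(R0, diag(n))
  X <- kronecker(diag(t_n), rep(1, n))
  y <- c(Y)
  Vi <- solve(V)
  C <- t(X) %*% Vi %*% X
  b <- solve(C, t(X) %*% Vi %*% y)
  r <- y - X %*% b
  as.numeric(-0.5 * (determinant(V)$modulus + determinant(C)$modulus +
                       t(r) %*% Vi %*% r + (n * t_n - t_n) * log(2 * pi)))
}

# independent single-trait ridge solve (SNP-BLUP with a fitted mean):
# [ n      1'Z          ] [mu  ]   [1'y ]
# [ Z'1    Z'Z + lambda ] [beta] = [Z'y ]
ridge_oracle <- function(Z, y, lambda) {
  n <- nrow(Z)
  m <- ncol(Z)
  A <- rbind(
    c(n, colSums(Z)),
    cbind(rowSums(t(Z)), crossprod(Z) + lambda * diag(m))
  )
  b <- c(sum(y), as.numeric(crossprod(Z, y)))
  sol <- unname(solve(A, b))
  list(mu = sol[1], beta = sol[-1], pred = as.numeric(Z %*% sol[-1]))
}

# Spearman rho from the classical rank-difference formula (no ties)
spearman_bruteforce <- function(x, y) {
  stopifnot(!anyDuplicated(x), !anyDuplicated(y))
  d <- rank(x) - rank(y)
  n <- length(x)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

# fabricate a snp_effect_table with given percentage columns (for the
# comparison operations, which only consume marker columns + percentages)
fake_effect_table <- function(pct1, pct2, chrom = NULL, pos = NULL) {
  m <- length(pct1)
  if (is.null(chrom)) chrom <- rep("1", m)
  if (is.null(pos)) pos <- seq_len(m) * 1000
  out <- data.frame(
    marker_id = sprintf("M%03d", seq_len(m)),
    chrom = chrom, pos = pos,
    u_env1 = sqrt(pct1), u_env2 = sqrt(pct2),
    var_env1 = pct1, var_env2 = pct2,
    pct_env1 = 100 * pct1 / sum(pct1),
    pct_env2 = 100 * pct2 / sum(pct2),
    stringsAsFactors = FALSE
  )
  attr(out, "envs") <- c("THI59", "THI74")
  attr(out, "allele_freq") <- rep(0.5, m)
  class(out) <- c("snp_effect_table", "data.frame")
  out
}
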