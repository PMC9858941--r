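make_backsolve_instance <- function(n = 40, m = 120, seed = 5) {
  ds <- sim_dataset(n = n, m = m, rg = 0.7, seed = seed, use_true_p = TRUE,
                    blend = 0)
  envs <- sort(unique(ds$sim$phenotypes$env))
  vc <- list(G0 = diag(2), R0 = diag(2), envs = envs)
  fit <- solve_mme(ds$sim$phenotypes, ds$G, vc)
  list(ds = ds, fit = fit)
}

test_that("back-solved effects reproduce the GEBVs they came from", {
  inst <- make_backsolve_instance()
  ds <- inst$ds
  eff <- backsolve_snp_effects(inst$fit, ds$g, ds$p)
  Z <- sweep(ds$g$dosages, 2, 2 * ds$p)
  u <- cbind(eff$u_env1, eff$u_env2)
  expect_lt(max(abs(Z %*% u - inst$fit$gebv_matrix)), 1e-8)
  expect_false(attr(eff, "pseudo_inverse"))
})

test_that("back-solving is linear in the breeding values", {
  inst <- make_backsolve_instance(seed = 6)
  ds <- inst$ds
  eff1 <- backsolve_snp_effects(inst$fit, ds$g, ds$p)
  gebv2 <- inst$fit$gebv
  gebv2$gebv <- 3 * gebv2$gebv
  eff3 <- backsolve_snp_effects(gebv2, ds$g, ds$p)
  expect_equal(eff3$u_env1, 3 * eff1$u_env1, tolerance = 1e-10)
  expect_equal(eff3$u_env2, 3 * eff1$u_env2, tolerance = 1e-10)
  # zero breeding values give zero effects
  gebv0 <- inst$fit$gebv
  gebv0$gebv <- 0
  eff0 <- backsolve_snp_effects(gebv0, ds$g, ds$p)
  expect_true(all(eff0$u_env1 == 0) && all(eff0$u_env2 == 0))
})

test_that("permuting markers permutes effects identically", {
  inst <- make_backsolve_instance(seed = 7)
  ds <- inst$ds
  eff <- backsolve_snp_effects(inst$fit, ds$g, ds$p)
  set.seed(1)
  perm <- sample(ncol(ds$g$dosages))
  g_perm <- geno_matrix(ds$g$dosages[, perm],
                        ds$g$map[perm, c("marker_id", "chrom", "pos")])
  eff_perm <- backsolve_snp_effects(inst$fit, g_perm, ds$p[perm])
  expect_equal(eff_perm$u_env1, eff$u_env1[perm], tolerance = 1e-10)
  expect_equal(eff_perm$marker_id, eff$marker_id[perm])
})

test_that("effects lie in the row space of the centered genotype matrix", {
  inst <- make_backsolve_instance(seed = 8)
  ds <- inst$ds
  eff <- backsolve_snp_effects(inst$fit, ds$g, ds$p)
  Z <- sweep(ds$g$dosages, 2, 2 * ds$p)
  u <- cbind(eff$u_env1, eff$u_env2)
  proj <- crossprod(Z, solve(tcrossprod(Z), Z %*% u))
  expect_lt(max(abs(u - proj)), 1e-8)
})

test_that("effects equal the direct SNP-BLUP ridge solution", {
  inst <- make_backsolve_instance(seed = 9)
  ds <- inst$ds
  eff <- backsolve_snp_effects(inst$fit, ds$g, ds$p)
  Z <- sweep(ds$g$dosages, 2, 2 * ds$p)
  Y <- matrix(ds$sim$phenotypes$value, ncol = 2)
  for (j in 1:2) {
    or <- ridge_oracle(Z, Y[, j], ds$G$scale)
    expect_lt(max(abs(or$beta - eff[[paste0("u_env", j)]])), 1e-6)
  }
})

test_that("a singular ZDZ' falls back to the pseudoinverse with a flag", {
  # observed-frequency centering zeroes column sums, making ZZ' rank-deficient
  ds <- sim_dataset(n = 25, m = 100, seed = 10, blend = 1e-6)
  envs <- sort(unique(ds$sim$phenotypes$env))
  fit <- solve_mme(ds$sim$phenotypes, ds$G,
                   list(G0 = diag(2), R0 = diag(2), envs = envs))
  expect_warning(eff <- backsolve_snp_effects(fit, ds$g, ds$p),
                 "pseudoinverse")
  expect_true(attr(eff, "pseudo_inverse"))
  # the blended-factorization route stays regular
  eff_r <- backsolve_snp_effects(fit, ds$g, ds$p,
                                 ridge = ds$G$scale * ds$G$epsilon)
  expect_false(attr(eff_r, "pseudo_inverse"))
})

test_that("explained variance follows 2p(1-p)u^2 and normalizes to 100%", {
  inst <- make_backsolve_instance(seed = 11)
  ds <- inst$ds
  eff <- backsolve_snp_effects(inst$fit, ds$g, ds$p)
  eff <- explained_variance(eff)
  expect_equal(eff$var_env1, 2 * ds$p * (1 - ds$p) * eff$u_env1^2,
               ignore_attr = TRUE)
  expect_true(all(eff$var_env1 >= 0) && all(eff$var_env2 >= 0))
  expect_equal(sum(eff$pct_env1), 100, tolerance = 1e-8)
  expect_equal(sum(eff$pct_env2), 100, tolerance = 1e-8)
  # hand value: p = 0.5, u = 1 gives 2 * 0.5 * 0.5 * 1 = 0.5
  eff$u_env1[1] <- 1
  v <- explained_variance(eff, p = rep(0.5, nrow(eff)))
  expect_equal(v$var_env1[1], 0.5)
})

test_that("all-zero effects make percentages undefined", {
  inst <- make_backsolve_instance(seed = 12)
  gebv0 <- inst$fit$gebv
  gebv0$gebv <- 0
  eff0 <- backsolve_snp_effects(gebv0, inst$ds$g, inst$ds$p)
  expect_error(explained_variance(eff0), "undefined")
})

test_that("markers with larger true effects explain more variance", {
  # needs more animals than markers: with m > n the back-solve can only
  # recover the projection of the effect vector onto the row space of Z and
  # per-marker estimates are too mixed for a strong rank coupling
  ds <- sim_dataset(n = 500, m = 150, rg = 0.9, noise = c(0.5, 0.5),
                    seed = 13)
  envs <- sort(unique(ds$sim$phenotypes$env))
  fit <- solve_mme(ds$sim$phenotypes, ds$G,
                   list(G0 = matrix(c(1, .9, .9, 1), 2), R0 = diag(0.5, 2),
                        envs = envs))
  eff <- backsolve_snp_effects(fit, ds$g, ds$p,
                               ridge = ds$G$scale * ds$G$epsilon)
  eff <- explained_variance(eff)
  rho <- cor(abs(ds$sim$true_effects$u_env1), eff$var_env1,
             method = "spearman")
  expect_gt(rho, 0.5)
})

test_that("dimension mismatches are rejected", {
  inst <- make_backsolve_instance(seed = 14)
  ds <- inst$ds
  g_small <- subset_geno_test(ds$g, 1:10)
  expect_error(backsolve_snp_effects(inst$fit, g_small, ds$p), "frequency per marker")
  bad_gebv <- inst$fit$gebv[inst$fit$gebv$animal_id != "A0001", ]
  expect_error(backsolve_snp_effects(bad_gebv, ds$g, ds$p), "missing for")
})
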