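test_that("top-k comparison matches hand enumeration on a 5-marker toy", {
  eff <- fake_effect_table(pct1 = c(5, 4, 3, 2, 1), pct2 = c(1, 2, 3, 4, 5))
  cmp <- top_k(eff, k = 2)
  # pct columns are renormalized to sum to 100: 5/15*100 etc.
  expect_equal(cmp$T_env1, 4 / 15 * 100)
  expect_equal(cmp$T_env2, 4 / 15 * 100)
  expect_equal(cmp$n_common, 0)
  expect_equal(cmp$n_different, 4)
  expect_equal(sum(cmp$quadrants$quadrant == "only_env1"), 2)
  expect_equal(sum(cmp$quadrants$quadrant == "only_env2"), 2)
  expect_equal(sum(cmp$quadrants$quadrant == "neither"), 1)
})

test_that("identical percentage columns give complete overlap", {
  pct <- c(10, 8, 6, 4, 2, 1, 1, 1)
  eff <- fake_effect_table(pct, pct)
  cmp <- suppressWarnings(top_k(eff, k = 3))
  expect_equal(cmp$n_common, 3)
  expect_equal(cmp$n_different, 0)
  expect_true(all(cmp$quadrants$quadrant %in% c("both", "neither")))
})

test_that("k equal to the table size marks every marker as shared", {
  eff <- fake_effect_table(c(3, 2, 1), c(1, 2, 3))
  cmp <- top_k(eff, k = 3)
  expect_equal(cmp$n_common, 3)
  expect_equal(cmp$T_env1, min(eff$pct_env1))
  expect_error(top_k(eff, k = 4), "between 1 and")
})

test_that("ties at the k-th value warn and break deterministically", {
  eff <- fake_effect_table(c(4, 3, 3, 1), c(4, 3, 2.5, 1))
  expect_warning(cmp <- top_k(eff, k = 2), "ties")
  # chromosome/position order decides: marker M002 (earlier position) enters
  expect_equal(cmp$quadrants$quadrant[2], "both")
  expect_equal(cmp$quadrants$quadrant[3], "neither")
})

test_that("top set sizes and quadrant labels are mutually consistent", {
  set.seed(33)
  eff <- fake_effect_table(rexp(200), rexp(200),
                           chrom = as.character(rep(1:5, 40)),
                           pos = rep(1:40 * 1e5, each = 5))
  k <- 50
  cmp <- top_k(eff, k)
  only1 <- sum(cmp$quadrants$quadrant == "only_env1")
  only2 <- sum(cmp$quadrants$quadrant == "only_env2")
  expect_equal(cmp$n_common + only1, k)
  expect_equal(cmp$n_common + only2, k)
  expect_equal(only1, only2)
  expect_equal(cmp$n_different, only1 + only2)
  # per-chromosome summary covers exactly k SNPs per environment
  for (e in cmp$envs) {
    sub <- cmp$per_chromosome[cmp$per_chromosome$env == e, ]
    expect_equal(sum(sub$n_top_snps), k)
  }
  # quadrant labels agree with the truncation thresholds
  q <- cmp$quadrants
  expect_true(all(q$pct_env1[q$quadrant == "both"] >= cmp$T_env1))
  expect_true(all(q$pct_env2[q$quadrant == "both"] >= cmp$T_env2))
  expect_true(all(q$pct_env2[q$quadrant == "only_env1"] < cmp$T_env2))
  expect_true(all(q$pct_env1[q$quadrant == "only_env2"] < cmp$T_env1))
})

test_that("marker annotation handles within, near and distant genes", {
  genes <- data.frame(
    gene = c("GA", "GB"), chrom = c("1", "1"),
    start = c(500000, 2000000), end = c(600000, 2100000),
    stringsAsFactors = FALSE
  )
  markers <- data.frame(
    marker_id = c("S1", "S2", "S3", "S4", "S5"),
    chrom = c("1", "1", "1", "1", "2"),
    pos = c(550000, 400000, 2150000, 1500000, 550000),
    stringsAsFactors = FALSE
  )
  ann <- annotate_markers(markers, genes, window = 600000)
  expect_equal(ann$gene, c("GA", "GA", "GB", "GB", NA))
  expect_equal(ann$relation, c("within", "upstream", "downstream",
                               "upstream", "none"))
  expect_equal(ann$distance_bp, c(0, 100000, 50000, 500000, NA))
  expect_equal(ann$annotation[1:4],
               c("within", "100 kb upstream", "50 kb downstream",
                 "500 kb upstream"))
  # S4 is 500 kb before GB's start: outside a 400 kb window in a stricter run
  ann2 <- annotate_markers(markers, genes, window = 400000)
  expect_equal(ann2$annotation[4], "unannotated")
})

test_that("DBVs are the centered-genotype by effect product", {
  d <- rbind(c(2, 1), c(0, 2))
  g <- toy_geno(d)
  p <- c(0.5, 0.375)
  eff <- fake_effect_table(c(1, 1), c(1, 1))[1:2, ]
  eff$marker_id <- colnames(g$dosages)
  eff$u_env1 <- c(0.5, 0.25)
  eff$u_env2 <- c(0, 1)
  attr(eff, "allele_freq") <- p
  class(eff) <- c("snp_effect_table", "data.frame")
  dbv <- compute_dbv(g, eff, p)
  Z <- sweep(d, 2, 2 * p)
  expect_equal(dbv$dbv_env1, as.numeric(Z %*% c(0.5, 0.25)))
  expect_equal(dbv$dbv_env2, as.numeric(Z %*% c(0, 1)))
  # zero effects give zero DBVs
  eff$u_env1 <- 0; eff$u_env2 <- 0
  dbv0 <- compute_dbv(g, eff, p)
  expect_true(all(dbv0$dbv_env1 == 0) && all(dbv0$dbv_env2 == 0))
})

test_that("mismatched marker sets are reported with the difference", {
  ds <- sim_dataset(n = 20, m = 30, seed = 3)
  envs <- sort(unique(ds$sim$phenotypes$env))
  fit <- solve_mme(ds$sim$phenotypes, ds$G,
                   list(G0 = diag(2), R0 = diag(2), envs = envs))
  eff <- backsolve_snp_effects(fit, ds$g, ds$p,
                               ridge = ds$G$scale * ds$G$epsilon)
  g_sub <- subset_geno_test(ds$g, 1:20)
  expect_error(compute_dbv(g_sub, eff, ds$p[1:20]), "marker sets differ")
})

test_that("rank correlations are exact on degenerate and hand-built cases", {
  set.seed(8)
  v <- rnorm(40)
  dbv_same <- structure(
    data.frame(animal_id = sprintf("A%02d", 1:40),
               dbv_env1 = v, dbv_env2 = v),
    envs = c("THI59", "THI74"), class = c("dbv_table", "data.frame")
  )
  rc <- rank_correlations(dbv_same)
  expect_equal(rc$spearman_rho, rep(1, 6))
  expect_true(all(rc$n_not_retained == 0))
  expect_equal(rc$n_selected[rc$basis == "env1"], c(4, 16, 40))

  dbv_rev <- dbv_same
  dbv_rev$dbv_env2 <- -v
  rc_rev <- rank_correlations(dbv_rev, fractions = 1.0)
  expect_equal(rc_rev$spearman_rho, rep(-1, 2))

  # 10-animal toy against the classical rank-difference formula
  x <- c(9.1, 7.4, 6.2, 5.9, 5.1, 4.4, 3.0, 2.5, 1.9, 0.3)
  y <- c(8.0, 8.8, 5.0, 6.6, 3.9, 5.6, 2.8, 3.1, 0.9, 1.5)
  dbv_toy <- structure(
    data.frame(animal_id = sprintf("T%02d", 1:10), dbv_env1 = x, dbv_env2 = y),
    envs = c("E1", "E2"), class = c("dbv_table", "data.frame")
  )
  rc_toy <- rank_correlations(dbv_toy, fractions = 1.0)
  expect_equal(rc_toy$spearman_rho[1], spearman_bruteforce(x, y))
})

test_that("constant DBVs flag an undefined correlation instead of failing", {
  dbv <- structure(
    data.frame(animal_id = sprintf("A%02d", 1:12),
               dbv_env1 = rep(1, 12), dbv_env2 = rnorm(12)),
    envs = c("E1", "E2"), class = c("dbv_table", "data.frame")
  )
  # both selection bases hit the constant vector, so two warnings surface
  expect_warning(
    expect_warning(rc <- rank_correlations(dbv, fractions = 1.0), "undefined"),
    "undefined"
  )
  expect_true(any(is.na(rc$spearman_rho)))
})

test_that("plot-ready tables are consistent with their sources", {
  eff <- fake_effect_table(c(5, 4, 3, 2), c(2, 3, 4, 5),
                           chrom = c("1", "1", "2", "2"),
                           pos = c(100, 200, 100, 300))
  tab <- manhattan_table(eff)
  expect_equal(nrow(tab), 8)
  # chromosome 2 offsets by the length of chromosome 1
  expect_equal(tab$cum_pos[tab$chrom == "2" & tab$env == tab$env[1]],
               c(100, 300) + 200)
  eff1 <- fake_effect_table(c(5, 4, 3), c(3, 4, 5))
  tab1 <- manhattan_table(eff1)
  expect_equal(tab1$cum_pos, tab1$pos)

  cmp <- top_k(eff, k = 2)
  qt <- quadrant_table(cmp)
  expect_equal(nrow(qt), 4)
  expect_identical(qt$quadrant, cmp$quadrants$quadrant)
})
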