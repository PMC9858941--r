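#' Remove animals with low genotype call rate
#'
#' Animals whose fraction of non-missing markers is strictly below
#' `min_call_rate` are removed (an animal at exactly the threshold is kept).
#' Survivor order is preserved.
#'
#' @param g a [geno_matrix()].
#' @param min_call_rate minimum fraction of non-missing calls (default 0.90).
#' @return the filtered [geno_matrix()], with attribute `"n_removed"`.
#' @export
filter_animals <- function(g, min_call_rate = 0.90) {
  stopifnot_geno(g)
  cr <- rowMeans(!is.na(g$dosages))
  keep <- cr >= min_call_rate
  if (!any(keep)) {
    stop("all animals removed by the call-rate filter", call. = FALSE)
  }
  out <- subset_geno(g, animals = which(keep))
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Marker quality control: sex chromosomes, call rate, MAF, HWE deviation
#'
#' Applies the marker filters in a fixed order, each computed on the markers
#' surviving the previous rule and on the animals present in `g` (run
#' [filter_animals()] first):
#' 1. remove all markers mapped to a sex chromosome (if
#'    `drop_sex_chromosomes`);
#' 2. remove markers with call rate strictly below `min_call_rate`;
#' 3. remove markers with minor allele frequency strictly below `min_maf`
#'    (frequencies from observed calls);
#' 4. remove markers whose observed heterozygote frequency deviates from the
#'    Hardy-Weinberg expectation 2p(1-p) by strictly more than `max_hwe_dev`.
#'
#' Each marker is counted under the first rule that removes it.
#'
#' @param g a [geno_matrix()].
#' @param min_call_rate minimum marker call rate (default 0.90).
#' @param min_maf minimum minor allele frequency (default 0.02).
#' @param max_hwe_dev maximum absolute deviation of observed heterozygosity
#'   from 2p(1-p) (default 0.15).
#' @param drop_sex_chromosomes remove markers on `sex_chromosomes` first
#'   (default TRUE).
#' @param sex_chromosomes chromosome labels treated as sex chromosomes.
#' @return list with elements `genotypes` (filtered [geno_matrix()]) and
#'   `report` (a `qc_report`, see [qc_genotypes()]).
#' @export
filter_markers <- function(g, min_call_rate = 0.90, min_maf = 0.02,
                           max_hwe_dev = 0.15, drop_sex_chromosomes = TRUE,
                           sex_chromosomes = c("X", "Y")) {
  stopifnot_geno(g)
  m_in <- n_markers(g)
  removed <- c(sex_chromosome = 0L, marker_call_rate = 0L, maf = 0L, hwe = 0L)

  cur <- g
  if (drop_sex_chromosomes) {
    on_sex <- cur$map$chrom %in% sex_chromosomes
    removed["sex_chromosome"] <- sum(on_sex)
    if (all(on_sex)) stop("all markers removed by QC (sex chromosomes)", call. = FALSE)
    if (any(on_sex)) cur <- subset_geno(cur, markers = which(!on_sex))
  }

  d <- cur$dosages
  n_obs <- colSums(!is.na(d))
  cr <- n_obs / nrow(d)
  low_cr <- cr < min_call_rate
  removed["marker_call_rate"] <- sum(low_cr)
  if (all(low_cr)) stop("all markers removed by QC (call rate)", call. = FALSE)
  if (any(low_cr)) cur <- subset_geno(cur, markers = which(!low_cr))

  d <- cur$dosages
  n_obs <- colSums(!is.na(d))
  p <- colSums(d, na.rm = TRUE) / (2 * n_obs)
  maf <- pmin(p, 1 - p)
  low_maf <- maf < min_maf
  removed["maf"] <- sum(low_maf)
  if (all(low_maf)) stop("all markers removed by QC (MAF)", call. = FALSE)
  if (any(low_maf)) {
    cur <- subset_geno(cur, markers = which(!low_maf))
    p <- p[!low_maf]
    n_obs <- n_obs[!low_maf]
  }

  d <- cur$dosages
  het_obs <- colSums(d == 1, na.rm = TRUE) / n_obs
  dev <- abs(het_obs - 2 * p * (1 - p))
  bad_hwe <- dev > max_hwe_dev
  removed["hwe"] <- sum(bad_hwe)
  if (all(bad_hwe)) stop("all markers removed by QC (HWE)", call. = FALSE)
  if (any(bad_hwe)) cur <- subset_geno(cur, markers = which(!bad_hwe))

  report <- new_qc_report(
    n_animals_in = n_animals(g), n_animals_out = n_animals(g),
    n_markers_in = m_in, n_markers_out = n_markers(cur),
    removed_by_rule = c(animal_call_rate = 0L, removed)
  )
  list(genotypes = cur, report = report)
}

#' Full genotype quality control
#'
#' Convenience wrapper: [filter_animals()] first, then [filter_markers()]
#' (so marker frequencies are computed on surviving animals), with a combined
#' report.
#'
#' @inheritParams filter_markers
#' @param min_animal_call_rate minimum animal call rate (default 0.90).
#' @return list with `genotypes` and `report` (class `qc_report`).
#' @export
qc_genotypes <- function(g, min_animal_call_rate = 0.90, min_call_rate = 0.90,
                         min_maf = 0.02, max_hwe_dev = 0.15,
                         drop_sex_chromosomes = TRUE,
                         sex_chromosomes = c("X", "Y")) {
  stopifnot_geno(g)
  n_in <- n_animals(g)
  ga <- filter_animals(g, min_call_rate = min_animal_call_rate)
  res <- filter_markers(ga, min_call_rate = min_call_rate, min_maf = min_maf,
                        max_hwe_dev = max_hwe_dev,
                        drop_sex_chromosomes = drop_sex_chromosomes,
                        sex_chromosomes = sex_chromosomes)
  rem <- res$report$removed_by_rule
  rem["animal_call_rate"] <- attr(ga, "n_removed")
  res$report <- new_qc_report(
    n_animals_in = n_in, n_animals_out = n_animals(res$genotypes),
    n_markers_in = n_markers(g), n_markers_out = n_markers(res$genotypes),
    removed_by_rule = rem
  )
  res
}

new_qc_report <- function(n_animals_in, n_animals_out, n_markers_in,
                          n_markers_out, removed_by_rule) {
  structure(list(
    n_animals_in = as.integer(n_animals_in),
    n_animals_out = as.integer(n_animals_out),
    n_markers_in = as.integer(n_markers_in),
    n_markers_out = as.integer(n_markers_out),
    removed_by_rule = as.list(removed_by_rule)
  ), class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("QC: animals %d -> %d, markers %d -> %d\n",
              x$n_animals_in, x$n_animals_out, x$n_markers_in, x$n_markers_out))
  for (nm in names(x$removed_by_rule)) {
    cat(sprintf("  removed by %-18s %d\n", paste0(nm, ":"),
                x$removed_by_rule[[nm]]))
  }
  invisible(x)
}

#' Mean-impute missing genotype calls
#'
#' Replaces each missing dosage by the marker's mean observed dosage (2p).
#' Non-missing entries are unchanged; imputed values are fractional.
#'
#' @param g a [geno_matrix()]; every marker must have at least one observed
#'   call.
#' @return a [geno_matrix()] without missing values.
#' @export
impute_missing <- function(g) {
  stopifnot_geno(g)
  d <- g$dosages
  if (!anyNA(d)) return(g)
  n_obs <- colSums(!is.na(d))
  if (any(n_obs == 0)) {
    stop("cannot impute: marker(s) with no observed calls: ",
         paste(head(colnames(d)[n_obs == 0], 5), collapse = ", "),
         call. = FALSE)
  }
  mean_dos <- colSums(d, na.rm = TRUE) / n_obs
  na_idx <- which(is.na(d), arr.ind = TRUE)
  d[na_idx] <- mean_dos[na_idx[, 2]]
  geno_matrix(d, g$map)
}
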