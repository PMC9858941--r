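#' Top-k SNP comparison between the two environments
#'
#' Selects, in each environment, the k SNPs with the largest percentage of
#' explained additive variance, records the truncation points (the percentage
#' of the k-th ranked SNP per environment), and classifies every marker into
#' the quadrants of the two-environment dispersion plot: `both` (top-k in
#' both environments), `only_env1`, `only_env2`, or `neither`. Ties at the
#' k-th value are broken deterministically by (percentage descending,
#' chromosome ascending, position ascending) and a warning is emitted.
#'
#' @param effects a `snp_effect_table` with percentage columns (see
#'   [explained_variance()]).
#' @param k number of top SNPs per environment (default 50).
#' @return an object of class `topk_comparison`: list with `k`, `T_env1`,
#'   `T_env2` (truncation points), `quadrants` (data.frame `marker_id`,
#'   `chrom`, `pos`, `pct_env1`, `pct_env2`, `quadrant`), `n_common`,
#'   `n_different` (markers in exactly one top set), `per_chromosome`
#'   (per-environment chromosome summary of the top sets) and `envs`.
#' @export
top_k <- function(effects, k = 50) {
  check_effect_pct(effects)
  m <- nrow(effects)
  if (k < 1 || k > m) {
    stop("`k` must lie between 1 and the number of markers (", m, ")",
         call. = FALSE)
  }
  envs <- attr(effects, "envs")
  chrom_key <- chrom_sort_key(effects$chrom)

  sel <- vector("list", 2)
  T_val <- numeric(2)
  for (j in 1:2) {
    pct <- effects[[paste0("pct_env", j)]]
    ord <- order(-pct, chrom_key, effects$pos)
    sel[[j]] <- ord[seq_len(k)]
    T_val[j] <- pct[ord[k]]
    if (k < m && pct[ord[k + 1]] == T_val[j]) {
      warning("ties at the k-th percentage in environment ", envs[j],
              "; broken by (chromosome, position)", call. = FALSE)
    }
  }

  in1 <- seq_len(m) %in% sel[[1]]
  in2 <- seq_len(m) %in% sel[[2]]
  quadrant <- ifelse(in1 & in2, "both",
              ifelse(in1, "only_env1",
              ifelse(in2, "only_env2", "neither")))
  quad <- data.frame(
    marker_id = effects$marker_id,
    chrom = effects$chrom,
    pos = effects$pos,
    pct_env1 = effects$pct_env1,
    pct_env2 = effects$pct_env2,
    quadrant = quadrant,
    stringsAsFactors = FALSE
  )

  per_chrom <- do.call(rbind, lapply(1:2, function(j) {
    idx <- sel[[j]]
    agg <- stats::aggregate(
      effects[[paste0("pct_env", j)]][idx],
      by = list(chrom = effects$chrom[idx]),
      FUN = sum
    )
    cnt <- table(effects$chrom[idx])
    data.frame(
      env = envs[j],
      chrom = agg$chrom,
      n_top_snps = as.integer(cnt[agg$chrom]),
      sum_pct_var = agg$x,
      stringsAsFactors = FALSE
    )
  }))
  per_chrom <- per_chrom[order(per_chrom$env,
                               chrom_sort_key(per_chrom$chrom)), ]
  rownames(per_chrom) <- NULL

  structure(list(
    k = as.integer(k),
    T_env1 = T_val[1],
    T_env2 = T_val[2],
    quadrants = quad,
    n_common = sum(in1 & in2),
    n_different = sum(xor(in1, in2)),
    per_chromosome = per_chrom,
    envs = envs
  ), class = "topk_comparison")
}

#' @export
print.topk_comparison <- function(x, ...) {
  cat(sprintf("top-%d SNP comparison (%s vs %s)\n", x$k, x$envs[1], x$envs[2]))
  cat(sprintf("  truncation points: %.4g%% / %.4g%%\n", x$T_env1, x$T_env2))
  cat(sprintf("  SNPs in common: %d; in one environment only: %d\n",
              x$n_common, x$n_different))
  invisible(x)
}

#' Annotate markers with nearby gene intervals
#'
#' For each marker, reports the gene whose interval contains it (relation
#' `"within"`, distance 0); otherwise the nearest gene on the same chromosome
#' within `window` bp, labelled `"upstream"` when the marker lies before the
#' gene start and `"downstream"` when it lies after the gene end (forward
#' axis; no strand information is used); otherwise the marker stays
#' unannotated (`NA` gene, relation `"none"`).
#'
#' @param markers data.frame with columns `marker_id`, `chrom`, `pos`
#'   (e.g. a subset of a `snp_effect_table`).
#' @param genes data.frame with columns `gene`, `chrom`, `start`, `end`
#'   (1-based inclusive; see [read_gene_intervals()]).
#' @param window maximum distance in bp for nearest-gene annotation
#'   (default 600000).
#' @return `markers` with added columns `gene`, `gene_start`, `gene_end`,
#'   `distance_bp`, `relation` and a human-readable `annotation`
#'   (e.g. `"100 kb upstream"`).
#' @export
annotate_markers <- function(markers, genes, window = 600000) {
  if (!all(c("marker_id", "chrom", "pos") %in% names(markers))) {
    stop("`markers` needs columns marker_id, chrom, pos", call. = FALSE)
  }
  if (!all(c("gene", "chrom", "start", "end") %in% names(genes))) {
    stop("`genes` needs columns gene, chrom, start, end", call. = FALSE)
  }
  if (any(genes$start > genes$end) || any(genes$start < 1)) {
    stop("gene intervals must satisfy 1 <= start <= end", call. = FALSE)
  }
  out <- markers
  out$gene <- NA_character_
  out$gene_start <- NA_real_
  out$gene_end <- NA_real_
  out$distance_bp <- NA_real_
  out$relation <- "none"
  out$annotation <- "unannotated"

  genes <- genes[order(genes$chrom, genes$start, genes$gene), , drop = FALSE]
  for (i in seq_len(nrow(out))) {
    cand <- genes[genes$chrom == as.character(out$chrom[i]), , drop = FALSE]
    if (nrow(cand) == 0) next
    pos <- out$pos[i]
    dist <- ifelse(pos < cand$start, cand$start - pos,
            ifelse(pos > cand$end, pos - cand$end, 0))
    best <- which.min(dist)   # ties: first by (start, gene) order
    if (dist[best] > window) next
    out$gene[i] <- cand$gene[best]
    out$gene_start[i] <- cand$start[best]
    out$gene_end[i] <- cand$end[best]
    out$distance_bp[i] <- dist[best]
    if (dist[best] == 0) {
      out$relation[i] <- "within"
      out$annotation[i] <- "within"
    } else {
      rel <- if (pos < cand$start[best]) "upstream" else "downstream"
      out$relation[i] <- rel
      out$annotation[i] <- sprintf("%g kb %s", dist[best] / 1000, rel)
    }
  }
  out
}

#' Direct genomic breeding values from SNP effects
#'
#' Reconstructs breeding values from genotypes and back-solved SNP effects:
#' \deqn{DBV = Z \hat u} per environment, with Z the dosage matrix centered
#' on the same allele frequencies used in the back-solving step.
#'
#' @param g an imputed [geno_matrix()].
#' @param effects a `snp_effect_table` covering exactly the markers of `g`.
#' @param p allele frequencies for centering; defaults to those stored on
#'   `effects`.
#' @return a `dbv_table`: data.frame `animal_id`, `dbv_env1`\[, `dbv_env2`\]
#'   with attribute `envs`.
#' @export
compute_dbv <- function(g, effects, p = NULL) {
  stopifnot_geno(g)
  if (!inherits(effects, "snp_effect_table")) {
    stop("`effects` must come from backsolve_snp_effects()", call. = FALSE)
  }
  d <- g$dosages
  if (anyNA(d)) {
    stop("genotypes contain missing calls; run impute_missing() first",
         call. = FALSE)
  }
  if (!identical(as.character(effects$marker_id), colnames(d))) {
    only_g <- setdiff(colnames(d), effects$marker_id)
    only_e <- setdiff(effects$marker_id, colnames(d))
    if (length(only_g) || length(only_e)) {
      stop("marker sets differ between genotypes and effects; ",
           "only in genotypes: ", paste(head(only_g, 3), collapse = ", "),
           "; only in effects: ", paste(head(only_e, 3), collapse = ", "),
           call. = FALSE)
    }
    effects <- effects[match(colnames(d), effects$marker_id), , drop = FALSE]
  }
  envs <- attr(effects, "envs")
  if (is.null(p)) p <- attr(effects, "allele_freq")
  if (is.null(p) || length(p) != ncol(d)) {
    stop("`p` must have one frequency per marker", call. = FALSE)
  }
  z <- sweep(d, 2, 2 * p, "-")
  out <- data.frame(animal_id = rownames(d), stringsAsFactors = FALSE)
  for (j in seq_along(envs)) {
    out[[paste0("dbv_env", j)]] <-
      as.numeric(z %*% effects[[paste0("u_env", j)]])
  }
  attr(out, "envs") <- envs
  class(out) <- c("dbv_table", "data.frame")
  out
}

#' Spearman reranking of selected animals between environments
#'
#' For each selection fraction f, selects the ceiling(f * n) animals with the
#' highest DBV in the selection-basis environment, computes the Spearman rank
#' correlation between their DBVs in the two environments, and counts how
#' many of them are absent from the other environment's equally sized top set
#' (`n_not_retained`). Selection based on environment 1 mirrors asking
#' whether animals selected in the first environment would still be the best
#' in the second; the symmetric environment-2-based report is also returned.
#'
#' @param dbv a `dbv_table` from [compute_dbv()] (needs two environments).
#' @param fractions selection fractions (default `c(0.10, 0.40, 1.00)`).
#' @return data.frame with columns `basis` (`env1`/`env2`), `fraction`,
#'   `n_selected`, `spearman_rho`, `n_not_retained`. Constant DBVs make the
#'   correlation undefined; it is reported as `NA` with a warning.
#' @export
rank_correlations <- function(dbv, fractions = c(0.10, 0.40, 1.00)) {
  if (!inherits(dbv, "dbv_table") || is.null(dbv$dbv_env2)) {
    stop("`dbv` must be a two-environment dbv_table (see compute_dbv)",
         call. = FALSE)
  }
  if (any(fractions <= 0 | fractions > 1)) {
    stop("fractions must lie in (0, 1]", call. = FALSE)
  }
  n <- nrow(dbv)
  if (n < 10) stop("need at least 10 animals", call. = FALSE)
  vals <- list(dbv$dbv_env1, dbv$dbv_env2)

  rows <- list()
  for (b in 1:2) {
    x <- vals[[b]]
    y <- vals[[3 - b]]
    ord_x <- order(-x, dbv$animal_id)
    ord_y <- order(-y, dbv$animal_id)
    for (f in fractions) {
      n_sel <- ceiling(f * n)
      sel <- ord_x[seq_len(n_sel)]
      other_top <- ord_y[seq_len(n_sel)]
      if (sd(x[sel]) == 0 || sd(y[sel]) == 0) {
        warning("constant DBVs in a selected set; Spearman rho undefined",
                call. = FALSE)
        rho <- NA_real_
      } else {
        rho <- cor(x[sel], y[sel], method = "spearman")
      }
      rows[[length(rows) + 1]] <- data.frame(
        basis = paste0("env", b),
        fraction = f,
        n_selected = n_sel,
        spearman_rho = rho,
        n_not_retained = length(setdiff(sel, other_top)),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "envs") <- attr(dbv, "envs")
  out
}

#' Plot-ready Manhattan table
#'
#' Long-format table of per-SNP explained-variance percentages with a
#' cumulative genome position (chromosomes laid end to end in natural order),
#' one row per marker and environment.
#'
#' @param effects a `snp_effect_table` with percentage columns.
#' @return data.frame `marker_id`, `chrom`, `pos`, `cum_pos`, `env`,
#'   `pct_var`.
#' @export
manhattan_table <- function(effects) {
  check_effect_pct(effects)
  envs <- attr(effects, "envs")
  key <- chrom_sort_key(effects$chrom)
  chroms <- unique(effects$chrom[order(key)])
  chrom_len <- vapply(chroms, function(cc) {
    max(effects$pos[effects$chrom == cc])
  }, numeric(1))
  offset <- setNames(cumsum(c(0, chrom_len[-length(chrom_len)])), chroms)
  cum_pos <- effects$pos + offset[effects$chrom]
  do.call(rbind, lapply(1:2, function(j) {
    data.frame(
      marker_id = effects$marker_id,
      chrom = effects$chrom,
      pos = effects$pos,
      cum_pos = unname(cum_pos),
      env = envs[j],
      pct_var = effects[[paste0("pct_env", j)]],
      stringsAsFactors = FALSE
    )
  }))
}

#' Plot-ready quadrant table
#'
#' The per-marker dispersion table of a [top_k()] comparison: both
#' environments' percentages plus the quadrant label.
#'
#' @param cmp a `topk_comparison` from [top_k()].
#' @return data.frame `marker_id`, `pct_env1`, `pct_env2`, `quadrant`.
#' @export
quadrant_table <- function(cmp) {
  if (!inherits(cmp, "topk_comparison")) {
    stop("`cmp` must come from top_k()", call. = FALSE)
  }
  cmp$quadrants[, c("marker_id", "pct_env1", "pct_env2", "quadrant")]
}

check_effect_pct <- function(effects) {
  if (!inherits(effects, "snp_effect_table")) {
    stop("expected a snp_effect_table (see backsolve_snp_effects)", call. = FALSE)
  }
  if (is.null(effects$pct_env1) || is.null(effects$pct_env2)) {
    stop("percentage columns missing; run explained_variance() first",
         call. = FALSE)
  }
  invisible(effects)
}

# numeric-aware chromosome ordering key ("2" before "10", labels after numbers)
chrom_sort_key <- function(chrom) {
  num <- suppressWarnings(as.numeric(chrom))
  key <- ifelse(is.na(num), Inf, num)
  # stable secondary order for non-numeric labels
  key + match(chrom, sort(unique(chrom))) * 1e-9
}
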