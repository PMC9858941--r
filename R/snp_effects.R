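#' Back-solve per-SNP effects from genomic breeding values
#'
#' Recovers marker effects from GEBVs by
#' \deqn{\hat u = D Z' (Z D Z')^{-1} \hat a}
#' per environment, where Z is the column-centered dosage matrix (M - 2P,
#' using the same allele frequencies as the GRM) and D a diagonal matrix of
#' per-SNP weights (identity by default — single pass, no iterative
#' reweighting). When Z D Z' is numerically singular the Moore-Penrose
#' pseudoinverse is used instead and the result is flagged (attribute
#' `pseudo_inverse`, plus a warning).
#'
#' @param gebv a [solve_mme()] fit, or a data.frame `animal_id`, `env`,
#'   `gebv` covering every animal of `g`.
#' @param g an imputed [geno_matrix()] (no missing calls).
#' @param p allele frequencies used for centering (default: observed
#'   frequencies of `g`); must match those used to build the GRM the GEBVs
#'   came from.
#' @param weights optional positive per-SNP weights (the diagonal of D).
#' @param ridge optional ridge added to the diagonal of Z D Z' before
#'   inversion (default 0, the exact back-solve; pass the GRM blending value
#'   times the GRM scale to reuse the blended factorization).
#' @return a `snp_effect_table`: data.frame `marker_id`, `chrom`, `pos`,
#'   `u_env1`\[, `u_env2`\] with attributes `envs` and `allele_freq`; variance
#'   columns are added by [explained_variance()].
#' @export
backsolve_snp_effects <- function(gebv, g, p = NULL, weights = NULL,
                                  ridge = 0) {
  stopifnot_geno(g)
  d <- g$dosages
  if (anyNA(d)) {
    stop("genotypes contain missing calls; run impute_missing() first",
         call. = FALSE)
  }
  A <- gebv_matrix_for(gebv, rownames(d))
  envs <- colnames(A)
  if (is.null(p)) p <- allele_frequencies(g)
  if (length(p) != ncol(d)) stop("`p` must have one frequency per marker", call. = FALSE)
  if (is.null(weights)) weights <- rep(1, ncol(d))
  if (length(weights) != ncol(d) || any(weights <= 0)) {
    stop("`weights` must be positive, one per marker", call. = FALSE)
  }

  z <- sweep(d, 2, 2 * p, "-")
  zw <- sweep(z, 2, weights, "*")
  K <- tcrossprod(zw, z)                       # Z D Z'
  if (ridge > 0) diag(K) <- diag(K) + ridge
  Ks <- (K + t(K)) / 2
  pseudo <- FALSE
  Kinv_a <- tryCatch(chol2inv(chol(Ks)) %*% A, error = function(e) NULL)
  if (is.null(Kinv_a)) {
    warning("Z D Z' is singular; using the Moore-Penrose pseudoinverse",
            call. = FALSE)
    Kinv_a <- MASS::ginv(Ks) %*% A
    pseudo <- TRUE
  }
  u <- sweep(crossprod(z, Kinv_a), 1, weights, "*")  # D Z' (ZDZ')^- a

  out <- data.frame(
    marker_id = g$map$marker_id,
    chrom = g$map$chrom,
    pos = g$map$pos,
    stringsAsFactors = FALSE
  )
  for (j in seq_along(envs)) out[[paste0("u_env", j)]] <- u[, j]
  attr(out, "envs") <- envs
  attr(out, "allele_freq") <- unname(p)
  attr(out, "pseudo_inverse") <- pseudo
  class(out) <- c("snp_effect_table", "data.frame")
  out
}

#' Per-SNP explained additive variance
#'
#' Fills the variance columns of a SNP-effect table: for SNP i,
#' \deqn{\hat\sigma^2_{u,i} = 2 p_i (1 - p_i) \hat u_i^2}
#' and the percentage of the summed per-SNP variance within each environment,
#' \eqn{100 \, \hat\sigma^2_{u,i} / \sum_j \hat\sigma^2_{u,j}} (so the
#' percentages sum to 100 in every environment and are comparable across
#' environments).
#'
#' @param effects a `snp_effect_table` from [backsolve_snp_effects()].
#' @param p allele frequencies; defaults to those stored on the table.
#' @return the table with added columns `var_env<j>` and `pct_env<j>` per
#'   environment.
#' @export
explained_variance <- function(effects, p = NULL) {
  if (!inherits(effects, "snp_effect_table")) {
    stop("`effects` must come from backsolve_snp_effects()", call. = FALSE)
  }
  envs <- attr(effects, "envs")
  if (is.null(p)) p <- attr(effects, "allele_freq")
  if (is.null(p) || length(p) != nrow(effects)) {
    stop("`p` must have one frequency per marker", call. = FALSE)
  }
  if (any(p <= 0 | p >= 1)) {
    stop("allele frequencies must lie strictly in (0, 1)", call. = FALSE)
  }
  w <- 2 * p * (1 - p)
  for (j in seq_along(envs)) {
    v <- w * effects[[paste0("u_env", j)]]^2
    tot <- sum(v)
    if (tot == 0) {
      stop("all SNP effects are zero in environment ", envs[j],
           "; percentages of explained variance are undefined", call. = FALSE)
    }
    effects[[paste0("var_env", j)]] <- v
    effects[[paste0("pct_env", j)]] <- 100 * v / tot
  }
  effects
}

# normalize a gblup_fit or long data.frame into an animals x envs GEBV matrix
# aligned to `ids`
gebv_matrix_for <- function(gebv, ids) {
  if (inherits(gebv, "gblup_fit")) {
    A <- gebv$gebv_matrix
  } else if (is.data.frame(gebv) &&
             all(c("animal_id", "env", "gebv") %in% names(gebv))) {
    envs <- sort(unique(as.character(gebv$env)))
    A <- matrix(NA_real_, length(unique(gebv$animal_id)), length(envs),
                dimnames = list(unique(as.character(gebv$animal_id)), envs))
    A[cbind(match(gebv$animal_id, rownames(A)),
            match(gebv$env, envs))] <- gebv$gebv
  } else {
    stop("`gebv` must be a gblup_fit or a data.frame with ",
         "animal_id, env, gebv", call. = FALSE)
  }
  missing_ids <- setdiff(ids, rownames(A))
  if (length(missing_ids) > 0) {
    stop("GEBVs missing for ", length(missing_ids), " genotyped animal(s), ",
         "e.g. ", paste(head(missing_ids, 3), collapse = ", "), call. = FALSE)
  }
  A <- A[ids, , drop = FALSE]
  if (anyNA(A)) stop("GEBV table has missing values", call. = FALSE)
  A
}
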