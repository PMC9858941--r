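#' Observed allele frequencies
#'
#' Frequency of the counted allele per marker, computed from observed
#' (non-missing) calls: p = sum(dosage) / (2 * n_observed).
#'
#' @param g a [geno_matrix()]; every marker needs at least one observed call.
#' @return named numeric vector of frequencies, one per marker.
#' @export
allele_frequencies <- function(g) {
  stopifnot_geno(g)
  d <- g$dosages
  n_obs <- colSums(!is.na(d))
  if (any(n_obs == 0)) {
    stop("marker(s) with no observed calls: ",
         paste(head(colnames(d)[n_obs == 0], 5), collapse = ", "),
         call. = FALSE)
  }
  colSums(d, na.rm = TRUE) / (2 * n_obs)
}

#' VanRaden (method 1) genomic relationship matrix
#'
#' Builds G = ZZ' / (2 * sum(p * (1 - p))) where Z is the column-centered
#' dosage matrix M - 2P, plus a small ridge `blend_epsilon` on the diagonal to
#' guarantee invertibility for REML and the mixed-model equations.
#'
#' @param g an imputed [geno_matrix()] (no missing calls; see
#'   [impute_missing()]).
#' @param p allele frequencies used for centering and for the denominator;
#'   defaults to the observed frequencies of `g`. All must lie strictly in
#'   (0, 1).
#' @param blend_epsilon ridge added to the diagonal (default 1e-6; 0 gives the
#'   unblended matrix).
#' @return an object of class `grm`: list with `mat` (animals x animals),
#'   `scale` (the denominator 2*sum(p(1-p))), `epsilon`, `animal_ids`.
#' @export
vanraden_g <- function(g, p = NULL, blend_epsilon = 1e-6) {
  stopifnot_geno(g)
  d <- g$dosages
  if (anyNA(d)) {
    stop("genotypes contain missing calls; run impute_missing() first",
         call. = FALSE)
  }
  if (is.null(p)) p <- allele_frequencies(g)
  if (length(p) != ncol(d)) {
    stop("`p` must have one frequency per marker", call. = FALSE)
  }
  if (any(p <= 0 | p >= 1)) {
    stop("allele frequencies must lie strictly in (0, 1); ",
         "remove monomorphic markers (MAF filter) first", call. = FALSE)
  }
  if (blend_epsilon < 0) stop("blend_epsilon must be >= 0", call. = FALSE)
  z <- sweep(d, 2, 2 * p, "-")
  denom <- 2 * sum(p * (1 - p))
  if (denom <= 0) stop("zero denominator: all markers monomorphic", call. = FALSE)
  gmat <- tcrossprod(z) / denom
  if (blend_epsilon > 0) {
    diag(gmat) <- diag(gmat) + blend_epsilon
  }
  structure(list(
    mat = gmat,
    scale = denom,
    epsilon = blend_epsilon,
    animal_ids = rownames(d)
  ), class = "grm")
}

#' @export
print.grm <- function(x, ...) {
  cat(sprintf("grm: %d animals, scale 2*sum(p(1-p)) = %.4f, blend epsilon = %g\n",
              length(x$animal_ids), x$scale, x$epsilon))
  cat(sprintf("  mean diagonal %.4f\n", mean(diag(x$mat))))
  invisible(x)
}

stopifnot_grm <- function(G) {
  if (!inherits(G, "grm")) stop("expected a `grm` (see ?vanraden_g)", call. = FALSE)
  invisible(G)
}
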