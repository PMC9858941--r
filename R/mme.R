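#' Solve the bivariate mixed-model equations for genomic breeding values
#'
#' Computes the BLUP solutions of Henderson's mixed-model equations for the
#' (bi-)trait GBLUP model at given variance components:
#' \deqn{\begin{pmatrix} X'R^{-1}X & X'R^{-1}Z \\ Z'R^{-1}X &
#'  Z'R^{-1}Z + G_0^{-1} \otimes G^{-1} \end{pmatrix}
#'  \begin{pmatrix}\hat\mu\\ \hat a\end{pmatrix} =
#'  \begin{pmatrix}X'R^{-1}y \\ Z'R^{-1}y\end{pmatrix}}
#' The random effect covers every animal in `G`, so animals without a record
#' in one or both environments still receive GEBVs through their genomic
#' relationships. The incidence structure is kept explicit: animals may have
#' records in any subset of the environments, and the residual covariance
#' between environments applies within animal.
#'
#' Internally the solutions are obtained from the equivalent
#' generalized-least-squares form
#' \eqn{\hat\mu = (X'V^{-1}X)^{-1}X'V^{-1}y},
#' \eqn{\hat a = \mathrm{Cov}(a, y)\, V^{-1}(y - X\hat\mu)} with
#' \eqn{V = Z(G_0 \otimes G)Z' + R}, which gives identical solutions but
#' never forms \eqn{G_0^{-1}} or \eqn{G^{-1}}: a genetic correlation at the
#' +/-1 boundary (singular but PSD `G0`) is handled exactly rather than
#' failing.
#'
#' @param y data.frame of pseudo-phenotypes (`animal_id`, `env`, `value`);
#'   records of animals absent from `G` are dropped with a warning.
#' @param G a [vanraden_g()] genomic relationship matrix.
#' @param vc a [fit_greml()] fit, or any list with elements `G0`, `R0`
#'   (t x t symmetric PSD matrices) and `envs`.
#' @return an object of class `gblup_fit`: list with
#'   * `gebv`: data.frame `animal_id`, `env`, `gebv` for every animal in `G`
#'     and every environment;
#'   * `gebv_matrix`: the same values as an animals x environments matrix;
#'   * `fixed_means`: named vector of estimated environment means;
#'   * `envs`, `n_records`.
#' @export
solve_mme <- function(y, G, vc) {
  stopifnot_grm(G)
  if (is.null(vc$G0) || is.null(vc$R0) || is.null(vc$envs)) {
    stop("`vc` must carry G0, R0 and envs (see fit_greml)", call. = FALSE)
  }
  envs <- vc$envs
  t_n <- length(envs)
  G0 <- as.matrix(vc$G0)
  R0 <- as.matrix(vc$R0)
  if (!isTRUE(all.equal(G0, t(G0), check.attributes = FALSE))) {
    stop("additive covariance block G0 must be symmetric", call. = FALSE)
  }
  if (!isTRUE(all.equal(R0, t(R0), check.attributes = FALSE))) {
    stop("residual covariance block R0 must be symmetric", call. = FALSE)
  }

  dat <- check_pheno(y)
  dat <- dat[dat$env %in% envs, , drop = FALSE]
  drop <- !(dat$animal_id %in% G$animal_ids)
  if (any(drop)) {
    warning(sum(drop), " record(s) of animals absent from the GRM dropped",
            call. = FALSE)
    dat <- dat[!drop, , drop = FALSE]
  }
  if (nrow(dat) == 0) stop("no usable records", call. = FALSE)
  if (!all(envs %in% dat$env)) {
    stop("environment(s) without records: ",
         paste(setdiff(envs, dat$env), collapse = ", "), call. = FALSE)
  }

  q <- length(G$animal_ids)
  ia <- match(dat$animal_id, G$animal_ids)
  it <- match(dat$env, envs)
  N <- nrow(dat)

  # V = Z (G0 x G) Z' + R over records
  V <- G0[it, it] * G$mat[ia, ia]
  same <- outer(ia, ia, "==")
  V <- V + R0[it, it] * same
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) {
    stop("phenotypic covariance V = Z(G0 x G)Z' + R is singular; ",
         "check that G is blended and R0 is positive definite", call. = FALSE)
  }
  Vi <- chol2inv(ch)

  X <- matrix(0, N, t_n)
  X[cbind(seq_len(N), it)] <- 1
  XtVi <- crossprod(X, Vi)
  C <- XtVi %*% X
  mu <- tryCatch(solve(C, XtVi %*% dat$value), error = function(e) NULL)
  if (is.null(mu)) {
    stop("fixed-effect block X'V^-1X is singular", call. = FALSE)
  }
  mu <- as.numeric(mu)
  py <- Vi %*% (dat$value - X %*% mu)

  # a_hat[a, i] = sum_s G0[i, it_s] * G[a, ia_s] * py_s
  a_hat <- matrix(0, q, t_n, dimnames = list(G$animal_ids, envs))
  for (i in seq_len(t_n)) {
    w <- as.numeric(py) * G0[i, it]
    a_hat[, i] <- G$mat[, ia, drop = FALSE] %*% w
  }

  gebv <- data.frame(
    animal_id = rep(G$animal_ids, t_n),
    env = rep(envs, each = q),
    gebv = as.numeric(a_hat),
    stringsAsFactors = FALSE
  )
  structure(list(
    gebv = gebv,
    gebv_matrix = a_hat,
    fixed_means = setNames(mu, envs),
    envs = envs,
    n_records = N
  ), class = "gblup_fit")
}

#' @export
print.gblup_fit <- function(x, ...) {
  cat(sprintf("GBLUP solutions: %d animals x %d environment(s), %d record(s)\n",
              nrow(x$gebv_matrix), length(x$envs), x$n_records))
  cat("fixed means:\n")
  print(round(x$fixed_means, 6))
  invisible(x)
}
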