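#' Variance components of the bi-trait GBLUP model by REML
#'
#' Fits, by restricted maximum likelihood, the model
#' \deqn{y = (I_t \otimes 1_n)\mu + a + e, \quad
#'       a \sim N(0, G_0 \otimes G), \quad e \sim N(0, R_0 \otimes I)}
#' where the t traits are the environments (t = 1 or 2 here), `G` is the
#' genomic relationship matrix and G0 / R0 are the t x t additive and
#' residual covariance matrices. Only the trait means are fitted as fixed
#' effects (the pseudo-phenotypes are already adjusted breeding values).
#'
#' The analysis set is the animals with a record in every environment and a
#' row in `G`. The likelihood is evaluated through the eigendecomposition of
#' `G` (canonical transformation), which makes every iteration O(n)
#' in the number of animals. Updates are expectation-maximization (EM) steps
#' accelerated by average-information (AI) Newton steps: the AI step is taken
#' whenever it increases the restricted likelihood (with step halving),
#' otherwise the EM step — whose ascent is guaranteed — is used, so the
#' log-likelihood is non-decreasing across iterations. After every update the
#' covariance matrices are projected onto the positive-semidefinite cone by
#' eigenvalue clipping at 1e-10 of the trace.
#'
#' Starting values assign half the phenotypic (co)variance to G0 and half
#' to R0. Convergence is declared when the largest absolute change of any
#' free parameter falls below `tol`.
#'
#' @param y data.frame of pseudo-phenotypes with columns `animal_id`, `env`,
#'   `value` (at most one record per animal and environment).
#' @param G a [vanraden_g()] genomic relationship matrix; must be positive
#'   definite (blended).
#' @param envs environment labels defining trait order; defaults to
#'   `sort(unique(y$env))`.
#' @param tol convergence tolerance on parameter changes (default 1e-8).
#' @param max_iter maximum number of iterations (default 200). Hitting it
#'   flags `converged = FALSE` rather than raising an error.
#' @param estimate_covariance if `FALSE`, the additive and residual
#'   covariances between environments are fixed at zero, so the bivariate fit
#'   decouples into independent single-trait fits.
#' @param verbose print the log-likelihood per iteration.
#' @return an object of class `var_components`: list with `G0`, `R0`,
#'   `genetic_correlation`, `loglik`, `loglik_trace`, `n_iter`, `converged`,
#'   `envs`, `n_animals`.
#' @export
fit_greml <- function(y, G, envs = NULL, tol = 1e-8, max_iter = 200,
                      estimate_covariance = TRUE, verbose = FALSE) {
  stopifnot_grm(G)
  dat <- check_pheno(y)
  if (is.null(envs)) envs <- sort(unique(dat$env))
  t_n <- length(envs)
  if (!all(dat$env %in% envs)) {
    dat <- dat[dat$env %in% envs, , drop = FALSE]
  }
  if (t_n < 1 || t_n > 2) {
    stop("fit_greml supports one or two environments", call. = FALSE)
  }

  # analysis set: animals with a record in every environment, present in G
  Y <- pheno_wide(dat, envs)
  ids <- rownames(Y)[stats::complete.cases(Y)]
  ids <- ids[ids %in% G$animal_ids]
  ids <- G$animal_ids[G$animal_ids %in% ids] # GRM order
  n <- length(ids)
  if (n < 2) stop("fewer than 2 animals with complete records in the GRM", call. = FALSE)
  if (n < 30) {
    warning("only ", n, " animals with complete records; ",
            "REML estimates will be unstable", call. = FALSE)
  }
  Y <- Y[ids, , drop = FALSE]

  eg <- eigen(G$mat[ids, ids], symmetric = TRUE)
  d <- eg$values
  if (min(d) <= 0) {
    stop("G is not positive definite; rebuild it with blend_epsilon > 0",
         call. = FALSE)
  }
  Yt <- crossprod(eg$vectors, Y)        # n x t
  xt <- as.numeric(crossprod(eg$vectors, rep(1, n)))

  # free parameters: lower triangles of G0 and R0 (diagonals only when
  # covariances are fixed at zero)
  free <- which(lower.tri(diag(t_n), diag = TRUE), arr.ind = TRUE)
  if (!estimate_covariance) free <- free[free[, 1] == free[, 2], , drop = FALSE]
  n_free <- nrow(free)

  # start at half the phenotypic (co)variance; the larger clip floor keeps
  # degenerate starts (e.g. identical phenotypes in both environments)
  # strictly inside the parameter space
  S <- cov(Y)
  if (!estimate_covariance) S[row(S) != col(S)] <- 0
  G0 <- psd_clip(S / 2, rel = 1e-6)
  R0 <- psd_clip(S / 2, rel = 1e-6)

  ll_trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  cur <- reml_pass(G0, R0, d, Yt, xt, full = TRUE)
  if (is.null(cur)) stop("starting values give a singular covariance", call. = FALSE)

  while (iter < max_iter) {
    iter <- iter + 1L
    ll_trace <- c(ll_trace, cur$ll)
    if (verbose) {
      message(sprintf("iter %3d logL = %.8f", iter, cur$ll))
    }

    # EM candidate (guaranteed ascent)
    G0_em <- G0 + G0 %*% ((cur$Q - cur$Tg) / n) %*% G0
    R0_em <- R0 + R0 %*% ((cur$Se - cur$Pe) / n) %*% R0
    if (!estimate_covariance) {
      G0_em[row(G0_em) != col(G0_em)] <- 0
      R0_em[row(R0_em) != col(R0_em)] <- 0
    }
    G0_em <- psd_clip(G0_em)
    R0_em <- psd_clip(R0_em)

    # AI candidate with step halving, falling back to EM
    theta <- c(G0[free], R0[free])
    cand <- NULL
    step <- ai_direction(cur, free, d_weighted = TRUE)
    if (!is.null(step)) {
      for (h in 0:9) {
        th_new <- theta + step / 2^h
        G0_ai <- unpack_sym(th_new[seq_len(n_free)], free, t_n)
        R0_ai <- unpack_sym(th_new[n_free + seq_len(n_free)], free, t_n)
        # candidates outside the PD cone fail the chol inside reml_pass and
        # trigger another halving, keeping the iterates interior (projecting
        # onto the boundary would trap the EM fallback at a singular G0)
        if (min(eigen(G0_ai, symmetric = TRUE, only.values = TRUE)$values) <= 0 ||
            min(eigen(R0_ai, symmetric = TRUE, only.values = TRUE)$values) <= 0) {
          next
        }
        p_ai <- reml_pass(G0_ai, R0_ai, d, Yt, xt, full = FALSE)
        if (!is.null(p_ai) && p_ai$ll >= cur$ll - 1e-10) {
          cand <- list(G0 = G0_ai, R0 = R0_ai)
          break
        }
      }
    }
    used_em <- is.null(cand)
    if (used_em) cand <- list(G0 = G0_em, R0 = R0_em)

    delta <- max(abs(c(cand$G0[free], cand$R0[free]) - theta))
    G0 <- cand$G0
    R0 <- cand$R0
    cur <- reml_pass(G0, R0, d, Yt, xt, full = TRUE)
    if (is.null(cur)) {
      stop("covariance became singular during iteration", call. = FALSE)
    }
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  ll_trace <- c(ll_trace, cur$ll)

  dimnames(G0) <- dimnames(R0) <- list(envs, envs)
  rg <- if (t_n == 2) {
    den <- sqrt(G0[1, 1] * G0[2, 2])
    if (den > 0) G0[1, 2] / den else NA_real_
  } else {
    NA_real_
  }
  structure(list(
    G0 = G0, R0 = R0,
    genetic_correlation = rg,
    loglik = cur$ll,
    loglik_trace = ll_trace,
    n_iter = iter,
    converged = converged,
    envs = envs,
    n_animals = n
  ), class = "var_components")
}

#' @export
print.var_components <- function(x, ...) {
  cat(sprintf("GREML fit: %d animals, %d iteration(s), %s\n",
              x$n_animals, x$n_iter,
              if (x$converged) "converged" else "NOT converged"))
  cat("additive covariance G0:\n")
  print(round(x$G0, 6))
  cat("residual covariance R0:\n")
  print(round(x$R0, 6))
  if (!is.na(x$genetic_correlation)) {
    cat(sprintf("genetic correlation: %.4f\n", x$genetic_correlation))
  }
  cat(sprintf("REML log-likelihood: %.6f\n", x$loglik))
  invisible(x)
}

# One sweep over the n eigen-blocks V_m = d_m G0 + R0 of the transformed
# model. Returns the REML log-likelihood and, when full = TRUE, the
# accumulators needed for scores, average information and EM updates:
#   PY  n x t matrix of V^-1 residuals (the transformed Py vector)
#   Tg = sum d_m P_m, Pe = sum P_m, Q = sum d_m PY_m PY_m',
#   Se = sum PY_m PY_m', with P_m the m-th diagonal block of the REML
#   projection matrix.
# Returns NULL when some V_m is not positive definite.
reml_pass <- function(G0, R0, d, Yt, xt, full = TRUE) {
  n <- length(d)
  t_n <- ncol(Yt)
  VI <- array(0, c(t_n, t_n, n))
  logdetV <- 0
  C <- matrix(0, t_n, t_n)
  Cy <- numeric(t_n)
  for (m in seq_len(n)) {
    Vm <- d[m] * G0 + R0
    ch <- tryCatch(chol(Vm), error = function(e) NULL)
    if (is.null(ch)) return(NULL)
    logdetV <- logdetV + 2 * sum(log(diag(ch)))
    Vi <- chol2inv(ch)
    VI[, , m] <- Vi
    C <- C + xt[m]^2 * Vi
    Cy <- Cy + xt[m] * (Vi %*% Yt[m, ])
  }
  chC <- tryCatch(chol(C), error = function(e) NULL)
  if (is.null(chC)) return(NULL)
  Cinv <- chol2inv(chC)
  bhat <- as.numeric(Cinv %*% Cy)

  PY <- matrix(0, n, t_n)
  quad <- 0
  for (m in seq_len(n)) {
    r <- Yt[m, ] - xt[m] * bhat
    py <- VI[, , m] %*% r
    PY[m, ] <- py
    quad <- quad + sum(r * py)
  }
  ll <- -0.5 * (logdetV + 2 * sum(log(diag(chC))) + quad +
                  (n * t_n - t_n) * log(2 * pi))
  if (!full) return(list(ll = ll, bhat = bhat))

  Tg <- matrix(0, t_n, t_n)
  Pe <- matrix(0, t_n, t_n)
  Q <- matrix(0, t_n, t_n)
  Se <- matrix(0, t_n, t_n)
  for (m in seq_len(n)) {
    Vi <- VI[, , m]
    Pm <- Vi - xt[m]^2 * (Vi %*% Cinv %*% Vi)
    Tg <- Tg + d[m] * Pm
    Pe <- Pe + Pm
    o <- tcrossprod(PY[m, ])
    Q <- Q + d[m] * o
    Se <- Se + o
  }
  list(ll = ll, bhat = bhat, PY = PY, VI = VI, Cinv = Cinv, xt = xt, d = d,
       Tg = Tg, Pe = Pe, Q = Q, Se = Se)
}

# Average-information Newton direction for the free parameters of (G0, R0).
# Scores use the identity tr(P dV) and y'P dV P y reduced to the block
# accumulators; the AI matrix is 0.5 * (dV_k Py)' P (dV_l Py).
ai_direction <- function(cur, free, d_weighted = TRUE) {
  t_n <- ncol(cur$PY)
  n <- nrow(cur$PY)
  n_free <- nrow(free)
  n_par <- 2 * n_free

  mult <- ifelse(free[, 1] == free[, 2], 1, 2)
  score <- numeric(n_par)
  for (k in seq_len(n_free)) {
    i <- free[k, 1]; j <- free[k, 2]
    score[k] <- -0.5 * mult[k] * (cur$Tg[i, j] - cur$Q[i, j])
    score[n_free + k] <- -0.5 * mult[k] * (cur$Pe[i, j] - cur$Se[i, j])
  }

  # u_k,m = dV_k,m PY_m for every free parameter
  U <- vector("list", n_par)
  for (k in seq_len(n_free)) {
    i <- free[k, 1]; j <- free[k, 2]
    u <- matrix(0, n, t_n)
    u[, i] <- cur$PY[, j]
    u[, j] <- u[, j] + cur$PY[, i]
    if (i == j) u[, i] <- cur$PY[, i]
    U[[k]] <- u * cur$d          # G0 block: dV = d_m E_ij
    U[[n_free + k]] <- u         # R0 block: dV = E_ij
  }

  AI <- matrix(0, n_par, n_par)
  svecs <- matrix(0, t_n, n_par)
  VIU <- vector("list", n_par)
  for (k in seq_len(n_par)) {
    viu <- matrix(0, n, t_n)
    for (m in seq_len(n)) {
      viu[m, ] <- cur$VI[, , m] %*% U[[k]][m, ]
    }
    VIU[[k]] <- viu
    svecs[, k] <- colSums(cur$xt * viu)
  }
  for (k in seq_len(n_par)) {
    for (l in k:n_par) {
      val <- 0.5 * (sum(U[[k]] * VIU[[l]]) -
                      as.numeric(t(svecs[, k]) %*% cur$Cinv %*% svecs[, l]))
      AI[k, l] <- val
      AI[l, k] <- val
    }
  }
  dir <- tryCatch(solve(AI, score), error = function(e) NULL)
  if (is.null(dir) || any(!is.finite(dir))) return(NULL)
  dir
}

# project a symmetric matrix onto the PD cone by clipping eigenvalues at
# 1e-10 of the trace (with an absolute floor so inverses exist)
psd_clip <- function(A, rel = 1e-10) {
  A <- (A + t(A)) / 2
  e <- eigen(A, symmetric = TRUE)
  floor_val <- max(rel * sum(abs(diag(A))), 1e-12)
  vals <- pmax(e$values, floor_val)
  B <- e$vectors %*% (vals * t(e$vectors))
  (B + t(B)) / 2
}

unpack_sym <- function(theta, free, t_n) {
  A <- matrix(0, t_n, t_n)
  for (k in seq_len(nrow(free))) {
    A[free[k, 1], free[k, 2]] <- theta[k]
    A[free[k, 2], free[k, 1]] <- theta[k]
  }
  A
}

check_pheno <- function(y) {
  if (!is.data.frame(y) || !all(c("animal_id", "env", "value") %in% names(y))) {
    stop("phenotypes must be a data.frame with columns animal_id, env, value",
         call. = FALSE)
  }
  if (anyDuplicated(y[, c("animal_id", "env")])) {
    stop("at most one record per animal and environment", call. = FALSE)
  }
  data.frame(animal_id = as.character(y$animal_id),
             env = as.character(y$env),
             value = as.numeric(y$value),
             stringsAsFactors = FALSE)
}

# long phenotype table -> animals x envs matrix (NA where no record)
pheno_wide <- function(dat, envs) {
  ids <- unique(dat$animal_id)
  Y <- matrix(NA_real_, length(ids), length(envs),
              dimnames = list(ids, envs))
  Y[cbind(match(dat$animal_id, ids), match(dat$env, envs))] <- dat$value
  Y
}
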