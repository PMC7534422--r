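#' Specify a univariate mixed model
#'
#' A lightweight container for `y = X beta + sum_k Z_k u_k + e` with
#' `u_k ~ N(0, sigma2_k A_k)` (`A_k` a kinship matrix or the identity) and a
#' residual that may carry one variance per declared group (heterogeneous
#' residual variances as block-diagonal structure).
#'
#' @param y Response vector.
#' @param X Fixed-effect design matrix (an intercept-only matrix if `NULL`).
#' @param random List of random terms, each `list(Z =, cov =, label =)` where
#'   `Z` is the n x q incidence matrix and `cov` the q x q covariance
#'   structure (`NULL` for identity).
#' @param resid_groups Factor of length n partitioning records into residual
#'   variance groups (`NULL` for a single variance).
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(y, X = NULL, random = list(), resid_groups = NULL) {
  n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  X <- as.matrix(X)
  if (nrow(X) != n) stop("X row count does not match y")
  for (k in seq_along(random)) {
    rt <- random[[k]]
    if (nrow(rt$Z) != n) stop("Z row count of random term ", k, " does not match y")
    if (!is.null(rt$cov) && ncol(rt$Z) != nrow(rt$cov))
      stop("Z/cov dimension mismatch in random term ", k)
    if (is.null(rt$label)) random[[k]]$label <- paste0("u", k)
  }
  if (is.null(resid_groups)) resid_groups <- factor(rep("residual", n))
  resid_groups <- droplevels(as.factor(resid_groups))
  structure(list(y = as.numeric(y), X = X, random = random,
                 resid_groups = resid_groups),
            class = "model_spec")
}

drop_aliased <- function(X) {
  q <- qr(X)
  if (q$rank < ncol(X)) {
    keep <- q$pivot[seq_len(q$rank)]
    warning("dropping ", ncol(X) - q$rank, " aliased fixed-effect column(s)")
    X <- X[, sort(keep), drop = FALSE]
  }
  X
}

cov_inverse <- function(A, q) {
  if (is.null(A)) return(list(Ainv = NULL, logdet = 0))
  A <- as.matrix(A)
  ridge <- 1e-6 * mean(diag(A))
  e <- eigen(A + diag(ridge, q), symmetric = TRUE)
  if (any(e$values <= 0)) stop("random-term covariance is not positive definite")
  list(Ainv = e$vectors %*% (t(e$vectors) / e$values), logdet = sum(log(e$values)))
}

#' EM-REML for a univariate mixed model
#'
#' Maximizes the restricted likelihood by EM (monotone, cone-respecting),
#' with a variance floor of `1e-10` times the phenotypic variance; estimates
#' at the floor are reported as 0. Convergence is declared when the change in
#' restricted log-likelihood falls below `tol`; hitting `maxit` flags
#' non-convergence, never silently. For the common single-kinship,
#' single-residual-group case an eigendecomposition-based profiled likelihood
#' (`engine = "eigen"`) is available and is the default through
#' `engine = "auto"`; it agrees with the generic EM path (tested to 1e-4 in
#' the variance ratio).
#'
#' @param spec A [model_spec()].
#' @param tol Convergence tolerance on the restricted log-likelihood.
#' @param maxit Iteration cap.
#' @param engine `"auto"`, `"em"`, or `"eigen"`.
#' @return An object of class `reml_fit`: variance components (`sigma2`,
#'   named by term label plus one per residual group), `loglik`,
#'   `loglik_trace`, `converged`, `iterations`, fixed effects `beta` with
#'   covariance `beta_cov`, random-effect solutions `u` (list), and fitted
#'   residuals.
#' @export
reml_fit <- function(spec, tol = 1e-8, maxit = 1000,
                     engine = c("auto", "em", "eigen")) {
  engine <- match.arg(engine)
  stopifnot(inherits(spec, "model_spec"))
  y <- spec$y; n <- length(y)
  X <- drop_aliased(spec$X)
  p <- ncol(X)
  if (n <= p) stop("more fixed-effect parameters than records")
  nK <- length(spec$random)
  ngrp <- nlevels(spec$resid_groups)
  if (engine == "auto")
    engine <- if (nK == 1L && ngrp == 1L) "eigen" else "em"
  if (engine == "eigen") {
    if (nK != 1L || ngrp != 1L)
      stop("eigen engine requires one random term and one residual group")
    return(reml_eigen_profiled(y, X, spec$random[[1]], tol))
  }
  reml_em(y, X, spec$random, spec$resid_groups, tol, maxit)
}

reml_em <- function(y, X, random, resid_groups, tol, maxit) {
  n <- length(y); p <- ncol(X)
  nK <- length(random)
  grp <- as.integer(resid_groups)
  ngrp <- max(grp)
  n_g <- tabulate(grp, ngrp)
  Zs <- lapply(random, function(r) as.matrix(r$Z))
  qk <- vapply(Zs, ncol, 1L)
  covs <- lapply(seq_len(nK), function(k) cov_inverse(random[[k]]$cov, qk[k]))
  W <- do.call(cbind, c(list(X), Zs))
  idx <- split(seq_len(p + sum(qk)),
               rep(seq_len(nK + 1L), c(p, qk)))
  vy <- stats::var(y)
  floorv <- 1e-10 * vy
  s2k <- rep(vy / (nK + 1), nK)
  s2g <- rep(vy / (nK + 1), ngrp)
  logdetA <- sum(vapply(covs, `[[`, 0, "logdet"))
  # one MME evaluation at given variances: restricted loglik + solutions
  mme_eval <- function(s2k, s2g) {
    w <- 1 / s2g[grp]
    C <- crossprod(W * sqrt(w))
    for (k in seq_len(nK)) {
      ik <- idx[[k + 1L]]
      Ak <- covs[[k]]$Ainv
      if (is.null(Ak)) {
        C[cbind(ik, ik)] <- C[cbind(ik, ik)] + 1 / s2k[k]
      } else {
        C[ik, ik] <- C[ik, ik] + Ak / s2k[k]
      }
    }
    rhs <- crossprod(W, w * y)
    ch <- tryCatch(chol(C), error = function(e) NULL)
    if (is.null(ch)) { C <- C + diag(1e-8 * mean(diag(C)), nrow(C)); ch <- chol(C) }
    Cinv <- chol2inv(ch)
    sol <- Cinv %*% rhs
    ll <- -0.5 * (sum(n_g * log(s2g)) + sum(qk * log(s2k)) + logdetA +
                    2 * sum(log(diag(ch))) + sum(w * y^2) - sum(rhs * sol))
    list(ll = ll, Cinv = Cinv, sol = sol)
  }
  em_step <- function(state, s2k, s2g) {
    Cinv <- state$Cinv; sol <- state$sol
    for (k in seq_len(nK)) {
      ik <- idx[[k + 1L]]
      uk <- sol[ik]
      Ak <- covs[[k]]$Ainv
      if (is.null(Ak)) {
        s2k[k] <- (sum(uk^2) + sum(diag(Cinv)[ik])) / qk[k]
      } else {
        s2k[k] <- (drop(crossprod(uk, Ak %*% uk)) +
                     sum(Ak * Cinv[ik, ik])) / qk[k]
      }
    }
    ehat <- y - drop(W %*% sol)
    dWCW <- rowSums((W %*% Cinv) * W)
    for (g in seq_len(ngrp)) {
      rows <- grp == g
      s2g[g] <- (sum(ehat[rows]^2) + sum(dWCW[rows])) / n_g[g]
    }
    list(s2k = pmax(s2k, floorv), s2g = pmax(s2g, floorv))
  }
  ll_trace <- numeric(0)
  ll_prev <- -Inf
  converged <- FALSE
  hist_theta <- list()
  state <- NULL
  for (it in seq_len(maxit)) {
    state <- mme_eval(s2k, s2g)
    ll <- state$ll
    ll_trace <- c(ll_trace, ll)
    if (abs(ll - ll_prev) < tol) { converged <- TRUE; break }
    ll_prev <- ll
    stepped <- em_step(state, s2k, s2g)
    s2k <- stepped$s2k; s2g <- stepped$s2g
    # Aitken extrapolation on log-variances every few iterations: EM has a
    # linear rate, so geometric extrapolation of the fixed-point sequence
    # speeds up the tail; a candidate is kept only if it improves the
    # restricted likelihood, preserving monotonicity.
    hist_theta <- c(hist_theta, list(log(c(s2k, s2g))))
    if (length(hist_theta) > 3) hist_theta <- hist_theta[-1]
    if (it %% 5 == 0 && length(hist_theta) == 3) {
      t0 <- hist_theta[[1]]; t1 <- hist_theta[[2]]; t2 <- hist_theta[[3]]
      d1 <- t1 - t0; d2 <- t2 - t1
      r <- ifelse(abs(d1) > 1e-14, d2 / d1, 0)
      r <- pmin(pmax(r, 0), 0.995)
      cand <- t2 + r / (1 - r) * d2
      cs2 <- pmax(exp(cand), floorv)
      ck <- cs2[seq_len(nK)]
      cg <- cs2[nK + seq_len(ngrp)]
      cand_state <- mme_eval(ck, cg)
      if (is.finite(cand_state$ll) && cand_state$ll >= ll) {
        s2k <- ck; s2g <- cg
        hist_theta <- list()
      }
    }
  }
  if (!converged) warning("EM-REML did not converge in ", maxit, " iterations")
  # quasi-Newton polish: near a boundary the likelihood flattens and EM can
  # declare convergence with a variance still drifting toward zero; a short
  # bounded L-BFGS run from the EM solution pins the stationary point
  obj <- function(theta) {
    s2 <- exp(theta)
    -mme_eval(s2[seq_len(nK)], s2[nK + seq_len(ngrp)])$ll
  }
  pol <- tryCatch(
    stats::optim(log(c(s2k, s2g)), obj, method = "L-BFGS-B",
                 lower = log(floorv), upper = log(1e6 * vy),
                 control = list(maxit = 100)),
    error = function(e) NULL)
  if (!is.null(pol) && -pol$value >= ll_trace[length(ll_trace)] - 1e-9) {
    s2 <- exp(pol$par)
    s2k <- s2[seq_len(nK)]; s2g <- s2[nK + seq_len(ngrp)]
  }
  # boundary snap: a random-term variance drifting toward zero flattens the
  # likelihood, so EM/L-BFGS stall above the boundary; if pinning it at the
  # floor costs (numerically) nothing, the boundary is the optimum
  ll_now <- mme_eval(s2k, s2g)$ll
  for (k in seq_len(nK)) {
    if (s2k[k] > floorv && s2k[k] < 1e-3 * vy) {
      s2_try <- s2k; s2_try[k] <- floorv
      if (mme_eval(s2_try, s2g)$ll >= ll_now - 5e-8) {
        s2k <- s2_try
        ll_now <- mme_eval(s2k, s2g)$ll
      }
    }
  }
  state <- mme_eval(s2k, s2g)
  ll <- state$ll
  ll_trace <- c(ll_trace, ll)
  sol <- state$sol; Cinv <- state$Cinv
  labels <- vapply(random, `[[`, "", "label")
  u <- lapply(seq_len(nK), function(k) {
    uk <- drop(sol[idx[[k + 1L]]])
    names(uk) <- colnames(Zs[[k]])
    uk
  })
  names(u) <- labels
  sigma2 <- c(stats::setNames(s2k, labels),
              stats::setNames(s2g, paste0("residual",
                                          if (ngrp > 1) paste0(".", levels(resid_groups)) else "")))
  sigma2[sigma2 <= floorv] <- 0
  beta <- drop(sol[idx[[1L]]]); names(beta) <- colnames(X)
  beta_cov <- Cinv[idx[[1L]], idx[[1L]], drop = FALSE]
  dimnames(beta_cov) <- list(colnames(X), colnames(X))
  structure(list(sigma2 = sigma2, loglik = ll, loglik_trace = ll_trace,
                 converged = converged, iterations = length(ll_trace),
                 beta = beta, beta_cov = beta_cov,
                 u = u, residuals = y - drop(W %*% sol),
                 n = n, rank_X = p, q_random = sum(qk), engine = "em"),
            class = "reml_fit")
}

# profiled REML over the variance ratio for one random term + iid residual
reml_eigen_profiled <- function(y, X, term, tol) {
  n <- length(y); p <- ncol(X)
  Z <- as.matrix(term$Z)
  A <- if (is.null(term$cov)) diag(ncol(Z)) else as.matrix(term$cov)
  M <- Z %*% A %*% t(Z)
  M <- sym(M) + diag(1e-6 * mean(diag(M)), n)
  e <- eigen(M, symmetric = TRUE)
  U <- e$vectors; lam <- pmax(e$values, 0)
  yt <- crossprod(U, y); Xt <- crossprod(U, X)
  prof <- function(loggamma) {
    g <- exp(loggamma)
    d <- 1 + g * lam
    XtD <- Xt / d
    XX <- crossprod(Xt, XtD)
    ch <- chol(XX)
    beta <- backsolve(ch, forwardsolve(t(ch), crossprod(XtD, yt)))
    r <- yt - Xt %*% beta
    rss <- sum(r^2 / d)
    s2e <- rss / (n - p)
    -0.5 * (sum(log(d)) + 2 * sum(log(diag(ch))) + (n - p) * (log(s2e) + 1))
  }
  opt <- stats::optimize(prof, c(-25, 25), maximum = TRUE, tol = 1e-10)
  g <- exp(opt$maximum)
  d <- 1 + g * lam
  XtD <- Xt / d
  XX <- crossprod(Xt, XtD)
  XXinv <- chol2inv(chol(XX))
  beta <- drop(XXinv %*% crossprod(XtD, yt))
  r <- yt - Xt %*% beta
  s2e <- sum(r^2 / d) / (n - p)
  s2u <- g * s2e
  # BLUP of the term: u_hat = s2u * A Z' V^-1 (y - X beta)
  Vinvr <- U %*% (r / d) / s2e
  uhat <- s2u * drop(A %*% crossprod(Z, Vinvr))
  names(uhat) <- colnames(Z)
  names(beta) <- colnames(X)
  beta_cov <- XXinv * s2e
  dimnames(beta_cov) <- list(colnames(X), colnames(X))
  sigma2 <- c(s2u, s2e)
  names(sigma2) <- c(term$label %||% "u1", "residual")
  structure(list(sigma2 = sigma2, loglik = opt$objective, loglik_trace = opt$objective,
                 converged = TRUE, iterations = 1L,
                 beta = beta, beta_cov = beta_cov,
                 u = stats::setNames(list(uhat), term$label %||% "u1"),
                 residuals = y - drop(X %*% beta) - drop(Z %*% uhat),
                 alpha = drop(Vinvr), n = n, rank_X = ncol(X),
                 q_random = ncol(Z), engine = "eigen"),
            class = "reml_fit")
}

#' @export
print.reml_fit <- function(x, ...) {
  cat("<reml_fit>", x$engine, "engine; logLik", format(x$loglik, digits = 8),
      if (!x$converged) "(NOT converged)" else "", "\n")
  print(round(x$sigma2, 6))
  invisible(x)
}

#' Extract BLUP random-effect solutions
#'
#' Solutions come from the mixed-model equations at the REML estimates;
#' individuals present in the covariance structure but without records are
#' predicted through their covariance rows (the genomic-prediction case),
#' because their incidence columns are zero but their `K` rows couple them to
#' the phenotyped set.
#'
#' @param fit A `reml_fit`.
#' @param term Label of the random term (default: the first).
#' @return Named numeric vector of BLUPs.
#' @export
blup <- function(fit, term = NULL) {
  stopifnot(inherits(fit, "reml_fit"))
  term <- term %||% names(fit$u)[1]
  if (!term %in% names(fit$u)) stop("no random term labelled ", term)
  fit$u[[term]]
}

#' Univariate GBLUP with genomic prediction
#'
#' Fits `y = X beta + u + e`, `u ~ N(0, sigma_u^2 K)`, on the phenotyped
#' individuals by profiled REML and predicts breeding values for every
#' individual in `K`.
#'
#' @param y Named response vector (names = individual ids) or plain vector
#'   with `ids` supplied.
#' @param K Kinship matrix covering at least the phenotyped individuals.
#' @param X Optional fixed-effect design for the phenotyped records.
#' @param ids Individual id per record (defaults to `names(y)`).
#' @return List with `fit` (a `reml_fit`), `gebv` (named vector over all ids
#'   in `K`), and `h2_hat` (the model-based ratio
#'   `sigma_u^2 / (sigma_u^2 + sigma_e^2)`).
#' @export
gblup <- function(y, K, X = NULL, ids = NULL) {
  ids <- ids %||% names(y)
  if (is.null(ids)) stop("supply record ids via names(y) or ids=")
  K <- as.matrix(K)
  if (!all(ids %in% rownames(K))) stop("K does not cover all phenotyped ids")
  obs <- unique(ids)
  Z <- outer(ids, obs, `==`) * 1
  colnames(Z) <- obs
  spec <- model_spec(y, X, random = list(list(Z = Z, cov = K[obs, obs], label = "genetic")))
  fit <- reml_fit(spec, engine = "eigen")
  s2u <- fit$sigma2[["genetic"]]
  gebv <- drop(s2u * K[, obs, drop = FALSE] %*% fit$alpha)
  names(gebv) <- rownames(K)
  list(fit = fit, gebv = gebv,
       h2_hat = s2u / (s2u + fit$sigma2[["residual"]]))
}

#' Wald F test for a single fixed-effect coefficient
#'
#' `F = (beta_hat / SE)^2` with 1 numerator degree of freedom; denominator
#' degrees of freedom by the containment approximation
#' `n - rank(X) - (number of random-effect levels used)`.
#'
#' @param fit A `reml_fit`.
#' @param coefficient Name of the coefficient in the fixed-effect design.
#' @return List with `F`, `ddf`, `p`, `estimate`, `se`.
#' @export
wald_f <- function(fit, coefficient) {
  stopifnot(inherits(fit, "reml_fit"))
  if (!coefficient %in% names(fit$beta))
    stop("coefficient ", coefficient, " not in the fitted fixed effects (aliased or absent)")
  est <- fit$beta[[coefficient]]
  se <- sqrt(fit$beta_cov[coefficient, coefficient])
  Fstat <- (est / se)^2
  ddf <- max(fit$n - fit$rank_X - fit$q_random, 1)
  list(F = Fstat, ddf = ddf,
       p = stats::pf(Fstat, 1, ddf, lower.tail = FALSE),
       estimate = est, se = se)
}
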