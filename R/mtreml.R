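#' Multi-trait GBLUP REML fit
#'
#' Fits the multi-trait GBLUP model `y = Xb + Zu + e` with
#' `u ~ N(0, K (x) G)` and `e ~ N(0, I (x) R)` by EM-REML, with a separate
#' fixed environment effect per trait. `G` may be unstructured or constrained
#' diagonal (the reduced model of the genetic-covariance likelihood-ratio
#' test). Two record levels are supported:
#'
#' * `level = "plant_mean"`: the response is the per-plant mean of fruit
#'   records (the parameter-estimation model for genetic correlations);
#' * `level = "fruit"`: individual fruit records (the selection model). This
#'   is handled by an exact reduction: scaling plant means by the square root
#'   of the fruit count turns the covariance into `Ktilde (x) G + I (x) R`
#'   plus an independent within-plant Wishart part on `R`, so the EM runs in
#'   the eigenbasis of `Ktilde` at per-plant cost.
#'
#' Records missing any of the requested traits are dropped for the fit.
#' `G` is bent back into the PSD cone (eigenvalue clip at `1e-6 * trace`)
#' whenever an EM step exits it.
#'
#' @param records Phenotype records (`plant`, `site`, `fruit`, trait columns).
#' @param traits Character vector of 2-3 trait names.
#' @param K Kinship matrix with ids covering the phenotyped plants.
#' @param structure `"unstructured"` or `"diagonal"` genetic covariance.
#' @param level `"plant_mean"` or `"fruit"`.
#' @param env_fixed Fit site as a fixed environment effect (default `TRUE`).
#' @param tol Convergence tolerance on the restricted log-likelihood change.
#' @param maxit Maximum EM iterations (non-convergence is flagged, never
#'   silent).
#' @return An object of class `trait_cov` with elements `G`, `R`, `B`,
#'   `structure`, `loglik`, `n_params`, `converged`, `iterations`, and the
#'   prediction kernel used by [mt_blup()].
#' @export
mt_reml_fit <- function(records, traits, K, structure = c("unstructured", "diagonal"),
                        level = c("plant_mean", "fruit"), env_fixed = TRUE,
                        tol = 1e-8, maxit = 1000) {
  structure <- match.arg(structure)
  level <- match.arg(level)
  T_ <- length(traits)
  if (T_ < 2 || T_ > 3) stop("mt_reml_fit supports 2 or 3 traits")
  if (!all(traits %in% names(records))) stop("trait column(s) missing from records")
  rec <- records[stats::complete.cases(records[traits]), , drop = FALSE]
  if (nrow(rec) == 0L) stop("no records complete for all requested traits")
  for (tr in traits)
    if (stats::var(rec[[tr]]) <= 0) stop("trait ", tr, " has zero variance")
  plants <- sort(unique(rec$plant))
  if (!all(plants %in% rownames(K))) stop("K does not cover all phenotyped plants")
  m <- length(plants)

  agg <- function(tr) tapply(rec[[tr]], factor(rec$plant, levels = plants), mean)
  Ybar <- sapply(traits, agg)
  n_i <- as.vector(table(factor(rec$plant, levels = plants)))
  site_of <- tapply(as.character(rec$site), factor(rec$plant, levels = plants),
                    function(s) s[1])
  X <- if (env_fixed && length(unique(site_of)) > 1L)
    stats::model.matrix(~ factor(site_of)) else matrix(1, m, 1)

  Ksub <- as.matrix(K)[plants, plants]
  ridge <- 1e-6 * mean(diag(Ksub))
  Ksub <- Ksub + diag(ridge, m)

  if (level == "fruit") {
    SSW <- matrix(0, T_, T_)
    ymat <- as.matrix(rec[traits])
    pl <- factor(rec$plant, levels = plants)
    centered <- ymat - Ybar[as.integer(pl), , drop = FALSE]
    SSW <- crossprod(centered)
    nu <- nrow(rec) - m
    dh <- sqrt(n_i)
    Z <- dh * Ybar                      # z_i = sqrt(n_i) * ybar_i
    Kt <- outer(dh, dh) * Ksub
    Xz <- dh * X
  } else {
    SSW <- matrix(0, T_, T_); nu <- 0
    dh <- rep(1, m)
    Z <- Ybar; Kt <- Ksub; Xz <- X
  }
  e <- eigen(Kt, symmetric = TRUE)
  U <- e$vectors; lambda <- pmax(e$values, 0)
  Yt <- crossprod(U, Z)
  Xt <- crossprod(U, Xz)

  v0 <- diag(stats::cov(Ybar))
  G0 <- diag(0.5 * v0, T_); R0 <- diag(0.5 * pmax(v0, 1e-8), T_)
  fit <- .mt_em_core(Yt, Xt, lambda, SSW, nu, structure == "diagonal",
                     tol, as.integer(maxit), G0, R0)
  if (!fit$converged)
    warning("mt_reml_fit did not converge in ", maxit, " EM iterations")
  G <- sym(fit$G); R <- sym(fit$R)
  dimnames(G) <- dimnames(R) <- list(traits, traits)
  n_params <- if (structure == "diagonal") T_ else T_ * (T_ + 1) / 2
  structure(list(G = G, R = R, B = fit$B, structure = structure,
                 loglik = fit$loglik, loglik_trace = fit$loglik_trace,
                 n_params = n_params + T_ * (T_ + 1) / 2,  # + free params of R
                 converged = fit$converged, iterations = fit$iterations,
                 traits = traits, level = level,
                 pred = list(ids = plants, M = (dh * U) %*% fit$S)),
            class = "trait_cov")
}

#' @export
print.trait_cov <- function(x, ...) {
  cat("<trait_cov>", x$structure, "G;", length(x$traits), "traits;",
      "logLik", format(x$loglik, digits = 8),
      if (!x$converged) "(NOT converged)" else "", "\n")
  cat("G:\n"); print(round(x$G, 4))
  cat("R:\n"); print(round(x$R, 4))
  invisible(x)
}

#' GEBVs from a multi-trait GBLUP fit
#'
#' Predicts breeding values for any individuals covered by `K`, including
#' unphenotyped ones, through their kinship rows with the phenotyped set
#' (`u_hat = K[new, obs] %*% kernel`).
#'
#' @param fit A `trait_cov` from [mt_reml_fit()].
#' @param K Kinship covering the wanted and the phenotyped individuals.
#' @param ids Individuals to predict (default: all rows of `K`).
#' @return Matrix individuals x traits of GEBVs.
#' @export
mt_blup <- function(fit, K, ids = NULL) {
  obs <- fit$pred$ids
  K <- as.matrix(K)
  ids <- ids %||% rownames(K)
  if (!all(obs %in% colnames(K))) stop("K lacks columns for the phenotyped set")
  if (!all(ids %in% rownames(K))) stop("K lacks rows for requested ids")
  BV <- K[ids, obs, drop = FALSE] %*% fit$pred$M
  dimnames(BV) <- list(ids, fit$traits)
  BV
}

#' Likelihood-ratio test for nested REML fits
#'
#' `statistic = 2 * (logLik_full - logLik_reduced)`; degrees of freedom are
#' the difference in free covariance parameters (1 for a single genetic
#' covariance in a bivariate model); p-value from the chi-square upper tail.
#'
#' @param full,reduced `trait_cov` fits of the same data, reduced nested in
#'   full.
#' @param df Override for the degrees of freedom.
#' @return List with `statistic`, `df`, `p`.
#' @export
lrt <- function(full, reduced, df = NULL) {
  stat <- 2 * (full$loglik - reduced$loglik)
  if (stat < -1e-6)
    stop("full-model likelihood below reduced-model likelihood: optimizer failure")
  stat <- max(stat, 0)
  df <- df %||% (full$n_params - reduced$n_params)
  if (df <= 0) stop("reduced model is not nested with fewer parameters")
  list(statistic = stat, df = df, p = stats::pchisq(stat, df, lower.tail = FALSE))
}
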