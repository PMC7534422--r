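#' Repeatability and narrow-sense heritability from variance components
#'
#' `t = (s2u + s2p) / (s2u + s2p + s2e)`; `h2 = s2u / (s2u + s2p + s2e)`.
#'
#' @param varcomp A `varcomp` fit or a numeric vector/list with elements
#'   `sigma_u2`, `sigma_p2`, `sigma_e2`.
#' @return List with `t` and `h2`.
#' @export
repeatability_heritability <- function(varcomp) {
  s <- c(varcomp$sigma_u2 %||% varcomp[["sigma_u2"]],
         varcomp$sigma_p2 %||% varcomp[["sigma_p2"]],
         varcomp$sigma_e2 %||% varcomp[["sigma_e2"]])
  if (any(s < 0)) stop("variance components must be non-negative")
  total <- sum(s)
  if (total <= 0) stop("all variance components are zero")
  list(t = (s[1] + s[2]) / total, h2 = s[1] / total)
}

#' Gain in accuracy from repeated measures
#'
#' `Delta_r = sqrt(1 / (t + (1 - t) / n))`: the accuracy ratio of selecting on
#' the mean of `n` repeated measures relative to a single measure. It is 1 at
#' `n = 1`, non-decreasing in `n`, and approaches `1 / sqrt(t)` as `n` grows.
#' The non-radical variant `1 / (t + (1 - t)/n)` (the squared ratio) is
#' exposed behind `radical = FALSE` for comparison.
#'
#' @param t Repeatability in `(0, 1]`.
#' @param n Number of repeated measures (>= 1); may be `Inf` if `t > 0`.
#' @param radical Return the accuracy ratio (default) rather than its square.
#' @return Numeric gain factor.
#' @export
accuracy_gain <- function(t, n, radical = TRUE) {
  stopifnot(all(t > 0), all(t <= 1), all(n >= 1))
  if (any(!is.finite(n)) && any(t == 0)) stop("t = 0 with infinite n is undefined")
  ratio2 <- 1 / (t + (1 - t) / n)
  if (radical) sqrt(ratio2) else ratio2
}

#' Maximum predictive ability expected from phenotypic selection
#'
#' The regression of true breeding value on phenotype has correlation
#' `sqrt(h2)`; this benchmarks genomic prediction models.
#'
#' @param h2 Narrow-sense heritability in `[0, 1]`.
#' @param digits Rounding (half-up) applied when building summary tables;
#'   `NULL` for the raw value.
#' @return `sqrt(h2)`, optionally rounded.
#' @export
pa_max <- function(h2, digits = NULL) {
  if (any(h2 < 0 | h2 > 1)) stop("h2 must lie in [0, 1]")
  out <- sqrt(h2)
  if (!is.null(digits)) out <- round_half_up(out, digits)
  out
}

#' Record weight for heterogeneous error variance of repeated-measure means
#'
#' `w = (1 - h2) / (c * h2 + (1 + (n - 1) t) / n - h2)` with `c` the
#' proportion of genetic variance captured by markers. Weights are positive
#' and strictly decreasing in `c`.
#'
#' @param h2 Heritability, `0 < h2 <= t`.
#' @param t Repeatability, `h2 <= t < 1`.
#' @param n Number of measurements (>= 1).
#' @param c Proportion of variance explained by markers, in `(0, 1)`.
#' @return Numeric weight.
#' @export
record_weight <- function(h2, t, n, c) {
  stopifnot(all(h2 > 0), all(h2 <= t), all(t < 1), all(n >= 1),
            all(c > 0), all(c < 1))
  denom <- c * h2 + (1 + (n - 1) * t) / n - h2
  if (any(denom <= 0)) stop("non-positive denominator in record weight")
  (1 - h2) / denom
}

#' Heritability of a linear selection index
#'
#' `h2_I = (b' G b) / (b' P b)` with `G`, `P` the genetic and phenotypic
#' covariance matrices of the component traits and `b` the index weights.
#'
#' @param G Genetic covariance matrix (symmetric).
#' @param P Phenotypic covariance matrix (symmetric positive definite).
#' @param b Index coefficient vector (nonzero).
#' @return Scalar index heritability.
#' @export
index_heritability <- function(G, P, b) {
  b <- as.numeric(b)
  if (all(b == 0)) stop("b must be nonzero")
  denom <- drop(crossprod(b, P %*% b))
  if (denom <= 0) stop("b' P b must be positive")
  drop(crossprod(b, G %*% b)) / denom
}

#' Environment-adjusted phenotypic correlations
#'
#' Each trait is regressed on environment indicators by least squares; the
#' residuals give pairwise Pearson correlations, with two-sided t-test
#' p-values and a Bonferroni adjustment over all pairs tested in the call.
#'
#' @param records Phenotype records with trait columns.
#' @param traits Trait names.
#' @param env Column name carrying the environment label (default `"site"`).
#' @param use_plant_means Correlate per-plant means (default) rather than raw
#'   rows, so repeated fruit on a plant do not inflate the sample size.
#' @return List with matrices `r` (correlations), `p` (raw p-values),
#'   `p_adj` (Bonferroni), `n` (pair counts), and `m_tests`.
#' @export
env_adjusted_pearson <- function(records, traits, env = "site",
                                 use_plant_means = TRUE) {
  stopifnot(all(traits %in% names(records)), env %in% names(records))
  dat <- records
  if (use_plant_means) {
    sp <- split(dat, dat$plant)
    dat <- do.call(rbind, lapply(sp, function(d) {
      out <- d[1, c("plant", env), drop = FALSE]
      for (tr in traits) out[[tr]] <- mean(d[[tr]], na.rm = TRUE)
      out
    }))
  }
  ef <- factor(dat[[env]])
  resid_mat <- sapply(traits, function(tr) {
    y <- dat[[tr]]
    ok <- !is.na(y)
    r <- rep(NA_real_, length(y))
    if (length(unique(ef[ok])) > 1L)
      r[ok] <- stats::residuals(stats::lm(y ~ ef, subset = ok))
    else r[ok] <- y[ok] - mean(y[ok])
    r
  })
  T_ <- length(traits)
  rmat <- pmat <- nmat <- matrix(NA_real_, T_, T_, dimnames = list(traits, traits))
  diag(rmat) <- 1
  for (i in seq_len(T_ - 1)) for (j in (i + 1):T_) {
    ok <- stats::complete.cases(resid_mat[, c(i, j)])
    n <- sum(ok)
    if (n < 3) next
    xi <- resid_mat[ok, i]; xj <- resid_mat[ok, j]
    if (stats::sd(xi) == 0 || stats::sd(xj) == 0) next  # undefined, left NA
    ct <- stats::cor.test(xi, xj)
    rmat[i, j] <- rmat[j, i] <- unname(ct$estimate)
    pmat[i, j] <- pmat[j, i] <- ct$p.value
    nmat[i, j] <- nmat[j, i] <- n
  }
  m_tests <- T_ * (T_ - 1) / 2
  padj <- pmin(pmat * m_tests, 1)
  list(r = rmat, p = pmat, p_adj = padj, n = nmat, m_tests = m_tests)
}

#' Genetic correlation from a bivariate REML fit
#'
#' `r_g = G12 / sqrt(G11 * G22)` from the unstructured fit; significance is
#' the likelihood-ratio test of unstructured vs diagonal genetic covariance.
#'
#' @param tc_full Unstructured `trait_cov` fit (2 traits).
#' @param tc_diag Optional diagonal fit of the same data for the LRT.
#' @return List with `r_g` and, when `tc_diag` is given, `lrt`.
#' @export
genetic_correlation <- function(tc_full, tc_diag = NULL) {
  G <- tc_full$G
  if (nrow(G) != 2) stop("genetic_correlation expects a bivariate fit")
  if (any(diag(G) <= 0)) stop("zero genetic variance: correlation undefined")
  rg <- G[1, 2] / sqrt(G[1, 1] * G[2, 2])
  rg <- max(min(rg, 1), -1)
  out <- list(r_g = rg)
  if (!is.null(tc_diag)) out$lrt <- lrt(tc_full, tc_diag)
  out
}

#' Pooled parameter summary table
#'
#' Per-trait repeatability, narrow-sense heritability and the phenotypic-
#' selection benchmark `PAmax = sqrt(h2)`, rounded half-up to 2 decimals.
#'
#' @param fits Named list of `varcomp` fits (one per trait).
#' @return data.frame with columns `trait`, `h2`, `t`, `PAmax`.
#' @export
param_table <- function(fits) {
  rows <- lapply(names(fits), function(tr) {
    f <- fits[[tr]]
    data.frame(trait = tr, h2 = round_half_up(f$h2, 2), t = round_half_up(f$t, 2),
               PAmax = pa_max(f$h2, digits = 2))
  })
  do.call(rbind, rows)
}
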