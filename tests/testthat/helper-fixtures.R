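# Shared small fixtures, built once per test run.

# A 150-plant F2 with two correlated traits, repeated fruit records, and its GRM.
fx_pop2 <- local({
  map <- make_map(200, 5, 100)
  founders <- make_founders(map)
  pop <- make_f2_population(founders, 150, map, seed = 101)
  arch <- assign_architecture(pop, h2 = c(A = 0.25, B = 0.25),
                              t = c(A = 0.55, B = 0.55),
                              G_corr = matrix(c(1, 0.7, 0.7, 1), 2),
                              seed = 102)
  records <- simulate_records(pop, arch, seed = 103)
  K <- vanraden_grm(pop_dosage(pop))
  list(map = map, pop = pop, arch = arch, records = records, K = K)
})

# Hand-constructed 10 x 10 QC fixture: individual 1 is 50% missing,
# marker 10 monomorphic, everything else clean and polymorphic.
fx_qc_geno <- local({
  set.seed(77)
  D <- matrix(rbinom(100, 2, 0.5), 10, 10)
  D[, 10] <- 2
  D[1, 1:5] <- NA
  # keep remaining markers polymorphic after dropping individual 1
  for (j in 1:9) if (length(unique(D[2:10, j])) == 1) D[2, j] <- (D[3, j] + 1) %% 3
  geno_matrix(sprintf("i%02d", 1:10), NULL, D)
})

# Deterministic 20-record instance for restricted-likelihood oracles.
# The individuals are one F2 family, so the kinship has real structure and
# the variance ratio is well identified (interior optimum).
fx_oracle <- local({
  omap <- make_map(60, 3, 80)
  opop <- make_f2_population(make_founders(omap), 20, omap, seed = 550)
  K <- vanraden_grm(pop_dosage(opop))
  set.seed(55)
  Ku <- unclass(K)
  Ks <- (Ku + t(Ku)) / 2 + diag(1e-4 * mean(diag(Ku)), 20)
  # strong genetic signal so the tiny instance has a clearly interior REML
  # optimum (a boundary optimum would make grid agreement ill-defined)
  u <- drop(crossprod(chol(Ks), rnorm(20))) * sqrt(2)
  y <- 1 + u + rnorm(20, 0, sqrt(0.4))
  names(y) <- opop$ids
  list(K = K, y = y)
})

# Dense-matrix restricted log-likelihood for y = mu + u + e, u ~ N(0, s2u*K):
# the independent oracle used against the REML engines.
oracle_remlik <- function(y, K, s2u, s2e) {
  n <- length(y)
  V <- s2u * as.matrix(K) + diag(s2e, n)
  X <- matrix(1, n, 1)
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) return(-Inf)
  Vi <- chol2inv(ch)
  XtVX <- crossprod(X, Vi %*% X)
  beta <- solve(XtVX, crossprod(X, Vi %*% y))
  r <- y - drop(X %*% beta)
  -0.5 * (2 * sum(log(diag(ch))) + log(XtVX[1, 1]) + drop(crossprod(r, Vi %*% r)))
}
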