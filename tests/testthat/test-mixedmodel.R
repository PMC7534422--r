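test_that("EM-REML equals closed-form ANOVA estimators in a balanced one-way layout", {
  set.seed(201)
  ngrp <- 10; nrep <- 5
  grp <- factor(rep(seq_len(ngrp), each = nrep))
  u <- rnorm(ngrp, 0, sqrt(2))
  y <- 5 + u[grp] + rnorm(ngrp * nrep, 0, 1)
  Z <- stats::model.matrix(~ 0 + grp)
  spec <- model_spec(y, NULL, random = list(list(Z = Z, cov = NULL, label = "grp")))
  fit <- reml_fit(spec, engine = "em", tol = 1e-12)
  msb <- summary(stats::aov(y ~ grp))[[1]]$`Mean Sq`
  s2e_anova <- msb[2]
  s2u_anova <- (msb[1] - msb[2]) / nrep
  expect_equal(unname(fit$sigma2[["grp"]]), s2u_anova, tolerance = 1e-6)
  expect_equal(unname(fit$sigma2[["residual"]]), s2e_anova, tolerance = 1e-6)
})

test_that("EM-REML restricted log-likelihood is monotone non-decreasing", {
  set.seed(202)
  y <- fx_oracle$y
  obs <- names(y)
  Z <- diag(length(y)); colnames(Z) <- obs
  spec <- model_spec(y, NULL,
                     random = list(list(Z = Z, cov = as.matrix(fx_oracle$K),
                                        label = "g")))
  fit <- reml_fit(spec, engine = "em")
  expect_true(all(diff(fit$loglik_trace) > -1e-7))
})

test_that("eigen-profiled and generic EM solvers agree on random instances", {
  set.seed(203)
  for (i in 1:10) {
    n <- 25
    D <- matrix(rbinom(n * 50, 2, 0.5), n, 50,
                dimnames = list(sprintf("x%02d", 1:n), NULL))
    K <- vanraden_grm(D)
    Ku <- unclass(K); Ks <- (Ku + t(Ku)) / 2 + diag(1e-4, n)
    u <- drop(crossprod(chol(Ks), rnorm(n))) * sqrt(0.4)
    y <- 2 + u + rnorm(n, 0, sqrt(0.6))
    Z <- diag(n); colnames(Z) <- rownames(D)
    spec <- model_spec(y, NULL, random = list(list(Z = Z, cov = Ku, label = "g")))
    fe <- reml_fit(spec, engine = "eigen")
    fm <- reml_fit(spec, engine = "em", tol = 1e-12, maxit = 50000)
    h2e <- fe$sigma2[["g"]] / sum(fe$sigma2)
    h2m <- fm$sigma2[["g"]] / sum(fm$sigma2)
    expect_lt(abs(h2e - h2m), 1e-4)
  }
})

test_that("REML optimum beats a grid of perturbed parameter points", {
  y <- fx_oracle$y
  K <- fx_oracle$K
  Z <- diag(length(y)); colnames(Z) <- names(y)
  spec <- model_spec(y, NULL, random = list(list(Z = Z, cov = as.matrix(K),
                                                 label = "g")))
  fit <- reml_fit(spec, engine = "eigen")
  s2u <- fit$sigma2[["g"]]; s2e <- fit$sigma2[["residual"]]
  ll_hat <- oracle_remlik(y, K, s2u, s2e)
  for (fu in c(0.5, 0.8, 1.25, 2)) {
    for (fe in c(0.5, 0.8, 1.25, 2, 1)) {
      if (fu == 1 && fe == 1) next
      expect_lte(oracle_remlik(y, K, s2u * fu, s2e * fe), ll_hat + 1e-6)
    }
  }
})

test_that("repeatability model recovers components and handles degenerate designs", {
  fx <- fx_pop2
  fit <- repeatability_fit(fx$records, "A", fx$K)
  expect_true(fit$converged)
  expect_true(all(c(fit$sigma_u2, fit$sigma_p2, fit$sigma_e2) >= 0))
  # modest n: only a loose sanity band on the point estimates
  expect_lt(abs(fit$t - 0.55), 0.15)
  expect_lt(abs(fit$h2 - 0.25), 0.25)
  # agreement with the generic EM engine (record-level MME) on a small subset
  plants <- fx$pop$ids[1:60]
  rec <- fx$records[fx$records$plant %in% plants, ]
  small <- repeatability_fit(rec, "A", fx$K)
  pl <- factor(rec$plant)
  Zp <- stats::model.matrix(~ 0 + pl)
  colnames(Zp) <- levels(pl)
  X <- stats::model.matrix(~ factor(rec$site))
  Ksub <- as.matrix(fx$K)[levels(pl), levels(pl)]
  spec <- model_spec(rec$A, X,
                     random = list(list(Z = Zp, cov = Ksub, label = "u"),
                                   list(Z = Zp, cov = NULL, label = "p")))
  em <- reml_fit(spec, engine = "em", tol = 1e-10, maxit = 3000)
  tot_em <- sum(em$sigma2)
  expect_lt(abs(small$h2 - em$sigma2[["u"]] / tot_em), 1e-3)
  expect_lt(abs(small$t - (em$sigma2[["u"]] + em$sigma2[["p"]]) / tot_em), 1e-3)
  # all plants single-fruit: permanent environment inestimable
  one <- fx$records[!duplicated(fx$records$plant), ]
  one$fruit <- 1L
  expect_error(repeatability_fit(one, "A", fx$K), "confounded")
})

test_that("duplicating every fruit shrinks the residual but not the plant-level variance", {
  fx <- fx_pop2
  fit1 <- repeatability_fit(fx$records, "A", fx$K)
  dup <- rbind(fx$records, transform(fx$records, fruit = fruit + 100L))
  fit2 <- repeatability_fit(dup, "A", fx$K)
  expect_lt(fit2$sigma_e2, fit1$sigma_e2)
  plant_level1 <- fit1$sigma_u2 + fit1$sigma_p2
  plant_level2 <- fit2$sigma_u2 + fit2$sigma_p2
  expect_lt(abs(plant_level2 - plant_level1) / plant_level1, 0.10)
})

test_that("multi-trait REML: nesting, independence, and convergence flags", {
  fx <- fx_pop2
  full <- mt_reml_fit(fx$records, c("A", "B"), fx$K, level = "plant_mean")
  diag_fit <- mt_reml_fit(fx$records, c("A", "B"), fx$K,
                          structure = "diagonal", level = "plant_mean")
  expect_lte(diag_fit$loglik, full$loglik + 1e-6)
  expect_identical(diag_fit$G[1, 2], 0)
  expect_true(isSymmetric(full$G, tol = 1e-10))
  expect_true(isSymmetric(full$R, tol = 1e-10))
  expect_true(all(eigen(full$G, only.values = TRUE)$values > -1e-8))
  # traits simulated with r_g = 0.7: the unstructured fit sees a positive
  # genetic covariance
  expect_gt(genetic_correlation(full)$r_g, 0.2)
  # zero-variance trait rejected
  rec0 <- fx$records; rec0$B <- 1
  expect_error(mt_reml_fit(rec0, c("A", "B"), fx$K), "zero variance")
})

test_that("independently generated traits give near-zero genetic correlation", {
  map <- make_map(150, 5, 90)
  f <- make_founders(map)
  pop <- make_f2_population(f, 250, map, seed = 211)
  arch <- assign_architecture(pop, h2 = c(A = 0.3, B = 0.3),
                              t = c(A = 0.55, B = 0.55), G_corr = diag(2),
                              seed = 212)
  rec <- simulate_records(pop, arch, seed = 213)
  Kp <- vanraden_grm(pop_dosage(pop))
  fit <- mt_reml_fit(rec, c("A", "B"), Kp, level = "plant_mean")
  rg <- genetic_correlation(fit)$r_g
  expect_lt(abs(rg), 3 / sqrt(250) * 3)  # generous 3-SE-style band
})

test_that("likelihood-ratio test identities", {
  fx <- fx_pop2
  full <- mt_reml_fit(fx$records, c("A", "B"), fx$K, level = "plant_mean")
  same <- lrt(full, full, df = 1)
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)
  expect_equal(stats::pchisq(3.84, 1, lower.tail = FALSE),
               lrt(list(loglik = 1.92, n_params = 5),
                   list(loglik = 0, n_params = 4))$p,
               tolerance = 1e-3)
  expect_error(lrt(list(loglik = -5, n_params = 5),
                   list(loglik = 0, n_params = 4)), "optimizer failure")
})

test_that("GBLUP shrinks to the mean and preserves ranking under K = I", {
  set.seed(221)
  n <- 40
  ids <- sprintf("i%02d", 1:n)
  K <- diag(n); dimnames(K) <- list(ids, ids)
  y <- rnorm(n, 10, 1)
  g <- gblup(stats::setNames(y, ids), K)
  # with K = I and an intercept, GEBV ranking equals ranking of centered y
  # (uniform shrinkage preserves order)
  expect_equal(order(g$gebv[ids]), order(y))
  # translation equivariance on an identified (kinship-structured) model:
  # adding a constant moves only the intercept, not the predictions
  yk <- fx_oracle$y
  gk <- gblup(yk, fx_oracle$K)
  gk2 <- gblup(yk + 7, fx_oracle$K)
  expect_equal(unname(gk2$gebv), unname(gk$gebv), tolerance = 1e-5)
  expect_equal(gk2$h2_hat, gk$h2_hat, tolerance = 1e-5)
})

test_that("genomic prediction of unphenotyped individuals correlates with true BVs", {
  fx <- fx_pop2
  u <- true_breeding_values(fx$pop, fx$arch)
  means <- tapply(fx$records$A, factor(fx$records$plant, levels = fx$pop$ids), mean)
  train <- fx$pop$ids[1:100]
  test <- fx$pop$ids[101:150]
  g <- gblup(stats::setNames(means[train], train), fx$K)
  ct <- stats::cor.test(g$gebv[test], u[match(test, fx$pop$ids), "A"])
  expect_gt(ct$estimate, 0)
  expect_lt(ct$p.value, 0.01)
  # near-zero heritability: GEBVs shrink toward zero
  set.seed(222)
  noise <- rnorm(100)
  g0 <- gblup(stats::setNames(noise, train), fx$K)
  expect_lt(stats::sd(g0$gebv), 0.25 * stats::sd(noise))
})

test_that("Wald F is zero for a null coefficient and scale-free", {
  tr <- simulate_gain_trial(gain_per_cycle = 0.4, seed = 231)
  gf <- suppressWarnings(gain_model_fit(tr))
  tr2 <- tr; tr2$y <- tr2$y * 2
  gf2 <- suppressWarnings(gain_model_fit(tr2))
  expect_equal(gf$F, gf2$F, tolerance = 1e-3)
  expect_equal(gf2$slope, 2 * gf$slope, tolerance = 1e-3)
  # orthogonalized response: slope exactly zero => F = 0, p = 1
  spec_x <- cbind(1, x = c(-1, 0, 1, -1, 0, 1))
  y0 <- c(1, 1, 1, 2, 2, 2)
  spec <- model_spec(y0, spec_x)
  f0 <- reml_fit(spec, engine = "em")
  w <- wald_f(f0, "x")
  expect_equal(w$F, 0, tolerance = 1e-10)
  expect_equal(w$p, 1, tolerance = 1e-8)
  expect_error(wald_f(f0, "nonexistent"), "not in the fitted")
})
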