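#' Predictive ability
#'
#' Pearson correlation between predicted GEBVs and the (masked) truth values
#' of validation individuals.
#'
#' @param gebv,truth Numeric vectors (>= 3 pairs, both non-constant).
#' @return Pearson correlation.
#' @export
predictive_ability <- function(gebv, truth) {
  ok <- stats::complete.cases(gebv, truth)
  if (sum(ok) < 3) stop("fewer than 3 complete pairs")
  if (stats::sd(gebv[ok]) == 0 || stats::sd(truth[ok]) == 0) {
    warning("constant vector: predictive ability undefined")
    return(NA_real_)
  }
  stats::cor(gebv[ok], truth[ok])
}

plant_mean_table <- function(records, traits) {
  plants <- sort(unique(records$plant))
  pl <- factor(records$plant, levels = plants)
  out <- data.frame(plant = plants, stringsAsFactors = FALSE)
  for (tr in traits)
    out[[tr]] <- as.vector(tapply(records[[tr]], pl,
                                  function(v) mean(v, na.rm = TRUE)))
  out$site <- as.vector(tapply(as.character(records$site), pl, function(s) s[1]))
  out
}

train_predict_pa <- function(means, trait, K, train_ids, test_ids) {
  tr_rows <- means[means$plant %in% train_ids, ]
  y <- tr_rows[[trait]]
  ok <- !is.na(y)
  y <- y[ok]; tr_rows <- tr_rows[ok, ]
  X <- if (length(unique(tr_rows$site)) > 1L)
    stats::model.matrix(~ factor(tr_rows$site)) else NULL
  g <- gblup(stats::setNames(y, tr_rows$plant), K, X = X)
  truth <- means[[trait]][match(test_ids, means$plant)]
  pred <- g$gebv[test_ids]
  if (sum(stats::complete.cases(pred, truth)) < 3 ||
      stats::sd(truth, na.rm = TRUE) == 0)
    return(NA_real_)
  suppressWarnings(predictive_ability(pred, truth))
}

#' Within-set cross-validation
#'
#' Random 80/20 train/test partitions, repeated `reps` times; GBLUP is
#' trained on the training plants' phenotypes and predictive ability is the
#' Pearson correlation between GEBVs and the held-out truth values. The same
#' random partitions are reused across traits so trait PAs are comparable.
#' The truth value is the plant mean of fruit records.
#'
#' @param records Phenotype records.
#' @param traits Trait names.
#' @param K Kinship covering the phenotyped plants.
#' @param test_frac Held-out fraction (default 0.2).
#' @param reps Number of random partitions (default 50).
#' @param seed Integer seed.
#' @return data.frame `scheme, trait, rep, train_size, pa` (class
#'   `cv_result`); undefined-PA replicates carry `NA`.
#' @export
within_cv <- function(records, traits, K, test_frac = 0.2, reps = 50, seed = 1) {
  means <- plant_mean_table(records, traits)
  n <- nrow(means)
  if (n < 10) stop("fewer than 10 phenotyped plants")
  with_seed(seed, {
    folds <- lapply(seq_len(reps), function(r)
      sample(means$plant, ceiling(test_frac * n)))
    out <- list()
    for (r in seq_len(reps)) {
      test_ids <- folds[[r]]
      train_ids <- setdiff(means$plant, test_ids)
      for (tr in traits) {
        pa <- train_predict_pa(means, tr, K, train_ids, test_ids)
        out[[length(out) + 1L]] <- data.frame(
          scheme = "within", trait = tr, rep = r,
          train_size = length(train_ids), pa = pa)
      }
    }
    res <- do.call(rbind, out)
    class(res) <- c("cv_result", "data.frame")
    res
  })
}

#' Across-set cross-validation
#'
#' Merges the training and test genotype sets on common markers, computes a
#' joint kinship on the union, trains GBLUP on all training individuals and
#' predicts all test individuals (one PA per trait).
#'
#' @param geno_train,geno_test `geno_matrix` objects.
#' @param records_train,records_test Phenotype records of the two sets.
#' @param traits Trait names.
#' @return A `cv_result` data.frame with one row per trait.
#' @export
across_cv <- function(geno_train, records_train, geno_test, records_test, traits) {
  merged <- merge_common(geno_train, geno_test)
  K <- vanraden_grm(mean_impute(merged))
  means_tr <- plant_mean_table(records_train, traits)
  means_te <- plant_mean_table(records_test, traits)
  means <- rbind(means_tr, means_te)
  out <- lapply(traits, function(tr) {
    pa <- train_predict_pa(means, tr, K, means_tr$plant, means_te$plant)
    data.frame(scheme = "across", trait = tr, rep = 1L,
               train_size = nrow(means_tr), pa = pa)
  })
  res <- do.call(rbind, out)
  class(res) <- c("cv_result", "data.frame")
  res
}

#' Stratified cross-validation over training-set sizes
#'
#' Training composites draw an equal number of individuals from each set;
#' the test set draws `per_set_test` individuals per set from the remainder.
#' Repeated `reps` times per training size; results are indexed by total
#' training size.
#'
#' @param sets List of `list(geno = , records = )` per population set.
#' @param per_set_train Vector of per-set training draws to sweep.
#' @param traits Trait names.
#' @param per_set_test Test individuals per set (default 25; must be > 0).
#' @param reps Replicates per size (default 50).
#' @param seed Integer seed.
#' @return A `cv_result` data.frame.
#' @export
stratified_cv <- function(sets, per_set_train, traits, per_set_test = 25,
                          reps = 50, seed = 1) {
  if (per_set_test <= 0) stop("per_set_test must be positive")
  merged <- sets[[1]]$geno
  if (length(sets) > 1)
    for (s in 2:length(sets)) merged <- merge_common(merged, sets[[s]]$geno)
  K <- vanraden_grm(mean_impute(merged))
  means_by_set <- lapply(sets, function(s) plant_mean_table(s$records, traits))
  means <- do.call(rbind, means_by_set)
  for (s in seq_along(sets)) {
    avail <- nrow(means_by_set[[s]])
    if (max(per_set_train) + per_set_test > avail)
      stop("set ", s, " has only ", avail, " individuals; cannot draw ",
           max(per_set_train), " training + ", per_set_test, " test")
  }
  with_seed(seed, {
    out <- list()
    for (size in per_set_train) {
      for (r in seq_len(reps)) {
        train_ids <- test_ids <- character(0)
        for (s in seq_along(sets)) {
          ids_s <- means_by_set[[s]]$plant
          tr_s <- sample(ids_s, size)
          te_s <- sample(setdiff(ids_s, tr_s), per_set_test)
          train_ids <- c(train_ids, tr_s)
          test_ids <- c(test_ids, te_s)
        }
        for (tr in traits) {
          pa <- train_predict_pa(means, tr, K, train_ids, test_ids)
          out[[length(out) + 1L]] <- data.frame(
            scheme = "stratified", trait = tr, rep = r,
            train_size = length(train_ids), pa = pa)
        }
      }
    }
    res <- do.call(rbind, out)
    class(res) <- c("cv_result", "data.frame")
    res
  })
}

#' Apply Smith-Hazel weights to phenotypes
#'
#' Weighted sum of the component trait phenotypes per record; records missing
#' any component are dropped (count in attribute `"n_dropped"`).
#'
#' @param records Phenotype records.
#' @param b Named index weights (names = trait columns).
#' @return Numeric vector of index phenotypes, aligned to the retained rows
#'   (attribute `"rows"`).
#' @export
phenotypic_index <- function(records, b) {
  traits <- names(b)
  if (is.null(traits)) stop("b must be named by trait")
  stopifnot(all(traits %in% names(records)))
  M <- as.matrix(records[traits])
  ok <- stats::complete.cases(M)
  vals <- drop(M[ok, , drop = FALSE] %*% as.numeric(b))
  attr(vals, "rows") <- which(ok)
  attr(vals, "n_dropped") <- sum(!ok)
  vals
}

#' Simulate a multi-site realized-gain trial
#'
#' Generates plot-mean responses conforming to the gain model: random site
#' effects, block effects nested in site with per-site variances, plot
#' effects nested in block only at sites with intra-block replicates, a fixed
#' per-cycle gain on the numeric cycle covariate, and residuals with separate
#' variances per harvesting mode.
#'
#' @param gain_per_cycle True slope on the cycle covariate.
#' @param cycle_codes Numeric codes of the populations present (default
#'   `c(1, 2, 3, 5)`: base population, phenotypic cycle, one intermediate GS
#'   cycle and the final cycle).
#' @param n_sites Number of sites; the last site has no intra-block reps and
#'   uses the second harvesting mode.
#' @param blocks_per_site Blocks per site.
#' @param intrablock_reps Plots per block at the sites that declare them.
#' @param site_sd,block_sd,plot_sd,resid_sd Standard deviations; `block_sd`
#'   and `resid_sd` may be vectors (recycled per site / harvest mode).
#' @param mu Overall mean.
#' @param seed Integer seed.
#' @return data.frame `site, block, plot, cycle, harvest, y`.
#' @export
simulate_gain_trial <- function(gain_per_cycle = 0.5, cycle_codes = c(1, 2, 3, 5),
                                n_sites = 4, blocks_per_site = 3,
                                intrablock_reps = 2, site_sd = 0.3,
                                block_sd = c(0.2, 0.3), plot_sd = 0.15,
                                resid_sd = c(0.4, 0.5), mu = 10, seed = 1) {
  with_seed(seed, {
    rows <- list()
    s_eff <- stats::rnorm(n_sites, 0, site_sd)
    for (s in seq_len(n_sites)) {
      has_plots <- s < n_sites   # the last site lacks intra-block reps
      harvest <- if (s < n_sites) "fruit_mode" else "plant_mode"
      bsd <- block_sd[(s - 1) %% length(block_sd) + 1]
      rsd <- if (harvest == "fruit_mode") resid_sd[1] else resid_sd[length(resid_sd)]
      for (b in seq_len(blocks_per_site)) {
        b_eff <- stats::rnorm(1, 0, bsd)
        n_plots <- if (has_plots) intrablock_reps else 1L
        for (pl in seq_len(n_plots)) {
          p_eff <- if (has_plots) stats::rnorm(1, 0, plot_sd) else 0
          for (cc in cycle_codes) {
            y <- mu + s_eff[s] + b_eff + p_eff + gain_per_cycle * cc +
              stats::rnorm(1, 0, rsd)
            rows[[length(rows) + 1L]] <- data.frame(
              site = paste0("S", s), block = paste0("B", b),
              plot = if (has_plots) paste0("P", pl) else NA_character_,
              cycle = cc, harvest = harvest, y = y)
          }
        }
      }
    }
    do.call(rbind, rows)
  })
}

#' Fit the realized-gain mixed model
#'
#' `y = mu + site + block(site) + plot(block) + c * cycle + e` on plot means,
#' with random site, per-site block variances, plot effects only at sites
#' with intra-block replicates, the numeric cycle covariate as fixed effect,
#' and residual variances grouped by harvesting mode. The slope on `cycle`
#' estimates the average gain per cycle; its significance is the Wald F test.
#'
#' @param trial data.frame from [simulate_gain_trial()] or with the same
#'   columns (`site, block, plot, cycle, harvest`, response).
#' @param response Response column (default `"y"`).
#' @return List of class `gain_fit`: `slope`, `se`, `F`, `ddf`, `p`,
#'   `sigma2`, `fit`.
#' @export
gain_model_fit <- function(trial, response = "y") {
  stopifnot(all(c("site", "block", "cycle") %in% names(trial)))
  if (length(unique(trial$cycle)) < 2) stop("need at least 2 distinct cycle codes")
  within_site_var <- tapply(trial$cycle, trial$site, function(x) length(unique(x)))
  if (all(within_site_var < 2))
    stop("cycle is confounded with site: every site holds a single cycle")
  y <- trial[[response]]
  n <- length(y)
  X <- cbind("(Intercept)" = 1, cycle = trial$cycle)
  random <- list(list(Z = stats::model.matrix(~ 0 + factor(trial$site)),
                      cov = NULL, label = "site"))
  for (s in unique(trial$site)) {
    rows_s <- trial$site == s
    blocks <- unique(trial$block[rows_s])
    if (length(blocks) < 2) next
    Z <- sapply(blocks, function(b) as.numeric(rows_s & trial$block == b))
    colnames(Z) <- paste0(s, ".", blocks)
    random[[length(random) + 1L]] <- list(Z = Z, cov = NULL,
                                          label = paste0("block.", s))
  }
  if ("plot" %in% names(trial)) {
    for (s in unique(trial$site)) {
      rows_s <- trial$site == s & !is.na(trial$plot)
      if (!any(rows_s)) next
      combos <- unique(trial[rows_s, c("block", "plot")])
      if (nrow(combos) < 2) next
      Z <- apply(combos, 1, function(cp)
        as.numeric(rows_s & trial$block == cp[["block"]] & trial$plot == cp[["plot"]]))
      colnames(Z) <- paste0(s, ".", combos$block, ".", combos$plot)
      random[[length(random) + 1L]] <- list(Z = Z, cov = NULL,
                                            label = paste0("plot.", s))
    }
  }
  resid_groups <- if ("harvest" %in% names(trial)) factor(trial$harvest) else NULL
  spec <- model_spec(y, X, random = random, resid_groups = resid_groups)
  fit <- reml_fit(spec, engine = "em")
  w <- wald_f(fit, "cycle")
  structure(list(slope = w$estimate, se = w$se, F = w$F, ddf = w$ddf, p = w$p,
                 sigma2 = fit$sigma2, fit = fit),
            class = "gain_fit")
}

#' @export
print.gain_fit <- function(x, ...) {
  cat("<gain_fit> slope =", signif(x$slope, 4), "+/-", signif(x$se, 3),
      "; Wald F =", signif(x$F, 4), "on 1,", x$ddf, "df; p =",
      format.pval(x$p), "\n")
  invisible(x)
}
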