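#' Smith-Hazel index coefficients
#'
#' `b = P^-1 G a`: the phenotype weights maximizing the correlation between
#' the index and the economically weighted breeding objective.
#'
#' @param P Phenotypic covariance matrix (positive definite).
#' @param G Genetic covariance matrix (symmetric).
#' @param a Economic weight vector.
#' @return Index coefficient vector `b`.
#' @export
smith_hazel <- function(P, G, a) {
  P <- as.matrix(P); G <- as.matrix(G); a <- as.numeric(a)
  stopifnot(nrow(P) == ncol(P), all(dim(P) == dim(G)), length(a) == nrow(P))
  rc <- rcond(P)
  if (rc < 1e-12)
    stop("P is numerically singular (reciprocal condition number ",
         format(rc, digits = 3), ")")
  b <- drop(solve(P, G %*% a))
  names(b) <- rownames(P) %||% names(a)
  b
}

#' Equal-weight (or weighted) GEBV selection index
#'
#' `I = sum_t a_t * GEBV_t` per individual; the default applies equal weights
#' across the traits of the breeding-value matrix.
#'
#' @param bv Matrix individuals x traits of GEBVs (no missing values).
#' @param a Economic weights (default: equal, 1 per trait).
#' @return Named numeric vector of index values.
#' @export
gebv_index <- function(bv, a = NULL) {
  bv <- as.matrix(bv)
  if (anyNA(bv)) stop("missing GEBV(s): index undefined")
  a <- a %||% rep(1, ncol(bv))
  if (length(a) != ncol(bv)) stop("weight length does not match trait count")
  drop(bv %*% as.numeric(a))
}

#' Truncation selection on index values
#'
#' Descending sort, ties broken by ascending individual id (deterministic);
#' the selected count is `ceiling(fraction * n)`.
#'
#' @param index Named numeric vector of index values.
#' @param fraction Selected fraction in `(0, 1]`.
#' @return List of class `selection_result`: `ranked` (data.frame `id`,
#'   `index`), `selected` (ids), `fraction`.
#' @export
select_fraction <- function(index, fraction) {
  if (length(index) == 0L) stop("no selection candidates")
  stopifnot(fraction > 0, fraction <= 1)
  ids <- names(index) %||% as.character(seq_along(index))
  ord <- order(-index, ids)
  k <- ceiling(fraction * length(index))
  structure(list(ranked = data.frame(id = ids[ord], index = unname(index[ord]),
                                     stringsAsFactors = FALSE),
                 selected = ids[ord][seq_len(k)], fraction = fraction),
            class = "selection_result")
}

#' Independent-culling selection on plant summaries
#'
#' Eligible plants sit in the top `top_frac` for every listed trait
#' (inclusive of the quantile threshold) and not in the bottom `bottom_frac`
#' for the yield trait. If more than `target_n` plants are eligible they are
#' ranked by mean within-trait rank and truncated; a shortfall returns all
#' eligibles with attribute `"shortfall"`.
#'
#' @param summaries data.frame with a `plant` column and per-trait summary
#'   values (typically plant means).
#' @param top_traits Traits requiring top-`top_frac` membership.
#' @param top_frac Top fraction for the listed traits (default 0.20).
#' @param yield_trait Trait with the bottom cut (`NULL` to skip).
#' @param bottom_frac Bottom fraction excluded for yield (default 0.50; 0
#'   makes the rule vacuous).
#' @param target_n Number of plants to pick (default 20: 10% of a 200-plant
#'   population).
#' @return A `selection_result`.
#' @export
independent_cull <- function(summaries, top_traits, top_frac = 0.20,
                             yield_trait = NULL, bottom_frac = 0.50,
                             target_n = 20) {
  stopifnot(all(top_traits %in% names(summaries)))
  if (!is.null(yield_trait)) stopifnot(yield_trait %in% names(summaries))
  ids <- as.character(summaries$plant)
  eligible <- rep(TRUE, nrow(summaries))
  for (tr in top_traits) {
    thr <- stats::quantile(summaries[[tr]], 1 - top_frac, type = 7, na.rm = TRUE)
    eligible <- eligible & summaries[[tr]] >= thr
  }
  if (!is.null(yield_trait) && bottom_frac > 0) {
    thr <- stats::quantile(summaries[[yield_trait]], bottom_frac, type = 7, na.rm = TRUE)
    eligible <- eligible & summaries[[yield_trait]] >= thr
  }
  elig_ids <- ids[eligible]
  rank_mat <- sapply(top_traits, function(tr) rank(-summaries[[tr]], ties.method = "average"))
  mean_rank <- rowMeans(rank_mat)
  ord <- order(!eligible, mean_rank, ids)
  ranked <- data.frame(id = ids[ord], mean_rank = mean_rank[ord],
                       eligible = eligible[ord], stringsAsFactors = FALSE)
  if (length(elig_ids) >= target_n) {
    sel <- ranked$id[ranked$eligible][seq_len(target_n)]
    shortfall <- 0L
  } else {
    sel <- elig_ids
    shortfall <- target_n - length(elig_ids)
  }
  out <- structure(list(ranked = ranked, selected = sel,
                        fraction = target_n / nrow(summaries)),
                   class = "selection_result")
  attr(out, "shortfall") <- shortfall
  out
}

#' Default configuration for the recurrent genomic-selection driver
#'
#' Trait architecture patterned on the squash population: index traits Brix
#' (`Bx`, h2 = 0.10, t = 0.45), percent dry matter (`DM`, h2 = 0.13,
#' t = 0.51) and flesh color a* (`a`, h2 = 0.23, t = 0.62), plus total fruit
#' weight (`Wt`, h2 = 0.12, once per plant) for the culling rule; genetic and
#' residual correlations follow the estimated correlation structure of those
#' traits.
#'
#' @param n_markers,n_chrom,pop_size,n_fruit_range,sites Simulation scale.
#' @return A config list for [run_recurrent_gs()].
#' @export
default_gs_config <- function(n_markers = 400, n_chrom = 10, pop_size = 200,
                              n_fruit_range = c(4, 6), sites = "E1") {
  traits <- c("Bx", "DM", "a", "Wt")
  G_corr <- matrix(c(
    1.00, 0.93, 0.24, -0.40,
    0.93, 1.00, 0.32, -0.24,
    0.24, 0.32, 1.00, -0.17,
    -0.40, -0.24, -0.17, 1.00), 4, 4, dimnames = list(traits, traits))
  R_corr <- matrix(c(
    1.00, 0.70, 0.50, -0.10,
    0.70, 1.00, 0.37, -0.10,
    0.50, 0.37, 1.00, -0.10,
    -0.10, -0.10, -0.10, 1.00), 4, 4, dimnames = list(traits, traits))
  list(n_markers = n_markers, n_chrom = n_chrom, chrom_length_cM = 90,
       pop_size = pop_size, sites = sites, n_fruit_range = n_fruit_range,
       h2 = c(Bx = 0.10, DM = 0.13, a = 0.23, Wt = 0.12),
       t = c(Bx = 0.45, DM = 0.51, a = 0.62, Wt = 0.12),
       yield = c(FALSE, FALSE, FALSE, TRUE),
       G_corr = G_corr, residual_corr = R_corr,
       index_traits = c("Bx", "DM", "a"), yield_trait = "Wt",
       cull_top_frac = 0.20, cull_bottom_frac = 0.50,
       selection_fraction = 0.10, sires_per_fruit = c(4, 5))
}

#' Recurrent genomic selection on a simulated population
#'
#' Executes the breeding scheme on synthetic data: a C0 base population is
#' phenotyped and selected by independent culling (top 20% for the three
#' quality traits, not bottom 50% for yield, 10% of the population kept);
#' subsequent cycles are selected on an equal-weight GEBV index from a
#' multi-trait GBLUP model, retrained whenever a field generation listed in
#' `retrain_at` is phenotyped; each selection is followed by random mating
#' with 4-5 sires per fruit and balanced half-sib family sizes. A model
#' trained at generation `k` becomes available for selections in later
#' generations (matching the one-generation genotyping lag of greenhouse
#' selection).
#'
#' With `selection_fraction = 1` every candidate is kept, no model is needed,
#' and the trajectory measures drift only.
#'
#' @param config Config list from [default_gs_config()] (entries may be
#'   overridden).
#' @param cycles Number of genomic-selection cycles after the phenotypic one.
#' @param retrain_at Generations whose data train a model (default `c(0, 2)`).
#' @param seed Integer seed driving all stages via fixed-offset child seeds.
#' @return List with `trajectory` (data.frame per generation: `generation`,
#'   `n`, `mean_true_index`, `sd_true_index`, `mean_index_gebv`,
#'   `sel_differential`) and `models` (trained `trait_cov` fits by
#'   generation).
#' @export
run_recurrent_gs <- function(config = default_gs_config(), cycles = 3,
                             retrain_at = c(0, 2), seed = 1) {
  cf <- config
  map <- make_map(cf$n_markers, cf$n_chrom, cf$chrom_length_cM)
  founders <- make_founders(map)
  pop <- make_f2_population(founders, cf$pop_size, map, seed = child_seed(seed, 0))
  arch <- assign_architecture(pop, h2 = cf$h2, t = cf$t, G_corr = cf$G_corr,
                              residual_corr = cf$residual_corr, sites = cf$sites,
                              yield = cf$yield, seed = child_seed(seed, 1))
  idx_traits <- cf$index_traits
  no_selection <- cf$selection_fraction >= 1
  models <- list()
  traj <- list()
  record_gen <- function(pop, gebv_index_vals = NULL, sel = NULL) {
    tbv <- true_breeding_values(pop, arch)
    ti <- rowSums(tbv[, idx_traits, drop = FALSE])
    sel_diff <- if (!is.null(sel)) mean(ti[match(sel, pop$ids)]) - mean(ti) else NA_real_
    data.frame(generation = pop$generation, n = pop_size(pop),
               mean_true_index = mean(ti), sd_true_index = stats::sd(ti),
               mean_index_gebv = if (is.null(gebv_index_vals)) NA_real_
               else mean(gebv_index_vals),
               sel_differential = sel_diff)
  }
  # one phenotypic cycle (C0) + `cycles` GS cycles + final recording pass
  gen_k <- 0L
  for (cyc in seq_len(cycles + 2L)) {
    gen_lab <- pop$generation
    # phenotype field generations: C0 always; later ones when they retrain
    train_here <- gen_k %in% retrain_at && !no_selection
    records <- NULL
    if (gen_k == 0L || train_here) {
      records <- simulate_records(pop, arch, sites = cf$sites,
                                  n_fruit_range = cf$n_fruit_range,
                                  seed = child_seed(seed, 10 + gen_k))
    }
    if (train_here) {
      K <- vanraden_grm(pop_dosage(pop))
      models[[as.character(gen_k)]] <- list(
        fit = mt_reml_fit(records, idx_traits, K, level = "fruit"),
        dosage = pop_dosage(pop))
    }
    if (cyc > cycles + 1L) { traj[[gen_lab]] <- record_gen(pop); break }
    if (gen_k == 0L) {
      # phenotypic independent culling on plant means
      sm <- stats::aggregate(records[c(idx_traits, cf$yield_trait)],
                             by = list(plant = records$plant), mean, na.rm = TRUE)
      if (no_selection) {
        sel <- sm$plant
      } else {
        target_n <- ceiling(cf$selection_fraction * pop_size(pop))
        cull <- independent_cull(sm, idx_traits, cf$cull_top_frac,
                                 cf$yield_trait, cf$cull_bottom_frac,
                                 target_n = target_n)
        sel <- cull$selected
        # a shortfall (too few plants pass every rule) is topped up by the
        # best remaining plants by mean within-trait rank, so the scheme
        # always advances the intended number of selections
        if (length(sel) < target_n)
          sel <- cull$ranked$id[seq_len(target_n)]
      }
      traj[[gen_lab]] <- record_gen(pop, sel = sel)
    } else if (no_selection) {
      sel <- pop$ids
      traj[[gen_lab]] <- record_gen(pop)
    } else {
      trained_gens <- as.integer(names(models))
      usable <- trained_gens[trained_gens < gen_k]
      if (length(usable) == 0L) stop("no trained model available at generation ", gen_lab)
      mdl <- models[[as.character(max(usable))]]
      joint <- vanraden_grm(rbind(mdl$dosage, pop_dosage(pop)))
      bv <- mt_blup(mdl$fit, joint, ids = pop$ids)
      ivals <- gebv_index(bv)
      sel <- select_fraction(ivals, cf$selection_fraction)$selected
      traj[[gen_lab]] <- record_gen(pop, ivals, sel)
    }
    pop <- random_mate(pop, sel, cf$pop_size, cf$sires_per_fruit,
                       seed = child_seed(seed, 100 + gen_k))
    gen_k <- gen_k + 1L
  }
  list(trajectory = do.call(rbind, traj), models = lapply(models, `[[`, "fit"),
       config = cf)
}
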