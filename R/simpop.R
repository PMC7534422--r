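#' Genetic map
#'
#' A marker map assigning every marker to one chromosome at a centimorgan
#' position. Positions must be non-negative and strictly increasing within a
#' chromosome.
#'
#' @param chrom Character or integer chromosome id per marker.
#' @param pos_cM Numeric position in centimorgans per marker.
#' @param id Optional marker ids (default `m1, m2, ...` in input order).
#' @return An object of class `genetic_map`: a data.frame with columns
#'   `chrom`, `pos_cM`, `id`.
#' @export
genetic_map <- function(chrom, pos_cM, id = NULL) {
  stopifnot(length(chrom) == length(pos_cM), length(chrom) >= 1L)
  if (is.null(id)) id <- paste0("m", seq_along(chrom))
  if (anyDuplicated(id)) stop("duplicate marker ids in map")
  if (any(pos_cM < 0)) stop("map positions must be non-negative")
  map <- data.frame(chrom = as.character(chrom), pos_cM = as.numeric(pos_cM),
                    id = as.character(id), stringsAsFactors = FALSE)
  for (ch in unique(map$chrom)) {
    p <- map$pos_cM[map$chrom == ch]
    if (any(diff(p) <= 0)) stop("positions must be strictly increasing within chromosome ", ch)
  }
  class(map) <- c("genetic_map", "data.frame")
  map
}

#' Evenly spaced genetic map
#'
#' Convenience constructor: `n_markers` split as evenly as possible over
#' `n_chrom` chromosomes of equal length.
#'
#' @param n_markers Total marker count.
#' @param n_chrom Number of chromosomes (default 20, the *C. moschata* count).
#' @param chrom_length_cM Chromosome length in cM.
#' @return A `genetic_map`.
#' @export
make_map <- function(n_markers, n_chrom = 20, chrom_length_cM = 90) {
  stopifnot(n_markers >= 1, n_chrom >= 1)
  per <- diff(round(seq(0, n_markers, length.out = n_chrom + 1)))
  chrom <- rep(paste0("chr", seq_len(n_chrom)), per)
  pos <- unlist(lapply(per, function(k) {
    if (k == 0) return(numeric(0))
    seq(0, chrom_length_cM, length.out = k + 2)[2:(k + 1)]
  }), use.names = FALSE)
  genetic_map(chrom, pos)
}

n_markers_map <- function(map) nrow(map)

#' Founder genomes of the biparental cross
#'
#' The two founders are fully homozygous purelines carrying opposite alleles
#' at every marker: the maximally informative biparental configuration, the
#' simulated analogue of crossing two divergent inbred cultivars.
#'
#' @param map A `genetic_map`.
#' @param n_markers Optional cross-check on the marker count.
#' @return List with genomes `A` and `B`; each genome is a list of two
#'   haplotypes (`h1`, `h2`), 0/1 integer vectors over markers.
#' @export
make_founders <- function(map, n_markers = NULL) {
  m <- n_markers_map(map)
  if (!is.null(n_markers) && n_markers != m)
    stop("n_markers (", n_markers, ") does not match map marker count (", m, ")")
  zero <- integer(m); one <- rep(1L, m)
  list(A = list(h1 = zero, h2 = zero), B = list(h1 = one, h2 = one))
}

#' Simulate one meiosis
#'
#' Crossover counts are Poisson with mean equal to the chromosome map length
#' in Morgans, crossover positions are uniform on the chromosome, and there is
#' no interference (Haldane model). Segments are copied alternately from the
#' two parental haplotypes starting from a fair-coin choice.
#'
#' @param genome A genome (list `h1`, `h2`).
#' @param map A `genetic_map` consistent with the genome.
#' @return A gamete haplotype (0/1 integer vector over markers).
#' @export
meiosis <- function(genome, map) {
  m <- n_markers_map(map)
  if (length(genome$h1) != m || length(genome$h2) != m)
    stop("genome haplotype length does not match map")
  gamete <- integer(m)
  chroms <- unique(map$chrom)
  for (ch in chroms) {
    idx <- which(map$chrom == ch)
    p <- map$pos_cM[idx]
    len_M <- (max(p) - min(p)) / 100
    n_xo <- if (len_M > 0) stats::rpois(1L, len_M) else 0L
    start <- sample.int(2L, 1L)
    if (n_xo == 0L) {
      src <- rep.int(start, length(idx))
    } else {
      xo <- sort(stats::runif(n_xo, min(p), max(p)))
      seg <- findInterval(p, xo)
      src <- (start - 1L + seg) %% 2L + 1L
    }
    h1 <- genome$h1[idx]; h2 <- genome$h2[idx]
    gamete[idx] <- ifelse(src == 1L, h1, h2)
  }
  gamete
}

cross_genomes <- function(dam_genome, sire_genome, map) {
  list(h1 = meiosis(dam_genome, map), h2 = meiosis(sire_genome, map))
}

new_population <- function(ids, H1, H2, dam, sire, generation, map) {
  structure(list(ids = ids, H1 = H1, H2 = H2, dam = dam, sire = sire,
                 generation = generation, map = map),
            class = "squash_pop")
}

#' @export
print.squash_pop <- function(x, ...) {
  cat("<squash_pop> generation", x$generation, "-", length(x$ids), "individuals,",
      ncol(x$H1), "markers\n")
  invisible(x)
}

pop_size <- function(pop) length(pop$ids)

#' Allele dosage matrix of a population
#'
#' @param pop A `squash_pop`.
#' @return Integer matrix individuals x markers with values 0/1/2 counting the
#'   founder-B allele; dimnames are individual and marker ids.
#' @export
pop_dosage <- function(pop) {
  D <- pop$H1 + pop$H2
  dimnames(D) <- list(pop$ids, pop$map$id)
  D
}

#' Simulate an F2 population from the founder cross
#'
#' The F1 (heterozygous at every marker by construction) is selfed: each F2
#' individual is formed from two independent F1 gametes. Generation label is
#' "C0", the base population of the breeding scheme.
#'
#' @param founders Output of [make_founders()].
#' @param n Number of F2 plants.
#' @param map A `genetic_map`.
#' @param seed Optional integer seed.
#' @return A `squash_pop`.
#' @export
make_f2_population <- function(founders, n, map, seed = NULL) {
  stopifnot(n >= 1)
  with_seed(seed, {
    f1 <- cross_genomes(founders$A, founders$B, map)
    m <- n_markers_map(map)
    H1 <- matrix(0L, n, m); H2 <- matrix(0L, n, m)
    for (i in seq_len(n)) {
      H1[i, ] <- meiosis(f1, map)
      H2[i, ] <- meiosis(f1, map)
    }
    ids <- sprintf("C0_%04d", seq_len(n))
    new_population(ids, H1, H2, dam = rep("F1", n), sire = rep("F1", n),
                   generation = "C0", map = map)
  })
}

next_generation_label <- function(label) {
  k <- suppressWarnings(as.integer(sub("^C", "", label)))
  if (is.na(k)) stop("generation label ", label, " is not of the form C<k>")
  paste0("C", k + 1L)
}

#' Random mating among selected plants
#'
#' Emulates the greenhouse random-mating step: each dam's fruit is pollinated
#' by a pool of 4-5 random sires (self excluded whenever another candidate
#' exists), each seed's sire is drawn uniformly from that fruit's pool, and
#' equal amounts of seed are taken from each half-sib (dam) family.
#'
#' @param pop A `squash_pop`.
#' @param selected_ids Ids of the selected plants (dams; also the sire pool).
#' @param n_progeny Total progeny to produce, balanced across dams.
#' @param sires_per_fruit Scalar or range for the per-fruit sire-pool size.
#' @param seed Optional integer seed.
#' @return A `squash_pop` with the next generation label.
#' @export
random_mate <- function(pop, selected_ids, n_progeny, sires_per_fruit = c(4, 5),
                        seed = NULL) {
  if (length(selected_ids) == 0L) stop("selected_ids is empty")
  sel <- match(selected_ids, pop$ids)
  if (anyNA(sel)) stop("selected_ids not all present in population")
  with_seed(seed, {
    map <- pop$map
    m <- n_markers_map(map)
    n_dams <- length(sel)
    per_dam <- rep(n_progeny %/% n_dams, n_dams)
    extra <- n_progeny %% n_dams
    if (extra > 0L) per_dam[seq_len(extra)] <- per_dam[seq_len(extra)] + 1L
    gen <- next_generation_label(pop$generation)
    H1 <- matrix(0L, n_progeny, m); H2 <- matrix(0L, n_progeny, m)
    dam_id <- character(n_progeny); sire_id <- character(n_progeny)
    row <- 0L
    for (d in seq_len(n_dams)) {
      dam_idx <- sel[d]
      candidates <- if (n_dams > 1L) sel[-d] else sel
      pool_size <- if (length(sires_per_fruit) > 1L)
        sample(seq(min(sires_per_fruit), max(sires_per_fruit)), 1L)
      else as.integer(sires_per_fruit)
      pool_size <- min(pool_size, length(candidates))
      pool <- if (length(candidates) == 1L) candidates
      else candidates[sample.int(length(candidates), pool_size)]
      dam_genome <- list(h1 = pop$H1[dam_idx, ], h2 = pop$H2[dam_idx, ])
      for (k in seq_len(per_dam[d])) {
        row <- row + 1L
        sire_idx <- if (length(pool) == 1L) pool else pool[sample.int(length(pool), 1L)]
        sire_genome <- list(h1 = pop$H1[sire_idx, ], h2 = pop$H2[sire_idx, ])
        H1[row, ] <- meiosis(dam_genome, map)
        H2[row, ] <- meiosis(sire_genome, map)
        dam_id[row] <- pop$ids[dam_idx]
        sire_id[row] <- pop$ids[sire_idx]
      }
    }
    ids <- sprintf("%s_%04d", gen, seq_len(n_progeny))
    new_population(ids, H1, H2, dam_id, sire_id, gen, map)
  })
}

#' Assign a multi-trait additive architecture to a population's markers
#'
#' Marker effects are drawn from a multivariate normal across traits with the
#' target genetic correlation matrix, then analytically rescaled per trait so
#' that the genic variance implied by F2 expected allele frequencies
#' (p = q = 0.5, variance = sum over markers of 2pq beta^2) equals the target
#' additive variance. With total phenotypic variance normalized to 1 per
#' trait, sigma_u^2 = h2, sigma_p^2 = t - h2, sigma_e^2 = 1 - t.
#'
#' Traits flagged in `yield` are measured once per plant; they carry no
#' permanent-environment variance (t is forced equal to h2 for them).
#'
#' @param pop A `squash_pop` (supplies the marker set).
#' @param h2 Named numeric vector of target narrow-sense heritabilities.
#' @param t Target repeatabilities (same names; `h2 <= t < 1`).
#' @param G_corr Target genetic correlation matrix across traits (PSD, unit
#'   diagonal); default identity.
#' @param residual_corr Fruit-level residual correlation across traits;
#'   default identity.
#' @param sites Character vector of site labels.
#' @param site_effect_sd SD of the site x trait fixed shifts (phenotypic SD
#'   units; environment is a main driver of between-plant variation, so the
#'   default is a substantial 0.5).
#' @param yield Logical vector flagging once-per-plant (yield) traits.
#' @param n_qtl Optional number of causal markers (default all markers:
#'   infinitesimal-style architecture).
#' @param seed Optional integer seed.
#' @return An object of class `trait_arch`.
#' @export
assign_architecture <- function(pop, h2, t = NULL, G_corr = NULL,
                                residual_corr = NULL, sites = c("E1", "E2", "E3"),
                                site_effect_sd = 0.5, yield = NULL, n_qtl = NULL,
                                seed = NULL) {
  traits <- names(h2)
  if (is.null(traits)) {
    traits <- paste0("trait", seq_along(h2))
    names(h2) <- traits
  }
  T_ <- length(traits)
  if (is.null(yield)) yield <- rep(FALSE, T_)
  if (is.null(t)) t <- h2
  t[yield] <- h2[yield]
  if (any(h2 <= 0 | h2 >= 1)) stop("h2 must lie in (0, 1)")
  if (any(t < h2)) stop("repeatability t must be >= h2 for every trait")
  if (any(t >= 1)) stop("t must be < 1")
  if (is.null(G_corr)) G_corr <- diag(T_)
  if (is.null(residual_corr)) residual_corr <- diag(T_)
  G_corr <- bend_psd(G_corr); diag(G_corr) <- 1
  residual_corr <- bend_psd(residual_corr); diag(residual_corr) <- 1
  with_seed(seed, {
    M <- n_markers_map(pop$map)
    causal <- if (is.null(n_qtl)) seq_len(M) else sort(sample.int(M, n_qtl))
    L <- chol(bend_psd(G_corr) + diag(1e-10, T_))
    B <- matrix(stats::rnorm(length(causal) * T_), length(causal), T_) %*% L
    sigma_u2 <- unname(h2)
    # genic variance at F2 (p = q = 1/2): 0.5 * sum(beta^2) per trait
    scale <- sqrt(sigma_u2 / (0.5 * colSums(B^2)))
    B <- sweep(B, 2, scale, `*`)
    effects <- matrix(0, M, T_, dimnames = list(pop$map$id, traits))
    effects[causal, ] <- B
    site_eff <- matrix(stats::rnorm(length(sites) * T_, 0, site_effect_sd),
                       length(sites), T_, dimnames = list(sites, traits))
    structure(list(traits = traits, effects = effects,
                   sigma_u2 = stats::setNames(sigma_u2, traits),
                   sigma_p2 = stats::setNames(t - h2, traits),
                   sigma_e2 = stats::setNames(1 - t, traits),
                   target_G_corr = G_corr, residual_corr = residual_corr,
                   site_effects = site_eff, sites = sites,
                   yield = stats::setNames(yield, traits)),
              class = "trait_arch")
  })
}

#' True breeding values under an architecture
#'
#' @param pop A `squash_pop`.
#' @param arch A `trait_arch`.
#' @return Matrix individuals x traits of true additive values, centered at
#'   the F2 expectation (dosage 1 at every marker).
#' @export
true_breeding_values <- function(pop, arch) {
  D <- pop_dosage(pop)
  (D - 1) %*% arch$effects
}

#' Simulate repeated-measure phenotype records
#'
#' Each fruit record is `site effect + u(plant) + p(plant) + e(fruit)`, with
#' `u` the true breeding value, `p ~ N(0, sigma_p^2)` a per-plant permanent
#' environment effect, and `e` a fruit-level residual (correlated across
#' traits via the architecture's residual correlation). The number of fruit
#' per plant is uniform on `n_fruit_range`. Yield traits are generated once
#' per plant on a separate row with `fruit = NA`.
#'
#' @param pop A `squash_pop`.
#' @param arch A `trait_arch`.
#' @param sites Site labels (default: the architecture's sites). Plants are
#'   assigned to sites in shuffled balanced fashion, two blocks per site.
#' @param n_fruit_range Integer range of fruit measured per plant.
#' @param seed Optional integer seed.
#' @return A data.frame with columns `plant, site, block, plot, fruit` and one
#'   column per trait.
#' @export
simulate_records <- function(pop, arch, sites = NULL, n_fruit_range = c(4, 6),
                             seed = NULL) {
  sites <- sites %||% arch$sites
  if (length(sites) == 0L) stop("sites must be nonempty")
  with_seed(seed, {
    n <- pop_size(pop)
    traits <- arch$traits
    T_ <- length(traits)
    u <- true_breeding_values(pop, arch)
    site_of <- sample(rep(sites, length.out = n))
    block_of <- sample(rep(1:2, length.out = n))
    fruit_traits <- traits[!arch$yield]
    yield_traits <- traits[arch$yield]
    nf <- if (n_fruit_range[1] == n_fruit_range[2]) rep(n_fruit_range[1], n)
    else sample(seq(n_fruit_range[1], n_fruit_range[2]), n, replace = TRUE)
    p_eff <- sapply(traits, function(tr) stats::rnorm(n, 0, sqrt(arch$sigma_p2[tr])))
    p_eff <- matrix(p_eff, n, T_, dimnames = list(NULL, traits))
    Rcor <- arch$residual_corr
    Lr <- chol(bend_psd(Rcor) + diag(1e-10, T_))
    se_mat <- arch$site_effects[site_of, , drop = FALSE]
    rows <- vector("list", n)
    for (i in seq_len(n)) {
      k <- nf[i]
      E <- matrix(stats::rnorm(k * T_), k, T_) %*% Lr
      E <- sweep(E, 2, sqrt(arch$sigma_e2), `*`)
      Y <- matrix(se_mat[i, ] + u[i, ] + p_eff[i, ], k, T_, byrow = TRUE) + E
      colnames(Y) <- traits
      df <- data.frame(plant = pop$ids[i], site = site_of[i], block = block_of[i],
                       plot = 1L, fruit = seq_len(k), stringsAsFactors = FALSE)
      for (tr in fruit_traits) df[[tr]] <- Y[, tr]
      if (length(yield_traits)) df[yield_traits] <- NA_real_
      if (length(yield_traits)) {
        ydf <- df[1, , drop = FALSE]
        ydf$fruit <- NA_integer_
        ydf[fruit_traits] <- NA_real_
        # yield value = site + u + fresh residual (no PE term for yield traits)
        yvals <- se_mat[i, yield_traits] + u[i, yield_traits] +
          stats::rnorm(length(yield_traits), 0, sqrt(arch$sigma_e2[yield_traits]))
        ydf[yield_traits] <- as.list(unname(yvals))
        df <- rbind(df, ydf)
      }
      rows[[i]] <- df
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Degrade genotypes with GBS-style depth and missingness structure
#'
#' Per-call read depth is Poisson(`depth_lambda`); calls below `min_depth`
#' become missing; additional uniform missingness is applied at `miss_rate`;
#' heterozygous calls with depth below 7 are miscalled homozygous with
#' probability `2 * (1/2)^depth` (both sampled alleles identical), the
#' depth at which two reads of each allele can no longer be guaranteed.
#'
#' @param pop_or_dosage A `squash_pop` or a dosage matrix (0/1/2).
#' @param miss_rate Uniform missingness rate in `[0, 1]`.
#' @param depth_lambda Mean per-call read depth.
#' @param min_depth Calls below this depth are set missing.
#' @param seed Optional integer seed.
#' @return A [geno_matrix()] with a `depth` layer; missing dosage is `NA`.
#' @export
degrade_genotypes <- function(pop_or_dosage, miss_rate = 0.1, depth_lambda = 8,
                              min_depth = 2, seed = NULL) {
  if (inherits(pop_or_dosage, "squash_pop")) {
    D <- pop_dosage(pop_or_dosage)
    markers <- pop_or_dosage$map
  } else {
    D <- pop_or_dosage
    markers <- NULL
  }
  stopifnot(miss_rate >= 0, miss_rate <= 1, depth_lambda >= 0)
  with_seed(seed, {
    n <- nrow(D); m <- ncol(D)
    depth <- matrix(stats::rpois(n * m, depth_lambda), n, m)
    D2 <- matrix(as.numeric(D), n, m, dimnames = dimnames(D))
    het <- which(D2 == 1 & depth < 7 & depth >= min_depth)
    if (length(het)) {
      p_err <- 2 * 0.5^depth[het]
      flip <- stats::runif(length(het)) < p_err
      if (any(flip)) D2[het[flip]] <- 2 * stats::rbinom(sum(flip), 1L, 0.5)
    }
    D2[depth < min_depth] <- NA
    if (miss_rate > 0) {
      extra <- stats::runif(n * m) < miss_rate
      D2[extra] <- NA
      depth[matrix(extra, n, m)] <- 0L
    }
    geno_matrix(ids = rownames(D) %||% paste0("ind", seq_len(n)),
                markers = markers, dosage = D2, depth = depth)
  })
}
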