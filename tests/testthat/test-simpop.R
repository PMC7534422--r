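test_that("founders are homozygous opposite and the F1 is fully heterozygous", {
  map <- make_map(4, 2, 50)
  f <- make_founders(map)
  expect_identical(f$A$h1, rep(0L, 4))
  expect_identical(f$A$h2, rep(0L, 4))
  expect_identical(f$B$h1, rep(1L, 4))
  expect_error(make_founders(map, n_markers = 7), "does not match")

  map2 <- make_map(1000, 10, 90)
  f2 <- make_founders(map2)
  dA <- f2$A$h1 + f2$A$h2
  dB <- f2$B$h1 + f2$B$h2
  expect_true(all(abs(dA - dB) == 2))
  # any F1 is heterozygous everywhere: forced by homozygous opposite parents
  set.seed(1)
  pop <- make_f2_population(f2, 1, map2, seed = 3)
  expect_identical(pop$dam, "F1")
  expect_identical(pop$sire, "F1")
})

test_that("genetic_map validates ordering and duplicates", {
  expect_error(genetic_map(c("1", "1"), c(5, 5)), "strictly increasing")
  expect_error(genetic_map("1", -2), "non-negative")
  expect_error(genetic_map(c("1", "1"), c(1, 2), id = c("a", "a")), "duplicate")
  m <- make_map(10, 3)
  expect_s3_class(m, "genetic_map")
  expect_equal(nrow(m), 10)
})

test_that("meiosis is a faithful copy for homozygotes and zero-length chromosomes", {
  map <- make_map(6, 2, 40)
  hom <- list(h1 = rep(1L, 6), h2 = rep(1L, 6))
  set.seed(2)
  expect_identical(meiosis(hom, map), rep(1L, 6))
  # single-marker chromosomes have zero map length: intact haplotype
  map0 <- genetic_map(c("1", "2"), c(0, 0))
  g <- list(h1 = c(0L, 0L), h2 = c(1L, 1L))
  set.seed(3)
  gam <- replicate(50, meiosis(g, map0))
  expect_true(all(gam %in% 0:1))
  expect_error(meiosis(list(h1 = 0L, h2 = 0L), map), "does not match")
})

test_that("recombination fraction over 100 cM matches the Haldane map function", {
  map <- genetic_map(c("1", "1"), c(0, 100))
  het <- list(h1 = c(0L, 0L), h2 = c(1L, 1L))
  n <- 10000
  set.seed(42)
  gam <- replicate(n, meiosis(het, map))
  rec_frac <- mean(gam[1, ] != gam[2, ])
  c_haldane <- (1 - exp(-2 * 1.0)) / 2  # 0.4323
  se <- sqrt(c_haldane * (1 - c_haldane) / n)
  expect_lt(abs(rec_frac - c_haldane), 3 * se)
})

test_that("F2 dosages segregate 1:2:1 with mean allele frequency 1/2", {
  map <- make_map(4, 2, 60)
  f <- make_founders(map)
  n <- 10000
  pop <- make_f2_population(f, n, map, seed = 11)
  D <- pop_dosage(pop)
  for (j in seq_len(ncol(D))) {
    freq <- tabulate(D[, j] + 1L, 3L) / n
    for (k in 1:3) {
      p0 <- c(0.25, 0.5, 0.25)[k]
      expect_lt(abs(freq[k] - p0), 3 * sqrt(p0 * (1 - p0) / n))
    }
  }
  expect_lt(abs(mean(D) / 2 - 0.5), 3 * sqrt(0.5 * 0.5 / (n * ncol(D))))
})

test_that("random mating balances half-sib families and uses sires uniformly", {
  pop <- fx_pop2$pop
  sel <- pop$ids[1:20]
  prog <- random_mate(pop, sel, 200, sires_per_fruit = c(4, 5), seed = 9)
  expect_equal(pop_size(prog), 200)
  expect_equal(prog$generation, "C1")
  expect_true(all(table(prog$dam) == 10))
  expect_error(random_mate(pop, character(0), 10), "empty")

  # a single selected plant can only self
  prog_self <- random_mate(pop, pop$ids[1], 10, seed = 10)
  expect_true(all(prog_self$dam == pop$ids[1] & prog_self$sire == pop$ids[1]))

  # sire usage across many progeny approaches the uniform expectation
  map <- make_map(4, 1, 10)
  f <- make_founders(map)
  small <- make_f2_population(f, 5, map, seed = 12)
  many <- random_mate(small, small$ids, 10000, sires_per_fruit = 4, seed = 13)
  counts <- table(factor(many$sire, levels = small$ids))
  p0 <- 1 / 4  # self excluded: each dam draws from the 4 others
  # each dam contributes 2000 seeds over its 4 candidate sires
  for (s in small$ids) {
    dams <- setdiff(small$ids, s)
    n_eligible <- sum(many$dam %in% dams)
    expect_lt(abs(counts[[s]] / n_eligible - p0),
              3 * sqrt(p0 * (1 - p0) / n_eligible))
  }
})

test_that("architecture hits variance targets and correlation structure", {
  pop <- fx_pop2$pop
  arch <- assign_architecture(pop, h2 = c(X = 0.25), t = c(X = 0.55), seed = 21)
  expect_equal(unname(arch$sigma_u2), 0.25)
  expect_equal(unname(arch$sigma_p2), 0.30)
  expect_equal(unname(arch$sigma_e2), 0.45)
  expect_error(assign_architecture(pop, h2 = c(X = 0.5), t = c(X = 0.3)), ">= h2")

  # realized additive variance in a large F2 close to the genic-variance target
  map <- make_map(100, 5, 90)
  f <- make_founders(map)
  big <- make_f2_population(f, 2000, map, seed = 22)
  arch2 <- assign_architecture(big, h2 = c(X = 0.25), t = c(X = 0.55), seed = 23)
  u <- true_breeding_values(big, arch2)
  expect_lt(abs(var(u[, 1]) - 0.25) / 0.25, 0.10)

  # independent traits: marker-effect vectors uncorrelated
  arch3 <- assign_architecture(big, h2 = c(X = 0.2, Y = 0.2), t = c(X = 0.5, Y = 0.5),
                               G_corr = diag(2), seed = 24)
  r <- cor(arch3$effects[, 1], arch3$effects[, 2])
  expect_lt(abs(r), 3 / sqrt(nrow(arch3$effects)))
})

test_that("phenotype records follow the generative repeatability model", {
  pop <- fx_pop2$pop
  # no plant or fruit noise: fruit identical, equal to site effect + true BV
  arch0 <- assign_architecture(pop, h2 = c(X = 0.999), t = c(X = 0.999),
                               sites = "E1", seed = 31)
  arch0$sigma_p2[] <- 0; arch0$sigma_e2[] <- 0
  rec0 <- simulate_records(pop, arch0, seed = 32)
  spread <- tapply(rec0$X, rec0$plant, function(v) diff(range(v)))
  expect_true(all(spread < 1e-12))
  u <- true_breeding_values(pop, arch0)
  one <- rec0[match(pop$ids, rec0$plant), ]
  expect_equal(one$X, unname(u[, 1] + arch0$site_effects["E1", "X"]), tolerance = 1e-10)

  # intraclass correlation of fruit within plants recovers t
  map <- make_map(100, 5, 90)
  f <- make_founders(map)
  big <- make_f2_population(f, 500, map, seed = 33)
  archt <- assign_architecture(big, h2 = c(X = 0.25), t = c(X = 0.55),
                               sites = "E1", seed = 34)
  rec <- simulate_records(big, archt, n_fruit_range = c(5, 5), seed = 35)
  a <- stats::aov(X ~ factor(plant), data = rec)
  ms <- summary(a)[[1]]$`Mean Sq`
  icc <- (ms[1] - ms[2]) / (ms[1] + 4 * ms[2])
  expect_lt(abs(icc - 0.55), 0.05)

  # yield traits appear once per plant with fruit = NA
  archy <- assign_architecture(pop, h2 = c(X = 0.2, Yld = 0.12),
                               t = c(X = 0.5, Yld = 0.12),
                               yield = c(FALSE, TRUE), seed = 36)
  recy <- simulate_records(pop, archy, seed = 37)
  yrows <- recy[is.na(recy$fruit), ]
  expect_equal(nrow(yrows), pop_size(pop))
  expect_true(all(!is.na(yrows$Yld)) && all(is.na(yrows$X)))
})

test_that("plant fruit-mean variance declines as sigma_u2+sigma_p2+sigma_e2/n", {
  map <- make_map(100, 5, 90)
  f <- make_founders(map)
  big <- make_f2_population(f, 800, map, seed = 41)
  arch <- assign_architecture(big, h2 = c(X = 0.25), t = c(X = 0.55),
                              sites = "E1", seed = 42)
  for (nf in c(1, 4, 10)) {
    rec <- simulate_records(big, arch, n_fruit_range = c(nf, nf),
                            seed = 43 + nf)
    pm <- tapply(rec$X, rec$plant, mean)
    expected <- 0.25 + 0.30 + 0.45 / nf
    expect_lt(abs(var(pm) - expected) / expected, 0.20)
  }
})

test_that("GBS degradation has Poisson depth-driven missingness and is seed-stable", {
  pop <- fx_pop2$pop
  D <- pop_dosage(pop)
  # effectively infinite depth, no uniform missingness: identity
  g_id <- degrade_genotypes(pop, miss_rate = 0, depth_lambda = 500, seed = 51)
  expect_equal(unname(g_id$dosage), unname(matrix(as.numeric(D), nrow(D), ncol(D))))
  # min_depth 2 at lambda 3: missing fraction ~ P(Poisson(3) < 2)
  g <- degrade_genotypes(pop, miss_rate = 0, depth_lambda = 3, min_depth = 2,
                         seed = 52)
  p0 <- exp(-3) * 4
  n <- length(g$dosage)
  expect_lt(abs(mean(is.na(g$dosage)) - p0), 3 * sqrt(p0 * (1 - p0) / n))
  # total missingness
  g_all <- degrade_genotypes(pop, miss_rate = 1, depth_lambda = 8, seed = 53)
  expect_true(all(is.na(g_all$dosage)))
  # determinism under a fixed seed
  g2 <- degrade_genotypes(pop, miss_rate = 0.1, depth_lambda = 3, seed = 54)
  g3 <- degrade_genotypes(pop, miss_rate = 0.1, depth_lambda = 3, seed = 54)
  expect_identical(g2$dosage, g3$dosage)
})

test_that("simulation drivers are bit-reproducible under a fixed seed", {
  map <- make_map(30, 3, 50)
  f <- make_founders(map)
  p1 <- make_f2_population(f, 25, map, seed = 61)
  p2 <- make_f2_population(f, 25, map, seed = 61)
  expect_identical(p1$H1, p2$H1)
  a1 <- assign_architecture(p1, h2 = c(X = 0.3), t = c(X = 0.5), seed = 62)
  r1 <- simulate_records(p1, a1, seed = 63)
  r2 <- simulate_records(p1, a1, seed = 63)
  expect_identical(r1, r2)
})
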