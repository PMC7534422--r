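test_that("minor allele frequency follows the dosage definition", {
  g <- geno_matrix(c("a", "b", "c"), NULL, rbind(c(0, 2, 0), c(1, 2, 0), c(2, 2, NA)))
  maf <- compute_maf(g)
  expect_equal(unname(maf[1]), 0.5)       # dosages 0,1,2
  expect_equal(unname(maf[2]), 0)         # monomorphic
  expect_equal(unname(maf[3]), 0)         # dosages 0,0
  g2 <- geno_matrix(letters[1:4], NULL, matrix(c(2, 2, 2, 1), 4, 1))
  expect_equal(unname(compute_maf(g2)), 1 / 8)
  g3 <- geno_matrix(c("a", "b"), NULL, matrix(NA_real_, 2, 1))
  expect_true(is.na(compute_maf(g3)))
})

test_that("depth masking hits exactly the low-depth calls", {
  D <- matrix(c(0, 1, 2, 1), 2, 2)
  dp <- matrix(c(5, 5, 5, 5), 2, 2)
  g <- geno_matrix(c("a", "b"), NULL, D, dp)
  expect_equal(set_low_depth_missing(g, 2)$dosage, g$dosage)
  dp2 <- dp; dp2[1, 2] <- 1
  g2 <- geno_matrix(c("a", "b"), NULL, D, dp2)
  masked <- set_low_depth_missing(g2, 2)
  expect_true(is.na(masked$dosage[1, 2]))
  expect_equal(sum(is.na(masked$dosage)), 1L)
  # the stricter cross-validation-set rule: depth below 7 all masked
  dp3 <- matrix(c(6, 7, 2, 10), 2, 2)
  g3 <- geno_matrix(c("a", "b"), NULL, D, dp3)
  masked7 <- set_low_depth_missing(g3, 7)
  expect_equal(unname(is.na(masked7$dosage)), dp3 < 7)
  expect_error(set_low_depth_missing(geno_matrix(c("a", "b"), NULL, D), 2),
               "no depth layer")
})

test_that("QC filter drops in fixed order and reports counts that sum", {
  filtered <- qc_filter(fx_qc_geno)
  expect_equal(length(filtered$ids), 9L)       # 50%-missing individual dropped
  expect_equal(nrow(filtered$markers), 9L)     # monomorphic marker dropped
  rep <- attr(filtered, "filter_report")
  expect_equal(rep$individuals_in, rep$individuals_dropped + length(filtered$ids))
  expect_equal(rep$markers_in, rep$markers_dropped + nrow(filtered$markers))
  # idempotence
  twice <- qc_filter(filtered)
  expect_equal(twice$dosage, filtered$dosage)
  # vacuous thresholds leave a clean matrix untouched
  clean <- geno_matrix(letters[1:4], NULL,
                       rbind(c(0, 1), c(2, 1), c(1, 0), c(1, 2)))
  same <- qc_filter(clean, maf_min = 0, max_marker_missing = 1, max_ind_missing = 1)
  expect_equal(same$dosage, clean$dosage)
  all_mono <- geno_matrix(c("a", "b"), NULL, matrix(2, 2, 2))
  expect_error(qc_filter(all_mono), "no markers survive")
})

test_that("parent-informed filter keeps homozygous-different markers only", {
  # 6 markers with three defects: m3 has a heterozygous parent call, m4 is
  # all-heterozygous in the progeny, m5 is 60% missing; m1, m2, m6 survive
  D <- rbind(c(0, 0, 1, 1, NA, 2),
             c(1, 1, 1, 1, NA, 1),
             c(2, 2, 1, 1, NA, 0),
             c(0, 1, 0, 1, 1, 1),
             c(1, 0, 2, 1, 2, 2))
  g <- geno_matrix(paste0("i", 1:5), NULL, D)
  pA <- c(0, 2, 1, 0, 0, 0)
  pB <- c(2, 0, 2, 2, 2, 2)
  kept <- parent_filter(g, pA, pB, max_missing = 0.5, max_het = 0.9)
  expect_equal(nrow(kept$markers), 3L)
  expect_setequal(kept$markers$id, c("m1", "m2", "m6"))
  # parents homozygous for the same allele: dropped
  expect_false("m1" %in%
    parent_filter(g, replace(pA, 1, 2), pB)$markers$id)
  expect_error(parent_filter(g, pA[1:3], pB[1:3]), "not aligned")
})

test_that("merging on common markers preserves order and stacks individuals", {
  mkA <- data.frame(chrom = "1", pos = 1:5, id = paste0("m", 1:5))
  mkB <- data.frame(chrom = "1", pos = 2:5, id = paste0("m", c(2, 3, 4, 11)))
  A <- geno_matrix(sprintf("a%02d", 1:12), mkA,
                   matrix(rbinom(60, 2, 0.5), 12, 5))
  B <- geno_matrix(sprintf("b%02d", 1:8), mkB,
                   matrix(rbinom(32, 2, 0.5), 8, 4))
  M <- merge_common(A, B)
  expect_equal(length(M$ids), 20L)
  expect_equal(M$markers$id, c("m2", "m3", "m4"))
  expect_equal(M$dosage["a03", "m3"], A$dosage["a03", "m3"])
  expect_equal(M$dosage["b05", "m4"], B$dosage["b05", "m4"])
  # identical marker sets: everything retained
  M2 <- merge_common(A, geno_matrix(paste0("c", 1:3), mkA,
                                    matrix(rbinom(15, 2, 0.5), 3, 5)))
  expect_equal(nrow(M2$markers), 5L)
  noshare <- geno_matrix("z1", data.frame(chrom = "9", pos = 1, id = "q1"),
                         matrix(1, 1, 1))
  expect_error(merge_common(A, noshare), "no common markers")
})

test_that("mean imputation fills with the marker mean and only that", {
  g <- geno_matrix(letters[1:3], NULL, rbind(c(0, 2), c(2, 2), c(NA, 0)))
  M <- mean_impute(g)
  expect_equal(M[3, 1], 1.0)
  expect_equal(M[, 2], c(a = 2, b = 2, c = 0))
  g4 <- geno_matrix(letters[1:4], NULL, matrix(c(2, 2, NA, 0), 4, 1))
  expect_equal(unname(mean_impute(g4)[3, 1]), 4 / 3)
  complete <- geno_matrix(letters[1:2], NULL, rbind(c(0, 1), c(2, 1)))
  expect_equal(mean_impute(complete), complete$dosage)
  allmiss <- geno_matrix(letters[1:2], NULL, matrix(NA_real_, 2, 1))
  expect_error(mean_impute(allmiss), "all-missing")
})

test_that("VanRaden GRM matches hand computation and is invariant", {
  K <- vanraden_grm(matrix(c(0, 2), 2, 1, dimnames = list(c("a", "b"), "m1")))
  expect_equal(unclass(K), matrix(c(2, -2, -2, 2), 2, dimnames = list(c("a", "b"), c("a", "b"))))
  # identical genotype rows are exchangeable
  D <- matrix(rbinom(80, 2, 0.5), 8, 10)
  D[2, ] <- D[1, ]
  K2 <- vanraden_grm(D)
  expect_equal(K2[1, 1], K2[2, 2])
  expect_equal(K2[1, 3], K2[2, 3])
  # invariance to marker order and allele flip
  perm <- sample(ncol(D))
  expect_equal(unclass(vanraden_grm(D[, perm])), unclass(vanraden_grm(D)),
               tolerance = 1e-10)
  expect_equal(unclass(vanraden_grm(2 - D)), unclass(vanraden_grm(D)),
               tolerance = 1e-10)
  # centering: column means of W are exactly zero
  p <- colMeans(D) / 2
  W <- sweep(D, 2, 2 * p)
  expect_true(max(abs(colMeans(W))) < 1e-12)
  expect_error(vanraden_grm(matrix(2, 3, 2)), "monomorphic")
  # large simulated F2: mean diagonal near 1
  K3 <- fx_pop2$K
  expect_lt(abs(mean(diag(K3)) - 1), 0.1)
})

test_that("012 and VCF renderings round-trip to the same dosages", {
  d <- withr::local_tempdir()
  g <- fx_qc_geno
  write_012(g, file.path(d, "toy"))
  back <- read_012(file.path(d, "toy"))
  expect_equal(unname(back$dosage), unname(g$dosage))
  expect_equal(back$ids, g$ids)
  skip_if_not_installed("vcfR")
  write_minimal_vcf(g, file.path(d, "toy.vcf"))
  vback <- read_vcf_minimal(file.path(d, "toy.vcf"))
  expect_equal(unname(vback$dosage), unname(g$dosage))
  expect_equal(vback$ids, g$ids)
})

test_that("kinship CSV round-trips", {
  d <- withr::local_tempdir()
  K <- fx_oracle$K
  write_kinship_csv(K, file.path(d, "k.csv"))
  K2 <- read_kinship_csv(file.path(d, "k.csv"))
  expect_equal(unclass(K2), unclass(K), tolerance = 1e-6)
})
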