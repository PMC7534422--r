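#!/usr/bin/env Rscript
# Stage 3: predictive ability of GBLUP under three cross-validation schemes.
#
# Within-set: random 80/20 partitions repeated 50 times with partitions
# shared across traits; truth is the plant mean of fruit records. Across-set:
# a model trained on the base population predicts one generation of random-
# mated progeny (the Prog scenario) after merging marker sets on common
# markers. Stratified: equal draws per set sweep the training size with a
# fixed test set of 25 per set. Requires results/data/ from 01_simulate.R.

library(squashgs)

seed <- 20260903
data_dir <- "results/data"
records <- read.csv(file.path(data_dir, "phenotypes.csv"))
K <- read_kinship_csv(file.path(data_dir, "kinship.csv"))
geno <- read_012(file.path(data_dir, "genotypes"))
traits <- c("Bx", "DM", "a")

cv_w <- within_cv(records, traits, K, test_frac = 0.2, reps = 50,
                  seed = child_seed(seed, 1))
summ <- aggregate(pa ~ trait, cv_w, function(x) c(mean = mean(x), sd = sd(x)))
cat("within-set predictive ability (50 reps):\n")
print(do.call(data.frame, summ), row.names = FALSE)

# across-set: re-simulate the training population from its 012 rendering is
# not possible (no haplotypes), so the progeny scenario re-runs the simulator
cf <- default_gs_config()
map <- make_map(cf$n_markers, cf$n_chrom, cf$chrom_length_cM)
pop <- make_f2_population(make_founders(map), cf$pop_size, map,
                          seed = child_seed(20260901, 0))  # same base as stage 1
arch <- assign_architecture(pop, h2 = cf$h2, t = cf$t, G_corr = cf$G_corr,
                            residual_corr = cf$residual_corr,
                            sites = c("E1", "E2", "E3"), yield = cf$yield,
                            seed = child_seed(20260901, 1))
prog <- random_mate(pop, pop$ids[1:40], 150, seed = child_seed(seed, 2))
rec_prog <- simulate_records(prog, arch, seed = child_seed(seed, 3))
gA <- geno_matrix(pop$ids, map, pop_dosage(pop))
gB <- geno_matrix(prog$ids, map, pop_dosage(prog))
rec_base <- simulate_records(pop, arch, seed = child_seed(20260901, 2))
cv_a <- across_cv(gA, rec_base, gB, rec_prog, traits)
cat("\nacross-set (base -> progeny) predictive ability:\n")
print(cv_a[, c("trait", "train_size", "pa")], row.names = FALSE)

sets <- list(list(geno = gA, records = rec_base),
             list(geno = gB, records = rec_prog))
cv_s <- stratified_cv(sets, per_set_train = c(25, 50, 100), traits = traits,
                      per_set_test = 25, reps = 20, seed = child_seed(seed, 4))
m <- aggregate(pa ~ trait + train_size, cv_s, mean)
cat("\nstratified scheme: mean PA by total training size\n")
print(reshape(m, idvar = "trait", timevar = "train_size", direction = "wide"),
      row.names = FALSE)

dir.create("results", showWarnings = FALSE)
write.csv(rbind(cv_w, cv_a, cv_s), "results/cv_results.csv", row.names = FALSE)
cat("\nwrote results/cv_results.csv\n")
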