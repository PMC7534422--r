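#!/usr/bin/env Rscript
# Stage 1: simulate the base breeding population.
#
# A biparental F2 of 200 plants is simulated from two fully divergent
# purelines over a 10-chromosome map with 400 markers, given three fruit
# quality traits (Brix, percent dry matter, flesh color a*) with the
# heritabilities/repeatabilities and genetic correlations estimated for this
# population, plus a once-per-plant yield trait. Genotypes are degraded with
# GBS-style depth and missingness, QC-filtered, mean-imputed, and turned into
# a VanRaden relationship matrix. Outputs go to results/data/.

library(squashgs)

seed <- 20260901
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cf <- default_gs_config()
map <- make_map(cf$n_markers, cf$n_chrom, cf$chrom_length_cM)
founders <- make_founders(map)
pop <- make_f2_population(founders, cf$pop_size, map, seed = child_seed(seed, 0))
arch <- assign_architecture(pop, h2 = cf$h2, t = cf$t, G_corr = cf$G_corr,
                            residual_corr = cf$residual_corr,
                            sites = c("E1", "E2", "E3"), yield = cf$yield,
                            seed = child_seed(seed, 1))
records <- simulate_records(pop, arch, n_fruit_range = cf$n_fruit_range,
                            seed = child_seed(seed, 2))

raw <- degrade_genotypes(pop, miss_rate = 0.05, depth_lambda = 8, min_depth = 1,
                         seed = child_seed(seed, 3))
masked <- set_low_depth_missing(raw, min_depth = 2)
clean <- qc_filter(masked)
rep <- attr(clean, "filter_report")
K <- vanraden_grm(mean_impute(clean))

cat(sprintf("simulated %d plants x %d markers; QC dropped %d individuals and %d markers\n",
            cf$pop_size, cf$n_markers, rep$individuals_dropped, rep$markers_dropped))
cat(sprintf("%d phenotype records (%.1f fruit/plant); mean K diagonal %.3f\n",
            nrow(records), mean(table(records$plant[!is.na(records$fruit)])),
            mean(diag(K))))

write_012(clean, file.path(out, "genotypes"))
write_kinship_csv(K, file.path(out, "kinship.csv"))
write.csv(records, file.path(out, "phenotypes.csv"), row.names = FALSE)
tbv <- true_breeding_values(pop, arch)
write.csv(data.frame(plant = rownames(tbv), tbv, check.names = FALSE),
          file.path(out, "true_breeding_values.csv"), row.names = FALSE)
cat("wrote genotypes (012 triplet), kinship.csv, phenotypes.csv, true_breeding_values.csv\n")
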