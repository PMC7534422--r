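#' Default end-to-end pipeline configuration
#'
#' All thresholds default to the study's stated values: MAF 0.05, 20% marker
#' missingness, 40% individual missingness, depth-2 masking, 80/20
#' cross-validation with 50 replicates, 10% index selection.
#'
#' @param profile `"selection_pipeline"` (depth-2 masking, 80% marker
#'   presence) or `"cv_pipeline"` (depth-7 masking, 50% marker presence).
#' @return Named list of stage parameters.
#' @export
default_pipeline_config <- function(profile = c("selection_pipeline", "cv_pipeline")) {
  profile <- match.arg(profile)
  list(
    profile = profile,
    sim = list(n_markers = 400, n_chrom = 10, pop_size = 200,
               n_fruit_range = c(4, 6), sites = c("E1", "E2"),
               miss_rate = 0.05, depth_lambda = 8),
    qc = list(maf_min = 0.05, max_marker_missing = 0.2, max_ind_missing = 0.4,
              min_depth = if (profile == "selection_pipeline") 2 else 7),
    traits = list(h2 = c(Bx = 0.10, DM = 0.13, a = 0.23),
                  t = c(Bx = 0.45, DM = 0.51, a = 0.62)),
    cv = list(test_frac = 0.2, reps = 10),
    selection = list(fraction = 0.10))
}

validate_config <- function(config, template = default_pipeline_config()) {
  unknown <- setdiff(names(config), names(template))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  for (k in names(config)) {
    if (is.list(template[[k]]) && is.list(config[[k]])) {
      bad <- setdiff(names(config[[k]]), names(template[[k]]))
      if (length(bad))
        stop("unknown config key(s) under '", k, "': ", paste(bad, collapse = ", "))
    }
  }
  utils::modifyList(template, config)
}

#' Run the full analysis pipeline on synthetic data
#'
#' Simulate a base population, degrade and QC the genotypes, build the
#' genomic relationship matrix, fit the repeatability model per trait,
#' produce the parameter table and within-set cross-validation, and return
#' everything with a manifest of seeds, thresholds and per-stage record
#' counts.
#'
#' @param config Pipeline configuration (see [default_pipeline_config()]);
#'   unknown keys are rejected before any compute.
#' @param seed Global integer seed.
#' @param out_dir Optional directory: tables are written as CSV and the
#'   manifest as JSON.
#' @return List with `geno`, `K`, `records`, `fits`, `params`, `cv`,
#'   `manifest`.
#' @export
run_pipeline <- function(config = list(), seed = 1, out_dir = NULL) {
  cf <- validate_config(config)
  map <- make_map(cf$sim$n_markers, cf$sim$n_chrom)
  founders <- make_founders(map)
  pop <- make_f2_population(founders, cf$sim$pop_size, map,
                            seed = child_seed(seed, 0))
  arch <- assign_architecture(pop, h2 = cf$traits$h2, t = cf$traits$t,
                              sites = cf$sim$sites, seed = child_seed(seed, 1))
  records <- simulate_records(pop, arch, n_fruit_range = cf$sim$n_fruit_range,
                              seed = child_seed(seed, 2))
  raw <- degrade_genotypes(pop, miss_rate = cf$sim$miss_rate,
                           depth_lambda = cf$sim$depth_lambda,
                           min_depth = 1, seed = child_seed(seed, 3))
  masked <- set_low_depth_missing(raw, min_depth = cf$qc$min_depth)
  clean <- qc_filter(masked, maf_min = cf$qc$maf_min,
                     max_marker_missing = cf$qc$max_marker_missing,
                     max_ind_missing = cf$qc$max_ind_missing)
  K <- vanraden_grm(mean_impute(clean))
  traits <- names(cf$traits$h2)
  keep <- records$plant %in% clean$ids
  records_f <- records[keep, , drop = FALSE]
  fits <- lapply(traits, function(tr) repeatability_fit(records_f, tr, K))
  names(fits) <- traits
  params <- param_table(fits)
  cv <- within_cv(records_f, traits, K, test_frac = cf$cv$test_frac,
                  reps = cf$cv$reps, seed = child_seed(seed, 4))
  manifest <- list(
    seed = seed, profile = cf$profile,
    thresholds = cf$qc,
    counts = list(simulated_individuals = cf$sim$pop_size,
                  simulated_markers = cf$sim$n_markers,
                  post_qc_individuals = length(clean$ids),
                  post_qc_markers = nrow(clean$markers),
                  phenotype_records = nrow(records_f)),
    filter_report = attr(clean, "filter_report"))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(params, file.path(out_dir, "param_table.csv"), row.names = FALSE)
    utils::write.csv(cv, file.path(out_dir, "cv_within.csv"), row.names = FALSE)
    write_kinship_csv(K, file.path(out_dir, "kinship.csv"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  list(geno = clean, K = K, records = records_f, fits = fits, params = params,
       cv = cv, manifest = manifest)
}

#' Load a pipeline configuration from YAML
#'
#' @param path YAML file whose keys mirror [default_pipeline_config()];
#'   unknown keys are rejected.
#' @return Validated configuration list.
#' @export
read_pipeline_config <- function(path) {
  validate_config(yaml::read_yaml(path))
}

#' Generate the shared toy fixtures
#'
#' Writes the small deterministic datasets used across the test suite: the
#' hand-constructed QC fixture, a tiny 012 + VCF rendering of the same
#' genotypes, a 20-record instance for the restricted-likelihood grid oracle,
#' and a 3-trait demo population. All fixtures are synthetic.
#'
#' @param dir Output directory.
#' @param seed Integer seed.
#' @return Invisibly, the list of written paths.
#' @export
generate_fixtures <- function(dir, seed = 42) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  # 10 x 10 QC fixture: individual 1 is 50% missing, marker 10 monomorphic
  g <- with_seed(child_seed(seed, 0), {
    D <- matrix(stats::rbinom(100, 2, 0.5), 10, 10)
    D[10, ] <- c(0, 1, 2, 0, 1, 2, 0, 1, 2, 0)  # keep marker stats stable
    D[, 10] <- 2                                 # monomorphic marker
    D[1, 1:5] <- NA                              # 50% missing individual
    geno_matrix(sprintf("i%02d", 1:10), NULL, D)
  })
  write_012(g, file.path(dir, "qc_fixture"))
  paths <- c(paths, file.path(dir, "qc_fixture.012"))
  # same genotypes as a minimal VCF
  vcf_path <- file.path(dir, "qc_fixture.vcf")
  write_minimal_vcf(g, vcf_path)
  paths <- c(paths, vcf_path)
  # 20-record grid-oracle instance: y = mu + u + e over a marker-derived K
  oracle <- with_seed(child_seed(seed, 1), {
    D <- matrix(stats::rbinom(20 * 60, 2, 0.5), 20, 60,
                dimnames = list(sprintf("p%02d", 1:20), NULL))
    K <- vanraden_grm(D)
    u <- drop(crossprod(chol(sym(unclass(K)) + diag(1e-4, 20)), stats::rnorm(20))) * sqrt(0.5)
    y <- 1 + u + stats::rnorm(20, 0, sqrt(0.5))
    list(K = K, y = y)
  })
  utils::write.csv(data.frame(id = names(oracle$y) %||% sprintf("p%02d", 1:20),
                              y = oracle$y),
                   file.path(dir, "oracle_y.csv"), row.names = FALSE)
  write_kinship_csv(oracle$K, file.path(dir, "oracle_K.csv"))
  paths <- c(paths, file.path(dir, "oracle_y.csv"), file.path(dir, "oracle_K.csv"))
  invisible(paths)
}

#' Write a genotype matrix as a minimal VCF
#'
#' GT and DP fields only, biallelic SNPs, uncompressed text.
#'
#' @param geno A `geno_matrix`.
#' @param path Output path.
#' @export
write_minimal_vcf <- function(geno, path) {
  D <- geno$dosage
  gt <- matrix("./.", nrow(geno$markers), length(geno$ids))
  for (v in 0:2) gt[t(D) == v] <- c("0/0", "0/1", "1/1")[v + 1]
  dp <- if (!is.null(geno$depth)) t(geno$depth) else
    matrix(10L, nrow(geno$markers), length(geno$ids))
  body <- vapply(seq_len(nrow(geno$markers)), function(i) {
    paste(c(geno$markers$chrom[i], geno$markers$pos[i], geno$markers$id[i],
            "A", "G", ".", "PASS", ".", "GT:DP",
            paste(gt[i, ], dp[i, ], sep = ":")), collapse = "\t")
  }, "")
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", geno$ids), collapse = "\t"))
  writeLines(c(hdr, body), path)
  invisible(path)
}
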