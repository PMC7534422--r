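#' Genotype matrix container
#'
#' Individuals x markers dosage matrix in `{0, 1, 2, NA}` with an optional
#' same-shape read-depth layer.
#'
#' @param ids Individual labels (unique).
#' @param markers A data.frame with columns `chrom`, `pos`/`pos_cM`, `id`, or
#'   `NULL` (synthetic marker ids are created).
#' @param dosage Numeric matrix individuals x markers; values 0/1/2 or `NA`.
#' @param depth Optional non-negative integer matrix of the same shape.
#' @return An object of class `geno_matrix`.
#' @export
geno_matrix <- function(ids, markers = NULL, dosage, depth = NULL) {
  dosage <- as.matrix(dosage)
  n <- nrow(dosage); m <- ncol(dosage)
  ids <- as.character(ids)
  if (length(ids) != n) stop("length(ids) != nrow(dosage)")
  if (anyDuplicated(ids)) stop("duplicate individual ids")
  if (is.null(markers)) {
    mk_id <- colnames(dosage) %||% paste0("m", seq_len(m))
    markers <- data.frame(chrom = "chr0", pos = seq_len(m), id = mk_id,
                          stringsAsFactors = FALSE)
  } else {
    markers <- as.data.frame(markers)
    if ("pos_cM" %in% names(markers) && !"pos" %in% names(markers))
      markers$pos <- markers$pos_cM
    markers <- markers[, intersect(c("chrom", "pos", "id"), names(markers))]
  }
  if (nrow(markers) != m) stop("marker table does not match dosage columns")
  if (anyDuplicated(markers$id)) stop("duplicate marker ids")
  if (!is.null(depth)) {
    depth <- as.matrix(depth)
    if (!all(dim(depth) == dim(dosage))) stop("depth layer shape mismatch")
    if (any(depth < 0, na.rm = TRUE)) stop("negative depths")
  }
  dimnames(dosage) <- list(ids, markers$id)
  structure(list(ids = ids, markers = markers, dosage = dosage, depth = depth),
            class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat("<geno_matrix>", length(x$ids), "individuals x", nrow(x$markers), "markers;",
      sprintf("%.1f%% missing", 100 * mean(is.na(x$dosage))),
      if (!is.null(x$depth)) "(with depth layer)" else "", "\n")
  invisible(x)
}

#' Per-marker minor allele frequency
#'
#' `maf = min(f, 1 - f)` with `f = mean(dosage) / 2` over non-missing calls.
#' Markers with no non-missing call get `NA` (they fail any MAF threshold).
#'
#' @param geno A `geno_matrix` or dosage matrix.
#' @return Named numeric vector of MAFs per marker.
#' @export
compute_maf <- function(geno) {
  D <- if (inherits(geno, "geno_matrix")) geno$dosage else as.matrix(geno)
  f <- colMeans(D, na.rm = TRUE) / 2
  f[is.nan(f)] <- NA_real_
  pmin(f, 1 - f)
}

#' Mask genotype calls below a read-depth threshold
#'
#' @param geno A `geno_matrix` with a depth layer.
#' @param min_depth Calls with depth strictly below this are set missing. The
#'   default 2 is the selection-pipeline rule; 7 reproduces the stricter
#'   cross-validation-set rule (the depth at which the caller can require two
#'   reads per allele of a heterozygote).
#' @return A `geno_matrix`.
#' @export
set_low_depth_missing <- function(geno, min_depth = 2) {
  stopifnot(inherits(geno, "geno_matrix"))
  if (is.null(geno$depth)) stop("genotype matrix has no depth layer")
  D <- geno$dosage
  D[geno$depth < min_depth] <- NA
  geno_matrix(geno$ids, geno$markers, D, geno$depth)
}

#' Standard genotype QC filter
#'
#' Applied in fixed order: (1) drop individuals whose missing fraction
#' exceeds `max_ind_missing`; (2) recompute per-marker statistics; (3) drop
#' markers whose missing fraction exceeds `max_marker_missing` or whose MAF is
#' below `maf_min`. The filter is idempotent.
#'
#' @param geno A `geno_matrix`.
#' @param maf_min Minimum minor allele frequency (default 0.05).
#' @param max_marker_missing Maximum per-marker missing fraction (default 0.2).
#' @param max_ind_missing Maximum per-individual missing fraction (default 0.4).
#' @return A `geno_matrix` with attribute `"filter_report"`: counts of
#'   individuals and markers dropped at each step.
#' @export
qc_filter <- function(geno, maf_min = 0.05, max_marker_missing = 0.2,
                      max_ind_missing = 0.4) {
  stopifnot(inherits(geno, "geno_matrix"))
  D <- geno$dosage
  ind_miss <- rowMeans(is.na(D))
  keep_ind <- ind_miss <= max_ind_missing
  D2 <- D[keep_ind, , drop = FALSE]
  maf <- compute_maf(D2)
  mk_miss <- colMeans(is.na(D2))
  keep_mk <- !is.na(maf) & maf >= maf_min & mk_miss <= max_marker_missing
  if (!any(keep_mk)) stop("no markers survive QC filtering")
  if (!any(keep_ind)) stop("no individuals survive QC filtering")
  out <- geno_matrix(geno$ids[keep_ind], geno$markers[keep_mk, , drop = FALSE],
                     D2[, keep_mk, drop = FALSE],
                     if (!is.null(geno$depth)) geno$depth[keep_ind, keep_mk, drop = FALSE])
  attr(out, "filter_report") <- list(
    individuals_in = length(keep_ind), individuals_dropped = sum(!keep_ind),
    markers_in = length(keep_mk), markers_dropped = sum(!keep_mk),
    thresholds = list(maf_min = maf_min, max_marker_missing = max_marker_missing,
                      max_ind_missing = max_ind_missing))
  out
}

#' Parent-informed marker filter
#'
#' Retains only markers that are non-missing homozygous in both parents with
#' different alleles (the informative configuration in a biparental cross),
#' have marker missingness at or below `max_missing`, and heterozygote
#' fraction strictly below `max_het`.
#'
#' @param geno A `geno_matrix` of the progeny.
#' @param parentA,parentB Parent dosage vectors aligned to `geno`'s markers
#'   (values 0/1/2 or `NA`).
#' @param max_missing Maximum per-marker missing fraction (default 0.5, the
#'   cross-validation-pipeline rule; the selection pipeline used 0.2, i.e.
#'   presence in at least 80% of candidates).
#' @param max_het Markers with heterozygote fraction at or above this are
#'   dropped (default 0.9).
#' @return A filtered `geno_matrix`.
#' @export
parent_filter <- function(geno, parentA, parentB, max_missing = 0.5, max_het = 0.9) {
  stopifnot(inherits(geno, "geno_matrix"))
  m <- nrow(geno$markers)
  if (length(parentA) != m || length(parentB) != m)
    stop("parent genotype vectors are not aligned to the marker set")
  homo_diff <- !is.na(parentA) & !is.na(parentB) &
    parentA %in% c(0, 2) & parentB %in% c(0, 2) & parentA != parentB
  D <- geno$dosage
  mk_miss <- colMeans(is.na(D))
  het <- colMeans(D == 1, na.rm = TRUE)
  het[is.nan(het)] <- 0
  keep <- homo_diff & mk_miss <= max_missing & het < max_het
  if (!any(keep)) stop("no markers survive the parent-informed filter")
  geno_matrix(geno$ids, geno$markers[keep, , drop = FALSE],
              D[, keep, drop = FALSE],
              if (!is.null(geno$depth)) geno$depth[, keep, drop = FALSE])
}

#' Merge two genotype sets on common markers
#'
#' Row-wise concatenation restricted to the marker-id intersection, in the
#' first set's marker order. Individual id sets must be disjoint (otherwise
#' ids of the second set are suffixed with ".B").
#'
#' @param genoA,genoB `geno_matrix` objects.
#' @return A merged `geno_matrix`.
#' @export
merge_common <- function(genoA, genoB) {
  common <- intersect(genoA$markers$id, genoB$markers$id)
  if (length(common) == 0L) stop("no common markers between the two sets")
  common <- genoA$markers$id[genoA$markers$id %in% common]
  ia <- match(common, genoA$markers$id)
  ib <- match(common, genoB$markers$id)
  idsB <- genoB$ids
  if (any(idsB %in% genoA$ids)) idsB <- paste0(idsB, ".B")
  D <- rbind(genoA$dosage[, ia, drop = FALSE], genoB$dosage[, ib, drop = FALSE])
  depth <- if (!is.null(genoA$depth) && !is.null(genoB$depth))
    rbind(genoA$depth[, ia, drop = FALSE], genoB$depth[, ib, drop = FALSE])
  geno_matrix(c(genoA$ids, idsB), genoA$markers[ia, , drop = FALSE], D, depth)
}

#' Mean-impute missing dosages
#'
#' Missing cells are replaced by the marker's non-missing mean; observed cells
#' are unchanged. The result is real-valued.
#'
#' @param geno A `geno_matrix` or dosage matrix.
#' @return A complete real-valued dosage matrix (individuals x markers).
#' @export
mean_impute <- function(geno) {
  D <- if (inherits(geno, "geno_matrix")) geno$dosage else as.matrix(geno)
  mu <- colMeans(D, na.rm = TRUE)
  if (anyNA(mu) || any(is.nan(mu)))
    stop("all-missing marker(s) present; filter before imputation")
  idx <- which(is.na(D), arr.ind = TRUE)
  if (nrow(idx)) D[idx] <- mu[idx[, 2]]
  D
}

#' VanRaden genomic relationship matrix
#'
#' Centers each marker at twice its allele frequency and scales by the total
#' expected heterozygosity: `K = W W' / (2 * sum(p * (1 - p)))` with
#' `W = dosage - 2p`.
#'
#' @param dosage_complete Complete (no `NA`) real dosage matrix, individuals x
#'   markers, or a `geno_matrix` with complete dosages.
#' @return A symmetric kinship matrix with individual-id dimnames, class
#'   `kinship`.
#' @export
vanraden_grm <- function(dosage_complete) {
  D <- if (inherits(dosage_complete, "geno_matrix")) dosage_complete$dosage
  else as.matrix(dosage_complete)
  if (anyNA(D)) stop("dosage matrix contains missing values; impute first")
  p <- colMeans(D) / 2
  denom <- 2 * sum(p * (1 - p))
  if (denom <= 0) stop("all markers monomorphic: GRM denominator is zero")
  W <- sweep(D, 2, 2 * p)
  K <- tcrossprod(W) / denom
  K <- sym(K)
  class(K) <- c("kinship", class(K))
  K
}

# -- file formats -----------------------------------------------------------

#' Write a genotype matrix in the VCFtools 012 dialect
#'
#' Produces `<prefix>.012` (rows = individuals, first column a 0-based row
#' index, values 0/1/2 with missing coded -1), `<prefix>.012.indv`
#' (individual ids) and `<prefix>.012.pos` (chromosome and position).
#'
#' @param geno A `geno_matrix`.
#' @param prefix Output path prefix.
#' @return The prefix, invisibly.
#' @export
write_012 <- function(geno, prefix) {
  stopifnot(inherits(geno, "geno_matrix"))
  D <- geno$dosage
  D[is.na(D)] <- -1
  tab <- cbind(seq_len(nrow(D)) - 1L, D)
  utils::write.table(tab, paste0(prefix, ".012"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  writeLines(geno$ids, paste0(prefix, ".012.indv"))
  utils::write.table(geno$markers[, c("chrom", "pos")], paste0(prefix, ".012.pos"),
                     sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' Read a genotype matrix from the VCFtools 012 dialect
#'
#' @param prefix Path prefix of the `.012`, `.012.indv`, `.012.pos` triplet.
#' @return A `geno_matrix` (missing cells where the file holds -1).
#' @export
read_012 <- function(prefix) {
  tab <- as.matrix(utils::read.table(paste0(prefix, ".012"), sep = "\t"))
  D <- tab[, -1, drop = FALSE]
  D[D == -1] <- NA
  ids <- readLines(paste0(prefix, ".012.indv"))
  pos <- utils::read.table(paste0(prefix, ".012.pos"), sep = "\t",
                           col.names = c("chrom", "pos"))
  markers <- data.frame(chrom = pos$chrom, pos = pos$pos,
                        id = paste0(pos$chrom, "_", pos$pos),
                        stringsAsFactors = FALSE)
  geno_matrix(ids, markers, D)
}

#' Minimal VCF reader (GT and DP only, biallelic SNPs)
#'
#' Reads genotypes and per-call depths from a VCF via the vcfR package.
#' Multi-allelic records are skipped with a message; the dosage counts the
#' ALT allele.
#'
#' @param path Path to an (uncompressed or gzipped) VCF.
#' @return A `geno_matrix` with a depth layer when DP is present.
#' @export
read_vcf_minimal <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("the vcfR package is required to read VCF files")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  alt <- vcfR::getALT(v)
  biallelic <- !grepl(",", alt) & nchar(alt) == 1
  n_skip <- sum(!biallelic)
  if (n_skip > 0) {
    message(n_skip, " multi-allelic or non-SNP record(s) skipped")
    v <- v[biallelic, ]
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  code <- function(g) {
    g <- sub("\\|", "/", g)
    out <- rep(NA_real_, length(g))
    out[g %in% c("0/0")] <- 0
    out[g %in% c("0/1", "1/0")] <- 1
    out[g %in% c("1/1")] <- 2
    out
  }
  D <- apply(gt, 2, code)
  fix <- vcfR::getFIX(v)
  markers <- data.frame(chrom = fix[, "CHROM"], pos = as.numeric(fix[, "POS"]),
                        id = ifelse(is.na(fix[, "ID"]) | fix[, "ID"] == ".",
                                    paste0(fix[, "CHROM"], "_", fix[, "POS"]),
                                    fix[, "ID"]),
                        stringsAsFactors = FALSE)
  depth <- NULL
  fmt <- v@gt[, 1]
  if (all(grepl("DP", fmt))) {
    dp <- vcfR::extract.gt(v, element = "DP", as.numeric = TRUE)
    depth <- t(dp)
    depth[is.na(depth)] <- 0L
  }
  geno_matrix(colnames(gt), markers, t(D), depth)
}

#' Write / read a kinship matrix as CSV
#'
#' Plain CSV with individual ids as header row and first column.
#'
#' @param K A kinship matrix with id dimnames.
#' @param path Output path.
#' @export
write_kinship_csv <- function(K, path) {
  df <- data.frame(id = rownames(K), as.data.frame(unclass(K), check.names = FALSE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_kinship_csv
#' @export
read_kinship_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  K <- as.matrix(df[, -1, drop = FALSE])
  rownames(K) <- df[[1]]
  storage.mode(K) <- "double"
  class(K) <- c("kinship", class(K))
  K
}
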