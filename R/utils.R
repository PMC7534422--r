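#' Derive a child seed from a global seed
#'
#' All stochastic drivers in the package consume one global seed and hand
#' fixed-offset child seeds to their stages, so that re-ordering or skipping
#' stages does not silently change downstream draws.
#'
#' @param seed Integer global seed.
#' @param offset Integer stage offset (>= 0).
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
child_seed <- function(seed, offset) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.numeric(offset))
  s <- (abs(as.numeric(seed)) %% 2147483647)
  as.integer((s * 48271 + 1009 * (offset + 1)) %% 2147483646 + 1)
}

#' Run an expression under a local RNG seed
#'
#' Sets the seed if one is given, restoring the caller's RNG state afterwards;
#' with `seed = NULL` the expression simply uses the current RNG stream.
#'
#' @param seed Integer seed or `NULL`.
#' @param expr Expression to evaluate.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  expr
}

# symmetrize a matrix (guards against tiny asymmetries from accumulation)
sym <- function(M) (M + t(M)) / 2

# nearest-PSD bend: clip eigenvalues below eps * trace
bend_psd <- function(M, eps = 1e-6) {
  M <- sym(M)
  e <- eigen(M, symmetric = TRUE)
  floorval <- eps * max(sum(diag(M)), .Machine$double.eps)
  if (all(e$values >= floorval)) return(M)
  v <- pmax(e$values, floorval)
  sym(e$vectors %*% (v * t(e$vectors)))
}

# half-up rounding to `digits` decimals (report-table presentation)
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a
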