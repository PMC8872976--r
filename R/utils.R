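`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the RNG seed, evaluates `code`, and restores the caller's RNG state,
#' so simulation functions are pure functions of their inputs and seed.
#'
#' @param seed integer scalar.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  code
}

#' Partition an axis into contiguous jackknife blocks
#'
#' Units are optionally shuffled once under `seed`, then cut into `n_blocks`
#' contiguous blocks of near-equal size. All block-jackknife computations in a
#' run should share one partition so that differences between estimates
#' propagate the sampling covariance of overlapping samples.
#'
#' @param n_units length of the axis (individuals or SNPs).
#' @param n_blocks number of blocks (2 <= n_blocks <= n_units).
#' @param seed integer; used only when `shuffle = TRUE`.
#' @param shuffle shuffle units before cutting? Use `TRUE` for individuals
#'   (arbitrary order) and `FALSE` for SNPs when genomic adjacency should be
#'   preserved within blocks.
#' @return A list of `n_blocks` integer vectors of unit indices.
#' @export
make_blocks <- function(n_units, n_blocks = 200L, seed = 1L, shuffle = TRUE) {
  n_units <- as.integer(n_units)
  n_blocks <- as.integer(n_blocks)
  if (n_blocks < 2L) stop("n_blocks must be at least 2")
  if (n_blocks > n_units) stop("n_blocks (", n_blocks, ") exceeds axis length (", n_units, ")")
  ord <- if (shuffle) with_seed(seed, sample.int(n_units)) else seq_len(n_units)
  base <- n_units %/% n_blocks
  sizes <- rep.int(base, n_blocks)
  extra <- n_units %% n_blocks
  if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  unname(split(ord, rep.int(seq_len(n_blocks), sizes)))
}

# jackknife variance of leave-one-block-out estimates:
# se^2 = (B-1)/B * sum((theta_b - mean(theta_b))^2)
jackknife_se <- function(theta_blocks) {
  b <- length(theta_blocks)
  sqrt((b - 1) / b * sum((theta_blocks - mean(theta_blocks))^2))
}

# symmetric PSD square root via eigen decomposition (tolerates semi-definite)
psd_sqrt <- function(s, tol = 1e-8) {
  e <- eigen(s, symmetric = TRUE)
  if (min(e$values) < -tol * max(abs(e$values)))
    stop("matrix is not positive semi-definite")
  e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
}

# standardize matrix columns by sample mean/sd; zero-variance columns error
# unless zero_ok, in which case they become all-zero columns
standardize_columns <- function(x, zero_ok = FALSE) {
  mu <- colMeans(x)
  sdv <- apply(x, 2L, sd)
  bad <- sdv == 0 | !is.finite(sdv)
  if (any(bad) && !zero_ok)
    stop(sum(bad), " zero-variance column(s); remove monomorphic SNPs first")
  sdv[bad] <- Inf
  sweep(sweep(x, 2L, mu, "-"), 2L, sdv, "/")
}
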