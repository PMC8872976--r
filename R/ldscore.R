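#' Per-SNP association scan of a residualized phenotype
#'
#' For each SNP, the z-statistic of the slope from a simple linear regression
#' of `y_resid` on the dosage (z = beta/se(beta), i.e. the regression
#' t-statistic). Monomorphic SNPs get `NA` z and a warning.
#'
#' @param panel a [genotype_panel][simulate_genotypes].
#' @param y_resid numeric phenotype aligned to the panel rows, already
#'   residualized on covariates (see [residualize()]); must have positive
#'   variance.
#' @return An `assoc_summary` data.frame: `snp_id`, `a1`, `a2`, `z`, `n_eff`.
#' @export
run_gwas <- function(panel, y_resid) {
  stopifnot(inherits(panel, "genotype_panel"))
  x <- panel$dosages
  n <- nrow(x)
  if (length(y_resid) != n) stop("phenotype not aligned to panel")
  if (n < 3L) stop("need at least 3 individuals")
  sdy <- sd(y_resid)
  if (!is.finite(sdy) || sdy == 0) stop("phenotype has zero variance")
  yc <- y_resid - mean(y_resid)
  cm <- colMeans(x)
  # cor(x_j, y) via cross-products; sd with n-1 denominator cancels
  sxy <- as.vector(crossprod(x, yc))              # sum x*yc = sum (x-mean)*yc
  sxx <- colSums(x^2) - n * cm^2
  syy <- sum(yc^2)
  mono <- sxx <= 0
  if (any(mono)) warning(sum(mono), " monomorphic SNP(s): z set to NA")
  r <- rep(NA_real_, ncol(x))
  r[!mono] <- sxy[!mono] / sqrt(sxx[!mono] * syy)
  r <- pmin(pmax(r, -1 + 1e-12), 1 - 1e-12)
  z <- r * sqrt((n - 2) / (1 - r^2))
  out <- data.frame(snp_id = panel$map$snp_id, a1 = panel$map$a1,
                    a2 = panel$map$a2, z = z, n_eff = n,
                    stringsAsFactors = FALSE)
  class(out) <- c("assoc_summary", "data.frame")
  out
}

#' LD scores from a genotype panel
#'
#' For SNP j, `ell_j` is the sum over SNPs k on the same chromosome within
#' `window_bp` base pairs (self included) of the bias-adjusted squared
#' correlation `r2_adj = r2 - (1 - r2)/(n - 2)`. The adjustment makes the
#' self term exactly 1 and drives the expected contribution of an unlinked
#' SNP to 0, so a linkage-equilibrium panel has mean LD score near 1.
#'
#' @param panel a [genotype_panel][simulate_genotypes] with n > 2 individuals.
#' @param window_bp physical window (default 1 Mb).
#' @return A data.frame with columns `snp_id`, `ell`.
#' @export
compute_ld_scores <- function(panel, window_bp = 1000000L) {
  stopifnot(inherits(panel, "genotype_panel"))
  n <- nrow(panel$dosages)
  if (n <= 2L) stop("need more than 2 individuals for the r2 bias adjustment")
  if (window_bp < 0) stop("window_bp must be >= 0")
  map <- panel$map
  ell <- numeric(nrow(map))
  for (ch in unique(map$chrom)) {
    ix <- which(map$chrom == ch)
    xs <- panel$dosages[, ix, drop = FALSE]
    r <- suppressWarnings(cor(xs))
    r[!is.finite(r)] <- 0
    r2 <- r^2
    r2 <- r2 - (1 - r2) / (n - 2)
    inwin <- abs(outer(map$bp[ix], map$bp[ix], "-")) <= window_bp
    ell[ix] <- rowSums(r2 * inwin)
  }
  data.frame(snp_id = map$snp_id, ell = ell, stringsAsFactors = FALSE)
}

# weighted least squares of y on x with intercept; returns slope/intercept
# plus the weighted sums needed for O(1) leave-block-out updates
wls_sums <- function(x, y, w) {
  list(sw = sum(w), swx = sum(w * x), swy = sum(w * y),
       swxx = sum(w * x^2), swxy = sum(w * x * y))
}

wls_solve <- function(s) {
  denom <- s$sw * s$swxx - s$swx^2
  if (abs(denom) < .Machine$double.eps * max(1, s$sw^2))
    stop("zero variance in the regressor; slope unidentifiable")
  slope <- (s$sw * s$swxy - s$swx * s$swy) / denom
  intercept <- (s$swy - slope * s$swx) / s$sw
  list(slope = slope, intercept = intercept)
}

wls_drop <- function(s, x, y, w, idx) {
  list(sw = s$sw - sum(w[idx]), swx = s$swx - sum(w[idx] * x[idx]),
       swy = s$swy - sum(w[idx] * y[idx]),
       swxx = s$swxx - sum(w[idx] * x[idx]^2),
       swxy = s$swxy - sum(w[idx] * x[idx] * y[idx]))
}

align_sumstats_ld <- function(sumstats, ld, min_shared = 50L) {
  ix <- match(ld$snp_id, sumstats$snp_id)
  keep <- !is.na(ix) & !is.na(sumstats$z[ix])
  if (sum(keep) < min_shared)
    stop("fewer than ", min_shared, " SNPs shared between sumstats and LD scores")
  list(ss = sumstats[ix[keep], , drop = FALSE], ell = ld$ell[keep])
}

#' Univariate LD score regression
#'
#' Regresses per-SNP chi-square statistics on LD scores by weighted least
#' squares with a free intercept, following the model
#' `E[chi2_j] = N h2 ell_j / M + N a + 1`. The heritability (on the scale of
#' the analysed phenotype, here the observed 0/1 scale) is `slope * M / N`.
#' Weights are `1/max(ell_j, 1)`, a single-pass heteroscedasticity weighting.
#' Standard errors come from a delete-one-block jackknife over 200 contiguous
#' SNP blocks in map order.
#'
#' @param sumstats an `assoc_summary` (columns `snp_id`, `z`, `n_eff`).
#' @param ld LD-score table from [compute_ld_scores()].
#' @param m total number of SNPs the heritability refers to (default: the
#'   number of regression SNPs).
#' @param n_blocks jackknife blocks.
#' @param min_snps minimum shared SNPs required (default 50; lower it only
#'   for toy examples).
#' @return List with `h2`, `intercept`, `se`, `n_snps`.
#' @export
ldsc_h2 <- function(sumstats, ld, m = NULL, n_blocks = 200L, min_snps = 50L) {
  al <- align_sumstats_ld(sumstats, ld, min_snps)
  ell <- al$ell
  m <- m %||% length(ell)
  chi2 <- al$ss$z^2
  n_bar <- mean(al$ss$n_eff)
  w <- 1 / pmax(ell, 1)
  s <- wls_sums(ell, chi2, w)
  fit <- wls_solve(s)
  h2 <- fit$slope * m / n_bar
  blocks <- make_blocks(length(ell), min(n_blocks, length(ell) %/% 2), shuffle = FALSE)
  theta <- vapply(blocks, function(b) {
    wls_solve(wls_drop(s, ell, chi2, w, b))$slope * m / n_bar
  }, numeric(1))
  list(h2 = h2, intercept = fit$intercept, se = jackknife_se(theta),
       n_snps = length(ell))
}

#' Harmonize two summary-statistic sets to a shared SNP map
#'
#' Matches SNPs by id; where the allele labels of `ss2` are swapped relative
#' to `ss1` the z-score sign is flipped; SNPs with irreconcilable alleles are
#' dropped with a warning.
#'
#' @param ss1,ss2 `assoc_summary` data.frames.
#' @return List of the two aligned summary sets.
#' @export
harmonize_sumstats <- function(ss1, ss2) {
  ix <- match(ss1$snp_id, ss2$snp_id)
  keep <- !is.na(ix)
  s1 <- ss1[keep, , drop = FALSE]
  s2 <- ss2[ix[keep], , drop = FALSE]
  same <- s1$a1 == s2$a1 & s1$a2 == s2$a2
  flip <- s1$a1 == s2$a2 & s1$a2 == s2$a1
  bad <- !(same | flip)
  if (any(bad)) {
    warning(sum(bad), " SNP(s) dropped: alleles irreconcilable")
    s1 <- s1[!bad, , drop = FALSE]; s2 <- s2[!bad, , drop = FALSE]
    flip <- flip[!bad]
  }
  s2$z[flip] <- -s2$z[flip]
  s2$a1 <- s1$a1; s2$a2 <- s1$a2
  list(ss1 = s1, ss2 = s2)
}

#' Bivariate LD score regression: genetic correlation
#'
#' Estimates the genetic covariance from the weighted regression of
#' `z1_j z2_j` on LD scores (`E[z1 z2] = sqrt(N1 N2) rho_g ell_j / M +
#' intercept`), the two univariate heritabilities from [ldsc_h2()] on the
#' shared SNPs, and reports `rg = gencov / sqrt(h2_1 h2_2)`. The standard
#' error is a delete-one-block jackknife of the full ratio over contiguous
#' SNP blocks, so the sampling noise shared by the three slopes propagates.
#'
#' @param ss1,ss2 `assoc_summary` data.frames (alleles are harmonized; z of
#'   `ss2` is sign-flipped where a1/a2 are swapped).
#' @param ld LD-score table covering the shared SNPs.
#' @param m total SNP count for scaling (default: regression SNPs).
#' @param n_blocks jackknife blocks.
#' @param min_snps minimum shared SNPs required (default 50).
#' @return An object of class `rg_estimate`: list with `rg`, `se`, `p`,
#'   `h2_1`, `h2_2`, `gencov`, `intercepts` (named: h2_1, h2_2, gencov),
#'   `n_snps`, and `flag_extreme` (TRUE when |rg| > 1.25).
#' @export
ldsc_rg <- function(ss1, ss2, ld, m = NULL, n_blocks = 200L, min_snps = 50L) {
  hs <- harmonize_sumstats(ss1, ss2)
  al1 <- align_sumstats_ld(hs$ss1, ld, min_snps)
  al2 <- align_sumstats_ld(hs$ss2, ld, min_snps)
  stopifnot(identical(al1$ss$snp_id, al2$ss$snp_id))
  ell <- al1$ell
  m <- m %||% length(ell)
  n1 <- mean(al1$ss$n_eff); n2 <- mean(al2$ss$n_eff)
  w <- 1 / pmax(ell, 1)
  s1 <- wls_sums(ell, al1$ss$z^2, w)
  s2 <- wls_sums(ell, al2$ss$z^2, w)
  sx <- wls_sums(ell, al1$ss$z * al2$ss$z, w)
  est <- function(a, b, x) {
    f1 <- wls_solve(a); f2 <- wls_solve(b); fx <- wls_solve(x)
    h2_1 <- f1$slope * m / n1
    h2_2 <- f2$slope * m / n2
    gencov <- fx$slope * m / sqrt(n1 * n2)
    h2prod <- h2_1 * h2_2
    list(h2_1 = h2_1, h2_2 = h2_2, gencov = gencov,
         rg = if (h2prod > 0) gencov / sqrt(h2prod) else NaN,
         intercepts = c(h2_1 = f1$intercept, h2_2 = f2$intercept,
                        gencov = fx$intercept))
  }
  full <- est(s1, s2, sx)
  if (!is.finite(full$rg))
    stop("rg undefined: a univariate heritability slope is non-positive")
  z1sq <- al1$ss$z^2; z2sq <- al2$ss$z^2; zz <- al1$ss$z * al2$ss$z
  blocks <- make_blocks(length(ell), min(n_blocks, length(ell) %/% 2), shuffle = FALSE)
  theta <- vapply(blocks, function(b) {
    e <- est(wls_drop(s1, ell, z1sq, w, b),
             wls_drop(s2, ell, z2sq, w, b),
             wls_drop(sx, ell, zz, w, b))
    e$rg
  }, numeric(1))
  theta <- theta[is.finite(theta)]
  se <- jackknife_se(theta)
  structure(list(
    rg = full$rg, se = se,
    p = if (se > 0) 2 * pnorm(-abs(full$rg) / se) else NA_real_,
    h2_1 = full$h2_1, h2_2 = full$h2_2, gencov = full$gencov,
    intercepts = full$intercepts, n_snps = length(ell),
    flag_extreme = abs(full$rg) > 1.25
  ), class = "rg_estimate")
}

#' @export
print.rg_estimate <- function(x, ...) {
  cat(sprintf("rg = %.4f (SE %.4f, p = %.3g); h2_1 = %.4f, h2_2 = %.4f; %d SNPs%s\n",
              x$rg, x$se, x$p, x$h2_1, x$h2_2, x$n_snps,
              if (x$flag_extreme) " [|rg| > 1.25]" else ""))
  invisible(x)
}

#' Jackknife-ready data for the genetic-correlation estimator
#'
#' Precomputes the weighted regression sums of bivariate LD score regression
#' so [rg_estimate_fn()] can recompute rg with any block of SNPs removed in
#' O(block) time. Used as the `data` argument of [jackknife_difference()],
#' [enrichment_trend()] and [component_attribution()] with
#' `estimator = rg_estimate_fn`; the resampling axis is the shared SNP set.
#'
#' @param ss1,ss2 `assoc_summary` data.frames (harmonized internally).
#' @param ld LD-score table from [compute_ld_scores()].
#' @param m total SNP count for scaling (default: regression SNPs).
#' @return An opaque list with `n_axis` and precomputed sums.
#' @export
rg_jack_data <- function(ss1, ss2, ld, m = NULL) {
  hs <- harmonize_sumstats(ss1, ss2)
  al1 <- align_sumstats_ld(hs$ss1, ld)
  al2 <- align_sumstats_ld(hs$ss2, ld)
  ell <- al1$ell
  dat <- list(
    n_axis = length(ell), ell = ell,
    z1sq = al1$ss$z^2, z2sq = al2$ss$z^2, zz = al1$ss$z * al2$ss$z,
    w = 1 / pmax(ell, 1),
    n1 = mean(al1$ss$n_eff), n2 = mean(al2$ss$n_eff),
    m = m %||% length(ell)
  )
  dat$s1 <- wls_sums(ell, dat$z1sq, dat$w)
  dat$s2 <- wls_sums(ell, dat$z2sq, dat$w)
  dat$sx <- wls_sums(ell, dat$zz, dat$w)
  attr(dat, "block_axis") <- "snps"
  dat
}

#' Genetic-correlation estimate with a block of SNPs removed
#'
#' @param dat output of [rg_jack_data()].
#' @param excl integer indices of SNPs to drop.
#' @return Scalar rg estimate.
#' @export
rg_estimate_fn <- function(dat, excl = integer(0)) {
  s1 <- dat$s1; s2 <- dat$s2; sx <- dat$sx
  if (length(excl)) {
    s1 <- wls_drop(s1, dat$ell, dat$z1sq, dat$w, excl)
    s2 <- wls_drop(s2, dat$ell, dat$z2sq, dat$w, excl)
    sx <- wls_drop(sx, dat$ell, dat$zz, dat$w, excl)
  }
  h2_1 <- wls_solve(s1)$slope * dat$m / dat$n1
  h2_2 <- wls_solve(s2)$slope * dat$m / dat$n2
  gencov <- wls_solve(sx)$slope * dat$m / sqrt(dat$n1 * dat$n2)
  if (h2_1 * h2_2 <= 0) return(NaN)
  gencov / sqrt(h2_1 * h2_2)
}
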