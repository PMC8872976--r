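#' Remove SNPs in a genomic region from a panel
#'
#' Drops SNPs on `chrom` with `start_bp <= bp <= end_bp` (closed interval,
#' 1-based). Conventionally used to strip the extreme-LD major
#' histocompatibility complex region before heritability estimation; see
#' [mhc_region()] for the canonical window.
#'
#' @param panel a [genotype_panel][simulate_genotypes].
#' @param chrom chromosome (integer).
#' @param start_bp,end_bp interval bounds, `start_bp <= end_bp`.
#' @return The filtered panel, with attribute `"n_removed"`; an empty result
#'   is allowed but warned about.
#' @export
exclude_region <- function(panel, chrom, start_bp, end_bp) {
  stopifnot(inherits(panel, "genotype_panel"))
  if (start_bp > end_bp) stop("start_bp must be <= end_bp")
  hit <- panel$map$chrom == chrom &
    panel$map$bp >= start_bp & panel$map$bp <= end_bp
  out <- panel
  if (any(hit)) {
    out$dosages <- panel$dosages[, !hit, drop = FALSE]
    out$map <- panel$map[!hit, , drop = FALSE]
    rownames(out$map) <- NULL
  }
  if (ncol(out$dosages) == 0L) warning("region exclusion removed every SNP")
  attr(out, "n_removed") <- sum(hit)
  out
}

#' The MHC exclusion window
#'
#' Chromosome 6, 28,866,528-33,775,446 bp: the major histocompatibility
#' complex region customarily removed before SNP-heritability estimation.
#'
#' @return Named list with `chrom`, `start_bp`, `end_bp`.
#' @export
mhc_region <- function() list(chrom = 6L, start_bp = 28866528L, end_bp = 33775446L)

#' Genomic relatedness matrix from standardized dosages
#'
#' `G = X_s X_s' / m` with `X_s` the column-standardized (sample mean/SD)
#' dosage matrix. Diagonal entries average about 1 and off-diagonals have
#' standard deviation about `1/sqrt(m)` for unrelated individuals.
#'
#' @param panel a [genotype_panel][simulate_genotypes] with no monomorphic SNPs.
#' @return An object of class `grm`: list with `values` (n x n symmetric
#'   matrix), `n_snps_used`, and `iid`.
#' @export
compute_grm <- function(panel) {
  stopifnot(inherits(panel, "genotype_panel"))
  m <- ncol(panel$dosages)
  if (m < 2L) stop("need at least 2 SNPs")
  xs <- standardize_columns(panel$dosages)
  g <- tcrossprod(xs) / m
  structure(list(values = g, n_snps_used = m, iid = rownames(panel$dosages)),
            class = "grm")
}

#' @export
print.grm <- function(x, ...) {
  cat("grm:", nrow(x$values), "individuals,", x$n_snps_used, "SNPs\n")
  invisible(x)
}

#' Ordinary-least-squares residuals of a phenotype on covariates
#'
#' Residualizes `y` on the covariate columns plus an intercept. With no
#' covariates this is mean-centring.
#'
#' @param y numeric vector.
#' @param covariates optional numeric matrix/data.frame, n x c, full column
#'   rank together with the intercept.
#' @return Numeric residual vector.
#' @export
residualize <- function(y, covariates = NULL) {
  y <- as.numeric(y)
  if (is.null(covariates) || NCOL(covariates) == 0L) return(y - mean(y))
  x <- cbind(1, as.matrix(covariates))
  if (qr(x)$rank < ncol(x)) stop("covariate matrix is rank deficient")
  fit <- lm.fit(x, y)
  as.numeric(fit$residuals)
}

#' Observed-to-liability scale conversion factor
#'
#' For a binary trait with population prevalence `K` analysed as 0/1 in a
#' sample with case proportion `P`, the observed-scale heritability converts
#' to the liability scale by
#' `[K(1-K)]^2 / [z^2 P(1-P)]`, where `z` is the standard-normal density at
#' the liability threshold `qnorm(1-K)`. When `P = K` (random ascertainment)
#' this reduces to `K(1-K)/z^2`.
#'
#' @param K population prevalence in (0, 1).
#' @param P sample case proportion in (0, 1); defaults to `K`.
#' @return The multiplicative conversion factor.
#' @export
conversion_factor <- function(K, P = K) {
  if (K <= 0 || K >= 1 || P <= 0 || P >= 1) stop("K and P must be in (0,1)")
  z <- dnorm(qnorm(1 - K))
  (K * (1 - K))^2 / (z^2 * P * (1 - P))
}

# --- Haseman-Elston machinery -----------------------------------------------
#
# The estimator regresses pairwise phenotype products y_i*y_j on GRM entries
# g_ij over observed pairs i<j (with intercept). All pair sums are expressed
# through matrix identities so that leave-one-block-out replicates cost
# O(block^2) instead of O(n^2):
#   sum_{i<j in S} g_ij      = (w'Gw  - sum_i w_i g_ii) / 2
#   sum_{i<j in S} g_ij^2    = (w'G2w - sum_i w_i g_ii^2) / 2
#   sum_{i<j in S} y_i y_j   = ((sum v)^2 - sum v^2) / 2
#   sum_{i<j in S} y_i y_j g_ij = (v'Gv - sum_i v_i^2 g_ii) / 2
# where w is the 0/1 observation mask, v the standardized phenotype zeroed at
# unobserved entries (so cross pairs contribute 0 where needed), G2 = G*G.

#' Jackknife-ready data for the Haseman-Elston estimator
#'
#' Precomputes the pair sums of the product-moment regression so that
#' [he_estimate()] can evaluate the heritability with any block of
#' individuals removed in O(block^2) time. `y01` may contain `NA` for
#' individuals that are missing or excluded under the phenotype; the axis is
#' the full GRM row set, so several phenotypes with different missingness can
#' share one block partition. Used as the `data` argument of
#' [jackknife_difference()], [enrichment_trend()] and
#' [component_attribution()] with `estimator = he_estimate`.
#'
#' @param y01 numeric 0/1/NA phenotype aligned to the GRM rows.
#' @param grm a [grm][compute_grm] (or plain symmetric matrix).
#' @param covariates optional covariate matrix over the same rows.
#' @param cf liability conversion factor applied to the slope (see
#'   [conversion_factor()]); 1 leaves the estimate on the observed scale.
#' @return An opaque list with `n_axis` and precomputed sums.
#' @export
he_jack_data <- function(y01, grm, covariates = NULL, cf = 1) {
  g <- if (inherits(grm, "grm")) grm$values else grm
  n <- nrow(g)
  stopifnot(length(y01) == n)
  w <- as.numeric(!is.na(y01))
  if (sum(w) < 3) stop("fewer than 3 observed individuals")
  obs <- which(w == 1)
  yo <- residualize(y01[obs], if (!is.null(covariates)) covariates[obs, , drop = FALSE])
  sdy <- sd(yo)
  if (sdy == 0) stop("phenotype has zero variance after residualization")
  v <- numeric(n)
  v[obs] <- (yo - mean(yo)) / sdy
  dg <- diag(g)
  g2w <- as.vector((g * g) %*% w)
  u <- as.vector(g %*% v)
  q <- as.vector(g %*% w)
  dat <- list(
    n_axis = n, g = g, v = v, w = w, dg = dg,
    u = u, q = q, g2w = g2w,
    tot_vGv = sum(v * u), tot_wGw = sum(w * q), tot_wG2w = sum(w * g2w),
    sv = sum(v), sv2 = sum(v^2), sw = sum(w),
    s_dg_w = sum(w * dg), s_dg2_w = sum(w * dg^2),
    s_dg_v2 = sum(v^2 * dg),
    cf = cf
  )
  attr(dat, "block_axis") <- "individuals"
  dat
}

#' Haseman-Elston estimate with a block of individuals removed
#'
#' Evaluates the product-moment regression slope (times the stored liability
#' conversion factor) on all observed pairs i < j excluding individuals in
#' `excl`. With `excl = integer(0)` this is the full-sample estimate.
#'
#' @param dat output of [he_jack_data()].
#' @param excl integer indices of individuals to drop.
#' @return Scalar heritability estimate.
#' @export
he_estimate <- function(dat, excl = integer(0)) {
  if (length(excl)) {
    gbb <- dat$g[excl, excl, drop = FALSE]
    vb <- dat$v[excl]; wb <- dat$w[excl]
    vGv <- dat$tot_vGv - 2 * sum(vb * dat$u[excl]) + as.numeric(vb %*% gbb %*% vb)
    wGw <- dat$tot_wGw - 2 * sum(wb * dat$q[excl]) + as.numeric(wb %*% gbb %*% wb)
    wG2w <- dat$tot_wG2w - 2 * sum(wb * dat$g2w[excl]) +
      as.numeric(wb %*% (gbb * gbb) %*% wb)
    sv <- dat$sv - sum(vb); sv2 <- dat$sv2 - sum(vb^2); sw <- dat$sw - sum(wb)
    s_dg_w <- dat$s_dg_w - sum(wb * dat$dg[excl])
    s_dg2_w <- dat$s_dg2_w - sum(wb * dat$dg[excl]^2)
    s_dg_v2 <- dat$s_dg_v2 - sum(vb^2 * dat$dg[excl])
  } else {
    vGv <- dat$tot_vGv; wGw <- dat$tot_wGw; wG2w <- dat$tot_wG2w
    sv <- dat$sv; sv2 <- dat$sv2; sw <- dat$sw
    s_dg_w <- dat$s_dg_w; s_dg2_w <- dat$s_dg2_w; s_dg_v2 <- dat$s_dg_v2
  }
  np <- (sw^2 - sw) / 2
  if (np < 2) return(NA_real_)
  s_g <- (wGw - s_dg_w) / 2
  s_gg <- (wG2w - s_dg2_w) / 2
  s_p <- (sv^2 - sv2) / 2
  s_pg <- (vGv - s_dg_v2) / 2
  denom <- np * s_gg - s_g^2
  if (abs(denom) < .Machine$double.eps * np^2)
    stop("GRM off-diagonal variance is zero; slope unidentifiable")
  ((np * s_pg - s_p * s_g) / denom) * dat$cf
}

#' Liability-scale SNP heritability by Haseman-Elston / PCGC regression
#'
#' Encodes case/control status 0/1, residualizes on covariates, standardizes,
#' and regresses pairwise phenotype products `y_i y_j` on GRM entries `g_ij`
#' over all observed pairs i < j (intercept included; diagonal excluded). The
#' slope is the observed-scale heritability, converted to the liability scale
#' by [conversion_factor()]. Under the assumption that the population
#' prevalence equals the pre-exclusion sample prevalence (random
#' ascertainment), this product-moment regression coincides with PCGC.
#' Standard errors come from a delete-one-block jackknife over individuals
#' (contiguous blocks after one seeded shuffle); pass a shared `blocks`
#' partition when estimates for several phenotypes will be compared.
#'
#' @param assignment a [case_control][assign_case_control] object whose status
#'   vector aligns row-for-row with the GRM.
#' @param grm a [grm][compute_grm] over the same individuals (all rows of the
#'   component table; missing/excluded individuals are masked internally).
#' @param covariates optional numeric matrix over the same rows.
#' @param K population prevalence; defaults to the assignment's pre-exclusion
#'   sample prevalence. A value different from the sample prevalence is
#'   honoured but flagged in the result (`K_overridden`).
#' @param n_blocks jackknife blocks (default 200).
#' @param seed seed for the block shuffle.
#' @param blocks optional block partition from [make_blocks()] over the full
#'   axis, overriding `n_blocks`/`seed`.
#' @return An object of class `heritability_estimate`: list with
#'   `h2_observed`, `h2_liability`, `se_liability`, `p`, `K`, `P`, `n_cases`,
#'   `n_controls`, `conversion`, `n_blocks`, `phenotype`.
#' @export
pcgc_h2 <- function(assignment, grm, covariates = NULL, K = NULL,
                    n_blocks = 200L, seed = 1L, blocks = NULL) {
  stopifnot(inherits(assignment, "case_control"), inherits(grm, "grm"))
  if (assignment$degenerate)
    stop("degenerate phenotype (zero cases or zero controls): ",
         assignment$phenotype)
  n <- nrow(grm$values)
  if (length(assignment$status) != n)
    stop("assignment and GRM are not aligned")
  y01 <- ifelse(assignment$status == "case", 1,
                ifelse(assignment$status == "control", 0, NA_real_))
  K <- K %||% assignment$prevalence
  k_overridden <- !isTRUE(all.equal(K, assignment$prevalence))
  P <- assignment$P
  cf <- conversion_factor(K, P)
  dat <- he_jack_data(y01, grm, covariates, cf = cf)
  h2_liab <- he_estimate(dat)
  if (is.null(blocks)) blocks <- make_blocks(n, n_blocks, seed, shuffle = TRUE)
  theta <- vapply(blocks, function(b) he_estimate(dat, b), numeric(1))
  se <- jackknife_se(theta[!is.na(theta)])
  structure(list(
    h2_observed = h2_liab / cf, h2_liability = h2_liab, se_liability = se,
    p = if (se > 0) 2 * pnorm(-abs(h2_liab) / se) else as.numeric(h2_liab == 0),
    K = K, P = P, K_overridden = k_overridden,
    n_cases = assignment$n_cases, n_controls = assignment$n_controls,
    conversion = cf, n_blocks = length(blocks),
    phenotype = assignment$phenotype
  ), class = "heritability_estimate")
}

#' @export
print.heritability_estimate <- function(x, ...) {
  cat(sprintf("%s: h2_liability = %.4f (SE %.4f, p = %.3g); K = %.4f, P = %.4f\n",
              x$phenotype, x$h2_liability, x$se_liability, x$p, x$K, x$P))
  invisible(x)
}
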