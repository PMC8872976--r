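#' Block-jackknife difference between two estimates on a shared axis
#'
#' Computes the difference (enriched minus reference) of an estimator applied
#' to two datasets that share a resampling axis — the same individuals for
#' GRM-based heritability, the same SNPs for LD-score regressions — and a
#' delete-one-block jackknife standard error that propagates the sampling
#' covariance induced by the overlap. Blocks are contiguous along the axis
#' after one seeded shuffle; pass `blocks` to reuse a partition across many
#' differences (required for a coherent set of comparisons).
#'
#' @param estimator function `(data, excl)` returning a scalar estimate with
#'   the axis units in `excl` removed (`excl = integer(0)` for the full
#'   sample). `data$n_axis` must give the axis length.
#' @param data_ref,data_enr the two datasets (reference and enriched).
#' @param n_blocks number of blocks (default 200).
#' @param seed seed for the block shuffle.
#' @param blocks optional shared partition from [make_blocks()].
#' @return An object of class `jackknife_result`: list with `delta`
#'   (full-sample difference), `se`, `p` (two-sided normal; `p = 1` when both
#'   `delta` and `se` are 0), `n_blocks`, `block_axis`.
#' @export
jackknife_difference <- function(estimator, data_ref, data_enr,
                                 n_blocks = 200L, seed = 1L, blocks = NULL) {
  n_axis <- data_ref$n_axis
  if (is.null(n_axis) || !identical(n_axis, data_enr$n_axis))
    stop("datasets must share the same resampling axis")
  if (is.null(blocks)) blocks <- make_blocks(n_axis, n_blocks, seed, shuffle = TRUE)
  delta <- estimator(data_enr, integer(0)) - estimator(data_ref, integer(0))
  theta <- vapply(blocks, function(b) {
    estimator(data_enr, b) - estimator(data_ref, b)
  }, numeric(1))
  theta <- theta[is.finite(theta)]
  se <- if (length(theta) >= 2) jackknife_se(theta) else NA_real_
  p <- if (isTRUE(se > 0)) 2 * pnorm(-abs(delta) / se)
       else if (isTRUE(se == 0)) as.numeric(delta == 0)
       else NA_real_
  structure(list(delta = delta, se = se, p = p, n_blocks = length(blocks),
                 block_axis = attr(data_ref, "block_axis") %||% NA_character_),
            class = "jackknife_result")
}

#' @export
print.jackknife_result <- function(x, ...) {
  cat(sprintf("delta = %.5f (SE %.5f, p = %.3g), %d blocks over %s\n",
              x$delta, x$se, x$p, x$n_blocks, x$block_axis))
  invisible(x)
}

#' Inverse-variance weighted pooling of difference estimates
#'
#' `mean_delta = sum(w_i delta_i) / sum(w_i)` with `w_i = 1/se_i^2` and
#' `se = sqrt(1/sum(w_i))`. A single-member group is returned unchanged.
#' Members with `se = 0` carry infinite weight, so when any are present the
#' pooled estimate is their plain mean with `se = 0` (the IVW limit).
#'
#' @param delta,se numeric vectors of member estimates and standard errors.
#' @return List with `mean_delta`, `se`, `p`, `n_members`.
#' @export
ivw_pool <- function(delta, se) {
  stopifnot(length(delta) == length(se), length(delta) >= 1)
  if (any(se < 0)) stop("negative standard error")
  if (any(se == 0)) {
    md <- mean(delta[se == 0])
    return(list(mean_delta = md, se = 0,
                p = as.numeric(md == 0), n_members = length(delta)))
  }
  w <- 1 / se^2
  md <- sum(w * delta) / sum(w)
  se_p <- sqrt(1 / sum(w))
  list(mean_delta = md, se = se_p, p = 2 * pnorm(-abs(md) / se_p),
       n_members = length(delta))
}

# IVW over the members with finite (delta, se); a group with none is
# reported as missing, never zero
ivw_pool_finite <- function(delta, se) {
  ok <- is.finite(delta) & is.finite(se)
  if (!any(ok))
    return(list(mean_delta = NA_real_, se = NA_real_, p = NA_real_,
                n_members = 0L))
  ivw_pool(delta[ok], se[ok])
}

#' Bonferroni-adjusted significance threshold
#'
#' @param alpha family-wise level in (0, 1).
#' @param n_tests number of tests (>= 1).
#' @return `alpha / n_tests`.
#' @export
bonferroni <- function(alpha = 0.05, n_tests) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0,1)")
  if (n_tests < 1) stop("n_tests must be >= 1")
  alpha / n_tests
}

# run one jackknife difference per non-reference phenotype against the
# reference, reusing a shared block partition
pairwise_differences <- function(estimator, data_by_phenotype, ref_name,
                                 targets, blocks) {
  lapply(targets, function(ph) {
    jackknife_difference(estimator, data_by_phenotype[[ref_name]],
                         data_by_phenotype[[ph]], blocks = blocks)
  })
}

#' Trend in estimates with phenotype enrichment
#'
#' Jackknife differences of each phenotype's estimate against the
#' cardinal-only reference, pooled by enrichment level with inverse-variance
#' weights. The reference level is reported as zero by definition.
#'
#' @param estimator estimator function `(data, excl)` as in
#'   [jackknife_difference()].
#' @param data_by_phenotype named list of jackknife-ready data objects, one
#'   per phenotype, all sharing the same axis.
#' @param definitions output of [enumerate_phenotypes()] (names must match
#'   `data_by_phenotype`).
#' @param reference name of the reference phenotype (default "Cardinal").
#' @param n_blocks,seed,blocks block partition controls (shared across all
#'   differences).
#' @return Data.frame with columns `group` (enrichment level), `mean_delta`,
#'   `se`, `p`, `n_members`.
#' @export
enrichment_trend <- function(estimator, data_by_phenotype, definitions,
                             reference = "Cardinal", n_blocks = 200L,
                             seed = 1L, blocks = NULL) {
  if (!reference %in% names(data_by_phenotype))
    stop("missing reference phenotype: ", reference)
  if (is.null(blocks))
    blocks <- make_blocks(data_by_phenotype[[reference]]$n_axis, n_blocks,
                          seed, shuffle = TRUE)
  avail <- intersect(definitions$name, names(data_by_phenotype))
  targets <- setdiff(avail, reference)
  diffs <- pairwise_differences(estimator, data_by_phenotype, reference,
                                targets, blocks)
  enr <- definitions$enrichment[match(targets, definitions$name)]
  ref_level <- definitions$enrichment[match(reference, definitions$name)]
  rows <- list(data.frame(group = ref_level, mean_delta = 0, se = 0, p = NA_real_,
                          n_members = 1L))
  for (lev in sort(unique(enr))) {
    sel <- which(enr == lev)
    pool <- ivw_pool_finite(vapply(diffs[sel], `[[`, numeric(1), "delta"),
                            vapply(diffs[sel], `[[`, numeric(1), "se"))
    rows[[length(rows) + 1L]] <- data.frame(
      group = lev, mean_delta = pool$mean_delta, se = pool$se, p = pool$p,
      n_members = pool$n_members)
  }
  out <- do.call(rbind, rows)
  attr(out, "differences") <- stats::setNames(diffs, targets)
  out
}

#' Attribute estimate differences to individual components
#'
#' For every pair of phenotypes differing by exactly one component, computes
#' the jackknife difference (enriched minus base) on shared blocks, pools the
#' pairs within each (added component, base enrichment) cell by inverse
#' variance — 25 cells for five components — and additionally reports each
#' component's across-enrichment IVW average over all its pairs
#' (`base_enrichment = "all"`). Pairs involving degenerate phenotypes (absent
#' from `data_by_phenotype`) are skipped with a message; a cell with no
#' estimable pair is reported as `NA`, never zero.
#'
#' @inheritParams enrichment_trend
#' @param pairs output of [component_pairs()].
#' @return Data.frame with columns `component`, `base_enrichment` (integer as
#'   character, or "all"), `mean_delta`, `se`, `p`, `n_members`.
#' @export
component_attribution <- function(estimator, data_by_phenotype, pairs,
                                  n_blocks = 200L, seed = 1L, blocks = NULL) {
  estimable <- pairs$base %in% names(data_by_phenotype) &
    pairs$enriched %in% names(data_by_phenotype)
  if (any(!estimable))
    message(sum(!estimable), " pair(s) skipped: degenerate or missing phenotype")
  if (!any(estimable)) stop("no estimable pairs")
  first <- data_by_phenotype[[pairs$base[which(estimable)[1]]]]
  if (is.null(blocks))
    blocks <- make_blocks(first$n_axis, n_blocks, seed, shuffle = TRUE)
  diffs <- vector("list", nrow(pairs))
  for (i in which(estimable)) {
    diffs[[i]] <- jackknife_difference(estimator,
                                       data_by_phenotype[[pairs$base[i]]],
                                       data_by_phenotype[[pairs$enriched[i]]],
                                       blocks = blocks)
  }
  pool_rows <- function(sel, comp, level) {
    sel <- sel[estimable[sel]]
    if (!length(sel))
      return(data.frame(component = comp, base_enrichment = level,
                        mean_delta = NA_real_, se = NA_real_, p = NA_real_,
                        n_members = 0L))
    pool <- ivw_pool_finite(vapply(diffs[sel], `[[`, numeric(1), "delta"),
                            vapply(diffs[sel], `[[`, numeric(1), "se"))
    data.frame(component = comp, base_enrichment = level,
               mean_delta = pool$mean_delta, se = pool$se, p = pool$p,
               n_members = pool$n_members)
  }
  rows <- list()
  for (comp in sort(unique(pairs$added_component))) {
    for (lev in sort(unique(pairs$base_enrichment))) {
      sel <- which(pairs$added_component == comp & pairs$base_enrichment == lev)
      rows[[length(rows) + 1L]] <- pool_rows(sel, comp, as.character(lev))
    }
    rows[[length(rows) + 1L]] <-
      pool_rows(which(pairs$added_component == comp), comp, "all")
  }
  out <- do.call(rbind, rows)
  attr(out, "differences") <- diffs
  out
}
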