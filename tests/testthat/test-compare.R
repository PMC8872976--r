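# simple jackknife-ready dataset: estimator = mean of the retained entries
mean_data <- function(x) {
  d <- list(n_axis = length(x), x = x)
  attr(d, "block_axis") <- "individuals"
  d
}
mean_est <- function(d, excl = integer(0)) {
  if (length(excl)) mean(d$x[-excl]) else mean(d$x)
}

test_that("identical data give a zero difference with zero SE and p = 1", {
  x <- rnorm(100)
  d <- mean_data(x)
  jk <- jackknife_difference(mean_est, d, d, n_blocks = 20, seed = 1)
  expect_equal(jk$delta, 0)
  expect_equal(jk$se, 0)
  expect_equal(jk$p, 1)
})

test_that("delete-one jackknife of a paired mean difference equals the closed form", {
  set.seed(5)
  n <- 120
  x <- rnorm(n); y <- x + rnorm(n, sd = 0.4)
  jk <- jackknife_difference(mean_est, mean_data(x), mean_data(y),
                             n_blocks = n, seed = 2)
  expect_equal(jk$delta, mean(y) - mean(x), tolerance = 1e-12)
  # paired-t closed form: sd(y - x)/sqrt(n)
  expect_equal(jk$se, sd(y - x) / sqrt(n), tolerance = 1e-9)
  expect_equal(jk$n_blocks, n)
})

test_that("block partitions are contiguous after one shuffle and respect bounds", {
  b <- make_blocks(103, 10, seed = 3)
  expect_length(b, 10)
  expect_equal(sort(unlist(b)), 1:103)
  expect_true(all(lengths(b) %in% c(10, 11)))
  expect_identical(make_blocks(103, 10, seed = 3), b)
  b2 <- make_blocks(10, 5, shuffle = FALSE)
  expect_equal(b2[[1]], 1:2)
  expect_error(make_blocks(10, 1), "at least 2")
  expect_error(make_blocks(10, 11), "exceeds")
})

test_that("the jackknife difference test is calibrated under a null difference", {
  set.seed(11)
  n <- 400; reps <- 100
  pvals <- numeric(reps)
  for (r in seq_len(reps)) {
    x <- rnorm(n)
    y <- x + rnorm(n, sd = 0.6)      # overlapping data, equal means
    jk <- jackknife_difference(mean_est, mean_data(x), mean_data(y),
                               n_blocks = 100, seed = r)
    pvals[r] <- jk$p
  }
  rate <- mean(pvals < 0.05)
  expect_lt(abs(rate - 0.05), 1.96 * sqrt(0.05 * 0.95 / reps))
})

test_that("inverse-variance pooling satisfies its closed-form identities", {
  # worked example: (0.10, 0.01) and (0.20, 0.02)
  pool <- ivw_pool(c(0.10, 0.20), c(0.01, 0.02))
  expect_equal(pool$mean_delta, 0.12, tolerance = 1e-12)
  expect_equal(pool$se, sqrt(1 / 12500), tolerance = 1e-12)
  expect_equal(pool$se, 0.00894, tolerance = 1e-3)

  # single member unchanged
  one <- ivw_pool(0.3, 0.05)
  expect_equal(one$mean_delta, 0.3)
  expect_equal(one$se, 0.05)

  # equal variances reduce to the arithmetic mean with se/sqrt(k)
  eq <- ivw_pool(c(0.1, 0.2, 0.3), rep(0.06, 3))
  expect_equal(eq$mean_delta, 0.2, tolerance = 1e-12)
  expect_equal(eq$se, 0.06 / sqrt(3), tolerance = 1e-12)

  # permutation invariance and machine-precision identity
  d <- c(0.05, -0.02, 0.11, 0.004); s <- c(0.01, 0.03, 0.02, 0.015)
  p1 <- ivw_pool(d, s); p2 <- ivw_pool(rev(d), rev(s))
  expect_identical(p1$mean_delta, sum(d / s^2) / sum(1 / s^2))
  expect_equal(p2$mean_delta, p1$mean_delta, tolerance = 1e-15)
  expect_equal(p2$se, p1$se, tolerance = 1e-15)
})

test_that("Bonferroni thresholds match the reference values", {
  expect_equal(bonferroni(0.05, 32), 0.0015625)
  expect_equal(round(bonferroni(0.05, 32), 4), 0.0016)
  expect_equal(bonferroni(0.05, 25), 0.002)
  expect_equal(bonferroni(0.05, 1), 0.05)
  expect_error(bonferroni(1.2, 10), "alpha")
})

test_that("enrichment trend: all phenotypes identical to the reference give zero deltas", {
  defs <- enumerate_phenotypes()
  x <- rnorm(200)
  data_by_ph <- setNames(lapply(seq_len(nrow(defs)), function(i) mean_data(x)),
                         defs$name)
  tr <- enrichment_trend(mean_est, data_by_ph, defs, n_blocks = 20, seed = 4)
  expect_equal(nrow(tr), 6)   # reference level + enrichment 2..6
  expect_true(all(tr$mean_delta == 0))
  expect_equal(tr$n_members, c(1L, 5L, 10L, 10L, 5L, 1L))
  expect_error(enrichment_trend(mean_est, data_by_ph[-1], defs),
               "missing reference")
})

test_that("component attribution pools pairs into 25 cells plus per-component averages", {
  defs <- enumerate_phenotypes()
  pairs <- component_pairs(defs)
  set.seed(6)
  # phenotype value = sum of fixed per-component offsets -> known cell deltas
  offsets <- setNames(c(0.5, -0.3, 0.1, 0, 0.2), mdd_components())
  base_x <- rnorm(300)
  data_by_ph <- setNames(lapply(seq_len(nrow(defs)), function(i) {
    mean_data(base_x + sum(offsets[defs$components[[i]]]))
  }), defs$name)
  at <- component_attribution(mean_est, data_by_ph, pairs, n_blocks = 30, seed = 7)
  expect_equal(nrow(at), 30L)  # 25 cells + 5 per-component rows
  cells <- at[at$base_enrichment != "all", ]
  expect_equal(nrow(cells), 25L)
  # every pair in a cell shares the same exact delta = the component offset
  for (cmp in mdd_components()) {
    got <- cells$mean_delta[cells$component == cmp]
    expect_equal(got, rep(offsets[[cmp]], 5), tolerance = 1e-10,
                 ignore_attr = TRUE)
  }
  # cell sizes follow choose(4, base_enrichment - 1): 1,4,6,4,1 per component
  for (cmp in mdd_components()) {
    sub <- cells[cells$component == cmp, ]
    expect_equal(sub$n_members[order(as.integer(sub$base_enrichment))],
                 c(1L, 4L, 6L, 4L, 1L))
  }
})

test_that("pair deltas telescope along any component chain", {
  arch <- test_arch(effect_seed = 8)
  panel <- simulate_genotypes(250, 150, seed = 9)
  tab <- simulate_components(panel, arch, seed = 10)
  grm <- compute_grm(panel)
  chain <- list(character(0), "duration", c("duration", "recurrence"),
                c("duration", "recurrence", "impairment"))
  ests <- vapply(chain, function(cc) {
    a <- assign_case_control(tab, cc)
    he_estimate(he_jack_data(
      ifelse(a$status == "case", 1, ifelse(a$status == "control", 0, NA)),
      grm, cf = conversion_factor(a$prevalence, a$P)))
  }, numeric(1))
  expect_equal(sum(diff(ests)), ests[length(ests)] - ests[1], tolerance = 1e-12)
})
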