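test_that("region exclusion uses a closed interval and leaves other SNPs untouched", {
  d <- matrix(rep(c(0L, 1L, 2L), length.out = 40), nrow = 4)
  panel <- toy_panel(d, bp = seq(100L, 1000L, by = 100L))

  none <- exclude_region(panel, chrom = 2, start_bp = 1, end_bp = 1e9)
  expect_identical(none$dosages, panel$dosages)
  expect_equal(attr(none, "n_removed"), 0L)

  cut <- exclude_region(panel, chrom = 1, start_bp = 300, end_bp = 700)
  expect_equal(attr(cut, "n_removed"), 5L)
  expect_equal(cut$map$bp, c(100L, 200L, 800L, 900L, 1000L))

  at_start <- exclude_region(panel, chrom = 1, start_bp = 300, end_bp = 300)
  expect_equal(attr(at_start, "n_removed"), 1L)  # boundary SNP removed
  expect_error(exclude_region(panel, 1, 500, 400), "start_bp")

  expect_equal(mhc_region()$chrom, 6L)
})

test_that("GRM matches hand computation and behaves for duplicated individuals", {
  # 2 individuals, 2 SNPs: dosages [[0,2],[2,0]], standardized +-1/sqrt(2)
  panel <- toy_panel(matrix(c(0L, 2L, 2L, 0L), 2, 2))
  g <- compute_grm(panel)
  expect_equal(g$values, matrix(c(0.5, -0.5, -0.5, 0.5), 2, 2,
                                dimnames = dimnames(g$values)))

  pan <- simulate_genotypes(60, 300, seed = 5)
  dup <- pan
  dup$dosages[2, ] <- dup$dosages[1, ]
  gd <- compute_grm(dup)$values
  expect_equal(gd[1, 2], (gd[1, 1] + gd[2, 2]) / 2)

  big <- compute_grm(simulate_genotypes(400, 2000, seed = 6))$values
  off <- big[upper.tri(big)]
  expect_lt(abs(sd(off) - 1 / sqrt(2000)), 0.3 / sqrt(2000))
  expect_lt(abs(mean(diag(big)) - 1), 0.1)
  # centred genotypes force row sums of G to 0: mean(off) = -tr(G)/(n(n-1))
  expect_equal(mean(off), -mean(diag(big)) / (400 - 1), tolerance = 1e-10)

  mono <- toy_panel(matrix(c(1L, 1L, 0L, 2L), 2, 2))
  expect_error(compute_grm(mono), "zero-variance|monomorphic")
})

test_that("residualization reduces to known closed forms", {
  y <- c(1, 2, 3, 5)
  expect_equal(residualize(y), y - mean(y))
  expect_equal(residualize(y, covariates = cbind(y)), rep(0, 4))
  # hand OLS on x = 0:3 -> slope 1.3, intercept 0.8
  expect_equal(residualize(y, covariates = cbind(0:3)), c(0.2, -0.1, -0.4, 0.3))
  expect_error(residualize(y, covariates = cbind(1:4, 2 * (1:4))), "rank")
})

test_that("liability conversion factor matches closed forms and is well behaved", {
  expect_equal(conversion_factor(0.5, 0.5), 0.25 / dnorm(0)^2)
  expect_equal(conversion_factor(0.5, 0.5), 1.570796, tolerance = 1e-6)
  for (k in c(0.05, 0.2, 0.47)) {
    z <- dnorm(qnorm(1 - k))
    expect_equal(conversion_factor(k), k * (1 - k) / z^2)
    # general formula at P != K
    expect_equal(conversion_factor(k, 0.3), (k * (1 - k))^2 / (z^2 * 0.3 * 0.7))
  }
  grid <- vapply(seq(0.01, 0.99, by = 0.01), conversion_factor, numeric(1))
  expect_true(all(is.finite(grid) & grid > 0))
  expect_error(conversion_factor(0, 0.5), "in \\(0,1\\)")
})

test_that("HE regression equals the brute-force pairwise-product oracle", {
  set.seed(77)
  n <- 50
  panel <- simulate_genotypes(n, 120, seed = 17)
  arch <- test_arch(effect_seed = 18)
  tab <- simulate_components(panel, arch, seed = 19)
  a <- assign_case_control(tab, c("recurrence"))
  grm <- compute_grm(panel)
  est <- pcgc_h2(a, grm, n_blocks = 10)

  # independent oracle: explicit loop over all i < j pairs, lm slope
  y01 <- ifelse(a$status == "case", 1, ifelse(a$status == "control", 0, NA))
  obs <- which(!is.na(y01))
  v <- as.numeric(scale(y01[obs]))
  g <- grm$values[obs, obs]
  prods <- c(); gs <- c()
  for (i in seq_along(obs)[-length(obs)]) {
    for (j in (i + 1):length(obs)) {
      prods <- c(prods, v[i] * v[j]); gs <- c(gs, g[i, j])
    }
  }
  slope <- unname(coef(lm(prods ~ gs))[2])
  expect_equal(est$h2_observed, slope, tolerance = 1e-8)
})

test_that("permuted phenotypes give heritability consistent with zero", {
  panel <- simulate_genotypes(1000, 600, seed = 23)
  arch <- test_arch(effect_seed = 24)
  tab <- simulate_components(panel, arch, seed = 25)
  grm <- compute_grm(panel)
  a <- assign_case_control(tab, character(0))
  set.seed(26)
  a$status <- a$status[sample(length(a$status))]
  est <- pcgc_h2(a, grm, seed = 27)
  expect_lt(abs(est$h2_liability), 2 * est$se_liability)
})

test_that("jackknife SE of the heritability shrinks as the sample grows", {
  arch <- test_arch(effect_seed = 33)
  ses <- vapply(c(400, 900, 2000), function(n) {
    panel <- simulate_genotypes(n, 500, seed = 34)
    tab <- simulate_components(panel, arch, seed = 35)
    a <- assign_case_control(tab, character(0))
    pcgc_h2(a, compute_grm(panel), n_blocks = 100, seed = 36)$se_liability
  }, numeric(1))
  expect_true(all(diff(ses) < 0))
})

test_that("degenerate phenotypes and misaligned inputs are refused", {
  panel <- simulate_genotypes(100, 50, seed = 41)
  grm <- compute_grm(panel)
  tab <- toy_component_table(cardinal = rep(1L, 100))
  a <- assign_case_control(tab, character(0))
  expect_true(a$degenerate)
  expect_error(pcgc_h2(a, grm), "degenerate")

  tab2 <- toy_component_table(cardinal = rep(c(0L, 1L), 30))
  a2 <- assign_case_control(tab2, character(0))
  expect_error(pcgc_h2(a2, grm), "not aligned")
})
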