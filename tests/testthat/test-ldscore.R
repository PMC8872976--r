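test_that("GWAS z-scores match the regression t-statistic and flag self-association", {
  # toy 6-individual single-SNP check against lm()
  x <- c(0L, 1L, 2L, 0L, 1L, 2L)
  y <- c(0.1, 0.2, 0.8, -0.3, 0.1, 0.5)
  panel <- toy_panel(cbind(x, matrix(rep(c(0L, 1L, 2L, 2L, 1L, 0L), 2), 6, 2)))
  ss <- run_gwas(panel, residualize(y))
  t_lm <- summary(lm(y ~ x))$coefficients["x", "t value"]
  expect_equal(ss$z[1], t_lm, tolerance = 1e-10)
  expect_equal(ss$n_eff, rep(6, 3))

  # phenotype equal to a SNP's standardized dosage maximizes |z| at that SNP
  pan <- simulate_genotypes(300, 80, seed = 3)
  ys <- as.numeric(scale(pan$dosages[, 37]))
  zz <- run_gwas(pan, residualize(ys))$z
  expect_equal(which.max(abs(zz)), 37L)

  mono <- toy_panel(cbind(c(1L, 1L, 1L, 1L), c(0L, 1L, 2L, 1L)))
  expect_warning(ssm <- run_gwas(mono, residualize(c(1, 0, 1, 0))), "monomorphic")
  expect_true(is.na(ssm$z[1]) && !is.na(ssm$z[2]))
})

test_that("a permuted phenotype is calibrated under the null", {
  pan <- simulate_genotypes(500, 1000, seed = 7)
  arch <- test_arch(effect_seed = 8)
  tab <- simulate_components(pan, arch, seed = 9)
  set.seed(10)
  y <- sample(as.numeric(tab$cardinal))
  ss <- run_gwas(pan, residualize(y))
  frac <- mean(abs(ss$z) > 1.96)
  expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / 1000))
})

test_that("LD scores: isolated SNP gives 1, duplicated SNP gives 2, LE panel mean near 1", {
  pan <- simulate_genotypes(500, 60, seed = 12)
  # window 0 bp: every SNP is isolated, ell = 1 exactly (adjusted self term)
  ld0 <- compute_ld_scores(pan, window_bp = 0)
  expect_equal(ld0$ell, rep(1, 60))

  dup <- pan
  dup$dosages[, 2] <- dup$dosages[, 1]
  lddup <- compute_ld_scores(dup, window_bp = 15000)
  expect_equal(lddup$ell[1], 2, tolerance = 1e-9)

  le <- simulate_genotypes(1500, 300, seed = 13)
  ldle <- compute_ld_scores(le, window_bp = 1e9)
  expect_lt(abs(mean(ldle$ell) - 1), 0.05)

  two <- toy_panel(matrix(c(0L, 1L, 2L, 1L, 0L, 2L), 3, 2))
  expect_error(compute_ld_scores(structure(list(dosages = two$dosages[1:2, ],
                                                map = two$map),
                                           class = "genotype_panel")),
               "more than 2")
})

test_that("univariate LDSC reduces to closed forms", {
  # constant chi2 = 1 -> slope 0, intercept 1
  ld <- data.frame(snp_id = sprintf("s%03d", 1:60), ell = seq(1, 3, length.out = 60))
  ss <- structure(data.frame(snp_id = ld$snp_id, a1 = "A", a2 = "G",
                             z = rep(1, 60), n_eff = 100),
                  class = c("assoc_summary", "data.frame"))
  fit <- ldsc_h2(ss, ld, n_blocks = 10)
  expect_equal(fit$h2, 0, tolerance = 1e-12)
  expect_equal(fit$intercept, 1, tolerance = 1e-12)

  # hand WLS on a printed toy table
  ell <- c(1, 2, 3, 4, 5)
  chi2 <- c(1.2, 1.7, 2.0, 2.6, 3.1)
  lds <- data.frame(snp_id = paste0("t", 1:5), ell = ell)
  sst <- structure(data.frame(snp_id = lds$snp_id, a1 = "A", a2 = "G",
                              z = sqrt(chi2), n_eff = 100),
                   class = c("assoc_summary", "data.frame"))
  fit2 <- ldsc_h2(sst, lds, m = 5, n_blocks = 2, min_snps = 5)
  w <- 1 / ell
  oracle <- unname(coef(lm(chi2 ~ ell, weights = w))[2]) * 5 / 100
  expect_equal(fit2$h2, oracle, tolerance = 1e-12)

  # scale invariance: multiplying all ell and M by c leaves h2 unchanged
  lds2 <- transform(lds, ell = ell * 7)
  fit3 <- ldsc_h2(sst, lds2, m = 5 * 7, n_blocks = 2, min_snps = 5)
  w2 <- 1 / pmax(ell * 7, 1)
  oracle3 <- unname(coef(lm(chi2 ~ I(ell * 7), weights = w2))[2]) * 35 / 100
  expect_equal(fit3$h2, oracle3, tolerance = 1e-12)
  expect_equal(fit3$h2, fit2$h2, tolerance = 1e-12)  # exact scale invariance

  expect_error(ldsc_h2(sst, transform(lds, ell = rep(2, 5)), n_blocks = 2,
                       min_snps = 5),
               "zero variance")
})

test_that("allele harmonization flips swapped z and drops irreconcilable SNPs", {
  ss1 <- structure(data.frame(snp_id = c("a", "b", "c"), a1 = c("A", "A", "A"),
                              a2 = c("G", "G", "G"), z = c(1, -2, 3), n_eff = 50),
                   class = c("assoc_summary", "data.frame"))
  ss2 <- ss1
  ss2$a1 <- c("A", "G", "T"); ss2$a2 <- c("G", "A", "C")
  expect_warning(h <- harmonize_sumstats(ss1, ss2), "irreconcilable")
  expect_equal(h$ss2$z, c(1, 2))
  expect_equal(h$ss1$snp_id, c("a", "b"))
})

test_that("bivariate LDSC: self-correlation is 1 and allele flips leave rg unchanged", {
  pan <- simulate_genotypes(2000, 600, n_chrom = 2, seed = 15,
                            ld_block_size = 4, ld_rho = 0.85)
  arch <- test_arch(h2_cardinal = 0.5, h2_external = 0.5,
                    rg_cardinal_external = 0.8, effect_seed = 16)
  tab <- simulate_components(pan, arch, seed = 17)
  ld <- compute_ld_scores(pan)
  ss1 <- run_gwas(pan, residualize(as.numeric(tab$cardinal)))
  self <- ldsc_rg(ss1, ss1, ld, n_blocks = 50)
  expect_equal(self$rg, 1, tolerance = 1e-9)
  expect_equal(self$se, 0, tolerance = 1e-9)

  ss2 <- simulate_external_sumstats(pan, arch, n_external = 2000, seed = 18)
  r <- ldsc_rg(ss1, ss2, ld, n_blocks = 50)
  flipped <- ss2
  flipped$a1 <- ss2$a2; flipped$a2 <- ss2$a1; flipped$z <- -ss2$z
  r_flip <- ldsc_rg(ss1, flipped, ld, n_blocks = 50)
  expect_equal(r$rg, r_flip$rg, tolerance = 1e-12)
  expect_equal(r$se, r_flip$se, tolerance = 1e-12)
})

test_that("jackknife SE of rg is calibrated against the replicate spread", {
  pan <- simulate_genotypes(800, 500, n_chrom = 2, seed = 21,
                            ld_block_size = 4, ld_rho = 0.85)
  ld <- compute_ld_scores(pan)
  xs <- scale(pan$dosages)
  m <- ncol(xs)
  set.seed(22)
  rgs <- numeric(60); ses <- numeric(60)
  for (r in 1:60) {
    b_shared <- rnorm(m); b1 <- rnorm(m); b2 <- rnorm(m)
    # true rg = 0.8: beta_i = sqrt(0.8)*shared + sqrt(0.2)*own, h2 = 0.5
    beta1 <- sqrt(0.5 / m) * (sqrt(0.8) * b_shared + sqrt(0.2) * b1)
    beta2 <- sqrt(0.5 / m) * (sqrt(0.8) * b_shared + sqrt(0.2) * b2)
    y1 <- as.vector(xs %*% beta1) + rnorm(800, sd = sqrt(0.5))
    y2 <- as.vector(xs %*% beta2) + rnorm(800, sd = sqrt(0.5))
    ss1 <- run_gwas(pan, residualize(y1))
    ss2 <- run_gwas(pan, residualize(y2))
    est <- ldsc_rg(ss1, ss2, ld, n_blocks = 50)
    rgs[r] <- est$rg; ses[r] <- est$se
  }
  ratio <- mean(ses) / sd(rgs)
  expect_gt(ratio, 0.7)
  expect_lt(ratio, 1.3)
  # and the recovery itself: mean estimate near the true 0.8
  expect_lt(abs(mean(rgs) - 0.8), 3 * sd(rgs) / sqrt(60))
})
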