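#' Component labels for the phenotype grid
#'
#' The five binary diagnostic components layered on the cardinal-symptom
#' baseline, in canonical order: episode recurrence, five or more symptoms,
#' long episode duration (> 6 months), functional impairment, and persistence
#' of symptoms during the episode.
#'
#' @return Character vector of length 5.
#' @export
mdd_components <- function() {
  c("recurrence", "symptoms5", "duration", "impairment", "persistence")
}

arch_traits <- function() c("cardinal", mdd_components(), "external_md")

# draw a pair of haplotype matrices (n x m, 0/1) with optional block LD:
# within an LD block, each haplotype allele copies its left neighbour with
# probability rho, else is a fresh Bernoulli(p) draw, giving r ~ rho^k decay
sim_haplotypes <- function(n, p, block_id, rho) {
  m <- length(p)
  h <- matrix(rbinom(n * m, 1L, rep(p, each = n)), n, m)
  if (!is.null(block_id) && rho > 0) {
    for (j in seq_len(m)[-1]) {
      if (block_id[j] == block_id[j - 1L]) {
        copy <- runif(n) < rho
        h[copy, j] <- h[copy, j - 1L]
      }
    }
  }
  h
}

sim_dosages <- function(n, p, block_id = NULL, rho = 0) {
  sim_haplotypes(n, p, block_id, rho) + sim_haplotypes(n, p, block_id, rho)
}

#' Simulate a genotype panel
#'
#' Draws an n x m dosage matrix with entries in \{0, 1, 2\}. Per-SNP minor
#' allele frequencies are uniform in `maf_bounds`; base-pair positions lie on
#' a regular grid within each chromosome. By default SNPs are in linkage
#' equilibrium (dosage = binomial(2, p)); `ld_block_size > 1` switches to a
#' haplotype-copying model in which SNPs within a block share their generating
#' frequency and adjacent alleles are copied with probability `ld_rho`, so
#' squared correlations decay roughly as `ld_rho^(2k)` with distance `k`.
#' Block LD gives the LD-score regressions a regressor with real variation.
#'
#' @param n individuals (>= 2).
#' @param m SNPs (>= 2).
#' @param maf_bounds length-2 interval inside (0, 0.5].
#' @param n_chrom number of chromosomes; SNPs are split evenly.
#' @param seed integer seed; the panel is a pure function of the arguments.
#' @param ld_block_size SNPs per LD block (1 = linkage equilibrium).
#' @param ld_rho haplotype copy probability within a block, in \[0, 1).
#' @param bp_spacing base pairs between adjacent grid positions.
#' @return An object of class `genotype_panel`: list with `dosages` (integer
#'   matrix, rownames = individual ids) and `map` (data.frame with columns
#'   `snp_id`, `chrom`, `bp`, `a1`, `a2`, `freq`, `ld_block`), plus the
#'   generator settings needed to simulate further cohorts on the same map.
#' @export
simulate_genotypes <- function(n, m, maf_bounds = c(0.05, 0.5), n_chrom = 1L,
                               seed = 1L, ld_block_size = 1L, ld_rho = 0,
                               bp_spacing = 10000L) {
  n <- as.integer(n); m <- as.integer(m); n_chrom <- as.integer(n_chrom)
  if (n < 2L || m < 2L) stop("need n >= 2 and m >= 2")
  if (length(maf_bounds) != 2L || maf_bounds[1] > maf_bounds[2])
    stop("maf_bounds must be a non-empty interval")
  if (maf_bounds[1] <= 0 || maf_bounds[2] > 0.5)
    stop("maf_bounds must lie within (0, 0.5]")
  if (n_chrom < 1L || n_chrom > m) stop("invalid n_chrom")
  if (ld_block_size < 1L) stop("ld_block_size must be >= 1")
  if (ld_rho < 0 || ld_rho >= 1) stop("ld_rho must be in [0, 1)")

  chrom <- sort(rep_len(seq_len(n_chrom), m))
  bp <- unlist(lapply(split(seq_len(m), chrom),
                      function(ix) seq_along(ix) * bp_spacing), use.names = FALSE)
  block_id <- if (ld_block_size > 1L) {
    # block sizes cycle 1..ld_block_size so LD scores genuinely vary across
    # SNPs; blocks never straddle chromosomes
    bid <- integer(m); nxt <- 1L
    for (ch in unique(chrom)) {
      ix <- which(chrom == ch)
      sizes <- rep(seq_len(ld_block_size), length.out = length(ix))
      reps <- rep.int(seq_along(sizes), sizes)[seq_along(ix)]
      bid[ix] <- nxt + reps - 1L
      nxt <- max(bid[ix]) + 1L
    }
    bid
  } else seq_len(m)

  panel <- with_seed(seed, {
    p <- runif(max(block_id), maf_bounds[1], maf_bounds[2])[block_id]
    dos <- sim_dosages(n, p, block_id, ld_rho)
    list(p = p, dos = dos)
  })
  dosages <- panel$dos
  storage.mode(dosages) <- "integer"
  rownames(dosages) <- sprintf("id%05d", seq_len(n))
  map <- data.frame(
    snp_id = sprintf("snp%06d", seq_len(m)),
    chrom = chrom, bp = bp,
    a1 = "A", a2 = "G",
    freq = panel$p,
    ld_block = block_id,
    stringsAsFactors = FALSE
  )
  colnames(dosages) <- map$snp_id
  structure(list(dosages = dosages, map = map,
                 ld_rho = ld_rho, ld_block_size = ld_block_size),
            class = "genotype_panel")
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat("genotype_panel:", nrow(x$dosages), "individuals x", ncol(x$dosages),
      "SNPs on", length(unique(x$map$chrom)), "chromosome(s)\n")
  invisible(x)
}

validate_genotype_panel <- function(panel, maf_bounds = NULL) {
  stopifnot(inherits(panel, "genotype_panel"))
  d <- panel$dosages
  if (anyNA(d)) stop("genotype panel contains missing dosages")
  if (!all(d %in% 0:2)) stop("dosages must be in {0,1,2}")
  if (anyDuplicated(panel$map$snp_id)) stop("snp_ids must be unique")
  for (ch in unique(panel$map$chrom)) {
    bp <- panel$map$bp[panel$map$chrom == ch]
    if (is.unsorted(bp, strictly = TRUE)) stop("bp not strictly increasing within chromosome ", ch)
  }
  if (!is.null(maf_bounds)) {
    f <- panel$map$freq
    if (any(f < maf_bounds[1] | f > maf_bounds[2]))
      stop("allele frequencies outside configured bounds")
  }
  invisible(TRUE)
}

#' Define a multivariate liability-threshold architecture
#'
#' Describes seven correlated liabilities: the cardinal-symptom baseline, the
#' five diagnostic components, and an external major-depression trait measured
#' in an independent cohort. Each trait has a liability-scale heritability and
#' a population prevalence; genetic and environmental correlation matrices tie
#' the traits together. Because both correlation matrices have unit diagonal,
#' the implied total liability variance h2 + (1 - h2) is 1 for every trait.
#'
#' Genetic effect vectors are drawn once under `effect_seed` and shared by all
#' cohorts simulated from the architecture, so the true genetic correlation
#' between any two traits — including between a cohort phenotype and the
#' external trait — equals the corresponding `genetic_corr` entry.
#'
#' @param h2 named numeric vector of liability heritabilities in \[0, 1\] for
#'   the traits in [mdd_components()] order plus `cardinal` and `external_md`.
#' @param genetic_corr,env_corr 7 x 7 symmetric positive semi-definite
#'   correlation matrices (unit diagonal) over the same traits.
#' @param prevalence named numeric vector of trait prevalences in (0, 1\].
#' @param exclusion_rate probability an individual carries the exclusion flag
#'   (screening analogue for schizophrenia/bipolar/substance abuse).
#' @param effect_seed integer seed for the shared SNP effect draws.
#' @return An object of class `component_architecture`.
#' @export
component_architecture <- function(h2, genetic_corr, env_corr, prevalence,
                                   exclusion_rate = 0, effect_seed = 1L) {
  traits <- arch_traits()
  h2 <- h2[traits]; prevalence <- prevalence[traits]
  if (anyNA(h2) || anyNA(prevalence))
    stop("h2 and prevalence must be named for all traits: ",
         paste(traits, collapse = ", "))
  if (any(h2 < 0 | h2 > 1)) stop("h2 outside [0,1]")
  if (any(prevalence <= 0 | prevalence > 1)) stop("prevalence outside (0,1]")
  if (exclusion_rate < 0 || exclusion_rate >= 1) stop("exclusion_rate outside [0,1)")
  for (nm in c("genetic_corr", "env_corr")) {
    s <- get(nm)
    if (!isTRUE(all.equal(dim(s), c(7L, 7L))) ||
        !isTRUE(all.equal(s, t(s))) ||
        !isTRUE(all.equal(unname(diag(s)), rep(1, 7))))
      stop(nm, " must be 7x7 symmetric with unit diagonal")
    ev <- eigen(s, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8) stop(nm, " is not positive semi-definite")
    dimnames(s) <- list(traits, traits)
    assign(nm, s)
  }
  structure(list(traits = traits, h2 = h2, genetic_corr = genetic_corr,
                 env_corr = env_corr, prevalence = prevalence,
                 exclusion_rate = exclusion_rate,
                 effect_seed = as.integer(effect_seed)),
            class = "component_architecture")
}

#' Default liability architecture used by the pipeline
#'
#' Heritabilities bracket the 0.10-0.16 band typical of SNP-based estimates
#' for depression phenotypes; the cardinal baseline prevalence is set near the
#' questionnaire endorsement proportion (~0.56) and component prevalences in
#' the 0.35-0.45 band, so that joint endorsement of all components lands
#' under 0.1 at desk scale. Genetic correlations among internal traits are
#' 0.6, and 0.8 between the cardinal baseline and the external trait.
#'
#' @inheritParams component_architecture
#' @return A `component_architecture`.
#' @export
default_architecture <- function(exclusion_rate = 0.025, effect_seed = 1L) {
  traits <- arch_traits()
  h2 <- c(cardinal = 0.13, recurrence = 0.15, symptoms5 = 0.16,
          duration = 0.10, impairment = 0.12, persistence = 0.12,
          external_md = 0.13)
  prev <- c(cardinal = 0.56, recurrence = 0.35, symptoms5 = 0.40,
            duration = 0.35, impairment = 0.45, persistence = 0.40,
            external_md = 0.30)
  g <- matrix(0.60, 7, 7); diag(g) <- 1
  g[7, 1] <- g[1, 7] <- 0.80
  g[7, 2:6] <- g[2:6, 7] <- 0.55
  e <- matrix(0.45, 7, 7); diag(e) <- 1
  e[7, -7] <- e[-7, 7] <- 0   # external cohort: independent environment
  dimnames(g) <- dimnames(e) <- list(traits, traits)
  component_architecture(h2 = h2, genetic_corr = g, env_corr = e,
                         prevalence = prev, exclusion_rate = exclusion_rate,
                         effect_seed = effect_seed)
}

#' @export
print.component_architecture <- function(x, ...) {
  cat("component_architecture over", length(x$traits), "traits\n")
  print(data.frame(trait = x$traits, h2 = unname(x$h2),
                   prevalence = unname(x$prevalence)))
  invisible(x)
}

# shared SNP effect matrix (m x 7) with per-SNP covariance Sigma_g / m,
# Sigma_g = D(sqrt(h2)) %*% genetic_corr %*% D(sqrt(h2)); drawn under the
# architecture's effect_seed so cohorts share true genetic effects
draw_effects <- function(arch, m) {
  sig_g <- outer(sqrt(arch$h2), sqrt(arch$h2)) * arch$genetic_corr
  s <- psd_sqrt(sig_g)
  b <- with_seed(arch$effect_seed, matrix(rnorm(m * 7), m, 7) / sqrt(m)) %*% s
  colnames(b) <- arch$traits
  b
}

# dichotomize a liability at its realized upper-K quantile so the sample
# prevalence is exact by construction (K = 1 means everyone is a case)
threshold_liability <- function(liab, k) {
  n <- length(liab)
  n_case <- round(k * n)
  if (n_case >= n) return(rep(1L, n))
  if (n_case <= 0) return(rep(0L, n))
  cut <- sort(liab, decreasing = TRUE)[n_case]
  as.integer(liab >= cut)
}

#' Simulate binary component endorsements under the liability model
#'
#' For each trait the liability is a standardized-genotype score (using the
#' shared effect vectors of `arch`) plus a correlated environmental draw;
#' the binary indicator is 1 when the liability exceeds its realized
#' upper-prevalence quantile, so the sample prevalence of each trait matches
#' its target exactly. Exclusion flags are Bernoulli(`exclusion_rate`),
#' independent of component values. With `missing_rate > 0` each component
#' response (not the exclusion flag) is independently masked, a coarse
#' analogue of questionnaire skip patterns.
#'
#' @param panel a [genotype_panel][simulate_genotypes].
#' @param arch a [component_architecture()].
#' @param seed integer seed for the environmental and exclusion draws (SNP
#'   effects come from `arch$effect_seed`).
#' @param missing_rate per-entry missingness probability in \[0, 1).
#' @return A `component_table` data.frame with columns `iid`, `cardinal`, the
#'   five components (integer 0/1/NA), and `excluded` (logical). The realized
#'   liability matrix is attached as attribute `"liabilities"`.
#' @export
simulate_components <- function(panel, arch, seed = 1L, missing_rate = 0) {
  stopifnot(inherits(panel, "genotype_panel"),
            inherits(arch, "component_architecture"))
  if (missing_rate < 0 || missing_rate >= 1) stop("missing_rate outside [0,1)")
  n <- nrow(panel$dosages); m <- ncol(panel$dosages)
  beta <- draw_effects(arch, m)
  xs <- standardize_columns(panel$dosages)
  gval <- xs %*% beta                      # n x 7 genetic liabilities
  sig_e <- outer(sqrt(1 - arch$h2), sqrt(1 - arch$h2)) * arch$env_corr
  se_sqrt <- psd_sqrt(sig_e)
  drawn <- with_seed(seed, {
    env <- matrix(rnorm(n * 7), n, 7) %*% se_sqrt
    excl <- runif(n) < arch$exclusion_rate
    miss <- if (missing_rate > 0) matrix(runif(n * 6) < missing_rate, n, 6) else NULL
    list(env = env, excl = excl, miss = miss)
  })
  liab <- gval + drawn$env
  colnames(liab) <- arch$traits
  internal <- setdiff(arch$traits, "external_md")
  ind <- vapply(internal, function(tr) threshold_liability(liab[, tr], arch$prevalence[[tr]]),
                integer(n))
  if (!is.null(drawn$miss)) ind[drawn$miss] <- NA_integer_
  tab <- data.frame(iid = rownames(panel$dosages), ind,
                    excluded = drawn$excl, stringsAsFactors = FALSE)
  class(tab) <- c("component_table", "data.frame")
  attr(tab, "liabilities") <- liab
  tab
}

#' Simulate GWAS summary statistics for an independent external cohort
#'
#' A fresh cohort of `n_external` individuals is simulated on the same SNP map
#' (same generating frequencies and LD process as `panel_template`) using the
#' SAME genetic effect vectors — drawn under the architecture's `effect_seed`
#' — so the true genetic correlation between the external trait and any
#' internal trait is the corresponding `genetic_corr` entry. The binary trait
#' is generated by realized-quantile thresholding and a GWAS of the
#' mean-centred status on dosage yields per-SNP Z and N.
#'
#' @param panel_template the internal cohort's [genotype_panel][simulate_genotypes]
#'   (supplies the SNP map and LD settings; its individuals are not reused).
#' @param arch a [component_architecture()].
#' @param trait architecture trait to measure in the external cohort.
#' @param n_external external cohort size (>= 100).
#' @param seed integer seed for the external cohort's genotype and
#'   environment draws.
#' @return An `assoc_summary` data.frame: `snp_id`, `a1`, `a2`, `z`, `n_eff`.
#' @export
simulate_external_sumstats <- function(panel_template, arch,
                                       trait = "external_md",
                                       n_external = 5000L, seed = 1L) {
  stopifnot(inherits(panel_template, "genotype_panel"),
            inherits(arch, "component_architecture"))
  if (!trait %in% arch$traits) stop("unknown trait label: ", trait)
  n_external <- as.integer(n_external)
  if (n_external < 100L) stop("n_external must be >= 100")
  map <- panel_template$map
  m <- nrow(map)
  beta <- draw_effects(arch, m)[, trait]
  h2 <- arch$h2[[trait]]
  sim <- with_seed(seed, {
    dos <- sim_dosages(n_external, map$freq, map$ld_block, panel_template$ld_rho)
    env <- rnorm(n_external, sd = sqrt(1 - h2))
    list(dos = dos, env = env)
  })
  xs <- standardize_columns(sim$dos, zero_ok = TRUE)
  liab <- as.vector(xs %*% beta) + sim$env
  y <- threshold_liability(liab, arch$prevalence[[trait]])
  ext_panel <- structure(list(dosages = sim$dos, map = map), class = "genotype_panel")
  run_gwas(ext_panel, residualize(y))
}
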