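# architecture builder with scalar knobs, shared across test files
test_arch <- function(h2_cardinal = 0.3, h2_components = 0.2, h2_external = 0.3,
                      prev_cardinal = 0.5, prev_components = 0.4,
                      prev_external = 0.5, g_internal = 0.5, g_external = 0.5,
                      rg_cardinal_external = g_external, e_internal = 0.3,
                      exclusion_rate = 0, effect_seed = 1L) {
  traits <- c("cardinal", mdd_components(), "external_md")
  h2 <- stats::setNames(c(h2_cardinal, rep(h2_components, 5), h2_external), traits)
  prev <- stats::setNames(c(prev_cardinal, rep(prev_components, 5), prev_external),
                          traits)
  g <- matrix(g_internal, 7, 7); diag(g) <- 1
  g[7, -7] <- g[-7, 7] <- g_external
  g[1, 7] <- g[7, 1] <- rg_cardinal_external
  e <- matrix(e_internal, 7, 7); diag(e) <- 1
  e[7, -7] <- e[-7, 7] <- 0
  dimnames(g) <- dimnames(e) <- list(traits, traits)
  component_architecture(h2 = h2, genetic_corr = g, env_corr = e,
                         prevalence = prev, exclusion_rate = exclusion_rate,
                         effect_seed = effect_seed)
}

# hand-constructable genotype panel around a dosage matrix
toy_panel <- function(dosages, chrom = NULL, bp = NULL) {
  n <- nrow(dosages); m <- ncol(dosages)
  chrom <- chrom %||% rep(1L, m)
  bp <- bp %||% (seq_len(m) * 1000L)
  rownames(dosages) <- sprintf("id%03d", seq_len(n))
  map <- data.frame(snp_id = sprintf("s%03d", seq_len(m)), chrom = chrom,
                    bp = bp, a1 = "A", a2 = "G",
                    freq = colMeans(dosages) / 2, ld_block = seq_len(m),
                    stringsAsFactors = FALSE)
  colnames(dosages) <- map$snp_id
  structure(list(dosages = dosages, map = map, ld_rho = 0, ld_block_size = 1L),
            class = "genotype_panel")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# component table from explicit vectors (NA allowed)
toy_component_table <- function(cardinal, recurrence = cardinal,
                                symptoms5 = cardinal, duration = cardinal,
                                impairment = cardinal, persistence = cardinal,
                                excluded = rep(FALSE, length(cardinal))) {
  tab <- data.frame(iid = sprintf("id%03d", seq_along(cardinal)),
                    cardinal = cardinal, recurrence = recurrence,
                    symptoms5 = symptoms5, duration = duration,
                    impairment = impairment, persistence = persistence,
                    excluded = excluded, stringsAsFactors = FALSE)
  class(tab) <- c("component_table", "data.frame")
  tab
}
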