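# TSV writers/readers with '#'-prefixed header metadata ----------------------

write_tsv_meta <- function(df, path, meta = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(meta))
    writeLines(paste0("# ", names(meta), ": ", unname(meta)), con)
  suppressWarnings(
    write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = TRUE)
  )
  invisible(path)
}

read_tsv_meta <- function(path) {
  read.table(path, header = TRUE, sep = "\t", comment.char = "#",
             stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write / read a component table
#'
#' TSV with columns `IID cardinal recurrence symptoms5 duration impairment
#' persistence excluded`; missing component responses are coded `NA`,
#' `excluded` is 0/1.
#'
#' @param table a `component_table` (see [simulate_components()]).
#' @param path file path.
#' @param meta optional named character vector written as `# key: value`
#'   header lines.
#' @return The path (write) or a `component_table` data.frame (read).
#' @export
write_component_table <- function(table, path, meta = character()) {
  out <- data.frame(IID = table$iid, table[c("cardinal", mdd_components())],
                    excluded = as.integer(table$excluded))
  write_tsv_meta(out, path, meta)
}

#' @rdname write_component_table
#' @export
read_component_table <- function(path) {
  raw <- read_tsv_meta(path)
  need <- c("IID", "cardinal", mdd_components(), "excluded")
  if (!all(need %in% names(raw))) stop("component table lacks required columns")
  tab <- data.frame(iid = as.character(raw$IID),
                    raw[c("cardinal", mdd_components())],
                    excluded = as.logical(raw$excluded),
                    stringsAsFactors = FALSE)
  class(tab) <- c("component_table", "data.frame")
  tab
}

#' Write / read LDSC-style summary statistics
#'
#' TSV with columns `SNP A1 A2 Z N`.
#'
#' @param ss an `assoc_summary` data.frame.
#' @param path file path.
#' @param meta optional named header metadata.
#' @export
write_sumstats <- function(ss, path, meta = character()) {
  write_tsv_meta(data.frame(SNP = ss$snp_id, A1 = ss$a1, A2 = ss$a2,
                            Z = ss$z, N = ss$n_eff), path, meta)
}

#' @rdname write_sumstats
#' @export
read_sumstats <- function(path) {
  raw <- read_tsv_meta(path)
  if (!all(c("SNP", "A1", "A2", "Z", "N") %in% names(raw)))
    stop("sumstats file lacks SNP/A1/A2/Z/N columns")
  out <- data.frame(snp_id = as.character(raw$SNP), a1 = as.character(raw$A1),
                    a2 = as.character(raw$A2), z = as.numeric(raw$Z),
                    n_eff = as.numeric(raw$N), stringsAsFactors = FALSE)
  class(out) <- c("assoc_summary", "data.frame")
  out
}

#' Write a PLINK-style phenotype file for one case/control assignment
#'
#' Columns `FID IID status` with 1 = control, 2 = case, `NA` =
#' missing/excluded.
#'
#' @param assignment a [case_control][assign_case_control] object.
#' @param iid individual ids aligned to the assignment.
#' @param path file path.
#' @param meta optional named header metadata.
#' @export
write_case_control_plink <- function(assignment, iid, path, meta = character()) {
  status <- ifelse(assignment$status == "case", 2L,
                   ifelse(assignment$status == "control", 1L, NA_integer_))
  write_tsv_meta(data.frame(FID = iid, IID = iid, status = status), path, meta)
}

#' Write / read the genotype TSV dialect
#'
#' `<prefix>.dosages.tsv` holds one row per individual (first column `IID`,
#' remaining columns = per-SNP dosages); `<prefix>.snps.tsv` holds the SNP
#' map. An alternative to [write_plink()] when a diff-able text panel is
#' preferred.
#'
#' @param panel a [genotype_panel][simulate_genotypes].
#' @param prefix path prefix.
#' @export
write_panel_tsv <- function(panel, prefix) {
  dos <- data.frame(IID = rownames(panel$dosages), panel$dosages,
                    check.names = FALSE)
  write_tsv_meta(dos, paste0(prefix, ".dosages.tsv"))
  write_tsv_meta(panel$map, paste0(prefix, ".snps.tsv"))
  invisible(prefix)
}

#' @rdname write_panel_tsv
#' @export
read_panel_tsv <- function(prefix) {
  dos <- read_tsv_meta(paste0(prefix, ".dosages.tsv"))
  map <- read_tsv_meta(paste0(prefix, ".snps.tsv"))
  d <- as.matrix(dos[, -1, drop = FALSE])
  storage.mode(d) <- "integer"
  rownames(d) <- as.character(dos$IID)
  if (is.null(map$ld_block)) map$ld_block <- seq_len(nrow(map))
  structure(list(dosages = d, map = map, ld_rho = 0,
                 ld_block_size = 1L), class = "genotype_panel")
}

# Configuration ----------------------------------------------------------------

#' Default pipeline configuration
#'
#' A desk-scale run: 2,000 individuals by 3,000 SNPs over 6 chromosomes with
#' block LD, an 8,000-individual external cohort, the default liability
#' architecture, 200 jackknife blocks, a 1 Mb LD-score window, and an
#' extreme-LD exclusion window analogous in role to the MHC removal. All
#' randomness is governed by the explicit seeds; the population prevalence
#' policy is the pre-exclusion sample prevalence.
#'
#' @return A nested configuration list (see the vignette for field meanings).
#' @export
default_config <- function() {
  list(
    simulation = list(
      n = 2000L, m = 3000L, n_chrom = 6L, maf_bounds = c(0.05, 0.5),
      ld_block_size = 3L, ld_rho = 0.8, bp_spacing = 10000L,
      genotype_seed = 11L, component_seed = 12L, external_seed = 13L,
      effect_seed = 14L, n_external = 8000L,
      external_traits = "external_md",
      exclusion_rate = 0.025, missing_rate = 0
    ),
    phenotypes = list(components = mdd_components()),
    estimation = list(
      K_policy = "sample_pre_exclusion",
      n_blocks = 200L, jackknife_seed = 17L,
      ld_window_bp = 1000000L,
      exclude_region = list(chrom = 2L, start_bp = 2000000L, end_bp = 2200000L)
    ),
    output = list(write_genotypes = FALSE, write_plink = FALSE)
  )
}

#' Read and validate a YAML run configuration
#'
#' Unspecified fields fall back to [default_config()]. Validation failures
#' raise errors naming the offending field.
#'
#' @param path YAML file.
#' @return A validated configuration list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  merged <- modifyList(default_config(), cfg)
  validate_config(merged)
  merged
}

validate_config <- function(cfg) {
  sim <- cfg$simulation
  for (f in c("n", "m", "n_chrom", "genotype_seed", "component_seed",
              "external_seed", "effect_seed", "n_external"))
    if (!is.numeric(sim[[f]]) || length(sim[[f]]) != 1 || sim[[f]] <= 0)
      stop("config error: simulation$", f, " must be a positive number")
  if (length(sim$maf_bounds) != 2 || sim$maf_bounds[1] > sim$maf_bounds[2])
    stop("config error: simulation$maf_bounds must be a valid interval")
  est <- cfg$estimation
  if (!identical(est$K_policy, "sample_pre_exclusion"))
    stop("config error: estimation$K_policy must be 'sample_pre_exclusion'")
  if (!is.numeric(est$n_blocks) || est$n_blocks < 2)
    stop("config error: estimation$n_blocks must be >= 2")
  invisible(TRUE)
}

#' Hash a configuration
#'
#' MD5 of the canonical YAML serialization; written into the header of every
#' pipeline output so reruns are attributable to an exact configuration.
#'
#' @param config configuration list.
#' @return Character hash.
#' @export
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(config), tmp)
  unname(tools::md5sum(tmp))
}

# Pipeline ---------------------------------------------------------------------

config_architecture <- function(cfg) {
  arch <- default_architecture(exclusion_rate = cfg$simulation$exclusion_rate,
                               effect_seed = cfg$simulation$effect_seed)
  arch
}

stage_marker <- function(out_dir, stage) file.path(out_dir, paste0(".done_", stage))

require_stage <- function(out_dir, stage, needed_by) {
  if (!file.exists(stage_marker(out_dir, stage)))
    stop("dependency error: stage '", stage, "' must run before '", needed_by, "'")
}

fmt_num <- function(x) ifelse(is.na(x), "NA", formatC(x, digits = 10, format = "g"))

# deterministic reconstruction of the simulated objects from the config
build_sim_state <- function(cfg) {
  sim <- cfg$simulation
  arch <- config_architecture(cfg)
  panel <- simulate_genotypes(sim$n, sim$m, sim$maf_bounds, sim$n_chrom,
                              seed = sim$genotype_seed,
                              ld_block_size = sim$ld_block_size,
                              ld_rho = sim$ld_rho, bp_spacing = sim$bp_spacing)
  comp <- simulate_components(panel, arch, seed = sim$component_seed,
                              missing_rate = sim$missing_rate)
  external <- lapply(seq_along(sim$external_traits), function(i) {
    simulate_external_sumstats(panel, arch, trait = sim$external_traits[i],
                               n_external = sim$n_external,
                               seed = sim$external_seed + i - 1L)
  })
  names(external) <- sim$external_traits
  list(arch = arch, panel = panel, components = comp, external = external)
}

#' Run the analysis pipeline end to end
#'
#' Stages: `simulate` (genotype panel, component table, external summary
#' statistics), `phenotypes` (32 definitions, assignments, manifest), `h2`
#' (GRM + liability heritability per phenotype), `rg` (LD scores, per-
#' phenotype GWAS, genetic correlation with each external trait), `compare`
#' (enrichment trends and component attribution for h2 and rg on shared
#' jackknife blocks), and `report` (JSON + TSV bundle). Every output carries
#' the config hash and seeds in `#` header lines; two runs with an identical
#' configuration are byte-identical. Running a stage whose prerequisites have
#' not been run in `out_dir` raises a dependency error.
#'
#' @param config configuration list (see [default_config()],
#'   [read_run_config()]).
#' @param out_dir output directory (created if needed).
#' @param stages character vector of stages, or `"all"`.
#' @return Invisibly, a list with the in-memory results of the executed
#'   stages.
#' @export
run_pipeline <- function(config = default_config(), out_dir,
                         stages = "all") {
  all_stages <- c("simulate", "phenotypes", "h2", "rg", "compare", "report")
  if (identical(stages, "all")) stages <- all_stages
  if (!all(stages %in% all_stages))
    stop("unknown stage(s): ", paste(setdiff(stages, all_stages), collapse = ", "))
  validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  meta <- c(config_hash = hash,
            seed = paste(config$simulation$genotype_seed,
                         config$simulation$component_seed,
                         config$simulation$external_seed,
                         config$simulation$effect_seed, sep = "/"))
  state <- list(config = config, meta = meta)

  mark <- function(stage) file.create(stage_marker(out_dir, stage))

  if ("simulate" %in% stages) {
    message("[simulate] generating cohorts")
    state <- c(state, build_sim_state(config))
    write_component_table(state$components, file.path(out_dir, "components.tsv"), meta)
    for (tr in names(state$external))
      write_sumstats(state$external[[tr]],
                     file.path(out_dir, paste0("sumstats_", tr, ".tsv")), meta)
    if (isTRUE(config$output$write_genotypes))
      write_panel_tsv(state$panel, file.path(out_dir, "panel"))
    if (isTRUE(config$output$write_plink))
      write_plink(state$panel, file.path(out_dir, "panel"))
    mark("simulate")
  }

  ensure_sim <- function(stage) {
    require_stage(out_dir, "simulate", stage)
    if (is.null(state$panel)) state <<- c(state, build_sim_state(config))
  }

  ensure_phenotypes <- function(stage) {
    require_stage(out_dir, "phenotypes", stage)
    if (is.null(state$assignments)) state <<- c(state, build_phenotypes(state))
  }

  build_phenotypes <- function(state) {
    defs <- enumerate_phenotypes(config$phenotypes$components)
    assignments <- lapply(seq_len(nrow(defs)), function(i)
      assign_case_control(state$components, defs[i, ]))
    names(assignments) <- defs$name
    list(definitions = defs, assignments = assignments)
  }

  if ("phenotypes" %in% stages) {
    ensure_sim("phenotypes")
    message("[phenotypes] enumerating definitions and assigning status")
    state <- c(state, build_phenotypes(state))
    defs <- state$definitions
    manifest <- data.frame(
      name = defs$name,
      components = vapply(defs$components, paste, character(1), collapse = ","),
      enrichment = defs$enrichment,
      n_cases = vapply(state$assignments, `[[`, integer(1), "n_cases"),
      n_controls = vapply(state$assignments, `[[`, integer(1), "n_controls"),
      prevalence = fmt_num(vapply(state$assignments, `[[`, numeric(1), "prevalence")),
      degenerate = vapply(state$assignments, `[[`, logical(1), "degenerate")
    )
    write_tsv_meta(manifest, file.path(out_dir, "manifest.tsv"), meta)
    status <- vapply(state$assignments, function(a)
      ifelse(a$status == "case", "2", ifelse(a$status == "control", "1", "NA")),
      character(length(state$components$iid)))
    status_df <- data.frame(IID = state$components$iid, status, check.names = FALSE)
    write_tsv_meta(status_df, file.path(out_dir, "status.tsv"), meta)
    mark("phenotypes")
  }

  # panel after the configured extreme-LD region exclusion
  analysis_panel <- function() {
    if (!is.null(state$apanel)) return(state$apanel)
    ex <- config$estimation$exclude_region
    p <- if (!is.null(ex))
      exclude_region(state$panel, ex$chrom, ex$start_bp, ex$end_bp)
    else state$panel
    state$apanel <<- p
    p
  }

  if ("h2" %in% stages) {
    ensure_sim("h2"); ensure_phenotypes("h2")
    message("[h2] GRM + PCGC/HE heritability for ", length(state$assignments),
            " phenotypes")
    pan <- analysis_panel()
    grm <- compute_grm(pan)
    n <- nrow(grm$values)
    blocks <- make_blocks(n, config$estimation$n_blocks,
                          config$estimation$jackknife_seed, shuffle = TRUE)
    ests <- list()
    for (ph in names(state$assignments)) {
      a <- state$assignments[[ph]]
      if (a$degenerate) { message("  skipping degenerate phenotype: ", ph); next }
      ests[[ph]] <- pcgc_h2(a, grm, blocks = blocks)
    }
    state$grm <- grm
    state$h2_blocks <- blocks
    state$h2 <- ests
    tab <- data.frame(
      phenotype = names(ests),
      enrichment = state$definitions$enrichment[match(names(ests), state$definitions$name)],
      n_cases = vapply(ests, `[[`, integer(1), "n_cases"),
      n_controls = vapply(ests, `[[`, integer(1), "n_controls"),
      K = fmt_num(vapply(ests, `[[`, numeric(1), "K")),
      P = fmt_num(vapply(ests, `[[`, numeric(1), "P")),
      h2_obs = fmt_num(vapply(ests, `[[`, numeric(1), "h2_observed")),
      h2_liab = fmt_num(vapply(ests, `[[`, numeric(1), "h2_liability")),
      se = fmt_num(vapply(ests, `[[`, numeric(1), "se_liability")),
      p = fmt_num(vapply(ests, `[[`, numeric(1), "p"))
    )
    write_tsv_meta(tab, file.path(out_dir, "h2_estimates.tsv"), meta)
    mark("h2")
  }

  build_phenotype_sumstats <- function(pan) {
    lapply(state$assignments, function(a) {
      if (a$degenerate) return(NULL)
      obs <- which(a$status %in% c("case", "control"))
      y <- as.numeric(a$status[obs] == "case")
      sub <- structure(list(dosages = pan$dosages[obs, , drop = FALSE],
                            map = pan$map), class = "genotype_panel")
      suppressWarnings(run_gwas(sub, residualize(y)))
    })
  }

  if ("rg" %in% stages) {
    ensure_sim("rg"); ensure_phenotypes("rg")
    message("[rg] LD scores, per-phenotype GWAS, LDSC genetic correlations")
    pan <- analysis_panel()
    ld <- compute_ld_scores(pan, config$estimation$ld_window_bp)
    write_tsv_meta(data.frame(SNP = ld$snp_id, L2 = fmt_num(ld$ell)),
                   file.path(out_dir, "ldscores.tsv"), meta)
    ph_ss <- build_phenotype_sumstats(pan)
    state$ld <- ld
    state$phenotype_sumstats <- ph_ss
    rows <- list(); rgs <- list()
    for (tr in names(state$external)) {
      for (ph in names(ph_ss)) {
        if (is.null(ph_ss[[ph]])) next
        est <- tryCatch(
          ldsc_rg(ph_ss[[ph]], state$external[[tr]], ld,
                  n_blocks = config$estimation$n_blocks),
          error = function(e) {
            message("  rg undefined for ", ph, " vs ", tr, ": ",
                    conditionMessage(e))
            NULL
          })
        rgs[[tr]][[ph]] <- est
        na <- fmt_num(NA_real_)
        rows[[length(rows) + 1L]] <- if (is.null(est)) {
          data.frame(phenotype = ph, external_trait = tr, rg = na, se = na,
                     p = na, h2_1 = na, h2_2 = na, int_1 = na, int_2 = na,
                     int_gc = na)
        } else data.frame(
          phenotype = ph, external_trait = tr,
          rg = fmt_num(est$rg), se = fmt_num(est$se), p = fmt_num(est$p),
          h2_1 = fmt_num(est$h2_1), h2_2 = fmt_num(est$h2_2),
          int_1 = fmt_num(est$intercepts[["h2_1"]]),
          int_2 = fmt_num(est$intercepts[["h2_2"]]),
          int_gc = fmt_num(est$intercepts[["gencov"]]))
      }
    }
    state$rg <- rgs
    write_tsv_meta(do.call(rbind, rows), file.path(out_dir, "rg_estimates.tsv"), meta)
    mark("rg")
  }

  if ("compare" %in% stages) {
    require_stage(out_dir, "h2", "compare")
    require_stage(out_dir, "rg", "compare")
    ensure_sim("compare"); ensure_phenotypes("compare")
    message("[compare] jackknife differences, IVW pooling")
    pan <- analysis_panel()
    if (is.null(state$grm)) state$grm <- compute_grm(pan)
    if (is.null(state$ld)) state$ld <- compute_ld_scores(pan, config$estimation$ld_window_bp)
    if (is.null(state$phenotype_sumstats))
      state$phenotype_sumstats <- build_phenotype_sumstats(pan)
    defs <- state$definitions
    pairs <- component_pairs(defs)
    n <- nrow(state$grm$values)
    blocks_ind <- state$h2_blocks %||%
      make_blocks(n, config$estimation$n_blocks,
                  config$estimation$jackknife_seed, shuffle = TRUE)

    he_data <- list()
    for (ph in names(state$assignments)) {
      a <- state$assignments[[ph]]
      if (a$degenerate) next
      y01 <- ifelse(a$status == "case", 1,
                    ifelse(a$status == "control", 0, NA_real_))
      he_data[[ph]] <- he_jack_data(y01, state$grm,
                                    cf = conversion_factor(a$prevalence, a$P))
    }
    trend_h2 <- enrichment_trend(he_estimate, he_data, defs, blocks = blocks_ind)
    attr_h2 <- component_attribution(he_estimate, he_data, pairs, blocks = blocks_ind)
    write_compare <- function(df, file) {
      num <- vapply(df, is.numeric, logical(1)) & names(df) != "group"
      df[num] <- lapply(df[num], fmt_num)
      write_tsv_meta(df, file.path(out_dir, file), meta)
    }
    write_compare(trend_h2, "trend_h2.tsv")
    write_compare(attr_h2, "attribution_h2.tsv")
    state$trend_h2 <- trend_h2; state$attribution_h2 <- attr_h2

    state$trend_rg <- list(); state$attribution_rg <- list()
    for (tr in names(state$external)) {
      rg_data <- list()
      for (ph in names(state$phenotype_sumstats)) {
        if (is.null(state$phenotype_sumstats[[ph]])) next
        rg_data[[ph]] <- rg_jack_data(state$phenotype_sumstats[[ph]],
                                      state$external[[tr]], state$ld)
      }
      blocks_snp <- make_blocks(rg_data[[1]]$n_axis, config$estimation$n_blocks,
                                config$estimation$jackknife_seed, shuffle = TRUE)
      trend_rg <- enrichment_trend(rg_estimate_fn, rg_data, defs, blocks = blocks_snp)
      attr_rg <- component_attribution(rg_estimate_fn, rg_data, pairs,
                                       blocks = blocks_snp)
      write_compare(trend_rg, paste0("trend_rg_", tr, ".tsv"))
      write_compare(attr_rg, paste0("attribution_rg_", tr, ".tsv"))
      state$trend_rg[[tr]] <- trend_rg
      state$attribution_rg[[tr]] <- attr_rg
    }
    mark("compare")
  }

  if ("report" %in% stages) {
    for (st in c("phenotypes", "h2", "rg", "compare"))
      require_stage(out_dir, st, "report")
    message("[report] assembling bundle")
    h2_tab <- read_tsv_meta(file.path(out_dir, "h2_estimates.tsv"))
    rg_tab <- read_tsv_meta(file.path(out_dir, "rg_estimates.tsv"))
    manifest <- read_tsv_meta(file.path(out_dir, "manifest.tsv"))
    rep_tab <- merge(manifest[c("name", "enrichment", "n_cases", "n_controls",
                                "prevalence")],
                     h2_tab[c("phenotype", "h2_liab", "se", "p")],
                     by.x = "name", by.y = "phenotype", all.x = TRUE)
    for (tr in unique(rg_tab$external_trait)) {
      sub <- rg_tab[rg_tab$external_trait == tr,
                    c("phenotype", "rg", "se", "p")]
      names(sub) <- c("name", paste0(c("rg_", "rg_se_", "rg_p_"), tr))
      rep_tab <- merge(rep_tab, sub, by = "name", all.x = TRUE)
    }
    rep_tab <- rep_tab[order(match(rep_tab$name, manifest$name)), ]
    write_tsv_meta(rep_tab, file.path(out_dir, "report.tsv"), meta)
    bundle <- list(
      config_hash = unname(meta[["config_hash"]]),
      manifest = manifest, h2 = h2_tab, rg = rg_tab,
      trend_h2 = read_tsv_meta(file.path(out_dir, "trend_h2.tsv")),
      attribution_h2 = read_tsv_meta(file.path(out_dir, "attribution_h2.tsv")),
      bonferroni = list(phenotypes = bonferroni(0.05, nrow(manifest)),
                        attribution_cells = bonferroni(0.05, 25L))
    )
    for (tr in unique(rg_tab$external_trait)) {
      bundle[[paste0("trend_rg_", tr)]] <-
        read_tsv_meta(file.path(out_dir, paste0("trend_rg_", tr, ".tsv")))
      bundle[[paste0("attribution_rg_", tr)]] <-
        read_tsv_meta(file.path(out_dir, paste0("attribution_rg_", tr, ".tsv")))
    }
    jsonlite::write_json(bundle, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    mark("report")
  }

  invisible(state)
}
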