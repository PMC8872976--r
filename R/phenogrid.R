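cap1 <- function(x) paste0(toupper(substring(x, 1, 1)), substring(x, 2))

phenotype_name <- function(components) {
  if (length(components) == 0L) return("Cardinal")
  paste(c("Cardinal", cap1(components)), collapse = " + ")
}

#' Enumerate the combinatorial phenotype definitions
#'
#' Every subset of the binary components, layered on the always-required
#' cardinal-symptom baseline, defines one phenotype; five components give
#' 2^5 = 32 definitions. Definitions are returned in canonical order: by
#' enrichment (1 + number of components), then lexicographically by the
#' components' canonical positions. Names follow the
#' "Cardinal + Recurrence + Impairment" convention.
#'
#' @param component_names character vector of unique component labels
#'   (default [mdd_components()]).
#' @return A data.frame with columns `name`, `enrichment`, and list-column
#'   `components`.
#' @export
enumerate_phenotypes <- function(component_names = mdd_components()) {
  if (anyDuplicated(component_names)) stop("component labels must be unique")
  k <- length(component_names)
  subsets <- list(integer(0))
  if (k > 0) {
    for (s in seq_len(k)) {
      cmb <- utils::combn(k, s, simplify = FALSE)
      subsets <- c(subsets, cmb)
    }
  }
  comps <- lapply(subsets, function(ix) component_names[ix])
  out <- data.frame(
    name = vapply(comps, phenotype_name, character(1)),
    enrichment = vapply(comps, function(cc) 1L + length(cc), integer(1)),
    stringsAsFactors = FALSE
  )
  out$components <- comps
  stopifnot(!anyDuplicated(out$name))
  out
}

resolve_components <- function(defn) {
  if (is.character(defn)) return(defn)
  if (is.data.frame(defn) && nrow(defn) == 1L && "components" %in% names(defn))
    return(defn$components[[1]])
  if (is.list(defn) && !is.null(defn$components)) {
    cc <- defn$components
    if (is.list(cc)) cc <- cc[[1]]
    return(cc)
  }
  stop("cannot interpret phenotype definition")
}

#' Assign case/control status for one phenotype definition
#'
#' A participant is a case when the cardinal baseline and every component in
#' the definition are endorsed; a control when at least one required element
#' (cardinal or a listed component) is explicitly not endorsed; and missing
#' when neither can be resolved because of missing responses. The exclusion
#' flag (screening analogue) overrides all of these. The sample prevalence is
#' computed before applying exclusions, matching the convention that the
#' population prevalence is taken to equal the pre-exclusion sample
#' prevalence.
#'
#' @param table a `component_table` (see [simulate_components()] or
#'   [read_component_table()]).
#' @param defn a one-row definition from [enumerate_phenotypes()], or a
#'   character vector of component names (possibly empty = cardinal only).
#' @return An object of class `case_control`: list with `status` (factor with
#'   levels case/control/missing/excluded, one per row of `table`),
#'   `n_cases`, `n_controls`, `n_missing` (post-exclusion counts),
#'   `prevalence` (pre-exclusion sample prevalence), `P` (post-exclusion case
#'   proportion), `degenerate` flag, `phenotype` name, and `components`.
#' @export
assign_case_control <- function(table, defn) {
  comps <- resolve_components(defn)
  need <- c("cardinal", comps)
  miss_cols <- setdiff(need, names(table))
  if (length(miss_cols)) stop("table lacks component column(s): ",
                              paste(miss_cols, collapse = ", "))
  req <- as.matrix(table[need])
  storage.mode(req) <- "integer"
  n <- nrow(req)
  n_yes <- rowSums(req == 1L, na.rm = TRUE)
  any_no <- rowSums(req == 0L, na.rm = TRUE) > 0L
  is_case <- !any_no & n_yes == ncol(req)   # all endorsed, none missing
  is_control <- any_no                      # at least one explicit non-endorsement
  status <- rep("missing", n)
  status[is_control] <- "control"
  status[is_case] <- "case"
  cases_pre <- sum(is_case); controls_pre <- sum(is_control)
  if (cases_pre + controls_pre == 0L)
    stop("no resolvable individuals for phenotype ", phenotype_name(comps))
  prevalence <- cases_pre / (cases_pre + controls_pre)
  excl <- as.logical(table$excluded)
  excl[is.na(excl)] <- FALSE
  status[excl] <- "excluded"
  status <- factor(status, levels = c("case", "control", "missing", "excluded"))
  n_cases <- sum(status == "case"); n_controls <- sum(status == "control")
  structure(list(
    status = status,
    n_cases = n_cases, n_controls = n_controls,
    n_missing = sum(status == "missing"),
    prevalence = prevalence,
    P = if (n_cases + n_controls > 0) n_cases / (n_cases + n_controls) else NA_real_,
    degenerate = n_cases == 0L || n_controls == 0L,
    phenotype = phenotype_name(comps), components = comps
  ), class = "case_control")
}

#' @export
print.case_control <- function(x, ...) {
  cat(sprintf("%s: %d cases / %d controls (%d missing); pre-exclusion prevalence %.4f%s\n",
              x$phenotype, x$n_cases, x$n_controls, x$n_missing, x$prevalence,
              if (x$degenerate) " [DEGENERATE]" else ""))
  invisible(x)
}

#' Pairs of phenotypes differing by exactly one component
#'
#' For each component c and each subset S of the remaining components, the
#' pair (S, S + c) differs only in c, so any difference in downstream
#' estimates between the two phenotypes is attributed to c. With five
#' components this yields 80 pairs (16 per component), grouped into
#' 5 x 5 = 25 attribution cells by (added component, base enrichment).
#'
#' @param definitions the complete output of [enumerate_phenotypes()].
#' @return A data.frame with columns `base`, `enriched`, `added_component`,
#'   `base_enrichment`.
#' @export
component_pairs <- function(definitions) {
  comps_all <- sort(unique(unlist(definitions$components)))
  k <- length(comps_all)
  if (nrow(definitions) != 2^k)
    stop("definition list incomplete: expected ", 2^k, " subsets, got ",
         nrow(definitions))
  key <- vapply(definitions$components,
                function(cc) paste(sort(cc), collapse = "|"), character(1))
  rows <- list()
  for (i in seq_len(nrow(definitions))) {
    s <- definitions$components[[i]]
    for (cmp in setdiff(comps_all, s)) {
      enr_key <- paste(sort(c(s, cmp)), collapse = "|")
      j <- match(enr_key, key)
      rows[[length(rows) + 1L]] <- data.frame(
        base = definitions$name[i],
        enriched = definitions$name[j],
        added_component = cmp,
        base_enrichment = definitions$enrichment[i],
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  out[order(out$added_component, out$base_enrichment, out$base), , drop = FALSE]
}
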