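---
title: "Methods: combinatorial depression phenotypes and their genetic architecture"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: combinatorial depression phenotypes and their genetic architecture}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mddgrid)
```

## The question the package addresses

Major depression is defined differently across genetic studies: from a single
self-report item up to full structured-interview criteria. `mddgrid` studies
how much that operational choice matters for two quantities at the heart of
psychiatric genetics: the SNP-based heritability of the phenotype on the
liability scale, and its genetic correlation with externally defined
depression traits. The design is combinatorial: a cardinal-symptom baseline
(depressed mood or anhedonia, always required) is enriched with every subset
of five binary diagnostic components — episode recurrence, five or more
symptoms, long episode duration (> 6 months), functional impairment, and
persistence of symptoms — giving `2^5 = 32` phenotype definitions. Estimates
are then compared across definitions, with differences attributed to the
single component by which two definitions differ.

Individual-level cohort data of this kind are access-restricted, so the
package pairs the estimators with a synthetic-data module that generates the
three inputs the analysis needs: a genotype panel, a per-individual table of
binary component endorsements, and an independent external cohort's GWAS
summary statistics. Every generative parameter is explicit, which turns the
whole pipeline into a testable object with known ground truth.

## Phenotype construction

`enumerate_phenotypes()` returns the 32 definitions in canonical order
(by enrichment = 1 + number of components, then lexicographically), named
"Cardinal", "Cardinal + Recurrence", and so on. `assign_case_control()`
implements the status rules:

* **case** — the cardinal baseline and every listed component are endorsed;
* **control** — at least one required element (the cardinal item or a listed
  component) is *explicitly* not endorsed. A participant missing one
  component but explicitly negative on another is still a control;
* **missing** — neither resolvable, because of missing responses. We set
  unresolvable rows to missing rather than control: this is the conservative
  reading where the sources are silent;
* **excluded** — a screening flag (analogue of schizophrenia / bipolar /
  substance-abuse screening) that overrides all of the above.

Controls are deliberately *not* screened for depression itself; screening
controls against sub-threshold presentations inflates liability-scale
heritability. Two consequences of the control rule are used as invariants in
the test suite: adding a component can only shrink the case set and grow the
control set, and the case set of an enriched definition is nested in that of
any sub-definition.

The population prevalence `K` of each phenotype is taken to equal its sample
prevalence computed **before** exclusions are applied — the `K_policy` of the
pipeline. `pcgc_h2()` accepts an explicit `K` override but flags it.

## Heritability: Haseman–Elston / PCGC regression

With random ascertainment — which is exactly what the `K = P` prevalence
policy asserts — PCGC regression reduces to Haseman–Elston product-moment
regression. We implement that reduction directly: encode status 0/1,
residualize on covariates (OLS, intercept included), standardize, and regress
pairwise phenotype products \(y_i y_j\) on GRM entries \(g_{ij}\) over all
observed pairs \(i < j\) (intercept included; diagonal excluded). The GRM is
\(X_s X_s^\top / m\) on column-standardized dosages. The observed-scale slope
converts to the liability scale with

\[
h^2_{liab} = h^2_{obs} \cdot \frac{[K(1-K)]^2}{z^2\,P(1-P)},
\]

where \(z\) is the standard-normal density at the threshold
\(\Phi^{-1}(1-K)\); at \(P = K\) this is \(K(1-K)/z^2\). Full
ascertainment-corrected PCGC is intentionally out of scope: under the stated
prevalence policy the two coincide, and outside it the package would be the
wrong tool. This is a documented limitation, not an approximation we hide.

An extreme-LD region is removed before the GRM is formed
(`exclude_region()`, closed interval). On real genotypes that window is the
MHC (`mhc_region()`, chr6:28,866,528–33,775,446); the packaged desk-scale
configuration removes an analogous small window on its simulated map so the
code path is exercised.

Covariates enter by pre-residualization of the 0/1 status. This matches how
the GWAS side treats covariates and keeps the estimator linear; it is an
approximation relative to a fixed-effect liability model and is stated as
such.

### Standard errors and comparisons

All standard errors are delete-one-block jackknives. Individuals are shuffled
once under a stored seed and cut into 200 contiguous blocks; the same
partition serves every phenotype in a run. That shared partition is what
makes *differences* between phenotypes honest: the phenotypes are computed on
overlapping samples, and leave-block-out replicates of the difference carry
the sampling covariance of the overlap into the SE. Two numerical choices are
worth stating. First, jackknife replicates keep the full-sample
residualization/standardization of the phenotype fixed and delete pairs only;
re-standardizing inside each replicate would perturb estimates at
\(O(1/n)\) and is not worth the cost. Second, all pair sums are expressed
through matrix identities (`he_jack_data()` / `he_estimate()`), so each
replicate costs \(O(b^2)\) for block size \(b\) rather than \(O(n^2)\); the
leave-block-out estimates are exact, not approximations.

Differences are pooled two ways, mirroring the two scientific questions:
by enrichment level against the cardinal-only reference
(`enrichment_trend()`), and per added component within each base-enrichment
level (`component_attribution()`, 25 cells = 5 components x 5 levels), in
both cases by fixed-effect inverse-variance weighting
(`ivw_pool()`). Two-sided normal p-values are used on \(\delta/SE\) (no
t-correction: 200 blocks make the normal reference adequate), with Bonferroni
thresholds 0.05/32 and 0.05/25 for the two families. A cell whose members are
all degenerate is reported missing, never zero.

The block axis is individuals for GRM-based heritability differences and
SNPs for LD-score-regression differences — each estimator is resampled along
the axis it actually aggregates over. Where a source would leave this
ambiguous, it is our recorded choice.

## Genetic correlation: LD score regression

Per-phenotype summary statistics come from simple linear regression of the
residualized 0/1 status on dosage (`run_gwas()`; z is the slope
t-statistic). LD scores are computed from the panel itself
(`compute_ld_scores()`): for SNP j, the sum over same-chromosome SNPs within
a physical window (default 1 Mb, standing in for the conventional 1 cM) of
the bias-adjusted squared correlation \(r^2 - (1-r^2)/(n-2)\), self term
included. The adjustment makes an unlinked SNP contribute zero in
expectation, so a linkage-equilibrium panel has mean LD score 1 — a property
the tests check, as is the exact value 1 for an isolated SNP and 2 for a
perfectly duplicated one.

Univariate LDSC regresses \(\chi^2_j\) on \(\ell_j\) by weighted least
squares with a free intercept and single-pass weights
\(1/\max(\ell_j, 1)\) — a deliberate simplification of LDSC's iterative
two-step weighting, adequate at desk scale and documented here. Bivariate
LDSC regresses \(z_{1j} z_{2j}\) on \(\ell_j\) and reports
\(r_g = \widehat{gencov} / \sqrt{\hat h^2_1 \hat h^2_2}\), with alleles
harmonized (z sign-flipped where a1/a2 are swapped) and the SE from a
delete-one-block jackknife of the *full ratio* over SNP blocks. When either
univariate slope is non-positive, \(r_g\) is undefined; the estimator raises
an explicit error and the pipeline records the phenotype's row as missing.
Estimates with \(|r_g| > 1.25\) are flagged. No HapMap3-style SNP filtering
analogue exists because the simulated panel has no array or imputation
quality strata; one panel serves both the heritability and the correlation
sides, a recorded divergence from workflows that use genotyped SNPs for one
and imputed SNPs for the other.

## The synthetic-data generator

`component_architecture()` specifies seven correlated liabilities — the
cardinal baseline, the five components, and one external depression trait —
via per-trait liability heritabilities \(h^2_t\), prevalences \(K_t\), and
genetic/environmental correlation matrices (both with unit diagonal, so
total liability variance is 1 by construction). Generation proceeds as:

1. **Effects.** An \(m \times 7\) effect matrix is drawn once under the
   architecture's `effect_seed` with per-SNP covariance
   \(\Sigma_g/m\), \(\Sigma_g = D_{\sqrt{h^2}}\,G\,D_{\sqrt{h^2}}\) (via a
   PSD matrix square root). Because both the internal cohort and the external
   cohort use the *same* effect draw, the true genetic correlation between
   any two traits equals the corresponding entry of \(G\) — the ground truth
   the recovery tests exploit.
2. **Liabilities.** Genetic value = standardized-genotype score; environment
   drawn with covariance \(D_{\sqrt{1-h^2}}\,E\,D_{\sqrt{1-h^2}}\).
3. **Thresholding.** Indicators are set by the *realized* upper-\(K_t\)
   quantile rather than the theoretical \(\Phi^{-1}(1-K_t)\), so sample
   prevalences are exact by construction — this stabilizes small-sample
   tests at no cost to the liability model.
4. **Exclusions / missingness.** Exclusion flags are Bernoulli, independent
   of component values. By default components are observed for everyone; an
   optional `missing_rate` masks entries independently, a coarse stand-in
   for questionnaire skip logic, which is not modelled item-by-item.

Genotypes are binomial(2, p) with p uniform in the configured MAF bounds
(default [0.05, 0.5]). LD is off by default; the block-LD mode generates
haplotypes in which an allele copies its left neighbour within a block with
probability `ld_rho`, block sizes cycling 1..`ld_block_size` so that LD
scores vary across SNPs (a constant LD score would leave the LDSC slope
unidentifiable). The generator does **not** emulate realistic human LD maps,
ancestry structure, imputation, or genotyping batch artifacts — so passing
tests demonstrate estimator correctness under the stated model, not
robustness to those real-data complications.

### Default architecture

The defaults (`default_architecture()`, used by the pipeline) are fixed once:
liability heritabilities 0.10–0.16 across traits, bracketing the band
typically reported for depression phenotypes at this granularity; cardinal
prevalence 0.56 (about the proportion endorsing a cardinal item among
questionnaire respondents in cohorts of this kind) and component prevalences
0.35–0.45, which put joint endorsement of everything under 0.1 at desk
scale; genetic correlations 0.6 among internal traits and 0.8 between the
cardinal baseline and the external trait; exclusion rate 0.025. These are
study conditions, not tuning knobs.

## Pipeline, configuration, determinism

`run_pipeline()` executes `simulate -> phenotypes -> h2 -> rg -> compare ->
report` against a single YAML-configurable specification
(`default_config()`, `read_run_config()`; a copy of the packaged
configuration ships in `inst/extdata/config_small.yaml`). Every output TSV
carries the MD5 hash of the configuration and the seeds in `#` header lines,
all randomness flows from the explicit seeds, and two runs of the same
configuration are byte-identical — one of the acceptance checks. Running a
stage whose prerequisites are absent from the output directory is a
dependency error. The `report` stage bundles everything into `report.tsv`
and `report.json`.

Problem sizes in the packaged configuration — 2,000 individuals by 3,000
SNPs, an 8,000-individual external cohort, 200 jackknife blocks — are the
package's chosen desk scale: large enough that heritabilities in the 0.1
band are estimable with SEs around 0.05–0.08, small enough that the full
pipeline and its tests run in minutes. At this scale some of the 32
phenotypes can have a non-positive univariate LDSC slope in any given
realization; their genetic correlations are honestly reported as missing
rather than forced.

## Known limitations

* PCGC is implemented only in its random-ascertainment (HE) reduction;
  ascertained case-control designs need the full estimator.
* Covariate handling is pre-residualization, not a fixed-effect liability
  model.
* LDSC weights are single-pass; intercepts are free but not interpreted as
  sample-overlap estimates.
* The generator's LD is block-structured and synthetic; LD-score variation
  is present but not map-realistic.
* Skip-logic missingness is reduced to an independent masking rate.
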