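---
title: "Methods: robust paired-biofluid metabolite correlation analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: robust paired-biofluid metabolite correlation analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metabopair)
```

## The problem

Targeted metabolomics by multiple-reaction-monitoring (MRM) LC-MS/MS yields
relative peak areas for a panel of low-molecular-weight metabolites. When the
same subjects contribute two matched biofluids — blood plasma and
cerebrospinal fluid (CSF) — the per-metabolite association between the two
fluids becomes a biologically meaningful quantity: metabolites whose plasma
and CSF levels track each other are candidates for passive or regulated
exchange across the blood-brain barrier, and a correlation present in healthy
controls but absent in patients with high-grade glioma (or vice versa) points
at disease-related changes in transport or metabolism.

`metabopair` implements that analysis end to end for a cohort of matched
plasma/CSF samples measured in replicates: preprocessing, per-metabolite
robust regression and weighted correlation, group-wise comparison, a
metabolite-metabolite correlation network with block-model structure, pathway
overrepresentation, and profile-level projections. A synthetic-cohort
generator with planted ground truth makes every stage testable without access
to patient data.

## Preprocessing model

Input is a long-format table of integrated peak areas keyed by (subject,
group, fluid, replicate, metabolite). The fixed pipeline order is:

1. **Replicate averaging** on the raw area scale (`average_replicates()`),
   one sample per (subject, fluid); a cell is missing only if all replicates
   are missing.
2. **Natural-log transform** (`ln_transform()`), `ln(area + pseudocount)`.
   The default pseudocount is 0 with zero areas masked missing: peak areas
   from integrated chromatograms are strictly positive when detected, so
   zeros denote non-detection rather than true zero concentration, and
   imputing them would fabricate signal. The order — average first, then
   log — follows the working definition of the profile values as "ln of the
   average peak area"; the two orders differ by Jensen's inequality and a
   regression test pins the implemented one.
3. **Detection filter** (`filter_detected()`): keep metabolites present in at
   least a fraction `min_fraction_per_fluid` (default 0.8) of plasma samples
   *and* of CSF samples. The original study screened 289 metabolites and
   analyzed 101, without stating the reduction rule; this dual-fluid
   detection filter is our stand-in, deliberately exposed as a parameter and
   documented as such. It is idempotent.
4. **Pairing** (`build_paired_table()`): per-subject matched vectors
   `S_PL` and `S_CSF` of ln mean peak areas; subjects lacking either fluid
   are dropped with a warning. Missing cells are excluded pairwise from all
   regressions — no imputation, the simplest defensible policy for a
   dataset this small.

## Robust correlation model

For each metabolite and scope (combined cohort, patients = glioma group,
controls), CSF is regressed on plasma across subjects with a Huber
M-estimator fitted by iteratively reweighted least squares (`huber_irls()`):

* tuning constant `k = 1.345` (95% Gaussian efficiency, the field's default),
  convergence tolerance `1e-8` on coefficients, at most 50 iterations;
* residual scale re-estimated each iteration as `MAD(e)/0.6745`; when the
  MAD collapses to zero with nonzero residuals (more than half the points
  exactly on a line), the centered mean absolute deviation over 0.7979 is
  used so that gross outliers are still standardized and downweighted;
* weights `w_i = 1` if `|e_i|/scale <= k`, else `k * scale / |e_i|`.

The reported effect size is the **Huber-weighted Pearson correlation**
(`weighted_correlation()`): the ordinary correlation formula evaluated under
the normalized Huber weights. With unit weights it reduces to Pearson's r
exactly; with a contaminated observation the weight shrinks toward zero and
the correlation of the clean majority is recovered. The regression is
oriented CSF-on-plasma (plasma on the x axis); the correlation itself is
symmetric, orientation only matters for residual attribution.

### Significance

Two p-values are reported per record. `p_ols` is the classical t-test of the
Pearson correlation (`correlation_pvalue()`, `t = r sqrt((n-2)/(1-r^2))`,
`df = n - 2`). For the Huber correlation, the same formula is **not** used:
because the weights are estimated from the same data, the weighted |r| is
biased upward under the null, and the naive t-test measured a type-I error
of ~0.08 at the cohort size (n = 31) instead of 0.05 — an effective-sample-
size correction does not repair it, since the bias is in the statistic, not
the degrees of freedom. `p_huber` is therefore the t-test of the **Huber
slope** with the standard M-estimation sandwich variance
(`huber_slope_pvalue()`): clipped residuals in the numerator, the fraction
of unclipped observations in the denominator, Huber's small-sample
correction factor, `df = n - 2`. This is the test family reported by the
standard robust-regression implementations (e.g. `MASS::summary.rlm` and
Python's statsmodels RLM), it reduces exactly to the OLS slope t-test when no
observation is clipped, and it measured a type-I error of 0.053-0.055 at
n = 31 under the package's own null simulation. At n = 11 (the control
group) it remains slightly liberal (~0.065) — small-sample M-estimation
inference is approximate, and downstream classifications should be read
accordingly.

Records with fewer than 3 complete pairs or a degenerate design are emitted
with `NA` statistics and a flag, never silently dropped, so result tables
keep one row per metabolite per scope.

### Residual attribution

Residuals of a metabolite's fit are scaled to unit sum of squares
(`scale_residuals()`); the squared scaled residuals then partition the
lack-of-fit mass across subjects, and group sums give the patient and
control shares. The scaling rule's wording is ambiguous between
per-metabolite-across-subjects (implemented as the default) and
per-subject-across-metabolites; `scale_residual_matrix(margin = "subject")`
provides the alternative reading.

## Group comparison

`significant_sets()` collects, at level `alpha = 0.05` on raw `p_huber`
(matching the study's reporting; Benjamini-Hochberg within scope is available
behind `adjust = "BH"` but off by default), the significant metabolites of
each scope and their three-way intersection. The combined scope refits on the
pooled subjects rather than meta-combining group statistics.

`classify_lost()` labels a metabolite **lost in patients** when it is
significant *and* strong in controls (`p < alpha`, `|R| >= min_abs_r`) but
not significant in patients, and symmetrically for **lost in controls**.
`min_abs_r = 0.7` reflects that every published example of a "retained"
correlation had |R| at or above ~0.74; it is a reverse-engineered,
configurable heuristic, not a published rule. Lists are ranked by the
significant scope's p-value.

## Correlation network and block model

`pairwise_correlations()` computes the Huber-weighted correlation for every
metabolite pair over the pooled rows — one row per (subject, fluid), both
groups together. `build_graph()` turns pairs with `p < 0.05` and positive
weight into edges (both parameters configurable; an absolute-value variant
exists). The positive-only default reflects that the published
95th-percentile analysis thresholds a positive weight distribution.

The two-block structure is recovered with a **flat degree-corrected
stochastic block model** selected by minimum description length
(`fit_dcsbm()`): the microcanonical DC-SBM entropy in nats plus uniform
encoding costs for the block edge-count matrix, per-block degree sequences,
and the partition. Minimization is greedy single-vertex descent from random
initializations with (default) 20 seeded restarts; blocks may empty out, so
an Erdős–Rényi-like graph legitimately collapses to one block. This
deliberately replaces the original nested, weighted block model: at ~100
vertices a flat 2-block model is sufficient to express the reported
structure, is exactly testable against exhaustive search on small instances,
and avoids re-implementing a hierarchical sampler; the study's printed
"entropy" value is specific to its nested weighted model and is not a
reproduction target.

`percentile_subgraph()` keeps edges with weight strictly above the q-th
percentile (linear interpolation, R's quantile type 7; default q = 0.95,
matching the "R > threshold" reading of the published subgraph), and
`connected_components()` returns components with at least `min_vertices = 3`
vertices ("more than a pair of vertices and an edge").

## Overrepresentation analysis

`enrich()` is standard ORA: for a query set of compound IDs, each pathway's
overlap is tested with the one-sided hypergeometric tail
(`P(X >= k)`, computed via `stats::phyper`), adjusted across pathways by
Benjamini-Hochberg. The universe defaults to all compounds in the collection
and can be overridden with the analyzed panel. Name-to-compound
harmonization uses an explicit two-column mapping (`read_id_map()`) — no
fuzzy matching. Published FDR values from pathway databases are not
reproducible here because they depend on the database release and its entity
universe; only the method is reproduced. `min_found` defaults to 1; the
study's "more than one metabolite found" convention corresponds to 2.

## Projections

`pca_embed()` (SVD scores, deterministic sign convention) and `umap_embed()`
(delegated to the `uwot` package, contract limited to shape, finiteness and
seed determinism — the embedding is visualization, not inference) operate on
replicate-level ln profiles, one point per measurement. `opls_da_fit()`
implements two-class OPLS-DA: Trygg-Wold orthogonal signal correction
(default one orthogonal component) followed by single-component PLS1, with
k-fold cross-validation refitting the entire chain per fold and reporting
CV accuracy and Q². Orthogonal scores are orthogonal to the class vector by
construction (asserted to 1e-8 in tests). The source study names OPLS-DA
under an enrichment heading but uses it for class separation; it is
implemented here as class separation only.

## The synthetic cohort

`simulation_config()` / `simulate_dataset()` generate the default "stated
world": 20 glioma and 11 control subjects (the study's cohort), 2 fluids,
3 replicates, 101 metabolites. Per subject and metabolite, a latent
(ln-plasma, ln-CSF) pair is bivariate normal with metabolite-specific means
(plasma ln-mean uniform on 8-16, CSF lower by up to 2) and SDs
(uniform 0.4-1.0), and a group-specific correlation. The default planted
correlation classes mirror the study's reported set structure:

| class | count | rho patients | rho controls |
|---|---|---|---|
| shared significant | 16 | 0.8 | 0.8 |
| lost in patients | 7 | 0.0 | 0.9 |
| lost in controls | 53 | 0.9 | 0.0 |
| weak background | 25 | 0.2 | 0.2 |

The counts come from the published tables (7 and 53 rows; 16 shared), and
the implied marginal counts (~23 control-significant, ~69
patient-significant) land close to the reported 23/68 without further
tuning. Cross-metabolite structure is planted through per-(subject, block)
factors with loading 0.9 on two default blocks of 8 metabolites; keeping
each block inside one correlation class makes the planted plasma-CSF
correlations exactly attainable (the generator records *achieved*
correlations whenever a user-specified block crosses classes and forces
clamping). Outliers (default off; fraction and magnitude configurable)
shift the latent CSF value by `outlier_scale` (default 5) CSF standard
deviations with random sign — a single, clean mechanism for Huber weighting
to suppress. Replicates multiply the latent area by mean-one log-normal
noise with CV 0.1, a typical MRM replicate variability. An optional block of
"screened but poorly detected" metabolites (present in ~30% of CSF samples)
exercises the 289-to-101 detection filter.

What the generator does **not** emulate: batch and run-order effects,
retention-time drift, censoring at the detection limit correlated with
abundance, non-Gaussian biological covariance beyond the block factors, and
missingness mechanisms other than all-or-nothing non-detection. A green test
on this world therefore establishes correctness of the statistical
machinery under its stated assumptions — not robustness to every artifact
of real LC-MS/MS data.

One known emergent artifact is documented rather than patched: because both
fluids are pooled as rows and CSF abundances are systematically lower, the
pooled pairwise-correlation background is positive and the default synthetic
network is denser (~2500-3300 edges at 101 vertices) than the study's 1115.
The network-analysis tests that need controlled density construct their
graphs directly.

## Numerical and design choices

* JSON (not YAML) pipeline configs: the guaranteed R stack includes
  `jsonlite` but no YAML parser.
* All randomness flows from explicit integer seeds; `fit_dcsbm()` and
  `umap_embed()` are deterministic given their seed, and the full pipeline
  writes byte-identical numeric outputs on re-run.
* Percentile thresholds use linear interpolation (quantile type 7) with
  strict `>` retention; ties at the threshold are dropped.
* `fit_dcsbm()` accepts moves only when the description length strictly
  decreases (beyond 1e-12), so descent is monotone by construction; label
  symmetry is resolved by occupancy relabelling.
* Insufficient-data and degenerate-design conditions are typed conditions
  (`insufficient_data_error`, `degenerate_design_error`) so callers can
  produce flagged records instead of failures.

## Known limitations

* p-values for the Huber correlation are asymptotic; at n = 11 they are
  mildly liberal (~0.065 at nominal 0.05), which inflates the
  false-positive side of `classify_lost()` at small group sizes.
* The DC-SBM is flat with a fixed block budget; genuinely hierarchical
  structure is out of scope.
* No multiple-testing correction across the metabolite panel by default
  (matching the study's raw p < 0.05 reporting); enable `adjust = "BH"` to
  change that.
* The detection filter is a stand-in for an unpublished selection rule.
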