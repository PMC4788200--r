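---
title: "Identifying context-specific miRNA-mRNA interactions with mirlink"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying context-specific miRNA-mRNA interactions with mirlink}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirlink)
```

## The problem

MicroRNAs repress their target mRNAs, predominantly by promoting
degradation. Sequence-based prediction databases (microCosm,
TargetScan-style) list hundreds of candidate targets per miRNA from seed
complementarity, hybridization thermodynamics and site conservation — but
most of those candidates are not active in any one tissue or disease.
`mirlink` combines the two available evidence sources to produce a
context-specific candidate list:

1. **Expression evidence.** In paired miRNA/mRNA profiles from the same
   samples, an active repressive interaction should show *negative*
   co-expression. For every pair \((x, y)\) of a miRNA and an mRNA we test

   \[ H_0: \rho_\lambda \ge 0 \quad\text{vs}\quad H_1: \rho_\lambda < 0, \]

   where \(\lambda \in \{\text{Pearson, Spearman, Kendall}\}\). The
   composite null is handled as the standard boundary test at
   \(\rho = 0\): for Pearson, the lower tail of
   \(t = r\sqrt{n-2}/\sqrt{1-r^2}\) on \(n-2\) degrees of freedom;
   Spearman runs the same machinery on within-feature ranks; Kendall uses
   \(\tau\) with a normal-approximation lower tail and is restricted to
   small problems. Multiple testing is controlled with Benjamini–Hochberg
   (or Bonferroni) over the *full family of computed pairs* — all
   \(n_{\text{miRNA}} \times n_{\text{mRNA}}\) of them — so reported FDR
   thresholds refer to the complete search space, not a pre-filtered one.

2. **Sequence evidence.** Prediction databases enter as plain
   (miRNA, mRNA) pair lists. The final decision rule declares a pair an
   interaction when it is significantly negatively correlated **and**
   predicted in at least `min_dat_sum` databases.

Each retained pair is annotated with two-group differential expression of
both partners and a deregulation score

\[ \text{score} = -2\,(\text{logratio}_{\text{miRNA}} \times \text{logratio}_{\text{mRNA}}), \]

which is positive when the two fold-changes oppose each other (consistent
with repression in a disease-vs-control comparison) and grows with the
joint magnitude of deregulation. We read the score as a linear product
rather than an exponentiation: only the linear form can change sign, which
is what lets opposed fold-changes map to positive scores and concordant
ones to negative scores, as the network colouring assumes.

## What differential expression is (and is not) used for

DE is an *annotation*, never a filter. With unbalanced designs (public
tumour cohorts often have very few controls) DE-based pre-filtering risks
false negatives, whereas the correlation test uses every sample. The four
quantities every method reports — log ratio (case minus control, log2
units), mean expression, p, adjusted p — feed the score, the node
colouring and the report tables. Four methods are available:

* `diffexp_ttest()` — Welch (default) or pooled two-sample t.
* `diffexp_wilcoxon()` — rank-sum p; effect summaries stay mean-based so
  columns remain comparable across methods.
* `diffexp_modt()` — moderated t via empirical-Bayes variance shrinkage
  (fitted with limma; `trend = TRUE` lets the prior variance follow mean
  expression). This is the default: it is the standard choice at small
  group sizes.
* `diffexp_rankprod()` — rank product with label-permutation p values
  (always BH-adjusted). We use permutations rather than a gamma
  approximation for small-sample honesty; the permutation count is the
  main cost knob (`n_perm`, default 500, minimum 100).

Degenerate inputs are handled explicitly: a feature with zero variance in
both groups gets p = 1 when the group means are equal and the smallest
representable double otherwise, with a warning — the reference
distribution is undefined there, and this keeps the output total so the
pair-table row-count contract survives.

## Numerical and determinism choices

* **Sample order.** All two-group tests canonicalise sample order (sorted
  names) before computing, which makes results bit-identical under any
  input column permutation, and makes the rank-product test exactly
  symmetric under a label swap. `align_dataset()` likewise sorts the
  shared samples.
* **Blocked correlation.** `correlate_all()` assembles the pair table in
  blocks of `block_rows` miRNAs, but each coefficient is always computed
  as the same per-row product, so results are bitwise independent of the
  block size. Peak intermediate memory is proportional to
  `block_rows * n_mRNA`.
* **Constant features** yield (cor = 0, p = 1, `constant = TRUE`) instead
  of `NaN`, preserving the exact `n_miRNA * n_mRNA` row count.
* **p-value floor.** One-sided p values are clamped into \((0, 1]\) at the
  smallest positive double, so downstream `log`/sorting never meets a zero.
* **Ties** in `top_interactions()` (and hence in network edge selection)
  break lexicographically by (pval, miRNA, mRNA); exports sort their
  lines, so re-running a configuration reproduces every output file
  byte-for-byte.

## Enrichment

`enrich()` is a flat one-sided hypergeometric over-representation test of
a target set against GMT gene-set collections:
\(P(X \ge k)\) with the universe defaulting to the expressed mRNAs of the
analysed dataset. Conditional GO-graph elimination is deliberately not
implemented — with pair-list inputs there is no ontology topology to
condition on; results on nested GO sets should be read accordingly.
Depletion is not tested.

## Comparing interactomes across datasets

For multiple datasets analysed with the same pipeline:

* `shared_interactions()` computes exact Venn cells (pairs significant and
  predicted in exactly each subset of datasets); the cells partition the
  union.
* `specific_interactions()` defines a focal-specific pair as significant
  and predicted in the focal dataset and in no other, *and measurable
  (both features expressed) in every other dataset*. The measurability
  requirement is a deliberate strictness: without it, "specific" conflates
  biology with missingness. Pass `universes = NULL` to disable it.
* `build_pair_matrix()` + `cluster_pairs()` cluster the correlation
  profiles (pairs measured in all datasets, significant in at least one)
  with k-means, default k = 4. We use `stats::kmeans` with Lloyd's
  algorithm and `n_init = 10` random restarts under a fixed seed; plain
  random initial centers restarted several times are in practice as
  reliable as more elaborate seeding at these problem sizes, and keep the
  implementation on the canonical library call. Centers are mean
  correlation profiles.
* `cluster_datasets()` applies average-linkage hierarchical clustering to
  the dataset columns of the center matrix (the linkage is configurable;
  average is the neutral default when no linkage is dictated) and a PCA of
  the datasets on standardized center profiles, i.e. computed from the
  correlation matrix.

## The synthetic validation scenario

`simulate_dataset()` generates paired data with known ground truth. The
defaults are the package's standard validation conditions:

| parameter | default | meaning |
|---|---|---|
| `n_mirna`, `n_mrna` | 300, 3000 | expressed feature counts |
| `n_control`, `n_case` | 30, 30 | samples per group |
| `n_true_pairs` | 500 | planted regulations |
| `beta` | 0.75 | target log2 units per miRNA log2 unit |
| `noise_sd` | 1 | residual sd of targets (log2) |
| `de_fraction`, `de_shift` | 0.2, 1 | fraction of features shifted between groups, by 1 log2 unit |
| `db_sensitivity` | 0.9 | chance a database lists a true pair |
| `db_decoy_rate` | 5 | decoys per database, as a multiple of the true pairs |

miRNA values are Normal(8, 1) on the log2 scale; each planted target is
\(8(1+\beta) - \beta\,x + \varepsilon\), giving population correlation
\(\rho = -\beta/\sqrt{\beta^2 + \sigma^2}\) (`expected_rho()`), i.e.
\(-0.6\) at the defaults. A 20% DE fraction at one log2 unit is a
moderate, realistic deregulation level for tumour-vs-normal comparisons;
each target mRNA is regulated by exactly one miRNA, which keeps planted
correlations interpretable in closed form. Decoy database pairs are drawn
uniformly from non-true pairs without replacement.

The generator is Gaussian on the log2 scale because that is the scale the
pipeline consumes; `simulate_counts()` provides a small Poisson-lognormal
count emitter for exercising the median filter
(`filter_low_expression()`, which keeps features with median raw count at
or above the threshold — the boundary value is kept). What the generator
does **not** emulate: count-level mean–variance coupling, batch structure,
correlated co-regulation modules, miRNA competition for shared targets,
and id-version drift between expression data and databases. Passing tests
therefore demonstrate statistical correctness of the machinery, not
robustness to those real-data pathologies; normalisation and batch
correction are explicitly upstream of this package.

Under the default scenario, running the full pipeline (BH at 0.05 plus
one-database support) recovers over 80% of the database-listed planted
pairs with an empirical FDR well under 10% — this is recomputed from
scratch by `scripts/acceptance.R` and asserted by the test suite.

## Validation design notes

The test suite checks the statistical core against independent oracles:
brute-force BH/Bonferroni, exact hypergeometric pmf summation, exhaustive
rank-sum enumeration, and label-permutation references for the t and
correlation tests. One subtlety is worth recording: the permutation test
of a correlation conditions on the observed data, so its p differs from
the unconditional t-based p by a term of order \(1/n\). At \(n = 15\) that
gap is comparable to the Monte-Carlo band of a 20,000-draw oracle, so the
small-\(n\) check allows for both error sources, while the strict
3-sigma-binomial equivalence check runs at \(n = 100\), where the two
tests genuinely coincide to Monte-Carlo precision. Type-I calibration is
asserted on a 200 x 500 global-null simulation at \(n = 50\): the
fraction of one-sided p < 0.05 must sit inside the 99% binomial interval
around 0.05.

Problem sizes used by the default test run are deliberately modest (the
full-size scenario appears once, shared across checks); every simulation
is seeded and bit-reproducible.

## Known limitations

* Join keys are exact string matches; miRBase/HGNC alias resolution must
  happen upstream, and unmatched ids surface as zero database flags
  rather than being guessed.
* The network export stores kind and direction as attributes and leaves
  shapes/colours to a Cytoscape style file; conventions for miRNA shape
  differ between sources, so we do not hard-code one into the files.
* Kendall correlation is quadratic per pair and gated by
  `kendall_max_pairs` (default 2e6 pairs).
* The report renders numeric tables only; figures are left to interactive
  use (`plot()` on a fit) so that everything in the report is exactly
  re-derivable from the stage TSVs.
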