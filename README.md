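# mirlink

Context-specific miRNA–mRNA interaction discovery from paired expression
data.

## What it does, and for whom

MicroRNAs repress their target mRNAs, mostly by promoting degradation.
Sequence-based target prediction databases (microCosm- or TargetScan-style
pair lists) cast a wide net: most of their predicted pairs are not active
in any one tissue or disease. For a researcher with paired miRNA and mRNA
expression profiles from the same samples (tumour vs. normal, treated vs.
untreated, ...), `mirlink` filters those predictions down to the pairs
that behave like active repression *in that context*.

The decision rule combines both evidence sources. For every miRNA–mRNA
pair the package tests

    H0: rho >= 0   vs   H1: rho < 0

(one-sided negative correlation; Pearson by default, with p from the
lower tail of `t = r*sqrt(n-2)/sqrt(1-r^2)`), controls the FDR with
Benjamini–Hochberg across the **full family of all n_miRNA × n_mRNA
pairs**, and keeps the significant pairs that are also predicted in at
least a configurable number of databases. Each retained interaction is
annotated with two-group differential expression of both partners
(moderated t by default; t, Wilcoxon and rank-product are available) and
the deregulation score

    score = -2 * (logratio_miRNA * logratio_mRNA)

which is positive when the fold-changes oppose each other, as repression
predicts. Downstream helpers build the interaction network (Cytoscape SIF
export with node/edge attributes), run hypergeometric gene-set
over-representation on target sets, summarise targets per miRNA and
coverage, compare interactomes across datasets (shared/specific
interactions, k-means on correlation profiles, dataset clustering and
PCA), and render a standardised HTML report.

Normalisation and batch correction are upstream: inputs are assumed to be
properly normalized log2-scale matrices (raw counts are accepted only to
apply the median-count filter and a log2 transform).

## A worked example

```r
library(mirlink)

# paired synthetic dataset with 40 planted regulations and two
# partly-overlapping prediction databases
sim <- simulate_dataset(simulation_config(n_mirna = 50, n_mrna = 500,
  n_control = 20, n_case = 20, n_true_pairs = 40, seed = 42))

fit <- mirlink(sim$dataset, databases = sim$databases)
fit
#> miRNA-mRNA interactome fit
#>   dataset:      50 miRNAs x 500 mRNAs, 40 samples
#>   pairs tested: 25,000 (pearson, one-sided negative)
#>   significant: 43 (adj.pval < 0.05)
#>   interactions: 31 (supported by >= 1 database(s))

summary(fit)
#> Interactome summary: 50 miRNAs x 500 mRNAs, 40 samples
#>
#> Correlation summary over 25,000 pairs
#>   mean coefficient: -0.002208
#>   p<0.05    1,504 (6.02%)
#>   p<0.01    406 (1.62%)
#>   FDR<0.05  43 (0.17%)
#>   FDR<0.01  21 (0.08%)
#>
#> Decision rule (adj.pval < 0.05 and predicted in >= 1 database(s)):
#>   significant negative pairs: 43
#>   predicted pairs (any db):   438
#>   final interactions:         31
#>
#> Top interactions:
#>       miRNA       mRNA    cor adj.pval dat.sum    score
#> 1  miR-0036 gene-00248 -0.769 8.77e-05       2  0.16119
#> 2  miR-0020 gene-00112 -0.757 8.88e-05       2  1.50100
#> ...
```

Reading the output: of 25,000 tested pairs, 43 are significantly
negatively correlated at FDR < 0.05 over the whole family; 31 of those
are also database-predicted and constitute the interactome. In the top
table, `dat.sum` counts supporting databases and `score` is positive where
the miRNA and its target moved in opposite directions between groups. The
columns of `fit$combined` follow the conventional combined-table schema
(`miRNA, mRNA, cor, pval, adj.pval, logratio.miRNA, logratio.mRNA,
meanExp.miRNA, meanExp.mRNA, dat.<db>..., dat.sum, score`).

From here:

```r
net <- build_network(fit$combined, max_edges = 20)
export_sif(net, "interactome")          # .sif + node/edge attribute TSVs
top_interactions(fit$combined, n = 15)  # deterministic top table
plot(fit)                               # correlation density with cutoffs
```

File-to-file use (YAML config listing the expression/phenotype/database
paths) and report generation:

```r
run_pipeline("config.yaml")   # writes every stage TSV + manifest + report
```

or from a shell via the thin wrapper
`Rscript inst/scripts/mirlink-cli.R run -c config.yaml` (also
`simulate`, `report` subcommands).

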