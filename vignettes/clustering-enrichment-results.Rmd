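---
title: "Clustering multi-condition enrichment results by shared genes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clustering multi-condition enrichment results by shared genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(enrichclust)
```

## The problem

Over-representation analysis (ORA) of a differential-expression experiment
against several gene-set databases routinely returns dozens of terms that
describe the same underlying biology: "defense response to virus",
"cellular response to type I interferon" and "interferon signaling" may all
be carried by nearly the same genes. When several conditions (cell types,
stimulations, disease states) and up/down-regulated subsets are analysed
side by side, the redundancy multiplies and the result table stops being
interpretable.

enrichclust condenses such results by clustering terms on their **shared
enriched genes** rather than on term-name semantics. The workflow is:

1. ORA of each condition's gene list (optionally split into up- and
   downregulated subsets) against each library, with
   Benjamini–Hochberg (BH) adjustment and top-N selection per stratum;
2. a weighted term-similarity graph from pairwise Jaccard indices of the
   per-term enriched-gene sets, pruned at a threshold `ts`;
3. Walktrap community detection on the pruned graph;
4. pooling of per-term p-values into one p-value per
   cluster × condition × regulation cell;
5. deterministic plain-text prompts so that any large language model can
   label the clusters, with replies mapped back by cluster id;
6. heatmap / bubble-plot exports for cross-condition comparison.

## The statistical model

### Over-representation test

For a query of $n$ genes drawn from a background universe of $N$ genes, the
overlap $k$ with a term of $K$ genes is tested with the upper-tail
hypergeometric probability

$$P = \sum_{i=k}^{\min(n,K)} \frac{\binom{K}{i}\binom{N-K}{n-i}}{\binom{N}{n}},$$

i.e. $P(X \ge k)$, equivalent to the one-sided Fisher exact test. The
background defaults to the union of the library's gene sets, because no
better universe is knowable from a GMT file alone; it can be widened with a
user-supplied universe (`gene_set_library(background = ...)`), which is the
right thing to do when the assay interrogated a defined gene panel.

Adjusted p-values are computed by BH **within one library × condition ×
regulation stratum, over all terms of the library**, before any overlap-size
or significance filter. Each such ORA run is one multiple-testing family;
filtering first would understate the number of tests performed. Bonferroni
is available for users who want family-wise control. Query genes outside
the background cannot be tested and are dropped with a message.

Defaults: `padj_max = 0.05` (strict `<`, the conventional FDR cut),
`min_genes = 2` (a one-gene overlap carries no clustering information),
`top_n = 5` per stratum (small enough that a heatmap over many conditions
stays readable, and the canonical choice when comparing against manually
curated summaries). Ties in the ranking are broken by larger overlap, then
term name, so ranking is deterministic.

### Term similarity and clustering

Each retained term is represented by the union, across all strata where it
was retained, of the **genes of the dataset that matched the term** — not
the term's full library set. Two terms are compared with the Jaccard index
$J(A,B) = |A \cap B| / |A \cup B|$; edges with $J \ge ts$ (and $J > 0$)
form a weighted undirected graph. Using matched genes rather than full sets
means the clustering reflects the redundancy actually present in this
dataset; two large pathways that share half their catalogue but were hit by
disjoint gene subsets here will not be merged.

Communities are found by the Walktrap algorithm (short random walks get
trapped in dense neighbourhoods), run per connected component; among the
cuts of the agglomeration's merge sequence the one with maximal weighted
Newman modularity is returned, with ties resolved toward the coarser
partition (fewer, larger clusters favour summarization and make the choice
deterministic). Isolated terms stay as singleton clusters. Cluster ids are
relabeled by decreasing size, then lexicographically smallest member, so
identical inputs always give identical labels.

The pruning threshold `ts` defaults to 0.3: high enough that incidental
one-gene overlaps between unrelated pathways (typically $J < 0.1$) are
discarded, low enough that genuinely overlapping programmes (typically
$J > 0.5$) stay connected. It is the one parameter worth tuning per
dataset; `evaluate_thresholds()` sweeps a grid and reports cluster count,
connected-component count and modularity so the plateau can be picked by
eye. The walk length defaults to 4, the algorithm's canonical setting; on
graphs of tens to hundreds of terms, neighbouring values rarely change the
partition.

### Pooling cluster evidence

Per cluster × condition × regulation cell, the adjusted p-values of the
contributing terms are combined with one of

* **Fisher**: $-2\sum \ln p_i \sim \chi^2_{2k}$;
* **Stouffer**: $\sum z_i / \sqrt{k}$, $z_i = \Phi^{-1}(1-p_i)$;
* **weighted Z** (Liptak): $\sum w_i z_i / \sqrt{\sum w_i^2}$;
* **Cauchy combination**: $T = \sum w_i \tan((0.5-p_i)\pi)/\sum w_i$,
  $p = 0.5 - \arctan(T)/\pi$.

The default is the Cauchy combination because the combined tests are
strongly dependent — terms in one cluster share genes by construction — and
the Cauchy statistic keeps its size under arbitrary dependence, while
Fisher/Stouffer become anti-conservative. Adjusted (not raw) p-values are
pooled so per-library multiplicity stays accounted for; `use_adjusted =
FALSE` switches to raw. Weighted methods default to weights equal to each
term's overlap count `k` (larger matched overlaps carry more evidence);
`weights_rule = "equal"` restores unweighted behaviour.

P-values are floored at `p_floor = 1e-10` *before* pooling (the transforms
diverge at 0) and the pooled value is capped at the same floor. The floor
only biases values already below it and keeps $-\log_{10}$ colour scales on
a readable range (max 10). The same term retained from several databases
within a cell is counted once — its best p-value enters the pooling —
because identical copies of one test must not multiply evidence. No
additional multiplicity correction is applied across cluster × condition
cells; the pooled values are descriptive summaries for comparison, not new
hypothesis tests, and are documented as such.

### Cluster coherence

To compare alternative partitions of the same terms, each term in a
multi-term cluster is scored by the Jaccard index between its gene set and
the union of its cluster mates' genes; the mean over all such terms is the
partition's coherence. Singletons are excluded (their score is undefined,
not zero) — a partition should not be able to buy coherence by isolating
every term.

## Annotation round trip

`build_annotation_prompt()` writes a deterministic prompt enumerating each
cluster's member terms (optionally with their source databases) and asks
for one `cluster_id<TAB>label` line per cluster. Prompts with more than 200
terms are split into numbered parts, since very long prompts tend to come
back incomplete. `parse_annotation_reply()` reads the reply back, warns on
unknown ids, and `apply_annotations()` fills the summary table (placeholder
`Cluster <id>` where no label exists). No network call is made by the
package; the prompt/reply files are the interface, which keeps the
annotation step auditable and model-agnostic.

## The synthetic benchmark

`generate_fixture()` builds a library with planted block structure: blocks
of `terms_per_block` terms share a block core, all terms share a small
global pool sized so cross-block pairs hit a target Jaccard
(`between_block_overlap`, default 0.05), and term-unique tails size the
within-block Jaccard (`within_block_overlap`, default 0.8). With the
default geometry (3 blocks × 4 terms × 30 genes) the realized similarities
are ≈ 0.82 within and ≈ 0.05 between, i.e. clearly separated but not
degenerate. Each of the 4 conditions receives the genes of one block
(round-robin) plus 25 random off-library noise genes and random log2
fold-changes — emulating a DE gene list that mixes a real programme with
background noise.

What the fixture does **not** emulate: the scale-free size distribution of
real libraries, hierarchical (nested) term relationships, correlated
p-values from shared DE machinery, and genes appearing in many unrelated
terms. Recovering the planted partition (adjusted Rand index 1 across
`ts` ∈ [0.2, 0.5] and seeds) therefore demonstrates correctness of the
machinery, not performance on real data, where cluster boundaries are
genuinely ambiguous and `ts` matters.

Test problem sizes were chosen so the whole suite exercises every exact
oracle exhaustively where feasible (all hypergeometric cases to N = 30, all
walktrap graphs to 8 nodes against the best cut of their own merge
sequence, the bridge graph against exhaustive modularity maximization over
all 4140 partitions) and samples elsewhere (1000 random BH vectors, 100
random graphs, 100 random relabelings for the coherence comparison).

## Numerical and degenerate-input choices

* `hypergeom_pvalue` delegates to `phyper(k - 1, ...)`, the numerically
  stable tail; infeasible `(k, n, K, N)` combinations are rejected rather
  than clamped.
* An edgeless graph has undefined modularity: `modularity_score()` errors,
  `walktrap_cluster()` records `NA`, and `evaluate_thresholds()` reports 0
  for plotting.
* A regulation split may leave a subset empty; that stratum is skipped
  rather than erroring, so a condition with only upregulated genes still
  contributes.
* `ts = 0` keeps every positive-similarity edge but never creates
  zero-weight edges between disjoint terms.
* Exact p-value zeros are rejected by `pool_pvalues()`; the pipeline floors
  first, so the error surfaces only on direct misuse.
* All output tables print numerics with 17 significant digits, so
  write/read round-trips are exact and pipeline runs are byte-deterministic
  for a given configuration and seed (no timestamps are written).

## Worked example

```{r example, eval = FALSE}
fix <- generate_fixture(seed = 1)
cfg <- pipeline_config(conditions = fix$conditions,
                       libraries = list(fix$library),
                       logfc_col = "log2fc", ts = 0.3,
                       out_dir = "enrichclust_run", make_plots = TRUE,
                       ts_grid = seq(0.05, 0.95, by = 0.05), seed = 1)
res <- run_pipeline(cfg)
res$assignment
term_coherence(res$term_gene_map, res$assignment)
```

On real data, replace `conditions`/`libraries` with
`conditions_file = "genes.csv"` and `gmt_files = c("go_bp.gmt", ...)`, send
`annotation_prompt.txt` to a language model of your choice, save the reply,
and re-run with `annotations_file = "reply.txt"`.

## Known limitations

* The background universe is only as good as the supplied GMT; Enrichr's
  exact internal backgrounds are not reproduced, so p-values can differ
  from the web service for the same lists.
* No gene-identifier conversion is performed; inputs must already use the
  same symbol namespace as the libraries (symbols are upper-cased for
  matching, which suits human HGNC symbols but not case-sensitive
  namespaces).
* Pooled cluster p-values inherit the dependence of their member terms;
  they rank clusters within this analysis and should not be re-used as
  calibrated significance statements.
* Clustering quality degrades gracefully but noticeably when true overlap
  structure is weak (within-cluster Jaccard approaching `ts`); the
  threshold-evaluation profile is the diagnostic to consult.
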