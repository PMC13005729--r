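# enrichclust

Gene-set enrichment analysis run across several databases (GO, Reactome,
BioPlanet, custom GMT libraries, ...) and several experimental conditions
produces long term lists full of redundancy: many terms are carried by
nearly the same genes. **enrichclust** condenses such results into
gene-coherent clusters and makes them comparable across conditions. It is
aimed at transcriptomics analysts (bulk or single-cell) who need one
readable summary instead of hundreds of overlapping terms.

The core method:

1. **Over-representation test.** Each condition's gene list (optionally
   split into up-/downregulated subsets at a log2 fold-change threshold) is
   tested against every library term with the upper-tail hypergeometric
   probability
   `P(X >= k)` for overlap `k`, query size `n`, term size `K` and
   background `N`; Benjamini–Hochberg adjustment is applied per
   library × condition × regulation family, then the top-N terms with
   `p_adj < 0.05` per stratum are retained.
2. **Term-similarity graph.** Retained terms are linked by the Jaccard
   index `J(A,B) = |A∩B| / |A∪B|` of their enriched-gene sets; edges with
   `J < ts` (default 0.3) are pruned.
3. **Walktrap clustering.** Communities of the weighted graph are found by
   the Walktrap algorithm; the merge-sequence cut maximizing weighted
   modularity `Q = Σ_c (e_cc − a_c²)` is returned.
4. **P-value pooling.** Per cluster × condition × regulation, member
   p-values are combined by Fisher, Stouffer, weighted-Z or the Cauchy
   combination test (default, robust under dependence), floored at 1e-10.
5. **Annotation.** A deterministic plain-text prompt lets any LLM label the
   clusters; replies (`cluster_id<TAB>label` lines) are mapped back. No
   network access is used by the package itself.
6. **Export.** Heatmaps (−log10 pooled p), bubble tables, GraphML/JSON
   graphs, and a threshold-evaluation profile, each with a CSV side-car.

## Worked example

The package ships a synthetic benchmark generator with planted cluster
structure, which doubles as a quick tour:

```r
library(enrichclust)

fix <- generate_fixture(seed = 1)     # 3 blocks x 4 terms, 4 conditions
cfg <- pipeline_config(conditions = fix$conditions,
                       libraries = list(fix$library),
                       logfc_col = "log2fc", ts = 0.3,
                       out_dir = "demo_run", make_plots = FALSE, seed = 1)
res <- run_pipeline(cfg)
#> read 4 condition(s) and 1 library
#> retained 16 hit(s) over 12 unique term(s)
#> found 3 cluster(s) at ts = 0.3

res$assignment
#> <cluster_assignment> 12 term(s) in 3 cluster(s); modularity 0.6667

res$summary[, 1:8]
#>   cluster_id annotation condition regulation pooled_p n_terms_total n_terms_here n_genes
#> 1          1  Cluster 1     cond1        all    1e-10             4            4      39
#> 2          1  Cluster 1     cond4        all    1e-10             4            4      39
#> 3          2  Cluster 2     cond2        all    1e-10             4            4      39
#> 4          3  Cluster 3     cond3        all    1e-10             4            4      39

term_coherence(res$term_gene_map, res$assignment)
#> <coherence_report> 12 term(s), 12 in multi-term clusters; mean Jaccard 0.6923
```

The three planted blocks are recovered exactly (one cluster per block,
modularity 2/3 for three equal cliques), every cluster is maximally
significant in exactly the condition that received its genes (pooled p at
the 1e-10 floor), and the per-term gene coherence (mean Jaccard 0.69
against the rest of each cluster) is far above what size-matched random
partitions achieve (≈ 0.26).

For real data, point `pipeline_config()` at your own inputs:

```r
cfg <- pipeline_config(conditions_file = "genes.csv",   # gene,condition[,log2fc]
                       gmt_files = c("go_bp.gmt", "reactome.gmt"),
                       logfc_col = "log2fc", logfc_threshold = 1,
                       ts = 0.3, out_dir = "myrun")
run_pipeline(cfg)
```

then send `myrun/annotation_prompt.txt` to an LLM, save its reply, and
re-run with `annotations_file = "reply.txt"` to get labeled summaries.
`evaluate_thresholds()` (or `ts_grid =` in the config) profiles cluster
count, connected components and modularity across `ts` values to guide the
threshold choice. A minimal shell wrapper with `simulate` and `run`
subcommands is installed under `inst/cli/enrichclust`.

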