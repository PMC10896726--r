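# senmetflux

Cellular senescence — the durable cell-cycle arrest triggered by oncogene
activation, DNA damage or replicative exhaustion — rewires central carbon
and lipid metabolism. Time-resolved studies that profile both the
metabolome and the transcriptome of cells under several senescence
inducers face a chain of analysis problems: each inducer is measured as an
independent batch with its own technical offsets; differential features
must be called per time course; temporally coexpressed modules must be
detected; and metabolites that track many genes across *every* inducer —
candidate regulatory hubs such as glycerol-3-phosphate and
phosphoethanolamine — must be found in a cross-omics correlation network.

senmetflux implements that chain as a tested R package, for analysts
working with multi-batch time-course metabolomics/transcriptomics:

* **Batch-correction benchmark** — reference scaling X' = X · R_p / C_p,b
  (reference = pooled QC, uninduced day-0, or the batch mean), quantile
  normalization, and a parametric empirical-Bayes location/scale
  adjustment that can estimate batch parameters on the uninduced baselines
  only. Methods are scored by the relative standard deviation
  r.s.d. = sigma_{p,s} / mu_{p,s} per peak and cross-batch sample identity,
  the repeatability sigma2_between / (sigma2_between + sigma2_within), and
  the Bhattacharyya distance
  DB = 1/8 d' S^-1 d + 1/2 ln(det S / sqrt(det S1 det S2)) between batch
  clusters.
* **Differential calling** — per-batch one-way ANOVA over timepoints with
  Benjamini–Hochberg FDR (metabolites: q < 0.05; genes additionally
  |log2FC| >= log2(1.5)), a bottom-40% expression filter, and
  product:precursor ratio fold changes between course end and start.
* **Coexpression modules** — soft-thresholded unsigned correlation
  networks, topological overlap, average-linkage clustering with a
  deepSplit-style cut, module eigenprofiles and merge threshold 0.60, plus
  an integrated trajectory PCA.
* **Gene–metabolite network** — per-dataset Spearman correlation of all
  differential gene x metabolite pairs, selection of pairs with
  |rho| > 0.5 in every dataset, bipartite network assembly and exact
  Brandes betweenness hub ranking.
* **Enrichment** — hypergeometric over-representation against GMT
  collections and pre-ranked permutation GSEA.
* **Synthetic studies** — a generator that plants temporal modules, hub
  metabolites and multiplicative batch effects with full ground truth, so
  the whole pipeline is validated end-to-end without any download.

## Worked example

Generate the default synthetic study (4 inducer batches x 6 timepoints x
3 replicates; 60 metabolites, 500 genes, 5 planted modules, 2 hub
metabolites with 30 partner genes each), inject the planted batch
effects, and run the stages:

```r
library(senmetflux)

study    <- generate_study(synthetic_config(seed = 42))
measured <- inject_batch_effects(study$metabolome, study$meta, study$truth)

# --- batch-correction benchmark (shared-design configuration with QC pools)
bench  <- generate_study(synthetic_config(shared_dynamics = TRUE,
                                          qc_fraction = 0.1, seed = 42))
report <- benchmark_methods(
  inject_batch_effects(bench$metabolome, bench$meta, bench$truth),
  bench$meta, methods = c("batch_mean", "baseline", "qc", "eb"))
report
#> <benchmark_report>
#>       method median_rsd median_repeatability mean_batch_bhattacharyya rank_rsd
#> 1       none     0.6454               0.5226                7.717e-02        5
#> 2 batch_mean     0.1779               0.9412                8.393e-05        1
#> 3   baseline     0.1943               0.9177                2.543e-04        2
#> 4         qc     0.1969               0.9080                3.007e-04        3
#> 5         eb     0.2041               0.8519                6.395e-03        4
```

Uncorrected, a typical peak varies by ~65% across batches for the same
sample identity; every correction method brings that below 21% and lifts
repeatability from 0.52 to over 0.85, with batch-mean reference scaling
ranked first on all three metrics (the planted distortion is exactly the
kind it removes).

```r
# --- differential calling and the cross-inducer network
ml <- log_transform(measured)
tl <- low_expression_filter(log_transform(
  inject_batch_effects(study$transcriptome, study$meta, study$truth)))
dm <- differential_analysis(ml, study$meta)
dg <- differential_analysis(tl, study$meta)
length(select_differential(dm)); length(select_differential(dg))
#> [1] 60
#> [1] 273

tabs  <- lapply(unique(study$meta$batch),
                function(b) spearman_pairs(tl, ml, study$meta, b))
pairs <- overlap_select(tabs, threshold = 0.5)
net   <- build_network(pairs)
net
#> <bipartite_graph> 31 genes + 2 metabolites, 31 edges
rank_hubs(net, top_k = 3, type = "metabolite")[, c("id", "degree",
                                                   "betweenness", "rank")]
#>     id degree betweenness rank
#> 1 M001     16         120    1
#> 2 M002     15         105    2
study$truth$hub_features
#> [1] "M001" "M002"
```

Only the two planted hub metabolites survive the
|rho| > 0.5-in-every-batch overlap with substantial degree, and they take
the top two betweenness ranks — the synthetic analogue of finding the
same hub metabolites in every senescence model.

```r
# --- module detection on batch-free profiles
prof <- collapse_replicates_median(log_transform(study$metabolome), study$meta)
mods <- cluster_modules(prof$values, min_size = 3, deep_split = 3,
                        merge_threshold = 0.60)
table(mods$labels)
#>  0  1  2  3  4  5
#>  2 12 12 12 11 11
```

The five planted modules are recovered exactly (adjusted Rand index 1);
the two unassigned features (label 0) are the hub metabolites, whose
trajectories deliberately match no module.

The full chain — ingest/simulate, differential, benchmark, modules,
integration, enrichment, report — also runs as one call:

```r
cfg <- pipeline_config(synthetic = synthetic_config(seed = 42),
                       out_dir = "run42", seed = 42)
run_pipeline(cfg)
make_report("run42")   # writes run42/report.txt
```

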