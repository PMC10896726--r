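---
title: "Methods: models, parameters and design choices in senmetflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in senmetflux}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

senmetflux analyses time-resolved metabolome and transcriptome profiles of
cells driven into senescence by different stressors (oncogene activation,
DNA damage, replicative exhaustion), each stressor measured as an
independent batch. This vignette documents the statistical models, the
tunable parameters with their defaults, the synthetic-data generator used
to validate every stage, and the places where the design was genuinely open
and a choice had to be made.

## Data model

All stages consume an `omics_matrix` (features x samples, tagged with
modality and scale) aligned against a `sample_meta` table (batch, day,
replicate, role). Raw intensities are strictly positive MS peak areas or
array intensities; missing cells are `NA`, never zero, and are imputed as
half the feature's minimum observed positive value before the base-2 log
transform — a common metabolomics convention for values below the
detection limit. Sample identity for every cross-batch comparison is the
(timepoint, replicate, role) triple: the position a sample occupies in its
batch's design.

## Differential calling

Within each batch, each feature is tested with a one-way ANOVA across
timepoint groups — time is the only within-batch design variable — and
p-values are Benjamini-Hochberg adjusted within the batch. Metabolites are
called at q < 0.05; genes additionally need a maximum absolute log2 fold
change (any timepoint versus the course start) of at least log2(1.5) ~
0.585. The "1.5x" rule is ambiguous between `|log2FC| >= log2(1.5)` and
`|log2FC| >= 1.5`; the milder reading is the default and the threshold is
an explicit argument (`fc_threshold`), so the stricter reading is one call
away. Constant features get F = 0, p = 1 (untestable-as-null). The ANOVA
is computed row-wise from group sums for speed; the test suite pins it to
`stats::aov` at 1e-12.

Metabolite-ratio signatures (product:precursor pairs such as
lactate:pyruvate or G3P:DHAP) are summarized as the fold change of the
within-sample ratio between the end and the start of each time course.
The ratio is formed per sample *before* averaging replicates, so any
common per-sample scaling factor cancels exactly; per-replicate end ratios
feed a two-sided t-test against 1. The reference timepoint is an argument,
because a course may need a non-default proliferative control (for example
a late passage that is still proliferating).

## Batch-correction benchmark

Five correction methods are implemented behind one interface:

* three **reference-scaling** schemes — every peak is multiplied by
  `R_p / C_p,b`, the grand average over all samples divided by the mean of
  the batch's reference samples (pooled QC injections, uninduced day-0
  samples, or all batch samples). A purely multiplicative per-(peak, batch)
  distortion is removed exactly by the batch-mean scheme; means are
  arithmetic on the raw scale.
* **quantile normalization** (via `limma::normalizeQuantiles`): every
  column is forced onto the mean order-statistic distribution.
* a **parametric empirical-Bayes location/scale adjustment** on log data:
  per-(feature, batch) additive and multiplicative effects are estimated,
  shrunk across features with method-of-moments normal / inverse-gamma
  priors, and removed. Uniquely, the batch parameters can be estimated on a
  designated sample role — by default the uninduced baselines, which is the
  right choice when treated samples genuinely differ between batches — and
  then applied to all samples. With `estimate_on = "all"` the procedure
  reproduces `sva::ComBat` to machine precision (pinned in the tests).

Three metrics score each method on the raw intensity scale:

* **r.s.d.** — per peak and sample identity, the unbiased standard
  deviation over batches divided by the mean. Scale-free and zero for
  perfect agreement.
* **repeatability** — per peak, `s2_between / (s2_between + s2_within)`
  over identities; in [0, 1], high when identities are distinct and their
  repeated measurements tight.
* **Bhattacharyya distance** between batch clusters in a PCA-reduced
  space (2 components by default, so each cluster has more points than
  dimensions): `1/8 d'S^-1 d + 1/2 ln(det S / sqrt(det S1 det S2))` with S
  the average covariance. The square root in the determinant term is part
  of the standard definition and makes the distance zero for identical
  clusters; a `printed_form` flag provides the variant without it, which
  is not guaranteed non-negative and is off by default. A diagonal ridge
  (`1e-6 x trace/dim`) is added only when the pooled covariance is
  singular, so exact supplied moments give exact distances (the 1-D
  closed form is matched to 1e-9).

The metrics presume that the same identity measured in different batches
is comparable — i.e. that batches re-measure one underlying design. The
benchmark is therefore validated on the generator's *shared-dynamics*
configuration (below). In the study design proper, different inducers
follow different kinetics, cross-batch identity variation is dominated by
real biology, and no correction method can (or should) remove it; the
benchmark on such data ranks methods relatively but the absolute r.s.d.
floor is biological.

## Coexpression modules

Median-collapsed per-timepoint profiles are clustered with a
weighted-correlation network procedure: unsigned adjacency `|cor|^beta`
(Pearson, unsigned — the method's default, chosen because responses of
either sign belong in one temporal module), topological-overlap similarity,
average-linkage clustering of `1 - TOM`, a height cut, size filtering
(minimum 3 for metabolites, 100 for genes), and iterative merging of
modules whose eigenprofiles (first principal component of the
standardized member profiles, sign-oriented to the member mean) are too
close.

Two parameters deserve explanation:

* **Soft power.** For each candidate power the scale-free topology fit is
  evaluated by regressing log10 p(k) on log10 k over 10 logarithmic
  connectivity bins. The chosen power is the lowest with R^2 >= 0.8 and a
  non-positive slope; if no candidate qualifies — typical for modular
  rather than scale-free data — the elbow of the R^2 curve is used, defined
  as the most negative second difference (the strongest bend toward
  diminishing returns). Degenerate inputs (all features identical) fall
  back to the median candidate with a warning.
* **deepSplit.** The published dynamic hybrid tree cut is not
  re-implemented; its aggressiveness levels 0..4 map to a static cut at
  0.99, 0.95, 0.85, 0.65 and 0.55 of the tree height. The mapping was fixed
  by requiring that, on noiseless module structure, singleton features with
  deliberately decorrelated profiles separate from genuine modules at level
  3; oversplit fragments of one module are re-merged by the eigenprofile
  step, so the cut errs on the aggressive side by design.
* **Merging.** "Correlation threshold for cluster merging = 0.60" is read
  as a merge *cut height* on eigenprofile dissimilarity: modules merge
  while `1 - cor < 0.60`, i.e. correlation above 0.40 — matching the
  mergeCutHeight semantics of the established tool. `merge_on =
  "correlation"` flips the reading so 0.60 is the correlation cutoff
  itself. After merging, the invariant `max pairwise eigenprofile
  correlation <= 1 - merge threshold` is asserted on every run.

The integrated trajectory PCA runs on centered, unit-scaled,
batch-corrected profiles (scaling is unstated upstream; the
correlation-circle display presumes unit scale, and the circle coordinates
are correlations of features with component scores, hence bounded by 1).

## Gene-metabolite integration

Spearman correlations are computed between every differential gene and
metabolite on median-collapsed per-timepoint profiles within each dataset
(replicate-level correlation would mix replicate noise into what is meant
to be a temporal-profile similarity); at least 4 shared timepoints are
required. Pairs with `|rho| > 0.5` in *every* dataset — sign consistency
deliberately not required — become edges of an undirected, unweighted
bipartite network. Pairs missing in any dataset are excluded, not imputed.
Hubs are ranked by exact Brandes betweenness (raw values; the
normalization by `(n-1)(n-2)/2` is reported for cross-graph comparability
and yields the same order), ties broken by degree then id. Disconnected
components are kept; betweenness accrues within components.

## Enrichment

Over-representation uses the upper-tail hypergeometric test on set overlap
within a declared universe, BH-adjusted across the sets of one collection.
Pre-ranked GSEA ranks genes by end-versus-start log2 fold change and runs
the weighted running sum (hits advance by `|score|^weight` normalized by
the total hit weight, misses retreat by `1/(N-K)`), with a gene-label
permutation null — only ranked lists exist here, so phenotype permutation
is not applicable. Defaults: weight 1, 1000 permutations. NES divides the
ES by the mean |ES| of matching-sign permutations. The permutation p is
one-sided within the matching-sign null pool with a +1 correction;
computing it against the full pool would double the size of the test, and
the suite verifies type-I calibration at the 5% level against a binomial
interval.

## The synthetic-data generator

`generate_study()` emulates the study design: 4 batches (inducers) x 6
timepoints (days 0-14) x 3 replicates by default, 60 metabolites and 500
genes, 5 planted temporal modules per modality, and 2 hub metabolites
whose latent trajectories are copied to 30 partner genes each. Raw
intensities are `exp(baseline + amplitude x trajectory + noise)`, so they
are strictly positive like MS peak areas; the downstream log transform is
the analysis's first step. Trajectories are built per (module, batch) from
three shape primitives (linear ramp, logistic switch, Gaussian transient)
with random parameters and signs, standardized within batch, and blended
50:50 with their standardized rank vector so that sorted trajectory values
keep well-separated gaps — without this, a transient's near-tied baseline
points make 6-point rank correlations unstable under replicate noise.

Two rejection constraints make the planted structure recoverable by
construction at any seed: on the metabolite side, concatenated trajectory
correlations are capped (0.35 between modules, 0.25 against hubs, so
modules neither merge at the 0.40 eigenprofile bound nor absorb hubs); and
every non-hub metabolite-trajectory x gene-trajectory pair must have at
least one batch with `|Spearman| <= 0.2`, so replicate noise cannot lift a
spurious pair over the 0.5 network threshold in all batches at once. A
candidate failing its constraints is locally repaired by redrawing single
batch rows; a residual violation is reported as a warning. These screens
need resolution to be satisfiable — at least about 4 timepoints and 3
batches — which the default design comfortably provides. Unassigned
("noise") genes, 10% by default, are flat baselines with replicate noise
only: they fail the differential screen and so never reach the network,
which is also how housekeeping genes behave.

Calibration choices not derivable from any upstream description, fixed
once: replicate noise sd 0.2 on the natural-log scale (≈ 20% r.s.d.,
typical for targeted MS), batch effects `exp(shift_b + eps_fb)` with a
batch-wide shift sd 0.5 and per-feature scatter sd 0.25 (batch effects of
1.5-3x, typical for inter-run MS drift), feature baselines log-normal
around e^11 counts, per-feature response amplitudes 0.8-1.6 log-units.
Batch effects are drawn into the ground truth and applied explicitly by
`inject_batch_effects()`, so every analysis can run on clean and distorted
versions of the same study.

The generator has two dynamic regimes. The default gives every batch its
own trajectory realization per module — inducer-specific kinetics, the
regime in which module and hub recovery are validated. `shared_dynamics =
TRUE` re-measures the same trajectories in every batch, which is the
regime the r.s.d./repeatability metrics assume and the one used to
validate the batch-correction benchmark (with `qc_fraction = 0.1` so the
QC reference scheme is exercised).

What passing these tests does and does not show: the generator plants
clean low-rank module structure, exactly multiplicative batch effects and
homoscedastic log-normal noise. Real data add peak-annotation ambiguity,
heteroscedastic and correlated noise, missingness patterns tied to
abundance, drift within batches, and modules with fuzzy boundaries.
Recovery of planted structure demonstrates that the pipeline is correct
and well-calibrated, not that real studies will yield equally crisp
modules or hubs.

## Problem sizes and numerical conventions

The validation suite runs desk-scale: the default study (60 x 72 and
500 x 72 matrices), 100-seed x 200-feature null simulations for FDR
calibration, 200 simulated null rankings for GSEA calibration, 100 random
graphs (<= 12 nodes) against the exact path-enumeration betweenness
oracle, and 200 random matrices against the brute-force TOM formula.
Numerical conventions: unbiased (n-1) variance estimators throughout;
median replicate collapse uses the mean-of-middle convention for even
counts; the bottom-40% expression filter removes `floor(0.4 n)` genes with
lexicographic tie-breaks; average-linkage merge heights are sorted to
undo floating-point inversions; eigenprofile signs orient toward the
member mean profile.

## Known limitations

* The dynamic tree cut is a documented simplification, not the published
  hybrid algorithm; deepSplit levels are comparable in spirit, not in
  detail.
* The EB adjustment implements the parametric prior only (no
  nonparametric variant) and requires complete matrices.
* The generator does not simulate raw spectra, retention-time drift or
  annotation errors; QC samples are pooled means plus noise.
* Betweenness is exact, not sampled; graphs far beyond ~10^4 nodes would
  need approximation, which is out of scope at this study's scale.
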