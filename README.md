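# subtypewalk

Transcriptional subtype discovery and subtype-specific driver-subnetwork
inference for tumor expression cohorts, with a fully synthetic benchmark
generator so every stage can be exercised and tested without external data.

## The problem

Bulk tumor cohorts are molecularly heterogeneous: distinct transcriptional
subtypes carry distinct combinations of somatic mutations and copy-number
changes, and pooling all tumors against normals hides the subtype-specific
driver pathways. `subtypewalk` implements an integrated pipeline for
colorectal-cancer-style cohort analysis:

1. **Cross-dataset normalization** — probe-to-gene collapse (multi-gene
   probes dropped, per-sample median over same-gene probes), per-dataset
   mean centering, common-gene merging, optional centering to normal
   reference samples.
2. **Co-expression modules** — all-pairs Pearson correlation; a
   *knowledge-guided* threshold chosen where mean Resnik semantic similarity
   of gene pairs rises sharply with |r| on both the positive and negative
   side; iterative clique enumeration (ICE) over the thresholded network,
   merging maximal cliques that overlap heavily, keeping modules of ≥ 20
   genes.
3. **Consensus subtyping** — average-linkage hierarchical clustering under
   the 1 − Pearson distance over resampled sample subsets; cluster number
   chosen from the area under the consensus CDF; SigClust significance for
   cluster pairs; silhouette widths
   `s(i) = (b(i) − a(i)) / max(a(i), b(i))` with positive-silhouette
   samples kept as the *core* of each subtype.
4. **Subtype classifier** — nearest shrunken centroids (PAM):
   `d'_ik = sign(d_ik) · max(|d_ik| − Δ, 0)` with
   `d_ik = (x̄_ik − x̄_i) / (m_k (s_i + s0))`, repeated stratified 10-fold
   cross-validation, and per-subtype signature assignment by one-tailed
   Student t-tests against every other subtype; a permutation test of
   signature functional coherence.
5. **Driver subnetworks** — the core inference. Binary mutation
   (non-silent calls) and CNV (copy ratio ≥ 1.2 or ≤ 0.8) matrices are
   column-normalized and row-summed into per-gene weights
   `S(i) = Σ_j m_ij / Σ_i m_ij`, combined with equal weight and normalized
   into a start probability vector `p0`. A random walk with restart,
   `p_{t+1} = (1 − r) W p_t + r p0` with `r = 0.5` on the column-normalized
   adjacency of the signaling network's largest connected component, scores
   every gene; 1000 permutations of the start probabilities give a *local*
   p-value (same gene's permuted scores — guards against topology) and a
   *global* p-value (pooled permuted scores of all genes). The largest
   connected component of genes with local p < 0.05 **and** global p < 0.05
   is the subtype's driver subnetwork.
6. **Downstream characterization** — hypergeometric cross-tabulation with
   BH correction, developmental-stage correlation of subtype centroids,
   per-sample signature scoring (e.g. EMT programs), Kaplan–Meier curves
   and the k-group log-rank test.

A synthetic cohort generator plants co-expression modules (latent-factor
model), subtypes (module-activity shifts), batch offsets, scale-free
signaling networks with connected driver-gene sets, alteration matrices,
module-coherent ontologies and subtype-dependent survival — with full
ground truth, so recovery can be measured.

## Worked example

```r
library(subtypewalk)

spec <- cohort_spec(seed = 7L)               # 600 genes, 180 samples, 3 subtypes
cohort <- gen_expression_cohort(spec)

res <- run_subtype_discovery(cohort$expr, threshold = 0.45,
                             k_range = 2:5, n_resamples = 100, seed = 8L)
res$modules
#> module_set: 9 module(s), 273 unique genes
res$consensus
#> consensus_result over k = 2, 3, 4, 5
#> area under consensus CDF:
#>      2      3      4      5
#> 0.4577 0.6689 0.6792 0.6934
res$k
#> [1] 3

core <- res$assignment[res$assignment$core, ]
nrow(core)                                   # 175 of 180 samples are core
adjusted_rand_index(setNames(core$label, core$sample),
                    cohort$truth$sample_subtype[core$sample])
#> [1] 0.948

net <- gen_signaling_network(300, 3, seed = 9L,
                             genes = rownames(cohort$expr$values))
cohort$truth$driver_genes <- plant_drivers(net, 3, 12, seed = 9L)
alt <- gen_alteration_data(net, cohort$truth, seed = 9L)
drv <- run_driver_inference(net, alt$mut, alt$cnv, labels = res$labels,
                            n_perm = 1000, seed = 10L)
sapply(drv, function(d) igraph::vcount(d$subnetwork))
#>  1  2  3
#> 11 12 12

surv <- gen_survival(cohort$truth, censor_rate = 0.2, seed = 11L)
km_logrank(surv)
#> log-rank chi-square = 25.114 on 2 df, p = 3.521e-06
```

Reading the numbers: the nine planted modules are recovered with 273 of
their genes; consensus stability jumps from k = 2 to k = 3 and flattens, so
three subtypes are called; the core-sample labels agree with the planted
truth at adjusted Rand index 0.95; each subtype's driver subnetwork
(11–12 genes) recovers its planted 12-gene alteration cluster; and the
planted per-subtype hazards separate the Kaplan–Meier curves decisively.

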