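---
title: "Methods: subtype discovery and driver-network inference in subtypewalk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: subtype discovery and driver-network inference in subtypewalk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette describes the statistical models and the design choices behind
`subtypewalk`, in the spirit of a methods supplement: what each stage
assumes, which parameters matter and why their defaults are what they are,
what the synthetic benchmark does and does not emulate, and where the
implementation had to make choices that the underlying methods literature
leaves open.

## 1. Cross-dataset normalization

Expression matrices are assumed complete (no `NA`s) on a log2 scale, genes
by samples, with a dataset-of-origin label per sample. Probe-level data are
collapsed by dropping probes mapping to more than one gene and taking the
per-sample median over probes of the same gene; medians are computed per
sample independently, and ties among an even number of probes resolve to
the mean of the central pair (the standard median). `NA`s are rejected
rather than imputed because imputation would distort the gene–gene
correlations that module discovery rests on.

Per-dataset mean centering (`center_within_dataset`) removes additive
platform and batch offsets under the assumption that dataset effects are
gene-wise additive and subtype composition is comparable across datasets.
The operation is idempotent, and merging disjoint cohorts commutes with
centering (tolerance 1e-9 in the tests). Centering to reference samples
(`center_to_reference`) expresses tumors relative to normal tissue and is
kept separate because the reference set is a scientific choice, not a
batch artifact.

## 2. Knowledge-guided co-expression network and ICE modules

All unordered gene pairs are scored by Pearson correlation (zero-variance
genes are skipped and reported). Instead of an arbitrary cutoff, the
network threshold is chosen where gene pairs become *functionally* similar:
pairs are binned by `r` (bin width 0.05 over [−1, 1] — fine enough to
localize a sharp rise while keeping bins populated) and the mean Resnik
semantic similarity per bin is compared to a baseline formed by all bins
with |r| < 0.3. The selected threshold is the smallest nonnegative bin edge
whose first populated bin exceeds the baseline by at least 2 pooled
standard errors *on both the positive and negative side* — requiring both
signs guards against a rise driven by one direction only. A flat curve is
an error instructing a manual choice; an analyst-supplied threshold always
wins. 0.45 is the conventional operating point for cohorts of this kind
and is the default in the pipeline wrapper.

Resnik gene-pair similarity is the maximum information content over common
ancestors of the two genes' annotation closures, with
IC(t) = −ln(annotated fraction). The maximum (rather than best-match
average) is the most common gene-level aggregation and is monotone under
annotation refinement; the IC base only rescales the curve. An unannotated
gene is an error, deliberately distinguishable from a true similarity of 0
(sharing only the root).

Module discovery enumerates maximal cliques of at least `min_clique = 5`
nodes, processes them in decreasing size — ties broken by the
lexicographically smallest sorted member list, purely for determinism — and
merges a clique into the existing module with which it shares the largest
fraction of its own nodes, when that fraction reaches
`merge_overlap = 0.5`. Both values follow the ICE literature's usual
settings rather than a prescription; they are exposed as arguments. Modules
below `min_module = 20` unique genes are dropped to keep only major
transcriptional programs.

## 3. Consensus subtyping, SigClust, core samples

Consensus clustering draws 80% of samples without replacement (default
1000 resamples; the pipeline wrapper uses 250 and the test suite 100, which
the consensus areas tolerate at these problem sizes), clusters each draw by
average-linkage hierarchical clustering under the 1 − Pearson distance, and
records co-clustering fractions among co-drawn pairs. Pairs never co-drawn
are flagged missing and excluded from the consensus CDF. These parameters
follow the established consensus-clustering protocol for expression
subtyping. The cluster number rule — the largest k whose relative gain in
area under the consensus CDF over k − 1 exceeds 0.1 — mechanizes the usual
visual "CDF elbow" reading; it is an aid and never overrides a
user-supplied k.

SigClust asks whether a 2-way split could arise from a single Gaussian:
the observed statistic is the cluster index (within-cluster SS over total
SS) of the *given* split; null datasets are simulated from a
diagonal-covariance Gaussian whose per-feature variances are floored at a
background noise variance estimated by the MAD of the centered data, and
each null dataset is scored by its best 2-means split. The add-one
estimator keeps p in (0, 1].

Silhouette widths use the same 1 − Pearson distance over the selected
module genes (using all selected genes, not module summaries). Samples in
singleton clusters have no within-cluster distance; their silhouette is set
to 0 — neither core nor anti-core — with a loud warning, mirroring the
common convention. Core samples are those with strictly positive
silhouette.

## 4. Nearest shrunken centroid classifier and signatures

The classifier follows the standard PAM construction: pooled within-class
SD `s_i`, fudge `s0 = median(s_i)`, `m_k = sqrt(1/n_k − 1/n)`, soft
thresholding of the standardized centroid differences, discriminant with a
`−2 ln(prior)` term, and posteriors as the softmax of `−δ_k/2`. Class
priors default to empirical class frequencies (the PAM default). When every
gene is shrunk away the posteriors reduce exactly to the priors.
Cross-validation is stratified, 10-fold, repeated (default 100 times); the
chosen operating point on the error curve is the analyst's, since the
error-minimal and the most-interpretable model need not coincide.

Signature assignment uses one-tailed two-sample Student t-tests with
pooled variance (the classic Student form; a Welch option is not offered
because the method being reproduced specifies Student). A gene is "up in
subtype k" only if it is significantly higher in k than in *each* other
subtype separately — the stricter reading of "compared to all other
subtypes"; a pooled mode (k vs all other samples in one test) is available
via `mode = "pooled"`. Raw p < 0.05 is used deliberately, with no
multiple-testing correction: this step reproduces a published signature
definition, not a discovery screen. Stage 2 applies the mirrored rule for
down-regulation to genes not already assigned; the result is a partition
(up ∪ down ∪ unassigned). Functional coherence of a signature is tested by
permuting same-size gene sets from the classifier background and comparing
mean pairwise Resnik similarity (add-one p-value).

## 5. Random walk with restart and permutation significance

Alteration matrices are binary: mutations are 1 for any non-silent call
(classes outside the known silent/non-silent vocabularies warn and count as
non-silent by default — the conservative choice for a driver screen); CNV
is 1 for copy ratio ≥ 1.2 or ≤ 0.8, both inclusive. Start probabilities
perform column-wise normalization (each sample's alterations divided by its
total, so hypermutated samples do not dominate; all-zero columns contribute
0, defining 0/0 = 0) followed by row-wise summation, then combine mutation
and CNV by plain summation — equal weight — and normalize globally.
Duplicating every sample leaves the vector unchanged, which the tests check
by brute force. Genes carrying alterations but absent from the network are
dropped with a message before normalization, because the walk is defined on
the network's largest connected component only.

The walk iterates `p ← (1 − r) W p + r p0` with `W` the column-normalized
adjacency (equal transition probability to each neighbor; edges are treated
as unweighted) and restart `r = 0.5`. Convergence is declared when the L1
change between iterations falls below 1e-6 (the NetWalker convention), with
a hard cap of 10⁴ iterations that errors with the residual rather than
returning silently. The iteration conserves probability mass exactly, and
on graphs up to 50 nodes the fixed point is verified against the direct
linear solve `p = r (I − (1 − r) W)⁻¹ p0` to 1e-8.

Permutations shuffle the observed start-probability *values* across all
network genes, zeros included — the literal reading of "randomly permuted
start probabilities". Local p compares a gene's observed score to its own
permutation scores; global p to the pooled permutation scores of all genes.
(Pooling "per permutation" versus "across all permutations × genes" counts
the same exceedances, so only the pooled form exists.) Both use the add-one
estimator; the smallest attainable local p is 1/(1 + n_perm), so n_perm
must exceed 19 for calls at α = 0.05. The driver subnetwork is the largest
connected component of genes significant at both levels, with ties broken
by node count, then edge count, then smallest member name; no significant
genes yields an empty graph with a warning, not an error.

The method scores proximity to alteration mass; it cannot distinguish
activating from deactivating alterations. The downstream characterization
stage (signature scores, stage correlations) is the intended place to check
expression consistency of an inferred pathway's direction.

## 6. Downstream statistics

Cross-tabulations report, per cell, the count, *both* the row and the
column percentage (published tables mix the two conventions implicitly;
emitting both, labeled, avoids the ambiguity), fold enrichment
observed/(row·col/total) under the explicit independence formula, the
hypergeometric upper-tail p and BH FDR over all cells. Development-related
genes are those with |Spearman ρ| > 0.9 against the timepoint rank, ranked
by median absolute deviation (top 1000); constant genes have undefined ρ
and are excluded. Stage correlations get 95% CIs by the Fisher z-transform
with n = number of genes — the CI method is an assumption, stated here
because the convention is rarely printed. Kaplan–Meier estimation and the
k-group log-rank test are delegated to the `survival` package (tied event
times follow the standard aggregated-risk-set formula); Cox regression is
out of scope — users who need covariate adjustment should call `survival`
directly on the same table.

## 7. The synthetic benchmark: what it emulates, and what it does not

`cohort_spec()` defines the conditions under which the pipeline is
validated. Each planted module is driven by a single latent factor per
sample; a module gene observes `loading × factor + N(0, noise_sd)`, with
loading magnitude `module_correlation = 0.85` and a fifth of members given
negative loadings so that co-expression includes anticorrelated genes (and
the negative arm of the threshold curve is populated). The factor has
within-subtype SD `factor_sd` and mean `subtype_effect` in the one subtype
the module marks. Batch effects are additive per-gene, per-dataset offsets
(`batch_sd = 0.3` log2 units) — exactly the structure per-dataset centering
removes. Subtypes are interleaved within datasets so centering does not
erase subtype signal.

Defaults: 600 genes, 3 × 60 samples, 3 subtypes, 9 modules of 25–35 genes
(three marking each subtype), `subtype_effect = 0.7 = 2 × noise_sd`,
`factor_sd = noise_sd = 0.35`. The factor's within-subtype SD is the one
quantity the emulated study does not characterize; setting it equal to the
residual scale encodes strongly separated subtypes, which matches the
emulated setting — a cohort whose subtype classifier achieved
cross-validation error below 1% is a cohort with nearly separable
subtypes. Under these defaults the marginal within-module correlation is
about 0.58 (the subtype-mean variation itself contributes co-expression),
comfortably above the 0.45 threshold.

Driver structure: a preferential-attachment network (300 nodes, 3 edges
per new node in the benchmark) with one connected 12-gene driver set per
subtype, grown by randomized breadth-first expansion; alterations are
Bernoulli with `driver_rate = 0.6` on a subtype's drivers in its own
samples and `background_rate = 0.01` elsewhere, mutation and CNV drawn
independently (the neutral case for an equal-weight combination). Survival
times are exponential per subtype (defaults chosen so 5-year survival
spans roughly 50–77% at per-month hazards 0.0116/0.0044/0.0077), censoring
independent exponential with rate set so the expected censored fraction
equals `censor_rate`.

What the generator does **not** emulate: heavy-tailed expression noise,
gene–gene correlation outside modules, overlapping or nested modules,
mutational signatures, hypermutators, copy-number segment structure (gene
level only), microsatellite instability or methylation phenotypes, and
non-proportional hazards. Passing the recovery benchmarks therefore shows
the pipeline's machinery is correct under its own model assumptions — not
that real cohorts will be as clean.

## 8. Numerical choices and problem sizes

All stochastic functions take explicit integer seeds and are bitwise
reproducible. Tolerances: per-dataset centering and merge/center
commutation 1e-9; silhouette and start-probability brute-force agreement
1e-12; walk vs linear solve 1e-8; walk convergence 1e-6 (L1). Ties: clique
ordering lexicographic after size; driver-component selection by nodes,
edges, then smallest member; median ties by the standard mean-of-central
rule. Degenerate inputs error loudly (all-zero alteration matrices, empty
gene intersections, singleton classes) except where a defined value is the
established convention (singleton-cluster silhouette 0, empty driver
subnetwork with warning).

The test suite and acceptance script run the full pipeline at 600 genes ×
180 samples with 100 consensus resamples and 1000 walk permutations per
subtype — sizes chosen so the whole validation completes in minutes on one
CPU while leaving every recovery margin wide (adjusted Rand index ≥ 0.9
for core samples; driver recall ≥ 0.8 at precision ≥ 0.5). The chance-level
cross-validation check averages over independent noise datasets as well as
CV repeats, because the CV error conditional on a single finite noise
dataset fluctuates widely around the 2/3 chance level.

## 9. Known limitations

- Threshold selection needs a populated negative correlation arm; cohorts
  without anticorrelated co-expression require a manual threshold.
- ICE merging is greedy in clique order; a different (still deterministic)
  order could assign boundary genes differently between overlapping
  modules.
- SigClust uses diagonal covariance only; strongly correlated features
  make the null conservative.
- The global permutation p-value pools scores across genes whose
  distributions differ with degree; the local p-value is the topology
  guard, and both are required for a driver call.
- Directionality of signaling (activation vs inhibition) is not modeled.
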