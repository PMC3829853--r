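#' End-to-end subtype discovery from a normalized cohort
#'
#' Chains the expression arm of the pipeline: per-dataset centering,
#' all-pairs correlation, co-expression network construction (threshold
#' either supplied or selected from the knowledge-guided similarity curve),
#' iterative clique enumeration for modules, consensus clustering over the
#' module genes, cluster-count selection and silhouette-based core-sample
#' calling.
#'
#' @param expr an [expr_matrix()] (raw; centering is applied internally).
#' @param threshold absolute-correlation threshold; `NULL` invokes
#'   [select_threshold()] on the knowledge-guided curve, which then requires
#'   `ont` and `annotations`.
#' @param ont,annotations optional ontology and annotations for the curve.
#' @param k_range candidate cluster numbers (default `2:5`).
#' @param k fixed cluster number; `NULL` lets [choose_k()] decide.
#' @param n_resamples consensus resampling iterations.
#' @param min_module minimum module size (default 20).
#' @param seed integer seed.
#' @return List with `modules` (a `module_set`), `module_genes`,
#'   `threshold`, `consensus`, `k`, `labels` (named integer vector) and
#'   `assignment` (a `subtype_assignment` with silhouettes and core flags).
#' @export
run_subtype_discovery <- function(expr, threshold = 0.45, ont = NULL,
                                  annotations = NULL, k_range = 2:5,
                                  k = NULL, n_resamples = 250,
                                  min_module = 20, seed = 1L) {
  centered <- center_within_dataset(expr)
  cors <- pairwise_correlations(centered)
  if (is.null(threshold)) {
    if (is.null(ont) || is.null(annotations))
      stop("threshold selection needs an ontology and annotations")
    genes <- rownames(centered$values)
    S <- resnik_matrix(genes, ont, annotations)
    curve <- threshold_curve(cors, S)
    threshold <- select_threshold(curve)
  }
  network <- build_network(cors, threshold)
  modules <- ice_modules(network, min_module = min_module)
  module_genes <- sort(unique(unlist(modules$modules)))
  if (length(module_genes) == 0L)
    stop("no modules of size >= ", min_module, " found")
  consensus <- consensus_cluster(centered, module_genes, k_range,
                                 n_resamples = n_resamples, seed = seed)
  if (is.null(k)) k <- choose_k(consensus)
  labels <- consensus_labels(consensus, k)
  assignment <- core_samples(centered, labels, genes = module_genes)
  list(modules = modules, module_genes = module_genes,
       threshold = threshold, consensus = consensus, k = k,
       labels = labels, assignment = assignment)
}

#' Per-subtype driver subnetwork inference
#'
#' For each subtype, restricts the alteration matrices to that subtype's
#' samples, derives alteration-weighted start probabilities, runs the
#' random walk with restart, assesses local and global permutation
#' significance and extracts the driver subnetwork.
#'
#' @param network undirected `igraph` signaling network.
#' @param mut,cnv binary alteration matrices (genes x samples); `cnv` may
#'   be `NULL`.
#' @param labels subtype label per sample (named by sample id); only
#'   samples present in the matrices are used.
#' @param n_perm permutations per subtype (default 1000).
#' @param r restart probability (default 0.5).
#' @param alpha significance cutoff (default 0.05).
#' @param seed integer seed.
#' @return Named list per subtype, each with `p0`, `significance` and
#'   `subnetwork`.
#' @export
run_driver_inference <- function(network, mut, cnv = NULL, labels,
                                 n_perm = 1000, r = 0.5, alpha = 0.05,
                                 seed = 1L) {
  samples <- intersect(colnames(mut), names(labels))
  if (length(samples) == 0L) stop("no labeled samples in alteration data")
  out <- list()
  for (k in sort(unique(labels[samples]))) {
    sk <- samples[labels[samples] == k]
    p0 <- start_probabilities(mut[, sk, drop = FALSE],
                              if (is.null(cnv)) NULL
                              else cnv[, sk, drop = FALSE])
    sig <- permutation_significance(network, p0, n_perm = n_perm, r = r,
                                    seed = seed + as.integer(factor(
                                      k, sort(unique(labels[samples])))))
    sub <- extract_driver_subnetwork(network, sig, alpha = alpha)
    out[[as.character(k)]] <- list(p0 = p0, significance = sig,
                                   subnetwork = sub)
  }
  out
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same samples;
#' 1 means identical partitions (up to label names), 0 the expected
#' agreement of independent labelings.
#'
#' @param a,b label vectors over the same samples (matched by names when
#'   both are named).
#' @return The adjusted Rand index.
#' @export
adjusted_rand_index <- function(a, b) {
  if (!is.null(names(a)) && !is.null(names(b))) {
    shared <- intersect(names(a), names(b))
    a <- a[shared]; b <- b[shared]
  }
  if (length(a) != length(b)) stop("labelings must cover the same samples")
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}
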