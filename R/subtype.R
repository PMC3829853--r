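#' Consensus average-linkage hierarchical clustering
#'
#' Repeatedly draws a fraction of samples without replacement, clusters each
#' draw by average-linkage hierarchical clustering under the
#' 1 - Pearson-correlation distance, and records for every sample pair the
#' fraction of co-drawn resamples in which the pair landed in the same
#' cluster. The resulting consensus matrices (one per candidate `k`) and the
#' areas under their empirical CDFs quantify clustering stability.
#'
#' @param expr an [expr_matrix()].
#' @param genes genes to cluster on (e.g. module genes); must be present in
#'   `expr`.
#' @param k_range candidate cluster counts, each in `[2, n_samples - 1]`.
#' @param n_resamples number of resampling iterations (default 1000).
#' @param sample_fraction fraction of samples drawn per iteration.
#' @param seed integer seed.
#' @return Object of class `consensus_result`: list with `k_range`,
#'   `consensus` (list of symmetric matrices; entries for pairs never
#'   co-drawn are `NA` and excluded from the CDF), `auc` (area under the
#'   consensus CDF per `k`) and the call parameters.
#' @export
consensus_cluster <- function(expr, genes, k_range, n_resamples = 1000,
                              sample_fraction = 0.8, seed = 1L) {
  stopifnot(inherits(expr, "expr_matrix"))
  missing <- setdiff(genes, rownames(expr$values))
  if (length(missing))
    stop("gene(s) not in expression matrix: ",
         paste(utils::head(missing, 5), collapse = ", "))
  n <- ncol(expr$values)
  k_range <- sort(unique(as.integer(k_range)))
  if (any(k_range < 2L) || any(k_range > n - 1L))
    stop("k_range must lie within [2, n_samples - 1]")
  v <- expr$values[genes, , drop = FALSE]
  D <- 1 - stats::cor(v)
  set.seed(seed)
  n_draw <- max(2L, floor(sample_fraction * n))
  co_sampled <- matrix(0, n, n)
  co_cluster <- lapply(k_range, function(k) matrix(0, n, n))
  names(co_cluster) <- as.character(k_range)
  for (b in seq_len(n_resamples)) {
    idx <- sort(sample.int(n, n_draw))
    co_sampled[idx, idx] <- co_sampled[idx, idx] + 1
    hc <- stats::hclust(stats::as.dist(D[idx, idx]), method = "average")
    for (k in k_range) {
      if (k >= n_draw) next
      labs <- stats::cutree(hc, k = k)
      same <- outer(labs, labs, "==")
      ck <- as.character(k)
      co_cluster[[ck]][idx, idx] <- co_cluster[[ck]][idx, idx] + same
    }
  }
  samples <- colnames(expr$values)
  consensus <- lapply(co_cluster, function(cc) {
    m <- cc / co_sampled
    m[co_sampled == 0] <- NA_real_
    diag(m) <- 1
    dimnames(m) <- list(samples, samples)
    m
  })
  auc <- vapply(consensus, function(m) {
    vals <- m[upper.tri(m)]
    vals <- vals[!is.na(vals)]
    xs <- sort(unique(c(0, vals, 1)))
    cdf <- stats::ecdf(vals)
    sum(diff(xs) * cdf(xs[-length(xs)]))
  }, numeric(1))
  structure(list(k_range = k_range, consensus = consensus, auc = auc,
                 n_resamples = n_resamples,
                 sample_fraction = sample_fraction, seed = seed,
                 genes = genes),
            class = "consensus_result")
}

#' @export
print.consensus_result <- function(x, ...) {
  cat("consensus_result over k =", paste(x$k_range, collapse = ", "), "\n")
  cat("area under consensus CDF:\n")
  print(round(x$auc, 4))
  invisible(x)
}

#' Plot the per-k consensus CDF areas
#'
#' @param x a `consensus_result`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.consensus_result <- function(x, ...) {
  graphics::plot(x$k_range, x$auc, type = "b", xlab = "k",
                 ylab = "area under consensus CDF", ...)
  invisible(x)
}

#' Choose the number of clusters from consensus stability
#'
#' Returns the largest `k` whose relative increase in area under the
#' consensus CDF over `k - 1` exceeds `rel_increase`; with no such `k` the
#' smallest candidate is returned. The rule is an aid mirroring visual CDF
#' inspection, never a silent override of an analyst-specified `k`.
#'
#' @param result a [consensus_cluster()] result with at least one `k`.
#' @param rel_increase required relative area increase (default 0.1).
#' @return The selected `k`.
#' @export
choose_k <- function(result, rel_increase = 0.1) {
  stopifnot(inherits(result, "consensus_result"))
  ks <- result$k_range
  if (length(ks) == 1L) return(ks)
  auc <- result$auc
  gain <- diff(auc) / abs(auc[-length(auc)])
  passing <- ks[-1L][gain > rel_increase]
  if (length(passing)) max(passing) else min(ks)
}

#' Final cluster labels at a chosen k
#'
#' Average-linkage hierarchical clustering of `1 - consensus` at the chosen
#' `k`, the standard way to read labels off a consensus matrix. Pairs never
#' co-drawn (NA entries) are treated as never co-clustering.
#'
#' @param result a [consensus_cluster()] result.
#' @param k one of the result's `k_range`.
#' @return Named integer vector of cluster labels per sample.
#' @export
consensus_labels <- function(result, k) {
  stopifnot(inherits(result, "consensus_result"))
  ck <- as.character(k)
  if (!ck %in% names(result$consensus)) stop("k = ", k, " was not evaluated")
  m <- result$consensus[[ck]]
  m[is.na(m)] <- 0
  hc <- stats::hclust(stats::as.dist(1 - m), method = "average")
  stats::cutree(hc, k = k)
}

#' SigClust significance of a two-cluster split
#'
#' Tests whether a given two-group split of samples is significant against
#' the null of a single multivariate Gaussian. The statistic is the
#' 2-cluster index (within-cluster sum of squares over total sum of squares)
#' of the given split; the null distribution is the cluster index of the
#' best 2-means split of data simulated from a diagonal-covariance Gaussian
#' whose per-feature variances are floored at a background noise variance
#' estimated by the median absolute deviation of the centered data.
#'
#' @param expr an [expr_matrix()].
#' @param samplesA,samplesB disjoint sample sets, each of size >= 2.
#' @param n_sim number of null simulations (default 1000).
#' @param seed integer seed.
#' @param genes optional gene subset (default: all genes).
#' @return List with `p` (add-one permutation p-value in `(0, 1]`),
#'   `observed_ci` and the vector of simulated cluster indices.
#' @export
sigclust_pair <- function(expr, samplesA, samplesB, n_sim = 1000, seed = 1L,
                          genes = NULL) {
  stopifnot(inherits(expr, "expr_matrix"))
  if (length(intersect(samplesA, samplesB)))
    stop("sample sets must be disjoint")
  if (length(samplesA) < 2L || length(samplesB) < 2L)
    stop("each cluster needs at least 2 samples")
  v <- expr$values
  if (!is.null(genes)) v <- v[genes, , drop = FALSE]
  X <- t(v[, c(samplesA, samplesB), drop = FALSE])  # samples x features
  n <- nrow(X)
  if (n < 4L) stop("need at least 4 samples in total")
  labs <- rep(1:2, c(length(samplesA), length(samplesB)))
  ci_of_split <- function(X, labs) {
    total <- sum(scale(X, scale = FALSE)^2)
    within <- sum(vapply(unique(labs), function(g) {
      sum(scale(X[labs == g, , drop = FALSE], scale = FALSE)^2)
    }, numeric(1)))
    within / total
  }
  observed <- ci_of_split(X, labs)
  Xc <- scale(X, scale = FALSE)
  v_feat <- apply(Xc, 2L, stats::var)
  s2_bg <- stats::mad(as.numeric(Xc))^2
  lambda <- pmax(v_feat, s2_bg)
  set.seed(seed)
  sims <- vapply(seq_len(n_sim), function(i) {
    Z <- matrix(stats::rnorm(n * length(lambda)), n) %*%
      diag(sqrt(lambda), length(lambda))
    km <- stats::kmeans(Z, centers = 2L, nstart = 3L)
    ci_of_split(Z, km$cluster)
  }, numeric(1))
  p <- (1 + sum(sims <= observed)) / (1 + n_sim)
  list(p = p, observed_ci = observed, null_ci = sims)
}

#' Silhouette widths and core-sample selection
#'
#' For each sample, `a(i)` is its mean distance to the other members of its
#' own cluster and `b(i)` the smallest mean distance to the members of any
#' other cluster; the silhouette width is
#' `s(i) = (b(i) - a(i)) / max(a(i), b(i))`. Samples with positive `s(i)`
#' are flagged as core samples, the reliable representatives of their
#' subtype. Singleton clusters leave `a(i)` undefined; such samples get
#' `s(i) = 0` (neither core nor anti-core) with a loud warning.
#'
#' @param expr an [expr_matrix()].
#' @param labels named (by sample) or column-ordered cluster labels; at
#'   least 2 nonempty clusters.
#' @param genes optional gene subset used for the distance (default: all).
#' @param distance `"pearson"` (1 - Pearson correlation between samples, the
#'   default used throughout the pipeline) or `"euclidean"`.
#' @return Object of class `subtype_assignment`: data frame with columns
#'   `sample`, `label`, `silhouette`, `core`.
#' @export
core_samples <- function(expr, labels, genes = NULL,
                         distance = c("pearson", "euclidean")) {
  stopifnot(inherits(expr, "expr_matrix"))
  distance <- match.arg(distance)
  v <- expr$values
  if (!is.null(genes)) v <- v[genes, , drop = FALSE]
  samples <- colnames(v)
  if (!is.null(names(labels))) labels <- labels[samples]
  if (length(labels) != length(samples)) stop("one label per sample required")
  labels <- as.vector(labels)
  tab <- table(labels)
  if (length(tab) < 2L) stop("need at least 2 clusters")
  D <- if (distance == "pearson") 1 - stats::cor(v)
       else as.matrix(stats::dist(t(v)))
  n <- length(samples)
  sil <- numeric(n)
  singleton <- names(tab)[tab == 1L]
  if (length(singleton))
    warning("singleton cluster(s) ", paste(singleton, collapse = ", "),
            ": silhouette set to 0 for their samples")
  for (i in seq_len(n)) {
    own <- labels[i]
    if (tab[[as.character(own)]] == 1L) { sil[i] <- 0; next }
    a <- mean(D[i, labels == own & seq_len(n) != i])
    b <- min(vapply(setdiff(names(tab), as.character(own)), function(g)
      mean(D[i, labels == g]), numeric(1)))
    sil[i] <- (b - a) / max(a, b)
  }
  structure(data.frame(sample = samples, label = labels, silhouette = sil,
                       core = sil > 0, stringsAsFactors = FALSE),
            class = c("subtype_assignment", "data.frame"))
}

#' Write a subtype assignment table
#'
#' Tab-delimited columns: sample, label, silhouette, core.
#'
#' @param assignment a [core_samples()] result.
#' @param path file path.
#' @export
write_assignment <- function(assignment, path) {
  utils::write.table(as.data.frame(assignment), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
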