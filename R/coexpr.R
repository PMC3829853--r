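#' Number of unordered gene pairs
#'
#' @param n number of genes.
#' @return `n * (n - 1) / 2` as a double (exact for any realistic `n`).
#' @examples
#' n_gene_pairs(10481)  # 54,920,440
#' @export
n_gene_pairs <- function(n) choose(as.numeric(n), 2)

#' All pairwise Pearson correlations between genes
#'
#' Emits every unordered gene pair exactly once (no self-pairs). Genes with
#' zero variance cannot be correlated; their pairs are skipped and the genes
#' reported in a message.
#'
#' @param expr an [expr_matrix()] with at least 3 samples.
#' @return Data frame with columns `geneA`, `geneB`, `r`, ordered so that
#'   `geneA < geneB` within each row.
#' @export
pairwise_correlations <- function(expr) {
  stopifnot(inherits(expr, "expr_matrix"))
  v <- expr$values
  if (ncol(v) < 3L) stop("need at least 3 samples to correlate genes")
  sds <- apply(v, 1L, stats::sd)
  zero_var <- rownames(v)[sds == 0]
  if (length(zero_var)) {
    message("skipping ", length(zero_var),
            " zero-variance gene(s): ",
            paste(utils::head(zero_var, 5), collapse = ", "))
    v <- v[sds > 0, , drop = FALSE]
  }
  if (nrow(v) < 2L) stop("fewer than 2 genes with variance")
  cm <- stats::cor(t(v))
  idx <- which(upper.tri(cm), arr.ind = TRUE)
  data.frame(geneA = rownames(cm)[idx[, 1L]],
             geneB = colnames(cm)[idx[, 2L]],
             r = cm[idx],
             stringsAsFactors = FALSE)
}

#' Functional-similarity profile over correlation bins
#'
#' The knowledge-guided threshold selection device: gene pairs are binned by
#' their correlation coefficient, and the average semantic similarity of the
#' pairs in each bin is computed. Biologically meaningful co-expression shows
#' up as a sharp rise in mean similarity beyond some `|r|`.
#'
#' @param correlations data frame from [pairwise_correlations()].
#' @param similarity either a symmetric gene x gene similarity matrix (see
#'   [resnik_matrix()]) or a function `f(geneA, geneB)` returning a score.
#' @param bins breakpoints partitioning `[-1, 1]`; default width 0.05.
#' @return Object of class `threshold_curve`: data frame with per-bin `lo`,
#'   `hi`, `n_pairs`, `mean_sim`, `se_sim` and an `empty` flag.
#' @export
threshold_curve <- function(correlations, similarity,
                            bins = seq(-1, 1, by = 0.05)) {
  bins <- sort(bins)
  if (bins[1L] > -1 || bins[length(bins)] < 1)
    stop("bins must cover [-1, 1]")
  if (is.matrix(similarity)) {
    sim <- similarity[cbind(correlations$geneA, correlations$geneB)]
  } else if (is.function(similarity)) {
    sim <- mapply(similarity, correlations$geneA, correlations$geneB)
  } else stop("'similarity' must be a matrix or a function")
  bin_id <- findInterval(correlations$r, bins, rightmost.closed = TRUE,
                         all.inside = TRUE)
  n_bins <- length(bins) - 1L
  out <- data.frame(lo = bins[-length(bins)], hi = bins[-1L],
                    n_pairs = 0L, mean_sim = NA_real_, se_sim = NA_real_)
  for (b in seq_len(n_bins)) {
    s <- sim[bin_id == b]
    out$n_pairs[b] <- length(s)
    if (length(s)) {
      out$mean_sim[b] <- mean(s)
      out$se_sim[b] <- if (length(s) > 1L) stats::sd(s) / sqrt(length(s)) else 0
    }
  }
  out$empty <- out$n_pairs == 0L
  class(out) <- c("threshold_curve", "data.frame")
  out
}

#' Select a correlation threshold from a similarity curve
#'
#' With `manual` given, that value is returned untouched (mirroring an
#' analyst reading the curve). Otherwise the rule is: take the mean
#' similarity of all pairs with `|r| < baseline_max` as baseline; return the
#' smallest nonnegative bin edge `e >= baseline_max` at which the first
#' non-empty bin on the positive side (starting at `e`) *and* its mirrored
#' negative bin both exceed the baseline by at least `n_se` pooled standard
#' errors.
#'
#' @param curve a [threshold_curve()].
#' @param manual optional analyst-chosen threshold, returned as-is.
#' @param baseline_max bins entirely inside `(-baseline_max, baseline_max)`
#'   form the baseline (default 0.3).
#' @param n_se required number of pooled standard errors above baseline.
#' @return The selected absolute-correlation threshold.
#' @export
select_threshold <- function(curve, manual = NULL, baseline_max = 0.3,
                             n_se = 2) {
  if (!is.null(manual)) return(manual)
  stopifnot(inherits(curve, "threshold_curve"))
  if (nrow(curve) == 0L) stop("empty curve")
  base_bins <- curve[curve$lo >= -baseline_max & curve$hi <= baseline_max &
                       !curve$empty, ]
  if (nrow(base_bins) == 0L)
    stop("no populated baseline bins below |r| = ", baseline_max,
         "; choose a threshold manually")
  n_base <- sum(base_bins$n_pairs)
  base_mean <- sum(base_bins$mean_sim * base_bins$n_pairs) / n_base
  base_var <- sum((base_bins$se_sim^2 * base_bins$n_pairs^2)) / n_base^2
  exceeds <- function(bin) {
    !is.na(bin$mean_sim) &&
      bin$mean_sim - base_mean >= n_se * sqrt(bin$se_sim^2 + base_var)
  }
  pos <- curve[curve$lo >= baseline_max, ]
  pos <- pos[order(pos$lo), ]
  for (i in seq_len(nrow(pos))) {
    e <- pos$lo[i]
    pbin <- pos[!pos$empty & pos$lo >= e, ][1, ]
    nbin <- curve[!curve$empty & curve$hi <= -e, ]
    nbin <- if (nrow(nbin)) nbin[which.max(nbin$hi), ] else NULL
    if (!is.null(nbin) && nrow(pbin) && !is.na(pbin$lo) &&
        exceeds(pbin) && exceeds(nbin))
      return(e)
  }
  stop("no bin edge satisfies the knowledge-guided rule on both sides; ",
       "inspect the curve and pass a manual threshold")
}

#' Build a co-expression network by absolute-correlation thresholding
#'
#' @param correlations data frame from [pairwise_correlations()].
#' @param threshold absolute-correlation cutoff in `(0, 1)`; an edge is kept
#'   iff `|r| >= threshold`. Isolated genes are excluded.
#' @return An undirected `igraph` graph with edge attribute `r` (the signed
#'   correlation).
#' @export
build_network <- function(correlations, threshold) {
  if (!(threshold > 0 && threshold < 1))
    stop("threshold must lie in (0, 1)")
  keep <- abs(correlations$r) >= threshold
  if (!any(keep)) stop("no edges survive threshold ", threshold)
  el <- correlations[keep, , drop = FALSE]
  g <- igraph::graph_from_data_frame(el[, c("geneA", "geneB")],
                                     directed = FALSE)
  igraph::E(g)$r <- el$r
  g
}

#' Iterative clique enumeration for module discovery
#'
#' Enumerates all maximal cliques of at least `min_clique` nodes and
#' processes them in decreasing size (ties broken by the lexicographically
#' smallest sorted member list, for determinism). A clique sharing at least
#' `merge_overlap` of its own nodes with an already-formed module is merged
#' into the module with the largest such overlap; otherwise it seeds a new
#' module. Modules with fewer than `min_module` unique genes are dropped,
#' keeping only the major, relatively independent co-expression programs.
#'
#' @param network `igraph` co-expression network.
#' @param min_clique minimum maximal-clique size to consider (default 5).
#' @param min_module minimum genes for a reported module (default 20).
#' @param merge_overlap fraction of a clique's nodes that must be inside a
#'   module to merge, measured as `|clique ∩ module| / |clique|`.
#' @return Object of class `module_set`: list with `modules` (named list of
#'   gene vectors) and `provenance` (per-module seed clique).
#' @export
ice_modules <- function(network, min_clique = 5, min_module = 20,
                        merge_overlap = 0.5) {
  if (igraph::vcount(network) == 0L) stop("empty network")
  cl <- igraph::max_cliques(network, min = min_clique)
  cl <- lapply(cl, function(v) sort(igraph::V(network)$name[v]))
  if (length(cl)) {
    key <- vapply(cl, paste, character(1), collapse = "\x01")
    cl <- cl[order(-lengths(cl), key)]
  }
  modules <- list()
  seeds <- list()
  for (clique in cl) {
    if (length(modules)) {
      ov <- vapply(modules, function(m)
        length(intersect(clique, m)) / length(clique), numeric(1))
      best <- which.max(ov)
      if (ov[best] >= merge_overlap) {
        modules[[best]] <- sort(union(modules[[best]], clique))
        next
      }
    }
    modules[[length(modules) + 1L]] <- clique
    seeds[[length(seeds) + 1L]] <- clique
  }
  keep <- lengths(modules) >= min_module
  modules <- modules[keep]
  seeds <- seeds[keep]
  if (length(modules)) {
    nm <- sprintf("module%02d", seq_along(modules))
    names(modules) <- nm
    names(seeds) <- nm
  }
  structure(list(modules = modules, provenance = seeds), class = "module_set")
}

#' @export
print.module_set <- function(x, ...) {
  cat(sprintf("module_set: %d module(s), %d unique genes\n",
              length(x$modules),
              length(unique(unlist(x$modules)))))
  invisible(x)
}

#' Read / write gene sets in GMT format
#'
#' One line per set: name, description, then tab-separated members.
#'
#' @param sets named list of character vectors.
#' @param path file path.
#' @param description description field (recycled).
#' @export
write_gmt <- function(sets, path, description = "na") {
  description <- rep_len(description, length(sets))
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], description[i], sets[[i]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gmt
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  stats::setNames(lapply(parts, function(p) p[-(1:2)]),
                  vapply(parts, `[`, character(1), 1L))
}
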