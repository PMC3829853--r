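#' Binarize somatic mutation calls to a gene x sample matrix
#'
#' An entry is 1 iff the gene carries at least one non-silent call in the
#' sample. Silent/synonymous classes are excluded via a configurable list;
#' variant classes outside the known silent and non-silent vocabularies
#' trigger a warning and are treated as non-silent by default (the
#' conservative choice for a driver screen).
#'
#' @param calls data frame of MAF-like records with columns `sample`, `gene`
#'   and `variant_class`.
#' @param genes,samples row/column universes of the output matrix (columns
#'   with no calls are retained as all-zero).
#' @param silent_classes variant classes that do not count as alterations.
#' @param unknown_is_silent treat unknown classes as silent instead.
#' @return Binary integer matrix, `genes` x `samples`.
#' @export
binarize_mutations <- function(calls, genes, samples,
                               silent_classes = c("Silent", "synonymous"),
                               unknown_is_silent = FALSE) {
  req <- c("sample", "gene", "variant_class")
  if (!all(req %in% names(calls)))
    stop("'calls' needs columns: ", paste(req, collapse = ", "))
  known_nonsilent <- c("Missense_Mutation", "Nonsense_Mutation",
                       "Frame_Shift_Del", "Frame_Shift_Ins",
                       "In_Frame_Del", "In_Frame_Ins", "Splice_Site",
                       "Nonstop_Mutation", "Translation_Start_Site",
                       "missense", "nonsense", "frameshift")
  unknown <- setdiff(unique(calls$variant_class),
                     c(silent_classes, known_nonsilent))
  if (length(unknown))
    warning("unknown variant class(es) treated as ",
            if (unknown_is_silent) "silent" else "non-silent", ": ",
            paste(utils::head(unknown, 5), collapse = ", "))
  silent <- silent_classes
  if (unknown_is_silent) silent <- c(silent, unknown)
  calls <- calls[!(calls$variant_class %in% silent), , drop = FALSE]
  calls <- calls[calls$gene %in% genes & calls$sample %in% samples, ,
                 drop = FALSE]
  m <- matrix(0L, length(genes), length(samples),
              dimnames = list(genes, samples))
  if (nrow(calls)) m[cbind(calls$gene, calls$sample)] <- 1L
  m
}

#' Binarize gene-level copy-number ratios
#'
#' An entry is 1 iff the copy ratio marks a gain (`>= hi`) or a loss
#' (`<= lo`); both cutoffs are inclusive. Ratios must be positive.
#'
#' @param ratios numeric matrix, genes x samples, of copy ratios.
#' @param hi gain cutoff (default 1.2).
#' @param lo loss cutoff (default 0.8).
#' @return Binary integer matrix with the same dimnames.
#' @export
binarize_cnv <- function(ratios, hi = 1.2, lo = 0.8) {
  if (any(ratios <= 0)) stop("copy ratios must be positive")
  m <- matrix(as.integer(ratios >= hi | ratios <= lo),
              nrow(ratios), ncol(ratios), dimnames = dimnames(ratios))
  m
}

#' Alteration-weighted start probabilities for the random walk
#'
#' Each binary matrix is column-normalized (each sample's alterations are
#' divided by the sample's total alteration count, down-weighting
#' hypermutated samples; all-zero columns contribute 0) and then summed per
#' gene, giving `S_mut(i)` and `S_cnv(i)`. The two kinds are combined with
#' equal weight by plain summation and globally normalized to a probability
#' vector.
#'
#' @param mut binary mutation matrix (genes x samples).
#' @param cnv binary CNV matrix with the same dimnames, or `NULL` for a
#'   mutation-only analysis.
#' @return Object of class `start_prob`: list with `p0` (named, sums to 1),
#'   and the audit components `s_mut` and `s_cnv`.
#' @export
start_probabilities <- function(mut, cnv = NULL) {
  if (is.null(cnv)) {
    cnv <- mut * 0L
  } else {
    if (!identical(dimnames(mut), dimnames(cnv)))
      stop("mutation and CNV matrices must share gene and sample universes")
  }
  if (!all(mut %in% c(0L, 1L)) || !all(cnv %in% c(0L, 1L)))
    stop("alteration matrices must be binary")
  col_norm_rowsum <- function(m) {
    cs <- colSums(m)
    cs[cs == 0] <- 1  # all-zero columns contribute 0 anyway
    rowSums(sweep(m, 2L, cs, "/"))
  }
  s_mut <- col_norm_rowsum(mut)
  s_cnv <- col_norm_rowsum(cnv)
  total <- sum(s_mut) + sum(s_cnv)
  if (total == 0) stop("no alterations at all: start probabilities undefined")
  p0 <- (s_mut + s_cnv) / total
  structure(list(p0 = p0, s_mut = s_mut, s_cnv = s_cnv),
            class = "start_prob")
}

#' @export
print.start_prob <- function(x, ...) {
  nz <- sum(x$p0 > 0)
  cat(sprintf("start_prob over %d genes (%d nonzero), sum = %.6f\n",
              length(x$p0), nz, sum(x$p0)))
  invisible(x)
}

#' Random walk with restart on a signaling network
#'
#' Iterates `p <- (1 - r) * W p + r * p0` from `p = p0`, where `W` is the
#' column-normalized adjacency matrix of the network's largest connected
#' component (equal transition probability to each neighbor), until the L1
#' change between iterations falls below `epsilon`. The walk operates on the
#' largest connected component only; start probabilities for genes outside
#' it are dropped (with a message) and the remainder renormalized. The
#' steady state scores each gene's proximity to the alteration-weighted seed
#' distribution.
#'
#' @param network undirected `igraph` network with named vertices.
#' @param p0 a [start_probabilities()] result or a named nonnegative vector.
#' @param r restart probability in `(0, 1]` (default 0.5).
#' @param epsilon L1 convergence tolerance (default 1e-6).
#' @param max_iter iteration cap (default 10000); non-convergence errors
#'   with the final residual.
#' @return Object of class `walk_scores`: list with `score` (named vector
#'   over the component, sums to 1), `p0` (as used), `r`, `iterations`,
#'   `residual`.
#' @export
random_walk <- function(network, p0, r = 0.5, epsilon = 1e-6,
                        max_iter = 10000L) {
  if (!(r > 0 && r <= 1)) stop("restart probability must lie in (0, 1]")
  if (inherits(p0, "start_prob")) p0 <- p0$p0
  if (is.null(names(p0))) stop("p0 must be named by gene")
  comp <- igraph::components(network)
  keep <- igraph::V(network)$name[comp$membership == which.max(comp$csize)]
  g <- igraph::induced_subgraph(network, keep)
  dropped <- setdiff(names(p0), keep)
  if (length(dropped) && any(p0[dropped] > 0))
    message("dropping ", sum(p0[dropped] > 0),
            " gene(s) with start mass outside the largest component")
  p0v <- stats::setNames(numeric(length(keep)), keep)
  shared <- intersect(names(p0), keep)
  p0v[shared] <- p0[shared]
  if (any(p0v < 0)) stop("start probabilities must be nonnegative")
  if (sum(p0v) == 0) stop("no start mass on the largest component")
  p0v <- p0v / sum(p0v)
  A <- igraph::as_adjacency_matrix(g, sparse = TRUE)
  A <- A[keep, keep]
  W <- A %*% Matrix_col_inv(A)
  p <- p0v
  for (it in seq_len(max_iter)) {
    p_new <- as.numeric((1 - r) * (W %*% p)) + r * p0v
    res <- sum(abs(p_new - p))
    p <- p_new
    if (res < epsilon) {
      names(p) <- keep
      return(structure(list(score = p, p0 = p0v, r = r, iterations = it,
                            residual = res),
                       class = "walk_scores"))
    }
  }
  stop("random walk did not converge in ", max_iter,
       " iterations (residual ", signif(res, 3), ")")
}

# diagonal matrix of inverse column sums (degree inverse for 0/1 adjacency)
Matrix_col_inv <- function(A) {
  cs <- Matrix::colSums(A)
  cs[cs == 0] <- 1
  Matrix::Diagonal(x = 1 / cs)
}

#' @export
print.walk_scores <- function(x, ...) {
  cat(sprintf("walk_scores: %d genes, r = %g, converged in %d iteration(s)",
              length(x$score), x$r, x$iterations),
      sprintf("(residual %.2g)\n", x$residual))
  invisible(x)
}

#' Permutation significance of walk scores
#'
#' Each permutation shuffles the observed start-probability values across
#' the network genes (values preserved, assignment randomized, zeros
#' included) and reruns the walk. The local p-value compares a gene's
#' observed score to its own permutation scores, guarding against
#' significance driven purely by network topology; the global p-value
#' compares it to the pooled permutation scores of all genes. Both use the
#' add-one estimator, so the smallest attainable local p is
#' `1 / (1 + n_perm)`.
#'
#' @inheritParams random_walk
#' @param n_perm number of permutations (default 1000).
#' @param seed integer seed.
#' @return Object of class `significance_result`: data frame with columns
#'   `gene`, `p0`, `score`, `local_p`, `global_p`.
#' @export
permutation_significance <- function(network, p0, n_perm = 1000, r = 0.5,
                                     epsilon = 1e-6, seed = 1L) {
  if (n_perm < 1L) stop("n_perm must be at least 1")
  obs <- random_walk(network, p0, r = r, epsilon = epsilon)
  genes <- names(obs$score)
  n_genes <- length(genes)
  set.seed(seed)
  perm_scores <- matrix(NA_real_, n_genes, n_perm, dimnames = list(genes))
  for (b in seq_len(n_perm)) {
    p0_perm <- stats::setNames(sample(obs$p0), genes)
    perm_scores[, b] <- random_walk(network, p0_perm, r = r,
                                    epsilon = epsilon)$score
  }
  local_ge <- rowSums(perm_scores >= obs$score)
  local_p <- (1 + local_ge) / (1 + n_perm)
  pooled <- sort(as.numeric(perm_scores))
  # #{pooled >= s} via binary search on the sorted pool
  global_ge <- length(pooled) -
    findInterval(obs$score, pooled, left.open = TRUE)
  global_p <- (1 + global_ge) / (1 + n_perm * n_genes)
  structure(data.frame(gene = genes, p0 = obs$p0, score = obs$score,
                       local_p = local_p, global_p = global_p,
                       stringsAsFactors = FALSE, row.names = NULL),
            class = c("significance_result", "data.frame"))
}

#' Extract the driver subnetwork
#'
#' Induces the subgraph on genes significant at both the local and the
#' global level (`local_p < alpha` and `global_p < alpha`) and returns its
#' largest connected component; ties are broken by node count, then edge
#' count, then the lexicographically smallest member. With no significant
#' gene an empty graph is returned with a warning.
#'
#' @param network undirected `igraph` network with named vertices.
#' @param sig a [permutation_significance()] result.
#' @param alpha significance cutoff applied to both p-values (default 0.05).
#' @return An `igraph` subgraph (possibly empty).
#' @export
extract_driver_subnetwork <- function(network, sig, alpha = 0.05) {
  stopifnot(inherits(sig, "significance_result"))
  hits <- sig$gene[sig$local_p < alpha & sig$global_p < alpha]
  hits <- intersect(hits, igraph::V(network)$name)
  if (length(hits) == 0L) {
    warning("no gene significant at alpha = ", alpha,
            "; returning empty subnetwork")
    return(igraph::make_empty_graph(0, directed = FALSE))
  }
  sub <- igraph::induced_subgraph(network, hits)
  comp <- igraph::components(sub)
  stats_by_comp <- lapply(seq_len(comp$no), function(ci) {
    vs <- igraph::V(sub)$name[comp$membership == ci]
    cg <- igraph::induced_subgraph(sub, vs)
    list(n = length(vs), e = igraph::ecount(cg), first = min(vs))
  })
  ord <- order(-vapply(stats_by_comp, `[[`, numeric(1), "n"),
               -vapply(stats_by_comp, `[[`, numeric(1), "e"),
               vapply(stats_by_comp, `[[`, character(1), "first"))
  best <- ord[1L]
  igraph::induced_subgraph(sub,
                           igraph::V(sub)$name[comp$membership == best])
}

#' Hypergeometric gene-set enrichment with BH correction
#'
#' For every set in the collection: overlap with the query genes, the
#' hypergeometric upper-tail p-value for that overlap given the background
#' universe, and the Benjamini-Hochberg FDR over all tested sets.
#'
#' @param query_genes genes to test (subset of `background`).
#' @param background background gene universe.
#' @param collections named list of gene sets (see [read_gmt()]).
#' @return Data frame with columns `set`, `set_size`, `overlap`, `p`,
#'   `fdr`, ordered by p.
#' @export
geneset_enrichment <- function(query_genes, background, collections) {
  if (length(collections) == 0L) stop("empty gene-set collection")
  if (!all(query_genes %in% background))
    stop("query genes must be a subset of the background")
  N <- length(background)
  n_query <- length(query_genes)
  rows <- lapply(names(collections), function(nm) {
    set <- intersect(collections[[nm]], background)
    k <- length(intersect(set, query_genes))
    p <- stats::phyper(k - 1, length(set), N - length(set), n_query,
                       lower.tail = FALSE)
    data.frame(set = nm, set_size = length(set), overlap = k, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- stats::p.adjust(out$p, method = "BH")
  out[order(out$p), , drop = FALSE]
}

#' Read / write network edge lists
#'
#' Two-column tab-delimited edge lists; `read_edge_list` also accepts the
#' three-column SIF dialect (`geneA interaction geneB`).
#'
#' @param path file path.
#' @return `read_edge_list` returns an undirected `igraph` graph.
#' @export
read_edge_list <- function(path) {
  tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  el <- if (ncol(tab) >= 3L && !is.numeric(tab[[2L]]))
    tab[, c(1L, 3L)] else tab[, 1:2]
  names(el) <- c("from", "to")
  igraph::graph_from_data_frame(el, directed = FALSE)
}

#' @param network an `igraph` graph to write.
#' @rdname read_edge_list
#' @export
write_edge_list <- function(network, path) {
  el <- igraph::as_edgelist(network)
  utils::write.table(el, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read / write MAF-like mutation tables
#'
#' Minimal tab-delimited dialect with columns `sample`, `gene`,
#' `variant_class`.
#'
#' @param path file path.
#' @export
read_maf <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' @param calls data frame with columns `sample`, `gene`, `variant_class`.
#' @rdname read_maf
#' @export
write_maf <- function(calls, path) {
  utils::write.table(calls[, c("sample", "gene", "variant_class")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Convert a binary alteration matrix to MAF-like long records
#'
#' @param mat binary genes x samples matrix.
#' @param variant_class class label for the emitted records.
#' @return Data frame with columns `sample`, `gene`, `variant_class`.
#' @export
alteration_to_maf <- function(mat, variant_class = "Missense_Mutation") {
  idx <- which(mat != 0, arr.ind = TRUE)
  data.frame(sample = colnames(mat)[idx[, 2L]],
             gene = rownames(mat)[idx[, 1L]],
             variant_class = variant_class,
             stringsAsFactors = FALSE)
}
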