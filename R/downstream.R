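#' Cross-tabulation association between two sample labelings
#'
#' Builds the contingency table over the shared samples and reports, per
#' cell: count, row percentage (count / row total), column percentage
#' (count / column total), fold enrichment (observed / expected under
#' independence, i.e. count / (row total * column total / grand total)),
#' the hypergeometric upper-tail p-value of the overlap, and the
#' Benjamini-Hochberg FDR over all cells. Both percentage conventions are
#' emitted and labeled so neither has to be inferred from context.
#'
#' @param labelsA,labelsB named vectors, sample -> class; at least one
#'   shared sample is required.
#' @return Object of class `crosstab`: list with `table` (the contingency
#'   matrix) and `cells`, a data frame with one row per cell.
#' @export
crosstab_association <- function(labelsA, labelsB) {
  shared <- intersect(names(labelsA), names(labelsB))
  if (length(shared) == 0L) stop("no shared samples between the labelings")
  a <- factor(labelsA[shared])
  b <- factor(labelsB[shared])
  tab <- table(a, b)
  N <- sum(tab)
  rows <- expand.grid(row = rownames(tab), col = colnames(tab),
                      stringsAsFactors = FALSE)
  cells <- do.call(rbind, lapply(seq_len(nrow(rows)), function(i) {
    r <- rows$row[i]; cl <- rows$col[i]
    k <- tab[r, cl]
    rt <- sum(tab[r, ]); ct <- sum(tab[, cl])
    p <- stats::phyper(k - 1, ct, N - ct, rt, lower.tail = FALSE)
    data.frame(row = r, col = cl, count = as.integer(k),
               row_total = rt, col_total = ct,
               row_pct = 100 * k / rt, col_pct = 100 * k / ct,
               fold = k / (rt * ct / N), p = p,
               stringsAsFactors = FALSE)
  }))
  cells$fdr <- stats::p.adjust(cells$p, method = "BH")
  structure(list(table = tab, cells = cells), class = "crosstab")
}

#' @export
print.crosstab <- function(x, ...) {
  print(x$table)
  cat("\nper-cell statistics:\n")
  print(x$cells, digits = 3)
  invisible(x)
}

#' Select development-related genes from a timecourse
#'
#' Keeps genes whose expression is strongly monotone in developmental time
#' (absolute Spearman correlation with the timepoint rank above `rho_min`),
#' then returns the `n_top` of those with the largest median absolute
#' deviation across timepoints (all of them if fewer pass). Constant genes
#' have an undefined rank correlation and are excluded.
#'
#' @param timecourse numeric matrix, genes x ordered timepoints (at least
#'   4 timepoints).
#' @param rho_min absolute Spearman cutoff (default 0.9).
#' @param n_top number of genes to return (default 1000).
#' @return Character vector of selected genes, MAD-ranked.
#' @export
select_development_genes <- function(timecourse, rho_min = 0.9,
                                     n_top = 1000) {
  if (ncol(timecourse) < 4L) stop("need at least 4 timepoints")
  timeranks <- seq_len(ncol(timecourse))
  sds <- apply(timecourse, 1L, stats::sd)
  candidates <- timecourse[sds > 0, , drop = FALSE]
  if (nrow(candidates) == 0L) stop("no non-constant genes")
  rho <- apply(candidates, 1L, function(x)
    stats::cor(x, timeranks, method = "spearman"))
  passing <- candidates[abs(rho) > rho_min, , drop = FALSE]
  if (nrow(passing) == 0L)
    stop("no gene passes |spearman rho| > ", rho_min)
  mads <- apply(passing, 1L, stats::mad)
  rownames(passing)[order(mads, decreasing = TRUE)][
    seq_len(min(n_top, nrow(passing)))]
}

#' Correlate subtype centroids with developmental timepoints
#'
#' For each (subtype, timepoint) pair, the Pearson correlation between the
#' subtype's mean expression profile over the selected genes and the
#' timepoint's profile over the same genes, with a 95% confidence interval
#' by the Fisher z-transform at `n = number of genes`.
#'
#' @param centroids numeric matrix, genes x subtypes, of per-subtype mean
#'   expression.
#' @param timecourse numeric matrix, genes x timepoints.
#' @param genes genes to use; at least 4 must be present in both matrices.
#' @return Data frame with columns `subtype`, `timepoint`, `r`, `ci_lo`,
#'   `ci_hi`.
#' @export
stage_correlation <- function(centroids, timecourse, genes) {
  genes <- intersect(genes,
                     intersect(rownames(centroids), rownames(timecourse)))
  if (length(genes) < 4L) stop("fewer than 4 shared genes")
  n <- length(genes)
  zcrit <- stats::qnorm(0.975)
  out <- expand.grid(subtype = colnames(centroids),
                     timepoint = colnames(timecourse),
                     stringsAsFactors = FALSE)
  out$r <- mapply(function(s, t)
    stats::cor(centroids[genes, s], timecourse[genes, t]),
    out$subtype, out$timepoint)
  z <- atanh(pmin(pmax(out$r, -1 + 1e-15), 1 - 1e-15))
  se <- 1 / sqrt(n - 3)
  out$ci_lo <- tanh(z - zcrit * se)
  out$ci_hi <- tanh(z + zcrit * se)
  out
}

#' Per-sample signature score
#'
#' The mean, per sample, of gene-centered expression over the genes of the
#' signature present in the matrix (absent genes are reported in a
#' message). Centering is per gene across all samples, so the score
#' measures relative up- or down-regulation of the program in each sample.
#'
#' @param expr an [expr_matrix()].
#' @param gene_set character vector of signature genes; at least one must
#'   be present.
#' @return Named numeric vector of per-sample scores.
#' @export
signature_score <- function(expr, gene_set) {
  stopifnot(inherits(expr, "expr_matrix"))
  present <- intersect(gene_set, rownames(expr$values))
  if (length(present) == 0L)
    stop("no signature gene present in the expression matrix")
  absent <- setdiff(gene_set, present)
  if (length(absent))
    message(length(absent), " signature gene(s) absent from the matrix")
  v <- expr$values[present, , drop = FALSE]
  v <- v - rowMeans(v)
  colMeans(v)
}

#' Kaplan-Meier curves and k-group log-rank test
#'
#' Product-limit survival estimates per group and the k-group log-rank
#' chi-square statistic with `k - 1` degrees of freedom, testing the null
#' of equal hazards across all groups. Fitting is delegated to the survival
#' package ([survival::survfit()] / [survival::survdiff()]); tied event
#' times are handled by the standard aggregated-risk-set formula.
#'
#' @param surv data frame with columns `sample`, `time` (positive), `event`
#'   (1 = death, 0 = censored) and `group`; at least 2 groups and 1 event.
#' @return Object of class `km_logrank`: list with `fit` (a `survfit`
#'   object), `chisq`, `df` and `p`.
#' @export
km_logrank <- function(surv) {
  req <- c("time", "event", "group")
  if (!all(req %in% names(surv)))
    stop("'surv' needs columns: ", paste(req, collapse = ", "))
  if (any(surv$time <= 0)) stop("survival times must be positive")
  if (!all(surv$event %in% c(0, 1))) stop("event must be 0/1")
  if (length(unique(surv$group)) < 2L) stop("need at least 2 groups")
  if (sum(surv$event) < 1L) stop("need at least 1 event")
  surv$group <- factor(surv$group)
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = surv)
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = surv)
  df <- length(sd$n) - 1L
  p <- stats::pchisq(sd$chisq, df = df, lower.tail = FALSE)
  structure(list(fit = fit, chisq = unname(sd$chisq), df = df, p = p),
            class = "km_logrank")
}

#' @export
print.km_logrank <- function(x, ...) {
  cat(sprintf("log-rank chi-square = %.3f on %d df, p = %.4g\n",
              x$chisq, x$df, x$p))
  invisible(x)
}

#' @param x a `km_logrank` object.
#' @param ... passed to `plot.survfit`.
#' @rdname km_logrank
#' @export
plot.km_logrank <- function(x, ...) {
  graphics::plot(x$fit, xlab = "time", ylab = "survival", ...)
  invisible(x)
}

#' Read / write survival tables
#'
#' Tab-delimited columns: sample, time, event, group.
#'
#' @param path file path.
#' @export
read_survival_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' @param surv survival data frame.
#' @rdname read_survival_table
#' @export
write_survival_table <- function(surv, path) {
  utils::write.table(surv, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
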