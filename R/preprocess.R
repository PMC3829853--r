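#' Collapse probe-level measurements to gene level
#'
#' Probes mapping to more than one gene are dropped as unresolvable; when
#' several probes map to the same gene the per-sample median across those
#' probes represents the gene. Medians are taken per sample independently
#' (no pooling across samples); ties among an even number of probes resolve
#' to the arithmetic mean of the two central values, the standard median.
#'
#' @param probe_matrix numeric matrix, probes x samples, with probe rownames
#'   and sample colnames.
#' @param mapping data frame with columns `probe` and `gene`, one row per
#'   probe-gene pair. Probes absent from the mapping are dropped.
#' @param dataset dataset label(s) for the output [expr_matrix()].
#' @return An [expr_matrix()] at gene level.
#' @export
collapse_probes <- function(probe_matrix, mapping, dataset = "dataset1") {
  if (!is.matrix(probe_matrix) || is.null(rownames(probe_matrix)))
    stop("'probe_matrix' must be a matrix with probe rownames")
  if (!all(c("probe", "gene") %in% names(mapping)))
    stop("'mapping' needs columns 'probe' and 'gene'")
  mapping <- unique(mapping[, c("probe", "gene")])
  n_genes_per_probe <- table(mapping$probe)
  multi <- names(n_genes_per_probe)[n_genes_per_probe > 1L]
  mapping <- mapping[!(mapping$probe %in% multi), , drop = FALSE]
  mapping <- mapping[mapping$probe %in% rownames(probe_matrix), , drop = FALSE]
  if (nrow(mapping) == 0L)
    stop("no probes remain after removing multi-gene and unmapped probes")
  genes <- sort(unique(mapping$gene))
  probes_of <- split(mapping$probe, mapping$gene)
  out <- matrix(NA_real_, length(genes), ncol(probe_matrix),
                dimnames = list(genes, colnames(probe_matrix)))
  for (g in genes) {
    sub <- probe_matrix[probes_of[[g]], , drop = FALSE]
    out[g, ] <- if (nrow(sub) == 1L) sub[1L, ] else apply(sub, 2L, stats::median)
  }
  expr_matrix(out, dataset)
}

#' Center each gene within its dataset of origin
#'
#' For every gene, the mean over the samples of each dataset is subtracted
#' from that dataset's measurements, making expression levels comparable
#' across datasets profiled on different platforms or in different batches.
#' The operation is idempotent and leaves each gene with mean zero within
#' every dataset.
#'
#' @param expr an [expr_matrix()].
#' @return An [expr_matrix()] of the same shape, centered per dataset.
#' @export
center_within_dataset <- function(expr) {
  stopifnot(inherits(expr, "expr_matrix"))
  v <- expr$values
  for (d in unique(expr$dataset)) {
    idx <- which(expr$dataset == d)
    v[, idx] <- v[, idx, drop = FALSE] - rowMeans(v[, idx, drop = FALSE])
  }
  expr_matrix(v, expr$dataset)
}

#' Merge multiple cohorts on their common genes
#'
#' Restricts every cohort to the intersection of gene sets and concatenates
#' samples, preserving dataset-of-origin labels. Duplicate sample ids across
#' cohorts are an error.
#'
#' @param cohorts list of [expr_matrix()] objects (at least two).
#' @return A single merged [expr_matrix()].
#' @export
merge_cohorts <- function(cohorts) {
  if (!is.list(cohorts) || length(cohorts) < 2L)
    stop("'cohorts' must be a list of at least two expression matrices")
  stopifnot(all(vapply(cohorts, inherits, logical(1), "expr_matrix")))
  common <- Reduce(intersect, lapply(cohorts, function(x) rownames(x$values)))
  if (length(common) == 0L) stop("no genes common to all cohorts")
  all_samples <- unlist(lapply(cohorts, function(x) colnames(x$values)))
  if (anyDuplicated(all_samples))
    stop("duplicate sample id(s) across cohorts: ",
         paste(utils::head(unique(all_samples[duplicated(all_samples)]), 5),
               collapse = ", "))
  v <- do.call(cbind, lapply(cohorts, function(x)
    x$values[common, , drop = FALSE]))
  ds <- unlist(lapply(cohorts, function(x) x$dataset))
  expr_matrix(v, ds)
}

#' Center each gene on its mean over a set of reference samples
#'
#' Used to express tumor profiles relative to normal tissue: each gene's mean
#' over the reference (e.g. normal mucosa) samples is subtracted from all of
#' its measurements, so reference samples end up with mean zero.
#'
#' @param expr an [expr_matrix()].
#' @param reference_samples character vector of sample ids to use as the
#'   reference; must be a nonempty subset of the samples.
#' @return An [expr_matrix()] centered to the reference.
#' @export
center_to_reference <- function(expr, reference_samples) {
  stopifnot(inherits(expr, "expr_matrix"))
  if (length(reference_samples) == 0L) stop("empty reference sample set")
  missing <- setdiff(reference_samples, colnames(expr$values))
  if (length(missing))
    stop("unknown reference sample(s): ",
         paste(utils::head(missing, 5), collapse = ", "))
  ref_mean <- rowMeans(expr$values[, reference_samples, drop = FALSE])
  expr_matrix(expr$values - ref_mean, expr$dataset)
}
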