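#' Expression matrix with dataset-of-origin labels
#'
#' The central carrier of the pipeline: a genes x samples numeric matrix
#' (log2 scale) plus, for every sample, the label of the dataset it came
#' from. Cross-dataset normalization, module discovery, subtyping and
#' classification all operate on this container.
#'
#' Missing values are rejected outright: the arrays this pipeline targets are
#' complete after upstream summarization, and silent imputation would distort
#' the gene-gene correlations that module discovery depends on.
#'
#' @param values numeric matrix, genes in rows (unique rownames), samples in
#'   columns (unique colnames); no `NA`/`NaN` allowed.
#' @param dataset character vector of dataset labels, either named by sample
#'   id or in column order; recycled to length 1 if a single label is given.
#' @return An object of class `expr_matrix`: a list with elements `values`
#'   (the matrix) and `dataset` (named character vector, one label per
#'   sample).
#' @examples
#' m <- matrix(rnorm(12), 3, 4,
#'             dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' em <- expr_matrix(m, dataset = c("A", "A", "B", "B"))
#' em
#' @export
expr_matrix <- function(values, dataset) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must have gene rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene identifiers in 'values'")
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample identifiers in 'values'")
  if (anyNA(values))
    stop("missing values are not allowed in an expression matrix")
  ns <- ncol(values)
  if (length(dataset) == 1L) dataset <- rep(dataset, ns)
  if (!is.null(names(dataset))) {
    if (!setequal(names(dataset), colnames(values)))
      stop("names of 'dataset' do not match sample ids")
    dataset <- dataset[colnames(values)]
  } else {
    if (length(dataset) != ns)
      stop("'dataset' must have one label per sample")
    names(dataset) <- colnames(values)
  }
  structure(list(values = values, dataset = as.character(dataset)),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d genes x %d samples, %d dataset(s) [%s]\n",
              nrow(x$values), ncol(x$values),
              length(unique(x$dataset)),
              paste(utils::head(unique(x$dataset), 5), collapse = ", ")))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Subset an expression matrix by genes and/or samples
#'
#' @param x an `expr_matrix`.
#' @param genes,samples character vectors of identifiers to keep (default:
#'   all). Unknown identifiers are an error.
#' @return An `expr_matrix` restricted to the requested genes and samples.
#' @export
subset_expr <- function(x, genes = NULL, samples = NULL) {
  stopifnot(inherits(x, "expr_matrix"))
  v <- x$values
  if (!is.null(genes)) {
    missing <- setdiff(genes, rownames(v))
    if (length(missing))
      stop("unknown gene(s): ", paste(utils::head(missing, 5), collapse = ", "))
    v <- v[genes, , drop = FALSE]
  }
  if (!is.null(samples)) {
    missing <- setdiff(samples, colnames(v))
    if (length(missing))
      stop("unknown sample(s): ", paste(utils::head(missing, 5), collapse = ", "))
    v <- v[, samples, drop = FALSE]
  }
  expr_matrix(v, x$dataset[colnames(v)])
}

#' Read / write tab-delimited expression matrices
#'
#' The on-disk format is the field's plain-text convention: a header row of
#' sample ids, first column gene ids, tab separated. The sample annotation
#' sidecar is a two-column table (sample, dataset).
#'
#' @param path file path of the matrix.
#' @param annotation_path path of the sample-annotation table; if `NULL` on
#'   read, all samples get dataset label `"dataset1"`.
#' @return `read_expr_matrix` returns an `expr_matrix`;
#'   `write_expr_matrix` invisibly returns `path`.
#' @export
read_expr_matrix <- function(path, annotation_path = NULL) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  genes <- as.character(tab[[1L]])
  m <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- genes
  if (anyNA(m)) stop("missing values in expression file: ", path)
  if (!is.null(annotation_path)) {
    ann <- utils::read.delim(annotation_path, stringsAsFactors = FALSE)
    ds <- stats::setNames(as.character(ann[[2L]]), as.character(ann[[1L]]))
  } else {
    ds <- stats::setNames(rep("dataset1", ncol(m)), colnames(m))
  }
  expr_matrix(m, ds)
}

#' @param x an `expr_matrix` to write.
#' @rdname read_expr_matrix
#' @export
write_expr_matrix <- function(x, path, annotation_path = NULL) {
  stopifnot(inherits(x, "expr_matrix"))
  tab <- data.frame(gene = rownames(x$values), x$values,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(annotation_path)) {
    ann <- data.frame(sample = colnames(x$values), dataset = x$dataset,
                      stringsAsFactors = FALSE)
    utils::write.table(ann, annotation_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
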