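#' Rooted ontology DAG
#'
#' A minimal container for a rooted directed acyclic graph of terms, as used
#' for information-content based semantic similarity. Edges point child ->
#' parent (`is_a`).
#'
#' @param parents named list: for each non-root term, the character vector of
#'   its parent term ids. Terms that appear only as parents are allowed; the
#'   root is the unique term with no parents.
#' @return An object of class `ontology`: list with `terms` (character),
#'   `parents` (named list) and `ancestors` (named list of ancestor sets,
#'   each including the term itself).
#' @export
ontology <- function(parents) {
  terms <- union(names(parents), unlist(parents, use.names = FALSE))
  terms <- sort(unique(terms))
  parents <- parents[intersect(names(parents), terms)]
  roots <- setdiff(terms, names(parents))
  roots <- union(roots, names(parents)[lengths(parents) == 0L])
  if (length(roots) != 1L)
    stop("ontology must have exactly one root, found: ",
         paste(roots, collapse = ", "))
  anc <- vector("list", length(terms))
  names(anc) <- terms
  get_anc <- function(t, seen = character()) {
    if (!is.null(anc[[t]])) return(anc[[t]])
    if (t %in% seen) stop("cycle detected at term ", t)
    ps <- parents[[t]]
    res <- t
    for (p in ps) res <- union(res, get_anc(p, c(seen, t)))
    anc[[t]] <<- res
    res
  }
  for (t in terms) get_anc(t)
  structure(list(terms = terms, parents = parents, root = roots,
                 ancestors = anc),
            class = "ontology")
}

#' @export
print.ontology <- function(x, ...) {
  cat(sprintf("ontology: %d terms, root '%s'\n", length(x$terms), x$root))
  invisible(x)
}

#' Ancestor-closed annotation sets
#'
#' Propagates direct gene annotations up the DAG: a gene annotated to a term
#' is implicitly annotated to every ancestor of that term. All downstream
#' information-content computations operate on these closed sets.
#'
#' @param ont an [ontology()].
#' @param annotations named list, gene -> character vector of directly
#'   annotated term ids.
#' @return Named list, gene -> ancestor-closed term set.
#' @export
annotation_closure <- function(ont, annotations) {
  stopifnot(inherits(ont, "ontology"))
  unknown <- setdiff(unlist(annotations, use.names = FALSE), ont$terms)
  if (length(unknown))
    stop("annotation to unknown term(s): ",
         paste(utils::head(unknown, 5), collapse = ", "))
  lapply(annotations, function(ts)
    unique(unlist(ont$ancestors[ts], use.names = FALSE)))
}

#' Information content of ontology terms
#'
#' IC(t) = -ln(fraction of annotated genes annotated to t or any of its
#' descendants). With ancestor-closed annotation sets this fraction is simply
#' the share of genes whose closed set contains t. The root is implied for
#' every annotated gene, so IC(root) = 0.
#'
#' @param ont an [ontology()].
#' @param annotations named list, gene -> direct term ids.
#' @return Named numeric vector of IC values over all terms that annotate at
#'   least one gene (terms annotating none are omitted: their IC is
#'   undefined).
#' @export
information_content <- function(ont, annotations) {
  closed <- annotation_closure(ont, annotations)
  n <- length(closed)
  if (n == 0L) stop("no annotated genes")
  counts <- table(unlist(closed, use.names = FALSE))
  ic <- -log(as.numeric(counts) / n)
  names(ic) <- names(counts)
  ic
}

#' Resnik semantic similarity between two genes
#'
#' The gene-level Resnik similarity is the maximum, over all pairs of terms
#' annotating the two genes, of the information content of the pair's most
#' informative common ancestor. Because annotation sets are ancestor-closed,
#' this equals the maximum IC over the intersection of the two genes' closed
#' term sets. Genes sharing only the root score 0; an unannotated gene is an
#' error (distinguishable from a true similarity of 0).
#'
#' @param geneA,geneB gene identifiers.
#' @param ont an [ontology()].
#' @param annotations named list gene -> direct term ids.
#' @param index optional precomputed [resnik_index()]; supply it when scoring
#'   many pairs.
#' @return Nonnegative similarity score.
#' @seealso [resnik_matrix()] for all-pairs computation.
#' @export
resnik_similarity <- function(geneA, geneB, ont = NULL, annotations = NULL,
                              index = NULL) {
  if (is.null(index)) index <- resnik_index(ont, annotations)
  for (g in c(geneA, geneB))
    if (is.null(index$closed[[g]]) || length(index$closed[[g]]) == 0L)
      stop("gene '", g, "' has no ontology annotations")
  shared <- intersect(index$closed[[geneA]], index$closed[[geneB]])
  if (length(shared) == 0L) return(0)
  max(index$ic[shared], na.rm = TRUE)
}

#' Precomputed index for repeated Resnik queries
#'
#' @inheritParams resnik_similarity
#' @return List with `closed` annotation sets and `ic` vector.
#' @export
resnik_index <- function(ont, annotations) {
  structure(list(closed = annotation_closure(ont, annotations),
                 ic = information_content(ont, annotations)),
            class = "resnik_index")
}

#' All-pairs Resnik similarity matrix
#'
#' Computes the full symmetric gene x gene Resnik similarity matrix by
#' sweeping terms in decreasing information content: the first term found
#' shared by a pair is its most informative common ancestor.
#'
#' @param genes character vector of genes to score (all must be annotated).
#' @inheritParams resnik_similarity
#' @return Symmetric numeric matrix with `genes` as dimnames.
#' @export
resnik_matrix <- function(genes, ont = NULL, annotations = NULL, index = NULL) {
  if (is.null(index)) index <- resnik_index(ont, annotations)
  missing <- genes[vapply(genes, function(g)
    is.null(index$closed[[g]]) || length(index$closed[[g]]) == 0L, logical(1))]
  if (length(missing))
    stop("unannotated gene(s): ", paste(utils::head(missing, 5), collapse = ", "))
  n <- length(genes)
  S <- matrix(NA_real_, n, n, dimnames = list(genes, genes))
  ord <- order(index$ic, decreasing = TRUE)
  terms <- names(index$ic)[ord]
  ics <- unname(index$ic[ord])
  has_term <- function(t) vapply(index$closed[genes], function(cl) t %in% cl,
                                 logical(1))
  for (k in seq_along(terms)) {
    idx <- which(has_term(terms[[k]]))
    if (length(idx) < 1L) next
    block <- S[idx, idx, drop = FALSE]
    block[is.na(block)] <- ics[[k]]
    S[idx, idx] <- block
    if (!anyNA(S)) break
  }
  S[is.na(S)] <- 0
  S
}

#' Write / read a minimal OBO file
#'
#' Writes the `[Term]` stanza dialect with `id`, `name` and `is_a` lines;
#' `read_obo` parses exactly that dialect back into an [ontology()].
#'
#' @param ont an [ontology()].
#' @param path file path.
#' @return `write_obo` invisibly returns `path`; `read_obo` returns an
#'   [ontology()].
#' @export
write_obo <- function(ont, path) {
  stopifnot(inherits(ont, "ontology"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("format-version: 1.2", con)
  for (t in ont$terms) {
    writeLines(c("", "[Term]", paste0("id: ", t), paste0("name: ", t)), con)
    for (p in ont$parents[[t]])
      writeLines(paste0("is_a: ", p), con)
  }
  invisible(path)
}

#' @rdname write_obo
#' @export
read_obo <- function(path) {
  lines <- readLines(path)
  parents <- list()
  cur <- NULL
  for (ln in lines) {
    if (ln == "[Term]") { cur <- NULL; next }
    if (startsWith(ln, "id: ")) {
      cur <- sub("^id: ", "", ln)
      if (is.null(parents[[cur]])) parents[[cur]] <- character()
    } else if (startsWith(ln, "is_a: ") && !is.null(cur)) {
      parents[[cur]] <- c(parents[[cur]], sub("^is_a: ", "", ln))
    }
  }
  ontology(parents)
}

#' Write / read gene-to-term annotations
#'
#' Two-column tab-delimited table (gene, term), one row per direct
#' annotation.
#'
#' @param annotations named list gene -> term ids.
#' @param path file path.
#' @export
write_annotations <- function(annotations, path) {
  tab <- data.frame(
    gene = rep(names(annotations), lengths(annotations)),
    term = unlist(annotations, use.names = FALSE),
    stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_annotations
#' @export
read_annotations <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  split(as.character(tab[[2L]]), as.character(tab[[1L]]))
}
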