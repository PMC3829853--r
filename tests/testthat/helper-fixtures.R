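# Small fixtures built in code; everything is deterministic under set.seed.

# genes x samples expr_matrix of iid normals
random_expr <- function(n_genes = 10, n_samples = 8, seed = 1,
                        dataset = "d1") {
  set.seed(seed)
  m <- matrix(rnorm(n_genes * n_samples), n_genes, n_samples,
              dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                              sprintf("s%03d", seq_len(n_samples))))
  expr_matrix(m, dataset)
}

# two well-separated sample groups in gene space: group A is shifted up on
# the first half of the genes, group B on the second half
separated_expr <- function(n_per_group = 10, n_genes = 20, shift = 6,
                           seed = 1) {
  set.seed(seed)
  m <- matrix(rnorm(n_genes * 2 * n_per_group), n_genes)
  half <- seq_len(n_genes %/% 2)
  ga <- seq_len(n_per_group)
  m[half, ga] <- m[half, ga] + shift
  m[-half, -ga] <- m[-half, -ga] + shift
  dimnames(m) <- list(sprintf("g%03d", seq_len(n_genes)),
                      sprintf("s%03d", seq_len(2 * n_per_group)))
  list(expr = expr_matrix(m, "d1"),
       group = rep(c("A", "B"), each = n_per_group))
}

# five-term toy DAG:  root -> a, b;  a -> c;  a,b -> d
toy_ontology <- function() {
  ontology(list(root = character(), a = "root", b = "root",
                c = "a", d = c("a", "b")))
}

toy_annotations <- function() {
  list(g1 = "c", g2 = "c", g3 = "d", g4 = "b", g5 = "root")
}

# brute-force gene-pair Resnik: enumerate all direct-term pairs, all common
# ancestors of each pair, take max IC; independent of annotation closure.
brute_resnik <- function(geneA, geneB, ont, annotations) {
  n <- length(annotations)
  closed <- lapply(annotations, function(ts)
    unique(unlist(ont$ancestors[ts])))
  ic_of <- function(t) {
    cnt <- sum(vapply(closed, function(cl) t %in% cl, logical(1)))
    -log(cnt / n)
  }
  best <- -Inf
  for (ta in annotations[[geneA]]) for (tb in annotations[[geneB]]) {
    common <- intersect(ont$ancestors[[ta]], ont$ancestors[[tb]])
    for (t in common) best <- max(best, ic_of(t))
  }
  if (is.infinite(best)) 0 else best
}

# brute-force silhouette from a distance matrix and labels
brute_silhouette <- function(D, labels) {
  n <- length(labels)
  vapply(seq_len(n), function(i) {
    own <- labels[i]
    idx_own <- setdiff(which(labels == own), i)
    if (!length(idx_own)) return(0)
    a <- mean(D[i, idx_own])
    b <- min(vapply(setdiff(unique(labels), own), function(g)
      mean(D[i, labels == g]), numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
}

# plain nearest-centroid classifier with pooled-SD standardization,
# written independently of the package's shrunken-centroid code path
brute_nearest_centroid <- function(train, labels, test, priors) {
  classes <- sort(unique(labels))
  n <- length(labels)
  overall <- rowMeans(train)
  cent <- sapply(classes, function(k)
    rowMeans(train[, labels == k, drop = FALSE]))
  ss <- 0
  for (k in classes) {
    tk <- train[, labels == k, drop = FALSE]
    ss <- ss + rowSums((tk - rowMeans(tk))^2)
  }
  s <- sqrt(ss / (n - length(classes)))
  s0 <- median(s)
  disc <- sapply(seq_along(classes), function(ki)
    colSums((test - cent[, classes[ki]])^2 / (s + s0)^2) -
      2 * log(priors[ki]))
  classes[apply(matrix(disc, ncol = length(classes)), 1, which.min)]
}

# log-rank chi-square by direct observed-minus-expected tabulation over
# event times (2 groups), the textbook formula
brute_logrank <- function(time, event, group) {
  groups <- sort(unique(group))
  stopifnot(length(groups) == 2)
  taus <- sort(unique(time[event == 1]))
  O <- 0; E <- 0; V <- 0
  for (tau in taus) {
    at_risk <- time >= tau
    d <- sum(event == 1 & time == tau)
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == groups[1])
    d1 <- sum(event == 1 & time == tau & group == groups[1])
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1)
      V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O - E)^2 / V
}

# expand a counts matrix into two paired sample->label vectors
expand_counts <- function(counts) {
  a <- character(0); b <- character(0)
  for (r in rownames(counts)) for (cl in colnames(counts)) {
    a <- c(a, rep(r, counts[r, cl]))
    b <- c(b, rep(cl, counts[r, cl]))
  }
  ids <- sprintf("s%04d", seq_along(a))
  list(a = setNames(a, ids), b = setNames(b, ids))
}
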