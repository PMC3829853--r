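#' Train a nearest shrunken centroid (PAM) classifier
#'
#' Computes, per gene `i` and class `k`, the standardized centroid difference
#' `d_ik = (xbar_ik - xbar_i) / (m_k * (s_i + s0))` with
#' `m_k = sqrt(1/n_k - 1/n)`, `s_i` the pooled within-class standard
#' deviation and `s0` the median of the `s_i` (the fudge factor guarding
#' against near-zero variances). At shrinkage `delta` the differences are
#' soft-thresholded, `d'_ik = sign(d_ik) * max(|d_ik| - delta, 0)`; genes
#' with `d'_ik = 0` for every class drop out of the classifier. Class priors
#' default to the empirical class frequencies.
#'
#' @param expr an [expr_matrix()].
#' @param labels class label per sample (named by sample or column-ordered);
#'   at least 2 classes, each with at least 2 samples.
#' @param delta_grid nonnegative shrinkage values the fit should support.
#' @return Object of class `nsc_fit` holding the centroids, pooled SDs,
#'   `s0`, priors, `m_k`, the unshrunken `d` matrix and `delta_grid`.
#' @seealso [predict.nsc_fit()], [active_genes()], [cv_error_curve()].
#' @export
train_nsc <- function(expr, labels, delta_grid = 0) {
  stopifnot(inherits(expr, "expr_matrix"))
  if (any(delta_grid < 0)) stop("shrinkage values must be nonnegative")
  v <- expr$values
  samples <- colnames(v)
  if (!is.null(names(labels))) labels <- labels[samples]
  if (length(labels) != length(samples)) stop("one label per sample required")
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  n_k <- table(factor(labels, classes))
  if (length(classes) < 2L) stop("need at least 2 classes")
  if (any(n_k < 2L)) stop("every class needs at least 2 samples")
  n <- length(labels)
  overall <- rowMeans(v)
  centroids <- vapply(classes, function(k)
    rowMeans(v[, labels == k, drop = FALSE]), numeric(nrow(v)))
  ss_within <- vapply(classes, function(k) {
    vk <- v[, labels == k, drop = FALSE]
    rowSums((vk - rowMeans(vk))^2)
  }, numeric(nrow(v)))
  s <- sqrt(rowSums(ss_within) / (n - length(classes)))
  if (all(s == 0)) stop("zero pooled within-class SD for every gene")
  s0 <- stats::median(s)
  m_k <- sqrt(1 / as.numeric(n_k) - 1 / n)
  names(m_k) <- classes
  d <- sweep(centroids - overall, 2L, m_k, "/") / (s + s0)
  priors <- as.numeric(n_k) / n
  names(priors) <- classes
  structure(list(genes = rownames(v), classes = classes,
                 overall = overall, centroids = centroids,
                 s = s, s0 = s0, m_k = m_k, d = d, priors = priors,
                 delta_grid = sort(unique(delta_grid))),
            class = "nsc_fit")
}

#' @export
print.nsc_fit <- function(x, ...) {
  cat(sprintf("nsc_fit: %d genes, %d classes (%s), s0 = %.4g\n",
              length(x$genes), length(x$classes),
              paste(x$classes, collapse = ", "), x$s0))
  for (d in x$delta_grid)
    cat(sprintf("  delta = %g: %d active gene(s)\n", d,
                length(active_genes(x, d))))
  invisible(x)
}

#' Soft-thresholded centroid differences at a given shrinkage
#'
#' @param fit an `nsc_fit`.
#' @param delta nonnegative shrinkage.
#' @return Matrix of `d'_ik` values (genes x classes).
#' @export
shrunken_d <- function(fit, delta) {
  stopifnot(inherits(fit, "nsc_fit"), delta >= 0)
  sign(fit$d) * pmax(abs(fit$d) - delta, 0)
}

#' Genes surviving shrinkage
#'
#' @inheritParams shrunken_d
#' @return Character vector of genes with a nonzero shrunken difference in
#'   at least one class.
#' @export
active_genes <- function(fit, delta) {
  dp <- shrunken_d(fit, delta)
  fit$genes[rowSums(abs(dp) > 0) > 0]
}

#' Predict subtype labels and posteriors
#'
#' Uses the discriminant
#' `delta_k(x) = sum_i (x_i - xbar'_ik)^2 / (s_i + s0)^2 - 2 ln(prior_k)`,
#' where `xbar'_ik = xbar_i + m_k (s_i + s0) d'_ik` is the shrunken class
#' centroid; the predicted class minimizes the discriminant and posteriors
#' are the softmax of `-delta_k / 2`. With every gene shrunk away the
#' posteriors reduce to the class priors.
#'
#' @param object an `nsc_fit`.
#' @param expr an [expr_matrix()] containing (at least) the model's genes.
#' @param delta shrinkage at which to predict (default: smallest in the
#'   fit's grid).
#' @param ... unused.
#' @return Data frame with `sample`, `label` and one posterior column per
#'   class.
#' @export
predict.nsc_fit <- function(object, expr, delta = object$delta_grid[1L],
                            ...) {
  stopifnot(inherits(expr, "expr_matrix"))
  missing <- setdiff(object$genes, rownames(expr$values))
  if (length(missing))
    stop("model gene(s) missing from expression matrix: ",
         paste(utils::head(missing, 5), collapse = ", "))
  v <- expr$values[object$genes, , drop = FALSE]
  dp <- shrunken_d(object, delta)
  sc <- object$overall +
    sweep(dp, 2L, object$m_k, "*") * (object$s + object$s0)
  w <- 1 / (object$s + object$s0)^2
  disc <- vapply(seq_along(object$classes), function(k) {
    colSums((v - sc[, k])^2 * w) - 2 * log(object$priors[k])
  }, numeric(ncol(v)))
  disc <- matrix(disc, ncol = length(object$classes),
                 dimnames = list(colnames(v), object$classes))
  logp <- -disc / 2
  logp <- logp - apply(logp, 1L, max)
  post <- exp(logp) / rowSums(exp(logp))
  out <- data.frame(sample = colnames(v),
                    label = object$classes[apply(disc, 1L, which.min)],
                    stringsAsFactors = FALSE)
  cbind(out, as.data.frame(post))
}

#' Repeated stratified cross-validation error curve
#'
#' Runs `folds`-fold stratified cross-validation `repeats` times and reports
#' the mean misclassification rate at each shrinkage value, the standard
#' device for choosing how far to shrink the classifier.
#'
#' @inheritParams train_nsc
#' @param folds number of folds (default 10); every class must have at least
#'   this many samples.
#' @param repeats number of repetitions (default 100).
#' @param seed integer seed.
#' @return Data frame with columns `delta`, `mean_error`, and `n_active`
#'   (active genes at that shrinkage in the full-data fit).
#' @export
cv_error_curve <- function(expr, labels, delta_grid = 0, folds = 10,
                           repeats = 100, seed = 1L) {
  stopifnot(inherits(expr, "expr_matrix"))
  samples <- colnames(expr$values)
  if (!is.null(names(labels))) labels <- labels[samples]
  labels <- as.character(labels)
  n_k <- table(labels)
  if (any(n_k < folds))
    stop("every class needs at least ", folds, " samples for ", folds,
         "-fold stratified CV")
  delta_grid <- sort(unique(delta_grid))
  set.seed(seed)
  err <- matrix(0, repeats, length(delta_grid))
  for (rep_i in seq_len(repeats)) {
    fold_of <- integer(length(labels))
    for (k in names(n_k)) {
      idx <- sample(which(labels == k))
      fold_of[idx] <- rep_len(seq_len(folds), length(idx))
    }
    wrong <- numeric(length(delta_grid))
    for (f in seq_len(folds)) {
      test_idx <- which(fold_of == f)
      train <- subset_expr(expr, samples = samples[-test_idx])
      test <- subset_expr(expr, samples = samples[test_idx])
      fit <- train_nsc(train, labels[-test_idx], delta_grid)
      for (j in seq_along(delta_grid)) {
        pred <- predict(fit, test, delta = delta_grid[j])
        wrong[j] <- wrong[j] + sum(pred$label != labels[test_idx])
      }
    }
    err[rep_i, ] <- wrong / length(labels)
  }
  full <- train_nsc(expr, labels, delta_grid)
  data.frame(delta = delta_grid,
             mean_error = colMeans(err),
             n_active = vapply(delta_grid, function(d)
               length(active_genes(full, d)), integer(1)))
}

#' Assign classifier genes to subtype signatures
#'
#' Stage 1: a gene is "up in subtype k" iff a one-tailed two-sample Student
#' t-test (pooled variance) gives p below `alpha` for k against each other
#' subtype separately (the strict reading of "compared to all other
#' subtypes"; `mode = "pooled"` compares k against all other samples pooled
#' in a single test instead). Stage 2 applies the mirrored rule to the
#' remaining genes for down-regulation. Genes failing both stages stay
#' unassigned. Raw p-values are used deliberately - no multiple-testing
#' correction is applied at this step.
#'
#' @param expr an [expr_matrix()] restricted to the classifier genes.
#' @param labels subtype label per sample; every subtype needs >= 2 samples.
#' @param alpha per-test significance level (default 0.05).
#' @param mode `"each"` (test against every other subtype separately) or
#'   `"pooled"` (one test against all other samples).
#' @return Object of class `signature_set`: list with `up` and `down` (named
#'   lists of gene vectors per subtype) and `unassigned`.
#' @export
assign_signatures <- function(expr, labels, alpha = 0.05,
                              mode = c("each", "pooled")) {
  stopifnot(inherits(expr, "expr_matrix"))
  mode <- match.arg(mode)
  v <- expr$values
  samples <- colnames(v)
  if (!is.null(names(labels))) labels <- labels[samples]
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) < 2L) stop("need at least 2 subtypes")
  if (any(table(labels) < 2L)) stop("every subtype needs at least 2 samples")

  # one-tailed pooled-variance t-test p-values, vectorized over genes:
  # p for H1 "mean(group1) > mean(group2)"
  t_p_greater <- function(idx1, idx2) {
    x1 <- v[, idx1, drop = FALSE]; x2 <- v[, idx2, drop = FALSE]
    n1 <- length(idx1); n2 <- length(idx2)
    m1 <- rowMeans(x1); m2 <- rowMeans(x2)
    ss1 <- rowSums((x1 - m1)^2); ss2 <- rowSums((x2 - m2)^2)
    sp2 <- (ss1 + ss2) / (n1 + n2 - 2)
    tstat <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
    stats::pt(tstat, df = n1 + n2 - 2, lower.tail = FALSE)
  }
  up_in <- function(k, pool) {
    idx_k <- which(labels == k)
    if (mode == "pooled") {
      t_p_greater(idx_k, which(labels != k)) < alpha
    } else {
      others <- setdiff(classes, k)
      Reduce(`&`, lapply(others, function(o)
        t_p_greater(idx_k, which(labels == o)) < alpha))
    }
  }
  down_in <- function(k) {
    idx_k <- which(labels == k)
    if (mode == "pooled") {
      t_p_greater(which(labels != k), idx_k) < alpha
    } else {
      others <- setdiff(classes, k)
      Reduce(`&`, lapply(others, function(o)
        t_p_greater(which(labels == o), idx_k) < alpha))
    }
  }
  genes <- rownames(v)
  up <- stats::setNames(vector("list", length(classes)), classes)
  for (k in classes) up[[k]] <- genes[up_in(k)]
  assigned <- unique(unlist(up))
  down <- stats::setNames(vector("list", length(classes)), classes)
  for (k in classes) {
    dn <- genes[down_in(k)]
    down[[k]] <- setdiff(dn, assigned)
    assigned <- union(assigned, down[[k]])
  }
  structure(list(up = up, down = down,
                 unassigned = setdiff(genes, assigned)),
            class = "signature_set")
}

#' @export
print.signature_set <- function(x, ...) {
  for (k in names(x$up))
    cat(sprintf("%s: %d signature gene(s) (%d up, %d down)\n", k,
                length(x$up[[k]]) + length(x$down[[k]]),
                length(x$up[[k]]), length(x$down[[k]])))
  cat(length(x$unassigned), "unassigned gene(s)\n")
  invisible(x)
}

#' Write signatures as GMT with _UP/_DN set names
#'
#' @param sig a [assign_signatures()] result.
#' @param path file path.
#' @export
write_signatures <- function(sig, path) {
  sets <- c(stats::setNames(sig$up, paste0(names(sig$up), "_UP")),
            stats::setNames(sig$down, paste0(names(sig$down), "_DN")))
  write_gmt(sets[lengths(sets) > 0], path)
}

#' Permutation test of signature functional coherence
#'
#' The observed statistic is the mean pairwise Resnik similarity over the
#' signature genes; the null distribution is the same statistic on random
#' same-size draws from the background gene set. The add-one estimator keeps
#' p in `(0, 1]`.
#'
#' @param signature gene set to test (subset of `background`, >= 2 genes).
#' @param background gene universe to draw null sets from.
#' @param ont an [ontology()].
#' @param annotations named list gene -> direct term ids.
#' @param n_perm number of random draws (default 1000, must be >= 1).
#' @param seed integer seed.
#' @param sim optional precomputed similarity matrix over the background
#'   (see [resnik_matrix()]); avoids recomputation across repeated tests.
#' @return List with `p`, `observed` and the vector of null statistics.
#' @export
coherence_test <- function(signature, background, ont, annotations,
                           n_perm = 1000, seed = 1L, sim = NULL) {
  if (n_perm < 1L) stop("n_perm must be at least 1")
  if (length(signature) < 2L) stop("signature needs at least 2 genes")
  if (!all(signature %in% background))
    stop("signature must be a subset of background")
  if (length(background) < length(signature))
    stop("background smaller than signature")
  S <- if (is.null(sim)) resnik_matrix(background, ont, annotations)
       else sim[background, background]
  mean_pairwise <- function(gs) {
    sub <- S[gs, gs, drop = FALSE]
    mean(sub[upper.tri(sub)])
  }
  observed <- mean_pairwise(signature)
  set.seed(seed)
  null <- vapply(seq_len(n_perm), function(i)
    mean_pairwise(sample(background, length(signature))), numeric(1))
  p <- (1 + sum(null >= observed)) / (1 + n_perm)
  list(p = p, observed = observed, null = null)
}
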