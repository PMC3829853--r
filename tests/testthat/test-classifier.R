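test_that("unshrunken NSC equals an independent nearest-centroid classifier", {
  for (i in 1:5) {
    set.seed(800 + i)
    n <- sample(12:40, 1)
    em <- random_expr(10, n, seed = 900 + i)
    labels <- sample(c("A", "B", "C"), n, replace = TRUE)
    while (min(table(labels)) < 2)
      labels <- sample(c("A", "B", "C"), n, replace = TRUE)
    fit <- train_nsc(em, labels, delta_grid = 0)
    pred <- predict(fit, em, delta = 0)
    priors <- table(labels)[sort(unique(labels))] / n
    brute <- brute_nearest_centroid(em$values, labels, em$values,
                                    as.numeric(priors))
    expect_identical(pred$label, brute)
  }
})

test_that("shrunken differences match hand arithmetic on a 2x2 toy", {
  # 2 genes, 2 classes, 3 samples each; work the formulas by hand
  m <- rbind(g1 = c(1, 2, 3, 7, 8, 9),
             g2 = c(5, 5, 5, 5, 5, 5.3))
  colnames(m) <- paste0("s", 1:6)
  em <- expr_matrix(m, "d1")
  labels <- rep(c("A", "B"), each = 3)
  fit <- train_nsc(em, labels, delta_grid = c(0, 1))
  n <- 6; nk <- 3
  mk <- sqrt(1 / nk - 1 / n)
  s1 <- sqrt((sum((c(1, 2, 3) - 2)^2) + sum((c(7, 8, 9) - 8)^2)) / (n - 2))
  d11 <- (2 - 5) / (mk * (s1 + fit$s0))
  expect_equal(fit$d["g1", "A"], d11)
  expect_equal(shrunken_d(fit, 1)["g1", "A"],
               sign(d11) * max(abs(d11) - 1, 0))
  # delta = 0 keeps every gene; huge delta removes all of them
  expect_setequal(active_genes(fit, 0), c("g1", "g2"))
  expect_length(active_genes(fit, max(abs(fit$d)) + 1), 0)
})

test_that("with every gene shrunk away posteriors fall back to class priors", {
  sep <- separated_expr(12, 10, shift = 4, seed = 61)
  fit <- train_nsc(sep$expr, sep$group, delta_grid = 0)
  big <- max(abs(fit$d)) + 1
  pred <- predict(fit, sep$expr, delta = big)
  expect_equal(unname(as.matrix(pred[, c("A", "B")])[1, ]),
               unname(fit$priors), tolerance = 1e-9)
})

test_that("active-gene count is non-increasing in the shrinkage", {
  em <- random_expr(30, 24, seed = 62)
  labels <- rep(c("A", "B", "C"), each = 8)
  fit <- train_nsc(em, labels)
  grid <- seq(0, 3, by = 0.1)
  counts <- vapply(grid, function(d) length(active_genes(fit, d)), integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("prediction recovers centroids, normalizes posteriors, checks genes", {
  sep <- separated_expr(10, 12, shift = 5, seed = 63)
  fit <- train_nsc(sep$expr, sep$group, delta_grid = 0)
  pred <- predict(fit, sep$expr)
  expect_true(all(pred$label == sep$group))
  expect_equal(unname(rowSums(as.matrix(pred[, c("A", "B")]))),
               rep(1, 20), tolerance = 1e-9)
  # a sample placed exactly on a shrunken class centroid gets that class
  sc <- fit$overall + fit$m_k["A"] * (fit$s + fit$s0) * shrunken_d(fit, 0)[, "A"]
  em1 <- expr_matrix(matrix(sc, ncol = 1,
                            dimnames = list(fit$genes, "probe")), "d1")
  expect_equal(predict(fit, em1)$label, "A")
  small <- subset_expr(sep$expr, genes = fit$genes[-1])
  expect_error(predict(fit, small), "missing")
})

test_that("cross-validation is deterministic and nails separable data", {
  sep <- separated_expr(12, 10, shift = 6, seed = 64)
  cv1 <- cv_error_curve(sep$expr, sep$group, delta_grid = 0, folds = 4,
                        repeats = 3, seed = 7)
  cv2 <- cv_error_curve(sep$expr, sep$group, delta_grid = 0, folds = 4,
                        repeats = 3, seed = 7)
  expect_identical(cv1, cv2)
  expect_equal(cv1$mean_error, 0)
  expect_error(cv_error_curve(sep$expr, sep$group, folds = 13),
               "at least 13")
})

test_that("signature assignment finds planted directions and partitions genes", {
  set.seed(65)
  n_per <- 20
  labels <- rep(c("s1", "s2", "s3"), each = n_per)
  m <- matrix(rnorm(5 * 60, sd = 0.1), 5, 60,
              dimnames = list(paste0("g", 1:5), paste0("x", 1:60)))
  m["g1", labels == "s1"] <- m["g1", labels == "s1"] + 3   # up in s1
  m["g2", labels == "s2"] <- m["g2", labels == "s2"] - 3   # down in s2
  m["g4", labels != "s3"] <- m["g4", labels != "s3"] + 3   # up in s1 AND s2
  # g3 identically distributed; g5 too
  em <- expr_matrix(m, "d1")
  sig <- assign_signatures(em, labels)
  expect_true("g1" %in% sig$up$s1)
  expect_true("g2" %in% sig$down$s2)
  expect_true("g3" %in% sig$unassigned)
  # up in two subtypes equally fails "vs each other subtype", but the same
  # gene is detected as DOWN in the remaining subtype by stage 2
  expect_false("g4" %in% c(sig$up$s1, sig$up$s2))
  expect_true("g4" %in% sig$down$s3)
  all_assigned <- c(unlist(sig$up), unlist(sig$down), sig$unassigned)
  expect_setequal(all_assigned, rownames(m))
  expect_equal(anyDuplicated(all_assigned), 0L)
})

test_that("signature assignment matches t.test p-values", {
  em <- random_expr(6, 30, seed = 66)
  labels <- rep(c("A", "B"), each = 15)
  sig <- assign_signatures(em, labels, alpha = 0.2)
  for (g in rownames(em$values)) {
    p <- t.test(em$values[g, labels == "A"], em$values[g, labels == "B"],
                alternative = "greater", var.equal = TRUE)$p.value
    expect_identical(g %in% sig$up$A, p < 0.2)
  }
})

test_that("coherence test flags shared-deep-term signatures", {
  ont <- ontology(list(root = character(), mid = "root", deep = "mid"))
  genes <- sprintf("g%02d", 1:30)
  ann <- setNames(rep(list("mid"), 30), genes)
  for (g in genes[1:5]) ann[[g]] <- c("mid", "deep")
  ct <- coherence_test(genes[1:5], genes, ont, ann, n_perm = 99, seed = 3)
  expect_equal(ct$p, 1 / 100)
  expect_error(coherence_test(genes[1:5], genes, ont, ann, n_perm = 0),
               "at least 1")
  expect_error(coherence_test(genes[1:2], genes[3:10], ont, ann, 10),
               "subset")
})

test_that("coherence p-values are roughly uniform for random signatures", {
  ont <- toy_ontology()
  genes <- sprintf("g%02d", 1:40)
  set.seed(67)
  ann <- setNames(lapply(1:40, function(i)
    sample(c("a", "b", "c", "d"), sample(1:2, 1))), genes)
  S <- resnik_matrix(genes, ont, ann)
  ps <- vapply(1:60, function(i) {
    set.seed(1000 + i)
    sig <- sample(genes, 6)
    coherence_test(sig, genes, n_perm = 49, seed = i, sim = S)$p
  }, numeric(1))
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})
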