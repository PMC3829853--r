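test_that("cross-tabulation reproduces counts, percentages and folds", {
  # build labelings realizing a fixed 2x2 table (8, 2; 3, 7)
  samples <- sprintf("s%02d", 1:20)
  a <- setNames(rep(c("r1", "r2"), each = 10), samples)
  b <- setNames(c(rep("c1", 8), rep("c2", 2), rep("c1", 3), rep("c2", 7)),
                samples)
  ct <- crosstab_association(a, b)
  cell <- ct$cells[ct$cells$row == "r1" & ct$cells$col == "c1", ]
  expect_equal(cell$count, 8)
  expect_equal(cell$row_pct, 80)
  expect_equal(cell$col_pct, 100 * 8 / 11)
  expect_equal(cell$fold, 8 / (10 * 11 / 20))
  expect_error(crosstab_association(c(x = "a"), c(y = "b")), "shared")
})

test_that("crosstab hypergeometric p matches exact enumeration on small tables", {
  samples <- sprintf("s%02d", 1:20)
  a <- setNames(rep(c("r1", "r2"), each = 10), samples)
  b <- setNames(c(rep("c1", 10), rep("c2", 10)), samples)
  ct <- crosstab_association(a, b)
  cell <- ct$cells[ct$cells$row == "r1" & ct$cells$col == "c1", ]
  # exact tail: overlap >= 10 when drawing 10 of 20 with 10 marked
  p_brute <- choose(10, 10) * choose(10, 0) / choose(20, 10)
  expect_equal(cell$p, p_brute, tolerance = 1e-12)
  # general small-table check against full enumeration
  set.seed(91)
  a2 <- setNames(sample(c("x", "y"), 15, TRUE), sprintf("t%02d", 1:15))
  b2 <- setNames(sample(c("u", "v"), 15, TRUE), sprintf("t%02d", 1:15))
  ct2 <- crosstab_association(a2, b2)
  for (i in seq_len(nrow(ct2$cells))) {
    cell <- ct2$cells[i, ]
    ks <- cell$count:min(cell$row_total, cell$col_total)
    p_enum <- sum(sapply(ks, function(k)
      choose(cell$col_total, k) *
        choose(15 - cell$col_total, cell$row_total - k) /
        choose(15, cell$row_total)))
    expect_equal(cell$p, p_enum, tolerance = 1e-12)
  }
})

test_that("fold enrichment centers on 1 for independent labelings", {
  set.seed(92)
  samples <- sprintf("s%03d", 1:200)
  a <- setNames(sample(c("r1", "r2"), 200, TRUE), samples)
  folds <- replicate(300, {
    b <- setNames(sample(c("c1", "c2"), 200, TRUE), samples)
    ct <- crosstab_association(a, b)
    ct$cells$fold[1]
  })
  expect_equal(mean(folds), 1, tolerance = 0.05)
})

test_that("development-gene selection filters by rho then ranks by MAD", {
  set.seed(93)
  tc <- matrix(rnorm(200 * 7, sd = 0.05), 200, 7,
               dimnames = list(sprintf("g%03d", 1:200), paste0("t", 1:7)))
  # monotone genes with varying amplitude
  for (i in 1:50) tc[i, ] <- i * (1:7) / 7 + rnorm(7, sd = 1e-3)
  tc[51, ] <- 5  # constant: excluded
  genes <- select_development_genes(tc, n_top = 20)
  expect_length(genes, 20)
  # MAD ranking: the largest-amplitude monotone genes come first
  mads <- apply(tc[genes, ], 1, mad)
  expect_true(all(diff(order(mads, decreasing = TRUE)) > 0))
  expect_setequal(genes, sprintf("g%03d", 50:31))
  expect_false("g051" %in%
    select_development_genes(tc, n_top = 200))
  expect_error(select_development_genes(tc[, 1:3]), "4 timepoints")
})

test_that("stage correlations hit +-1 on exact and negated profiles", {
  set.seed(94)
  genes <- sprintf("g%02d", 1:30)
  profile <- rnorm(30)
  tc <- cbind(t1 = profile, t2 = rnorm(30))
  rownames(tc) <- genes
  cent <- cbind(sub1 = profile, sub2 = -profile)
  rownames(cent) <- genes
  sc <- stage_correlation(cent, tc, genes)
  expect_equal(sc$r[sc$subtype == "sub1" & sc$timepoint == "t1"], 1)
  expect_equal(sc$r[sc$subtype == "sub2" & sc$timepoint == "t1"], -1)
  mid <- sc[sc$subtype == "sub1" & sc$timepoint == "t2", ]
  expect_true(mid$ci_lo <= mid$r && mid$r <= mid$ci_hi)
  expect_error(stage_correlation(cent[1:3, , drop = FALSE], tc, genes),
               "4 shared")
})

test_that("signature scores average centered expression over present genes", {
  m <- rbind(g1 = c(1, 2, 3), g2 = c(10, 10, 13))
  colnames(m) <- paste0("s", 1:3)
  em <- expr_matrix(m, "d1")
  s1 <- signature_score(em, "g1")
  expect_equal(unname(s1), c(-1, 0, 1))  # single gene: its centered values
  expect_message(s2 <- signature_score(em, c("g1", "gX")), "absent")
  expect_equal(unname(s2), c(-1, 0, 1))
  expect_equal(mean(signature_score(em, c("g1", "g2"))), 0, tolerance = 1e-12)
  expect_error(signature_score(em, "nope"), "no signature gene")
})

test_that("a planted expression shift is recovered by the signature score", {
  set.seed(95)
  m <- matrix(rnorm(40 * 60, sd = 0.2), 40, 60,
              dimnames = list(sprintf("g%02d", 1:40), sprintf("s%02d", 1:60)))
  shifted <- sprintf("s%02d", 1:20)
  m[1:10, shifted] <- m[1:10, shifted] + 1
  em <- expr_matrix(m, "d1")
  sc <- signature_score(em, sprintf("g%02d", 1:10))
  expect_equal(mean(sc[shifted]) - mean(sc[!names(sc) %in% shifted]), 1,
               tolerance = 0.1)
})

test_that("log-rank matches a hand observed-minus-expected tabulation", {
  surv <- data.frame(sample = paste0("s", 1:8),
                     time = c(6, 6, 6, 7, 10, 12, 15, 8),
                     event = c(1, 1, 1, 1, 0, 1, 0, 1),
                     group = rep(c("A", "B"), each = 4))
  kl <- km_logrank(surv)
  expect_equal(kl$chisq,
               brute_logrank(surv$time, surv$event, surv$group),
               tolerance = 1e-9)
  expect_equal(kl$df, 1)
  # identical groups: no signal at all
  surv2 <- surv
  surv2$group <- rep(c("A", "B"), 4)
  surv2$time <- rep(c(5, 9, 11, 13), each = 2)
  surv2$event <- 1
  kl2 <- km_logrank(surv2)
  expect_equal(kl2$chisq, 0, tolerance = 1e-9)
  expect_equal(kl2$p, 1, tolerance = 1e-9)
  expect_error(km_logrank(surv[surv$group == "A", ]), "2 groups")
})

test_that("KM curves start at 1 and never increase", {
  truth <- list(sample_subtype = setNames(rep(1:3, each = 30),
                                          sprintf("s%02d", 1:90)),
                survival_hazard = c(0.03, 0.01, 0.02))
  surv <- gen_survival(truth, censor_rate = 0.3, seed = 4)
  kl <- km_logrank(surv)
  s <- kl$fit$surv
  strata <- rep(seq_along(kl$fit$strata), kl$fit$strata)
  for (g in unique(strata)) {
    sg <- s[strata == g]
    expect_lte(sg[1], 1)
    expect_true(all(diff(sg) <= 1e-12))
  }
  f <- tempfile()
  write_survival_table(surv, f)
  expect_equal(read_survival_table(f), surv)
})

test_that("log-rank p-values are uniform under equal hazards", {
  truth <- list(sample_subtype = setNames(rep(1:2, each = 30),
                                          sprintf("s%02d", 1:60)),
                survival_hazard = c(0.02, 0.02))
  ps <- vapply(1:200, function(i)
    km_logrank(gen_survival(truth, censor_rate = 0.1, seed = 2000 + i))$p,
    numeric(1))
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})
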