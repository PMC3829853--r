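test_that("mutation binarization keeps non-silent calls only, once per gene", {
  calls <- data.frame(
    sample = c("s1", "s1", "s1", "s2", "s2"),
    gene = c("A", "A", "B", "A", "C"),
    variant_class = c("Missense_Mutation", "Missense_Mutation", "Silent",
                      "Nonsense_Mutation", "Silent"))
  m <- binarize_mutations(calls, genes = c("A", "B", "C"),
                          samples = c("s1", "s2", "s3"))
  expect_equal(m["A", "s1"], 1L)          # two calls still collapse to 1
  expect_equal(m["B", "s1"], 0L)          # silent-only -> 0
  expect_equal(unname(m[, "s3"]), c(0L, 0L, 0L))  # empty column retained
  calls$variant_class[1] <- "Weird_Class"
  expect_warning(m2 <- binarize_mutations(calls, c("A", "B", "C"),
                                          c("s1", "s2", "s3")), "unknown")
  expect_equal(m2["A", "s1"], 1L)         # unknown defaults to non-silent
})

test_that("CNV binarization uses inclusive gain/loss cutoffs", {
  r <- matrix(c(1.2, 1.0, 0.8, 1.19, 0.81, 2.5), 2, 3,
              dimnames = list(c("A", "B"), c("s1", "s2", "s3")))
  m <- binarize_cnv(r)
  expect_equal(as.vector(m), c(1L, 0L, 1L, 0L, 0L, 1L))
  r[1, 1] <- -0.1
  expect_error(binarize_cnv(r), "positive")
})

test_that("start probabilities match the worked 2x2 example", {
  mut <- matrix(c(1L, 1L, 1L, 0L), 2, 2,
                dimnames = list(c("A", "B"), c("s1", "s2")))
  p0 <- start_probabilities(mut)
  # s1 has 2 alterations -> each worth 1/2; s2 has 1 -> worth 1
  expect_equal(unname(p0$s_mut), c(1.5, 0.5))
  expect_equal(unname(p0$p0), c(0.75, 0.25))
  expect_equal(sum(p0$p0), 1, tolerance = 1e-12)
})

test_that("start probabilities: degenerate and invariance cases", {
  one <- matrix(c(0L, 1L, 0L, 0L), 2, 2,
                dimnames = list(c("A", "B"), c("s1", "s2")))
  expect_equal(unname(start_probabilities(one)$p0), c(0, 1))
  zero <- one * 0L
  expect_error(start_probabilities(zero), "no alterations")
  expect_error(start_probabilities(one, zero[1, , drop = FALSE]), "share")
  # duplicating every sample leaves p0 unchanged; check on random matrices
  for (i in 1:10) {
    set.seed(70 + i)
    m <- matrix(rbinom(50, 1, 0.3), 10, 5,
                dimnames = list(paste0("g", 1:10), paste0("s", 1:5)))
    if (sum(m) == 0) m[1, 1] <- 1L
    storage.mode(m) <- "integer"
    m2 <- cbind(m, m)
    colnames(m2) <- paste0("s", 1:10)
    expect_equal(unname(start_probabilities(m)$p0),
                 unname(start_probabilities(m2)$p0), tolerance = 1e-12)
    # brute-force oracle: explicit double loop over the formulas
    cs <- colSums(m)
    s_brute <- sapply(seq_len(nrow(m)), function(i)
      sum(sapply(seq_len(ncol(m)), function(j)
        if (cs[j] > 0) m[i, j] / cs[j] else 0)))
    expect_equal(unname(start_probabilities(m)$p0),
                 s_brute / sum(s_brute), tolerance = 1e-12)
  }
})

test_that("restart 1 returns the start vector; 2-node closed form holds", {
  g <- igraph::graph_from_edgelist(rbind(c("A", "B")), directed = FALSE)
  p0 <- c(A = 1, B = 0)
  expect_equal(random_walk(g, p0, r = 1)$score, c(A = 1, B = 0))
  # fixed point of p = 0.5 W p + 0.5 p0 on a single edge: p = (2/3, 1/3)
  w <- random_walk(g, p0, r = 0.5, epsilon = 1e-12)
  expect_equal(w$score, c(A = 2 / 3, B = 1 / 3), tolerance = 1e-9)
})

test_that("uniform seeds on a regular graph give uniform scores", {
  ring <- igraph::make_ring(8)
  igraph::V(ring)$name <- paste0("g", 1:8)
  p0 <- setNames(rep(1 / 8, 8), paste0("g", 1:8))
  w <- random_walk(ring, p0, r = 0.5)
  expect_equal(unname(w$score), rep(1 / 8, 8), tolerance = 1e-9)
})

test_that("walk agrees with the direct linear solve and conserves mass", {
  for (i in 1:5) {
    g <- gen_signaling_network(50, 2, seed = 80 + i)
    set.seed(90 + i)
    p0 <- runif(50)
    p0 <- setNames(p0 / sum(p0), igraph::V(g)$name)
    w <- random_walk(g, p0, r = 0.5, epsilon = 1e-12)
    expect_equal(sum(w$score), 1, tolerance = 1e-12)
    A <- as.matrix(igraph::as_adjacency_matrix(g))
    A <- A[names(w$score), names(w$score)]
    W <- sweep(A, 2, colSums(A), "/")
    direct <- 0.5 * solve(diag(50) - 0.5 * W, p0[names(w$score)])
    expect_equal(w$score, direct, tolerance = 1e-8)
  }
})

test_that("raising a gene's start probability never lowers its score", {
  g <- gen_signaling_network(40, 2, seed = 85)
  genes <- igraph::V(g)$name
  set.seed(86)
  base <- runif(40); base <- setNames(base / sum(base), genes)
  s_base <- random_walk(g, base, r = 0.5, epsilon = 1e-10)$score
  for (target in sample(genes, 5)) {
    boosted <- base
    boosted[target] <- boosted[target] + 0.5
    boosted <- boosted / sum(boosted)
    s_boost <- random_walk(g, boosted, r = 0.5, epsilon = 1e-10)$score
    expect_gte(s_boost[target], s_base[target] - 1e-12)
  }
})

test_that("the walk restricts itself to the largest connected component", {
  g <- igraph::graph_from_edgelist(rbind(c("A", "B"), c("B", "C"),
                                         c("X", "Y")), directed = FALSE)
  p0 <- c(A = 0.5, B = 0.25, C = 0.15, X = 0.1, Y = 0)
  expect_message(w <- random_walk(g, p0, r = 0.5), "largest component")
  expect_setequal(names(w$score), c("A", "B", "C"))
  expect_equal(sum(w$score), 1, tolerance = 1e-12)
})

test_that("a planted star-hub holding the seed mass is maximally significant", {
  # on a star, the hub's score strictly exceeds any leaf-seeded score, so
  # the only permutations matching the observed hub score are those that
  # return the dominant mass to the hub itself; the local p must equal the
  # add-one count of exactly those permutations (replayed independently)
  g <- igraph::make_star(50, mode = "undirected")
  genes <- sprintf("g%02d", 1:50)
  igraph::V(g)$name <- genes
  hub <- genes[1]
  p0 <- setNames(c(0.9, rep(0.1 / 49, 49)), genes)
  sig <- permutation_significance(g, p0, n_perm = 99, seed = 5)
  p0_used <- random_walk(g, p0, r = 0.5)$p0
  set.seed(5)
  hub_hits <- sum(vapply(1:99, function(b)
    sample(p0_used)[match(hub, names(p0_used))] > 0.5, logical(1)))
  expect_equal(sig$local_p[sig$gene == hub], (1 + hub_hits) / 100)
  expect_gte(hub_hits, 0)
  sig2 <- permutation_significance(g, p0, n_perm = 99, seed = 5)
  expect_identical(sig, sig2)  # seed determinism
  expect_true(all(sig$local_p > 0 & sig$local_p <= 1))
  expect_true(all(sig$global_p > 0 & sig$global_p <= 1))
})

test_that("uniform seeds make every local p-value 1 by permutation invariance", {
  ring <- igraph::make_ring(10)
  igraph::V(ring)$name <- paste0("g", 1:10)
  p0 <- setNames(rep(0.1, 10), paste0("g", 1:10))
  sig <- permutation_significance(ring, p0, n_perm = 19, seed = 2)
  expect_true(all(sig$local_p == 1))
})

test_that("driver subnetworks are the largest significant component", {
  g <- igraph::graph_from_edgelist(
    rbind(c("a", "b"), c("b", "c"), c("c", "d"), c("d", "e"),
          c("p", "q"), c("q", "r"), c("z1", "z2")), directed = FALSE)
  sig <- structure(data.frame(
    gene = c("a", "b", "c", "d", "e", "p", "q", "r", "z1", "z2"),
    p0 = 0.1, score = 0.1,
    local_p = c(rep(0.01, 8), 0.5, 0.5),
    global_p = c(rep(0.01, 8), 0.01, 0.01)),
    class = c("significance_result", "data.frame"))
  sub <- extract_driver_subnetwork(g, sig)
  expect_setequal(igraph::V(sub)$name, c("a", "b", "c", "d", "e"))
  sig$local_p[] <- 0.9
  expect_warning(empty <- extract_driver_subnetwork(g, sig), "no gene")
  expect_equal(igraph::vcount(empty), 0)
})

test_that("hypergeometric enrichment matches exhaustive tail enumeration", {
  background <- sprintf("g%02d", 1:20)
  query <- background[1:5]
  sets <- list(hit = background[1:6], miss = background[15:20])
  enr <- geneset_enrichment(query, background, sets)
  # exhaustive upper tail for the 'hit' set: overlap >= observed
  k_obs <- length(intersect(sets$hit, query))
  p_brute <- sum(sapply(k_obs:5, function(k)
    choose(6, k) * choose(14, 5 - k) / choose(20, 5)))
  expect_equal(enr$p[enr$set == "hit"], p_brute, tolerance = 1e-12)
  expect_equal(enr$p[enr$set == "miss"], 1)  # disjoint -> upper tail at 0
  expect_error(geneset_enrichment(query, background, list()), "empty")
  expect_error(geneset_enrichment(c(query, "zz"), background, sets),
               "subset")
})

test_that("network and MAF files round-trip, including the SIF dialect", {
  g <- gen_signaling_network(20, 2, seed = 88)
  f <- tempfile()
  write_edge_list(g, f)
  back <- read_edge_list(f)
  expect_equal(igraph::ecount(back), igraph::ecount(g))
  expect_setequal(igraph::V(back)$name, igraph::V(g)$name)
  sif <- tempfile()
  el <- igraph::as_edgelist(g)
  writeLines(paste(el[, 1], "pp", el[, 2], sep = "\t"), sif)
  back2 <- read_edge_list(sif)
  expect_equal(igraph::ecount(back2), igraph::ecount(g))
  calls <- data.frame(sample = c("s1", "s2"), gene = c("A", "B"),
                      variant_class = "Missense_Mutation")
  fm <- tempfile()
  write_maf(calls, fm)
  expect_equal(read_maf(fm), calls)
  m <- matrix(c(1L, 0L, 0L, 1L), 2, 2,
              dimnames = list(c("A", "B"), c("s1", "s2")))
  maf <- alteration_to_maf(m)
  expect_setequal(paste(maf$sample, maf$gene), c("s1 A", "s2 B"))
})
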