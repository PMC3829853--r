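#' Specification of a synthetic multi-dataset tumor cohort
#'
#' Defines the conditions under which every downstream stage is exercised: a
#' multi-dataset expression cohort with planted co-expression modules whose
#' shared latent factors shift in mean between planted subtypes, additive
#' per-dataset batch offsets, and pure-noise filler genes.
#'
#' Defaults describe a cohort of 180 samples in three balanced datasets with
#' three subtypes and nine planted modules of 25-35 genes (three marking
#' each subtype). The subtype effect (0.7) is twice the residual scale
#' (0.35), and the within-subtype factor heterogeneity equals the residual
#' scale, emulating strongly separated subtypes; the marginal within-module
#' gene-gene correlation under these settings is about 0.58, above a 0.45
#' network threshold.
#'
#' @param n_genes total number of genes.
#' @param n_samples_per_dataset integer vector, samples per dataset.
#' @param n_subtypes number of planted subtypes.
#' @param n_modules number of planted co-expression modules.
#' @param module_size_range length-2 integer vector; module sizes are drawn
#'   uniformly from this range. Sizes below 20 would make planted modules
#'   undiscoverable under the pipeline's minimum module size.
#' @param module_correlation within-module latent-factor loading in `[0, 1]`.
#' @param subtype_effect shift (expression units on the latent factor) of a
#'   module's factor mean in the subtype the module marks.
#' @param factor_sd within-subtype standard deviation of a module's latent
#'   factor - the within-subtype heterogeneity of module activity.
#' @param batch_sd standard deviation of the additive per-gene, per-dataset
#'   batch offset.
#' @param noise_sd residual (within-gene) standard deviation.
#' @param neg_loading_frac fraction of each module's genes given a negative
#'   loading, so co-expression includes anticorrelated members.
#' @param survival_hazard per-subtype exponential event rate (per month),
#'   recycled to `n_subtypes`.
#' @param seed integer seed; fully determines every generated artifact.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_genes = 600,
                        n_samples_per_dataset = c(60, 60, 60),
                        n_subtypes = 3,
                        n_modules = 9,
                        module_size_range = c(25, 35),
                        module_correlation = 0.85,
                        subtype_effect = 0.7,
                        factor_sd = 0.35,
                        batch_sd = 0.3,
                        noise_sd = 0.35,
                        neg_loading_frac = 0.2,
                        survival_hazard = c(0.0116, 0.0044, 0.0077),
                        seed = 1L) {
  spec <- list(n_genes = as.integer(n_genes),
               n_samples_per_dataset = as.integer(n_samples_per_dataset),
               n_subtypes = as.integer(n_subtypes),
               n_modules = as.integer(n_modules),
               module_size_range = as.integer(module_size_range),
               module_correlation = module_correlation,
               subtype_effect = subtype_effect,
               factor_sd = factor_sd,
               batch_sd = batch_sd,
               noise_sd = noise_sd,
               neg_loading_frac = neg_loading_frac,
               survival_hazard = rep_len(survival_hazard, n_subtypes),
               seed = as.integer(seed))
  if (spec$n_genes <= 0L || any(spec$n_samples_per_dataset <= 0L) ||
      spec$n_subtypes <= 0L || spec$n_modules <= 0L ||
      any(spec$module_size_range <= 0L))
    stop("all counts in a cohort spec must be positive")
  if (spec$module_size_range[1L] > spec$module_size_range[2L])
    stop("module_size_range must be nondecreasing")
  if (spec$module_correlation < 0 || spec$module_correlation > 1)
    stop("module_correlation must lie in [0, 1]")
  if (spec$batch_sd < 0 || spec$noise_sd < 0 || spec$factor_sd < 0)
    stop("scales must be nonnegative")
  if (any(spec$survival_hazard <= 0))
    stop("survival hazards must be positive")
  class(spec) <- "cohort_spec"
  spec
}

#' Generate a synthetic expression cohort with planted structure
#'
#' Each planted module is driven by one latent factor per sample, with
#' within-subtype standard deviation `factor_sd` and a mean of
#' `subtype_effect` in the subtype the module marks (module `m` marks
#' subtype `((m - 1) mod n_subtypes) + 1`).
#' A gene in the module observes `loading * factor + Normal(0, noise_sd)`,
#' where the loading magnitude is `module_correlation` and a fixed fraction
#' of members carry a negative sign. Genes outside every module are
#' `Normal(0, noise_sd)` noise. Every gene has a baseline log2 level drawn
#' once, and every (gene, dataset) pair receives an additive batch offset
#' `Normal(0, batch_sd)`. Subtypes are interleaved within each dataset so
#' per-dataset centering does not remove subtype signal.
#'
#' @param spec a [cohort_spec()].
#' @return A list with `expr` (an [expr_matrix()]) and `truth`, a list with
#'   `sample_subtype` (named integer vector), `module_members` (named list of
#'   gene sets), `module_subtype` (which subtype each module marks),
#'   `gene_loading` (signed loading per module gene), `survival_hazard`, and
#'   `driver_genes` (empty; filled by [plant_drivers()] once a network
#'   exists).
#' @export
gen_expression_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n_ds <- length(spec$n_samples_per_dataset)
  gene_ids <- sprintf("g%04d", seq_len(spec$n_genes))
  sample_ids <- unlist(lapply(seq_len(n_ds), function(d)
    sprintf("d%d_s%03d", d, seq_len(spec$n_samples_per_dataset[d]))))
  dataset <- rep(sprintf("dataset%d", seq_len(n_ds)),
                 spec$n_samples_per_dataset)
  names(dataset) <- sample_ids
  # balanced subtype interleave within each dataset
  subtype <- unlist(lapply(spec$n_samples_per_dataset, function(ns)
    rep_len(seq_len(spec$n_subtypes), ns)))
  names(subtype) <- sample_ids

  size_pool <- seq(spec$module_size_range[1L], spec$module_size_range[2L])
  sizes <- size_pool[sample.int(length(size_pool), spec$n_modules,
                                replace = TRUE)]
  if (sum(sizes) > spec$n_genes)
    stop("module sizes sum to ", sum(sizes), " > n_genes = ", spec$n_genes)
  starts <- cumsum(c(1L, sizes[-length(sizes)]))
  module_members <- lapply(seq_len(spec$n_modules), function(m)
    gene_ids[seq(starts[m], length.out = sizes[m])])
  names(module_members) <- sprintf("module%02d", seq_len(spec$n_modules))
  module_subtype <- ((seq_len(spec$n_modules) - 1L) %% spec$n_subtypes) + 1L
  names(module_subtype) <- names(module_members)

  n_samp <- length(sample_ids)
  baseline <- stats::rnorm(spec$n_genes, mean = 7, sd = 1)
  x <- matrix(stats::rnorm(spec$n_genes * n_samp, sd = spec$noise_sd),
              spec$n_genes, n_samp, dimnames = list(gene_ids, sample_ids))
  gene_loading <- numeric(0)
  for (m in seq_len(spec$n_modules)) {
    members <- module_members[[m]]
    mu <- ifelse(subtype == module_subtype[m], spec$subtype_effect, 0)
    f <- stats::rnorm(n_samp, mean = mu, sd = spec$factor_sd)
    n_neg <- floor(length(members) * spec$neg_loading_frac)
    signs <- rep(1, length(members))
    if (n_neg > 0L) signs[seq_len(n_neg)] <- -1
    loadings <- signs * spec$module_correlation
    names(loadings) <- members
    gene_loading <- c(gene_loading, loadings)
    x[members, ] <- x[members, , drop = FALSE] + outer(loadings, f)
  }
  batch <- matrix(stats::rnorm(spec$n_genes * n_ds, sd = spec$batch_sd),
                  spec$n_genes, n_ds)
  x <- x + baseline + batch[, match(dataset, unique(dataset)), drop = FALSE]

  truth <- list(sample_subtype = subtype,
                module_members = module_members,
                module_subtype = module_subtype,
                gene_loading = gene_loading,
                survival_hazard = spec$survival_hazard,
                driver_genes = list())
  list(expr = expr_matrix(x, dataset), truth = truth)
}

#' Generate a scale-free signaling network
#'
#' Preferential-attachment (Barabasi-Albert) growth: each new node attaches
#' `edges_per_node` edges to existing nodes with probability proportional to
#' degree, yielding a connected undirected graph with a heavy-tailed degree
#' distribution, the canonical stand-in for curated signaling networks.
#'
#' @param n_nodes number of nodes.
#' @param edges_per_node edges attached per new node (`1` gives a tree).
#' @param seed integer seed.
#' @param genes optional gene universe to draw node names from (must have at
#'   least `n_nodes` entries); defaults to `g0001`-style ids.
#' @return An undirected connected `igraph` graph with named vertices.
#' @export
gen_signaling_network <- function(n_nodes, edges_per_node = 3, seed = 1L,
                                  genes = NULL) {
  if (n_nodes <= edges_per_node || edges_per_node < 1L)
    stop("need n_nodes > edges_per_node >= 1")
  set.seed(seed)
  g <- igraph::sample_pa(n_nodes, m = edges_per_node, directed = FALSE)
  if (is.null(genes)) {
    nm <- sprintf("g%04d", seq_len(n_nodes))
  } else {
    if (length(genes) < n_nodes)
      stop("gene universe smaller than n_nodes")
    nm <- sample(genes, n_nodes)
  }
  igraph::V(g)$name <- nm
  g
}

#' Plant connected driver-gene sets on a network
#'
#' For each subtype, grows a random connected subgraph of the given size by
#' breadth-first expansion from a random start node, preferring nodes not
#' already claimed by another subtype. The returned sets satisfy the ground
#' truth invariant that each subtype's drivers induce a connected subgraph.
#'
#' @param network an `igraph` signaling network with named vertices.
#' @param n_subtypes number of driver sets to plant.
#' @param n_per_subtype genes per driver set.
#' @param seed integer seed.
#' @return Named list `subtype1`, ... of gene-id vectors.
#' @export
plant_drivers <- function(network, n_subtypes = 3, n_per_subtype = 12,
                          seed = 1L) {
  set.seed(seed)
  all_nodes <- igraph::V(network)$name
  used <- character(0)
  out <- vector("list", n_subtypes)
  for (k in seq_len(n_subtypes)) {
    avail <- setdiff(all_nodes, used)
    start <- sample(avail, 1L)
    members <- start
    while (length(members) < n_per_subtype) {
      nb <- setdiff(unique(unlist(lapply(members, function(v)
        igraph::neighbors(network, v)$name))), members)
      nb_new <- setdiff(nb, used)
      pool <- if (length(nb_new)) nb_new else nb
      if (!length(pool)) break
      members <- c(members, sample(pool, 1L))
    }
    used <- union(used, members)
    out[[k]] <- sort(members)
  }
  names(out) <- sprintf("subtype%d", seq_len(n_subtypes))
  out
}

#' Generate binary mutation and copy-number alteration matrices
#'
#' For samples of subtype `k`, genes in `truth$driver_genes[[k]]` are altered
#' with probability `driver_rate`; all other (gene, sample) entries with
#' probability `background_rate`. Mutation and CNV matrices are drawn
#' independently, the neutral case for a method combining them with equal
#' weight.
#'
#' @param network `igraph` network whose named vertices define the gene rows.
#' @param truth ground-truth list with `sample_subtype` and `driver_genes`
#'   (see [gen_expression_cohort()] and [plant_drivers()]).
#' @param background_rate per-entry alteration probability off drivers.
#' @param driver_rate per-entry alteration probability on planted drivers.
#' @param seed integer seed.
#' @return List with binary matrices `mut` and `cnv` (genes x samples).
#' @export
gen_alteration_data <- function(network, truth, background_rate = 0.01,
                                driver_rate = 0.6, seed = 1L) {
  if (!(background_rate >= 0 && background_rate < driver_rate &&
        driver_rate <= 1))
    stop("need 0 <= background_rate < driver_rate <= 1")
  genes <- igraph::V(network)$name
  absent <- setdiff(unlist(truth$driver_genes), genes)
  if (length(absent))
    stop("driver gene(s) absent from network: ",
         paste(utils::head(absent, 5), collapse = ", "))
  samples <- names(truth$sample_subtype)
  rate <- matrix(background_rate, length(genes), length(samples),
                 dimnames = list(genes, samples))
  for (k in seq_along(truth$driver_genes)) {
    sk <- samples[truth$sample_subtype == k]
    rate[truth$driver_genes[[k]], sk] <- driver_rate
  }
  set.seed(seed)
  draw <- function() {
    m <- matrix(as.integer(stats::runif(length(rate)) < rate),
                nrow(rate), ncol(rate), dimnames = dimnames(rate))
    m
  }
  list(mut = draw(), cnv = draw())
}

#' Generate subtype-dependent survival times
#'
#' Event times are exponential with the per-subtype hazard in
#' `truth$survival_hazard`; censoring times are independent exponentials with
#' rate chosen so that the expected censored fraction equals `censor_rate`
#' (`censor_rate = 0` observes every event).
#'
#' @param truth ground-truth list with `sample_subtype` and `survival_hazard`.
#' @param censor_rate target probability that a sample is censored.
#' @param seed integer seed.
#' @return Data frame with columns `sample`, `time`, `event` (1 = death),
#'   `group` (true subtype).
#' @export
gen_survival <- function(truth, censor_rate = 0.2, seed = 1L) {
  if (censor_rate < 0 || censor_rate >= 1)
    stop("censor_rate must lie in [0, 1)")
  hz <- truth$survival_hazard
  if (any(hz <= 0)) stop("hazards must be positive")
  set.seed(seed)
  subtype <- truth$sample_subtype
  lambda <- hz[subtype]
  t_event <- stats::rexp(length(subtype), rate = lambda)
  if (censor_rate > 0) {
    mu <- lambda * censor_rate / (1 - censor_rate)
    t_cens <- stats::rexp(length(subtype), rate = mu)
  } else {
    t_cens <- rep(Inf, length(subtype))
  }
  data.frame(sample = names(subtype),
             time = pmin(t_event, t_cens),
             event = as.integer(t_event <= t_cens),
             group = paste0("subtype", subtype),
             stringsAsFactors = FALSE)
}

#' Generate a random ontology with module-coherent annotations
#'
#' Builds a rooted random DAG with a shallow layer of general terms under the
#' root, a set of deeper terms, and one dedicated deep term per planted
#' module. Genes of a module are all annotated to that module's deep term
#' (high information content), making module members functionally coherent;
#' every gene additionally gets one or two shallow-term annotations and a
#' direct root annotation, so cross-module pairs mostly share only general
#' terms.
#'
#' @param n_terms total number of terms (at least 2).
#' @param genes gene universe to annotate.
#' @param truth ground-truth list with `module_members` (may be an empty list
#'   for a module-free ontology).
#' @param seed integer seed.
#' @return List with `ontology` (an [ontology()]) and `annotations` (named
#'   list gene -> direct term ids).
#' @export
gen_ontology_and_annotations <- function(n_terms, genes, truth, seed = 1L) {
  if (n_terms < 2L) stop("need at least 2 terms")
  set.seed(seed)
  n_modules <- length(truth$module_members)
  terms <- sprintf("T%04d", seq_len(n_terms))
  root <- terms[1L]
  parents <- stats::setNames(vector("list", n_terms), terms)
  parents[[root]] <- character()
  n_rest <- n_terms - 1L
  n_module_terms <- min(n_modules, n_rest)
  n_shallow <- max(1L, min(n_rest - n_module_terms,
                           ceiling((n_rest - n_module_terms) / 2)))
  shallow <- terms[seq(2L, length.out = n_shallow)]
  deep <- setdiff(terms[-1L], shallow)
  for (t in shallow) parents[[t]] <- root
  prev <- shallow
  for (t in deep) {
    parents[[t]] <- sample(prev, 1L)
    prev <- c(prev, t)
  }
  module_terms <- if (n_module_terms > 0L)
    utils::tail(deep, n_module_terms) else character()
  ont <- ontology(parents)

  annotations <- stats::setNames(vector("list", length(genes)), genes)
  for (g in genes) {
    n_sh <- sample(1:2, 1L)
    annotations[[g]] <- unique(c(root, sample(shallow, min(n_sh,
                                                           length(shallow)))))
  }
  if (n_module_terms > 0L) {
    for (m in seq_len(n_modules)) {
      tm <- module_terms[((m - 1L) %% n_module_terms) + 1L]
      for (g in intersect(truth$module_members[[m]], genes))
        annotations[[g]] <- unique(c(annotations[[g]], tm))
    }
  }
  list(ontology = ont, annotations = annotations)
}
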