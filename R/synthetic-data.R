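#' Generate a synthetic cancer/normal expression cohort with planted DEGs
#'
#' Emulates a quantile-normalized log2 microarray cohort: each gene's
#' baseline intensity comes from a low (non-expressed) or high (expressed)
#' Gaussian component, reproducing the two-component pooled-intensity
#' structure that the expressed-gene filter assumes; Gaussian noise with a
#' common standard deviation is added on the log2 scale. A fraction of the
#' expressed genes receives a +/- `effect_size` mean shift in the cancer
#' samples.
#'
#' @param n_genes total number of genes (default 1000).
#' @param n_cancer,n_normal samples per class (default 10 each).
#' @param frac_de fraction of expressed genes planted as differentially
#'   expressed, in \[0, 1) (default 0.1).
#' @param effect_size absolute mean shift of planted genes in cancer
#'   samples, log2 units (default 2).
#' @param noise_sd per-observation Gaussian noise sd, log2 units
#'   (default 1).
#' @param expressed_frac fraction of genes in the expressed (high)
#'   component (default 0.7).
#' @param mean_low,mean_high component baseline means, log2 units
#'   (defaults 4 and 10).
#' @param genes optional gene identifiers (length `n_genes`).
#' @param force_de identifiers always planted as DE (must be expressed;
#'   they are added to the expressed component if needed).
#' @param seed integer seed; the generator is bit-reproducible.
#' @param dataset_id,cancer_type cohort identifiers.
#' @return A list with `dataset` (an [expression_dataset()]) and `truth`
#'   (class `synthetic_truth`: `planted_deg` data frame with per-gene
#'   effects, `expressed_genes`, `params`).
#' @export
generate_expression_cohort <- function(n_genes = 1000L, n_cancer = 10L,
                                       n_normal = 10L, frac_de = 0.1,
                                       effect_size = 2, noise_sd = 1,
                                       expressed_frac = 0.7,
                                       mean_low = 4, mean_high = 10,
                                       genes = NULL, force_de = NULL,
                                       seed = 1L,
                                       dataset_id = "synthetic",
                                       cancer_type = "cancer") {
  if (n_genes < 1L || n_cancer < 1L || n_normal < 1L) {
    stop("counts must be positive")
  }
  if (frac_de < 0 || frac_de >= 1) stop("frac_de must be in [0, 1)")
  if (expressed_frac <= 0 || expressed_frac > 1) {
    stop("expressed_frac must be in (0, 1]")
  }
  params <- list(n_genes = n_genes, n_cancer = n_cancer,
                 n_normal = n_normal, frac_de = frac_de,
                 effect_size = effect_size, noise_sd = noise_sd,
                 expressed_frac = expressed_frac, mean_low = mean_low,
                 mean_high = mean_high, genes = genes,
                 force_de = force_de, seed = seed,
                 dataset_id = dataset_id, cancer_type = cancer_type)
  if (is.null(genes)) {
    genes <- sprintf("g%04d", seq_len(n_genes))
  }
  stopifnot(length(genes) == n_genes)
  out <- with_seed(seed, {
    n_expr <- round(n_genes * expressed_frac)
    expressed <- sample(genes, n_expr)
    expressed <- union(expressed, intersect(force_de, genes))
    baseline <- ifelse(genes %in% expressed, mean_high, mean_low)
    n_de <- round(frac_de * length(expressed))
    planted <- union(sample(setdiff(expressed, force_de),
                            max(0L, n_de - length(force_de))),
                     intersect(force_de, genes))
    effect <- stats::setNames(
      sample(c(-1, 1), length(planted), replace = TRUE) * effect_size,
      planted)
    n_samp <- n_cancer + n_normal
    values <- baseline +
      matrix(stats::rnorm(n_genes * n_samp, sd = noise_sd), n_genes)
    labels <- c(rep("cancer", n_cancer), rep("normal", n_normal))
    idx <- match(planted, genes)
    if (length(idx) > 0L && n_cancer > 0L) {
      values[idx, seq_len(n_cancer)] <-
        values[idx, seq_len(n_cancer), drop = FALSE] + effect
    }
    dimnames(values) <- list(genes, sprintf("s%03d", seq_len(n_samp)))
    list(values = values, labels = labels, expressed = expressed,
         planted = planted, effect = effect)
  })
  dataset <- expression_dataset(out$values, out$labels,
                                dataset_id = dataset_id,
                                cancer_type = cancer_type)
  truth <- structure(
    list(planted_deg = data.frame(gene = out$planted,
                                  effect = unname(out$effect),
                                  stringsAsFactors = FALSE),
         expressed_genes = out$expressed, params = params),
    class = "synthetic_truth")
  list(dataset = dataset, truth = truth)
}

#' Generate a synthetic interactome with a planted dense module
#'
#' An Erdos-Renyi background graph with a planted dense subgraph whose
#' members include the seed genes; the gene-set catalog labels the seeds,
#' the cancer-associated genes (the planted module plus a random share of
#' the background) and the non-CAG remainder.
#'
#' @param n_nodes number of nodes (default 200).
#' @param mean_degree expected background degree (default 6).
#' @param module_size planted module size (default 8).
#' @param module_density edge probability inside the module; must exceed
#'   the background density (default 1 = clique).
#' @param n_seed_genes how many module members are seed genes (default 2).
#' @param cag_frac share of non-module nodes also labelled CAG
#'   (default 0.3).
#' @param seed integer seed.
#' @return A list with `network` ([igraph::graph] including isolated
#'   nodes), `catalog` ([gene_set_catalog()]) and `truth`
#'   (`planted_module`, `params`).
#' @export
generate_ppi_network <- function(n_nodes = 200L, mean_degree = 6,
                                 module_size = 8L, module_density = 1,
                                 n_seed_genes = 2L, cag_frac = 0.3,
                                 seed = 1L) {
  if (module_size > n_nodes) stop("module_size exceeds n_nodes")
  p_bg <- mean_degree / (n_nodes - 1L)
  if (module_density <= p_bg) {
    stop("infeasible density: module_density must exceed background density")
  }
  if (n_seed_genes > module_size) stop("n_seed_genes exceeds module_size")
  params <- list(n_nodes = n_nodes, mean_degree = mean_degree,
                 module_size = module_size,
                 module_density = module_density,
                 n_seed_genes = n_seed_genes, cag_frac = cag_frac,
                 seed = seed)
  nodes <- sprintf("g%04d", seq_len(n_nodes))
  out <- with_seed(seed, {
    pairs <- utils::combn(n_nodes, 2L)
    bg <- pairs[, stats::runif(ncol(pairs)) < p_bg, drop = FALSE]
    module <- sample(nodes, module_size)
    mpairs <- utils::combn(module, 2L)
    mod <- mpairs[, stats::runif(ncol(mpairs)) <= module_density,
                  drop = FALSE]
    edges <- data.frame(
      from = c(nodes[bg[1L, ]], mod[1L, ]),
      to = c(nodes[bg[2L, ]], mod[2L, ]), stringsAsFactors = FALSE)
    others <- setdiff(nodes, module)
    extra_cags <- sample(others, round(cag_frac * length(others)))
    list(edges = edges, module = module,
         seeds = module[seq_len(n_seed_genes)], extra_cags = extra_cags)
  })
  network <- interaction_network(out$edges, nodes = nodes)
  cags <- setdiff(union(out$module, out$extra_cags), out$seeds)
  catalog <- gene_set_catalog(
    seed_set = out$seeds, cag_set = cags,
    non_cag_set = setdiff(nodes, union(cags, out$seeds)))
  truth <- structure(list(planted_module = out$module, params = params),
                     class = "synthetic_truth")
  list(network = network, catalog = catalog, truth = truth)
}

#' Generate multi-species interactomes with planted conserved triads
#'
#' Each planted triad is a triangle over three ortholog groups,
#' instantiated as protein interactions in every species; background edges
#' between random group pairs are added independently per species at rate
#' `edge_noise`. Per-species ortholog maps assign `proteins_per_group`
#' proteins to each group.
#'
#' @param n_groups number of ortholog groups (default 30).
#' @param n_species number of species, the first being `"human"`
#'   (default 3, from human/mouse/yeast/fly/worm).
#' @param proteins_per_group proteins per group per species (default 2).
#' @param n_triads number of planted triads over disjoint groups
#'   (default 1); ignored when `planted_triads` is given.
#' @param planted_triads optional list of character triples of group
#'   identifiers.
#' @param edge_noise probability of a background edge per unordered group
#'   pair per species (default 0.05).
#' @param seed integer seed.
#' @return A list with `networks` (named list of protein graphs), `maps`
#'   (named list of [ortholog_map()]s), `seed_set` (human proteins of the
#'   first group of each triad) and `truth` (`planted_triads`, `params`).
#' @export
generate_multi_species <- function(n_groups = 30L, n_species = 3L,
                                   proteins_per_group = 2L, n_triads = 1L,
                                   planted_triads = NULL,
                                   edge_noise = 0.05, seed = 1L) {
  pool <- c("human", "mouse", "yeast", "fly", "worm")
  if (n_species < 2L || n_species > length(pool)) {
    stop("n_species must be between 2 and 5")
  }
  species <- pool[seq_len(n_species)]
  groups <- sprintf("OG%03d", seq_len(n_groups))
  if (is.null(planted_triads)) {
    if (3L * n_triads > n_groups) stop("too many triads for n_groups")
    planted_triads <- lapply(seq_len(n_triads), function(i) {
      groups[(3L * (i - 1L) + 1L):(3L * i)]
    })
  }
  if (!all(unlist(planted_triads) %in% groups)) {
    stop("planted triads reference unknown groups")
  }
  params <- list(n_groups = n_groups, n_species = n_species,
                 proteins_per_group = proteins_per_group,
                 n_triads = length(planted_triads),
                 edge_noise = edge_noise, seed = seed)
  res <- with_seed(seed, {
    networks <- list(); maps <- list()
    for (sp in species) {
      prot <- outer(groups, seq_len(proteins_per_group),
                    function(g, i) paste0(sp, "_", g, "_p", i))
      map <- stats::setNames(rep(groups, times = proteins_per_group),
                             as.vector(prot))
      first_of <- function(g) paste0(sp, "_", g, "_p1")
      ea <- character(0); eb <- character(0)
      for (tri in planted_triads) {
        pr <- vapply(tri, first_of, character(1))
        ea <- c(ea, pr[1L], pr[1L], pr[2L])
        eb <- c(eb, pr[2L], pr[3L], pr[3L])
      }
      if (edge_noise > 0) {
        gp <- utils::combn(groups, 2L)
        pick <- stats::runif(ncol(gp)) < edge_noise
        for (j in which(pick)) {
          pa <- sample(names(map)[map == gp[1L, j]], 1L)
          pb <- sample(names(map)[map == gp[2L, j]], 1L)
          ea <- c(ea, pa); eb <- c(eb, pb)
        }
      }
      networks[[sp]] <- interaction_network(
        data.frame(from = ea, to = eb, stringsAsFactors = FALSE),
        nodes = as.vector(prot))
      maps[[sp]] <- ortholog_map(map, sp)
    }
    list(networks = networks, maps = maps)
  })
  target <- species[1L]
  seed_set <- vapply(planted_triads, function(tri) {
    paste0(target, "_", tri[1L], "_p1")
  }, character(1))
  truth <- structure(list(planted_triads = planted_triads,
                          params = params),
                     class = "synthetic_truth")
  list(networks = res$networks, maps = res$maps, seed_set = seed_set,
       truth = truth)
}

#' Generate a synthetic copy-number/mutation alteration table
#'
#' Binomial case counts per gene, cancer type and event class.
#'
#' @param genes character vector of gene identifiers.
#' @param cancer_types character vector of cancer types.
#' @param rates named numeric vector of per-event-class alteration rates
#'   in \[0, 1\] (e.g. `c(gain = 0.1, loss = 0.05)`).
#' @param total_cases cases assayed per cancer type (default 100).
#' @param seed integer seed.
#' @return An [alteration_table()].
#' @export
generate_alteration_table <- function(genes, cancer_types,
                                      rates = c(gain = 0.1, loss = 0.05),
                                      total_cases = 100L, seed = 1L) {
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
  grid <- expand.grid(gene = genes, cancer_type = cancer_types,
                      event_class = names(rates),
                      stringsAsFactors = FALSE)
  grid$case_count <- with_seed(seed, stats::rbinom(
    nrow(grid), total_cases, rates[grid$event_class]))
  grid$total_cases <- total_cases
  alteration_table(grid)
}

#' Write or read a synthetic-truth manifest
#'
#' The manifest records the generator parameters (including the seed), so
#' regeneration from the manifest reproduces the data exactly.
#'
#' @param truth a `synthetic_truth` object.
#' @param path JSON output path.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(truth)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(obj, class = "synthetic_truth")
}
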