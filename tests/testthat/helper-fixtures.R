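# in-code fixtures shared across test files

# tiny 3-gene x 4-sample dataset with known values
toy_dataset <- function() {
  m <- matrix(c(1, 2, 3, 4,
                5, 6, 7, 8,
                2, 2, 2, 2), nrow = 3, byrow = TRUE,
              dimnames = list(c("gA", "gB", "gC"),
                              c("s1", "s2", "s3", "s4")))
  expression_dataset(m, c("cancer", "cancer", "normal", "normal"),
                     dataset_id = "toy", cancer_type = "toytype")
}

write_toy_expression <- function(dir = withr::local_tempdir(
                                   .local_envir = parent.frame())) {
  mp <- file.path(dir, "expr.tsv")
  lp <- file.path(dir, "labels.tsv")
  write_expression_tsv(toy_dataset(), mp, lp)
  list(matrix = mp, labels = lp)
}

# undirected graph from a two-column character matrix
graph_from_pairs <- function(...) {
  pairs <- matrix(c(...), ncol = 2, byrow = TRUE)
  interaction_network(data.frame(from = pairs[, 1], to = pairs[, 2],
                                 stringsAsFactors = FALSE))
}

# random connected-ish weighted graph for walk tests
random_weighted_graph <- function(n, p = 0.06, seed = 1) {
  g <- degnet:::with_seed(seed, {
    g <- igraph::sample_gnp(n, p)
    igraph::V(g)$name <- sprintf("n%03d", seq_len(n))
    igraph::set_edge_attr(g, "weight",
                          value = stats::runif(igraph::ecount(g)))
  })
  g
}

# a hand-scored cancer_type_summary from explicit vectors
manual_summary <- function(genes, p, lfc, type) {
  structure(data.frame(gene = genes, p_representative = p,
                       lfc_representative = lfc,
                       n_datasets = 1L, stringsAsFactors = FALSE),
            cancer_type = type,
            class = c("cancer_type_summary", "data.frame"))
}

# brute-force oracle: all connected induced k-subgraphs of a graph,
# canonical keys, independent of the ESU implementation
brute_force_motif_keys <- function(g, k) {
  ids <- igraph::V(g)$name
  if (length(ids) < k) return(character(0))
  keys <- character(0)
  el <- igraph::as_edgelist(g)
  ekeys <- paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]), sep = "\r")
  for (sub in utils::combn(sort(ids), k, simplify = FALSE)) {
    pairs <- utils::combn(sub, 2)
    present <- paste(pmin(pairs[1, ], pairs[2, ]),
                     pmax(pairs[1, ], pairs[2, ]), sep = "\r") %in% ekeys
    if (!any(present)) next
    sg <- igraph::induced_subgraph(g, sub)
    if (!igraph::is_connected(sg)) next
    ea <- pmin(pairs[1, present], pairs[2, present])
    eb <- pmax(pairs[1, present], pairs[2, present])
    o <- order(ea, eb)
    keys <- c(keys, paste0(paste(sub, collapse = ","), "|",
                           paste(paste(ea[o], eb[o], sep = "-"),
                                 collapse = ";")))
  }
  sort(keys)
}

# brute-force oracle for the full conserved-motif pipeline: enumerate all
# k-subsets of target proteins directly, map to groups, re-derive the
# collapsed group pattern by set operations, and apply the conservation,
# interactome and seed tests
brute_force_conserved <- function(networks, maps, seed_set,
                                  target = "human", k = 3,
                                  min_species = 2) {
  # collapsed group edge set per species, by direct set operations
  group_edges <- function(g, map) {
    el <- igraph::as_edgelist(g)
    keep <- el[, 1] %in% names(map$map) & el[, 2] %in% names(map$map)
    ga <- unname(map$map[el[keep, 1]]); gb <- unname(map$map[el[keep, 2]])
    ok <- ga != gb
    unique(paste(pmin(ga[ok], gb[ok]), pmax(ga[ok], gb[ok]), sep = "\r"))
  }
  ge <- lapply(names(networks), function(sp) {
    group_edges(networks[[sp]], maps[[sp]])
  })
  names(ge) <- names(networks)
  tmap <- maps[[target]]$map
  tnet <- networks[[target]]
  el <- igraph::as_edgelist(tnet)
  pkeys <- paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]), sep = "\r")
  prots <- intersect(igraph::V(tnet)$name, names(tmap))
  out <- character(0)
  if (length(prots) < k) return(out)
  for (S in utils::combn(sort(prots), k, simplify = FALSE)) {
    gs <- unname(tmap[S])
    if (length(unique(gs)) != k) next
    # group pattern of these k groups in each species' collapsed network
    gp <- utils::combn(sort(unique(gs)), 2)
    pat_in <- function(edges) {
      paste(gp[1, ], gp[2, ], sep = "\r") %in% edges
    }
    pat_t <- pat_in(ge[[target]])
    if (!any(pat_t)) next
    # connectivity of the group pattern
    sg <- igraph::graph_from_edgelist(
      cbind(gp[1, pat_t], gp[2, pat_t]), directed = FALSE)
    if (igraph::vcount(sg) != k || !igraph::is_connected(sg)) next
    # conservation: identical pattern over the same groups elsewhere
    support <- sum(vapply(ge, function(e) identical(pat_in(e), pat_t),
                          logical(1)))
    if (support < min_species) next
    # every group edge must be realized by this instantiation
    g_of <- stats::setNames(S, gs)
    pa <- g_of[gp[1, pat_t]]; pb <- g_of[gp[2, pat_t]]
    if (!all(paste(pmin(pa, pb), pmax(pa, pb), sep = "\r") %in% pkeys)) next
    if (!any(S %in% seed_set)) next
    out <- c(out, paste(S, collapse = ","))
  }
  sort(out)
}
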