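#' Collapse a protein interaction network to ortholog groups
#'
#' Maps every protein node to its ortholog group and contracts the
#' network: an edge between two groups exists when any protein edge maps
#' across them. Self-loops (from many-to-one mapping) and duplicate edges
#' are removed; unmapped proteins are dropped with a warning.
#'
#' @param network an undirected [igraph::graph] over proteins.
#' @param map an [ortholog_map()] for the network's species.
#' @return An object of class `group_network` with fields `species` and
#'   `graph` (simple undirected [igraph::graph] over group identifiers).
#' @export
collapse_to_groups <- function(network, map) {
  nodes <- igraph::V(network)$name
  mapped <- intersect(nodes, names(map$map))
  if (length(mapped) == 0L) {
    stop("no network node is covered by the ortholog map")
  }
  if (length(mapped) < length(nodes)) {
    warning(sprintf("dropped %d unmapped protein(s)",
                    length(nodes) - length(mapped)))
  }
  groups <- unique(unname(map$map[mapped]))
  el <- igraph::as_edgelist(network)
  keep <- el[, 1L] %in% mapped & el[, 2L] %in% mapped
  ga <- unname(map$map[el[keep, 1L]])
  gb <- unname(map$map[el[keep, 2L]])
  not_self <- ga != gb
  edges <- data.frame(from = ga[not_self], to = gb[not_self],
                      stringsAsFactors = FALSE)
  g <- interaction_network(edges, nodes = groups)
  structure(list(species = map$species, graph = g),
            class = "group_network")
}

# adjacency list keyed by vertex index, sorted
adj_list <- function(g) {
  lapply(igraph::as_adj_list(g), function(v) sort(as.integer(v)))
}

#' Enumerate connected induced subgraphs (motifs) of size k
#'
#' Exact enumeration by the ESU algorithm. Each motif is canonicalized by
#' its sorted node identifiers plus a canonical edge encoding, and labelled
#' with its isomorphism class (for k = 3: `"path"` or `"triangle"`; other
#' sizes use the sorted degree sequence, which is discriminating for
#' k <= 4).
#'
#' @param gnet a `group_network` or [igraph::graph].
#' @param k motif size, 2 to 4 (default 3).
#' @return A named list of `group_motif` objects keyed by canonical form;
#'   each has fields `groups` (sorted identifiers), `edges` (data frame
#'   `a`, `b`), `class_label`, `key`.
#' @export
enumerate_motifs <- function(gnet, k = 3L) {
  if (k < 2L || k > 4L) stop("motif size k must be between 2 and 4")
  g <- if (inherits(gnet, "group_network")) gnet$graph else gnet
  n <- igraph::vcount(g)
  out <- list()
  if (n < k) return(out)
  ids <- igraph::V(g)$name
  adj <- adj_list(g)
  record <- function(sub) {
    m <- make_group_motif(ids[sub], adj, sub)
    out[[m$key]] <<- m
  }
  extend <- function(sub, ext, v) {
    if (length(sub) == k) {
      record(sub)
      return(invisible(NULL))
    }
    while (length(ext) > 0L) {
      w <- ext[1L]
      ext <- ext[-1L]
      # exclusive neighborhood of w: neighbors > v not already reachable
      excl <- setdiff(adj[[w]][adj[[w]] > v],
                      c(sub, unlist(adj[sub], use.names = FALSE)))
      extend(c(sub, w), union(ext, excl), v)
    }
  }
  for (v in seq_len(n)) {
    ext0 <- adj[[v]][adj[[v]] > v]
    if (k == 1L) record(v) else extend(v, ext0, v)
  }
  out
}

# build a canonical group_motif from vertex indices
make_group_motif <- function(node_ids, adj, sub) {
  o <- order(node_ids)
  node_ids <- node_ids[o]
  sub <- sub[o]
  ea <- character(0); eb <- character(0)
  for (i in seq_along(sub)) {
    for (j in seq_along(sub)) {
      if (i < j && sub[j] %in% adj[[sub[i]]]) {
        ea <- c(ea, node_ids[i]); eb <- c(eb, node_ids[j])
      }
    }
  }
  structure(list(groups = node_ids,
                 edges = data.frame(a = ea, b = eb,
                                    stringsAsFactors = FALSE),
                 class_label = motif_class_label(node_ids, ea, eb),
                 key = paste0(paste(node_ids, collapse = ","), "|",
                              paste(paste(ea, eb, sep = "-"),
                                    collapse = ";"))),
            class = "group_motif")
}

motif_class_label <- function(nodes, ea, eb) {
  k <- length(nodes)
  degs <- sort(table(factor(c(ea, eb), levels = nodes)))
  if (k == 2L) return("edge")
  if (k == 3L) return(if (length(ea) == 3L) "triangle" else "path")
  paste0("k", k, ":", paste(degs, collapse = ""))
}

#' Cross-species conserved motifs
#'
#' A group-level motif is conserved when the same ortholog groups with the
#' same edge pattern occur in the target species (human) and in at least
#' `min_species - 1` other species.
#'
#' @param per_species named list (by species) of motif sets from
#'   [enumerate_motifs()].
#' @param target target species name (default `"human"`).
#' @param min_species minimum number of supporting species including the
#'   target (default 2).
#' @return Named list of `group_motif` objects with a `species_support`
#'   field added.
#' @export
conserved_motifs <- function(per_species, target = "human",
                             min_species = 2L) {
  if (length(per_species) < 2L) stop("at least two species required")
  if (!target %in% names(per_species)) {
    stop(sprintf("target species '%s' absent from input", target))
  }
  out <- list()
  for (key in names(per_species[[target]])) {
    support <- names(per_species)[vapply(per_species, function(ms) {
      key %in% names(ms)
    }, logical(1))]
    if (length(support) >= min_species) {
      m <- per_species[[target]][[key]]
      m$species_support <- sort(support)
      out[[key]] <- m
    }
  }
  out
}

#' Expand a group-level motif to concrete protein motifs
#'
#' Takes the Cartesian product of the target species' member proteins per
#' group and keeps the instantiations in which every motif edge exists as
#' an interaction in the real interactome.
#'
#' @param motif a `group_motif`.
#' @param map the target species' [ortholog_map()].
#' @param interactome the target species' protein [igraph::graph].
#' @return A list of `protein_motif` objects (`proteins`, `edges`,
#'   `groups`, `class_label`, `contains_seed` = NA until filtered); empty
#'   when some group has no member protein or no instantiation survives.
#' @export
expand_to_proteins <- function(motif, map, interactome) {
  members <- lapply(motif$groups, function(g) {
    names(map$map)[map$map == g]
  })
  if (any(lengths(members) == 0L)) {
    warning(sprintf("group(s) with no protein in species '%s': %s",
                    map$species,
                    paste(motif$groups[lengths(members) == 0L],
                          collapse = ", ")))
    return(list())
  }
  edge_keys <- {
    el <- igraph::as_edgelist(interactome)
    paste(pmin(el[, 1L], el[, 2L]), pmax(el[, 1L], el[, 2L]), sep = "\r")
  }
  combos <- expand.grid(members, stringsAsFactors = FALSE)
  gi_a <- match(motif$edges$a, motif$groups)
  gi_b <- match(motif$edges$b, motif$groups)
  out <- list()
  for (r in seq_len(nrow(combos))) {
    prots <- as.character(combos[r, ])
    if (anyDuplicated(prots)) next
    pa <- prots[gi_a]; pb <- prots[gi_b]
    keys <- paste(pmin(pa, pb), pmax(pa, pb), sep = "\r")
    if (!all(keys %in% edge_keys)) next
    o <- order(prots)
    out[[length(out) + 1L]] <- structure(
      list(proteins = prots[o],
           edges = data.frame(a = pmin(pa, pb), b = pmax(pa, pb),
                              stringsAsFactors = FALSE),
           groups = motif$groups, class_label = motif$class_label,
           species_support = motif$species_support,
           contains_seed = NA),
      class = "protein_motif")
  }
  out
}

#' Keep protein motifs containing at least one seed gene
#'
#' Final filtering step of the conserved-motif pipeline: motifs without an
#' ARS/AIMP (seed) member are dropped and duplicate instantiations (same
#' protein set and edge pattern) are collapsed.
#'
#' @param motifs list of `protein_motif` objects.
#' @param seed_set character vector of seed protein identifiers.
#' @return De-duplicated list of `protein_motif`s with
#'   `contains_seed = TRUE`.
#' @export
filter_seed_motifs <- function(motifs, seed_set) {
  keys <- character(0)
  out <- list()
  for (m in motifs) {
    if (!any(m$proteins %in% seed_set)) next
    key <- paste0(paste(m$proteins, collapse = ","), "|",
                  paste(paste(m$edges$a, m$edges$b, sep = "-"),
                        collapse = ";"))
    if (key %in% keys) next
    keys <- c(keys, key)
    m$contains_seed <- TRUE
    out[[length(out) + 1L]] <- m
  }
  out
}

#' Full cross-species conserved-motif pipeline
#'
#' Collapses each species' protein network to ortholog groups, enumerates
#' size-k connected motifs per species, intersects them across species
#' (anchored at the target species), expands the conserved group motifs
#' back to concrete protein interactions in the target interactome, and
#' keeps the motifs containing at least one seed gene.
#'
#' @param networks named list (by species) of protein [igraph::graph]s.
#' @param maps named list (by species) of [ortholog_map()]s.
#' @param seed_set character vector of seed protein identifiers in the
#'   target species.
#' @param target target species (default `"human"`).
#' @param k motif size (default 3).
#' @param min_species minimum supporting species including the target.
#' @return List of `protein_motif` objects.
#' @export
find_conserved_motifs <- function(networks, maps, seed_set,
                                  target = "human", k = 3L,
                                  min_species = 2L) {
  if (!target %in% names(networks)) {
    stop(sprintf("target species '%s' absent from networks", target))
  }
  per_species <- lapply(names(networks), function(sp) {
    enumerate_motifs(collapse_to_groups(networks[[sp]], maps[[sp]]), k = k)
  })
  names(per_species) <- names(networks)
  conserved <- conserved_motifs(per_species, target = target,
                                min_species = min_species)
  expanded <- unlist(lapply(conserved, expand_to_proteins,
                            map = maps[[target]],
                            interactome = networks[[target]]),
                     recursive = FALSE)
  filter_seed_motifs(expanded %||% list(), seed_set)
}

#' Write protein motifs to a TSV table
#' @param motifs list of `protein_motif`s.
#' @param path output path.
#' @export
write_motif_table <- function(motifs, path) {
  rows <- lapply(motifs, function(m) {
    data.frame(proteins = paste(m$proteins, collapse = ","),
               groups = paste(m$groups, collapse = ","),
               edges = paste(paste(m$edges$a, m$edges$b, sep = "-"),
                             collapse = ";"),
               class = m$class_label,
               species_support = paste(m$species_support %||% "",
                                       collapse = ","),
               contains_seed = isTRUE(m$contains_seed),
               stringsAsFactors = FALSE)
  })
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(proteins = character(0), groups = character(0),
               edges = character(0), class = character(0),
               species_support = character(0),
               contains_seed = logical(0))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(df)
}
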