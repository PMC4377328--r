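#' Convert a P value to a significance Z value
#'
#' Z = Phi^{-1}(1 - p): the inverse standard normal cumulative distribution
#' of the complementary P, so smaller P gives larger Z and P > 0.5 gives a
#' negative Z. P is clamped to \[1e-15, 1 - 1e-15\].
#'
#' @param p numeric vector of P values in (0, 1].
#' @return Numeric vector of Z values.
#' @export
p_to_z <- function(p) {
  p <- pmin(pmax(p, 1e-15), 1 - 1e-15)
  stats::qnorm(1 - p)
}

#' Co-association score of an interaction edge
#'
#' The fraction of cancer types in which both endpoint genes are
#' differentially expressed. Under the default `"measured"` denominator,
#' cancer types where either endpoint lacks expression data are dropped
#' from the denominator; `"total"` uses the full number of types in scope.
#'
#' @param de_a,de_b logical vectors of per-cancer-type DE indicators for
#'   the two endpoints (NA = no data in that type), equal length >= 1.
#' @param denominator `"measured"` or `"total"`.
#' @return A number in \[0, 1\].
#' @export
co_association_score <- function(de_a, de_b,
                                 denominator = c("measured", "total")) {
  denominator <- match.arg(denominator)
  if (length(de_a) != length(de_b) || length(de_a) == 0L) {
    stop("DE indicator vectors must be nonempty and of equal length")
  }
  measured <- !is.na(de_a) & !is.na(de_b)
  num <- sum(de_a & de_b & measured, na.rm = TRUE)
  den <- if (denominator == "measured") sum(measured) else length(de_a)
  if (den == 0L) {
    warning("no cancer type with data for both endpoints; score set to 0")
    return(0)
  }
  num / den
}

#' Deregulation score of a node in a network model
#'
#' For each cancer type, the Z values of the node's direct interactors in
#' the model are summed (the node's own Z is excluded); the score is the
#' average of these per-type sums over cancer types. With the default
#' `"measured"` denominator the average runs over the types in which at
#' least one interactor has a defined Z; `"total"` averages over all types
#' in scope (missing Z contributes 0). Isolated nodes score 0.
#'
#' @param node a node identifier present in the model.
#' @param model a [build_network_model()] result.
#' @param denominator `"measured"` or `"total"`; defaults to the model's.
#' @return A single number.
#' @export
deregulation_score <- function(node, model,
                               denominator = model$denominator) {
  if (!node %in% model$nodes$id) {
    stop(sprintf("node '%s' is not in the model", node))
  }
  nb <- igraph::neighbors(model$graph, node)$name
  if (length(nb) == 0L) return(0)
  zs <- model$z[nb, , drop = FALSE]
  per_type <- colSums(zs, na.rm = TRUE)
  has_data <- colSums(!is.na(zs)) > 0L
  if (denominator == "measured") {
    if (!any(has_data)) return(0)
    mean(per_type[has_data])
  } else {
    mean(per_type)
  }
}

#' Build the seed-gene cancer network model with node and edge scores
#'
#' The model contains the seed genes present in the interactome plus their
#' first-neighbor cancer-associated genes, with the interactome edges
#' induced on this node set. Each node carries one Z value per cancer type,
#' converted from the representative P values; each node gets a
#' deregulation score and each edge a co-association score.
#'
#' @param interactome an undirected [igraph::graph].
#' @param catalog a [gene_set_catalog()]; `seed_set` anchors the model,
#'   `cag_set` is the allowed first-neighbor universe.
#' @param summaries list of [summarize_cancer_type()] results, one per
#'   cancer type (names taken from their `cancer_type` attributes when the
#'   list is unnamed).
#' @param alpha significance level for the per-type DE indicator
#'   (representative P <= alpha; default 0.05).
#' @param denominator `"measured"` (default) or `"total"`; see
#'   [co_association_score()] and [deregulation_score()].
#' @return An object of class `network_model`: fields `graph` (edge
#'   attribute `weight` = co-association score), `nodes` (data frame `id`,
#'   `role`, `deregulation_score`), `edges` (data frame `a`, `b`,
#'   `co_association_score`), `z` and `de` (node-by-type matrices),
#'   `types`, `alpha`, `denominator`.
#' @export
build_network_model <- function(interactome, catalog, summaries,
                                alpha = 0.05,
                                denominator = c("measured", "total")) {
  denominator <- match.arg(denominator)
  if (is.null(names(summaries)) || any(!nzchar(names(summaries)))) {
    names(summaries) <- vapply(summaries, function(s) {
      as.character(attr(s, "cancer_type") %||% "type")
    }, character(1))
  }
  types <- names(summaries)
  net_nodes <- igraph::V(interactome)$name
  seed <- intersect(catalog$seed_set, net_nodes)
  if (length(seed) == 0L) {
    stop("no seed gene is present in the interactome")
  }
  nb <- neighbors_of_set(interactome, seed, restrict = catalog$cag_set)
  ids <- c(seed, nb$first)
  g <- igraph::induced_subgraph(interactome, ids)
  ids <- igraph::V(g)$name
  z <- matrix(NA_real_, nrow = length(ids), ncol = length(types),
              dimnames = list(ids, types))
  de <- matrix(NA, nrow = length(ids), ncol = length(types),
               dimnames = list(ids, types))
  for (ty in types) {
    s <- summaries[[ty]]
    i <- match(ids, s$gene)
    z[, ty] <- p_to_z(s$p_representative[i])
    de[, ty] <- s$p_representative[i] <= alpha
  }
  model <- list(graph = g, z = z, de = de, types = types, alpha = alpha,
                denominator = denominator)
  model$nodes <- data.frame(
    id = ids,
    role = ifelse(ids %in% seed, "seed", "first_neighbor"),
    stringsAsFactors = FALSE)
  class(model) <- "network_model"
  model$nodes$deregulation_score <- vapply(
    ids, deregulation_score, numeric(1), model = model,
    denominator = denominator)
  el <- igraph::as_edgelist(g)
  score <- if (nrow(el) > 0L) {
    vapply(seq_len(nrow(el)), function(k) {
      co_association_score(de[el[k, 1L], ], de[el[k, 2L], ],
                           denominator = denominator)
    }, numeric(1))
  } else numeric(0)
  model$edges <- data.frame(a = el[, 1L], b = el[, 2L],
                            co_association_score = score,
                            stringsAsFactors = FALSE)
  if (nrow(el) > 0L) {
    model$graph <- igraph::set_edge_attr(model$graph, "weight",
                                         value = score)
  }
  model
}

#' @export
print.network_model <- function(x, ...) {
  cat(sprintf(
    "<network_model: %d nodes (%d seed), %d edges, %d cancer types>\n",
    nrow(x$nodes), sum(x$nodes$role == "seed"), nrow(x$edges),
    length(x$types)))
  invisible(x)
}

#' Write a network model's node and edge tables to TSV
#'
#' @param model a `network_model`.
#' @param node_path,edge_path output paths.
#' @export
write_network_model <- function(model, node_path, edge_path) {
  utils::write.table(model$nodes, node_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(model$edges, edge_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(model)
}
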