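#' Column-stochastic transition matrix of a scored network
#'
#' Edge weights are the co-association scores floored at `weight_floor` so
#' zero-scored edges remain traversable; each column is normalized to sum
#' to one. The walk is restricted to the largest connected component.
#'
#' @param model a [build_network_model()] result or an [igraph::graph]
#'   (edge attribute `weight` used when present, else unweighted).
#' @param weight_floor positive lower bound applied to edge weights
#'   (default 0.01).
#' @param restrict_lcc restrict to the largest connected component
#'   (default TRUE).
#' @return A dense column-stochastic matrix with node identifiers as
#'   dimnames.
#' @export
build_transition_matrix <- function(model, weight_floor = 0.01,
                                    restrict_lcc = TRUE) {
  g <- if (inherits(model, "network_model")) model$graph else model
  if (igraph::vcount(g) == 0L) stop("empty model")
  if (weight_floor <= 0) stop("weight_floor must be positive")
  if (restrict_lcc) {
    comp <- igraph::components(g)
    keep <- which(comp$membership == which.max(comp$csize))
    g <- igraph::induced_subgraph(g, keep)
  }
  ids <- igraph::V(g)$name
  n <- length(ids)
  W <- matrix(0, n, n, dimnames = list(ids, ids))
  el <- igraph::as_edgelist(g, names = FALSE)
  if (nrow(el) > 0L) {
    w <- igraph::edge_attr(g, "weight")
    if (is.null(w)) w <- rep(1, nrow(el))
    w <- pmax(w, weight_floor)
    W[cbind(el[, 2L], el[, 1L])] <- w
    W[cbind(el[, 1L], el[, 2L])] <- w
  }
  cs <- colSums(W)
  zero <- cs == 0
  if (any(zero)) {
    # isolated nodes: walker stays put
    W[cbind(which(zero), which(zero))] <- 1
    cs[zero] <- 1
  }
  sweep(W, 2L, cs, "/")
}

#' Random walk with restart
#'
#' Iterates p <- c W p + (1 - c) p0 until the L1 norm of the change falls
#' below `tol`. `continue_prob` is the probability of continuing the walk
#' at each step (0.75, i.e. restart probability 0.25).
#'
#' @param W column-stochastic transition matrix.
#' @param p0 initial/restart distribution summing to 1; default uniform
#'   over all nodes.
#' @param continue_prob walk continuation probability in (0, 1)
#'   (default 0.75).
#' @param tol L1 convergence tolerance (default 1e-6).
#' @param max_iter iteration cap (default 10000).
#' @return An object of class `rwr_result`: `p_inf` (named steady-state
#'   probabilities), `iterations`, `residual`, `residuals` (per-iteration
#'   L1 changes) and `prob_sums` (per-iteration probability totals, always
#'   1 up to rounding: the update conserves mass).
#' @export
rwr <- function(W, p0 = NULL, continue_prob = 0.75, tol = 1e-6,
                max_iter = 10000L) {
  n <- ncol(W)
  if (is.null(p0)) p0 <- rep(1 / n, n)
  if (abs(sum(p0) - 1) > 1e-9) stop("p0 must sum to 1")
  if (continue_prob <= 0 || continue_prob >= 1) {
    stop("continue_prob must be in (0, 1)")
  }
  p <- p0
  restart <- (1 - continue_prob) * p0
  residuals <- numeric(0)
  prob_sums <- numeric(0)
  for (it in seq_len(max_iter)) {
    p_new <- continue_prob * as.vector(W %*% p) + restart
    res <- sum(abs(p_new - p))
    residuals <- c(residuals, res)
    prob_sums <- c(prob_sums, sum(p_new))
    p <- p_new
    if (res < tol) {
      names(p) <- colnames(W)
      return(structure(list(p_inf = p, iterations = it, residual = res,
                            residuals = residuals, prob_sums = prob_sums),
                       class = "rwr_result"))
    }
  }
  stop(sprintf("random walk did not converge in %d iterations (residual %.3g)",
               max_iter, res))
}

#' Direct linear-system solution of the random walk with restart
#'
#' Closed form p = (1 - c) (I - c W)^{-1} p0, used as an independent check
#' of the iterative solver.
#'
#' @inheritParams rwr
#' @return Named numeric vector of steady-state probabilities.
#' @export
rwr_direct <- function(W, p0 = NULL, continue_prob = 0.75) {
  n <- ncol(W)
  if (is.null(p0)) p0 <- rep(1 / n, n)
  p <- (1 - continue_prob) * solve(diag(n) - continue_prob * W, p0)
  stats::setNames(as.vector(p), colnames(W))
}

#' Degree-preserving randomization of a network
#'
#' Rewires edges by double-edge swaps (10 |E| attempted swaps), preserving
#' every node's degree; edge weights, if present, are randomly permuted
#' onto the rewired edges.
#'
#' @param g an [igraph::graph].
#' @return A rewired graph with the same degree sequence.
#' @export
randomize_edges <- function(g) {
  m <- igraph::ecount(g)
  if (m < 2L) stop("cannot rewire a graph with fewer than 2 edges")
  w <- igraph::edge_attr(g, "weight")
  gr <- igraph::rewire(g, igraph::keeping_degseq(loops = FALSE,
                                                 niter = 10L * m))
  if (!is.null(w)) {
    gr <- igraph::set_edge_attr(gr, "weight", value = sample(w))
  }
  gr
}

#' Empirical node significance of walk probabilities via randomized networks
#'
#' Runs the random walk on `n_rand` degree-preserving randomizations of the
#' model network (same uniform restart vector) and compares each real
#' node's steady-state probability to a pooled null. Because walk
#' probability correlates strongly with degree, nodes are binned into
#' degree quintiles by default and each node is compared to the null pool
#' of its own stratum. P values use a plus-one pseudocount and a
#' right-sided test, so they are never zero.
#'
#' @param model a `network_model` or [igraph::graph].
#' @param n_rand number of randomized networks (>= 100; default 1000).
#' @param seed integer seed.
#' @param continue_prob,tol,max_iter,weight_floor passed to the walk.
#' @param stratify compare within degree quintiles (default TRUE).
#' @return An object of class `rwr_null`: data frame `nodes` with columns
#'   `id`, `degree`, `p_inf`, `p_value`, plus the observed `rwr_result`
#'   and settings.
#' @export
randomized_null_p <- function(model, n_rand = 1000L, seed = 1L,
                              continue_prob = 0.75, tol = 1e-6,
                              max_iter = 10000L, weight_floor = 0.01,
                              stratify = TRUE) {
  if (n_rand < 100L) stop("n_rand must be at least 100")
  g <- if (inherits(model, "network_model")) model$graph else model
  W <- build_transition_matrix(g, weight_floor = weight_floor,
                               restrict_lcc = FALSE)
  obs <- rwr(W, continue_prob = continue_prob, tol = tol,
             max_iter = max_iter)
  ids <- names(obs$p_inf)
  deg <- igraph::degree(g)[ids]
  if (stratify) {
    br <- unique(stats::quantile(deg, probs = seq(0, 1, 0.2)))
    stratum <- if (length(br) > 2L) {
      cut(deg, breaks = br, include.lowest = TRUE, labels = FALSE)
    } else rep(1L, length(deg))
  } else {
    stratum <- rep(1L, length(deg))
  }
  null_by_stratum <- with_seed(seed, {
    draws <- replicate(n_rand, {
      gr <- randomize_edges(g)
      Wr <- build_transition_matrix(gr, weight_floor = weight_floor,
                                    restrict_lcc = FALSE)
      rwr(Wr, continue_prob = continue_prob, tol = tol,
          max_iter = max_iter)$p_inf[ids]
    })
    split(as.vector(draws), rep(stratum, times = n_rand))
  })
  p_value <- vapply(seq_along(ids), function(i) {
    pool <- null_by_stratum[[as.character(stratum[i])]]
    (1 + sum(pool >= obs$p_inf[i])) / (1 + length(pool))
  }, numeric(1))
  nodes <- data.frame(id = ids, degree = as.integer(deg),
                      p_inf = as.vector(obs$p_inf), p_value = p_value,
                      stringsAsFactors = FALSE)
  structure(list(nodes = nodes, observed = obs, n_rand = n_rand,
                 continue_prob = continue_prob, stratify = stratify),
            class = "rwr_null")
}

#' Extract key functional modules from significant walk probabilities
#'
#' Induces the subgraph on nodes with empirical P below `alpha` and keeps
#' each connected component that contains at least one seed gene, sorted
#' by size (largest first).
#'
#' @param model a `network_model` or [igraph::graph].
#' @param node_p named numeric vector of per-node P values, or an
#'   `rwr_null` object.
#' @param alpha significance cutoff (strict: P < alpha; default 0.05).
#' @param seed_set character vector of seed gene identifiers.
#' @return A list of `key_module` objects, each with fields `nodes`,
#'   `edges` (data frame `a`, `b`), `contains_seed` (always TRUE) and
#'   `p_values`.
#' @export
extract_key_modules <- function(model, node_p, alpha = 0.05, seed_set) {
  g <- if (inherits(model, "network_model")) model$graph else model
  if (inherits(node_p, "rwr_null")) {
    node_p <- stats::setNames(node_p$nodes$p_value, node_p$nodes$id)
  }
  covered <- intersect(igraph::V(g)$name, names(node_p))
  sig <- covered[node_p[covered] < alpha]
  if (length(sig) == 0L) return(list())
  sub <- igraph::induced_subgraph(g, sig)
  comp <- igraph::components(sub)
  mods <- lapply(seq_len(comp$no), function(k) {
    members <- igraph::V(sub)$name[comp$membership == k]
    if (!any(members %in% seed_set)) return(NULL)
    mg <- igraph::induced_subgraph(sub, members)
    el <- igraph::as_edgelist(mg)
    structure(list(nodes = members,
                   edges = data.frame(a = el[, 1L], b = el[, 2L],
                                      stringsAsFactors = FALSE),
                   contains_seed = TRUE,
                   p_values = node_p[members]),
              class = "key_module")
  })
  mods <- Filter(Negate(is.null), mods)
  mods[order(vapply(mods, function(m) length(m$nodes), numeric(1)),
             decreasing = TRUE)]
}

#' @export
print.key_module <- function(x, ...) {
  cat(sprintf("<key_module: %d nodes, %d edges>\n", length(x$nodes),
              nrow(x$edges)))
  invisible(x)
}
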