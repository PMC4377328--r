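test_that("group collapsing removes self-loops and duplicates", {
  # identity map: isomorphic network
  g <- graph_from_pairs("A", "B", "B", "C")
  id_map <- ortholog_map(c(A = "gA", B = "gB", C = "gC"), "human")
  gn <- collapse_to_groups(g, id_map)
  expect_equal(igraph::ecount(gn$graph), 2L)
  expect_setequal(igraph::V(gn$graph)$name, c("gA", "gB", "gC"))

  # same-group edge becomes a removed self-loop
  m2 <- ortholog_map(c(A = "g1", B = "g1", C = "g2"), "human")
  gn2 <- collapse_to_groups(g, m2)
  expect_equal(igraph::ecount(gn2$graph), 1L)  # only g1-g2 survives

  # two protein edges across the same group pair collapse to one
  g3 <- graph_from_pairs("A1", "B1", "A2", "B2")
  m3 <- ortholog_map(c(A1 = "gA", A2 = "gA", B1 = "gB", B2 = "gB"),
                     "human")
  gn3 <- collapse_to_groups(g3, m3)
  expect_equal(igraph::ecount(gn3$graph), 1L)

  expect_error(collapse_to_groups(g, ortholog_map(c(Z = "g"), "x")),
               "no network node")
  expect_warning(collapse_to_groups(g, ortholog_map(
    c(A = "g1", B = "g2"), "x")), "unmapped")

  # collapsing never increases node or edge counts
  for (s in 1:4) {
    gg <- random_weighted_graph(20, p = 0.2, seed = s)
    prot <- igraph::V(gg)$name
    grp <- degnet:::with_seed(s, sample(paste0("og", 1:8), 20, TRUE))
    gn <- suppressWarnings(collapse_to_groups(
      gg, ortholog_map(setNames(grp, prot), "x")))
    expect_lte(igraph::vcount(gn$graph), igraph::vcount(gg))
    expect_lte(igraph::ecount(gn$graph), igraph::ecount(gg))
  }
})

test_that("motif enumeration matches brute force and labels classes", {
  tri <- graph_from_pairs("x", "y", "y", "z", "x", "z")
  m <- enumerate_motifs(tri, k = 3)
  expect_length(m, 1L)
  expect_equal(m[[1]]$class_label, "triangle")

  p4 <- graph_from_pairs("a", "b", "b", "c", "c", "d")
  m2 <- enumerate_motifs(p4, k = 3)
  expect_length(m2, 2L)
  expect_true(all(vapply(m2, `[[`, character(1), "class_label") ==
                  "path"))

  empty <- interaction_network(data.frame(from = character(0),
                                          to = character(0)),
                               nodes = c("a", "b", "c"))
  expect_length(enumerate_motifs(empty, k = 3), 0L)
  expect_error(enumerate_motifs(tri, k = 5), "between 2 and 4")

  # ESU equals exhaustive subset enumeration on random graphs, k = 2..4
  for (s in 1:5) {
    g <- random_weighted_graph(11, p = 0.25, seed = s + 20)
    for (k in 2:4) {
      expect_equal(sort(names(enumerate_motifs(g, k = k))),
                   brute_force_motif_keys(g, k))
    }
  }
})

test_that("conservation is anchored at the target species", {
  mk <- function(...) enumerate_motifs(graph_from_pairs(...), k = 3)
  human <- mk("g1", "g2", "g2", "g3", "g4", "g5", "g5", "g6")
  yeast <- mk("g1", "g2", "g2", "g3")
  fly <- mk("g4", "g5", "g5", "g6")
  cons <- conserved_motifs(list(human = human, yeast = yeast, fly = fly))
  expect_length(cons, 2L)
  expect_setequal(unlist(lapply(cons, function(m)
    paste(m$groups, collapse = ","))), c("g1,g2,g3", "g4,g5,g6"))
  expect_equal(cons[[1]]$species_support, c("human", "yeast"))
  # a motif in yeast+fly but not human is excluded
  y2 <- mk("g7", "g8", "g8", "g9")
  cons2 <- conserved_motifs(list(human = human, yeast = y2, fly = y2))
  expect_length(cons2, 0L)
  # disjoint motif sets
  expect_length(conserved_motifs(list(human = human, yeast = list())),
                0L)
  expect_error(conserved_motifs(list(a = human, b = yeast), "human"),
               "target")
})

test_that("group motifs expand to interactome-supported protein motifs", {
  motif <- enumerate_motifs(graph_from_pairs("G1", "G2", "G2", "G3"),
                            k = 3)[[1]]
  # singleton groups, all edges present: exactly one instantiation
  map1 <- ortholog_map(c(p1 = "G1", p2 = "G2", p3 = "G3"), "human")
  inter1 <- graph_from_pairs("p1", "p2", "p2", "p3")
  out1 <- expand_to_proteins(motif, map1, inter1)
  expect_length(out1, 1L)
  expect_setequal(out1[[1]]$proteins, c("p1", "p2", "p3"))

  # one group of size 2; only one of the two candidates has both edges
  map2 <- ortholog_map(c(p1 = "G1", p2a = "G2", p2b = "G2", p3 = "G3"),
                       "human")
  inter2 <- graph_from_pairs("p1", "p2a", "p2a", "p3", "p1", "p2b")
  out2 <- expand_to_proteins(motif, map2, inter2)
  expect_length(out2, 1L)
  expect_true("p2a" %in% out2[[1]]$proteins)

  # required edge absent everywhere -> empty
  inter3 <- graph_from_pairs("p1", "p2a", "p1", "p2b")
  expect_length(expand_to_proteins(motif, map2, inter3), 0L)

  # group without member proteins -> empty with a warning
  map4 <- ortholog_map(c(p1 = "G1", p2 = "G2"), "human")
  expect_warning(out4 <- expand_to_proteins(motif, map4, inter1), "G3")
  expect_length(out4, 0L)
})

test_that("seed filtering keeps only ARS/AIMP-containing motifs, deduped", {
  pm <- function(prots) structure(
    list(proteins = sort(prots),
         edges = data.frame(a = sort(prots)[1], b = sort(prots)[2]),
         groups = c("G1", "G2", "G3"), class_label = "path",
         contains_seed = NA), class = "protein_motif")
  motifs <- list(pm(c("KARS", "x", "y")), pm(c("a", "b", "c")),
                 pm(c("KARS", "x", "y")))
  out <- filter_seed_motifs(motifs, "KARS")
  expect_length(out, 1L)
  expect_true(out[[1]]$contains_seed)
  expect_length(filter_seed_motifs(motifs, "ZZZ"), 0L)
})

test_that("full pipeline equals the brute-force oracle and recovers triads", {
  # planted conserved triads, no background noise: exact recovery
  ms <- generate_multi_species(n_groups = 9, n_species = 3,
                               n_triads = 2, edge_noise = 0, seed = 3)
  found <- find_conserved_motifs(ms$networks, ms$maps, ms$seed_set)
  grp <- sort(vapply(found, function(m) paste(m$groups, collapse = ","),
                     character(1)))
  planted <- sort(vapply(ms$truth$planted_triads, paste,
                         character(1), collapse = ","))
  expect_equal(unique(grp), planted)

  # noisy small instances: package output equals exhaustive enumeration
  for (s in 1:4) {
    ms <- generate_multi_species(n_groups = 6, n_species = 3,
                                 proteins_per_group = 2, n_triads = 1,
                                 edge_noise = 0.25, seed = s)
    found <- suppressWarnings(find_conserved_motifs(
      ms$networks, ms$maps, seed_set = igraph::V(
        ms$networks$human)$name))
    got <- sort(vapply(found, function(m)
      paste(sort(m$proteins), collapse = ","), character(1)))
    oracle <- brute_force_conserved(
      ms$networks, ms$maps,
      seed_set = igraph::V(ms$networks$human)$name)
    expect_equal(got, oracle)
  }
})
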