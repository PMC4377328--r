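test_that("expression TSV round-trips and validates", {
  paths <- write_toy_expression()
  ds <- read_expression_tsv(paths$matrix, paths$labels,
                            dataset_id = "toy", cancer_type = "toytype")
  expect_equal(dim(ds$values), c(3L, 4L))
  expect_equal(ds$genes, c("gA", "gB", "gC"))
  expect_equal(ds$labels, c("cancer", "cancer", "normal", "normal"))
  expect_equal(ds$values, toy_dataset()$values)

  # duplicate gene id names the offender
  tf <- withr::local_tempfile()
  writeLines(c("gene\ts1\ts2", "gX\t1\t2", "gX\t3\t4"), tf)
  expect_error(read_expression_tsv(tf, paths$labels), "gX")

  # empty body
  tf2 <- withr::local_tempfile()
  writeLines("gene\ts1\ts2", tf2)
  expect_error(read_expression_tsv(tf2, paths$labels), "no genes")

  # non-numeric cell located
  tf3 <- withr::local_tempfile()
  writeLines(c("gene\ts1\ts2", "gX\t1\toops"), tf3)
  lf3 <- withr::local_tempfile()
  writeLines(c("s1\tcancer", "s2\tnormal"), lf3)
  expect_error(read_expression_tsv(tf3, lf3), "non-numeric")

  # missing label
  lf4 <- withr::local_tempfile()
  writeLines("s1\tcancer", lf4)
  expect_error(read_expression_tsv(tf, lf4), "missing a label|duplicate")
})

test_that("edge-list reading collapses duplicates and drops self-loops", {
  sif <- withr::local_tempfile()
  writeLines(c("A pp B", "B pp A"), sif)
  g <- read_edge_list(sif, dialect = "sif")
  expect_equal(igraph::ecount(g), 1L)

  loop <- withr::local_tempfile()
  writeLines("A pp A", loop)
  expect_warning(g2 <- read_edge_list(loop, dialect = "sif"),
                 "1 self-loop")
  expect_equal(igraph::ecount(g2), 0L)

  tsv <- withr::local_tempfile()
  writeLines("A\tB\t0.7", tsv)
  g3 <- read_edge_list(tsv, dialect = "tsv")
  expect_equal(igraph::E(g3)$weight, 0.7)

  bad <- withr::local_tempfile()
  writeLines(c("A\tB", "C"), bad)
  expect_error(read_edge_list(bad, dialect = "tsv"), "line 2")
})

test_that("edge count is invariant to line order and endpoint order", {
  pairs <- c("A\tB", "B\tC", "C\tD", "A\tC")
  for (perm in list(pairs, rev(pairs),
                    c("B\tA", "C\tB", "D\tC", "C\tA"))) {
    tf <- withr::local_tempfile()
    writeLines(perm, tf)
    g <- read_edge_list(tf, dialect = "tsv")
    expect_equal(igraph::ecount(g), 4L)
    expect_setequal(igraph::V(g)$name, c("A", "B", "C", "D"))
  }
})

test_that("gene-set catalog parses, validates and round-trips", {
  tf <- withr::local_tempfile()
  writeLines("seed\t.\tKARS\tGARS", tf)
  cat1 <- read_gene_sets(tf)
  expect_length(cat1$seed_set, 2L)

  tf2 <- withr::local_tempfile()
  writeLines(c("seed\t.\tKARS", "cag\t.\tX\tY", "non_cag\t.\tY\tZ"), tf2)
  expect_error(read_gene_sets(tf2), "both cag and non_cag")

  tf3 <- withr::local_tempfile()
  writeLines(character(0), tf3)
  expect_error(read_gene_sets(tf3), "seed")

  tf4 <- withr::local_tempfile()
  writeLines("cag\t.\tX", tf4)
  expect_error(read_gene_sets(tf4), "seed")

  cat2 <- gene_set_catalog(c("KARS", "GARS"), c("X", "Y"), c("Z"))
  out <- withr::local_tempfile()
  write_gene_sets(cat2, out)
  expect_equal(read_gene_sets(out), cat2)
})

test_that("neighbor tiers follow the restriction rule", {
  path <- graph_from_pairs("A", "B", "B", "C")
  nb <- neighbors_of_set(path, "A", restrict = c("B", "C"))
  expect_equal(nb$first, "B")
  expect_equal(nb$second, "C")

  tri <- graph_from_pairs("A", "B", "B", "C", "A", "C")
  nb2 <- neighbors_of_set(tri, "A", restrict = c("B", "C"))
  expect_setequal(nb2$first, c("B", "C"))
  expect_length(nb2$second, 0L)

  iso <- interaction_network(data.frame(from = "B", to = "C"),
                             nodes = c("A", "B", "C"))
  nb3 <- neighbors_of_set(iso, "A")
  expect_length(nb3$first, 0L)
  expect_length(nb3$second, 0L)

  expect_warning(nb4 <- neighbors_of_set(path, c("A", "ZZ")), "ZZ")
  expect_error(neighbors_of_set(path, "ZZ"),
               "no seed gene") |> suppressWarnings()
})

test_that("neighbor tiers are always disjoint from each other and the seed", {
  for (s in 1:5) {
    g <- random_weighted_graph(40, p = 0.1, seed = s)
    seed <- igraph::V(g)$name[1:3]
    nb <- neighbors_of_set(g, seed)
    expect_length(intersect(nb$first, nb$second), 0L)
    expect_length(intersect(nb$first, seed), 0L)
    expect_length(intersect(nb$second, seed), 0L)
  }
})

test_that("group alteration frequency is cases over group size", {
  tab <- alteration_table(data.frame(
    gene = c("g1", "g2", "g3"), cancer_type = "lung",
    event_class = "gain", case_count = c(2L, 3L, 7L),
    total_cases = 50L, stringsAsFactors = FALSE))
  grp <- sprintf("g%d", 1:10)
  expect_equal(group_alteration_frequency(tab, grp, "lung", "loss"), 0)
  expect_equal(group_alteration_frequency(tab, grp, "lung", "gain"),
               (2 + 3 + 7) / 10)
  # genes not in the table contribute zero
  expect_equal(
    group_alteration_frequency(tab, c(grp, "g99"), "lung", "gain"),
    12 / 11)
  expect_error(group_alteration_frequency(tab, character(0), "lung",
                                          "gain"), "empty")
  expect_error(alteration_table(data.frame(
    gene = "a", cancer_type = "x", event_class = "gain",
    case_count = 5L, total_cases = 3L)), "exceeds")
})
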