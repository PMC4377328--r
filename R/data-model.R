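#' Construct a validated expression dataset
#'
#' Bundles one cohort's log2 gene-by-sample intensity matrix with its
#' cancer/normal sample labels. All downstream differential testing operates
#' on this container.
#'
#' @param values numeric matrix of log2 intensities, genes in rows, samples in
#'   columns. Dimnames are taken as gene and sample identifiers when `genes`
#'   or `samples` are not given.
#' @param labels character vector of per-sample classes, each `"cancer"` or
#'   `"normal"`, in column order (or named by sample identifier).
#' @param genes,samples optional identifier vectors overriding dimnames.
#' @param dataset_id,cancer_type free-text identifiers for the cohort.
#' @return An object of class `expression_dataset` with fields `dataset_id`,
#'   `cancer_type`, `genes`, `samples`, `labels`, `values`.
#' @export
expression_dataset <- function(values, labels, genes = rownames(values),
                               samples = colnames(values),
                               dataset_id = "dataset", cancer_type = "cancer") {
  values <- as.matrix(values)
  if (is.null(genes) || is.null(samples)) {
    stop("gene and sample identifiers are required (dimnames or arguments)")
  }
  if (nrow(values) == 0L) stop("no genes: expression matrix body is empty")
  if (nrow(values) != length(genes) || ncol(values) != length(samples)) {
    stop("matrix dimensions do not match gene/sample identifier lengths")
  }
  genes <- as.character(genes)
  samples <- as.character(samples)
  dup <- genes[duplicated(genes)]
  if (length(dup) > 0L) {
    stop(sprintf("duplicate gene identifier(s): %s",
                 paste(unique(dup), collapse = ", ")))
  }
  if (!is.null(names(labels))) {
    missing <- setdiff(samples, names(labels))
    if (length(missing) > 0L) {
      stop(sprintf("sample(s) missing a label: %s",
                   paste(missing, collapse = ", ")))
    }
    labels <- labels[samples]
  }
  labels <- as.character(labels)
  if (length(labels) != length(samples)) {
    stop("labels length does not match number of samples")
  }
  if (!all(labels %in% c("cancer", "normal"))) {
    stop("labels must be 'cancer' or 'normal'")
  }
  if (!all(is.finite(values))) stop("expression values must all be finite")
  storage.mode(values) <- "double"
  dimnames(values) <- list(genes, samples)
  structure(
    list(dataset_id = dataset_id, cancer_type = cancer_type, genes = genes,
         samples = samples, labels = labels, values = values),
    class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("<expression_dataset '%s' (%s): %d genes x %d samples (%d cancer / %d normal)>\n",
              x$dataset_id, x$cancer_type, length(x$genes), length(x$samples),
              sum(x$labels == "cancer"), sum(x$labels == "normal")))
  invisible(x)
}

#' Read an expression matrix and its sample labels from TSV
#'
#' The matrix file has a header row of sample identifiers and gene
#' identifiers in the first column; the label file has two columns,
#' sample identifier and class (`cancer`/`normal`), no header.
#'
#' @param path path to the gene-by-sample TSV matrix.
#' @param labels_path path to the two-column sample-label TSV.
#' @param dataset_id,cancer_type cohort identifiers attached to the result.
#' @return An [expression_dataset()], with row and column order preserved
#'   from the file.
#' @export
read_expression_tsv <- function(path, labels_path,
                                dataset_id = basename(path),
                                cancer_type = "cancer") {
  raw <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                           colClasses = "character")
  if (nrow(raw) == 0L) stop("no genes: expression matrix body is empty")
  genes <- raw[[1L]]
  body <- raw[, -1L, drop = FALSE]
  num <- suppressWarnings(vapply(body, as.numeric, numeric(nrow(body))))
  num <- matrix(num, nrow = nrow(body),
                dimnames = list(genes, colnames(body)))
  bad <- which(is.na(num) & body != "NA", arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf("non-numeric cell at gene '%s', sample '%s'",
                 genes[bad[1L, 1L]], colnames(body)[bad[1L, 2L]]))
  }
  lab <- utils::read.delim(labels_path, header = FALSE,
                           colClasses = "character")
  labels <- stats::setNames(lab[[2L]], lab[[1L]])
  expression_dataset(num, labels, dataset_id = dataset_id,
                     cancer_type = cancer_type)
}

#' Write an expression dataset to TSV matrix + label files
#'
#' Inverse of [read_expression_tsv()]: round-trips content exactly up to
#' numeric formatting.
#'
#' @param dataset an [expression_dataset()].
#' @param path,labels_path output paths.
#' @export
write_expression_tsv <- function(dataset, path, labels_path) {
  df <- data.frame(gene = dataset$genes, dataset$values,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(dataset$samples, dataset$labels),
                     labels_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(dataset)
}

#' Read an undirected interaction network from a SIF or TSV edge list
#'
#' Produces a simple undirected graph: duplicate lines and reversed
#' duplicates collapse to one edge, and self-loops are dropped with a
#' warning giving their count.
#'
#' @param path path to the edge-list file.
#' @param dialect `"sif"` (`node relation node` per line, whitespace
#'   separated) or `"tsv"` (two identifier columns with an optional third
#'   numeric weight column).
#' @return An undirected simple [igraph::graph] with an `weight` edge
#'   attribute when the input carries one.
#' @export
read_edge_list <- function(path, dialect = c("tsv", "sif")) {
  dialect <- match.arg(dialect)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  from <- character(0); to <- character(0); w <- numeric(0)
  has_weight <- FALSE
  for (i in seq_along(lines)) {
    parts <- strsplit(trimws(lines[[i]]), "[\t ]+")[[1L]]
    if (dialect == "sif") {
      if (length(parts) < 3L) {
        stop(sprintf("malformed SIF line %d: '%s'", i, lines[[i]]))
      }
      from <- c(from, rep(parts[1L], length(parts) - 2L))
      to <- c(to, parts[-(1:2)])
    } else {
      if (length(parts) < 2L || length(parts) > 3L) {
        stop(sprintf("malformed TSV edge line %d: '%s'", i, lines[[i]]))
      }
      from <- c(from, parts[1L]); to <- c(to, parts[2L])
      if (length(parts) == 3L) {
        wi <- suppressWarnings(as.numeric(parts[3L]))
        if (is.na(wi)) stop(sprintf("malformed weight on line %d", i))
        has_weight <- TRUE
        w <- c(w, wi)
      } else {
        w <- c(w, NA_real_)
      }
    }
  }
  edges <- data.frame(from = from, to = to, stringsAsFactors = FALSE)
  if (has_weight) edges$weight <- w
  interaction_network(edges)
}

#' Build a validated interaction network from an edge data frame
#'
#' @param edges data frame with columns `from`, `to` and optional `weight`.
#' @param nodes optional superset of node identifiers to include as
#'   (possibly isolated) vertices.
#' @return An undirected simple [igraph::graph].
#' @export
interaction_network <- function(edges, nodes = NULL) {
  self <- edges$from == edges$to
  if (any(self)) {
    warning(sprintf("dropped %d self-loop(s)", sum(self)))
    edges <- edges[!self, , drop = FALSE]
  }
  # unordered uniqueness: canonicalize endpoint order, keep first weight
  a <- pmin(edges$from, edges$to)
  b <- pmax(edges$from, edges$to)
  keep <- !duplicated(paste(a, b, sep = "\r"))
  out <- data.frame(from = a[keep], to = b[keep], stringsAsFactors = FALSE)
  if ("weight" %in% names(edges)) out$weight <- edges$weight[keep]
  igraph::graph_from_data_frame(out, directed = FALSE, vertices = nodes)
}

#' Read a GMT-like gene-set catalog
#'
#' Each line is `set-name<TAB>description<TAB>member1<TAB>member2...`.
#' Recognized set names are `seed` (the ARS/AIMP family), `cag`
#' (cancer-associated genes) and `non_cag` (negative controls).
#'
#' @param path path to the gene-set file.
#' @return A list of class `gene_set_catalog` with character-vector fields
#'   `seed_set`, `cag_set`, `non_cag_set`.
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty gene-set file: a seed set is required")
  sets <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "\t")[[1L]]
    if (length(parts) < 3L) stop(sprintf("malformed gene-set line: '%s'", ln))
    sets[[parts[1L]]] <- unique(parts[-(1:2)])
  }
  gene_set_catalog(seed_set = sets[["seed"]],
                   cag_set = sets[["cag"]] %||% character(0),
                   non_cag_set = sets[["non_cag"]] %||% character(0))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname read_gene_sets
#' @param seed_set,cag_set,non_cag_set character vectors of gene identifiers.
#' @export
gene_set_catalog <- function(seed_set, cag_set = character(0),
                             non_cag_set = character(0)) {
  if (is.null(seed_set) || length(seed_set) == 0L) {
    stop("seed set is missing or empty")
  }
  overlap <- intersect(cag_set, non_cag_set)
  if (length(overlap) > 0L) {
    stop(sprintf("gene(s) in both cag and non_cag sets: %s",
                 paste(overlap, collapse = ", ")))
  }
  structure(list(seed_set = unique(seed_set), cag_set = unique(cag_set),
                 non_cag_set = unique(non_cag_set)),
            class = "gene_set_catalog")
}

#' Write a gene-set catalog to a GMT-like file
#' @param catalog a `gene_set_catalog`.
#' @param path output path.
#' @export
write_gene_sets <- function(catalog, path) {
  lines <- c(
    paste(c("seed", ".", catalog$seed_set), collapse = "\t"),
    if (length(catalog$cag_set))
      paste(c("cag", ".", catalog$cag_set), collapse = "\t"),
    if (length(catalog$non_cag_set))
      paste(c("non_cag", ".", catalog$non_cag_set), collapse = "\t"))
  writeLines(lines, path)
  invisible(catalog)
}

#' Read a per-species ortholog-group map
#'
#' Two-column TSV (protein identifier, ortholog-group identifier), many
#' proteins to one group; group identifiers are shared across species.
#'
#' @param path path to the map TSV (no header).
#' @param species species tag attached to the map.
#' @return A list of class `ortholog_map` with fields `species` and `map`
#'   (named character vector, protein -> group).
#' @export
read_ortholog_map <- function(path, species) {
  df <- utils::read.delim(path, header = FALSE, colClasses = "character")
  ortholog_map(stats::setNames(df[[2L]], df[[1L]]), species)
}

#' @rdname read_ortholog_map
#' @param map named character vector, protein identifier -> group identifier.
#' @export
ortholog_map <- function(map, species) {
  if (anyDuplicated(names(map))) {
    dup <- names(map)[duplicated(names(map))]
    stop(sprintf("protein(s) mapped to more than one group: %s",
                 paste(unique(dup), collapse = ", ")))
  }
  structure(list(species = species, map = map), class = "ortholog_map")
}

#' Read a copy-number / mutation alteration table
#'
#' TSV with header columns `gene`, `cancer_type`, `event_class`,
#' `case_count`, `total_cases`.
#'
#' @param path path to the TSV file.
#' @return A validated data frame of class `alteration_table`.
#' @export
read_alteration_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, colClasses = c(
    gene = "character", cancer_type = "character",
    event_class = "character", case_count = "integer",
    total_cases = "integer"))
  alteration_table(df)
}

#' @rdname read_alteration_table
#' @param df data frame with the columns above.
#' @export
alteration_table <- function(df) {
  need <- c("gene", "cancer_type", "event_class", "case_count", "total_cases")
  if (!all(need %in% names(df))) {
    stop(sprintf("alteration table missing column(s): %s",
                 paste(setdiff(need, names(df)), collapse = ", ")))
  }
  if (any(df$case_count < 0) || any(df$total_cases <= 0)) {
    stop("case_count must be nonnegative and total_cases positive")
  }
  if (any(df$case_count > df$total_cases)) {
    stop("case_count exceeds total_cases")
  }
  class(df) <- c("alteration_table", class(df))
  df
}

#' First and second network neighbors of a seed set
#'
#' First neighbors are the direct interactors of the seed genes restricted
#' to an allowed universe (for example the cancer-associated genes),
#' excluding the seeds themselves; second neighbors are direct interactors
#' of the first neighbors, again restricted, excluding both earlier tiers.
#'
#' @param network an undirected [igraph::graph].
#' @param seed character vector of seed gene identifiers. Seeds absent from
#'   the network are dropped with a warning.
#' @param restrict character vector: the allowed neighbor universe. `NULL`
#'   means all network nodes.
#' @return A list with character-vector fields `first` and `second`.
#' @export
neighbors_of_set <- function(network, seed, restrict = NULL) {
  nodes <- igraph::V(network)$name
  missing <- setdiff(seed, nodes)
  if (length(missing) > 0L) {
    warning(sprintf("seed gene(s) absent from network, ignored: %s",
                    paste(missing, collapse = ", ")))
  }
  seed <- intersect(seed, nodes)
  if (length(seed) == 0L) stop("no seed gene is present in the network")
  if (is.null(restrict)) restrict <- nodes
  direct <- function(set) {
    unique(unlist(lapply(
      igraph::adjacent_vertices(network, set), function(v) v$name)))
  }
  first <- setdiff(intersect(direct(seed), restrict), seed)
  second <- if (length(first) > 0L) {
    setdiff(intersect(direct(first), restrict), union(seed, first))
  } else character(0)
  list(first = first, second = second)
}

#' Per-group alteration frequency
#'
#' The number of alteration cases (e.g. copy-number amplifications) recorded
#' for the group's genes in one cancer type and event class, divided by the
#' number of genes in the group. Genes absent from the table contribute
#' zero cases.
#'
#' @param table an [alteration_table()].
#' @param group nonempty character vector of gene identifiers.
#' @param cancer_type,event_class values selecting the table rows.
#' @return A single nonnegative number.
#' @export
group_alteration_frequency <- function(table, group, cancer_type,
                                       event_class) {
  if (length(group) == 0L) stop("group is empty")
  rows <- table$gene %in% group &
    table$cancer_type == cancer_type &
    table$event_class == event_class
  sum(table$case_count[rows]) / length(group)
}

#' Write an interaction network as a SIF or weighted TSV edge list
#' @param network an [igraph::graph].
#' @param path output path.
#' @param dialect `"sif"` or `"tsv"`.
#' @export
write_edge_list <- function(network, path, dialect = c("tsv", "sif")) {
  dialect <- match.arg(dialect)
  el <- igraph::as_edgelist(network)
  if (dialect == "sif") {
    writeLines(paste(el[, 1L], "pp", el[, 2L]), path)
  } else {
    w <- igraph::edge_attr(network, "weight")
    df <- if (is.null(w)) data.frame(el[, 1L], el[, 2L]) else
      data.frame(el[, 1L], el[, 2L], w)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(network)
}
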