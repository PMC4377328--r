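#' Validate a pipeline configuration
#'
#' The configuration is a named list (or a JSON file of one) with blocks:
#' \describe{
#'   \item{seed}{integer; mandatory, forces reproducibility.}
#'   \item{params}{`n_perm`, `alpha`, `continue_prob`, `n_rand`, `k`,
#'     `weight_floor`, `denominator`, `min_species` — all optional with
#'     the package defaults.}
#'   \item{simulate}{generator settings: `n_cancer_types`,
#'     `datasets_per_type`, `cohort` (passed to
#'     [generate_expression_cohort()]), `network` (passed to
#'     [generate_ppi_network()]), optional `species` (passed to
#'     [generate_multi_species()]).}
#'   \item{inputs}{alternatively, file paths: `expression` (list of
#'     `matrix`/`labels`/`cancer_type` entries), `network`
#'     (`path`/`dialect`), `gene_sets`.}
#' }
#' Unknown keys are rejected.
#'
#' @param config named list or path to a JSON config file.
#' @return The validated config with defaults filled in.
#' @export
pipeline_config <- function(config) {
  if (is.character(config)) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  allowed <- c("seed", "params", "simulate", "inputs", "out_dir")
  unknown <- setdiff(names(config), allowed)
  if (length(unknown) > 0L) {
    stop(sprintf("unknown config key(s): %s",
                 paste(unknown, collapse = ", ")))
  }
  if (is.null(config$seed)) stop("config must set an integer seed")
  defaults <- list(n_perm = 1000L, alpha = 0.05, continue_prob = 0.75,
                   n_rand = 1000L, k = 3L, weight_floor = 0.01,
                   denominator = "measured", min_species = 2L)
  p <- utils::modifyList(defaults, config$params %||% list())
  bad_param <- setdiff(names(p), names(defaults))
  if (length(bad_param) > 0L) {
    stop(sprintf("unknown param(s): %s", paste(bad_param, collapse = ", ")))
  }
  if (p$alpha <= 0 || p$alpha >= 1) stop("alpha must be in (0, 1)")
  if (p$continue_prob <= 0 || p$continue_prob >= 1) {
    stop("continue_prob must be in (0, 1)")
  }
  if (p$n_perm < 100L) stop("n_perm must be at least 100")
  if (p$n_rand < 100L) stop("n_rand must be at least 100")
  if (!p$denominator %in% c("measured", "total")) {
    stop("denominator must be 'measured' or 'total'")
  }
  config$params <- p
  if (is.null(config$simulate) && is.null(config$inputs)) {
    stop("config must provide either 'simulate' or 'inputs'")
  }
  config
}

#' Run the end-to-end analysis pipeline
#'
#' Wires the stages together: per-dataset DEG identification, per-type
#' Stouffer summaries, seed network model with deregulation and
#' co-association scores, random-walk key-module detection with the
#' randomized-network null, and (when multi-species inputs are configured)
#' conserved-motif discovery. All stage tables are written as TSV to
#' `out_dir` along with a `manifest.json` holding the full configuration,
#' its hash and the package version, sufficient to reproduce the outputs
#' exactly.
#'
#' @param config a [pipeline_config()] (list or JSON path).
#' @param out_dir output directory (created if absent); overrides
#'   `config$out_dir`.
#' @return Invisibly, a list with the stage objects (`results`,
#'   `summaries`, `model`, `null`, `modules`, `motifs`) and `files`.
#' @export
run_pipeline <- function(config, out_dir = config$out_dir) {
  config <- pipeline_config(config)
  if (is.null(out_dir)) stop("an output directory is required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- config$params
  seed <- as.integer(config$seed)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  # --- assemble inputs -------------------------------------------------
  sim <- config$simulate
  if (!is.null(sim)) {
    net_args <- utils::modifyList(list(seed = seed),
                                  sim$network %||% list())
    net <- stage("simulate-network",
                 do.call(generate_ppi_network, net_args))
    network <- net$network
    catalog <- net$catalog
    n_types <- sim$n_cancer_types %||% 2L
    n_ds <- sim$datasets_per_type %||% 1L
    nodes <- igraph::V(network)$name
    datasets <- list()
    for (ty in seq_len(n_types)) {
      for (d in seq_len(n_ds)) {
        args <- utils::modifyList(
          list(n_genes = length(nodes), genes = nodes,
               force_de = net$truth$planted_module,
               seed = seed + 1000L * ty + d,
               dataset_id = sprintf("sim_t%d_d%d", ty, d),
               cancer_type = sprintf("type%d", ty)),
          sim$cohort %||% list())
        datasets[[length(datasets) + 1L]] <-
          stage("simulate-cohort",
                do.call(generate_expression_cohort, args))$dataset
      }
    }
  } else {
    inp <- config$inputs
    network <- stage("read-network",
                     read_edge_list(inp$network$path,
                                    dialect = inp$network$dialect %||% "tsv"))
    catalog <- stage("read-gene-sets", read_gene_sets(inp$gene_sets))
    datasets <- lapply(inp$expression, function(e) {
      stage("read-expression",
            read_expression_tsv(e$matrix, e$labels,
                                dataset_id = e$dataset_id %||%
                                  basename(e$matrix),
                                cancer_type = e$cancer_type %||% "cancer"))
    })
  }

  # --- differential expression per dataset -----------------------------
  results <- lapply(datasets, function(ds) {
    stage(paste0("deg-", ds$dataset_id),
          identify_degs(ds, alpha = p$alpha, n_perm = p$n_perm,
                        seed = seed))
  })
  files <- character(0)
  for (r in results) {
    f <- file.path(out_dir, sprintf("deg_%s.tsv", attr(r, "dataset_id")))
    utils::write.table(r, f, sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, f)
  }

  # --- per-cancer-type summaries ---------------------------------------
  types <- unique(vapply(results, attr, character(1), "cancer_type"))
  summaries <- lapply(types, function(ty) {
    members <- Filter(function(r) attr(r, "cancer_type") == ty, results)
    stage(paste0("summarize-", ty), summarize_cancer_type(members, ty))
  })
  names(summaries) <- types
  for (ty in types) {
    f <- file.path(out_dir, sprintf("summary_%s.tsv", ty))
    utils::write.table(summaries[[ty]], f, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files <- c(files, f)
  }

  # --- network model and scores ----------------------------------------
  model <- stage("score", build_network_model(
    network, catalog, summaries, alpha = p$alpha,
    denominator = p$denominator))
  node_f <- file.path(out_dir, "model_nodes.tsv")
  edge_f <- file.path(out_dir, "model_edges.tsv")
  write_network_model(model, node_f, edge_f)
  files <- c(files, node_f, edge_f)

  # --- key modules ------------------------------------------------------
  null <- stage("modules", randomized_null_p(
    model, n_rand = p$n_rand, seed = seed,
    continue_prob = p$continue_prob, weight_floor = p$weight_floor))
  modules <- extract_key_modules(model, null, alpha = p$alpha,
                                 seed_set = catalog$seed_set)
  f <- file.path(out_dir, "node_p.tsv")
  utils::write.table(null$nodes, f, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  files <- c(files, f)
  mod_df <- if (length(modules) > 0L) {
    do.call(rbind, lapply(seq_along(modules), function(i) {
      data.frame(module = i, gene = modules[[i]]$nodes,
                 p_value = unname(modules[[i]]$p_values),
                 stringsAsFactors = FALSE)
    }))
  } else {
    data.frame(module = integer(0), gene = character(0),
               p_value = numeric(0))
  }
  f <- file.path(out_dir, "modules.tsv")
  utils::write.table(mod_df, f, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  files <- c(files, f)

  # --- conserved motifs (optional) -------------------------------------
  motifs <- NULL
  if (!is.null(sim) && !is.null(sim$species)) {
    sp_args <- utils::modifyList(list(seed = seed), sim$species)
    ms <- stage("simulate-species",
                do.call(generate_multi_species, sp_args))
    motifs <- stage("motifs", find_conserved_motifs(
      ms$networks, ms$maps, ms$seed_set, target = "human", k = p$k,
      min_species = p$min_species))
    f <- file.path(out_dir, "motifs.tsv")
    write_motif_table(motifs, f)
    files <- c(files, f)
  }

  # --- manifest ---------------------------------------------------------
  cfg_json <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                               null = "null")
  manifest <- list(
    config = config,
    config_md5 = unname(tools::md5sum(
      local({tf <- tempfile(); writeLines(cfg_json, tf); tf}))),
    seed = seed,
    package_version = as.character(utils::packageVersion("degnet")),
    outputs = basename(files))
  mf <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA,
                       null = "null")
  files <- c(files, mf)
  invisible(list(results = results, summaries = summaries, model = model,
                 null = null, modules = modules, motifs = motifs,
                 files = files))
}
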