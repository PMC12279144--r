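#' Export a network for external rendering
#'
#' Writes GraphML or DOT via igraph.  Nodes carry their variable class
#' (`vclass`) as an attribute; edges carry `strength` and `direction`
#' where available, plus a visual `weight` attribute proportional to
#' strength (edge thickness proportional to strength is the
#' conventional rendering).
#'
#' @param edges a [dag()] or edge-list data frame (columns `from`,
#'   `to`, optionally `strength`, `direction`).
#' @param meta a [variable_meta()] table for node attributes.
#' @param path output file path.
#' @param format `"graphml"` or `"dot"`.
#' @return `path`, invisibly.
#' @export
export_graph <- function(edges, meta, path, format = c("graphml", "dot")) {
  format <- match.arg(format)
  e <- edge_pairs(edges)
  nodes <- attr(edges, "nodes")
  if (is.null(nodes) && inherits(edges, "mixbn_dag")) nodes <- edges$nodes
  if (is.null(nodes)) nodes <- unique(c(e))
  verts <- data.frame(name = nodes,
                      vclass = meta$vclass[match(nodes, meta$name)],
                      stringsAsFactors = FALSE)
  ed <- data.frame(from = e[, 1], to = e[, 2], stringsAsFactors = FALSE)
  if (is.data.frame(edges) && "strength" %in% names(edges)) {
    ed$strength <- edges$strength
    ed$direction <- edges$direction
    ed$weight <- edges$strength
  }
  g <- igraph::graph_from_data_frame(ed, directed = TRUE, vertices = verts)
  igraph::write_graph(g, path, format = format)
  invisible(path)
}

#' Pipeline configuration
#'
#' Bundles the inputs and tuning parameters of the end-to-end analysis:
#' impute, bootstrap-average, threshold, summarise.
#'
#' @param data a [mixbn_data()], or a path readable by [read_data()]
#'   (then `metadata` must be given).
#' @param metadata a [variable_meta()] table or metadata file path.
#' @param constraints a [constraint_set()], a constraints file path, or
#'   `NULL`.
#' @param output_dir directory for artefacts (created if needed).
#' @param n_replicates bootstrap replicates (default 1000).
#' @param strength_threshold numeric in `[0, 1]`, or `NULL` for the
#'   analytic estimate.
#' @param direction_threshold numeric in `[0, 1]` (default 0.5).
#' @param seed master seed for imputation and bootstrap.
#' @param search_params a [search_params()].
#' @param imputation_params an [imputation_params()].
#' @param blanket_nodes variables whose Markov blankets to extract.
#' @return A list of class `mixbn_config`.
#' @export
pipeline_config <- function(data, metadata = NULL, constraints = NULL,
                            output_dir = "mixbn_output",
                            n_replicates = 1000L,
                            strength_threshold = NULL,
                            direction_threshold = 0.5, seed = 1L,
                            search_params = mixbn::search_params(),
                            imputation_params = mixbn::imputation_params(seed = seed),
                            blanket_nodes = character(0)) {
  stopifnot(is.null(strength_threshold) ||
              (strength_threshold >= 0 && strength_threshold <= 1),
            direction_threshold >= 0, direction_threshold <= 1,
            n_replicates >= 1)
  structure(list(data = data, metadata = metadata, constraints = constraints,
                 output_dir = output_dir,
                 n_replicates = as.integer(n_replicates),
                 strength_threshold = strength_threshold,
                 direction_threshold = direction_threshold,
                 seed = as.integer(seed), search_params = search_params,
                 imputation_params = imputation_params,
                 blanket_nodes = blanket_nodes),
            class = "mixbn_config")
}

#' Run the end-to-end analysis
#'
#' Stages, in order: load inputs, impute missing data (skipped, and
#' logged as such, when the data are complete), bootstrap-average the
#' network, threshold it (analytic threshold unless overridden),
#' summarise (degree summary, class-edge matrix, requested Markov
#' blankets) and write every artefact with a JSON provenance sidecar
#' recording the configuration, seeds and package version.  All stages
#' are deterministic given the configuration.
#'
#' @param config a [pipeline_config()].
#' @return Invisibly, a list with the imputed data, the average
#'   network, the thresholded edges, the threshold used and the
#'   summaries; artefacts are written under `config$output_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "mixbn_config"))
  out <- config$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out, "pipeline.log")
  logf <- function(fmt, ...) cat(sprintf(paste0(fmt, "\n"), ...),
                                 file = log_path, append = TRUE)
  cat("", file = log_path)

  data <- config$data
  if (is.character(data)) data <- read_data(data, config$metadata)
  constraints <- config$constraints
  if (is.character(constraints))
    constraints <- read_constraints(constraints, data$meta)
  logf("stage=load samples=%d variables=%d missing_cells=%d seed=%d",
       n_samples(data), n_variables(data), sum(data$missing), config$seed)

  if (is_complete(data)) {
    imputed <- data
    logf("stage=impute skipped=complete_data")
  } else {
    imputed <- impute(data, constraints, config$search_params,
                      config$imputation_params)
    logf("stage=impute imputed_cells=%d seed=%d", sum(data$missing),
         config$imputation_params$seed)
  }
  write_data(imputed, file.path(out, "imputed_data.tsv"))

  avg <- bootstrap_average(imputed, constraints, config$search_params,
                           n_replicates = config$n_replicates,
                           seed = config$seed)
  logf("stage=average replicates=%d pairs=%d seed=%d",
       config$n_replicates, nrow(avg), config$seed)
  write_edge_table(avg, file.path(out, "average_network.csv"))

  thr <- config$strength_threshold
  if (is.null(thr)) {
    thr <- estimate_strength_threshold(avg$strength)
    logf("stage=threshold analytic_threshold=%.6f level=%.4f",
         thr, attr(thr, "level"))
  } else logf("stage=threshold fixed_threshold=%.6f", thr)
  net <- threshold_network(avg, thr, config$direction_threshold)
  logf("stage=threshold kept_edges=%d direction_threshold=%.2f",
       nrow(net), config$direction_threshold)
  write_edge_table(net, file.path(out, "thresholded_edges.csv"))
  export_graph(net, data$meta, file.path(out, "network.graphml"), "graphml")

  summaries <- list(strength_threshold = as.numeric(thr))
  if (nrow(net)) {
    deg <- degree_summary(net)
    summaries$degree <- deg
    logf("stage=summarize mean_out_per_parent=%.3f mean_in_per_child=%.3f",
         deg$mean_out_per_parent, deg$mean_in_per_child)
    cem <- class_edge_matrix(net, data$meta)
    summaries$class_edge_matrix <- cem
    utils::write.csv(as.data.frame(cem), file.path(out, "class_edge_matrix.csv"))
  }
  blankets <- list()
  for (v in config$blanket_nodes) {
    bl <- markov_blanket(net, v)
    blankets[[v]] <- bl
    sub <- subnetwork(net, c(v, bl))
    write_edge_table(sub, file.path(out, paste0("blanket_", v, ".csv")))
    logf("stage=blanket node=%s size=%d", v, length(bl))
  }
  summaries$blankets <- blankets

  provenance <- list(
    package = "mixbn",
    version = as.character(utils::packageVersion("mixbn")),
    seed = config$seed,
    imputation_seed = config$imputation_params$seed,
    n_replicates = config$n_replicates,
    strength_threshold = as.numeric(thr),
    direction_threshold = config$direction_threshold,
    config_hash = config_hash(config),
    files = list.files(out))
  jsonlite::write_json(provenance, file.path(out, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE)
  invisible(list(imputed = imputed, average = avg, edges = net,
                 strength_threshold = as.numeric(thr),
                 summaries = summaries))
}

# Stable fingerprint of the configuration: md5 of its serialised
# canonical form (paths and parameter values).
config_hash <- function(config) {
  strip <- config
  strip$data <- if (is.character(config$data)) config$data else "<in-memory>"
  strip$metadata <- if (is.character(config$metadata)) config$metadata
    else "<in-memory>"
  strip$constraints <- if (is.character(config$constraints))
    config$constraints else "<in-memory>"
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(strip, tmp, version = 2)
  unname(tools::md5sum(tmp))
}
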