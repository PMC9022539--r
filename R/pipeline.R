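#' Run the full coordinate-biogenesis prediction pipeline
#'
#' Executes the stages in fixed order: load/merge catalogs, enumerate
#' triads, contextualize against expression (when DE tables are given),
#' filter direct gene A -> gene B regulation (when an edge list is
#' given), compute pair prevalence, and optionally run pathway
#' over-representation on the effector (gene B) set. Row counts per
#' stage are recorded so every pruning step is traceable; outputs are
#' deterministic for fixed inputs and seed. On a stage failure the
#' partial summary is flushed to the output directory with a
#' stage-failure marker before the error propagates.
#'
#' @param config A named list (or path to a YAML/JSON file) with entries:
#'   `catalogs` (list of `list(path =, dialect =)` or `cb_catalog`
#'   objects), `species`, `regulator`, `mrna_de` / `mirna_de` (paths or
#'   data.frames, optional), `mode` (`"down_down"` or `"full_pattern"`),
#'   `fc_threshold`, `p_threshold`, `tf_edges` (path or data.frame,
#'   optional), `gmt` + `background` (optional enrichment inputs),
#'   `out_dir` (optional output directory), `seed`.
#' @return A run summary list: `counts` per stage, `outputs` (written
#'   file paths), `config` echo, plus the result tables (`triads`,
#'   `contextualized`, `prevalence`, `enrichment`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- if (grepl("\\.json$", config)) jsonlite::read_json(config, simplifyVector = TRUE)
              else yaml::read_yaml(config)
  }
  cfg <- config
  cfg$mode <- cfg$mode %||% "down_down"
  cfg$fc_threshold <- cfg$fc_threshold %||% 1.5
  cfg$p_threshold <- cfg$p_threshold %||% 0.05
  cfg$seed <- cfg$seed %||% 1L
  .check_range(cfg$fc_threshold > 1, "fc_threshold must be > 1")
  .check_range(cfg$p_threshold > 0 && cfg$p_threshold <= 1, "p_threshold must lie in (0, 1]")
  out_dir <- cfg$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  set.seed(cfg$seed)

  counts <- list()
  outputs <- character()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      if (!is.null(out_dir)) {
        fail <- list(failed_stage = name, error = conditionMessage(e),
                     counts = counts)
        jsonlite::write_json(fail, file.path(out_dir, "summary.json"),
                             auto_unbox = TRUE, pretty = TRUE)
      }
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  catalog <- stage("load_catalogs", {
    cats <- lapply(cfg$catalogs, function(ct) {
      if (inherits(ct, "cb_catalog")) return(ct)
      load_catalog(ct$path, dialect = ct$dialect %||% "generic_tsv",
                   species = cfg$species %||% "unknown")
    })
    Reduce(merge_catalogs, cats)
  })
  counts$catalog_sites <- nrow(catalog$sites)
  counts$catalog_pairs <- nrow(catalog$index)

  triads <- stage("enumerate", enumerate_triads(catalog, regulator = cfg$regulator))
  counts$enumerated <- nrow(triads)

  mrna_de <- stage("read_expression", .as_de(cfg$mrna_de))
  mirna_de <- stage("read_expression", .as_de(cfg$mirna_de))
  if (!is.null(mrna_de)) {
    contextualized <- stage("contextualize",
      contextualize(triads, mrna_de, mirna_de, mode = cfg$mode,
                    fc_threshold = cfg$fc_threshold,
                    p_threshold = cfg$p_threshold))
    counts$contextualized <- nrow(contextualized)
  } else {
    contextualized <- triads
    counts$contextualized <- NA_integer_  # not applicable without DE tables
  }

  edges <- stage("read_edges", {
    if (is.null(cfg$tf_edges)) NULL
    else if (is.data.frame(cfg$tf_edges)) cfg$tf_edges
    else read_edges(cfg$tf_edges)
  })
  final <- stage("filter_direct_regulation",
                 filter_direct_regulation(contextualized, edges))
  counts$final <- nrow(final)

  prevalence <- stage("prevalence", pair_prevalence(final))
  counts$pairs <- nrow(prevalence)

  enrichment <- NULL
  if (!is.null(cfg$gmt) && !is.null(cfg$background)) {
    enrichment <- stage("enrich", {
      sets <- read_gmt(cfg$gmt)
      bg <- if (length(cfg$background) == 1 && file.exists(cfg$background))
        readLines(cfg$background) else cfg$background
      coll <- gene_set_collection(sets, bg, attr(sets, "descriptions"))
      enrich(unique(final$gene_b), coll)
    })
    counts$enriched_sets <- nrow(enrichment)
  }

  if (!is.null(out_dir)) {
    wt <- function(df, name) {
      p <- file.path(out_dir, name)
      utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
      outputs <<- c(outputs, p)
    }
    wt(triads, "triads.tsv")
    wt(final, "contextualized_triads.tsv")
    wt(prevalence, "prevalence.tsv")
    if (!is.null(enrichment)) wt(enrichment, "enrichment.tsv")
    np <- file.path(out_dir, "network.json")
    export_network(final, format = "json", path = np)
    outputs <- c(outputs, np)
  }

  summary <- list(counts = counts, outputs = outputs,
                  config = cfg[setdiff(names(cfg), c("catalogs", "out_dir"))],
                  triads = triads, contextualized = contextualized,
                  prevalence = prevalence, enrichment = enrichment,
                  final = final)
  if (!is.null(out_dir)) {
    # summary carries run-relative paths so identical configs written to
    # different directories produce byte-identical summaries
    jsonlite::write_json(list(counts = counts, outputs = basename(outputs),
                              config = summary$config),
                         file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  summary
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.check_range <- function(ok, msg) if (!isTRUE(ok)) stop(msg, call. = FALSE)

.as_de <- function(x) {
  if (is.null(x)) return(NULL)
  if (is.data.frame(x)) { .validate_de(x); return(x) }
  read_expression(x)
}

#' Export a triad set as a typed network
#'
#' Renders triads as a network with node types `regulator_miRNA`,
#' `secondary_miRNA`, `gene_a`, `gene_b` and typed edges: regulator ->
#' gene A and secondary -> gene A / gene B targeting edges, plus a
#' regulator -> secondary coordination edge. Formats: a flat edge TSV, a
#' GraphML-style XML document, or JSON (which round-trips losslessly via
#' [read_network()]).
#'
#' @param triads data.frame with at least `regulator`, `gene_a`,
#'   `secondary`, `gene_b`.
#' @param format One of `"edge_tsv"`, `"graphml"`, `"json"`.
#' @param path Output file; when `NULL` the network object (nodes/edges
#'   data.frames) is returned without writing.
#' @return The network as `list(nodes =, edges =)`, invisibly when
#'   written to a file.
#' @export
export_network <- function(triads, format = c("json", "edge_tsv", "graphml"),
                           path = NULL) {
  format <- match.arg(format)
  nd <- function(id, type) data.frame(id = id, type = rep(type, length(id)),
                                      stringsAsFactors = FALSE)
  ed <- function(from, to, type) data.frame(from = from, to = to,
                                            type = rep(type, length(from)),
                                            stringsAsFactors = FALSE)
  nodes <- unique(rbind(
    nd(triads$regulator, "regulator_miRNA"),
    nd(triads$secondary, "secondary_miRNA"),
    nd(triads$gene_a, "gene_a"),
    nd(triads$gene_b, "gene_b")
  ))
  edges <- unique(rbind(
    ed(triads$regulator, triads$gene_a, "targets"),
    ed(triads$secondary, triads$gene_a, "targets"),
    ed(triads$secondary, triads$gene_b, "targets"),
    ed(triads$regulator, triads$secondary, "coordinates")
  ))
  rownames(nodes) <- NULL; rownames(edges) <- NULL
  net <- list(nodes = nodes, edges = edges)
  if (is.null(path)) return(net)
  if (format == "json") {
    jsonlite::write_json(net, path, dataframe = "rows", auto_unbox = TRUE,
                         pretty = TRUE)
  } else if (format == "edge_tsv") {
    utils::write.table(edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else if (format == "graphml") {
    esc <- function(x) gsub("&", "&amp;", gsub("<", "&lt;", x, fixed = TRUE), fixed = TRUE)
    lines <- c(
      '<?xml version="1.0" encoding="UTF-8"?>',
      '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
      '  <key id="type" for="all" attr.name="type" attr.type="string"/>',
      '  <graph id="cb_network" edgedefault="directed">',
      sprintf('    <node id="%s"><data key="type">%s</data></node>',
              esc(nodes$id), esc(nodes$type)),
      sprintf('    <edge source="%s" target="%s"><data key="type">%s</data></edge>',
              esc(edges$from), esc(edges$to), esc(edges$type)),
      '  </graph>',
      '</graphml>')
    writeLines(lines, path)
  }
  invisible(net)
}

#' Read a JSON network written by [export_network()]
#'
#' @param path JSON file path.
#' @return `list(nodes =, edges =)` of data.frames.
#' @export
read_network <- function(path) {
  net <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (length(net$nodes) == 0)
    net$nodes <- data.frame(id = character(), type = character(), stringsAsFactors = FALSE)
  if (length(net$edges) == 0)
    net$edges <- data.frame(from = character(), to = character(), type = character(),
                            stringsAsFactors = FALSE)
  list(nodes = as.data.frame(net$nodes, stringsAsFactors = FALSE),
       edges = as.data.frame(net$edges, stringsAsFactors = FALSE))
}
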