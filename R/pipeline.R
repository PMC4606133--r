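# End-to-end pipeline: cluster -> distinct subgraphs -> distinct patterns ->
# optional GO scoring -> optional overlap validation, with per-stage JSON/TSV
# artifacts. All artifact content is deterministic given the config and seed
# (timestamps go only to run.log).

#' Pipeline configuration
#'
#' @param networks named list: network name -> edge-list TSV path or
#'   `ppi_graph`.
#' @param label_map `label_map` object or TSV path (protein -> cluster
#'   label). Exactly one of `label_map` / `fasta` must be given.
#' @param fasta protein FASTA path; labels are derived with
#'   [cluster_sequences()].
#' @param rnsc an [rnsc_params()] object (its seed is overridden by `seed`).
#' @param min_edges minimum module edge count for distinctness (default 3).
#' @param mode pattern matching mode, `"exact"` or `"paper_greedy"`.
#' @param obo,gaf optional GO ontology (OBO) and annotation (GAF) paths; when
#'   both are present the GO scoring stage runs.
#' @param references optional named list (network name -> edge-list TSV path
#'   or `ppi_graph`); when present the validation stage runs.
#' @param out_dir output directory (created if needed).
#' @param seed integer seed for every stochastic stage.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(networks, label_map = NULL, fasta = NULL,
                            rnsc = rnsc_params(), min_edges = 3,
                            mode = c("exact", "paper_greedy"), obo = NULL,
                            gaf = NULL, references = NULL, out_dir,
                            seed = 1) {
  mode <- match.arg(mode)
  if (is.null(names(networks)) || anyDuplicated(names(networks)))
    stop("`networks` must be a uniquely named list")
  if (length(networks) < 2)
    stop("the pipeline compares networks; supply at least 2")
  if (is.null(label_map) && is.null(fasta))
    stop("supply either `label_map` or `fasta` for node labeling")
  if (!is.null(references) && is.null(names(references)))
    stop("`references` must be a named list")
  if (xor(is.null(obo), is.null(gaf)))
    stop("supply both `obo` and `gaf`, or neither")
  structure(list(networks = networks, label_map = label_map, fasta = fasta,
                 rnsc = rnsc, min_edges = min_edges, mode = mode, obo = obo,
                 gaf = gaf, references = references, out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

load_network_arg <- function(x) {
  if (inherits(x, "ppi_graph")) x else read_edge_list(x)
}

stage <- function(name, log, expr) {
  log(sprintf("stage %s: start", name))
  res <- tryCatch(expr, error = function(e)
    stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE))
  log(sprintf("stage %s: done", name))
  res
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

module_json <- function(m) {
  list(id = m$id, network = m$network, nodes = m$graph$nodes,
       edges = lapply(seq_len(nrow(m$graph$edges)), function(i)
         unname(m$graph$edges[i, ])),
       bitstring = m$canonical$bitstring)
}

#' Run the full distinct-module discovery pipeline
#'
#' Stages: load inputs, cluster every network with RNSC and extract modules,
#' identify distinct subgraphs, reduce them to distinct patterns, then
#' optionally score pattern witnesses against random same-size subgraphs with
#' GO semantic similarity and validate distinct subgraphs against reference
#' networks. Artifacts (JSON/TSV) are written to `config$out_dir`; a rerun
#' with the same config and seed reproduces them byte for byte. A failing
#' stage aborts with a stage-tagged error, preserving earlier artifacts.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress progress messages.
#' @return Invisibly, a list with the per-stage in-memory results (`modules`,
#'   `distinct`, `patterns`, `summary`, optional `go`, `validation`) and
#'   `out_dir`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "run.log")
  log_con <- file(log_path, "w")
  on.exit(close(log_con))
  log <- function(msg) {
    writeLines(sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                       msg), log_con)
    if (!quiet) message(msg)
  }

  nets <- stage("load", log, lapply(config$networks, load_network_arg))

  lm <- stage("labels", log, {
    if (!is.null(config$label_map)) {
      if (inherits(config$label_map, "label_map")) config$label_map
      else load_label_map(config$label_map)
    } else {
      cluster_sequences(config$fasta)
    }
  })

  # config echo (paths and parameters only, deterministic)
  echo <- list(networks = lapply(config$networks, function(x)
    if (inherits(x, "ppi_graph"))
      sprintf("<in-memory: %d nodes, %d edges>", length(x$nodes),
              nrow(x$edges)) else as.character(x)),
    rnsc = unclass(config$rnsc), min_edges = config$min_edges,
    mode = config$mode, obo = config$obo, gaf = config$gaf,
    references = if (is.null(config$references)) NULL else
      lapply(config$references, function(x)
        if (inherits(x, "ppi_graph"))
          sprintf("<in-memory: %d nodes, %d edges>", length(x$nodes),
                  nrow(x$edges)) else as.character(x)),
    seed = config$seed)
  jsonlite::write_json(echo, file.path(config$out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  modules <- stage("cluster", log, {
    params <- config$rnsc
    params$seed <- config$seed
    out <- lapply(names(nets), function(net) {
      p <- rnsc_cluster(nets[[net]], params)
      log(sprintf("  %s: %d clusters, naive cost %d, scaled cost %.3f",
                  net, p$n_clusters, p$naive_cost, p$scaled_cost))
      extract_modules(nets[[net]], p, network = net)
    })
    names(out) <- names(nets)
    out
  })
  jsonlite::write_json(lapply(modules, function(ms) lapply(ms, module_json)),
                       file.path(config$out_dir, "modules.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  distinct <- stage("distinct", log, {
    tables <- build_label_table(modules)
    find_distinct_subgraphs(tables, min_edges = config$min_edges)
  })
  jsonlite::write_json(
    lapply(distinct, function(ds) lapply(ds, function(d)
      module_json(d$module))),
    file.path(config$out_dir, "distinct_subgraphs.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_tsv(subgraph_size_table(distinct),
            file.path(config$out_dir, "distinct_subgraph_sizes.tsv"))

  patterns <- stage("patterns", log,
    find_distinct_patterns(distinct, modules, lm, mode = config$mode,
                           min_edges = config$min_edges))
  jsonlite::write_json(
    lapply(patterns, function(ps) lapply(ps, function(p)
      list(pattern = p$key, n_edges = p$n_edges,
           witnesses = as.list(p$witnesses)))),
    file.path(config$out_dir, "distinct_patterns.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  pat_sizes <- do.call(rbind, c(list(
    data.frame(network = character(), n_edges = integer(),
               count = integer(), stringsAsFactors = FALSE)),
    lapply(names(patterns), function(net) {
      sz <- vapply(patterns[[net]], function(p) p$n_edges, 0L)
      if (length(sz) == 0) return(NULL)
      tab <- table(sz)
      data.frame(network = net, n_edges = as.integer(names(tab)),
                 count = as.integer(tab), stringsAsFactors = FALSE)
    })))
  write_tsv(pat_sizes, file.path(config$out_dir, "distinct_pattern_sizes.tsv"))

  go_res <- NULL
  if (!is.null(config$obo)) {
    go_res <- stage("go", log, {
      ann <- go_annotation(read_obo(config$obo), read_gaf(config$gaf))
      rows <- list()
      for (net in names(distinct)) {
        for (d in distinct[[net]]) {
          sc <- subgraph_edge_scores(d, ann)
          rows[[length(rows) + 1L]] <-
            data.frame(network = net, subgraph_id = d$id,
                       n_edges = length(sc), mean_score = mean(sc),
                       stringsAsFactors = FALSE)
        }
      }
      do.call(rbind, rows)
    })
    write_tsv(go_res, file.path(config$out_dir, "go_scores.tsv"))
  } else {
    log("stage go: skipped (no OBO/GAF configured)")
  }

  val_res <- NULL
  if (!is.null(config$references)) {
    val_res <- stage("validate", log, {
      refs <- lapply(config$references, load_network_arg)
      overlap_matrix(distinct, refs)
    })
    write_tsv(val_res$rates, file.path(config$out_dir,
                                       "validation_rates.tsv"))
    fr <- data.frame(network = rownames(val_res$fraction),
                     val_res$fraction, check.names = FALSE,
                     stringsAsFactors = FALSE)
    write_tsv(fr, file.path(config$out_dir, "validation_fraction.tsv"))
    pv <- data.frame(network = rownames(val_res$p_values),
                     val_res$p_values, check.names = FALSE,
                     stringsAsFactors = FALSE)
    write_tsv(pv, file.path(config$out_dir, "validation_p_values.tsv"))
  } else {
    log("stage validate: skipped (no references configured)")
  }

  summary_df <- data.frame(
    network = names(nets),
    n_nodes = vapply(nets, function(g) length(g$nodes), 0L),
    n_edges = vapply(nets, function(g) nrow(g$edges), 0L),
    n_modules = vapply(modules, length, 0L),
    n_distinct_subgraphs = vapply(distinct, length, 0L),
    n_distinct_patterns = vapply(patterns, length, 0L),
    stringsAsFactors = FALSE)
  rownames(summary_df) <- NULL
  write_tsv(summary_df, file.path(config$out_dir, "summary.tsv"))
  log("pipeline complete")

  invisible(list(networks = nets, label_map = lm, modules = modules,
                 distinct = distinct, patterns = patterns, go = go_res,
                 validation = val_res, summary = summary_df,
                 out_dir = config$out_dir))
}
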