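# Restricted-neighbourhood-search clustering (RNSC).
#
# Tabu-assisted local search over partitions, minimizing first a naive and
# then a scaled misclassification cost. The search itself lives in
# src/rnsc.cpp; this file owns the cost definitions, the per-component
# orchestration and module extraction.

#' RNSC parameter set
#'
#' Defaults are the published settings for PPI-network clustering: tabu list
#' tolerance 1, tabu length 50, naive and scaled stopping tolerances 15,
#' diversification frequency 50, shuffling diversification length 3.
#'
#' @param tabu_tolerance times a vertex must appear in the tabu list before
#'   moves of that vertex are forbidden.
#' @param tabu_length number of recent moves kept in the tabu list.
#' @param naive_stopping_tolerance steps the naive phase may run without
#'   improving its best cost before stopping.
#' @param scaled_stopping_tolerance same, for the scaled phase.
#' @param diversification_frequency a shuffling diversification is performed
#'   every this many steps.
#' @param shuffling_diversification_length vertices moved per diversification.
#' @param seed integer seed governing the initial random clustering and all
#'   diversification randomness.
#' @param max_steps hard per-phase step cap (safety bound, rarely reached).
#' @return An object of class `rnsc_params`.
#' @export
rnsc_params <- function(tabu_tolerance = 1L, tabu_length = 50L,
                        naive_stopping_tolerance = 15L,
                        scaled_stopping_tolerance = 15L,
                        diversification_frequency = 50L,
                        shuffling_diversification_length = 3L,
                        seed = 1L, max_steps = 50000L) {
  p <- list(tabu_tolerance = as.integer(tabu_tolerance),
            tabu_length = as.integer(tabu_length),
            naive_stopping_tolerance = as.integer(naive_stopping_tolerance),
            scaled_stopping_tolerance = as.integer(scaled_stopping_tolerance),
            diversification_frequency = as.integer(diversification_frequency),
            shuffling_diversification_length =
              as.integer(shuffling_diversification_length),
            seed = as.integer(seed), max_steps = as.integer(max_steps))
  counts <- p[setdiff(names(p), "seed")]
  if (any(vapply(counts, function(x) is.na(x) || x < 1L, TRUE)))
    stop("all rnsc_params counts must be integers >= 1")
  structure(p, class = "rnsc_params")
}

# per-vertex bookkeeping shared by both cost functions:
# misplaced_v = |neighbours outside v's cluster| +
#               |non-neighbour co-members of v's cluster|
cost_terms <- function(g, assignment) {
  g <- as_ppi_graph(g)
  a <- assignment[g$nodes]
  if (anyNA(a)) stop("assignment must cover every node of the graph")
  cl <- as.integer(factor(as.character(a), levels = unique(as.character(a))))
  n <- length(g$nodes)
  deg <- integer(n)
  dsame <- integer(n)
  if (nrow(g$edges) > 0) {
    i <- match(g$edges[, 1], g$nodes)
    j <- match(g$edges[, 2], g$nodes)
    deg <- tabulate(c(i, j), nbins = n)
    same <- cl[i] == cl[j]
    dsame <- tabulate(c(i[same], j[same]), nbins = n)
  }
  sz <- tabulate(cl)
  mis <- (deg - dsame) + (sz[cl] - 1L - dsame)
  list(mis = mis, denom = sz[cl] + deg - dsame, n = n)
}

#' Naive RNSC cost of a partition
#'
#' Sum over vertices of the number of misplaced connections: neighbours
#' outside the vertex's cluster plus non-neighbours inside it.
#'
#' @param g a `ppi_graph`.
#' @param assignment named vector (node -> cluster id) covering all nodes.
#' @return Integer cost (0 for a perfect clique partition).
#' @examples
#' g <- ppi_graph(rbind(c("a", "b"), c("b", "c")))
#' naive_cost(g, c(a = 1, b = 1, c = 1))  # 2: a and c are non-adjacent co-members
#' @export
naive_cost <- function(g, assignment) {
  sum(cost_terms(g, assignment)$mis)
}

#' Scaled RNSC cost of a partition
#'
#' The naive per-vertex term divided by the size of the vertex's relevant
#' neighbourhood (its cluster united with its neighbours), summed and
#' normalized by `|V|/3`. Emphasizes misplacements in small neighbourhoods.
#'
#' @inheritParams naive_cost
#' @return Non-negative numeric cost.
#' @export
scaled_cost <- function(g, assignment) {
  ct <- cost_terms(g, assignment)
  sum(ct$mis / ct$denom) * ct$n / 3
}

#' Cluster a network with restricted-neighbourhood search
#'
#' Runs the naive-cost phase to its stopping tolerance and then the
#' scaled-cost phase, maintaining a tabu list and performing shuffling
#' diversification, and returns the best partition found. Each connected
#' component is searched independently: no optimal partition under either
#' cost merges vertices across components, and seeding each component's RNG
#' stream from the global seed plus the component's canonical label makes the
#' clustering of a component a pure function of its content. Deterministic
#' given `params$seed`.
#'
#' @param g a nonempty `ppi_graph`.
#' @param params an [rnsc_params()] object.
#' @param debug when `TRUE`, the search cross-checks its incrementally
#'   maintained cost against a full recomputation after every accepted move
#'   and reports the largest discrepancy.
#' @return An object of class `rnsc_partition`: `assignment` (named integer
#'   vector, node -> cluster id), `naive_cost`, `scaled_cost`, `n_clusters`,
#'   and `diagnostics` (per-component best-cost traces and, in debug mode,
#'   the maximum incremental-vs-full cost discrepancy).
#' @export
rnsc_cluster <- function(g, params = rnsc_params(), debug = FALSE) {
  g <- as_ppi_graph(g)
  if (length(g$nodes) == 0) stop("cannot cluster an empty graph")
  stopifnot(inherits(params, "rnsc_params"))
  comps <- graph_components(g)
  assignment <- setNames(integer(length(g$nodes)), g$nodes)
  offset <- 0L
  traces <- list()
  max_diff <- 0
  for (nodes in comps) {
    if (length(nodes) <= 2) {
      assignment[nodes] <- offset + 1L
      offset <- offset + 1L
      next
    }
    sub <- induced_subgraph_ppi(g, nodes)
    adj <- adj_index(sub)
    adj0 <- lapply(adj, function(x) as.integer(x - 1L))
    seed_c <- derive_seed(params$seed, canonical_key(sub))
    res <- with_seed(seed_c, .rnsc_search_cpp(
      adj0, params$tabu_tolerance, params$tabu_length,
      params$naive_stopping_tolerance, params$scaled_stopping_tolerance,
      params$diversification_frequency,
      params$shuffling_diversification_length, params$max_steps, debug))
    assignment[sub$nodes] <- offset + res$assignment + 1L
    offset <- offset + res$n_clusters
    traces[[length(traces) + 1L]] <-
      list(nodes = length(nodes), naive_trace = res$naive_trace,
           scaled_trace = res$scaled_trace)
    max_diff <- max(max_diff, res$debug_max_diff)
  }
  structure(list(assignment = assignment,
                 naive_cost = naive_cost(g, assignment),
                 scaled_cost = scaled_cost(g, assignment),
                 n_clusters = length(unique(assignment)),
                 diagnostics = list(traces = traces,
                                    debug_max_diff = max_diff)),
            class = "rnsc_partition")
}

#' @export
print.rnsc_partition <- function(x, ...) {
  cat(sprintf("<rnsc_partition: %d nodes, %d clusters, naive cost %d, scaled cost %.3f>\n",
              length(x$assignment), x$n_clusters, x$naive_cost,
              x$scaled_cost))
  invisible(x)
}

#' Extract connected modules from a partition
#'
#' For every cluster, takes the node-induced subgraph and emits each of its
#' connected components as a module. Single-node modules are retained here
#' (they are filtered later by the minimum-edge threshold). Module ids are
#' assigned deterministically in canonical-label order.
#'
#' @param g the clustered `ppi_graph`.
#' @param partition an `rnsc_partition` (or any named node -> cluster vector).
#' @param network network name stamped on each module.
#' @return List of `ppi_module` objects: `id`, `network`, `graph`,
#'   `canonical`, `key`.
#' @export
extract_modules <- function(g, partition, network = "net") {
  g <- as_ppi_graph(g)
  assignment <- if (inherits(partition, "rnsc_partition"))
    partition$assignment else partition
  a <- assignment[g$nodes]
  if (anyNA(a)) stop("partition must cover every node of the graph")
  pieces <- list()
  for (nodes in split(g$nodes, as.character(a))) {
    sub <- induced_subgraph_ppi(g, nodes)
    for (comp in graph_components(sub)) {
      pieces[[length(pieces) + 1L]] <- induced_subgraph_ppi(sub, comp)
    }
  }
  keys <- vapply(pieces, canonical_key, "")
  o <- order(keys, method = "radix")
  lapply(seq_along(o), function(r) {
    gr <- pieces[[o[r]]]
    structure(list(id = sprintf("%s:%04d", network, r), network = network,
                   graph = gr, canonical = canonical_label(gr),
                   key = keys[o[r]]),
              class = "ppi_module")
  })
}

#' @export
print.ppi_module <- function(x, ...) {
  cat(sprintf("<module %s: %d nodes, %d edges>\n", x$id,
              length(x$graph$nodes), nrow(x$graph$edges)))
  invisible(x)
}
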