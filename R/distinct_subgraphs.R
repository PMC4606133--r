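# Distinct-subgraph identification: from per-network module sets, keep the
# modules whose exact node-and-edge content occurs in exactly one network and
# is not an edge-subset of any other module.

#' Build per-network canonical-label hash tables
#'
#' One table per network mapping the canonical label key of every module to
#' the module itself. Collisions are impossible because the canonical label
#' determines the node and edge sets exactly.
#'
#' @param modules_by_network named list (network -> list of `ppi_module`).
#' @return Named list of named lists (canonical key -> module).
#' @export
build_label_table <- function(modules_by_network) {
  stopifnot(is.list(modules_by_network), !is.null(names(modules_by_network)))
  lapply(modules_by_network, function(mods) {
    keys <- vapply(mods, function(m) m$key, "")
    setNames(mods, keys)
  })
}

#' Identify subgraphs distinct to a single network
#'
#' A module `m` of network `N` is a distinct subgraph iff (i) it has at least
#' `min_edges` edges, (ii) its canonical label is absent from every other
#' network's module table, and (iii) its edge set is not a subset of the edge
#' set of any other module in any network (including `N`; modules within one
#' network are node-disjoint under RNSC, so same-network enclosure only
#' matters for pluggable clusterers that emit overlapping modules).
#'
#' @param tables output of [build_label_table()] over at least two networks.
#' @param min_edges minimum edge count (default 3).
#' @return Named list (network -> list of `distinct_subgraph` objects, each a
#'   module carrying its network name).
#' @export
find_distinct_subgraphs <- function(tables, min_edges = 3) {
  stopifnot(is.list(tables))
  if (length(tables) < 2)
    stop("distinct-subgraph identification needs at least 2 networks")
  nets <- names(tables)
  # flat module list + inverted edge -> module-uid index for enclosure tests
  uid <- character()
  unet <- character()
  umod <- list()
  edge_index <- new.env(parent = emptyenv())
  for (net in nets) {
    for (m in tables[[net]]) {
      u <- paste0(net, "\r", m$key)
      uid <- c(uid, u)
      unet <- c(unet, net)
      umod[[u]] <- m
      for (ek in edge_keys(m$graph)) {
        edge_index[[ek]] <- c(edge_index[[ek]], u)
      }
    }
  }
  out <- setNames(vector("list", length(nets)), nets)
  for (net in nets) {
    kept <- list()
    for (m in tables[[net]]) {
      if (n_edges(m$graph) < min_edges) next
      others <- setdiff(nets, net)
      if (any(vapply(others, function(o) !is.null(tables[[o]][[m$key]]),
                     TRUE))) next
      # enclosure: a module containing every edge of m is exactly the
      # intersection of the inverted index over m's edges
      u <- paste0(net, "\r", m$key)
      sup <- Reduce(intersect, lapply(edge_keys(m$graph), function(ek)
        edge_index[[ek]]))
      if (length(setdiff(sup, u)) > 0) next
      kept[[length(kept) + 1L]] <-
        structure(list(module = m, network = net, id = m$id, key = m$key,
                       graph = m$graph),
                  class = c("distinct_subgraph", "ppi_module"))
    }
    out[[net]] <- kept
  }
  out
}

#' Edge-count size distribution of subgraph sets
#'
#' Histogram report of subgraph sizes by edge count, one row per
#' (network, n_edges).
#'
#' @param subgraphs_by_network named list (network -> list of modules or
#'   distinct subgraphs).
#' @return Data frame with columns `network`, `n_edges`, `count`.
#' @export
subgraph_size_table <- function(subgraphs_by_network) {
  rows <- list()
  for (net in names(subgraphs_by_network)) {
    sizes <- vapply(subgraphs_by_network[[net]], function(s)
      n_edges(as_ppi_graph(s)), 0L)
    if (length(sizes) == 0) next
    tab <- table(sizes)
    rows[[net]] <- data.frame(network = net,
                              n_edges = as.integer(names(tab)),
                              count = as.integer(tab),
                              stringsAsFactors = FALSE)
  }
  if (length(rows) == 0)
    return(data.frame(network = character(), n_edges = integer(),
                      count = integer(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$network, out$n_edges, method = "radix"), , drop = FALSE]
}
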