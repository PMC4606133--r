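# Core graph containers, canonical labeling and the exact isomorphism oracle.
#
# Graphs are stored as a sorted character vector of node identifiers plus an
# m x 2 character matrix of normalized undirected edges (first column before
# the second in C-locale order, no duplicates, no self-loops). All downstream
# stages key hash tables on the canonical label, so normalization at
# construction is what makes those keys well defined.

#' Construct an undirected protein-protein interaction graph
#'
#' Nodes are opaque string identifiers. Edges are unordered pairs; `(u,v)` and
#' `(v,u)` collapse to one edge, duplicates are dropped silently, and
#' self-loops are dropped with a warning (the upper-triangle canonical label
#' excludes the diagonal, so loops cannot be represented).
#'
#' @param edges two-column character matrix or data frame of endpoints, or
#'   `NULL` for an edgeless graph.
#' @param nodes optional character vector of additional (possibly isolated)
#'   node identifiers.
#' @return An object of class `ppi_graph` with elements `nodes` (sorted) and
#'   `edges` (normalized two-column matrix).
#' @examples
#' g <- ppi_graph(rbind(c("b", "a"), c("b", "c")))
#' g$edges
#' @export
ppi_graph <- function(edges = NULL, nodes = NULL) {
  if (is.null(edges) || (is.matrix(edges) && nrow(edges) == 0) ||
      (is.data.frame(edges) && nrow(edges) == 0)) {
    em <- matrix(character(), 0, 2)
  } else {
    if (is.data.frame(edges)) edges <- as.matrix(edges)
    if (!is.matrix(edges) || ncol(edges) != 2)
      stop("`edges` must be a two-column matrix or data frame")
    storage.mode(edges) <- "character"
    em <- edges
  }
  if (nrow(em) > 0) {
    loops <- em[, 1] == em[, 2]
    if (any(loops)) {
      warning(sprintf("dropping %d self-loop(s): undirected upper-triangle representation excludes the diagonal", sum(loops)))
      em <- em[!loops, , drop = FALSE]
    }
  }
  a <- unname(em[, 1])
  b <- unname(em[, 2])
  if (length(a) > 0) {
    lev <- csort(unique(c(a, b)))
    ia <- match(a, lev)
    ib <- match(b, lev)
    swap <- ia > ib
    if (any(swap)) {
      tmp <- a[swap]
      a[swap] <- b[swap]
      b[swap] <- tmp
      tmp <- ia[swap]
      ia[swap] <- ib[swap]
      ib[swap] <- tmp
    }
    keep <- !duplicated(ia * (length(lev) + 1) + ib)
    a <- a[keep]
    b <- b[keep]
  }
  allnodes <- csort(unique(c(a, b, as.character(nodes))))
  o <- order(match(a, allnodes), match(b, allnodes))
  structure(list(nodes = allnodes,
                 edges = cbind(a[o], b[o], deparse.level = 0)),
            class = "ppi_graph")
}

#' @export
print.ppi_graph <- function(x, ...) {
  cat(sprintf("<ppi_graph: %d nodes, %d edges>\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Number of nodes / edges of a graph
#' @param g a `ppi_graph` or `ppi_lgraph`.
#' @return Integer count.
#' @export
n_nodes <- function(g) length(as_ppi_graph(g)$nodes)

#' @rdname n_nodes
#' @export
n_edges <- function(g) nrow(as_ppi_graph(g)$edges)

#' Canonical string keys of a graph's edges
#'
#' One `"u\tv"` key per normalized edge; used for overlap and enclosure tests.
#' @param g a `ppi_graph` (or anything [as_ppi_graph()] accepts).
#' @return Character vector of edge keys.
#' @export
edge_keys <- function(g) {
  g <- as_ppi_graph(g)
  if (nrow(g$edges) == 0) return(character())
  paste(g$edges[, 1], g$edges[, 2], sep = "\t")
}

#' Coerce to a plain `ppi_graph`
#'
#' Accepts a `ppi_graph`, a labeled graph, or a module and returns the
#' underlying plain graph.
#' @param x object to coerce.
#' @return A `ppi_graph`.
#' @export
as_ppi_graph <- function(x) {
  if (inherits(x, "ppi_graph")) return(x)
  if (inherits(x, "ppi_lgraph")) return(x$graph)
  if (inherits(x, "ppi_module")) return(x$graph)
  stop("cannot coerce object of class ", paste(class(x), collapse = "/"),
       " to ppi_graph")
}

#' Attach node labels to a graph
#'
#' @param graph a `ppi_graph`.
#' @param labels named character vector mapping every node of `graph` to its
#'   cluster label.
#' @return An object of class `ppi_lgraph` with elements `graph` and `labels`
#'   (reordered to the graph's node order).
#' @export
labeled_graph <- function(graph, labels) {
  graph <- as_ppi_graph(graph)
  labels <- unlist(labels)
  storage.mode(labels) <- "character"
  missing <- setdiff(graph$nodes, names(labels))
  if (length(missing) > 0)
    stop("unlabeled node(s): ", paste(head(missing, 5), collapse = ", "))
  structure(list(graph = graph, labels = labels[graph$nodes]),
            class = "ppi_lgraph")
}

#' @export
print.ppi_lgraph <- function(x, ...) {
  cat(sprintf("<labeled ppi_graph: %d nodes, %d edges, %d labels>\n",
              length(x$graph$nodes), nrow(x$graph$edges),
              length(unique(x$labels))))
  invisible(x)
}

#' Canonical label of a graph
#'
#' The canonical label is the node list in ascending lexicographic (C-locale)
#' order followed by the concatenated upper-right triangle of the adjacency
#' matrix under that order, one character per node pair. Two graphs map to the
#' same canonical label exactly when they have identical node sets and
#' identical edge sets, and the label does not depend on the order in which
#' nodes or edges were supplied.
#'
#' @param g a `ppi_graph` (or labeled graph) with at least one node.
#' @return An object of class `canonical_label` with elements `sorted_nodes`
#'   and `bitstring` (length `n(n-1)/2`).
#' @examples
#' cl <- canonical_label(ppi_graph(rbind(c("a", "b"), c("b", "c"))))
#' cl$bitstring  # "101": pairs (a,b), (a,c), (b,c)
#' @export
canonical_label <- function(g) {
  g <- as_ppi_graph(g)
  n <- length(g$nodes)
  if (n < 1) stop("canonical label requires at least one node")
  m <- n * (n - 1L) / 2L
  if (nrow(g$edges) == 0) {
    bits <- paste(rep("0", m), collapse = "")
  } else {
    i <- match(g$edges[, 1], g$nodes)
    j <- match(g$edges[, 2], g$nodes)
    k <- (i - 1) * n - i * (i - 1) / 2 + (j - i)
    bits <- .bitstring_cpp(as.integer(k), as.integer(m))
  }
  structure(list(sorted_nodes = g$nodes, bitstring = bits),
            class = "canonical_label")
}

#' Single-string hash key of a canonical label
#'
#' @param x a `canonical_label`, or a graph to label first.
#' @return Character scalar usable as a hash-table key.
#' @export
canonical_key <- function(x) {
  if (!inherits(x, "canonical_label")) x <- canonical_label(x)
  paste0(paste(x$sorted_nodes, collapse = ","), "|", x$bitstring)
}

#' Graph pattern of a labeled graph
#'
#' Abstraction of a labeled graph obtained by replacing node identities with
#' their cluster labels: a sorted label multiset plus a multiset of unordered
#' label pairs with multiplicities. Invariant under any label-preserving
#' renaming of node identifiers.
#'
#' @param lg a `ppi_lgraph`.
#' @return An object of class `graph_pattern` with elements `labels` (sorted
#'   character vector) and `edges` (data frame `label_a`, `label_b`, `count`).
#' @examples
#' lg <- labeled_graph(ppi_graph(rbind(c("a1", "b1"), c("a5", "b2"))),
#'                     c(a1 = "A", a5 = "A", b1 = "B", b2 = "B"))
#' pattern_of(lg)$edges  # A-B with count 2
#' @export
pattern_of <- function(lg) {
  stopifnot(inherits(lg, "ppi_lgraph"))
  e <- lg$graph$edges
  if (nrow(e) == 0) {
    ed <- data.frame(label_a = character(), label_b = character(),
                     count = integer(), stringsAsFactors = FALSE)
  } else {
    la <- unname(lg$labels[e[, 1]])
    lb <- unname(lg$labels[e[, 2]])
    lev <- csort(unique(c(la, lb)))
    swap <- match(la, lev) > match(lb, lev)
    p1 <- ifelse(swap, lb, la)
    p2 <- ifelse(swap, la, lb)
    key <- paste(p1, p2, sep = "\t")
    tab <- table(key)
    ks <- csort(names(tab))
    parts <- strsplit(ks, "\t", fixed = TRUE)
    ed <- data.frame(label_a = vapply(parts, `[`, "", 1),
                     label_b = vapply(parts, `[`, "", 2),
                     count = as.integer(tab[ks]),
                     stringsAsFactors = FALSE)
  }
  structure(list(labels = csort(unname(lg$labels)), edges = ed),
            class = "graph_pattern")
}

#' Hash key of a graph pattern
#' @param p a `graph_pattern` or a `ppi_lgraph` to abstract first.
#' @return Character scalar.
#' @export
pattern_key <- function(p) {
  if (inherits(p, "ppi_lgraph")) p <- pattern_of(p)
  stopifnot(inherits(p, "graph_pattern"))
  paste0(paste(p$labels, collapse = ","), "||",
         paste(sprintf("%s-%s(%d)", p$edges$label_a, p$edges$label_b,
                       p$edges$count), collapse = ","))
}

# 0-based-free adjacency index: list over g$nodes of integer neighbour indices
adj_index <- function(g) {
  n <- length(g$nodes)
  out <- vector("list", n)
  for (v in seq_len(n)) out[[v]] <- integer()
  if (nrow(g$edges) > 0) {
    i <- match(g$edges[, 1], g$nodes)
    j <- match(g$edges[, 2], g$nodes)
    for (k in seq_along(i)) {
      out[[i[k]]] <- c(out[[i[k]]], j[k])
      out[[j[k]]] <- c(out[[j[k]]], i[k])
    }
  }
  out
}

#' Exact label-preserving subgraph isomorphism test
#'
#' Exhaustive backtracking search for an injection of the query's nodes into
#' the target's nodes that preserves node labels and maps every query edge to
#' a target edge. This is the exact oracle behind the `"exact"` matching mode
#' and the ground-truth audits of the synthetic-ensemble generator.
#'
#' @param query,target labeled graphs (`ppi_lgraph`) over the same label
#'   alphabet.
#' @return A list with elements `found` (logical) and `node_map` (named
#'   character vector, query node -> target node; empty when not found).
#' @export
is_subgraph_isomorphic_exact <- function(query, target) {
  stopifnot(inherits(query, "ppi_lgraph"), inherits(target, "ppi_lgraph"))
  qn <- query$graph$nodes
  tn <- target$graph$nodes
  nq <- length(qn)
  if (nq == 0) return(list(found = TRUE, node_map = character()))
  qadj <- adj_index(query$graph)
  tadj <- adj_index(target$graph)
  qdeg <- lengths(qadj)
  tdeg <- lengths(tadj)
  qlab <- unname(query$labels[qn])
  tlab <- unname(target$labels[tn])

  # assign high-degree query nodes first (nodes are pre-sorted, so ties break
  # on identifier order)
  ord <- order(-qdeg)
  cand0 <- lapply(seq_len(nq), function(q) {
    which(tlab == qlab[q] & tdeg >= qdeg[q])
  })
  if (any(lengths(cand0) == 0)) return(list(found = FALSE,
                                            node_map = character()))
  used <- logical(length(tn))
  map <- integer(nq)

  rec <- function(pos) {
    if (pos > nq) return(TRUE)
    q <- ord[pos]
    mapped_nb <- qadj[[q]][map[qadj[[q]]] > 0]
    for (t in cand0[[q]]) {
      if (used[t]) next
      ok <- TRUE
      for (nb in mapped_nb) {
        if (!(map[nb] %in% tadj[[t]])) { ok <- FALSE; break }
      }
      if (!ok) next
      map[q] <<- t
      used[t] <<- TRUE
      if (rec(pos + 1)) return(TRUE)
      map[q] <<- 0L
      used[t] <<- FALSE
    }
    FALSE
  }
  found <- rec(1)
  if (found) {
    list(found = TRUE, node_map = setNames(tn[map], qn))
  } else {
    list(found = FALSE, node_map = character())
  }
}

#' Node-induced subgraph
#'
#' @param g a `ppi_graph`.
#' @param nodes node identifiers to keep (must be a subset of `g$nodes`).
#' @return A `ppi_graph` on `nodes` with every edge of `g` internal to them.
#' @export
induced_subgraph_ppi <- function(g, nodes) {
  g <- as_ppi_graph(g)
  bad <- setdiff(nodes, g$nodes)
  if (length(bad) > 0)
    stop("nodes not in graph: ", paste(head(bad, 5), collapse = ", "))
  keep <- g$edges[, 1] %in% nodes & g$edges[, 2] %in% nodes
  ppi_graph(g$edges[keep, , drop = FALSE], nodes = nodes)
}

# igraph view of a ppi_graph (undirected, vertex names preserved)
as_igraph <- function(g) {
  g <- as_ppi_graph(g)
  igraph::graph_from_data_frame(
    d = data.frame(from = g$edges[, 1], to = g$edges[, 2],
                   stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = g$nodes, stringsAsFactors = FALSE))
}

#' Connected components of a graph
#'
#' @param g a `ppi_graph`.
#' @return List of character vectors of node identifiers, one per component,
#'   ordered by their smallest member.
#' @export
graph_components <- function(g) {
  g <- as_ppi_graph(g)
  if (length(g$nodes) == 0) return(list())
  memb <- igraph::components(as_igraph(g))$membership
  comps <- split(names(memb), memb)
  comps <- lapply(comps, csort)
  comps[order(vapply(comps, `[`, "", 1), method = "radix")]
}

#' Read an undirected edge list from a TSV file
#'
#' Two tab-separated columns of node identifiers; lines starting with `#` are
#' skipped; an optional header row named `node_a`/`node_b` (any case) is
#' recognized and dropped.
#'
#' @param path file path.
#' @return A `ppi_graph`.
#' @export
read_edge_list <- function(path) {
  df <- tryCatch(
    read.table(path, sep = "\t", comment.char = "#", header = FALSE,
               colClasses = "character", quote = "",
               stringsAsFactors = FALSE),
    error = function(e) NULL)
  if (is.null(df) || nrow(df) == 0) return(ppi_graph())
  if (ncol(df) < 2) stop("edge list needs two tab-separated columns: ", path)
  df <- df[, 1:2]
  if (tolower(df[1, 1]) %in% c("node_a", "source", "from"))
    df <- df[-1, , drop = FALSE]
  if (nrow(df) == 0) return(ppi_graph())
  ppi_graph(as.matrix(df))
}

#' Write an edge list TSV
#'
#' @param g a `ppi_graph`.
#' @param path output file path.
#' @param header optional comment lines (written prefixed with `#`).
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(g, path, header = NULL) {
  g <- as_ppi_graph(g)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  writeLines("node_a\tnode_b", con)
  if (nrow(g$edges) > 0)
    writeLines(paste(g$edges[, 1], g$edges[, 2], sep = "\t"), con)
  invisible(path)
}

#' Write a graph (optionally labeled) as JSON
#'
#' Schema: `{"nodes": [...], "edges": [[u, v], ...], "labels": {node: label}}`.
#'
#' @param g a `ppi_graph` or `ppi_lgraph`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_graph_json <- function(g, path) {
  labels <- NULL
  if (inherits(g, "ppi_lgraph")) {
    labels <- as.list(g$labels)
    g <- g$graph
  }
  g <- as_ppi_graph(g)
  edges <- lapply(seq_len(nrow(g$edges)), function(i) unname(g$edges[i, ]))
  obj <- list(nodes = g$nodes, edges = edges)
  if (!is.null(labels)) obj$labels <- labels
  jsonlite::write_json(obj, path, auto_unbox = FALSE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a graph from the JSON schema written by [write_graph_json()]
#'
#' @param path JSON file path.
#' @return A `ppi_lgraph` when labels are present, otherwise a `ppi_graph`.
#' @export
read_graph_json <- function(path) {
  obj <- jsonlite::read_json(path)
  edges <- do.call(rbind, lapply(obj$edges, function(e)
    c(as.character(e[[1]]), as.character(e[[2]]))))
  g <- ppi_graph(edges, nodes = unlist(obj$nodes))
  if (!is.null(obj$labels))
    return(labeled_graph(g, unlist(obj$labels)))
  g
}

#' Write a graph in GraphML format
#'
#' @param g a `ppi_graph`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(g, path) {
  igraph::write_graph(as_igraph(g), path, format = "graphml")
  invisible(path)
}
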