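# Edge-pattern index and the two pattern-matching algorithms that reduce
# distinct subgraphs to distinct subgraph patterns.
#
# The index holds three structures: subgraph -> edge patterns (ds1), the
# reverse index edge pattern -> subgraphs (ds2), and edge pattern -> expanded
# patterns with the same label pair but higher count (ds3). A candidate query
# is first filtered through the index (never losing a true match), then
# verified either with the greedy highest-degree matcher or the exact
# backtracking oracle.

edge_pattern_keys <- function(edges_df) {
  sprintf("%s\t%s\t%d", edges_df$label_a, edges_df$label_b, edges_df$count)
}

#' Build the three-part edge-pattern index
#'
#' @param subgraphs named list (subgraph id -> `ppi_lgraph`); every node must
#'   be labeled.
#' @return An object of class `pattern_index`: `ds1` (id -> edge-pattern data
#'   frame), `ds2` (pattern key -> subgraph ids), `ds3` (pattern key ->
#'   expanded pattern keys, same label pair, higher count), `sizes` (data
#'   frame of node/edge counts), `pair_counts` (label pair -> sorted counts
#'   present in the index).
#' @export
build_index <- function(subgraphs) {
  stopifnot(is.list(subgraphs))
  if (length(subgraphs) > 0 && is.null(names(subgraphs)))
    stop("subgraphs must be a named list")
  ds1 <- list()
  ds2 <- list()
  pair_counts <- list()
  n_nodes_v <- integer(length(subgraphs))
  n_edges_v <- integer(length(subgraphs))
  for (i in seq_along(subgraphs)) {
    lg <- subgraphs[[i]]
    stopifnot(inherits(lg, "ppi_lgraph"))
    id <- names(subgraphs)[i]
    ed <- pattern_of(lg)$edges
    ds1[[id]] <- ed
    n_nodes_v[i] <- length(lg$graph$nodes)
    n_edges_v[i] <- nrow(lg$graph$edges)
    if (nrow(ed) > 0) {
      for (r in seq_len(nrow(ed))) {
        k <- sprintf("%s\t%s\t%d", ed$label_a[r], ed$label_b[r], ed$count[r])
        pk <- paste(ed$label_a[r], ed$label_b[r], sep = "\t")
        ds2[[k]] <- c(ds2[[k]], id)
        pair_counts[[pk]] <- sort(unique(c(pair_counts[[pk]], ed$count[r])))
      }
    }
  }
  # ds3: for each indexed pattern, the indexed patterns with the same label
  # pair and strictly higher count
  ds3 <- list()
  for (pk in names(pair_counts)) {
    cs <- pair_counts[[pk]]
    for (c0 in cs) {
      k <- sprintf("%s\t%d", pk, c0)
      higher <- cs[cs > c0]
      ds3[[k]] <- if (length(higher) > 0)
        sprintf("%s\t%d", pk, higher) else character()
    }
  }
  structure(list(ds1 = ds1, ds2 = ds2, ds3 = ds3,
                 pair_counts = pair_counts,
                 sizes = data.frame(id = names(subgraphs),
                                    n_nodes = n_nodes_v,
                                    n_edges = n_edges_v,
                                    stringsAsFactors = FALSE),
                 subgraphs = subgraphs),
            class = "pattern_index")
}

#' @export
print.pattern_index <- function(x, ...) {
  cat(sprintf("<pattern_index: %d subgraphs, %d edge patterns>\n",
              length(x$ds1), length(x$ds2)))
  invisible(x)
}

#' Candidate matching subgraphs for a query (index filter)
#'
#' Prefilters indexed subgraphs with fewer nodes or edges than the query,
#' then, for each edge pattern of the query, takes the union of the reverse
#' index over the pattern and its expanded patterns, and intersects the
#' per-pattern candidate sets. An empty result proves the query's pattern is
#' absent from the indexed set; a non-empty result still needs verification.
#' The filter is sound: it never drops a subgraph into which the query has a
#' label-preserving embedding.
#'
#' @param query a `ppi_lgraph`.
#' @param index a [build_index()] object over the candidate universe.
#' @return Character vector of candidate subgraph ids (sorted).
#' @export
candidate_subgraphs <- function(query, index) {
  stopifnot(inherits(query, "ppi_lgraph"), inherits(index, "pattern_index"))
  qn <- length(query$graph$nodes)
  qe <- nrow(query$graph$edges)
  cands <- index$sizes$id[index$sizes$n_nodes >= qn &
                          index$sizes$n_edges >= qe]
  qp <- pattern_of(query)$edges
  for (r in seq_len(nrow(qp))) {
    if (length(cands) == 0) break
    pk <- paste(qp$label_a[r], qp$label_b[r], sep = "\t")
    cs <- index$pair_counts[[pk]]
    cs <- cs[cs >= qp$count[r]]  # the pattern itself plus expanded patterns
    if (length(cs) == 0) return(character())
    ids <- unique(unlist(index$ds2[sprintf("%s\t%d", pk, cs)],
                         use.names = FALSE))
    cands <- intersect(cands, ids)
  }
  csort(cands)
}

# Greedy highest-degree matcher: seed at the query node of highest degree,
# repeatedly extend to the unmatched query node of highest degree among those
# adjacent to matched nodes; a counterpart must share the label and cover the
# already-matched adjacencies; first compatible counterpart is taken and
# there is no backtracking, so the matcher can miss embeddings on symmetric
# candidates (the exact mode exists for that reason).
greedy_match <- function(query, target) {
  qn <- query$graph$nodes
  tn <- target$graph$nodes
  nq <- length(qn)
  if (nq == 0) return(TRUE)
  qadj <- adj_index(query$graph)
  tadj <- adj_index(target$graph)
  qdeg <- lengths(qadj)
  tdeg <- lengths(tadj)
  qlab <- unname(query$labels[qn])
  tlab <- unname(target$labels[tn])
  map <- integer(nq)           # 0 = unmatched
  used <- logical(length(tn))
  for (step in seq_len(nq)) {
    un <- which(map == 0L)
    frontier <- un[vapply(un, function(q)
      any(map[qadj[[q]]] > 0L), TRUE)]
    pool <- if (step == 1 || length(frontier) == 0) un else frontier
    q <- pool[order(-qdeg[pool])][1]   # ties: node-identifier order
    imgs <- map[qadj[[q]][map[qadj[[q]]] > 0L]]
    ok <- FALSE
    for (t in seq_along(tn)) {
      if (used[t] || tlab[t] != qlab[q]) next
      if (all(imgs %in% tadj[[t]])) {
        map[q] <- t
        used[t] <- TRUE
        ok <- TRUE
        break
      }
    }
    if (!ok) return(FALSE)     # halt: query node could not be matched
  }
  TRUE
}

#' Verify candidate matches of a query subgraph
#'
#' @param query a `ppi_lgraph`.
#' @param candidates list of `ppi_lgraph` candidates (from the index filter).
#' @param mode `"exact"` (backtracking label-preserving subgraph isomorphism,
#'   the default) or `"paper_greedy"` (highest-degree greedy extension
#'   without backtracking; fast but incomplete on symmetric candidates).
#' @return Logical vector, one verdict per candidate.
#' @export
verify_matching <- function(query, candidates,
                            mode = c("exact", "paper_greedy")) {
  mode <- match.arg(mode)
  stopifnot(inherits(query, "ppi_lgraph"))
  vapply(candidates, function(cand) {
    stopifnot(inherits(cand, "ppi_lgraph"))
    if (mode == "exact") {
      is_subgraph_isomorphic_exact(query, cand)$found
    } else {
      greedy_match(query, cand)
    }
  }, TRUE)
}

attach_labels <- function(x, label_of) {
  g <- as_ppi_graph(x)
  missing <- setdiff(g$nodes, names(label_of))
  if (length(missing) > 0)
    stop("unlabeled node(s): ", paste(head(missing, 5), collapse = ", "))
  labeled_graph(g, label_of[g$nodes])
}

#' Reduce distinct subgraphs to distinct subgraph patterns
#'
#' A distinct subgraph's pattern is distinct when it occurs in no other
#' network, either as a module or embedded inside a module: for every other
#' network, the index filter returns no candidate or verification rejects
#' every candidate. The candidate universe is all modules of the other
#' networks, not only their distinct subgraphs. Distinct subgraphs of one
#' network sharing a pattern collapse into a single distinct pattern with
#' multiple witnesses. Only subgraphs with at least `min_edges` edges are
#' processed.
#'
#' @param distinct_by_network output of [find_distinct_subgraphs()].
#' @param modules_by_network named list (network -> all modules, candidate
#'   universe).
#' @param label_of named character vector (node -> cluster label) or a
#'   `label_map`.
#' @param mode matching mode passed to [verify_matching()].
#' @param min_edges minimum edge count (default 3).
#' @return Named list (network -> list of `distinct_pattern` objects:
#'   `pattern`, `key`, `witnesses` (distinct-subgraph ids), `network`,
#'   `n_edges`).
#' @export
find_distinct_patterns <- function(distinct_by_network, modules_by_network,
                                   label_of, mode = c("exact", "paper_greedy"),
                                   min_edges = 3) {
  mode <- match.arg(mode)
  if (inherits(label_of, "label_map")) label_of <- label_of$label_of
  nets <- names(distinct_by_network)
  indices <- lapply(modules_by_network, function(mods) {
    labeled <- lapply(mods, attach_labels, label_of = label_of)
    names(labeled) <- vapply(mods, function(m) m$id, "")
    build_index(labeled)
  })
  out <- setNames(vector("list", length(nets)), nets)
  for (net in nets) {
    survivors <- list()
    for (ds in distinct_by_network[[net]]) {
      if (n_edges(as_ppi_graph(ds)) < min_edges) next
      q <- attach_labels(ds, label_of)
      found_elsewhere <- FALSE
      for (other in setdiff(names(indices), net)) {
        idx <- indices[[other]]
        cands <- candidate_subgraphs(q, idx)
        if (length(cands) == 0) next
        verdicts <- verify_matching(q, idx$subgraphs[cands], mode = mode)
        if (any(verdicts)) {
          found_elsewhere <- TRUE
          break
        }
      }
      if (!found_elsewhere)
        survivors[[length(survivors) + 1L]] <- list(id = ds$id, query = q)
    }
    keys <- vapply(survivors, function(s) pattern_key(s$query), "")
    pats <- list()
    for (k in unique(csort(keys))) {
      members <- survivors[keys == k]
      pats[[length(pats) + 1L]] <- structure(
        list(pattern = pattern_of(members[[1]]$query), key = k,
             witnesses = vapply(members, function(s) s$id, ""),
             network = net,
             n_edges = nrow(members[[1]]$query$graph$edges)),
        class = "distinct_pattern")
    }
    out[[net]] <- pats
  }
  out
}

#' @export
print.distinct_pattern <- function(x, ...) {
  cat(sprintf("<distinct_pattern [%s]: %d edges, %d witness(es) in %s>\n",
              x$key, x$n_edges, length(x$witnesses), x$network))
  invisible(x)
}
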