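# Minimum-subsumer GO semantic similarity.
#
# Term probabilities are Resnik-style annotation frequencies: p(term) is the
# fraction of a concept's annotations that hit the term or any descendant, so
# p(root) = 1 and p is monotone non-decreasing from child to parent. The
# similarity of two term sets is -ln of the probability of their least
# frequent shared (inclusive) ancestor; per-protein-pair scores sum the best
# per-concept similarities, clamped to [0, 10].

GO_CONCEPTS <- c("P", "F", "C")
NAMESPACE_TO_CONCEPT <- c(biological_process = "P", molecular_function = "F",
                          cellular_component = "C")

#' Read a GO ontology from an OBO file
#'
#' Minimal parser for `[Term]` stanzas: `id`, `name`, `namespace`, `is_a`
#' and (optionally) `relationship: part_of` links; obsolete terms are
#' dropped.
#'
#' @param path OBO file path.
#' @param include_part_of treat `part_of` relationships as parent links
#'   (default `FALSE`: `is_a` only).
#' @return An object of class `go_obo`: `id`, `name`, `namespace` (named
#'   character vectors) and `parents` (named list term -> parent terms).
#' @export
read_obo <- function(path, include_part_of = FALSE) {
  lines <- readLines(path, warn = FALSE)
  terms <- list()
  cur <- NULL
  in_term <- FALSE
  flush <- function(cur, terms) {
    if (!is.null(cur) && !isTRUE(cur$obsolete) && !is.null(cur$id))
      terms[[cur$id]] <- cur
    terms
  }
  for (ln in lines) {
    ln <- sub("\\s*!.*$", "", ln)  # strip OBO comments
    if (ln == "[Term]") {
      terms <- flush(cur, terms)
      cur <- list(parents = character())
      in_term <- TRUE
      next
    }
    if (grepl("^\\[", ln)) {       # other stanza type
      terms <- flush(cur, terms)
      cur <- NULL
      in_term <- FALSE
      next
    }
    if (!in_term || !nzchar(ln)) next
    if (grepl("^id: ", ln)) cur$id <- sub("^id: *", "", ln)
    else if (grepl("^name: ", ln)) cur$name <- sub("^name: *", "", ln)
    else if (grepl("^namespace: ", ln))
      cur$namespace <- sub("^namespace: *", "", ln)
    else if (grepl("^is_a: ", ln))
      cur$parents <- c(cur$parents, trimws(sub("^is_a: *", "", ln)))
    else if (include_part_of && grepl("^relationship: *part_of ", ln))
      cur$parents <- c(cur$parents,
                       trimws(sub("^relationship: *part_of *", "", ln)))
    else if (grepl("^is_obsolete: *true", ln)) cur$obsolete <- TRUE
  }
  terms <- flush(cur, terms)
  ids <- names(terms)
  structure(list(
    id = ids,
    name = setNames(vapply(terms, function(t) t$name %||% "", ""), ids),
    namespace = setNames(vapply(terms, function(t) t$namespace %||% "", ""),
                         ids),
    parents = setNames(lapply(terms, function(t)
      intersect(t$parents, ids)), ids)),
    class = "go_obo")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read protein annotations from a GAF 2.x file
#'
#' Comment lines (`!`) are skipped and rows whose qualifier contains `NOT`
#' are dropped. Only the object id (column 2), GO id (column 5) and aspect
#' (column 9) are used.
#'
#' @param path GAF file path.
#' @return Data frame with columns `protein`, `term`, `concept` (P/F/C).
#' @export
read_gaf <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^!", lines) & nzchar(lines)]
  if (length(lines) == 0)
    return(data.frame(protein = character(), term = character(),
                      concept = character(), stringsAsFactors = FALSE))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  keep <- vapply(parts, function(p)
    length(p) >= 9 && !grepl("NOT", p[4]), TRUE)
  parts <- parts[keep]
  data.frame(protein = vapply(parts, `[`, "", 2),
             term = vapply(parts, `[`, "", 5),
             concept = vapply(parts, `[`, "", 9),
             stringsAsFactors = FALSE)
}

# inclusive ancestor closure (a term is its own ancestor), memoized
ancestor_closure <- function(parents) {
  cache <- new.env(parent = emptyenv())
  anc <- function(t) {
    if (!is.null(cache[[t]])) return(cache[[t]])
    cache[[t]] <- t  # guard against accidental cycles
    out <- t
    for (p in parents[[t]]) out <- union(out, anc(p))
    cache[[t]] <- out
    out
  }
  for (t in names(parents)) anc(t)
  cache
}

#' Combine an ontology and annotations into a scoring object
#'
#' Estimates per-concept term probabilities as annotation frequencies: each
#' annotation row counts once for the annotated term and all of its
#' (inclusive) ancestors, divided by the concept's total annotation count.
#'
#' @param obo a [read_obo()] object.
#' @param gaf a [read_gaf()] data frame (or path to a GAF file).
#' @return An object of class `go_annotation`: `ancestors` (environment term
#'   -> inclusive ancestors), `prob` (list concept -> named probabilities),
#'   `annotations` (list concept -> list protein -> terms), `totals`.
#' @export
go_annotation <- function(obo, gaf) {
  stopifnot(inherits(obo, "go_obo"))
  if (is.character(gaf)) gaf <- read_gaf(gaf)
  gaf <- gaf[gaf$term %in% obo$id, , drop = FALSE]
  anc <- ancestor_closure(obo$parents)
  prob <- list()
  annotations <- list()
  totals <- list()
  for (cc in GO_CONCEPTS) {
    rows <- gaf[gaf$concept == cc, , drop = FALSE]
    totals[[cc]] <- nrow(rows)
    counts <- setNames(numeric(length(obo$id)), obo$id)
    if (nrow(rows) > 0) {
      for (r in seq_len(nrow(rows))) {
        a <- anc[[rows$term[r]]]
        counts[a] <- counts[a] + 1
      }
    }
    prob[[cc]] <- counts / max(1, totals[[cc]])
    annotations[[cc]] <- lapply(split(rows$term, rows$protein), unique)
  }
  structure(list(obo = obo, ancestors = anc, prob = prob,
                 annotations = annotations, totals = totals),
            class = "go_annotation")
}

#' @export
print.go_annotation <- function(x, ...) {
  cat(sprintf("<go_annotation: %d terms; %s annotations (P/F/C)>\n",
              length(x$obo$id),
              paste(unlist(x$totals), collapse = "/")))
  invisible(x)
}

#' Probability of the minimum subsumer of two term sets
#'
#' The least frequent of all GO terms ancestral (inclusively: a term is its
#' own ancestor) to both term sets under the given concept. Returns 1 when
#' the only shared ancestor is the concept root, and 1 with a warning when
#' the sets live in disjoint sub-DAGs and share no ancestor at all.
#'
#' @param terms_i,terms_j nonempty character vectors of GO term ids.
#' @param concept `"P"`, `"F"` or `"C"`.
#' @param annotation a [go_annotation()] object.
#' @return Probability in (0, 1].
#' @export
p_ms <- function(terms_i, terms_j, concept, annotation) {
  stopifnot(inherits(annotation, "go_annotation"),
            concept %in% GO_CONCEPTS,
            length(terms_i) > 0, length(terms_j) > 0)
  anc_i <- unique(unlist(lapply(terms_i, function(t)
    annotation$ancestors[[t]]), use.names = FALSE))
  anc_j <- unique(unlist(lapply(terms_j, function(t)
    annotation$ancestors[[t]]), use.names = FALSE))
  shared <- intersect(anc_i, anc_j)
  if (length(shared) == 0) {
    warning("term sets share no ancestor; returning P_ms = 1")
    return(1)
  }
  p <- annotation$prob[[concept]][shared]
  p <- p[p > 0]
  if (length(p) == 0) return(1)
  min(p)
}

#' GO semantic similarity of two proteins
#'
#' Per concept, the similarity is `-ln(P_ms)` of the proteins' term sets; a
#' concept in which either protein is unannotated contributes 0. The total
#' score is the sum of the per-concept best similarities, clamped to the
#' reported 0-10 range (per-concept values are returned unclamped).
#'
#' @param protein_i,protein_j protein identifiers.
#' @param annotation a [go_annotation()] object.
#' @return List with `per_concept` (named numeric, unclamped), `total`
#'   (clamped to \[0, 10\]) and `annotated` (logical: was any concept scored).
#' @export
go_similarity <- function(protein_i, protein_j, annotation) {
  stopifnot(inherits(annotation, "go_annotation"))
  per <- setNames(numeric(length(GO_CONCEPTS)), GO_CONCEPTS)
  any_scored <- FALSE
  for (cc in GO_CONCEPTS) {
    ti <- annotation$annotations[[cc]][[protein_i]]
    tj <- annotation$annotations[[cc]][[protein_j]]
    if (is.null(ti) || is.null(tj) || length(ti) == 0 || length(tj) == 0) {
      per[cc] <- 0
      next
    }
    any_scored <- TRUE
    per[cc] <- -log(p_ms(ti, tj, cc, annotation))
  }
  list(per_concept = per, total = min(10, max(0, sum(per))),
       annotated = any_scored)
}

#' Per-edge GO scores of a labeled subgraph
#'
#' @param subgraph a `ppi_graph` or `ppi_lgraph` (labels are not needed for
#'   scoring; nodes are protein ids).
#' @param annotation a [go_annotation()] object.
#' @return Numeric vector of total similarity scores, one per edge.
#' @export
subgraph_edge_scores <- function(subgraph, annotation) {
  g <- as_ppi_graph(subgraph)
  if (nrow(g$edges) == 0) return(numeric())
  vapply(seq_len(nrow(g$edges)), function(i)
    go_similarity(g$edges[i, 1], g$edges[i, 2], annotation)$total, 0)
}

#' Mean edge-level GO score of a group of subgraphs
#'
#' Flat mean of edge total scores over all edges of all subgraphs in the
#' group (the groups are typically the n-edge size classes of discovered
#' patterns and of matched random subgraphs).
#'
#' @param pattern_group nonempty list of subgraphs of equal edge count.
#' @param annotation a [go_annotation()] object.
#' @return Mean score (numeric scalar).
#' @export
mean_pattern_score <- function(pattern_group, annotation) {
  if (length(pattern_group) == 0)
    stop("mean_pattern_score is undefined for an empty group")
  scores <- unlist(lapply(pattern_group, subgraph_edge_scores,
                          annotation = annotation), use.names = FALSE)
  if (length(scores) == 0)
    stop("mean_pattern_score is undefined for edgeless subgraphs")
  mean(scores)
}

#' Seeded random connected subgraph with a given edge count
#'
#' Starts from a uniformly random edge and repeatedly adds a uniformly random
#' frontier edge (an unused edge incident to the current node set) until
#' `n_edges` are collected, restarting from a fresh random edge when the
#' frontier is exhausted.
#'
#' @param network a `ppi_graph` or `ppi_lgraph`.
#' @param n_edges number of edges of the subgraph.
#' @param seed integer seed.
#' @param max_restarts bound on restarts before giving up.
#' @return A subgraph of `network` (labeled when `network` is labeled).
#' @export
random_subgraph <- function(network, n_edges, seed, max_restarts = 200) {
  g <- as_ppi_graph(network)
  m <- nrow(g$edges)
  if (m < n_edges || n_edges < 1)
    stop("network has too few edges for the requested subgraph")
  ek <- edge_keys(g)
  # incidence: node -> indices of its edges
  inc <- split(rep(seq_len(m), 2), c(g$edges[, 1], g$edges[, 2]))
  pick <- with_seed(seed, {
    res <- NULL
    for (attempt in seq_len(max_restarts)) {
      chosen <- sample.int(m, 1)
      nodes <- unique(as.vector(g$edges[chosen, ]))
      while (length(chosen) < n_edges) {
        frontier <- setdiff(unique(unlist(inc[nodes], use.names = FALSE)),
                            chosen)
        if (length(frontier) == 0) break
        nxt <- frontier[sample.int(length(frontier), 1)]
        chosen <- c(chosen, nxt)
        nodes <- unique(c(nodes, as.vector(g$edges[nxt, ])))
      }
      if (length(chosen) == n_edges) {
        res <- chosen
        break
      }
    }
    res
  })
  if (is.null(pick))
    stop(sprintf("no connected %d-edge subgraph found in %d restarts",
                 n_edges, max_restarts))
  sub <- ppi_graph(g$edges[pick, , drop = FALSE])
  if (inherits(network, "ppi_lgraph"))
    return(labeled_graph(sub, network$labels[sub$nodes]))
  sub
}
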