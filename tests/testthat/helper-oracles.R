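# Independent oracles and random-instance generators shared by the tests.
# The embedding oracle deliberately uses a different strategy from the
# package's backtracking matcher: it enumerates *all* label-compatible
# injections and only then checks edge preservation.

clique <- function(nodes) t(combn(nodes, 2))

# random simple graph on n nodes with edge probability p
random_graph <- function(n, p = 0.4, prefix = "n") {
  nodes <- sprintf("%s%02d", prefix, seq_len(n))
  if (n < 2) return(ppi_graph(nodes = nodes))
  pairs <- t(combn(nodes, 2))
  keep <- runif(nrow(pairs)) < p
  ppi_graph(pairs[keep, , drop = FALSE], nodes = nodes)
}

random_labeled_graph <- function(n, p = 0.4, alphabet = c("A", "B", "C"),
                                 prefix = "n") {
  g <- random_graph(n, p, prefix)
  labeled_graph(g, setNames(sample(alphabet, n, replace = TRUE), g$nodes))
}

# Exhaustive injection-enumeration oracle for label-preserving subgraph
# isomorphism: recursion over query nodes through label-compatible target
# candidates, with edge checks deferred to complete assignments.
oracle_embedding_exists <- function(query, target) {
  qn <- query$graph$nodes
  tn <- target$graph$nodes
  nq <- length(qn)
  if (nq == 0) return(TRUE)
  tkeys <- edge_keys(target$graph)
  qe <- query$graph$edges
  cand <- lapply(seq_len(nq), function(i)
    which(unname(target$labels[tn]) == unname(query$labels[qn[i]])))
  if (any(lengths(cand) == 0)) return(FALSE)
  check_full <- function(map) {
    if (nrow(qe) == 0) return(TRUE)
    mapped <- cbind(tn[map[match(qe[, 1], qn)]], tn[map[match(qe[, 2], qn)]])
    swap <- mapped[, 1] > mapped[, 2]
    k <- paste(ifelse(swap, mapped[, 2], mapped[, 1]),
               ifelse(swap, mapped[, 1], mapped[, 2]), sep = "\t")
    all(k %in% tkeys)
  }
  rec <- function(i, map) {
    if (i > nq) return(check_full(map))
    for (t in cand[[i]]) {
      if (t %in% map) next
      if (rec(i + 1, c(map, t))) return(TRUE)
    }
    FALSE
  }
  rec(1, integer())
}

# two K5s joined by a single bridge edge (the RNSC sanity fixture)
two_clique_bridge <- function() {
  ppi_graph(rbind(clique(paste0("p", 1:5)), clique(paste0("q", 1:5)),
                  c("p1", "q1")))
}

# partition as a canonical set-of-sets string, for comparisons
partition_signature <- function(assignment) {
  blocks <- vapply(split(names(assignment), assignment), function(b)
    paste(sort(b, method = "radix"), collapse = ","), "")
  paste(sort(unname(blocks), method = "radix"), collapse = ";")
}

# write toy GO fixture to temp files, returning paths and metadata
toy_go_files <- function(...) {
  toy <- generate_toy_go(...)
  obo <- tempfile(fileext = ".obo")
  gaf <- tempfile(fileext = ".gaf")
  writeLines(toy$obo, obo)
  writeLines(toy$gaf, gaf)
  c(toy, list(obo_path = obo, gaf_path = gaf))
}
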