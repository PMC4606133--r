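test_that("graph construction normalizes edges, drops loops and duplicates", {
  expect_warning(g <- ppi_graph(rbind(c("a", "a"), c("b", "a"))),
                 "self-loop")
  expect_equal(g$edges, cbind("a", "b"))

  g2 <- ppi_graph(rbind(c("b", "a"), c("a", "b"), c("a", "b")))
  expect_equal(nrow(g2$edges), 1L)

  g3 <- ppi_graph(rbind(c("x", "y")), nodes = c("z", "w"))
  expect_equal(g3$nodes, c("w", "x", "y", "z"))
  expect_equal(n_edges(g3), 1L)
})

test_that("canonical label matches hand-enumerated bitstrings", {
  # path a-b, b-c: pairs (a,b),(a,c),(b,c) -> "101"
  cl <- canonical_label(ppi_graph(rbind(c("a", "b"), c("b", "c"))))
  expect_equal(cl$sorted_nodes, c("a", "b", "c"))
  expect_equal(cl$bitstring, "101")
  # triangle: complete graph -> "111"
  tri <- ppi_graph(rbind(c("a", "b"), c("b", "c"), c("a", "c")))
  expect_equal(canonical_label(tri)$bitstring, "111")
  # same triangle, edges supplied reversed and reordered -> identical label
  tri2 <- ppi_graph(rbind(c("c", "a"), c("c", "b"), c("b", "a")))
  expect_identical(canonical_label(tri), canonical_label(tri2))
})

test_that("canonical label is a pure function of node and edge sets", {
  set.seed(42)
  for (rep in 1:200) {
    n <- sample(2:10, 1)
    g <- random_graph(n, runif(1, 0.2, 0.8))
    base <- canonical_key(g)
    # shuffle edge rows and endpoint order
    for (k in 1:5) {
      e <- g$edges
      if (nrow(e) > 0) {
        e <- e[sample(nrow(e)), , drop = FALSE]
        flip <- runif(nrow(e)) < 0.5
        e[flip, ] <- e[flip, 2:1]
      }
      g2 <- ppi_graph(e, nodes = sample(g$nodes))
      expect_identical(canonical_key(g2), base)
    }
    # distinct edge sets give distinct labels
    if (n_edges(g) > 0) {
      g3 <- ppi_graph(g$edges[-1, , drop = FALSE], nodes = g$nodes)
      expect_false(canonical_key(g3) == base)
    }
  }
})

test_that("pattern abstraction collapses same-label edges with counts", {
  lg <- labeled_graph(ppi_graph(rbind(c("a1", "b1"), c("a5", "b2"))),
                      c(a1 = "A", a5 = "A", b1 = "B", b2 = "B"))
  p <- pattern_of(lg)
  expect_equal(p$edges,
               data.frame(label_a = "A", label_b = "B", count = 2L))

  # homotypic pair
  ph <- pattern_of(labeled_graph(ppi_graph(rbind(c("a1", "a2"))),
                                 c(a1 = "A", a2 = "A")))
  expect_equal(ph$edges$count, 1L)
  expect_equal(ph$edges$label_a, "A")
  expect_equal(ph$edges$label_b, "A")

  # triangle over three labels
  pt <- pattern_of(labeled_graph(
    ppi_graph(rbind(c("a1", "b1"), c("b1", "c1"), c("c1", "a1"))),
    c(a1 = "A", b1 = "B", c1 = "C")))
  expect_equal(nrow(pt$edges), 3L)
  expect_true(all(pt$edges$count == 1L))
})

test_that("patterns are invariant under label-preserving renaming", {
  set.seed(7)
  for (rep in 1:50) {
    lg <- random_labeled_graph(sample(3:8, 1), 0.5)
    new_ids <- setNames(sprintf("z%03d", sample(999, length(lg$graph$nodes))),
                        lg$graph$nodes)
    e <- lg$graph$edges
    e2 <- cbind(new_ids[e[, 1]], new_ids[e[, 2]])
    lg2 <- labeled_graph(ppi_graph(e2, nodes = unname(new_ids)),
                         setNames(unname(lg$labels), unname(new_ids)))
    expect_identical(pattern_key(lg2), pattern_key(lg))
  }
})

test_that("unlabeled nodes are rejected by name", {
  g <- ppi_graph(rbind(c("a", "b")))
  expect_error(labeled_graph(g, c(a = "A")), "unlabeled node.*b")
})

test_that("exact matcher agrees with the injection-enumeration oracle", {
  q <- labeled_graph(ppi_graph(rbind(c("x", "y"))), c(x = "A", y = "B"))
  t1 <- labeled_graph(ppi_graph(rbind(c("a1", "b1"), c("b1", "c1"))),
                      c(a1 = "A", b1 = "B", c1 = "C"))
  r <- is_subgraph_isomorphic_exact(q, t1)
  expect_true(r$found)
  expect_equal(unname(r$node_map), c("a1", "b1"))
  expect_equal(unname(q$labels[names(r$node_map)]),
               unname(t1$labels[r$node_map]))

  # triangle of As cannot embed into a path
  qt <- labeled_graph(ppi_graph(clique(c("x", "y", "z"))),
                      c(x = "A", y = "A", z = "A"))
  tp <- labeled_graph(ppi_graph(rbind(c("a1", "a2"), c("a2", "a3"))),
                      c(a1 = "A", a2 = "A", a3 = "A"))
  expect_false(is_subgraph_isomorphic_exact(qt, tp)$found)

  set.seed(11)
  for (rep in 1:200) {
    q <- random_labeled_graph(sample(2:5, 1), 0.6, c("A", "B"), prefix = "q")
    t <- random_labeled_graph(sample(2:6, 1), 0.5, c("A", "B"), prefix = "t")
    res <- is_subgraph_isomorphic_exact(q, t)
    expect_equal(res$found, oracle_embedding_exists(q, t))
    if (res$found && nrow(q$graph$edges) > 0) {
      # the returned map preserves labels and every query edge
      expect_equal(unname(q$labels[names(res$node_map)]),
                   unname(t$labels[res$node_map]))
      e <- q$graph$edges
      mapped <- cbind(res$node_map[e[, 1]], res$node_map[e[, 2]])
      swap <- mapped[, 1] > mapped[, 2]
      mk <- paste(ifelse(swap, mapped[, 2], mapped[, 1]),
                  ifelse(swap, mapped[, 1], mapped[, 2]), sep = "\t")
      expect_true(all(mk %in% edge_keys(t$graph)))
    }
  }
})

test_that("edge-list and JSON readers round-trip graphs", {
  g <- ppi_graph(rbind(c("a", "b"), c("b", "c")), nodes = "iso")
  tsv <- tempfile(fileext = ".tsv")
  write_edge_list(g, tsv, header = "fixture")
  g2 <- read_edge_list(tsv)
  expect_equal(g2$edges, g$edges)  # isolated nodes are not representable

  lg <- labeled_graph(g, c(a = "A", b = "B", c = "A", iso = "B"))
  js <- tempfile(fileext = ".json")
  write_graph_json(lg, js)
  lg2 <- read_graph_json(js)
  expect_identical(lg2$graph, lg$graph)
  expect_identical(lg2$labels, lg$labels)

  gm <- tempfile(fileext = ".graphml")
  write_graphml(g, gm)
  ig <- igraph::read_graph(gm, format = "graphml")
  expect_equal(igraph::gorder(ig), 4)
  expect_equal(igraph::gsize(ig), 2)
})
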