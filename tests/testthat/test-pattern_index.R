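lab <- function(g, ...) labeled_graph(g, c(...))

test_that("the three index structures are populated and mutually consistent", {
  s1 <- lab(ppi_graph(rbind(c("a1", "b1"), c("a5", "b2"), c("b3", "c1"))),
            a1 = "A", a5 = "A", b1 = "B", b2 = "B", b3 = "B", c1 = "C")
  s2 <- lab(ppi_graph(rbind(c("a9", "b9"))), a9 = "A", b9 = "B")
  s3 <- lab(ppi_graph(cbind(paste0("a", 1:4), paste0("b", 1:4))),
            a1 = "A", a2 = "A", a3 = "A", a4 = "A",
            b1 = "B", b2 = "B", b3 = "B", b4 = "B")
  idx <- build_index(list(s1 = s1, s2 = s2, s3 = s3))

  # ds1: edge patterns with multiplicities
  expect_equal(idx$ds1$s1$count[idx$ds1$s1$label_a == "A"], 2L)
  expect_equal(idx$ds1$s1$count[idx$ds1$s1$label_b == "C"], 1L)

  # ds2 is the exact inverse of ds1
  for (id in names(idx$ds1)) {
    ed <- idx$ds1[[id]]
    for (r in seq_len(nrow(ed))) {
      k <- sprintf("%s\t%s\t%d", ed$label_a[r], ed$label_b[r], ed$count[r])
      expect_true(id %in% idx$ds2[[k]])
    }
  }
  for (k in names(idx$ds2)) {
    parts <- strsplit(k, "\t")[[1]]
    for (id in idx$ds2[[k]]) {
      ed <- idx$ds1[[id]]
      hit <- ed$label_a == parts[1] & ed$label_b == parts[2] &
        ed$count == as.integer(parts[3])
      expect_true(any(hit))
    }
  }

  # ds3: expanded patterns are the same pair at strictly higher counts
  expect_equal(idx$ds3[["A\tB\t1"]], c("A\tB\t2", "A\tB\t4"))
  expect_equal(idx$ds3[["A\tB\t4"]], character())
})

test_that("index filtering matches the worked candidate examples", {
  # query {A-B(3)}, no other subgraph has A-B(k>=3) -> distinct outright
  q3 <- lab(ppi_graph(cbind(paste0("a", 1:3), paste0("b", 1:3))),
            a1 = "A", a2 = "A", a3 = "A", b1 = "B", b2 = "B", b3 = "B")
  small <- lab(ppi_graph(rbind(c("x1", "y1"))), x1 = "A", y1 = "B")
  expect_length(candidate_subgraphs(q3, build_index(list(m = small))), 0)

  # query {A-B(2)} vs a module with A-B(5): expansion makes it a candidate
  q2 <- lab(ppi_graph(cbind(paste0("a", 1:2), paste0("b", 1:2))),
            a1 = "A", a2 = "A", b1 = "B", b2 = "B")
  big <- lab(ppi_graph(cbind(paste0("x", 1:5), paste0("y", 1:5))),
             x1 = "A", x2 = "A", x3 = "A", x4 = "A", x5 = "A",
             y1 = "B", y2 = "B", y3 = "B", y4 = "B", y5 = "B")
  expect_equal(candidate_subgraphs(q2, build_index(list(big = big))), "big")

  # query {A-B(1), C-D(1)}: two modules each covering one pattern intersect away
  qm <- lab(ppi_graph(rbind(c("a1", "b1"), c("c1", "d1")),
                      nodes = character()),
            a1 = "A", b1 = "B", c1 = "C", d1 = "D")
  only_ab <- lab(ppi_graph(rbind(c("x1", "y1"), c("x1", "y2"))),
                 x1 = "A", y1 = "B", y2 = "B")
  only_cd <- lab(ppi_graph(rbind(c("u1", "v1"), c("u1", "v2"))),
                 u1 = "C", v1 = "D", v2 = "D")
  expect_length(candidate_subgraphs(qm, build_index(list(ab = only_ab,
                                                         cd = only_cd))), 0)

  # size prefilter: candidates with fewer nodes or edges than the query drop
  tri <- lab(ppi_graph(clique(c("p1", "p2", "p3"))),
             p1 = "A", p2 = "A", p3 = "A")
  pair <- lab(ppi_graph(rbind(c("r1", "r2"))), r1 = "A", r2 = "A")
  expect_length(candidate_subgraphs(tri, build_index(list(pair = pair))), 0)
})

test_that("index filtering is sound: no true embedding target is dropped", {
  set.seed(23)
  for (rep in 1:200) {
    q <- random_labeled_graph(sample(2:4, 1), 0.7, c("A", "B"), prefix = "q")
    if (n_edges(q$graph) == 0) next
    targets <- list()
    for (j in 1:4) {
      targets[[sprintf("t%d", j)]] <-
        random_labeled_graph(sample(2:10, 1), 0.4, c("A", "B"),
                             prefix = sprintf("t%d_", j))
    }
    idx <- build_index(targets)
    cands <- candidate_subgraphs(q, idx)
    for (id in names(targets)) {
      if (oracle_embedding_exists(q, targets[[id]]))
        expect_true(id %in% cands)
    }
  }
})

test_that("verification modes behave as documented", {
  # identity match succeeds in both modes
  tri <- lab(ppi_graph(clique(c("p1", "p2", "p3"))),
             p1 = "A", p2 = "B", p3 = "C")
  expect_true(verify_matching(tri, list(tri), mode = "exact"))
  expect_true(verify_matching(tri, list(tri), mode = "paper_greedy"))

  # star with 3 leaves cannot match a star with 2
  q <- lab(ppi_graph(rbind(c("c0", "l1"), c("c0", "l2"), c("c0", "l3"))),
           c0 = "A", l1 = "B", l2 = "B", l3 = "B")
  t2 <- lab(ppi_graph(rbind(c("d0", "m1"), c("d0", "m2"))),
            d0 = "A", m1 = "B", m2 = "B")
  expect_false(verify_matching(q, list(t2), mode = "paper_greedy"))
  expect_false(verify_matching(q, list(t2), mode = "exact"))

  # symmetric candidate where the greedy first pick dead-ends: the greedy
  # matcher misses the embedding that the exact matcher finds
  qt <- lab(ppi_graph(clique(c("q1", "q2", "q3"))),
            q1 = "A", q2 = "B", q3 = "B")
  adversary <- lab(ppi_graph(rbind(c("t1", "t2"), c("t1", "t3"), c("t1", "t4"),
                                   c("t3", "t4"))),
                   t1 = "A", t2 = "B", t3 = "B", t4 = "B")
  expect_false(verify_matching(qt, list(adversary), mode = "paper_greedy"))
  expect_true(verify_matching(qt, list(adversary), mode = "exact"))
})

test_that("exact verification agrees with the brute-force oracle", {
  set.seed(29)
  for (rep in 1:150) {
    q <- random_labeled_graph(sample(2:5, 1), 0.6, c("A", "B", "C"),
                              prefix = "q")
    t <- random_labeled_graph(sample(3:8, 1), 0.5, c("A", "B", "C"),
                              prefix = "t")
    expect_equal(unname(verify_matching(q, list(t), mode = "exact")),
                 oracle_embedding_exists(q, t))
  }
})

test_that("distinct patterns collapse witnesses and respect sub-subgraph hits", {
  lbl <- c(a1 = "A", a2 = "A", b1 = "B", b2 = "B", c1 = "C",
           x1 = "A", x2 = "B", x3 = "C", x4 = "D",
           w1 = "A", w2 = "B", w3 = "C",
           z1 = "Z", z2 = "Z", z3 = "Z", z4 = "Z",
           y1 = "Z", y2 = "Z", y3 = "Z")
  tri1 <- ppi_graph(clique(c("a1", "b1", "c1")))     # pattern ABC in n1
  tri2 <- ppi_graph(clique(c("w1", "w2", "w3")))     # same pattern, also n1
  k4 <- ppi_graph(clique(c("x1", "x2", "x3", "x4"))) # contains ABC in n2
  ztri <- ppi_graph(clique(c("z1", "z2", "z3")))     # unique Z pattern in n1
  ypath <- ppi_graph(rbind(c("y1", "y2"), c("y2", "y3")))  # 2-edge, n2

  mk <- function(g, net, id) structure(
    list(id = id, network = net, graph = g, canonical = canonical_label(g),
         key = canonical_key(g)), class = "ppi_module")
  modules <- list(
    n1 = list(mk(tri1, "n1", "n1:1"), mk(tri2, "n1", "n1:2"),
              mk(ztri, "n1", "n1:3")),
    n2 = list(mk(k4, "n2", "n2:1"), mk(ypath, "n2", "n2:2")))
  distinct <- find_distinct_subgraphs(build_label_table(modules))
  # all three n1 modules are distinct subgraphs (no verbatim repeats)
  expect_length(distinct$n1, 3)

  pats <- find_distinct_patterns(distinct, modules, lbl, mode = "exact")
  keys <- vapply(pats$n1, function(p) p$key, "")
  # ABC triangles are NOT distinct patterns: the pattern embeds in n2's K4
  expect_false(any(grepl("A,B,C", keys)))
  # the Z triangle is: one pattern
  expect_length(pats$n1, 1)
  expect_equal(pats$n1[[1]]$witnesses, "n1:3")

  # two same-pattern witnesses collapse once the blocker is removed
  modules2 <- list(n1 = modules$n1, n2 = list(mk(ypath, "n2", "n2:2")))
  distinct2 <- find_distinct_subgraphs(build_label_table(modules2))
  pats2 <- find_distinct_patterns(distinct2, modules2, lbl, mode = "exact")
  abc <- Filter(function(p) grepl("A,B,C", p$key), pats2$n1)
  expect_length(abc, 1)
  expect_setequal(abc[[1]]$witnesses, c("n1:1", "n1:2"))

  # pattern counts never exceed distinct-subgraph counts
  expect_lte(length(pats2$n1), length(distinct2$n1))
})
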