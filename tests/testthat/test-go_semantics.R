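# hand-built 4-term ontology per concept: root -> x -> {t1, t2}
# annotation counts chosen so p(x) = 0.25 in concept P
hand_ontology <- function() {
  obo <- c("format-version: 1.2", "")
  ns <- c(P = "biological_process", F = "molecular_function",
          C = "cellular_component")
  for (cc in names(ns)) {
    i <- match(cc, names(ns))
    tid <- function(k) sprintf("GO:%d00000%d", i, k)
    obo <- c(obo,
             "[Term]", paste0("id: ", tid(1)), "name: root",
             paste0("namespace: ", ns[[cc]]), "",
             "[Term]", paste0("id: ", tid(2)), "name: x",
             paste0("namespace: ", ns[[cc]]), paste0("is_a: ", tid(1)), "",
             "[Term]", paste0("id: ", tid(3)), "name: t1",
             paste0("namespace: ", ns[[cc]]), paste0("is_a: ", tid(2)), "",
             "[Term]", paste0("id: ", tid(4)), "name: t2",
             paste0("namespace: ", ns[[cc]]), paste0("is_a: ", tid(2)), "")
  }
  f <- tempfile(fileext = ".obo")
  writeLines(obo, f)
  read_obo(f)
}

gaf_rows <- function(entries) {
  # entries: data frame protein/term/concept
  vapply(seq_len(nrow(entries)), function(i)
    paste(c("TOY", entries$protein[i], entries$protein[i], "",
            entries$term[i], "TOY:1", "IEA", "", entries$concept[i], "", "",
            "protein", "taxon:9606", "20260101", "TOY", "", ""),
          collapse = "\t"), "")
}

test_that("minimum-subsumer probabilities match hand computations", {
  obo <- hand_ontology()
  # concept P: 8 annotations, 1 to t1, 1 to t2, 6 to the root directly
  ent <- data.frame(
    protein = sprintf("pr%d", 1:8),
    term = c("GO:1000003", "GO:1000004", rep("GO:1000001", 6)),
    concept = "P", stringsAsFactors = FALSE)
  gaf <- tempfile(fileext = ".gaf")
  writeLines(c("!gaf-version: 2.1", gaf_rows(ent)), gaf)
  ann <- go_annotation(obo, read_gaf(gaf))

  expect_equal(ann$prob$P[["GO:1000001"]], 1)      # root
  expect_equal(ann$prob$P[["GO:1000002"]], 0.25)   # x subsumes t1 and t2
  expect_equal(ann$prob$P[["GO:1000003"]], 0.125)

  # identical single terms: the term is its own least-frequent shared ancestor
  expect_equal(p_ms("GO:1000003", "GO:1000003", "P", ann), 0.125)
  # sibling leaves: shared ancestors {x, root}, min is p(x)
  expect_equal(p_ms("GO:1000003", "GO:1000004", "P", ann), 0.25)
  # terms sharing only the root
  expect_equal(p_ms("GO:1000001", "GO:1000003", "P", ann), 1)
  # disjoint sub-DAGs (different concepts' terms) -> 1 with warning
  expect_warning(pm <- p_ms("GO:1000003", "GO:2000003", "P", ann),
                 "no ancestor")
  expect_equal(pm, 1)
})

test_that("protein similarity sums per-concept bests, clamped to [0, 10]", {
  obo <- hand_ontology()
  # pa/pb share leaf t1 in P only; pc shares nothing beyond roots
  ent <- data.frame(
    protein = c("pa", "pb", "pc", "pc", rep(sprintf("fill%d", 1:10), 1)),
    term = c("GO:1000003", "GO:1000003", "GO:1000003", "GO:2000001",
             rep("GO:1000001", 10)),
    concept = c("P", "P", "P", "F", rep("P", 10)), stringsAsFactors = FALSE)
  gaf <- tempfile(fileext = ".gaf")
  writeLines(c("!gaf-version: 2.1", gaf_rows(ent)), gaf)
  ann <- go_annotation(obo, read_gaf(gaf))

  s <- go_similarity("pa", "pb", ann)
  # P: -ln p(t1) with p(t1) = 3/13; F and C unannotated contribute 0
  expect_equal(s$total, -log(3 / 13))
  expect_equal(unname(s$per_concept["F"]), 0)

  # root-only share scores 0
  s0 <- go_similarity("pa", sprintf("fill%d", 1), ann)
  expect_equal(s0$total, 0)

  # entirely unannotated pair flagged, score 0
  s3 <- go_similarity("ghost1", "ghost2", ann)
  expect_equal(s3$total, 0)
  expect_false(s3$annotated)
})

test_that("similarity totals exceeding 10 are clamped", {
  # one protein annotated to a leaf in each concept; leaf frequency 1/N with
  # N large enough that 3 * -ln(1/N) > 10
  obo <- hand_ontology()
  rows <- list()
  for (cc in c("P", "F", "C")) {
    i <- match(cc, c("P", "F", "C"))
    leaf <- sprintf("GO:%d000003", i)
    root <- sprintf("GO:%d000001", i)
    rows[[cc]] <- data.frame(
      protein = c("pa", "pb", sprintf("f%s%d", cc, 1:60)),
      term = c(leaf, leaf, rep(root, 60)),
      concept = cc, stringsAsFactors = FALSE)
  }
  gaf <- tempfile(fileext = ".gaf")
  writeLines(c("!gaf-version: 2.1", gaf_rows(do.call(rbind, rows))), gaf)
  ann <- go_annotation(obo, read_gaf(gaf))
  per_concept <- -log(2 / 62)
  expect_gt(3 * per_concept, 10)
  s <- go_similarity("pa", "pb", ann)
  expect_equal(s$total, 10)
  expect_equal(unname(s$per_concept["P"]), per_concept)  # unclamped
})

test_that("NOT-qualified GAF rows are dropped", {
  obo <- hand_ontology()
  ent <- data.frame(protein = c("pa", "pa"),
                    term = c("GO:1000003", "GO:1000004"),
                    concept = "P", stringsAsFactors = FALSE)
  lines <- gaf_rows(ent)
  parts <- strsplit(lines[2], "\t")[[1]]
  parts[4] <- "NOT"
  gaf <- tempfile(fileext = ".gaf")
  writeLines(c("!gaf-version: 2.1", lines[1], paste(parts, collapse = "\t")),
             gaf)
  df <- read_gaf(gaf)
  expect_equal(df$term, "GO:1000003")
})

test_that("group scores are flat averages over all edges", {
  obo <- hand_ontology()
  ent <- data.frame(protein = c("pa", "pb", "pc", "pd"),
                    term = rep("GO:1000003", 4),
                    concept = "P", stringsAsFactors = FALSE)
  gaf <- tempfile(fileext = ".gaf")
  writeLines(c("!gaf-version: 2.1", gaf_rows(ent)), gaf)
  ann <- go_annotation(obo, read_gaf(gaf))
  g1 <- ppi_graph(rbind(c("pa", "pb"), c("pb", "pc")))
  g2 <- ppi_graph(rbind(c("pc", "pd"), c("pa", "pd")))
  flat <- c(subgraph_edge_scores(g1, ann), subgraph_edge_scores(g2, ann))
  expect_equal(mean_pattern_score(list(g1, g2), ann), mean(flat))
  expect_error(mean_pattern_score(list(), ann), "empty")
})

test_that("lower minimum-subsumer probability strictly raises similarity", {
  p <- sort(runif(20, 0.01, 1))
  expect_true(all(diff(-log(p)) <= 0))
  expect_true(all(-log(p[p < 1]) > 0))
})

test_that("random subgraphs are connected, sized and seeded", {
  set.seed(37)
  net <- random_graph(40, 0.12)
  for (rep in 1:50) {
    rs <- random_subgraph(net, 4, seed = rep)
    expect_equal(n_edges(rs), 4L)
    expect_length(graph_components(rs), 1)
    expect_true(all(edge_keys(rs) %in% edge_keys(net)))
  }
  expect_identical(random_subgraph(net, 5, seed = 3),
                   random_subgraph(net, 5, seed = 3))
  # a triangle network with n_edges = 3 can only return the triangle itself
  tri <- ppi_graph(clique(c("a", "b", "c")))
  expect_identical(random_subgraph(tri, 3, seed = 1)$edges, tri$edges)
  # labels travel with the nodes when the network is labeled
  lnet <- labeled_graph(net, setNames(rep(c("A", "B"), 20), net$nodes))
  rl <- random_subgraph(lnet, 3, seed = 2)
  expect_s3_class(rl, "ppi_lgraph")
})
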