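# Seeded generator of multi-network ensembles with planted shared and
# network-unique modules, toy GO ontologies with analytically known term
# probabilities, and matched reference networks. Every downstream stage is
# testable against the machine-readable ground truth emitted here.
#
# Construction mirrors how the real comparison sets are built: all networks
# share one protein namespace, so the Erdos-Renyi background and the shared
# plants are the *same* nodes and edges in every network, while each unique
# plant is a small dense component wired in with fresh node identifiers and
# per-network reserved labels. A post-generation audit runs the exact
# isomorphism oracle to verify that no unique plant (and no unique pattern)
# leaks into another network.

clique_edges <- function(nodes) {
  if (length(nodes) < 2) return(matrix(character(), 0, 2))
  t(utils::combn(nodes, 2))
}

#' Specification of a synthetic network ensemble
#'
#' Defaults describe the study conditions used throughout the package's
#' tests: 9 networks of roughly 300 nodes and 1,000 edges, 5 shared planted
#' clique modules present in every network, and 3 unique planted clique
#' modules per network (sizes 3, 4, 5: 3 to 10 edges) carrying per-network
#' reserved labels.
#'
#' @param n_networks number of networks.
#' @param nodes_per_network approximate node count per network (background
#'   size is derived from it).
#' @param background_edge_prob Erdos-Renyi edge probability of the shared
#'   background.
#' @param shared_sizes clique sizes of the shared plants (all >= 3 nodes).
#' @param unique_sizes clique sizes of the per-network unique plants.
#' @param label_alphabet_size size of the shared cluster-label alphabet.
#' @param seed integer seed governing all randomness.
#' @return An object of class `ensemble_spec`.
#' @export
ensemble_spec <- function(n_networks = 9, nodes_per_network = 300,
                          background_edge_prob = 0.028,
                          shared_sizes = c(3, 4, 4, 4, 5),
                          unique_sizes = c(3, 4, 5),
                          label_alphabet_size = 40, seed = 1) {
  stopifnot(n_networks >= 2, all(shared_sizes >= 3), all(unique_sizes >= 3),
            background_edge_prob >= 0, background_edge_prob <= 1,
            label_alphabet_size >= 1)
  n_bg <- nodes_per_network - sum(shared_sizes) - sum(unique_sizes)
  if (n_bg < 0) stop("nodes_per_network too small for the planted modules")
  structure(list(n_networks = as.integer(n_networks),
                 nodes_per_network = as.integer(nodes_per_network),
                 background_edge_prob = background_edge_prob,
                 shared_sizes = as.integer(shared_sizes),
                 unique_sizes = as.integer(unique_sizes),
                 label_alphabet_size = as.integer(label_alphabet_size),
                 n_background = as.integer(n_bg),
                 seed = as.integer(seed)),
            class = "ensemble_spec")
}

#' Generate a labeled multi-network ensemble with planted modules
#'
#' @param spec an [ensemble_spec()].
#' @param max_resample bounded number of regeneration attempts should the
#'   leakage audit fail.
#' @return List with `networks` (named list of `ppi_graph`), `label_map`
#'   (a `label_map` covering every node of every network), `ground_truth`
#'   (per network, the planted unique subgraphs with node/edge sets,
#'   canonical keys and pattern keys, plus the shared plants) and `spec`.
#' @export
generate_ensemble <- function(spec = ensemble_spec(), max_resample = 5) {
  stopifnot(inherits(spec, "ensemble_spec"))
  for (attempt in seq_len(max_resample)) {
    ens <- with_seed(spec$seed + (attempt - 1L), build_ensemble(spec))
    if (audit_ensemble(ens)) return(ens)
  }
  stop("ensemble audit failed after bounded resampling")
}

build_ensemble <- function(spec) {
  alphabet <- sprintf("L%02d", seq_len(spec$label_alphabet_size))
  net_names <- sprintf("net%02d", seq_len(spec$n_networks))

  # shared Erdos-Renyi background, one instance reused by every network
  bg_nodes <- sprintf("b%04d", seq_len(spec$n_background))
  bg_edges <- matrix(character(), 0, 2)
  if (spec$n_background >= 2) {
    pairs <- t(utils::combn(bg_nodes, 2))
    keep <- runif(nrow(pairs)) < spec$background_edge_prob
    bg_edges <- pairs[keep, , drop = FALSE]
  }

  # shared plants: identical node ids, edges and labels in every network
  shared <- list()
  shared_edges <- matrix(character(), 0, 2)
  shared_nodes <- character()
  for (k in seq_along(spec$shared_sizes)) {
    nodes <- sprintf("s%02d_%d", k, seq_len(spec$shared_sizes[k]))
    ed <- clique_edges(nodes)
    shared[[k]] <- list(nodes = nodes, edges = ed)
    shared_edges <- rbind(shared_edges, ed)
    shared_nodes <- c(shared_nodes, nodes)
  }

  # unique plants: fresh node ids and a reserved label per plant per network
  unique_plants <- setNames(vector("list", spec$n_networks), net_names)
  for (i in seq_len(spec$n_networks)) {
    plants <- list()
    for (k in seq_along(spec$unique_sizes)) {
      nodes <- sprintf("u%02d_%02d_%d", i, k, seq_len(spec$unique_sizes[k]))
      plants[[k]] <- list(nodes = nodes, edges = clique_edges(nodes),
                          label = sprintf("U%02d_%02d", i, k))
    }
    unique_plants[[i]] <- plants
  }

  # one global label map over the shared namespace
  lbl <- c(setNames(sample(alphabet, length(bg_nodes), replace = TRUE),
                    bg_nodes),
           setNames(sample(alphabet, length(shared_nodes), replace = TRUE),
                    shared_nodes))
  for (i in seq_len(spec$n_networks)) {
    for (p in unique_plants[[i]]) {
      lbl[p$nodes] <- p$label
    }
  }
  lm <- label_map(names(lbl), unname(lbl))

  networks <- setNames(vector("list", spec$n_networks), net_names)
  ground_unique <- setNames(vector("list", spec$n_networks), net_names)
  for (i in seq_len(spec$n_networks)) {
    ue <- do.call(rbind, lapply(unique_plants[[i]], function(p) p$edges))
    un <- unlist(lapply(unique_plants[[i]], function(p) p$nodes))
    networks[[i]] <- ppi_graph(rbind(bg_edges, shared_edges, ue),
                               nodes = c(bg_nodes, shared_nodes, un))
    ground_unique[[i]] <- lapply(unique_plants[[i]], function(p) {
      g <- ppi_graph(p$edges)
      list(nodes = g$nodes, edges = g$edges, key = canonical_key(g),
           pattern_key = pattern_key(labeled_graph(g, lbl[g$nodes])))
    })
  }
  ground_shared <- lapply(shared, function(p) {
    g <- ppi_graph(p$edges)
    list(nodes = g$nodes, edges = g$edges, key = canonical_key(g),
         pattern_key = pattern_key(labeled_graph(g, lbl[g$nodes])))
  })
  list(networks = networks, label_map = lm,
       ground_truth = list(unique = ground_unique, shared = ground_shared),
       spec = spec)
}

# exact-oracle sweep: no unique plant may embed (label-preservingly) into any
# other network, i.e. its pattern occurs in exactly one network
audit_ensemble <- function(ens) {
  lbl <- ens$label_map$label_of
  nets <- names(ens$networks)
  labeled_nets <- lapply(ens$networks, function(g)
    labeled_graph(g, lbl[g$nodes]))
  for (net in nets) {
    for (plant in ens$ground_truth$unique[[net]]) {
      q <- labeled_graph(ppi_graph(plant$edges), lbl[plant$nodes])
      for (other in setdiff(nets, net)) {
        if (is_subgraph_isomorphic_exact(q, labeled_nets[[other]])$found)
          return(FALSE)
      }
    }
  }
  TRUE
}

#' Generate a toy GO ontology and annotation set with known probabilities
#'
#' Builds, for each of the three concepts, a complete `branching`-ary tree of
#' depth `depth`, annotates each protein to `annotations_per_protein`
#' uniformly drawn leaves per concept, and emits OBO text, GAF text and the
#' exact annotation counts (hence term probabilities) for closed-form checks.
#'
#' @param depth tree depth (>= 2; depth 2 with branching 2 gives 7 terms).
#' @param branching children per internal term.
#' @param n_proteins number of annotated proteins (ids `PROT001`, ...).
#' @param annotations_per_protein annotations per protein per concept.
#' @param seed integer seed.
#' @return List with `obo` (character lines), `gaf` (character lines),
#'   `counts` (data frame `concept`, `term`, `count`, `probability`),
#'   `leaves` (list concept -> leaf term ids) and `proteins`.
#' @export
generate_toy_go <- function(depth = 3, branching = 2, n_proteins = 50,
                            annotations_per_protein = 1, seed = 1) {
  stopifnot(depth >= 2, branching >= 2, n_proteins >= 1)
  concepts <- data.frame(code = GO_CONCEPTS,
                         namespace = names(NAMESPACE_TO_CONCEPT),
                         stringsAsFactors = FALSE)
  with_seed(seed, {
    obo <- c("format-version: 1.2", "")
    gaf <- c("!gaf-version: 2.1")
    rows <- list()
    leaves <- list()
    proteins <- sprintf("PROT%03d", seq_len(n_proteins))
    for (ci in seq_len(nrow(concepts))) {
      cc <- concepts$code[ci]
      ns <- concepts$namespace[ci]
      # complete tree, breadth-first ids; term 1 is the concept root
      n_terms <- sum(branching^(0:depth))
      tid <- function(k) sprintf("GO:%d%06d", ci, k)
      parent <- integer(n_terms)
      for (k in 2:n_terms) parent[k] <- ((k - 2) %/% branching) + 1
      depth_of <- integer(n_terms)
      for (k in 2:n_terms) depth_of[k] <- depth_of[parent[k]] + 1
      leaf_ids <- which(depth_of == depth)
      leaves[[cc]] <- tid(leaf_ids)
      for (k in seq_len(n_terms)) {
        obo <- c(obo, "[Term]", paste0("id: ", tid(k)),
                 paste0("name: toy term ", cc, " ", k),
                 paste0("namespace: ", ns),
                 if (k > 1) paste0("is_a: ", tid(parent[k])), "")
      }
      # annotate proteins to uniform random leaves
      counts <- setNames(integer(n_terms), tid(seq_len(n_terms)))
      for (p in proteins) {
        picks <- leaf_ids[sample.int(length(leaf_ids),
                                     annotations_per_protein,
                                     replace = TRUE)]
        for (k in picks) {
          gaf <- c(gaf, paste(c("TOY", p, p, "", tid(k), "TOY:0001", "IEA",
                                "", cc, "", "", "protein", "taxon:9606",
                                "20260101", "TOY", "", ""),
                              collapse = "\t"))
          while (TRUE) {  # increment k and all its ancestors
            counts[k] <- counts[k] + 1L
            if (k == 1) break
            k <- parent[k]
          }
        }
      }
      total <- n_proteins * annotations_per_protein
      rows[[cc]] <- data.frame(concept = cc, term = names(counts),
                               count = as.integer(counts),
                               probability = as.numeric(counts) / total,
                               stringsAsFactors = FALSE)
    }
    counts_df <- do.call(rbind, rows)
    rownames(counts_df) <- NULL
    list(obo = obo, gaf = gaf, counts = counts_df, leaves = leaves,
         proteins = proteins)
  })
}

#' Generate reference networks matched to an ensemble's ground truth
#'
#' For every network, builds a reference edge list containing a deterministic
#' `embed_fraction` of each of that network's planted-unique edges (selected
#' under the seed) plus `noise_edges` edges among fresh node identifiers
#' disjoint from every network's plants.
#'
#' @param ensemble output of [generate_ensemble()] (or any list with
#'   `ground_truth$unique`).
#' @param embed_fraction fraction of each unique plant's edges to embed.
#' @param noise_edges number of noise edges per reference.
#' @param seed integer seed.
#' @return Named list (network -> reference `ppi_graph`).
#' @export
generate_reference <- function(ensemble, embed_fraction = 1, noise_edges = 0,
                               seed = 1) {
  stopifnot(embed_fraction >= 0, embed_fraction <= 1)
  gt <- ensemble$ground_truth$unique
  with_seed(seed, {
    out <- setNames(vector("list", length(gt)), names(gt))
    for (net in names(gt)) {
      edges <- matrix(character(), 0, 2)
      for (plant in gt[[net]]) {
        m <- nrow(plant$edges)
        k <- round(embed_fraction * m)
        if (k > 0) {
          pick <- sort(sample.int(m, k))
          edges <- rbind(edges, plant$edges[pick, , drop = FALSE])
        }
      }
      if (noise_edges > 0) {
        xs <- sprintf("x_%s_%03d", net, seq_len(noise_edges * 2))
        noise <- cbind(xs[seq_len(noise_edges) * 2 - 1],
                       xs[seq_len(noise_edges) * 2])
        edges <- rbind(edges, noise)
      }
      out[[net]] <- ppi_graph(edges)
    }
    out
  })
}
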