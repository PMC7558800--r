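test_that("core numbers: cliques, trees, and igraph cross-check", {
  expect_equal(unname(core_decomposition(k_graph(5))), rep(4, 5))

  set.seed(2)
  tree <- igraph::sample_tree(12)
  igraph::V(tree)$name <- sprintf("T%02d", 1:12)
  expect_equal(unname(core_decomposition(tree)), rep(1, 12))

  for (seed in 1:25) {
    g <- er_graph(sample(5:25, 1), runif(1, 0.1, 0.5), seed = seed)
    expect_equal(core_decomposition(g),
                 igraph::coreness(g)[igraph::V(g)$name])
  }
})

test_that("vertex weights: clique, isolate, path center", {
  k5 <- k_graph(5)
  expect_equal(vertex_weight(k5, "K01"), 4.0)

  g <- named_graph(cbind(1, 2), n = 3)  # N03 isolated
  expect_equal(vertex_weight(g, "N03", degree_cutoff = 2), 0)

  path3 <- named_graph(rbind(c(1, 2), c(2, 3)))
  # center's closed neighborhood is the whole path: highest core 1,
  # that 1-core's loop-free density 2*2/(3*2) = 2/3
  expect_equal(vertex_weight(path3, "N02", degree_cutoff = 2), 2 / 3)
  # degree-1 ends fall under the degree cutoff
  expect_equal(vertex_weight(path3, "N01", degree_cutoff = 2), 0)
})

test_that("module score is density times node count", {
  g <- fixed_size_graph(5, 8)
  expect_equal(module_score(g, igraph::V(g)$name), 2 * 8 / 4)
  pair <- named_graph(cbind(1, 2))
  expect_equal(module_score(pair, c("N01", "N02")), 2.0)
  expect_error(module_score(pair, "N01"), "at least 2")
})

test_that("all 18 printed cluster rows satisfy score = round(2E/(N-1), 3)", {
  ct <- read_cluster_table(system.file("extdata", "ppi_clusters.tsv",
                                       package = "netpharm"))
  expect_equal(nrow(ct), 18)
  expect_equal(ct$Score, round(2 * ct$Edges / (ct$Nodes - 1), 3))
  # membership lists agree with the printed node counts
  expect_equal(lengths(ct$Members), ct$Nodes)
})

test_that("module_score recomputed on constructed graphs matches printed scores", {
  ct <- read_cluster_table(system.file("extdata", "ppi_clusters.tsv",
                                       package = "netpharm"))
  for (i in seq_len(nrow(ct))) {
    g <- fixed_size_graph(ct$Nodes[i], ct$Edges[i])
    s <- module_score(g, igraph::V(g)$name)
    expect_equal(round(s, 3), ct$Score[i], tolerance = 1e-9)
  }
})

test_that("find_modules reports disjoint cliques with closed-form scores", {
  # two disjoint K4 components
  g <- named_graph(rbind(t(utils::combn(1:4, 2)), t(utils::combn(5:8, 2))))
  mods <- find_modules(g)
  expect_length(mods, 2)
  expect_equal(vapply(mods, `[[`, numeric(1), "score"), c(4, 4))
  expect_setequal(mods[[1]]$members, sprintf("N%02d", 1:4))

  tri <- k_graph(3, prefix = "A")
  mt <- find_modules(tri)
  expect_length(mt, 1)
  expect_equal(mt[[1]]$score, 3)
  expect_equal(mt[[1]]$n_nodes, 3)
  expect_equal(mt[[1]]$n_edges, 3)

  expect_length(find_modules(igraph::make_empty_graph(0, directed = FALSE)), 0)
})

test_that("reported scores always equal 2E/(N-1) of the induced subgraph", {
  for (seed in 1:5) {
    g <- er_graph(60, 0.12, seed = seed)
    for (m in find_modules(g)) {
      expect_equal(m$score, 2 * m$n_edges / (m$n_nodes - 1), tolerance = 1e-9)
      expect_equal(m$score, module_score(g, m$members), tolerance = 1e-9)
      # induced subgraph is connected
      sub <- igraph::induced_subgraph(g, m$members)
      expect_true(igraph::is_connected(sub))
      # after haircut every member keeps >= 2 in-module neighbors
      expect_true(all(igraph::degree(sub) >= 2))
    }
  }
})

test_that("modules are disjoint in core members and deterministic", {
  g <- er_graph(80, 0.1, seed = 17)
  mods1 <- find_modules(g)
  cores <- unlist(lapply(mods1, `[[`, "core_members"))
  expect_equal(anyDuplicated(cores), 0)

  # same graph with permuted vertex order gives identical module sets
  set.seed(1)
  perm <- igraph::permute(g, sample(igraph::vcount(g)))
  mods2 <- find_modules(perm)
  expect_equal(lapply(mods1, function(m) sort(m$members)),
               lapply(mods2, function(m) sort(m$members)))
  expect_identical(module_table(mods1)$Score, module_table(mods2)$Score)
})

test_that("haircut equals brute-force 2-core pruning on small graphs", {
  # exhaustive over every labeled graph on <= 5 vertices
  for (n in 2:5) {
    for (edges in all_labeled_graphs(n)) {
      g <- named_graph(edges, n = n)
      adj <- netpharm:::graph_adjacency(g)
      got <- sort(igraph::V(g)$name[netpharm:::haircut_prune(adj, seq_len(n))])
      want <- sort(prune_k_oracle(g, igraph::V(g)$name, k = 2))
      expect_identical(got, want)
    }
  }
  # seeded random graphs at 6 and 7 vertices
  set.seed(123)
  for (rep in 1:400) {
    n <- sample(6:7, 1)
    g <- er_graph(n, runif(1, 0.2, 0.8), seed = 1000 + rep)
    adj <- netpharm:::graph_adjacency(g)
    got <- sort(igraph::V(g)$name[netpharm:::haircut_prune(adj, seq_len(n))])
    want <- sort(prune_k_oracle(g, igraph::V(g)$name, k = 2))
    expect_identical(got, want)
  }
})

test_that("planted modules are recovered from a sparse background", {
  ppi <- synth_ppi(synth_spec(seed = 4, n_background = 220,
                              module_sizes = 20, p_in = 0.6, p_out = 0.02))
  planted <- ppi$membership$symbol[ppi$membership$planted_module == 1]
  mods <- find_modules(ppi$graph)
  top <- mods[[1]]$members
  jac <- length(intersect(top, planted)) / length(union(top, planted))
  expect_gte(jac, 0.8)
})

test_that("fluff adds dense boundary nodes without entering core members", {
  # K4 core with a pendant triangle neighbor attached to two core nodes
  edges <- rbind(t(utils::combn(1:4, 2)), c(1, 5), c(2, 5))
  g <- named_graph(edges)
  mods <- find_modules(g, mcode_params(fluff = TRUE, fluff_threshold = 0.1,
                                       haircut = FALSE))
  expect_length(mods, 1)
  expect_true("N05" %in% mods[[1]]$members)
  expect_false("N05" %in% mods[[1]]$core_members)
})

test_that("module tables round-trip through writer and reader", {
  g <- er_graph(40, 0.15, seed = 9)
  mods <- find_modules(g)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_module_table(mods, path)
  back <- read_cluster_table(path)
  expect_equal(nrow(back), length(mods))
  expect_equal(back$Score, module_table(mods)$Score)
  expect_equal(back$Members[[1]], mods[[1]]$members)
})
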