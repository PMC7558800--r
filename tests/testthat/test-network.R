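write_edge_file <- function(df, col_names = c("node1", "node2", "combined_score")) {
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  names(df) <- col_names
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

test_that("reciprocal duplicates collapse keeping the max score", {
  path <- write_edge_file(data.frame(a = c("A", "B"), b = c("B", "A"),
                                     s = c(0.9, 0.95)))
  edges <- read_string_tsv(path)
  expect_equal(nrow(edges), 1)
  expect_equal(edges$score, 0.95)
  expect_equal(edges$node1, "A")
})

test_that("self-loops and sub-threshold scores are dropped", {
  path <- write_edge_file(data.frame(a = c("A", "A", "C"),
                                     b = c("A", "B", "D"),
                                     s = c(0.95, 0.9, 0.39)))
  edges <- read_string_tsv(path, score_min = 0.4)
  expect_equal(nrow(edges), 1)
  expect_equal(edges$node1, "A")
  expect_equal(edges$node2, "B")
})

test_that("0-999 score dialect is auto-detected and threshold rescaled", {
  path <- write_edge_file(data.frame(a = c("A", "C"), b = c("B", "D"),
                                     s = c(900, 399)))
  edges <- read_string_tsv(path, score_min = 0.4)
  expect_equal(nrow(edges), 1)
  expect_equal(edges$score, 900)  # stored on the file's scale
  # explicit unit scale keeps both (both scores >= 0.4 read as unit values)
  edges2 <- read_string_tsv(path, score_min = 0.4, scale = "unit")
  expect_equal(nrow(edges2), 2)
})

test_that("malformed rows are skipped and counted; all-filtered is an error", {
  path <- write_edge_file(data.frame(a = c("A", "", "C"), b = c("B", "X", "D"),
                                     s = c(0.9, 0.8, NA)))
  edges <- read_string_tsv(path)
  expect_equal(nrow(edges), 1)
  expect_equal(attr(edges, "n_skipped"), 2)

  low <- write_edge_file(data.frame(a = "A", b = "B", s = 0.1))
  expect_error(read_string_tsv(low), "network")
})

test_that("random rows match a brute-force dedup+filter oracle", {
  set.seed(99)
  nodes <- sprintf("G%02d", 1:25)
  df <- data.frame(a = sample(nodes, 200, TRUE), b = sample(nodes, 200, TRUE),
                   s = round(runif(200), 3))
  path <- write_edge_file(df)
  edges <- read_string_tsv(path, score_min = 0.4)

  # oracle: drop loops and low scores, canonicalize, keep max per pair
  keep <- df$a != df$b & df$s >= 0.4
  lo <- pmin(df$a, df$b)[keep]; hi <- pmax(df$a, df$b)[keep]
  sc <- df$s[keep]
  oracle <- aggregate(list(score = sc),
                      by = list(node1 = lo, node2 = hi), FUN = max)
  oracle <- oracle[order(oracle$node1, oracle$node2), ]
  rownames(oracle) <- NULL
  expect_equal(data.frame(edges[, c("node1", "node2", "score")]),
               oracle[, c("node1", "node2", "score")],
               ignore_attr = TRUE)
})

test_that("the reader is idempotent on its own re-serialized output", {
  set.seed(5)
  nodes <- sprintf("G%02d", 1:15)
  df <- data.frame(a = sample(nodes, 80, TRUE), b = sample(nodes, 80, TRUE),
                   s = round(runif(80, 0.4, 1), 3))
  first <- read_string_tsv(write_edge_file(df))
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_string_tsv(first, path2)
  second <- read_string_tsv(path2)
  expect_equal(data.frame(second), data.frame(first), ignore_attr = TRUE)
})

test_that("restricted networks keep categorized isolates and drop stray edges", {
  bundle <- make_bundle(c("A", "B", "C"), c("B", "X9"))
  edges <- data.frame(node1 = c("A", "A"), node2 = c("B", "ZZ"),
                      score = c(0.9, 0.9))
  g <- build_network(edges, bundle, restrict = TRUE)
  expect_setequal(igraph::V(g)$name, c("A", "B", "C", "X9"))
  expect_equal(igraph::ecount(g), 1)
  expect_equal(igraph::degree(g)[["C"]], 0)  # categorized isolate retained
  expect_false(any(is.na(igraph::V(g)$category)))

  g2 <- build_network(edges, bundle, restrict = FALSE)
  expect_true("ZZ" %in% igraph::V(g2)$name)
  expect_equal(igraph::ecount(g2), 2)
  expect_true(is.na(igraph::V(g2)$category[igraph::V(g2)$name == "ZZ"]))
})

test_that("node and edge counts match a set-based construction oracle", {
  set.seed(31)
  nodes <- sprintf("G%02d", 1:50)
  drug <- sample(nodes, 30)
  disease <- sample(nodes, 25)
  bundle <- make_bundle(drug, disease)
  categorized <- union(drug, disease)
  df <- data.frame(node1 = sample(nodes, 120, TRUE),
                   node2 = sample(nodes, 120, TRUE),
                   score = runif(120, 0.4, 1))
  df <- df[df$node1 != df$node2, ]
  g <- build_network(df, bundle, restrict = TRUE)
  expect_setequal(igraph::V(g)$name, categorized)
  pairs <- unique(paste(pmin(df$node1, df$node2), pmax(df$node1, df$node2))[
    df$node1 %in% categorized & df$node2 %in% categorized])
  expect_equal(igraph::ecount(g), length(pairs))
})

test_that("degree table ranks hubs with deterministic tie-breaks", {
  star <- named_graph(cbind(1, 2:6), prefix = "S")  # S01 center
  bundle <- make_bundle(sprintf("S%02d", 1:6), character(0))
  igraph::V(star)$category <- netpharm:::node_category(bundle, igraph::V(star)$name)
  df <- degree_table(star)
  expect_equal(df$symbol[1], "S01")
  expect_equal(df$degree[1], 5)
  expect_equal(df$degree[-1], rep(1, 5))
  expect_equal(df$symbol[-1], sort(df$symbol[-1]))  # lexicographic ties
  expect_error(degree_table(star, top_k = 0), "top_k")
})

test_that("degrees satisfy the handshake lemma and match adjacency counts", {
  g <- er_graph(30, 0.2, seed = 12)
  df <- degree_table(g)
  expect_equal(sum(df$degree), 2 * igraph::ecount(g))
  amat <- as.matrix(igraph::as_adjacency_matrix(g))
  oracle <- rowSums(amat)
  expect_equal(df$degree, unname(oracle[df$symbol]))
})

test_that("SIF and GraphML exports carry the network", {
  bundle <- make_bundle(c("A", "B"), c("B", "C"))
  g <- build_network(data.frame(node1 = c("A", "B"), node2 = c("B", "C"),
                                score = c(0.9, 0.8)), bundle)
  sif <- withr::local_tempfile(fileext = ".sif")
  write_sif(g, sif)
  expect_equal(sort(readLines(sif)), c("A pp B", "B pp C"))

  gml <- withr::local_tempfile(fileext = ".graphml")
  write_graphml(g, gml)
  back <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::ecount(back), 2)
  expect_setequal(igraph::V(back)$category, c("drug_only", "shared", "disease_only"))
})
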