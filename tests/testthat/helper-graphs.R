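# Graph-building helpers shared across test files. Oracles here are written
# against adjacency matrices so they share no code with the package's
# adjacency-list implementation.

# Named undirected graph from a 2-column edge matrix of 1-based indices.
named_graph <- function(edges, n = max(edges), prefix = "N") {
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (length(edges)) g <- igraph::add_edges(g, t(edges))
  igraph::V(g)$name <- sprintf("%s%02d", prefix, seq_len(n))
  g
}

# Erdos-Renyi G(n, p) with reproducible seed and named vertices.
er_graph <- function(n, p, seed) {
  set.seed(seed)
  g <- igraph::sample_gnp(n, p)
  igraph::V(g)$name <- sprintf("N%02d", seq_len(n))
  g
}

# Complete graph with named vertices.
k_graph <- function(n, prefix = "K") {
  g <- igraph::make_full_graph(n)
  igraph::V(g)$name <- sprintf("%s%02d", prefix, seq_len(n))
  g
}

# Deterministic graph with exactly n nodes and e edges: the first e pairs
# of K_n in lexicographic order.
fixed_size_graph <- function(n, e, prefix = "N") {
  stopifnot(e <= choose(n, 2))
  pairs <- t(utils::combn(n, 2))[seq_len(e), , drop = FALSE]
  named_graph(pairs, n = n, prefix = prefix)
}

# Adjacency-matrix oracle: iterative removal of nodes with < k neighbors
# among the kept set. Returns the kept vertex names.
prune_k_oracle <- function(graph, members, k = 2) {
  amat <- as.matrix(igraph::as_adjacency_matrix(graph))
  keep <- members
  repeat {
    if (!length(keep)) return(character(0))
    deg <- rowSums(amat[keep, keep, drop = FALSE])
    if (all(deg >= k)) return(keep)
    keep <- keep[deg >= k]
  }
}

# All labeled graphs on n nodes as a list of edge matrices (2^(n choose 2)).
all_labeled_graphs <- function(n) {
  pairs <- t(utils::combn(n, 2))
  m <- nrow(pairs)
  lapply(seq_len(2^m) - 1L, function(code) {
    pairs[bitwAnd(code, 2^(seq_len(m) - 1L)) > 0L, , drop = FALSE]
  })
}

# Minimal gene-set bundle over two symbol vectors.
make_bundle <- function(drug, disease) classify_nodes(drug, disease)
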