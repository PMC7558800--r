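#' Read a STRING-dialect TSV edge list
#'
#' Parses the tab-separated export format of protein-interaction databases:
#' a header naming two node columns and a combined-score column, one
#' undirected interaction per row. Reciprocal duplicates (A-B and B-A)
#' collapse to one edge keeping the maximum score, self-loops are dropped,
#' and edges scoring below `score_min` are removed. Gene symbols are
#' uppercased.
#'
#' Both common score dialects are accepted: probabilities on \[0,1\] and
#' integer scores on 0-999. With `scale = "auto"` (default) the dialect is
#' inferred from the maximum observed score; `score_min` is always given on
#' the 0-1 scale and rescaled internally when the file uses 0-999. Scores
#' are stored as found in the file.
#'
#' @param path File path (or connection) to the TSV export.
#' @param score_min Minimum combined score on the 0-1 scale (default 0.4,
#'   the usual "medium confidence" cut). Edges with score strictly below
#'   the threshold are dropped.
#' @param scale `"auto"`, `"unit"` (0-1) or `"string999"` (0-999).
#' @param columns Named vector mapping `node1`, `node2`, `score` to the
#'   file's column names (a leading `#` on the first header field is
#'   tolerated, as in STRING exports).
#' @return Data frame with columns `node1`, `node2`, `score`; one row per
#'   surviving undirected edge, endpoints ordered lexicographically. The
#'   number of malformed rows skipped is attached as attribute `n_skipped`.
#' @export
read_string_tsv <- function(path, score_min = 0.4,
                            scale = c("auto", "unit", "string999"),
                            columns = c(node1 = "node1", node2 = "node2",
                                        score = "combined_score")) {
  scale <- match.arg(scale)
  raw <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE)
  names(raw) <- sub("^#", "", names(raw))
  miss <- setdiff(unname(columns), names(raw))
  if (length(miss)) {
    stage_stop("network", "edge list lacks columns: ",
               paste(miss, collapse = ", "))
  }
  a <- toupper(trimws(as.character(raw[[columns[["node1"]]]])))
  b <- toupper(trimws(as.character(raw[[columns[["node2"]]]])))
  s <- suppressWarnings(as.numeric(raw[[columns[["score"]]]]))

  bad <- !nzchar(a) | !nzchar(b) | is.na(s)
  n_skipped <- sum(bad)
  a <- a[!bad]; b <- b[!bad]; s <- s[!bad]

  loops <- a == b
  a <- a[!loops]; b <- b[!loops]; s <- s[!loops]

  if (length(s)) {
    eff_min <- switch(scale,
      unit = score_min,
      string999 = score_min * 1000,
      auto = if (max(s) > 1.5) score_min * 1000 else score_min
    )
    keep <- s >= eff_min
    a <- a[keep]; b <- b[keep]; s <- s[keep]
  }

  # canonical endpoint order, then max-score dedup of reciprocal rows
  lo <- pmin(a, b); hi <- pmax(a, b)
  if (length(lo)) {
    key <- paste(lo, hi, sep = "\r")
    best <- tapply(s, key, max)
    parts <- strsplit(names(best), "\r", fixed = TRUE)
    edges <- data.frame(
      node1 = vapply(parts, `[`, character(1), 1L),
      node2 = vapply(parts, `[`, character(1), 2L),
      score = as.numeric(best),
      stringsAsFactors = FALSE
    )
    edges <- edges[order(edges$node1, edges$node2), , drop = FALSE]
    rownames(edges) <- NULL
  } else {
    edges <- data.frame(node1 = character(0), node2 = character(0),
                        score = numeric(0))
  }
  if (nrow(edges) == 0) {
    stage_stop("network", "no edges survive parsing and score filtering")
  }
  attr(edges, "n_skipped") <- n_skipped
  edges
}

#' Write an edge list back to STRING-dialect TSV
#'
#' @param edges Data frame with `node1`, `node2`, `score`.
#' @param path Output path.
#' @param columns Header names to emit for the three columns.
#' @return `path`, invisibly.
#' @export
write_string_tsv <- function(edges, path,
                             columns = c(node1 = "node1", node2 = "node2",
                                         score = "combined_score")) {
  df <- data.frame(edges$node1, edges$node2, edges$score)
  names(df) <- unname(columns[c("node1", "node2", "score")])
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Build the categorized interaction network
#'
#' Constructs an undirected simple igraph from a parsed edge list, labelling
#' every node with its gene-set category (`shared`, `drug_only`,
#' `disease_only`). With `restrict = TRUE` (default) only edges whose both
#' endpoints are categorized are kept, and categorized genes with no
#' surviving interaction are retained as isolated degree-0 nodes — so the
#' network's node set is exactly the categorized gene space.
#'
#' @param edges Data frame from [read_string_tsv()] (columns `node1`,
#'   `node2`, `score`).
#' @param bundle A `gene_set_bundle` from [classify_nodes()].
#' @param restrict Drop edges touching uncategorized symbols (default TRUE).
#'   With `restrict = FALSE` uncategorized endpoints are kept with category
#'   `NA`.
#' @return An igraph with vertex attributes `name` and `category` and edge
#'   attribute `score`.
#' @export
build_network <- function(edges, bundle, restrict = TRUE) {
  stopifnot(inherits(bundle, "gene_set_bundle"))
  categorized <- c(bundle$shared, bundle$drug_only, bundle$disease_only)
  if (restrict) {
    keep <- edges$node1 %in% categorized & edges$node2 %in% categorized
    edges <- edges[keep, , drop = FALSE]
    verts <- sort(unique(categorized))
  } else {
    verts <- sort(unique(c(categorized, edges$node1, edges$node2)))
  }
  g <- igraph::graph_from_data_frame(
    edges[, c("node1", "node2", "score")],
    directed = FALSE,
    vertices = data.frame(name = verts, stringsAsFactors = FALSE)
  )
  g <- igraph::simplify(g, edge.attr.comb = list(score = "max"))
  igraph::V(g)$category <- node_category(bundle, igraph::V(g)$name)
  g
}

#' Degree table with hub ranking
#'
#' Ranks network nodes by degree (number of interaction partners), the hub
#' criterion of network pharmacology: the higher a target's degree, the
#' more central it is to the drug-disease network. Ties are broken
#' lexicographically by symbol so the ranking is a reproducible total
#' order.
#'
#' @param network igraph from [build_network()].
#' @param top_k Optional integer: keep only the `top_k` highest-degree rows
#'   (overall, or within each category if `per_category`).
#' @param per_category Rank within each node category separately.
#' @return Data frame with columns `symbol`, `degree`, `category`.
#' @export
degree_table <- function(network, top_k = NULL, per_category = FALSE) {
  if (!is.null(top_k) && (!is_count(top_k) || top_k <= 0)) {
    stop("top_k must be a positive integer")
  }
  df <- data.frame(
    symbol = igraph::V(network)$name,
    degree = as.integer(igraph::degree(network)),
    category = if ("category" %in% igraph::vertex_attr_names(network)) {
      igraph::V(network)$category
    } else NA_character_,
    stringsAsFactors = FALSE
  )
  df <- df[order(-df$degree, df$symbol), , drop = FALSE]
  rownames(df) <- NULL
  if (per_category) {
    pieces <- split(df, df$category)
    pieces <- lapply(pieces, function(p) {
      if (!is.null(top_k)) p <- p[seq_len(min(top_k, nrow(p))), , drop = FALSE]
      p
    })
    df <- do.call(rbind, pieces)
    df <- df[order(-df$degree, df$symbol), , drop = FALSE]
    rownames(df) <- NULL
  } else if (!is.null(top_k)) {
    df <- df[seq_len(min(top_k, nrow(df))), , drop = FALSE]
  }
  df
}

#' Export a network as SIF
#'
#' Simple interaction format: one `A pp B` line per edge.
#'
#' @param network igraph.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sif <- function(network, path) {
  el <- igraph::as_edgelist(network)
  lines <- if (nrow(el)) paste(el[, 1], "pp", el[, 2]) else character(0)
  writeLines(lines, path)
  invisible(path)
}

#' Export a network as GraphML
#'
#' Carries the `category` vertex attribute and `score` edge attribute.
#'
#' @param network igraph.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(network, path) {
  igraph::write_graph(network, path, format = "graphml")
  invisible(path)
}
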