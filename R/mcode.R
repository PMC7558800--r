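# MCODE molecular-complex detection, implemented from scratch on plain
# adjacency lists. The igraph object is converted once at entry; everything
# after that is index arithmetic, so the algorithm is independent of any
# library's community-detection code.

#' MCODE parameters
#'
#' Parameter set for molecular-complex detection. Defaults are the
#' published plugin defaults: degree cutoff 2, node score cutoff 0.2,
#' k-core filter 2, haircut on, fluff off.
#'
#' @param degree_cutoff Nodes with whole-graph degree below this get vertex
#'   weight 0 and cannot nucleate or join dense regions (default 2).
#' @param node_score_cutoff Fraction in \[0,1): a neighbor joins a growing
#'   complex if its weight is at least `(1 - node_score_cutoff)` times the
#'   seed's weight (default 0.2).
#' @param k_core_filter Complexes lacking a k-core of this order are
#'   discarded (default 2).
#' @param haircut Iteratively remove members with fewer than 2 in-complex
#'   neighbors (default TRUE).
#' @param fluff Add boundary nodes whose closed-neighborhood density
#'   exceeds `fluff_threshold` (default FALSE).
#' @param fluff_threshold Density threshold for fluff (default 0.1).
#' @param max_depth Depth limit of the seed-and-grow traversal
#'   (default 100).
#' @return An object of class `mcode_params`.
#' @export
mcode_params <- function(degree_cutoff = 2, node_score_cutoff = 0.2,
                         k_core_filter = 2, haircut = TRUE, fluff = FALSE,
                         fluff_threshold = 0.1, max_depth = 100) {
  stopifnot(is_count(degree_cutoff),
            is_number(node_score_cutoff),
            node_score_cutoff >= 0, node_score_cutoff < 1,
            is_count(k_core_filter),
            is_flag(haircut), is_flag(fluff),
            is_number(fluff_threshold),
            is_count(max_depth), max_depth >= 1)
  structure(
    list(degree_cutoff = as.integer(degree_cutoff),
         node_score_cutoff = node_score_cutoff,
         k_core_filter = as.integer(k_core_filter),
         haircut = haircut, fluff = fluff,
         fluff_threshold = fluff_threshold,
         max_depth = as.integer(max_depth)),
    class = "mcode_params"
  )
}

#' @export
print.mcode_params <- function(x, ...) {
  cat(sprintf(paste0(
    "MCODE parameters: degree cutoff %d, node score cutoff %.2f, ",
    "k-core filter %d, haircut %s, fluff %s (threshold %.2f), max depth %d\n"),
    x$degree_cutoff, x$node_score_cutoff, x$k_core_filter,
    if (x$haircut) "on" else "off", if (x$fluff) "on" else "off",
    x$fluff_threshold, x$max_depth))
  invisible(x)
}

# igraph -> list of integer adjacency vectors (1-based, simple graph assumed)
graph_adjacency <- function(graph) {
  lapply(igraph::as_adj_list(graph, mode = "all"), as.integer)
}

# Iterative minimum-degree peeling on an integer adjacency list.
# Returns the core number of every vertex.
core_peel <- function(adj) {
  n <- length(adj)
  if (n == 0) return(integer(0))
  deg <- lengths(adj)
  alive <- rep(TRUE, n)
  core <- integer(n)
  k <- 0L
  for (step in seq_len(n)) {
    cand <- which(alive)
    v <- cand[which.min(deg[cand])]
    k <- max(k, deg[v])
    core[v] <- k
    alive[v] <- FALSE
    nb <- adj[[v]]
    nb <- nb[alive[nb]]
    deg[nb] <- deg[nb] - 1L
  }
  core
}

#' k-core decomposition
#'
#' Computes every node's core number: the largest k such that the node
#' belongs to a maximal subgraph in which every node has at least k
#' neighbors. This is the vertex-weighting substrate of MCODE.
#'
#' @param network An igraph (undirected, simple).
#' @return Named integer vector of core numbers.
#' @examples
#' g <- igraph::make_full_graph(5)
#' igraph::V(g)$name <- LETTERS[1:5]
#' core_decomposition(g)  # all 4
#' @export
core_decomposition <- function(network) {
  adj <- graph_adjacency(network)
  setNames(core_peel(adj), igraph::V(network)$name)
}

# Adjacency of the induced subgraph on vertex index set `verts`,
# re-indexed 1..length(verts).
induce_adj <- function(adj, verts) {
  pos <- integer(length(adj))
  pos[verts] <- seq_along(verts)
  lapply(verts, function(u) {
    nb <- adj[[u]]
    pos[nb[pos[nb] > 0L]]
  })
}

# Edge count of an induced subgraph given the parent adjacency list.
induced_edge_count <- function(adj, verts) {
  inset <- logical(length(adj))
  inset[verts] <- TRUE
  sum(vapply(verts, function(u) sum(inset[adj[[u]]]), integer(1))) %/% 2L
}

# Loop-free density of an induced subgraph: 2E / (N(N-1)).
induced_density <- function(adj, verts) {
  n <- length(verts)
  if (n < 2) return(0)
  2 * induced_edge_count(adj, verts) / (n * (n - 1))
}

# Vertex weight of index v: highest-core-ness of its closed neighborhood.
# H = induced subgraph on N[v]; k = max core number in H; C = k-core of H;
# weight = k * density(C). Degree below the cutoff forces weight 0.
vertex_weight_idx <- function(adj, v, degree_cutoff = 2L) {
  if (length(adj[[v]]) < degree_cutoff) return(0)
  nb <- c(v, adj[[v]])
  sub <- induce_adj(adj, nb)
  core <- core_peel(sub)
  kmax <- max(core)
  if (kmax == 0L) return(0)
  core_verts <- nb[core >= kmax]
  kmax * induced_density(adj, core_verts)
}

#' MCODE vertex weight
#'
#' The local density weight MCODE assigns to a node: the order k of the
#' highest k-core in the node's closed neighborhood, times the loop-free
#' density of that core. Nodes with degree below `degree_cutoff` get
#' weight 0.
#'
#' @param network An igraph.
#' @param v Node name (or index) to weight; `NULL` returns all weights.
#' @param degree_cutoff Minimum whole-graph degree (default 2).
#' @return Numeric weight, or a named vector of all weights when
#'   `v = NULL`.
#' @export
vertex_weight <- function(network, v = NULL, degree_cutoff = 2) {
  adj <- graph_adjacency(network)
  nms <- igraph::V(network)$name
  if (is.null(v)) {
    return(setNames(
      vapply(seq_along(adj), vertex_weight_idx, numeric(1),
             adj = adj, degree_cutoff = as.integer(degree_cutoff)),
      nms
    ))
  }
  idx <- if (is.character(v)) match(v, nms) else as.integer(v)
  if (is.na(idx) || idx < 1 || idx > length(adj)) stop("unknown vertex: ", v)
  vertex_weight_idx(adj, idx, as.integer(degree_cutoff))
}

#' MCODE cluster score
#'
#' Score of a detected module: loop-free density of the induced subgraph
#' times its node count, which simplifies to `2E / (N - 1)` for N nodes
#' and E induced edges.
#'
#' @param network An igraph.
#' @param members Character vector of member node names (at least 2).
#' @return Numeric score.
#' @examples
#' g <- igraph::make_full_graph(3)
#' igraph::V(g)$name <- c("A", "B", "C")
#' module_score(g, c("A", "B", "C"))  # a triangle scores 3
#' @export
module_score <- function(network, members) {
  members <- unique(members)
  if (length(members) < 2) {
    stop("module_score needs at least 2 member nodes")
  }
  idx <- match(members, igraph::V(network)$name)
  if (anyNA(idx)) {
    stop("members not in network: ",
         paste(members[is.na(idx)], collapse = ", "))
  }
  adj <- graph_adjacency(network)
  n <- length(idx)
  e <- induced_edge_count(adj, idx)
  2 * e / (n - 1)
}

# Iterative pruning of members with < 2 in-module neighbors (the haircut):
# equivalently, the 2-core of the candidate's induced subgraph.
haircut_prune <- function(adj, verts) {
  repeat {
    inset <- logical(length(adj))
    inset[verts] <- TRUE
    indeg <- vapply(verts, function(u) sum(inset[adj[[u]]]), integer(1))
    if (!length(verts) || all(indeg >= 2L)) return(verts)
    verts <- verts[indeg >= 2L]
  }
}

# Does the induced subgraph contain a k-core?
has_k_core <- function(adj, verts, k) {
  sub <- induce_adj(adj, verts)
  length(sub) > 0 && max(core_peel(sub)) >= k
}

# Connected components of an induced subgraph; returns list of vertex-index
# vectors (parent indexing).
induced_components <- function(adj, verts) {
  sub <- induce_adj(adj, verts)
  n <- length(sub)
  comp <- integer(n)
  cid <- 0L
  for (s in seq_len(n)) {
    if (comp[s] > 0L) next
    cid <- cid + 1L
    queue <- s
    comp[s] <- cid
    while (length(queue)) {
      u <- queue[[1]]; queue <- queue[-1]
      nb <- sub[[u]]
      new <- nb[comp[nb] == 0L]
      comp[new] <- cid
      queue <- c(queue, new)
    }
  }
  lapply(seq_len(cid), function(i) verts[comp == i])
}

#' Detect dense modules with MCODE
#'
#' Seed-and-grow molecular-complex detection. Nodes are weighted by
#' [vertex_weight()]; the highest-weight unvisited node seeds a complex,
#' which grows by breadth-first traversal admitting an unvisited neighbor
#' when its weight is at least `(1 - node_score_cutoff)` times the weight
#' of the node being expanded, down to `max_depth` levels. Thresholding
#' against the expanding node (rather than freezing the seed's weight)
#' lets a complex follow the weight gradient across a dense region whose
#' seed is a local outlier, while still refusing steps down into the
#' sparse background. Admitted nodes are marked visited.
#' Each candidate is then post-processed: discarded unless it contains a
#' `k_core_filter`-core; haircut iteratively removes members with fewer
#' than two in-complex neighbors; fluff optionally adds boundary nodes
#' with dense closed neighborhoods (fluffed nodes may repeat across
#' complexes and are exempt from the core-membership disjointness of the
#' output). If the haircut disconnects a candidate, the component
#' containing the seed is kept (the largest component, smallest first
#' member breaking ties, if the seed itself was pruned).
#'
#' All tie-breaks are lexicographic by node symbol, so the output is a
#' deterministic function of the graph and parameters. Modules are sorted
#' by score descending, then size descending, then seed symbol.
#'
#' @param network An igraph with named vertices.
#' @param params An [mcode_params()] object.
#' @return An object of class `mcode_modules`: a list of modules, each a
#'   list with `members` (discovery order), `core_members`, `fluffed`,
#'   `seed`, `n_nodes`, `n_edges`, `score`.
#' @export
find_modules <- function(network, params = mcode_params()) {
  stopifnot(inherits(params, "mcode_params"))
  n <- igraph::vcount(network)
  if (n == 0) {
    return(structure(list(), class = "mcode_modules"))
  }
  nms <- igraph::V(network)$name
  adj <- graph_adjacency(network)
  w <- vapply(seq_len(n), vertex_weight_idx, numeric(1),
              adj = adj, degree_cutoff = params$degree_cutoff)

  # seed order: weight descending, symbol ascending
  seed_order <- order(-w, nms)
  visited <- logical(n)
  raw <- list()

  for (s in seed_order) {
    if (visited[s]) next
    visited[s] <- TRUE
    members <- s
    frontier <- s
    depth <- 0L
    # recursive neighborhood inspection: a neighbor joins if its weight is
    # within the score cutoff of the node being expanded, so the complex
    # descends weight gradients inside a dense region without being capped
    # by the seed's (often locally extreme) weight
    while (length(frontier) && depth < params$max_depth) {
      nxt <- integer(0)
      for (u in frontier) {
        nb <- adj[[u]]
        nb <- nb[!visited[nb] & w[nb] >= w[u] * (1 - params$node_score_cutoff)]
        if (length(nb)) {
          nb <- nb[order(nms[nb])]
          visited[nb] <- TRUE
          nxt <- c(nxt, nb)
        }
      }
      members <- c(members, nxt)
      frontier <- nxt
      depth <- depth + 1L
    }
    if (length(members) >= 2) {
      raw[[length(raw) + 1L]] <- list(seed = s, members = members)
    }
  }

  # closed-neighborhood densities, needed only if fluffing
  nbhd_dens <- NULL
  if (params$fluff) {
    nbhd_dens <- vapply(seq_len(n), function(v) {
      induced_density(adj, c(v, adj[[v]]))
    }, numeric(1))
  }

  modules <- list()
  for (cand in raw) {
    verts <- cand$members
    if (!has_k_core(adj, verts, params$k_core_filter)) next
    if (params$haircut) {
      verts <- haircut_prune(adj, verts)
      if (length(verts) == 0) next
      comps <- induced_components(adj, verts)
      if (length(comps) > 1) {
        hit <- which(vapply(comps, function(cc) cand$seed %in% cc, logical(1)))
        if (length(hit) == 1) {
          verts <- comps[[hit]]
        } else {
          sizes <- lengths(comps)
          first <- vapply(comps, function(cc) min(nms[cc]), character(1))
          verts <- comps[[order(-sizes, first)[1]]]
        }
      }
    }
    core_verts <- verts
    fluffed <- integer(0)
    if (params$fluff) {
      inset <- logical(n)
      inset[verts] <- TRUE
      boundary <- setdiff(unique(unlist(adj[verts])), which(inset))
      fluffed <- boundary[nbhd_dens[boundary] > params$fluff_threshold]
      fluffed <- fluffed[order(nms[fluffed])]
      verts <- c(verts, fluffed)
    }
    if (length(verts) < 2) next
    n_nodes <- length(verts)
    n_edges <- induced_edge_count(adj, verts)
    modules[[length(modules) + 1L]] <- list(
      members = nms[verts],
      core_members = sort(nms[core_verts]),
      fluffed = nms[fluffed],
      seed = nms[cand$seed],
      n_nodes = n_nodes,
      n_edges = n_edges,
      score = 2 * n_edges / (n_nodes - 1)
    )
  }

  if (length(modules)) {
    ord <- order(-vapply(modules, `[[`, numeric(1), "score"),
                 -vapply(modules, `[[`, numeric(1), "n_nodes"),
                 vapply(modules, `[[`, character(1), "seed"))
    modules <- modules[ord]
  }
  structure(modules, class = "mcode_modules")
}

#' @export
print.mcode_modules <- function(x, ...) {
  cat(sprintf("MCODE modules: %d detected\n", length(x)))
  if (length(x)) {
    df <- module_table(x)
    df$Members <- ifelse(nchar(df$Members) > 60,
                         paste0(substr(df$Members, 1, 57), "..."),
                         df$Members)
    print(df, row.names = FALSE)
  }
  invisible(x)
}

#' Module report table
#'
#' Formats detected modules in the conventional cluster-report schema:
#' Cluster, Score (3 decimals), Nodes, Edges, Members (comma-joined in
#' discovery order).
#'
#' @param modules An `mcode_modules` object.
#' @return Data frame.
#' @export
module_table <- function(modules) {
  stopifnot(inherits(modules, "mcode_modules"))
  if (!length(modules)) {
    return(data.frame(Cluster = integer(0), Score = numeric(0),
                      Nodes = integer(0), Edges = integer(0),
                      Members = character(0)))
  }
  data.frame(
    Cluster = seq_along(modules),
    Score = round(vapply(modules, `[[`, numeric(1), "score"), 3),
    Nodes = vapply(modules, `[[`, numeric(1), "n_nodes"),
    Edges = vapply(modules, `[[`, numeric(1), "n_edges"),
    Members = vapply(modules, function(m) paste(m$members, collapse = ", "),
                     character(1)),
    stringsAsFactors = FALSE
  )
}

#' Write a module report table
#'
#' @param modules An `mcode_modules` object.
#' @param path Output path (tab-separated).
#' @return The table, invisibly.
#' @export
write_module_table <- function(modules, path) {
  df <- module_table(modules)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}

#' Read a cluster report table
#'
#' Parses the Cluster / Score / Nodes / Edges / Members schema written by
#' [write_module_table()] (and used by published cluster tables). The
#' comma-joined membership column is split into a list of symbol vectors.
#'
#' @param path File path.
#' @return Data frame with a `Members` list-column.
#' @export
read_cluster_table <- function(path) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                   check.names = FALSE)
  need <- c("Cluster", "Score", "Nodes", "Edges", "Members")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("cluster table lacks columns: ", paste(miss, collapse = ", "))
  }
  df$Members <- lapply(strsplit(df$Members, ","), function(x) {
    x <- trimws(x)
    x[nzchar(x)]
  })
  df
}
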