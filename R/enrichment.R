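#' Annotation collection
#'
#' A named set of annotation terms (GO terms, pathways, ...), each a set of
#' uppercase gene symbols, plus the background universe the
#' over-representation test counts against. By default the universe is the
#' union of all term members — the dependency-free stand-in for a curated
#' background — and can be overridden with, for example, all network genes.
#'
#' @param terms Named list of character vectors (term id -> gene symbols).
#' @param descriptions Optional named character vector of term
#'   descriptions; defaults to the term ids.
#' @param universe Optional character vector overriding the default
#'   universe (union of term members). Term genes outside an explicit
#'   universe are dropped from the terms.
#' @param name Collection label.
#' @return An object of class `annotation_collection`.
#' @export
annotation_collection <- function(terms, descriptions = NULL,
                                  universe = NULL, name = "collection") {
  if (!length(terms) || is.null(names(terms)) || any(!nzchar(names(terms)))) {
    stop("terms must be a non-empty named list")
  }
  terms <- lapply(terms, function(g) sort(unique(norm_symbols(g))))
  if (any(lengths(terms) == 0)) stop("empty annotation terms are not allowed")
  if (is.null(descriptions)) {
    descriptions <- setNames(names(terms), names(terms))
  }
  if (is.null(universe)) {
    universe <- sort(unique(unlist(terms, use.names = FALSE)))
  } else {
    universe <- sort(unique(norm_symbols(universe)))
    terms <- lapply(terms, function(g) intersect(g, universe))
    if (any(lengths(terms) == 0)) {
      stop("universe override leaves at least one term empty")
    }
  }
  structure(
    list(name = name, terms = terms,
         descriptions = descriptions[names(terms)], universe = universe),
    class = "annotation_collection"
  )
}

#' @export
print.annotation_collection <- function(x, ...) {
  cat(sprintf("Annotation collection '%s': %d terms, universe %d genes\n",
              x$name, length(x$terms), length(x$universe)))
  invisible(x)
}

#' Read a GMT gene-set file
#'
#' Tab-separated, one term per line: term id, description, then gene
#' symbols.
#'
#' @param path File path.
#' @param universe Optional universe override (see
#'   [annotation_collection()]).
#' @param name Collection label; defaults to the file name.
#' @return An `annotation_collection`.
#' @export
read_gmt <- function(path, universe = NULL, name = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty GMT file: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 3)) {
    stop("malformed GMT line (need id, description, >=1 gene)")
  }
  ids <- vapply(parts, `[`, character(1), 1L)
  desc <- vapply(parts, `[`, character(1), 2L)
  genes <- lapply(parts, function(p) p[-(1:2)])
  annotation_collection(setNames(genes, ids), setNames(desc, ids),
                        universe = universe,
                        name = if (is.null(name)) basename(path) else name)
}

#' Write an annotation collection as GMT
#'
#' @param collection An `annotation_collection`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "annotation_collection"))
  lines <- vapply(names(collection$terms), function(id) {
    paste(c(id, collection$descriptions[[id]], collection$terms[[id]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment of a p-value vector, preserving
#' the input order.
#'
#' @param pvals Numeric vector of p-values in \[0,1\].
#' @return Adjusted p-values in the same order.
#' @export
bh_adjust <- function(pvals) {
  if (!is.numeric(pvals) || anyNA(pvals) ||
      any(pvals < 0) || any(pvals > 1)) {
    stop("p-values must be numbers in [0, 1]")
  }
  p.adjust(pvals, method = "BH")
}

#' Over-representation analysis against an annotation collection
#'
#' For every term sharing at least one gene with the query, computes the
#' upper-tail hypergeometric probability of the observed overlap: with a
#' universe of N genes, K of them in the term and a query of n genes (both
#' counted within the universe), the p-value of an overlap of k is
#' \deqn{p = \sum_{i=k}^{\min(n,K)} \binom{K}{i}\binom{N-K}{n-i} /
#'   \binom{N}{n}.}
#' The EASE variant recomputes the tail with the overlap reduced by one
#' (floored at 0), a deliberately conservative score. Both are reported;
#' `method` selects which drives the FDR correction and ranking.
#' Fold enrichment is `(k/n) / (K/N)`, the observed-over-expected overlap
#' ratio. FDR is Benjamini-Hochberg across all terms tested within this
#' collection.
#'
#' Query genes outside the universe are dropped; the count is attached as
#' attribute `n_outside`.
#'
#' @param query Character vector of gene symbols.
#' @param collection An `annotation_collection`.
#' @param method `"hypergeometric"` (default) or `"ease"`.
#' @param fdr_alpha Significance level recorded on the result (default
#'   0.05); rows are flagged, not removed.
#' @return Data frame of class `enrichment_result`, ordered by
#'   [rank_enrichment()]: columns `term_id`, `description`, `k`, `n`, `K`,
#'   `N`, `p`, `p_ease`, `fdr`, `fold_enrichment`, `significant`.
#' @export
enrich <- function(query, collection, method = c("hypergeometric", "ease"),
                   fdr_alpha = 0.05) {
  stopifnot(inherits(collection, "annotation_collection"))
  method <- match.arg(method)
  query <- unique(norm_symbols(query))
  eff <- intersect(query, collection$universe)
  n_outside <- length(query) - length(eff)
  if (length(eff) == 0) {
    stage_stop("enrichment", "no query gene is in the annotation universe")
  }
  N <- length(collection$universe)
  n <- length(eff)
  bad <- lengths(collection$terms) > N
  if (any(bad)) {
    stage_stop("enrichment", "term larger than universe: ",
               paste(names(collection$terms)[bad], collapse = ", "))
  }

  ks <- vapply(collection$terms, function(g) length(intersect(g, eff)),
               integer(1))
  tested <- ks >= 1L
  ids <- names(collection$terms)[tested]
  k <- ks[tested]
  K <- lengths(collection$terms)[tested]

  # upper tail P(X >= k) for X ~ Hypergeometric(N, K, n)
  p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  p_ease <- phyper(pmax(k - 1, 0) - 1, K, N - K, n, lower.tail = FALSE)
  p_sel <- if (method == "ease") p_ease else p
  fdr <- bh_adjust(p_sel)

  res <- data.frame(
    term_id = ids,
    description = unname(collection$descriptions[ids]),
    k = as.integer(k), n = n, K = as.integer(K), N = N,
    p = as.numeric(p), p_ease = as.numeric(p_ease), fdr = as.numeric(fdr),
    fold_enrichment = (k / n) / (K / N),
    stringsAsFactors = FALSE
  )
  res$significant <- res$fdr <= fdr_alpha
  res <- rank_enrichment(res)
  attr(res, "method") <- method
  attr(res, "n_outside") <- n_outside
  class(res) <- c("enrichment_result", "data.frame")
  res
}

#' Rank enrichment records
#'
#' Orders records by degree of enrichment: ascending p-value, ties broken
#' by overlap count descending (larger counts first), then term id.
#'
#' @param records Data frame with columns `p` (or the method-selected
#'   p-value), `k` and `term_id`.
#' @param by Ranking rule; only `"p_then_count"` is defined.
#' @return The records, reordered.
#' @export
rank_enrichment <- function(records, by = "p_then_count") {
  stopifnot(identical(by, "p_then_count"))
  ord <- order(records$p, -records$k, records$term_id)
  out <- records[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("Over-representation result: %d terms tested (%s)\n",
              nrow(x), attr(x, "method")))
  print.data.frame(utils::head(x, 10), row.names = FALSE, digits = 4)
  if (nrow(x) > 10) cat(sprintf("  ... and %d more rows\n", nrow(x) - 10))
  invisible(x)
}

#' Write an enrichment table
#'
#' @param result An `enrichment_result`.
#' @param path Output path (tab-separated).
#' @return The table, invisibly.
#' @export
write_enrichment_table <- function(result, path) {
  write.table(as.data.frame(result), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(result)
}

#' Bubble-chart data export
#'
#' The x/y/size triples behind the conventional enrichment bubble chart:
#' fold enrichment on x, p-value, overlap count as bubble size.
#'
#' @param result An `enrichment_result`.
#' @param path Optional output path (tab-separated).
#' @param top Number of top-ranked terms to keep (default all).
#' @return Data frame with columns `term_id`, `description`,
#'   `fold_enrichment`, `p`, `k`.
#' @export
bubble_data <- function(result, path = NULL, top = nrow(result)) {
  df <- as.data.frame(result)[seq_len(min(top, nrow(result))),
                              c("term_id", "description",
                                "fold_enrichment", "p", "k")]
  rownames(df) <- NULL
  if (!is.null(path)) {
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  df
}
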