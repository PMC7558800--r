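#' Assemble per-herb and union target gene sets
#'
#' Collapses a compound-to-target mapping table (compound id, protein id,
#' gene symbol, species) into one gene-symbol set per herb plus their
#' union. Symbols are uppercased and trimmed; rows whose species differs
#' from `species` are dropped; rows whose compound is not in the screened
#' candidate set are dropped with a count reported in the result.
#'
#' @param mappings Data frame with columns `compound_id`, `gene_symbol` and
#'   optionally `protein_id`, `species`.
#' @param screened_compounds Character vector of compound ids retained by
#'   the ADME screen (passed plus whitelisted).
#' @param herb_of Named list mapping compound_id to a character vector of
#'   herb labels (see [herb_map()]).
#' @param species Species tag mappings must carry (default
#'   `"Homo sapiens"`); rows missing a species column are kept.
#' @return List with `per_herb` (named list of symbol vectors), `union`
#'   (character vector) and `dropped` (counts of unscreened-compound and
#'   species-mismatch rows).
#' @export
assemble_target_sets <- function(mappings, screened_compounds, herb_of,
                                 species = "Homo sapiens") {
  if (!is.data.frame(mappings) || nrow(mappings) == 0) {
    stage_stop("target_space", "empty target mapping table")
  }
  need <- c("compound_id", "gene_symbol")
  miss <- setdiff(need, names(mappings))
  if (length(miss)) {
    stage_stop("target_space", "mapping table lacks columns: ",
               paste(miss, collapse = ", "))
  }
  n0 <- nrow(mappings)
  if ("species" %in% names(mappings)) {
    keep <- is.na(mappings$species) | mappings$species == species
    mappings <- mappings[keep, , drop = FALSE]
  }
  n_species_dropped <- n0 - nrow(mappings)

  known <- mappings$compound_id %in% screened_compounds
  n_unscreened <- sum(!known)
  mappings <- mappings[known, , drop = FALSE]

  mappings$gene_symbol <- toupper(trimws(mappings$gene_symbol))
  mappings <- mappings[nzchar(mappings$gene_symbol), , drop = FALSE]

  herbs <- sort(unique(unlist(herb_of, use.names = FALSE)))
  per_herb <- setNames(vector("list", length(herbs)), herbs)
  for (h in herbs) {
    cps <- names(herb_of)[vapply(herb_of, function(x) h %in% x, logical(1))]
    per_herb[[h]] <- sort(unique(
      mappings$gene_symbol[mappings$compound_id %in% cps]
    ))
  }
  list(
    per_herb = per_herb,
    union = sort(unique(mappings$gene_symbol)),
    dropped = c(unscreened = n_unscreened, species = n_species_dropped)
  )
}

#' Filter disease genes by relevance score
#'
#' Keeps gene symbols whose disease-association relevance score is
#' strictly greater than `min_relevance` (default 2.5, the conventional
#' GeneCards cut). Duplicate symbols keep their maximum relevance before
#' filtering, matching how repeated export rows are normally resolved.
#'
#' @param records Data frame with columns `gene_symbol` and `relevance`.
#' @param min_relevance Exclusive threshold; a gene at exactly this score
#'   is excluded.
#' @return Sorted character vector of retained symbols.
#' @export
filter_disease_genes <- function(records, min_relevance = 2.5) {
  if (!is.data.frame(records)) {
    stage_stop("target_space", "disease-gene input must be a data frame")
  }
  if (nrow(records) == 0) return(character(0))
  need <- c("gene_symbol", "relevance")
  miss <- setdiff(need, names(records))
  if (length(miss)) {
    stage_stop("target_space", "disease-gene table lacks columns: ",
               paste(miss, collapse = ", "))
  }
  rel <- as.numeric(records$relevance)
  if (anyNA(rel) || any(rel < 0)) {
    stage_stop("target_space", "relevance scores must be non-negative numbers")
  }
  sym <- toupper(trimws(records$gene_symbol))
  best <- tapply(rel, sym, max)
  sort(names(best)[best > min_relevance])
}

#' Classify genes into shared / drug-only / disease-only categories
#'
#' The three-way partition behind the drug-target vs disease-gene Venn
#' diagram: genes hit by the formula's compounds and associated with the
#' disease (`shared`), formula targets not in the disease list
#' (`drug_only`), and disease genes not targeted (`disease_only`).
#'
#' @param drug_union Character vector of drug-target symbols.
#' @param disease Character vector of disease-gene symbols.
#' @param per_herb Optional named list of per-herb symbol sets, carried
#'   through for provenance.
#' @return An object of class `gene_set_bundle` with elements `per_herb`,
#'   `drug_union`, `disease`, `shared`, `drug_only`, `disease_only` and a
#'   `counts` vector.
#' @examples
#' b <- classify_nodes(c("A", "B", "C"), c("B", "C", "D"))
#' b$counts  # shared 2, drug_only 1, disease_only 1
#' @export
classify_nodes <- function(drug_union, disease, per_herb = list()) {
  drug_union <- sort(unique(norm_symbols(drug_union)))
  disease <- sort(unique(norm_symbols(disease)))
  shared <- intersect(drug_union, disease)
  drug_only <- setdiff(drug_union, disease)
  disease_only <- setdiff(disease, drug_union)
  structure(
    list(
      per_herb = per_herb,
      drug_union = drug_union,
      disease = disease,
      shared = shared,
      drug_only = drug_only,
      disease_only = disease_only,
      counts = c(shared = length(shared),
                 drug_only = length(drug_only),
                 disease_only = length(disease_only))
    ),
    class = "gene_set_bundle"
  )
}

#' @export
print.gene_set_bundle <- function(x, ...) {
  cat("Gene-set bundle\n")
  cat(sprintf("  drug union: %d   disease: %d\n",
              length(x$drug_union), length(x$disease)))
  cat(sprintf("  shared: %d   drug-only: %d   disease-only: %d\n",
              x$counts[["shared"]], x$counts[["drug_only"]],
              x$counts[["disease_only"]]))
  invisible(x)
}

# Category label for a vector of symbols under a bundle; NA if uncategorized.
node_category <- function(bundle, symbols) {
  out <- rep(NA_character_, length(symbols))
  out[symbols %in% bundle$shared] <- "shared"
  out[symbols %in% bundle$drug_only] <- "drug_only"
  out[symbols %in% bundle$disease_only] <- "disease_only"
  out
}

#' Read a two-column disease-gene table
#'
#' @param path File path to a delimited file with a header.
#' @param sep Separator; `NULL` auto-detects tab vs comma.
#' @param columns Named vector mapping `gene_symbol` and `relevance` to the
#'   file's column names.
#' @return Data frame with `gene_symbol` and `relevance` columns.
#' @export
read_disease_table <- function(path, sep = NULL,
                               columns = c(gene_symbol = "gene_symbol",
                                           relevance = "relevance")) {
  if (is.null(sep)) {
    hdr <- readLines(path, n = 1L)
    sep <- if (grepl("\t", hdr)) "\t" else ","
  }
  raw <- read.delim(path, sep = sep, stringsAsFactors = FALSE, check.names = FALSE)
  miss <- setdiff(unname(columns), names(raw))
  if (length(miss)) {
    stage_stop("target_space", "disease table lacks columns: ",
               paste(miss, collapse = ", "))
  }
  data.frame(gene_symbol = as.character(raw[[columns[["gene_symbol"]]]]),
             relevance = as.numeric(raw[[columns[["relevance"]]]]),
             stringsAsFactors = FALSE)
}

#' Read a compound-to-target mapping table
#'
#' @param path File path to a delimited file with a header.
#' @param sep Separator; `NULL` auto-detects tab vs comma.
#' @param columns Named vector mapping `compound_id`, `protein_id`,
#'   `gene_symbol`, `species` to the file's column names; `protein_id` and
#'   `species` are optional in the file.
#' @return Data frame with the canonical columns.
#' @export
read_mapping_table <- function(path, sep = NULL,
                               columns = c(compound_id = "compound_id",
                                           protein_id = "protein_id",
                                           gene_symbol = "gene_symbol",
                                           species = "species")) {
  if (is.null(sep)) {
    hdr <- readLines(path, n = 1L)
    sep <- if (grepl("\t", hdr)) "\t" else ","
  }
  raw <- read.delim(path, sep = sep, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("compound_id", "gene_symbol")
  miss <- setdiff(unname(columns[need]), names(raw))
  if (length(miss)) {
    stage_stop("target_space", "mapping table lacks columns: ",
               paste(miss, collapse = ", "))
  }
  out <- data.frame(compound_id = as.character(raw[[columns[["compound_id"]]]]),
                    gene_symbol = as.character(raw[[columns[["gene_symbol"]]]]),
                    stringsAsFactors = FALSE)
  if (columns[["protein_id"]] %in% names(raw)) {
    out$protein_id <- as.character(raw[[columns[["protein_id"]]]])
  }
  if (columns[["species"]] %in% names(raw)) {
    out$species <- as.character(raw[[columns[["species"]]]])
  }
  out
}

#' Write Venn counts of a gene-set bundle
#'
#' @param bundle A `gene_set_bundle`.
#' @param path Output path (tab-separated: category, count).
#' @return The summary data frame, invisibly.
#' @export
write_venn_counts <- function(bundle, path) {
  stopifnot(inherits(bundle, "gene_set_bundle"))
  df <- data.frame(category = names(bundle$counts),
                   count = as.integer(bundle$counts))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
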