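# Synthetic study-input generator. Every file dialect the pipeline consumes
# (compound table, compound-target mapping, disease-gene table, STRING-style
# TSV, GMT) can be produced here with planted ground truth, so each stage is
# testable at desk scale without any database access. Truth labels ride in
# sidecar tables; no analysis stage ever reads them.

#' Synthetic study specification
#'
#' Shape parameters for the generated inputs: a candidate-compound table
#' whose ADME properties straddle the screening thresholds, a
#' planted-partition interactome (dense blocks on a sparse background — the
#' structure density-based module detection assumes), and annotation
#' collections with one term deliberately over-represented in the first
#' planted block.
#'
#' @param seed Integer RNG seed; all generator randomness flows from it.
#' @param n_compounds Number of candidate compounds.
#' @param frac_pass Probability a compound is drawn to pass all three ADME
#'   criteria.
#' @param n_background Total number of genes (nodes) in the interactome.
#' @param module_sizes Integer vector of planted-block sizes (each >= 3).
#' @param p_in Within-block edge probability.
#' @param p_out Background edge probability (must be < `p_in`).
#' @param n_terms Number of random annotation terms.
#' @param enriched_term_overlap Number of first-block members seeded into
#'   the designated enriched term.
#' @param herb_labels Herb labels compounds are assigned to.
#' @param n_whitelist Number of compounds flagged as literature whitelist
#'   additions (default 0).
#' @return An object of class `synth_spec`.
#' @export
synth_spec <- function(seed = 1L, n_compounds = 100, frac_pass = 0.5,
                       n_background = 200, module_sizes = 20, p_in = 0.6,
                       p_out = 0.02, n_terms = 50,
                       enriched_term_overlap = 12,
                       herb_labels = c("HQ", "CX", "DL", "JC"),
                       n_whitelist = 0) {
  stopifnot(is_count(seed) || is_number(seed),
            is_count(n_compounds), n_compounds >= 1,
            is_number(frac_pass), frac_pass >= 0, frac_pass <= 1,
            is_count(n_background),
            all(module_sizes >= 3), sum(module_sizes) <= n_background,
            is_number(p_in), is_number(p_out),
            p_out >= 0, p_out < p_in, p_in <= 1,
            is_count(n_terms),
            is_count(enriched_term_overlap),
            is_count(n_whitelist), n_whitelist <= n_compounds)
  structure(
    list(seed = as.integer(seed), n_compounds = as.integer(n_compounds),
         frac_pass = frac_pass, n_background = as.integer(n_background),
         module_sizes = as.integer(module_sizes), p_in = p_in, p_out = p_out,
         n_terms = as.integer(n_terms),
         enriched_term_overlap = as.integer(enriched_term_overlap),
         herb_labels = herb_labels, n_whitelist = as.integer(n_whitelist)),
    class = "synth_spec"
  )
}

# Run expr with a deterministic RNG substream, restoring the caller's state.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed %% .Machine$integer.max)
  expr
}

synth_gene_names <- function(n) sprintf("G%04d", seq_len(n))

#' Generate a candidate-compound table with truth labels
#'
#' Each compound is drawn to pass all three ADME criteria with probability
#' `frac_pass`; property values are sampled just inside or just outside the
#' standard bounds (OB >= 30, Caco-2 > -0.4, DL >= 0.18), so the table
#' straddles the thresholds the screen tests. A failing compound violates
#' at least one, possibly several, criteria. The intended status is
#' recorded in the `truth` column; the screen never reads it.
#'
#' @param spec A [synth_spec()].
#' @return Data frame in the [read_compound_table()] layout plus a `truth`
#'   column (`"pass"`, `"fail"` or `"whitelist"`).
#' @export
synth_compound_table <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  with_seed(spec$seed + 101L, {
    n <- spec$n_compounds
    pass <- runif(n) < spec$frac_pass
    ob <- ifelse(pass, runif(n, 30, 100), NA)
    caco2 <- ifelse(pass, runif(n, -0.35, 1.5), NA)
    dl <- ifelse(pass, runif(n, 0.18, 1), NA)
    for (i in which(!pass)) {
      # fail at least one criterion; each independently with prob 1/2
      viol <- runif(3) < 0.5
      if (!any(viol)) viol[sample.int(3, 1)] <- TRUE
      ob[i] <- if (viol[1]) runif(1, 0, 29.9) else runif(1, 30, 100)
      caco2[i] <- if (viol[2]) runif(1, -1.2, -0.41) else runif(1, -0.35, 1.5)
      dl[i] <- if (viol[3]) runif(1, 0, 0.17) else runif(1, 0.18, 1)
    }
    wl <- rep(FALSE, n)
    if (spec$n_whitelist > 0) wl[sample.int(n, spec$n_whitelist)] <- TRUE
    n_herbs <- sample(c(1L, 2L), n, replace = TRUE, prob = c(0.7, 0.3))
    herbs <- vapply(n_herbs, function(k) {
      paste(sample(spec$herb_labels, k), collapse = ";")
    }, character(1))
    data.frame(
      compound_id = sprintf("CMP%04d", seq_len(n)),
      name = sprintf("compound-%04d", seq_len(n)),
      herbs = herbs,
      ob = round(ob, 3), caco2 = round(caco2, 4), dl = round(dl, 4),
      whitelist = wl,
      truth = ifelse(wl, "whitelist", ifelse(pass, "pass", "fail")),
      stringsAsFactors = FALSE
    )
  })
}

#' Generate a planted-partition interactome
#'
#' Planted-partition random graph: node pairs inside a planted block are
#' edged with probability `p_in`, all other pairs with `p_out`. Blocks
#' occupy the first `sum(module_sizes)` genes in order; the rest is sparse
#' background. Edges carry combined scores drawn on \[0.4, 0.99\] so the
#' full STRING-dialect reader path (including score filtering at the
#' default threshold) is exercised end-to-end.
#'
#' @param spec A [synth_spec()].
#' @return List with `edges` (data frame `node1`, `node2`, `score`;
#'   [write_string_tsv()] emits it with STRING-dialect headers),
#'   `membership` (data frame `symbol`, `planted_module`;
#'   0 = background) and `graph` (the igraph built from the edge list, with
#'   all `n_background` nodes).
#' @export
synth_ppi <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  with_seed(spec$seed + 202L, {
    n <- spec$n_background
    nms <- synth_gene_names(n)
    block <- integer(n)
    at <- 1L
    for (m in seq_along(spec$module_sizes)) {
      block[at:(at + spec$module_sizes[m] - 1L)] <- m
      at <- at + spec$module_sizes[m]
    }
    pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    same <- block[pairs[, 1]] == block[pairs[, 2]] & block[pairs[, 1]] > 0L
    prob <- ifelse(same, spec$p_in, spec$p_out)
    keep <- runif(nrow(pairs)) < prob
    i <- pairs[keep, 1]; j <- pairs[keep, 2]
    edges <- data.frame(
      node1 = nms[i], node2 = nms[j],
      score = round(runif(sum(keep), 0.4, 0.99), 3),
      stringsAsFactors = FALSE
    )
    edges <- edges[order(edges$node1, edges$node2), , drop = FALSE]
    rownames(edges) <- NULL
    g <- igraph::graph_from_data_frame(
      edges,
      directed = FALSE,
      vertices = data.frame(name = nms, stringsAsFactors = FALSE)
    )
    list(
      edges = edges,
      membership = data.frame(symbol = nms, planted_module = block,
                              stringsAsFactors = FALSE),
      graph = g
    )
  })
}

#' Generate an annotation collection with one planted enriched term
#'
#' Draws `n_terms` random term sets over the interactome's gene universe,
#' plus one designated term (`TERM_ENRICHED`) seeded with
#' `enriched_term_overlap` members of the planted module and padded with
#' random outside genes. With a large overlap the designated term is
#' genuinely over-represented in the planted module; with a
#' chance-level overlap it is not.
#'
#' @param spec A [synth_spec()].
#' @param planted_module_members Character vector of planted-module gene
#'   symbols (non-empty; overlap may not exceed its size).
#' @return List with `collection` (an [annotation_collection()]) and
#'   `truth` (data frame naming the designated term and its seeded
#'   overlap).
#' @export
synth_annotations <- function(spec, planted_module_members) {
  stopifnot(inherits(spec, "synth_spec"))
  planted_module_members <- norm_symbols(planted_module_members)
  if (!length(planted_module_members)) {
    stop("planted module members must be non-empty")
  }
  if (spec$enriched_term_overlap > length(planted_module_members)) {
    stop("enriched_term_overlap exceeds the planted module size")
  }
  with_seed(spec$seed + 303L, {
    universe <- synth_gene_names(spec$n_background)
    terms <- lapply(seq_len(spec$n_terms), function(i) {
      sample(universe, sample(10:30, 1))
    })
    names(terms) <- sprintf("TERM%03d", seq_len(spec$n_terms))
    outside <- setdiff(universe, planted_module_members)
    seeded <- if (spec$enriched_term_overlap > 0) {
      sample(planted_module_members, spec$enriched_term_overlap)
    } else character(0)
    pad <- sample(outside, min(15, length(outside)))
    terms[["TERM_ENRICHED"]] <- unique(c(seeded, pad))
    desc <- setNames(
      c(sprintf("random annotation %03d", seq_len(spec$n_terms)),
        "planted over-represented annotation"),
      names(terms)
    )
    list(
      collection = annotation_collection(terms, desc, universe = universe,
                                         name = "synthetic"),
      truth = data.frame(term_id = "TERM_ENRICHED",
                         seeded_overlap = length(seeded),
                         stringsAsFactors = FALSE)
    )
  })
}

#' Generate compound-target mappings and a disease-gene table
#'
#' Completes the pipeline's input set: every interactome gene is assigned
#' to the drug-target side, the disease side, or both, so the categorized
#' network covers the whole synthetic interactome. Drug-side genes are
#' mapped from randomly chosen screen-passing compounds; disease-side
#' genes get relevance scores above the conventional 2.5 cut, and decoy
#' rows (sub-threshold relevance, plus a few non-network symbols) exercise
#' the relevance filter. A handful of mapping rows reference unscreened
#' compounds and a non-target species to exercise the drop paths.
#'
#' @param spec A [synth_spec()].
#' @param compounds Compound table from [synth_compound_table()].
#' @param species Species tag written on mapping rows.
#' @return List with `mappings`, `disease` (data frames in the reader
#'   layouts) and `assignment` (truth: symbol, side).
#' @export
synth_target_space <- function(spec, compounds, species = "Homo sapiens") {
  stopifnot(inherits(spec, "synth_spec"), is.data.frame(compounds))
  with_seed(spec$seed + 404L, {
    nms <- synth_gene_names(spec$n_background)
    side <- sample(c("drug", "disease", "both"), spec$n_background,
                   replace = TRUE, prob = c(0.35, 0.35, 0.3))
    pass_ids <- compounds$compound_id[compounds$truth %in% c("pass", "whitelist")]
    if (!length(pass_ids)) stop("no screen-passing compounds to map from")

    drug_genes <- nms[side %in% c("drug", "both")]
    map_rows <- lapply(drug_genes, function(g) {
      cps <- sample(pass_ids, min(length(pass_ids), sample(1:3, 1)))
      data.frame(compound_id = cps,
                 protein_id = sprintf("P%s", substr(g, 2, 5)),
                 gene_symbol = g, species = species,
                 stringsAsFactors = FALSE)
    })
    mappings <- do.call(rbind, map_rows)
    # drop-path rows: unscreened compound + wrong species
    fail_ids <- setdiff(compounds$compound_id, pass_ids)
    if (length(fail_ids)) {
      mappings <- rbind(mappings, data.frame(
        compound_id = fail_ids[1], protein_id = "P0000",
        gene_symbol = drug_genes[1], species = species,
        stringsAsFactors = FALSE))
    }
    mappings <- rbind(mappings, data.frame(
      compound_id = pass_ids[1], protein_id = "P9999",
      gene_symbol = "MOUSEGENE", species = "Mus musculus",
      stringsAsFactors = FALSE))
    rownames(mappings) <- NULL

    disease_genes <- nms[side %in% c("disease", "both")]
    disease <- data.frame(
      gene_symbol = c(disease_genes,
                      sprintf("DECOY%02d", 1:5)),
      relevance = round(c(runif(length(disease_genes), 2.6, 30),
                          runif(5, 0, 2.4)), 3),
      stringsAsFactors = FALSE
    )
    list(
      mappings = mappings,
      disease = disease,
      assignment = data.frame(symbol = nms, side = side,
                              stringsAsFactors = FALSE)
    )
  })
}

#' Write a complete synthetic input set
#'
#' Emits every file the pipeline consumes, in the exact dialects its
#' readers parse, plus truth sidecars: `candidate_compounds.tsv`,
#' `target_mappings.tsv`, `disease_genes.tsv`, `ppi_edges.tsv` (STRING
#' dialect), `annotations.gmt`, `truth_modules.tsv`, `truth_terms.tsv`.
#'
#' @param spec A [synth_spec()].
#' @param dir Output directory (created if needed).
#' @return Named list of the written file paths, invisibly; the generated
#'   objects are attached as attribute `objects`.
#' @export
synth_pipeline_inputs <- function(spec, dir) {
  stopifnot(inherits(spec, "synth_spec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  compounds <- synth_compound_table(spec)
  ppi <- synth_ppi(spec)
  planted <- ppi$membership$symbol[ppi$membership$planted_module == 1L]
  ann <- synth_annotations(spec, planted)
  ts <- synth_target_space(spec, compounds)

  paths <- list(
    compounds = file.path(dir, "candidate_compounds.tsv"),
    mappings = file.path(dir, "target_mappings.tsv"),
    disease = file.path(dir, "disease_genes.tsv"),
    edges = file.path(dir, "ppi_edges.tsv"),
    gmt = file.path(dir, "annotations.gmt"),
    truth_modules = file.path(dir, "truth_modules.tsv"),
    truth_terms = file.path(dir, "truth_terms.tsv")
  )
  wt <- function(df, path) {
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  wt(compounds[, setdiff(names(compounds), "truth")], paths$compounds)
  wt(ts$mappings, paths$mappings)
  wt(ts$disease, paths$disease)
  write_string_tsv(ppi$edges, paths$edges)
  write_gmt(ann$collection, paths$gmt)
  wt(ppi$membership, paths$truth_modules)
  wt(ann$truth, paths$truth_terms)

  out <- paths
  attr(out, "objects") <- list(compounds = compounds, ppi = ppi,
                               annotations = ann, target_space = ts)
  invisible(out)
}
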