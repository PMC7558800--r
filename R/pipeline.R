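#' Pipeline configuration
#'
#' Collects every tunable of the five-stage analysis — input paths and
#' column names, the ADME screen criteria, the disease-gene relevance cut,
#' the interaction-score threshold and scale, the MCODE parameters, and
#' the enrichment settings. Defaults reproduce the conventional
#' thresholds: OB >= 30, Caco-2 > -0.4, DL >= 0.18, relevance > 2.5.
#'
#' @param compounds,mappings,disease,edges,gmt Input file paths (the
#'   compound table, compound-target mapping, disease-gene table,
#'   STRING-dialect edge list, GMT annotation collection).
#' @param out_dir Output directory for report tables and the manifest.
#' @param criteria A [screen_criteria()] object.
#' @param min_relevance Exclusive disease-gene relevance threshold
#'   (default 2.5).
#' @param score_min Minimum interaction combined score on the 0-1 scale
#'   (default 0.4).
#' @param score_scale `"auto"`, `"unit"` or `"string999"`.
#' @param restrict Keep only edges between categorized genes
#'   (default TRUE).
#' @param mcode An [mcode_params()] object.
#' @param enrich_method `"hypergeometric"` or `"ease"`.
#' @param fdr_alpha Enrichment significance level (default 0.05).
#' @param universe `"collection"` (union of term members, default) or
#'   `"network"` (all categorized network genes).
#' @param species Species tag required on mapping rows.
#' @param seed Integer seed recorded in the manifest (the analysis stages
#'   are deterministic; the seed pins any future stochastic extension).
#' @param compound_columns,mapping_columns,disease_columns,edge_columns
#'   Column-name maps passed to the respective readers.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(compounds, mappings, disease, edges, gmt,
                            out_dir,
                            criteria = screen_criteria(),
                            min_relevance = 2.5,
                            score_min = 0.4,
                            score_scale = c("auto", "unit", "string999"),
                            restrict = TRUE,
                            mcode = mcode_params(),
                            enrich_method = c("hypergeometric", "ease"),
                            fdr_alpha = 0.05,
                            universe = c("collection", "network"),
                            species = "Homo sapiens",
                            seed = 1L,
                            compound_columns = NULL,
                            mapping_columns = NULL,
                            disease_columns = NULL,
                            edge_columns = NULL) {
  stopifnot(inherits(criteria, "screen_criteria"),
            inherits(mcode, "mcode_params"),
            is_number(min_relevance), is_number(score_min),
            is_flag(restrict), is_number(fdr_alpha))
  structure(
    list(paths = list(compounds = compounds, mappings = mappings,
                      disease = disease, edges = edges, gmt = gmt),
         out_dir = out_dir,
         criteria = criteria,
         min_relevance = min_relevance,
         score_min = score_min,
         score_scale = match.arg(score_scale),
         restrict = restrict,
         mcode = mcode,
         enrich_method = match.arg(enrich_method),
         fdr_alpha = fdr_alpha,
         universe = match.arg(universe),
         species = species,
         seed = as.integer(seed),
         columns = list(compounds = compound_columns,
                        mappings = mapping_columns,
                        disease = disease_columns,
                        edges = edge_columns)),
    class = "pipeline_config"
  )
}

# Run a stage, guaranteeing the error message names the stage.
run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    msg <- conditionMessage(e)
    if (!startsWith(msg, paste0(name, ":"))) {
      msg <- sprintf("%s: %s", name, msg)
    }
    stop(msg, call. = FALSE)
  })
}

stage_log <- function(stage, ...) {
  kv <- c(...)
  message(sprintf("[netpharm] stage=%s %s", stage,
                  paste(names(kv), kv, sep = "=", collapse = " ")))
}

#' Run the full network-pharmacology pipeline
#'
#' Executes the five analysis stages in order — ADME screen, target-space
#' assembly, network construction, MCODE module detection, enrichment —
#' and writes the report bundle to `config$out_dir`: the screened-compound
#' table, Venn counts, degree table, module table, enrichment tables with
#' fold enrichment (for the categorized network gene set and for the
#' top-scoring module), bubble-chart data, SIF/GraphML exports, and a
#' machine-readable JSON manifest capturing the configuration, input
#' digests, row drops and package version. Any stage failure aborts with
#' an error message naming the stage.
#'
#' @param config A [pipeline_config()].
#' @return An object of class `netpharm_run`: list with the per-stage
#'   results (`screen`, `bundle`, `network`, `degree`, `modules`,
#'   `enrichment`) and `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  cols <- config$columns
  args_or <- function(x, default) if (is.null(x)) default else x

  ## stage 1: compound screen
  screen <- run_stage("compound_screen", {
    tbl <- if (is.null(cols$compounds)) {
      read_compound_table(config$paths$compounds)
    } else {
      read_compound_table(config$paths$compounds, columns = cols$compounds)
    }
    screen_compounds(tbl, config$criteria)
  })
  cand <- candidates(screen)
  stage_log("compound_screen",
            c(`in` = nrow(screen$passed) + nrow(screen$whitelisted) +
                nrow(screen$rejected),
              passed = nrow(screen$passed),
              whitelisted = nrow(screen$whitelisted),
              rejected = nrow(screen$rejected)))
  write_screen_table(screen, file.path(config$out_dir, "screened_compounds.tsv"))

  ## stage 2: target space
  bundle <- run_stage("target_space", {
    maps <- if (is.null(cols$mappings)) {
      read_mapping_table(config$paths$mappings)
    } else {
      read_mapping_table(config$paths$mappings, columns = cols$mappings)
    }
    dis_tbl <- if (is.null(cols$disease)) {
      read_disease_table(config$paths$disease)
    } else {
      read_disease_table(config$paths$disease, columns = cols$disease)
    }
    if (nrow(dis_tbl) == 0) {
      stage_stop("target_space", "disease-gene table is empty")
    }
    sets <- assemble_target_sets(maps, cand$compound_id, herb_map(cand),
                                 species = config$species)
    disease <- filter_disease_genes(dis_tbl, config$min_relevance)
    if (!length(disease)) {
      stage_stop("target_space",
                 "no disease gene passes the relevance filter")
    }
    b <- classify_nodes(sets$union, disease, per_herb = sets$per_herb)
    attr(b, "dropped") <- sets$dropped
    b
  })
  stage_log("target_space",
            c(drug_union = length(bundle$drug_union),
              disease = length(bundle$disease),
              shared = bundle$counts[["shared"]],
              drug_only = bundle$counts[["drug_only"]],
              disease_only = bundle$counts[["disease_only"]]))
  write_venn_counts(bundle, file.path(config$out_dir, "venn_counts.tsv"))

  ## stage 3: network
  network <- run_stage("network", {
    edges <- read_string_tsv(config$paths$edges,
                             score_min = config$score_min,
                             scale = config$score_scale,
                             columns = args_or(cols$edges,
                                               c(node1 = "node1",
                                                 node2 = "node2",
                                                 score = "combined_score")))
    build_network(edges, bundle, restrict = config$restrict)
  })
  deg <- degree_table(network)
  stage_log("network", c(nodes = igraph::vcount(network),
                         edges = igraph::ecount(network)))
  write.table(deg, file.path(config$out_dir, "degree_table.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write_sif(network, file.path(config$out_dir, "network.sif"))
  write_graphml(network, file.path(config$out_dir, "network.graphml"))

  ## stage 4: module detection
  modules <- run_stage("mcode", find_modules(network, config$mcode))
  stage_log("mcode", c(modules = length(modules)))
  write_module_table(modules, file.path(config$out_dir, "modules.tsv"))

  ## stage 5: enrichment
  enrichment <- run_stage("enrichment", {
    coll <- read_gmt(config$paths$gmt,
                     universe = if (config$universe == "network") {
                       igraph::V(network)$name
                     } else NULL)
    res <- list(
      network = enrich(igraph::V(network)$name, coll,
                       method = config$enrich_method,
                       fdr_alpha = config$fdr_alpha)
    )
    if (length(modules)) {
      res$top_module <- enrich(modules[[1]]$members, coll,
                               method = config$enrich_method,
                               fdr_alpha = config$fdr_alpha)
    }
    res
  })
  stage_log("enrichment",
            c(terms_network = nrow(enrichment$network),
              terms_top_module = if (is.null(enrichment$top_module)) 0
                                 else nrow(enrichment$top_module)))
  write_enrichment_table(enrichment$network,
                         file.path(config$out_dir, "enrichment_network.tsv"))
  if (!is.null(enrichment$top_module)) {
    write_enrichment_table(
      enrichment$top_module,
      file.path(config$out_dir, "enrichment_top_module.tsv"))
    bubble_data(enrichment$top_module,
                file.path(config$out_dir, "bubble_top_module.tsv"))
  }

  ## manifest
  manifest <- list(
    package = "netpharm",
    version = as.character(packageVersion("netpharm")),
    seed = config$seed,
    config = list(
      criteria = unclass(config$criteria),
      min_relevance = config$min_relevance,
      score_min = config$score_min,
      score_scale = config$score_scale,
      restrict = config$restrict,
      mcode = unclass(config$mcode),
      enrich_method = config$enrich_method,
      fdr_alpha = config$fdr_alpha,
      universe = config$universe,
      species = config$species
    ),
    inputs = lapply(config$paths, function(p) {
      list(path = p, md5 = unname(tools::md5sum(p)))
    }),
    counts = list(
      compounds_in = nrow(screen$passed) + nrow(screen$whitelisted) +
        nrow(screen$rejected),
      compounds_passed = nrow(screen$passed),
      compounds_whitelisted = nrow(screen$whitelisted),
      compounds_rejected = nrow(screen$rejected),
      mapping_rows_dropped = as.list(attr(bundle, "dropped")),
      drug_union = length(bundle$drug_union),
      disease = length(bundle$disease),
      venn = as.list(bundle$counts),
      network_nodes = igraph::vcount(network),
      network_edges = igraph::ecount(network),
      modules = length(modules)
    )
  )
  jsonlite::write_json(manifest,
                       file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  structure(
    list(screen = screen, bundle = bundle, network = network, degree = deg,
         modules = modules, enrichment = enrichment, manifest = manifest),
    class = "netpharm_run"
  )
}

#' @export
print.netpharm_run <- function(x, ...) {
  cat("netpharm pipeline run\n")
  cat(sprintf("  compounds: %d passed + %d whitelisted of %d\n",
              x$manifest$counts$compounds_passed,
              x$manifest$counts$compounds_whitelisted,
              x$manifest$counts$compounds_in))
  cat(sprintf("  gene space: %d drug-union, %d disease (%d shared)\n",
              x$manifest$counts$drug_union, x$manifest$counts$disease,
              x$manifest$counts$venn$shared))
  cat(sprintf("  network: %d nodes, %d edges; %d modules\n",
              x$manifest$counts$network_nodes,
              x$manifest$counts$network_edges,
              x$manifest$counts$modules))
  invisible(x)
}
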