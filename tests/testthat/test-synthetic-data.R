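test_that("degenerate pass fractions produce all-pass and all-fail tables", {
  all_pass <- synth_compound_table(synth_spec(seed = 1, n_compounds = 100,
                                              frac_pass = 1.0))
  scr <- screen_compounds(all_pass[, names(all_pass) != "truth"])
  expect_equal(nrow(scr$passed), 100)

  none <- synth_compound_table(synth_spec(seed = 1, n_compounds = 100,
                                          frac_pass = 0.0))
  scr0 <- screen_compounds(none[, names(none) != "truth"])
  expect_equal(nrow(scr0$passed), 0)
})

test_that("screen outcome agrees with truth labels and binomial bounds", {
  spec <- synth_spec(seed = 5, n_compounds = 1000, frac_pass = 0.3)
  tbl <- synth_compound_table(spec)
  scr <- screen_compounds(tbl[, names(tbl) != "truth"])
  # the screen recovers exactly the intended status
  expect_setequal(scr$passed$compound_id,
                  tbl$compound_id[tbl$truth == "pass"])
  # observed pass count within exact binomial 99% bounds of frac_pass
  bounds <- qbinom(c(0.005, 0.995), 1000, 0.3)
  expect_gte(nrow(scr$passed), bounds[1])
  expect_lte(nrow(scr$passed), bounds[2])
})

test_that("planted-partition extremes are deterministic", {
  ppi <- synth_ppi(synth_spec(seed = 2, n_background = 12, module_sizes = 5,
                              p_in = 1, p_out = 0))
  g <- ppi$graph
  expect_equal(igraph::vcount(g), 12)
  expect_equal(igraph::ecount(g), choose(5, 2))
  module <- ppi$membership$symbol[ppi$membership$planted_module == 1]
  sub <- igraph::induced_subgraph(g, module)
  expect_equal(igraph::ecount(sub), choose(5, 2))  # K5 plus isolates
})

test_that("edge counts sit inside 99% normal bounds of the model moments", {
  spec <- synth_spec(seed = 9, n_background = 150, module_sizes = c(15, 10),
                     p_in = 0.5, p_out = 0.03)
  ppi <- synth_ppi(spec)
  n_in <- sum(choose(spec$module_sizes, 2))
  n_out <- choose(150, 2) - n_in
  mu <- n_in * 0.5 + n_out * 0.03
  sd <- sqrt(n_in * 0.5 * 0.5 + n_out * 0.03 * 0.97)
  e <- igraph::ecount(ppi$graph)
  expect_gte(e, mu - 2.576 * sd)
  expect_lte(e, mu + 2.576 * sd)
})

test_that("generated TSV round-trips through the reader into the same graph", {
  ppi <- synth_ppi(synth_spec(seed = 3, n_background = 60, module_sizes = 8))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_string_tsv(ppi$edges, path)
  back <- read_string_tsv(path, score_min = 0.4)
  expect_equal(data.frame(back), ppi$edges, ignore_attr = TRUE)
})

test_that("same seed gives byte-identical generator output", {
  spec <- synth_spec(seed = 77)
  t1 <- synth_compound_table(spec)
  t2 <- synth_compound_table(spec)
  expect_identical(t1, t2)
  p1 <- synth_ppi(spec)
  p2 <- synth_ppi(spec)
  expect_identical(p1$edges, p2$edges)
  a1 <- synth_annotations(spec, p1$membership$symbol[1:20])
  a2 <- synth_annotations(spec, p2$membership$symbol[1:20])
  expect_identical(a1$collection$terms, a2$collection$terms)
})

test_that("a term equal to the planted module attains the minimum p", {
  spec <- synth_spec(seed = 6, n_background = 100, module_sizes = 15,
                     n_terms = 30, enriched_term_overlap = 15)
  ppi <- synth_ppi(spec)
  planted <- ppi$membership$symbol[ppi$membership$planted_module == 1]
  ann <- synth_annotations(spec, planted)
  res <- enrich(planted, ann$collection)
  expect_equal(res$term_id[1], "TERM_ENRICHED")
  expect_equal(min(res$p), res$p[res$term_id == "TERM_ENRICHED"])
})

test_that("chance-level overlap is non-significant in most replicates", {
  # designated term shares only an expected-by-chance slice of the module
  flags <- vapply(1:100, function(s) {
    spec <- synth_spec(seed = s, n_background = 100, module_sizes = 15,
                       n_terms = 30, enriched_term_overlap = 3)
    ppi <- synth_ppi(spec)
    planted <- ppi$membership$symbol[ppi$membership$planted_module == 1]
    ann <- synth_annotations(spec, planted)
    res <- enrich(planted, ann$collection, fdr_alpha = 0.05)
    row <- res[res$term_id == "TERM_ENRICHED", ]
    nrow(row) == 0 || !row$significant
  }, logical(1))
  expect_gte(mean(flags), 0.9)
})

test_that("overlap larger than the module is an input error", {
  spec <- synth_spec(seed = 1, n_background = 50, module_sizes = 5,
                     enriched_term_overlap = 10)
  ppi <- synth_ppi(spec)
  planted <- ppi$membership$symbol[ppi$membership$planted_module == 1]
  expect_error(synth_annotations(spec, planted), "overlap")
})

test_that("the full synthetic input set is written in consumable dialects", {
  dir <- withr::local_tempdir()
  spec <- synth_spec(seed = 10, n_compounds = 50, frac_pass = 0.6,
                     n_background = 80, module_sizes = 10,
                     enriched_term_overlap = 8)
  paths <- synth_pipeline_inputs(spec, dir)
  expect_true(all(file.exists(unlist(paths))))
  # every reader parses its file
  expect_equal(nrow(read_compound_table(paths$compounds)), 50)
  expect_gt(nrow(read_mapping_table(paths$mappings)), 0)
  expect_gt(nrow(read_disease_table(paths$disease)), 0)
  expect_gt(nrow(read_string_tsv(paths$edges)), 0)
  expect_gt(length(read_gmt(paths$gmt)$terms), 0)
  truth <- utils::read.delim(paths$truth_modules)
  expect_equal(nrow(truth), 80)
})
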