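# A hand-built nearest-gene map and pool for combinatorial tests:
# 10 genes in the target set, each with 3 mapped pool variants, plus 40
# off-set variants mapped to other genes.
toy_selection_inputs <- function(n_set_genes = 10, per_gene = 3,
                                 n_off = 40) {
  set_genes <- sprintf("SG%02d", seq_len(n_set_genes))
  off_genes <- sprintf("OG%02d", seq_len(8))
  on_ids <- sprintf("on_%02d_%d", rep(seq_len(n_set_genes), each = per_gene),
                    rep(seq_len(per_gene), n_set_genes))
  off_ids <- sprintf("off_%02d", seq_len(n_off))
  map <- data.frame(
    id = c(on_ids, off_ids),
    gene_id = c(rep(set_genes, each = per_gene),
                rep(off_genes, length.out = n_off)),
    distance = 0, stringsAsFactors = FALSE)
  list(map = map, pool = map$id,
       sets = list(TARGET = set_genes, OTHER = off_genes))
}

test_that("pathway selection yields exactly k in-set and K-k off-set variants", {
  inp <- toy_selection_inputs()
  spec <- select_from_pathway(inp$map, inp$pool, inp$sets, "TARGET",
                              K = 30, k = 15, seed = 1)
  e <- spec$entries
  expect_equal(nrow(e), 30)
  expect_equal(sum(e$origin == "pathway"), 15)
  expect_equal(sum(e$origin == "random"), 15)
  expect_false(anyDuplicated(e$id) > 0)
  # pathway picks map to distinct set genes when n' >= k
  expect_equal(length(unique(e$gene_id[e$origin == "pathway"])), 15 - 5)
})

test_that("pathway picks map to distinct genes when enough genes exist", {
  inp <- toy_selection_inputs(n_set_genes = 20)
  spec <- select_from_pathway(inp$map, inp$pool, inp$sets, "TARGET",
                              K = 20, k = 15, seed = 2)
  path <- spec$entries[spec$entries$origin == "pathway", ]
  expect_equal(length(unique(path$gene_id)), 15)
  expect_true(all(path$gene_id %in% inp$sets$TARGET))
  rand <- spec$entries[spec$entries$origin == "random", ]
  expect_false(any(rand$gene_id %in% inp$sets$TARGET))
})

test_that("k = 0 gives all-random selections off the target set", {
  inp <- toy_selection_inputs()
  spec <- select_from_pathway(inp$map, inp$pool, inp$sets, "TARGET",
                              K = 12, k = 0, seed = 3)
  expect_true(all(spec$entries$origin == "random"))
  expect_false(any(spec$entries$gene_id %in% inp$sets$TARGET))
})

test_that("round-robin keeps per-gene counts within one of each other", {
  inp <- toy_selection_inputs(n_set_genes = 5, per_gene = 4)
  spec <- select_from_pathway(inp$map, inp$pool, inp$sets, "TARGET",
                              K = 8, k = 8, seed = 4)
  counts <- table(spec$entries$gene_id[spec$entries$origin == "pathway"])
  expect_equal(sort(as.integer(counts)), c(1, 1, 2, 2, 2))  # pigeonhole
  expect_lte(max(counts) - min(counts), 1)
})

test_that("selection is deterministic in the seed and errors are informative", {
  inp <- toy_selection_inputs()
  a <- select_from_pathway(inp$map, inp$pool, inp$sets, "TARGET", 10, 5, seed = 9)
  b <- select_from_pathway(inp$map, inp$pool, inp$sets, "TARGET", 10, 5, seed = 9)
  expect_identical(a$entries, b$entries)
  c_ <- select_from_pathway(inp$map, inp$pool, inp$sets, "TARGET", 10, 5, seed = 10)
  expect_false(identical(a$entries$id, c_$entries$id))

  expect_error(select_from_pathway(inp$map, inp$pool, inp$sets, "MISSING", 5, 2),
               "not found")
  # k larger than all mapped pool variants of the set
  expect_error(select_from_pathway(inp$map, inp$pool, inp$sets, "TARGET",
                                   K = 40, k = 35, seed = 1),
               "map to genes")
  # K - k larger than the off-set pool
  expect_error(select_from_pathway(inp$map, inp$pool, inp$sets, "TARGET",
                                   K = 60, k = 10, seed = 1),
               "off-set")
})

test_that("explicit causal lists intersect with the genotype variants", {
  g <- geno_from_matrix(matrix(rbinom(30 * 4, 2, 0.4), 30),
                        ids = c("rs1", "rs2", "rs3", "rs4"))
  expect_warning(spec <- select_explicit(c("rs1", "rs2", "rsX"), g), "rsX")
  expect_identical(spec$entries$id, c("rs1", "rs2"))
  expect_true(all(spec$entries$origin == "explicit"))

  all_there <- select_explicit(c("rs4", "rs2"), g)
  expect_identical(all_there$entries$id, c("rs4", "rs2"))  # input order kept
  expect_error(suppressWarnings(select_explicit(c("nope", "nada"), g)),
               "none of the provided")
})

test_that("extract_causal_genotypes projects columns in spec order", {
  dos <- matrix(rbinom(25 * 6, 2, 0.4), 25)
  g <- geno_from_matrix(dos, ids = sprintf("rs%d", 1:6))
  spec <- select_explicit(c("rs5", "rs2", "rs6"), g)
  sub <- extract_causal_genotypes(g, spec)
  expect_equal(unname(sub$dosages), unname(dos[, c(5, 2, 6)]))
  rev_spec <- select_explicit(c("rs6", "rs2", "rs5"), g)
  sub_rev <- extract_causal_genotypes(g, rev_spec)
  expect_equal(unname(sub_rev$dosages), unname(sub$dosages[, 3:1]))
})

test_that("pathway-anchored causal variants stay inside the candidate window", {
  fix <- small_fixture(seed = 17)
  g <- simulate_genotypes(fix$panel, 400, seed = 18)
  map <- nearest_gene(g$variants, fix$ann$genes)
  pool <- candidate_pool(g)
  spec <- select_from_pathway(map, pool, fix$ann$sets, "SET_MEDIUM",
                              K = 12, k = 6, seed = 19)
  cg <- extract_causal_genotypes(g, spec)
  mafs <- gwasforge:::fold_maf(colMeans(cg$dosages) / 2)
  expect_true(all(mafs > 0.05 & mafs < 0.5))
  # spec serialization
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_causal_spec(spec, tsv, g)
  back <- read.table(tsv, header = TRUE, sep = "\t")
  expect_equal(as.character(back$ID), spec$entries$id)
  expect_equal(back$MAF, unname(mafs), tolerance = 1e-12)
})
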