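test_that("scores count matching abstracts as a percentage", {
  abs10 <- c(rep("This study concerns angiogenesis in tumors.", 3),
             rep("Unrelated membrane trafficking result.", 7))
  s <- score_gene(abs10, c("angiogenesis"))
  expect_equal(s$angioscore, 30)
  expect_equal(s$n_matching, 3L)
  expect_equal(score_gene(abs10[1:3], "angiogenesis")$angioscore, 100)
})

test_that("matching is whole-word, case-insensitive, phrase-aware", {
  expect_equal(score_gene("hemangiogenesisx was measured",
                          "angiogenesis")$n_matching, 0L)
  expect_equal(score_gene("ANGIOGENESIS drives growth",
                          "angiogenesis")$n_matching, 1L)
  expect_equal(score_gene("the tumor vasculature was dense",
                          c("tumor vasculature"))$n_matching, 1L)
  expect_equal(score_gene("tumor. vasculature next sentence",
                          c("tumor vasculature"))$n_matching, 0L)
})

test_that("score is invariant to abstract order and lexicon duplication", {
  abstracts <- c("angiogenic sprouting", "nothing here", "neovascularization")
  lex <- c("angiogenic", "neovascularization")
  s1 <- score_gene(abstracts, lex)
  s2 <- score_gene(rev(abstracts), c(lex, lex, lex[1]))
  expect_equal(s1$angioscore, s2$angioscore)
})

test_that("adding a non-matching abstract strictly lowers a positive score", {
  abstracts <- c("angiogenesis result", "plain result")
  s1 <- score_gene(abstracts, "angiogenesis")
  s2 <- score_gene(c(abstracts, "another plain result"), "angiogenesis")
  expect_lt(s2$angioscore, s1$angioscore)
})

test_that("genes without publications are flagged and excluded from groups", {
  corp <- publication_corpus(list(A = c("angiogenesis", "x"),
                                  B = character(),
                                  C = c("no match", "none")),
                             lexicon = "angiogenesis")
  sc <- angioscore(corp)
  expect_true(is.na(sc$angioscore[sc$gene == "B"]))
  expect_equal(sc$angioscore[sc$gene == "A"], 50)
})

test_that("corpus directory round trip preserves abstracts and lexicon", {
  genes <- sprintf("G%d", 1:5)
  corp <- simulate_corpus(genes, core_genes = genes[1:2],
                          pubs_per_gene = 6, seed = 3)
  dir <- withr::local_tempdir()
  write_corpus(corp, dir)
  back <- read_corpus(dir)
  expect_setequal(names(back$abstracts), genes)
  expect_equal(back$abstracts[["G1"]], corp$abstracts[["G1"]])
  expect_equal(back$lexicon, corp$lexicon)
})

test_that("group comparison recovers planted rates and is symmetric", {
  genes <- sprintf("G%02d", 1:60)
  corp <- simulate_corpus(genes, core_genes = genes[1:30],
                          invasive_genes = genes[31:60],
                          rate_core = 0.3, rate_other = 0.2,
                          pubs_per_gene = 200, seed = 5)
  sc <- angioscore(corp)
  cmp <- compare_groups(sc, genes[1:30], genes[31:60], top_n = 30)
  expect_equal(cmp$ratio, 1.5, tolerance = 0.1)
  expect_lt(cmp$p, 0.05)
  swapped <- compare_groups(sc, genes[31:60], genes[1:30], top_n = 30)
  expect_equal(swapped$ratio, 1 / cmp$ratio, tolerance = 1e-12)
  expect_equal(swapped$t, -cmp$t, tolerance = 1e-12)
})

test_that("identical corpora give ratio near 1; tiny groups error", {
  genes <- sprintf("G%02d", 1:40)
  corp <- simulate_corpus(genes, rate_other = 0.25, pubs_per_gene = 150,
                          seed = 6)
  sc <- angioscore(corp)
  cmp <- compare_groups(sc, genes[1:20], genes[21:40], top_n = 20)
  expect_equal(cmp$ratio, 1, tolerance = 0.1)
  expect_gt(cmp$p, 0.05)
  expect_error(compare_groups(sc, genes[1], genes[2], top_n = 1),
               "at least 2")
})

test_that("top hits are ranked by |log2FC| among significant proteins", {
  de <- data.frame(protein_id = sprintf("P%d", 1:5),
                   gene_symbol = sprintf("G%d", 1:5),
                   species = "human",
                   log2fc = c(3, -4, 1, 6, -2),
                   padj = c(0.001, 0.001, 0.001, 0.5, 0.001))
  de <- flag_hits(de, pipeline_config())
  expect_equal(top_hits(de, "invasive-up", 5), c("G1", "G3"))
  expect_equal(top_hits(de, "core-up", 1), "G2")
})
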