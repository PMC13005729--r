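test_that("regulation split honors the threshold band, with ties at zero going up", {
  cgl <- condition_genes("X", c("A", "B"), c(A = 1, B = -1))
  sp <- split_by_regulation(cgl, 0.5)
  expect_equal(sp$up$genes, "A")
  expect_equal(sp$down$genes, "B")

  cgl2 <- condition_genes("X", "A", c(A = 0.2))
  expect_message(sp2 <- split_by_regulation(cgl2, 0.5), "dropped")
  expect_length(sp2$up$genes, 0L)
  expect_length(sp2$down$genes, 0L)
  expect_equal(sp2$n_dropped, 1L)

  cgl3 <- condition_genes("X", c("A", "B", "C"), c(A = 0, B = 2, C = -2))
  sp3 <- split_by_regulation(cgl3, 0)
  expect_equal(sp3$up$genes, c("A", "B"))
  expect_equal(sp3$down$genes, "C")

  expect_error(split_by_regulation(condition_genes("X", "A"), 1), "log2 fold-change")
})

test_that("hypergeometric upper tail matches hand-derived values", {
  expect_identical(hypergeom_pvalue(0, 5, 5, 10), 1)        # P(X >= 0)
  expect_equal(hypergeom_pvalue(3, 5, 5, 10), 0.5, tolerance = 1e-14)  # (100+25+1)/252
  expect_equal(hypergeom_pvalue(5, 5, 5, 20), 1 / 15504, tolerance = 1e-14)
  expect_error(hypergeom_pvalue(6, 5, 5, 10), "infeasible")
  expect_error(hypergeom_pvalue(0, 5, 11, 10), "N")
})

test_that("hypergeometric tail is non-increasing in the overlap count", {
  for (case in list(c(8, 5, 20), c(10, 10, 30), c(3, 7, 12))) {
    n <- case[1]; K <- case[2]; N <- case[3]
    ks <- max(0, n + K - N):min(n, K)
    p <- hypergeom_pvalue(ks, n, K, N)
    expect_true(all(diff(p) <= 1e-15))
  }
})

test_that("BH adjustment reproduces hand-computed step-up values", {
  expect_equal(adjust_bh(0.05), 0.05)
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjust_bh(c(0.001, 1)), c(0.002, 1))
  expect_error(adjust_bh(c(0.5, 0)), "\\(0, 1\\]")
  expect_error(adjust_bh(c(0.5, 1.2)), "\\(0, 1\\]")
})

test_that("over-representation ranks an exactly matching term first and applies the size filter", {
  lib <- gene_set_library(list(
    T1 = c("A1", "A2", "A3", "A4"),
    T2 = c("B1", "B2", "B3"),
    T3 = c("C1", "C2", "C3", "C4", "C5")
  ), name = "toy")
  hits <- enrich_condition(c("A1", "A2", "A3", "A4"), lib, min_genes = 1)
  expect_equal(hits$term[which.min(hits$p_raw)], "T1")
  expect_equal(hits$k[hits$term == "T1"], 4L)

  # k = 2 overlap disappears under min_genes = 3
  hits2 <- enrich_condition(c("A1", "A2"), lib, min_genes = 3)
  expect_false("T1" %in% hits2$term)

  # query inside a widened background but disjoint from every set: no rows
  lib_bg <- gene_set_library(list(T1 = c("A1", "A2")), name = "toy",
                             background = c("A1", "A2", "Z1", "Z2"))
  expect_equal(nrow(enrich_condition(c("Z1", "Z2"), lib_bg, min_genes = 1)), 0L)
})

test_that("adjusted p-values are computed across the whole library before size filtering", {
  lib <- gene_set_library(list(
    T1 = c("A1", "A2", "A3"),
    T2 = c("A1", "B2", "B3"),
    T3 = c("C1", "C2", "C3")
  ), name = "toy")
  all_terms <- enrich_condition(c("A1", "A2", "A3"), lib, min_genes = 1)
  filtered <- enrich_condition(c("A1", "A2", "A3"), lib, min_genes = 2)
  # the surviving term keeps the p_adj it had in the full 3-test family
  expect_equal(filtered$p_adj[filtered$term == "T1"],
               all_terms$p_adj[all_terms$term == "T1"])
  # the BH family spans all 3 library terms, including T3 (k = 0), which
  # never reaches the output; reference tails computed by the exact sum
  N <- 8; n <- 3
  p_all <- c(hyper_tail_ref(3, n, 3, N),  # T1
             hyper_tail_ref(1, n, 3, N),  # T2
             hyper_tail_ref(0, n, 3, N))  # T3
  expect_equal(all_terms$p_raw, p_all[1:2], tolerance = 1e-12)
  expect_equal(all_terms$p_adj, bh_ref(p_all)[1:2], tolerance = 1e-12)
})

test_that("query genes outside the background are dropped with a message", {
  lib <- gene_set_library(list(T1 = c("A1", "A2")), name = "toy")
  expect_message(hits <- enrich_condition(c("A1", "A2", "ZZZ"), lib, min_genes = 1),
                 "outside the background")
  expect_equal(hits$n[1], 2L)
  expect_error(suppressMessages(enrich_condition("ZZZ", lib)), "background")
})

test_that("significance filtering and top-N ranking follow the stated tie rules", {
  hits <- make_hits(sprintf("t%d", 1:3), list("G1", "G2", "G3"),
                    p_adj = c(0.01, 0.04, 0.06))
  kept <- filter_and_rank(hits, padj_max = 0.05, top_n = 5)
  expect_equal(nrow(kept), 2L)  # strict < 0.05
  expect_equal(kept$rank, 1:2)

  hits7 <- make_hits(sprintf("t%d", 1:7), as.list(sprintf("G%d", 1:7)),
                     p_adj = seq(0.001, 0.04, length.out = 7))
  kept7 <- filter_and_rank(hits7, top_n = 5)
  expect_equal(nrow(kept7), 5L)
  expect_equal(kept7$rank, 1:5)
  expect_equal(kept7$term, sprintf("t%d", 1:5))

  # equal p_adj: larger overlap first
  tie <- make_hits(c("small", "big"),
                   list("G1", c("G1", "G2", "G3", "G4", "G5", "G6", "G7", "G8", "G9", "G10")),
                   p_adj = c(0.01, 0.01))
  expect_equal(filter_and_rank(tie, top_n = 2)$term, c("big", "small"))
  expect_error(filter_and_rank(tie, top_n = 0), "top_n")
})

test_that("aggregation concatenates tables and enforces key uniqueness", {
  a <- make_hits(c("t1", "t2", "t3"), as.list(sprintf("G%d", 1:3)), condition = "A")
  b <- make_hits(c("t1", "t4"), as.list(sprintf("G%d", 4:5)), condition = "B")
  agg <- aggregate_conditions(list(a, b))
  expect_equal(nrow(agg), 5L)
  expect_equal(sum(agg$term == "t1"), 2L)  # key includes condition
  expect_error(aggregate_conditions(list(a, a)), "duplicate")
})

test_that("a planted enriched term attains the stratum-minimum adjusted p-value", {
  set.seed(42)
  fix <- generate_fixture(seed = 42)
  planted_block <- fix$truth$condition_blocks[["cond1"]]
  planted_terms <- fix$truth$blocks[[sprintf("block%02d", planted_block)]]
  cond <- suppressWarnings(condition_lists_from_cond(fix, "cond1"))
  hits <- suppressMessages(
    enrich_condition(cond, fix$library, min_genes = 2, condition = "cond1"))
  expect_true(hits$term[which.min(hits$p_adj)] %in% planted_terms)
  expect_equal(min(hits$p_adj), min(hits$p_adj[hits$term %in% planted_terms]))
})
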