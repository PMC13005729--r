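test_that("pooling methods reproduce their closed forms", {
  # Fisher: chi-squared(2) survival at -2 log p is p itself
  set.seed(1)
  for (p in runif(20)) {
    expect_equal(pool_pvalues(p, "fisher"), p, tolerance = 1e-13)
  }
  # e^(-x/2) (1 + x/2) with x = -2 log(0.25)
  expect_equal(pool_pvalues(c(0.5, 0.5), "fisher"), 0.596574, tolerance = 1e-6)
  expect_equal(pool_pvalues(c(0.5, 0.5), "stouffer"), 0.5, tolerance = 1e-14)
  expect_equal(pool_pvalues(c(0.5, 0.5, 0.5), "cauchy"), 0.5, tolerance = 1e-14)
})

test_that("every pooling method is the identity on a single p-value", {
  set.seed(2)
  for (p in runif(10)) {
    for (m in c("fisher", "stouffer", "weighted_z", "cauchy")) {
      expect_equal(pool_pvalues(p, m, weights = 2.7), p, tolerance = 1e-12)
    }
  }
})

test_that("weighted Z with equal weights reduces to Stouffer", {
  set.seed(3)
  for (i in 1:100) {
    ps <- runif(sample(2:10, 1), min = 1e-6)
    w <- rep(runif(1, 0.1, 5), length(ps))
    expect_equal(pool_pvalues(ps, "weighted_z", weights = w),
                 pool_pvalues(ps, "stouffer"), tolerance = 1e-12)
  }
})

test_that("pooling is invariant under permutation of (p, weight) pairs", {
  set.seed(4)
  ps <- runif(6, 0.001, 0.999)
  w <- runif(6, 0.5, 3)
  for (m in c("fisher", "stouffer", "weighted_z", "cauchy")) {
    for (i in 1:5) {
      perm <- sample(6)
      expect_equal(pool_pvalues(ps[perm], m, weights = w[perm]),
                   pool_pvalues(ps, m, weights = w), tolerance = 1e-12)
    }
  }
})

test_that("the Cauchy combination is driven by its smallest p-value", {
  # pooling [p_min, 0.5, ..., 0.5] tends to k * p_min as p_min -> 0
  p_min <- 1e-12
  for (k in c(2, 5, 10)) {
    pooled <- pool_pvalues(c(p_min, rep(0.5, k - 1)), "cauchy")
    expect_lt(pooled / (k * p_min), 1.1)
    expect_gt(pooled / (k * p_min), 1 / 1.1)
  }
})

test_that("pooling rejects degenerate input", {
  expect_error(pool_pvalues(numeric(0), "fisher"), "at least one")
  expect_error(pool_pvalues(c(0.5, 0), "fisher"), "floor")
  expect_error(pool_pvalues(0.5, "cauchy", weights = c(1, 2)), "weights")
  expect_error(pool_pvalues(0.5, "cauchy", weights = -1), "weights")
})

test_that("p-value capping is a lower clamp", {
  expect_equal(cap_pvalue(1e-40, 1e-30), 1e-30)
  expect_equal(cap_pvalue(0.02, 1e-30), 0.02)
  expect_equal(cap_pvalue(1e-30, 1e-30), 1e-30)
  expect_error(cap_pvalue(0.5, 0), "floor")
})

two_cluster_assignment <- function() {
  structure(list(membership = c(t1 = 1L, t2 = 1L, t3 = 2L),
                 modularity = 0.1, walk_length = 4L),
            class = "cluster_assignment")
}

test_that("cluster summaries pool per cell with duplicate-term collapse", {
  a <- two_cluster_assignment()
  hits <- rbind(
    make_hits(c("t1", "t2"), list(c("G1", "G2"), c("G2", "G3")),
              condition = "A", p_adj = c(0.5, 0.5)),
    make_hits("t3", list("G9"), condition = "A", p_adj = 0.02)
  )
  rows <- summarize_clusters(hits, a, method = "fisher")
  expect_equal(nrow(rows), 2L)
  r1 <- rows[rows$cluster_id == 1, ]
  expect_equal(r1$pooled_p, 0.596574, tolerance = 1e-6)
  expect_equal(r1$n_terms_here, 2L)
  expect_equal(r1$n_terms_total, 2L)
  expect_equal(r1$n_genes, 3L)
  # single-term cluster: pooled p is the term's own adjusted p
  expect_equal(rows$pooled_p[rows$cluster_id == 2], 0.02)
  # no rows for conditions without contributing hits
  expect_false("B" %in% rows$condition)

  # the same term retained from two databases is pooled once, at its best p
  dup <- rbind(
    make_hits("t1", list(c("G1", "G2")), database = "db1", p_adj = 0.5),
    make_hits("t1", list(c("G1", "G4")), database = "db2", p_adj = 0.7)
  )
  rdup <- summarize_clusters(dup, a, method = "fisher")
  expect_equal(rdup$pooled_p, 0.5)
  expect_equal(rdup$n_terms_here, 1L)
  expect_equal(rdup$n_genes, 3L)  # gene union still spans both rows

  expect_error(summarize_clusters(make_hits("zz", list("G1")), a), "missing")
})

test_that("pooled values respect the display floor on both sides", {
  a <- two_cluster_assignment()
  hits <- make_hits(c("t1", "t2"), list("G1", "G2"), p_adj = c(1e-30, 1e-30))
  rows <- summarize_clusters(hits, a, method = "fisher", p_floor = 1e-10)
  expect_gte(min(rows$pooled_p), 1e-10)
})

test_that("annotation prompts are deterministic and complete", {
  a <- two_cluster_assignment()
  hits <- make_hits(c("t1", "t2", "t3"), list("G1", "G2", "G3"))
  p1 <- build_annotation_prompt(a, hits, style = "detailed")
  p2 <- build_annotation_prompt(a, hits, style = "detailed")
  expect_identical(p1, p2)
  for (t in c("t1", "t2", "t3")) {
    expect_equal(lengths(regmatches(p1, gregexpr(t, p1, fixed = TRUE))), 1L)
  }
  expect_match(p1, "Cluster 1")
  expect_match(p1, "Cluster 2")
  expect_match(p1, "cluster_id<TAB>label", fixed = TRUE)
})

test_that("oversized term lists are split into numbered prompt parts", {
  n <- 250L
  a <- structure(list(membership = stats::setNames(rep(1:25, each = 10),
                                                   sprintf("term%03d", 1:n)),
                      modularity = 0, walk_length = 4L),
                 class = "cluster_assignment")
  prompt <- build_annotation_prompt(a, style = "terse", chunk_size = 200L)
  expect_match(prompt, "part 1 of 2")
  expect_match(prompt, "part 2 of 2")
  # every term appears exactly once across all parts
  hits <- gregexpr("term[0-9]{3}", prompt)[[1]]
  expect_length(hits, n)
})

test_that("annotation replies parse into id -> label maps", {
  map <- parse_annotation_reply("1\tECM organization\n\n2\tInterferon response")
  expect_equal(map, c(`1` = "ECM organization", `2` = "Interferon response"))
  a <- two_cluster_assignment()
  expect_warning(m2 <- parse_annotation_reply("1\tX\n99\tbogus", a), "99")
  expect_equal(attr(m2, "unknown_ids"), 99L)
  expect_error(parse_annotation_reply("no tabs here"), "no 'cluster_id<TAB>label'")
})

test_that("annotations fill in with placeholders and are overwritable", {
  rows <- data.frame(cluster_id = c(1L, 2L), annotation = NA_character_)
  r1 <- apply_annotations(rows, c(`1` = "X"))
  expect_equal(r1$annotation, c("X", "Cluster 2"))
  r2 <- apply_annotations(r1, character(0))
  expect_equal(r2$annotation, c("Cluster 1", "Cluster 2"))
  r3 <- apply_annotations(r2, c(`1` = "A", `2` = "B"))
  expect_equal(r3$annotation, c("A", "B"))
})

test_that("per-term coherence matches hand-derived Jaccard values", {
  map <- list(A = c("g1", "g2"), B = c("g1", "g2", "g3"))
  a <- structure(list(membership = c(A = 1L, B = 1L)),
                 class = "cluster_assignment")
  rep1 <- term_coherence(map, a)
  expect_equal(rep1$per_term$jaccard_vs_rest, c(2 / 3, 2 / 3))
  expect_equal(rep1$mean_jaccard, 2 / 3)

  # all singletons: no defined value, mean undefined
  singles <- structure(list(membership = c(A = 1L, B = 2L)),
                       class = "cluster_assignment")
  rep2 <- term_coherence(map, singles)
  expect_true(all(is.na(rep2$per_term$jaccard_vs_rest)))
  expect_true(is.na(rep2$mean_jaccard))

  # identical gene sets in one cluster score 1
  dup_map <- list(A = c("g1", "g2"), B = c("g1", "g2"))
  rep3 <- term_coherence(dup_map, a)
  expect_equal(rep3$per_term$jaccard_vs_rest, c(1, 1))
})
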