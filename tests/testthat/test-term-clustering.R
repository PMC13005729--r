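test_that("term-gene maps union overlap genes across conditions", {
  hits <- rbind(
    make_hits("T", list(c("G1", "G2")), condition = "A"),
    make_hits("T", list(c("G2", "G3")), condition = "B"),
    make_hits("S", list("G9"), condition = "A")
  )
  map <- build_term_gene_map(hits)
  expect_equal(map$T, c("G1", "G2", "G3"))
  expect_equal(map$S, "G9")
  expect_equal(names(map), c("S", "T"))  # deterministic order
  expect_length(build_term_gene_map(make_hits("X", list("G1"))), 1L)
})

test_that("Jaccard similarity follows the set definition", {
  expect_equal(jaccard_similarity(c("a", "b"), c("a", "b")), 1)
  expect_equal(jaccard_similarity(c("a", "b"), c("c", "d")), 0)
  expect_equal(jaccard_similarity(c("g1", "g2", "g3"), c("g2", "g3", "g4")), 0.5)
  expect_error(jaccard_similarity(character(0), "a"), "empty")
})

test_that("graph construction prunes by threshold and keeps isolated terms", {
  map <- list(A = c("g1", "g2", "g3"), B = c("g2", "g3", "g4"), C = "z9")
  g <- build_term_graph(map, ts = 0.5)
  expect_equal(igraph::vcount(g), 3L)  # isolated C stays
  expect_equal(igraph::ecount(g), 1L)
  expect_equal(igraph::E(g)$weight, 0.5)

  g2 <- build_term_graph(map, ts = 0.7)
  expect_equal(igraph::ecount(g2), 0L)

  # ts = 0: complete over pairs sharing at least one gene, no 0-weight edges
  g0 <- build_term_graph(map, ts = 0)
  expect_equal(igraph::ecount(g0), 1L)
  expect_error(build_term_graph(map, ts = 1.5), "ts")
})

test_that("raising the threshold only removes edges (nestedness)", {
  set.seed(11)
  pool <- sprintf("g%02d", 1:30)
  map <- lapply(1:12, function(i) sample(pool, sample(4:10, 1)))
  names(map) <- sprintf("T%02d", 1:12)
  edge_key <- function(g) {
    e <- igraph::ends(g, igraph::E(g), names = TRUE)
    paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  }
  for (pair in list(c(0.1, 0.3), c(0.2, 0.5), c(0, 0.8))) {
    lo <- edge_key(build_term_graph(map, pair[1]))
    hi <- edge_key(build_term_graph(map, pair[2]))
    expect_true(all(hi %in% lo))
  }
})

test_that("walktrap clustering handles cliques, isolates and planted two-block graphs", {
  # complete graph: a single community
  k5 <- igraph::make_full_graph(5)
  igraph::V(k5)$name <- sprintf("T%d", 1:5)
  igraph::E(k5)$weight <- 1
  a5 <- walktrap_cluster(k5)
  expect_equal(unname(a5$membership), rep(1L, 5))

  # edgeless graph: every node its own singleton cluster
  e6 <- igraph::make_empty_graph(6, directed = FALSE)
  igraph::V(e6)$name <- sprintf("T%d", 1:6)
  a6 <- walktrap_cluster(e6)
  expect_equal(sort(unname(a6$membership)), 1:6)
  expect_true(is.na(a6$modularity))

  # two 4-cliques joined by a bridge: split exactly at the bridge, matching
  # the exhaustive maximum-modularity partition
  g <- two_clique_bridge_graph()
  a <- walktrap_cluster(g)
  expect_equal(max(a$membership), 2L)
  expect_equal(unname(a$membership[sprintf("T%02d", 1:4)]), rep(1L, 4))
  expect_equal(unname(a$membership[sprintf("T%02d", 5:8)]), rep(2L, 4))
  best <- exhaustive_best_partition(g)
  expect_equal(canon_partition(a$membership),
               canon_partition(stats::setNames(best$membership, igraph::V(g)$name)))
  expect_equal(a$modularity, best$modularity, tolerance = 1e-12)
  expect_error(walktrap_cluster(g, walk_length = 0), "walk_length")
})

test_that("cluster relabeling is deterministic: size-descending, then smallest member", {
  map <- list(A1 = c("x1", "x2"), A2 = c("x1", "x2", "x3"),
              B1 = c("y1", "y2"), B2 = c("y1", "y2", "y3"), B3 = c("y2", "y3"))
  g <- build_term_graph(map, ts = 0.3)
  a1 <- walktrap_cluster(g)
  a2 <- walktrap_cluster(build_term_graph(map, ts = 0.3))
  expect_identical(a1$membership, a2$membership)
  # B-block is larger, so it gets label 1
  expect_equal(unname(a1$membership[c("B1", "B2", "B3")]), rep(1L, 3))
  expect_equal(unname(a1$membership[c("A1", "A2")]), rep(2L, 2))
})

test_that("modularity matches hand values and the igraph reference", {
  g <- two_clique_bridge_graph()
  one <- stats::setNames(rep(1L, 8), igraph::V(g)$name)
  expect_equal(modularity_score(g, one), 0)

  # two disconnected triangles, partitioned by component: Q = 2 (1/2 - 1/4)
  tri2 <- igraph::graph_from_edgelist(
    rbind(c(1, 2), c(2, 3), c(1, 3), c(4, 5), c(5, 6), c(4, 6)),
    directed = FALSE)
  igraph::V(tri2)$name <- sprintf("T%d", 1:6)
  igraph::E(tri2)$weight <- 1
  comp <- stats::setNames(rep(1:2, each = 3), igraph::V(tri2)$name)
  expect_equal(modularity_score(tri2, comp), 0.5)

  set.seed(5)
  for (i in 1:20) {
    g <- random_connected_graph()
    mem <- sample(1:3, igraph::vcount(g), replace = TRUE)
    names(mem) <- igraph::V(g)$name
    expect_equal(modularity_score(g, mem),
                 igraph::modularity(g, mem[igraph::V(g)$name],
                                    weights = igraph::E(g)$weight),
                 tolerance = 1e-12)
    expect_lte(modularity_score(g, mem), 1)
  }
  edgeless <- igraph::make_empty_graph(2, directed = FALSE)
  igraph::V(edgeless)$name <- c("a", "b")
  expect_error(modularity_score(edgeless, c(a = 1, b = 2)), "edgeless")
})

test_that("threshold profiles report fully pruned graphs as all-singleton", {
  map <- list(A = c("g1", "g2", "g3"), B = c("g2", "g3", "g4"),
              C = c("g1", "g4"))
  prof <- evaluate_thresholds(map, c(0.2, 1.0))
  expect_equal(prof$ts, c(0.2, 1.0))
  # no two identical gene sets: at ts = 1 every term is its own component
  expect_equal(prof$n_components[2], 3L)
  expect_equal(prof$n_clusters[2], 3L)
  expect_equal(prof$modularity[2], 0)
  expect_error(evaluate_thresholds(map, numeric(0)), "non-empty")
})

test_that("graph exports round-trip through GraphML and node-link JSON", {
  map <- list(A = c("g1", "g2", "g3"), B = c("g2", "g3", "g4"), C = "z9")
  g <- build_term_graph(map, ts = 0.1)
  a <- walktrap_cluster(g)

  gm <- tempfile(fileext = ".graphml")
  export_graph(g, a, gm, format = "graphml")
  back <- igraph::read_graph(gm, format = "graphml")
  expect_setequal(igraph::V(back)$name, names(map))
  expect_equal(sort(igraph::E(back)$weight), sort(igraph::E(g)$weight))
  expect_equal(
    stats::setNames(igraph::V(back)$cluster_id, igraph::V(back)$name)[names(a$membership)],
    a$membership)

  js <- tempfile(fileext = ".json")
  export_graph(g, a, js, format = "json")
  doc <- jsonlite::fromJSON(js)
  expect_setequal(doc$nodes$term, names(map))
  expect_equal(nrow(doc$links), igraph::ecount(g))
  expect_equal(sort(doc$links$weight), sort(igraph::E(g)$weight))
})
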