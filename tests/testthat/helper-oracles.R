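# Independent reference implementations and small fixture builders used
# across the suite. These stay deliberately naive: direct transcriptions of
# the defining formulas, never calls into the code paths they check.

# Exact upper-tail hypergeometric probability from binomial coefficients:
# P(X >= k) = sum_{i=k}^{min(n,K)} C(K,i) C(N-K,n-i) / C(N,n)
hyper_tail_ref <- function(k, n, K, N) {
  i <- k:min(n, K)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# All upper tails at once for fixed (n, K, N): reverse cumulative sum of the
# exact pmf, indexed by k = lo..hi.
hyper_tails_ref <- function(n, K, N) {
  lo <- max(0, n + K - N)
  hi <- min(n, K)
  i <- lo:hi
  pmf <- choose(K, i) * choose(N - K, n - i) / choose(N, n)
  rev(cumsum(rev(pmf)))
}

# Benjamini-Hochberg step-up: sort descending, cumulative minimum of
# p * m / rank, unsort.
bh_ref <- function(p) {
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(p[o] * m / (m:1)))[ro]
}

# Canonical form of a membership vector so partitions compare up to label
# permutation.
canon_partition <- function(m) {
  if (!is.null(names(m))) m <- m[sort(names(m))]
  as.integer(factor(m, levels = unique(m)))
}

ari <- function(a, b) {
  if (!is.null(names(a)) && !is.null(names(b))) {
    b <- b[names(a)]
  }
  mclust::adjustedRandIndex(a, b)
}

# Minimal enrichment-hit table for clustering / pooling tests.
make_hits <- function(term, overlap, condition = "c1", regulation = "all",
                      database = "db", p_raw = 0.01, p_adj = p_raw,
                      n = 10L, N = 100L) {
  data.frame(
    term = term, database = database, condition = condition,
    regulation = regulation, overlap_genes = I(overlap),
    k = lengths(overlap), n = n, K = lengths(overlap), N = N,
    p_raw = p_raw, p_adj = p_adj, rank = NA_integer_,
    stringsAsFactors = FALSE
  )
}

# Random connected weighted graph on up to `max_n` named nodes.
random_connected_graph <- function(max_n = 8L) {
  repeat {
    n <- sample(3:max_n, 1L)
    g <- igraph::sample_gnp(n, stats::runif(1, 0.3, 0.9))
    if (igraph::is_connected(g) && igraph::ecount(g) > 0L) break
  }
  igraph::V(g)$name <- sprintf("T%02d", seq_len(n))
  igraph::E(g)$weight <- stats::runif(igraph::ecount(g), 0.2, 1)
  g
}

# Modularity of the cut of a walktrap merge sequence maximizing weighted
# modularity, recomputed independently of walktrap_cluster()'s selection.
best_walktrap_modularity <- function(g, walk_length = 4L) {
  wt <- igraph::cluster_walktrap(g, weights = igraph::E(g)$weight,
                                 steps = walk_length)
  qs <- vapply(seq_len(igraph::vcount(g)), function(no) {
    mem <- tryCatch(igraph::cut_at(wt, no = no), error = function(e) NULL)
    if (is.null(mem)) return(-Inf)
    igraph::modularity(g, mem, weights = igraph::E(g)$weight)
  }, numeric(1))
  max(qs)
}

# Exhaustive maximum-modularity partition by enumerating all set partitions
# (restricted growth strings); feasible up to ~10 nodes.
exhaustive_best_partition <- function(g) {
  n <- igraph::vcount(g)
  w <- igraph::E(g)$weight
  best_q <- -Inf
  best <- NULL
  recurse <- function(assign, next_label) {
    i <- length(assign) + 1L
    if (i > n) {
      q <- igraph::modularity(g, assign, weights = w)
      if (q > best_q) {
        best_q <<- q
        best <<- assign
      }
      return(invisible(NULL))
    }
    for (lab in seq_len(next_label)) {
      recurse(c(assign, lab), max(next_label, lab + 1L))
    }
  }
  recurse(integer(0), 1L)
  list(membership = best, modularity = best_q)
}

# Two 4-cliques joined by a single bridge edge, unit weights.
two_clique_bridge_graph <- function() {
  el <- rbind(t(utils::combn(1:4, 2)), t(utils::combn(5:8, 2)), c(4, 5))
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  igraph::V(g)$name <- sprintf("T%02d", 1:8)
  igraph::E(g)$weight <- 1
  g
}

run_fixture_pipeline <- function(fix, ts = 0.3, out_dir = tempfile("run_"),
                                 seed = 1L, ...) {
  cfg <- pipeline_config(conditions = fix$conditions,
                         libraries = list(fix$library), logfc_col = "log2fc",
                         ts = ts, out_dir = out_dir, make_plots = FALSE,
                         seed = seed, ...)
  suppressMessages(run_pipeline(cfg))
}

# One condition of a generated fixture as a condition_genes object.
condition_lists_from_cond <- function(fix, cond) {
  df <- fix$conditions[fix$conditions$condition == cond, , drop = FALSE]
  condition_genes(cond, df$gene, stats::setNames(df$log2fc, df$gene))
}
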