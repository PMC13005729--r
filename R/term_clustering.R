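#' Term -> gene map from retained enrichment hits
#'
#' For every term in the hit table, takes the union of its overlap genes
#' across all conditions, regulation subsets and databases where the term
#' was retained. These per-term gene sets (genes of the dataset matched by
#' the term, not the full library sets) are the basis of the similarity
#' graph.
#'
#' @param hits Enrichment hit table with `term` and `overlap_genes` columns.
#' @return Named list, term -> sorted character vector of gene symbols,
#'   alphabetically ordered by term.
#' @export
build_term_gene_map <- function(hits) {
  if (!is.data.frame(hits) || nrow(hits) == 0L) {
    stop("'hits' must be a non-empty hit table", call. = FALSE)
  }
  sp <- split(hits$overlap_genes, hits$term)
  m <- lapply(sp, function(gl) sort(unique(unlist(gl, use.names = FALSE))))
  m[order(names(m))]
}

#' Jaccard similarity of two gene sets
#'
#' `|A intersect B| / |A union B|`; 1 minus this value is the Jaccard
#' distance.
#'
#' @param a,b Non-empty character vectors (treated as sets).
#' @return Similarity in \[0, 1\].
#' @export
jaccard_similarity <- function(a, b) {
  if (!length(a) || !length(b)) {
    stop("Jaccard similarity is undefined for an empty set", call. = FALSE)
  }
  a <- unique(a)
  b <- unique(b)
  length(intersect(a, b)) / length(union(a, b))
}

#' Build the pruned term-similarity graph
#'
#' Computes all pairwise Jaccard similarities between term gene sets (via
#' the binary gene x term incidence matrix) and keeps an undirected weighted
#' edge for every pair with similarity >= `ts` and > 0. Terms that lose all
#' their edges remain in the graph as isolated nodes.
#'
#' @param map Term -> gene map from [build_term_gene_map].
#' @param ts Pruning threshold in \[0, 1\]; edges with similarity below `ts`
#'   are removed.
#' @return An [igraph][igraph::graph_from_data_frame] graph with vertex
#'   attributes `name` and `n_genes`, edge attribute `weight`, and graph
#'   attribute `ts`.
#' @export
build_term_graph <- function(map, ts = 0.3) {
  if (!is.list(map) || length(map) == 0L || is.null(names(map))) {
    stop("'map' must be a non-empty named term -> gene list", call. = FALSE)
  }
  if (!is_prob(ts)) {
    stop("'ts' must be a single value in [0, 1]", call. = FALSE)
  }
  if (any(lengths(map) == 0L)) {
    stop("every term must map to at least one gene", call. = FALSE)
  }
  terms <- names(map)
  vertices <- data.frame(name = terms, n_genes = unname(lengths(map)),
                         stringsAsFactors = FALSE)
  edges <- NULL
  if (length(terms) >= 2L) {
    genes <- sort(unique(unlist(map, use.names = FALSE)))
    M <- matrix(0L, nrow = length(genes), ncol = length(terms),
                dimnames = list(genes, terms))
    for (j in seq_along(terms)) M[map[[j]], j] <- 1L
    inter <- crossprod(M)
    sizes <- diag(inter)
    uni <- outer(sizes, sizes, `+`) - inter
    J <- inter / uni
    idx <- which(upper.tri(J) & J >= ts & J > 0, arr.ind = TRUE)
    if (nrow(idx)) {
      edges <- data.frame(from = terms[idx[, 1]], to = terms[idx[, 2]],
                          weight = J[idx], stringsAsFactors = FALSE)
      edges <- edges[order(edges$from, edges$to), , drop = FALSE]
    }
  }
  if (is.null(edges)) {
    edges <- data.frame(from = character(0), to = character(0),
                        weight = numeric(0))
  }
  g <- igraph::graph_from_data_frame(edges, directed = FALSE, vertices = vertices)
  g <- igraph::set_graph_attr(g, "ts", ts)
  g
}

#' Walktrap community detection over the term graph
#'
#' Runs the Walktrap (Pons-Latapy) agglomeration on each connected
#' component of the weighted graph and, within each component, returns the
#' cut of the merge sequence that maximizes weighted modularity (ties go to
#' the coarser partition). Isolated terms become singleton clusters.
#' Cluster ids are relabeled 1..C by decreasing cluster size, breaking ties
#' by the lexicographically smallest member term, so identical inputs yield
#' identical labels.
#'
#' @param graph Term graph from [build_term_graph].
#' @param walk_length Random-walk length (steps) of the Walktrap algorithm.
#' @return Object of class `cluster_assignment`: list with `membership`
#'   (named integer vector, term -> cluster id), `modularity` (weighted
#'   modularity of the returned partition over the whole graph, `NA` for an
#'   edgeless graph) and `walk_length`.
#' @export
walktrap_cluster <- function(graph, walk_length = 4L) {
  stopifnot(inherits(graph, "igraph"))
  if (igraph::vcount(graph) < 1L) stop("graph has no nodes", call. = FALSE)
  if (!is_count(walk_length, min = 1L)) {
    stop("'walk_length' must be a positive integer", call. = FALSE)
  }
  comp <- igraph::components(graph)
  vnames <- igraph::V(graph)$name
  membership <- integer(igraph::vcount(graph))
  names(membership) <- vnames
  next_id <- 0L
  for (ci in seq_len(comp$no)) {
    vids <- which(comp$membership == ci)
    if (length(vids) == 1L) {
      membership[vids] <- next_id + 1L
      next_id <- next_id + 1L
      next
    }
    sub <- igraph::induced_subgraph(graph, vids)
    wt <- igraph::cluster_walktrap(sub, weights = igraph::E(sub)$weight,
                                   steps = walk_length)
    best <- best_dendrogram_cut(sub, wt)
    membership[vids] <- best + next_id
    next_id <- next_id + max(best)
  }
  membership <- relabel_clusters(membership)
  q <- if (igraph::ecount(graph) > 0L) {
    igraph::modularity(graph, membership, weights = igraph::E(graph)$weight)
  } else {
    NA_real_
  }
  structure(list(membership = membership, modularity = q,
                 walk_length = as.integer(walk_length)),
            class = "cluster_assignment")
}

# Pick the merge level of a communities dendrogram maximizing weighted
# modularity; ties resolved toward fewer clusters.
best_dendrogram_cut <- function(graph, communities) {
  nv <- igraph::vcount(graph)
  w <- igraph::E(graph)$weight
  best_q <- -Inf
  best_mem <- NULL
  for (no in nv:1) {  # fine -> coarse so later (coarser) >= takes ties
    mem <- tryCatch(igraph::cut_at(communities, no = no),
                    error = function(e) NULL)
    if (is.null(mem)) next
    q <- igraph::modularity(graph, mem, weights = w)
    if (q >= best_q) {
      best_q <- q
      best_mem <- mem
    }
  }
  # contiguous ids within the component
  as.integer(factor(best_mem, levels = unique(best_mem)))
}

# Deterministic relabeling: decreasing size, ties by smallest member name.
relabel_clusters <- function(membership) {
  sizes <- table(membership)
  first_member <- vapply(names(sizes), function(cl) {
    min(names(membership)[membership == as.integer(cl)])
  }, character(1))
  ord <- order(-as.integer(sizes), first_member)
  new_ids <- stats::setNames(seq_along(ord), names(sizes)[ord])
  out <- as.integer(new_ids[as.character(membership)])
  names(out) <- names(membership)
  out
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("<cluster_assignment> %d term(s) in %d cluster(s); modularity %s\n",
              length(x$membership), max(x$membership),
              if (is.na(x$modularity)) "undefined (edgeless graph)" else
                sprintf("%.4f", x$modularity)))
  invisible(x)
}

#' Weighted Newman modularity of a partition
#'
#' `Q = sum_c (e_cc - a_c^2)` where `e_cc` is the fraction of total edge
#' weight falling inside cluster `c` and `a_c` the fraction of total
#' weighted degree attached to `c`. Computed directly from the edge list
#' (independently of igraph's own modularity routine, which serves as a
#' cross-check in the tests).
#'
#' @param graph Weighted undirected graph with at least one edge.
#' @param assignment A `cluster_assignment`, or a membership vector named by
#'   (or aligned with) the graph's vertices.
#' @return Modularity Q (at most 1).
#' @export
modularity_score <- function(graph, assignment) {
  stopifnot(inherits(graph, "igraph"))
  if (igraph::ecount(graph) == 0L) {
    stop("modularity is undefined for an edgeless graph", call. = FALSE)
  }
  membership <- if (inherits(assignment, "cluster_assignment")) {
    assignment$membership
  } else {
    assignment
  }
  vnames <- igraph::V(graph)$name
  if (!is.null(names(membership))) {
    if (!all(vnames %in% names(membership))) {
      stop("membership does not cover every graph node", call. = FALSE)
    }
    membership <- membership[vnames]
  } else if (length(membership) != length(vnames)) {
    stop("membership length does not match the number of nodes", call. = FALSE)
  }
  w <- igraph::E(graph)$weight %||% rep(1, igraph::ecount(graph))
  ends <- igraph::ends(graph, igraph::E(graph), names = TRUE)
  total <- sum(w)
  same <- membership[ends[, 1]] == membership[ends[, 2]]
  e_cc <- tapply(w[same], membership[ends[, 1]][same], sum) / total
  strength <- igraph::strength(graph, weights = w)
  a_c <- tapply(strength, membership, sum) / (2 * total)
  sum(e_cc) - sum(a_c^2)
}

#' Sweep the pruning threshold and profile the clustering
#'
#' For every threshold in `ts_grid`, builds the pruned graph, clusters it
#' with Walktrap and records edge count, cluster count, connected-component
#' count and modularity (reported as 0 when the pruned graph has no edges).
#' Used to choose `ts` by inspecting how the graph decomposes.
#'
#' @param map Term -> gene map from [build_term_gene_map].
#' @param ts_grid Numeric vector of thresholds in \[0, 1\] (sorted and
#'   deduplicated internally).
#' @param walk_length Passed to [walktrap_cluster].
#' @return Data frame of class `threshold_profile` with columns `ts`,
#'   `n_edges`, `n_clusters`, `n_components`, `modularity`; `ts` strictly
#'   increasing.
#' @export
evaluate_thresholds <- function(map, ts_grid, walk_length = 4L) {
  if (!length(ts_grid)) stop("'ts_grid' must be non-empty", call. = FALSE)
  if (any(!vapply(ts_grid, is_prob, logical(1)))) {
    stop("'ts_grid' values must lie in [0, 1]", call. = FALSE)
  }
  ts_grid <- sort(unique(as.numeric(ts_grid)))
  rows <- lapply(ts_grid, function(ts) {
    g <- build_term_graph(map, ts)
    a <- walktrap_cluster(g, walk_length = walk_length)
    data.frame(
      ts = ts,
      n_edges = igraph::ecount(g),
      n_clusters = max(a$membership),
      n_components = igraph::components(g)$no,
      modularity = if (is.na(a$modularity)) 0 else a$modularity
    )
  })
  out <- do.call(rbind, rows)
  class(out) <- c("threshold_profile", "data.frame")
  out
}

#' Export the term graph for external viewers
#'
#' Writes the clustered term graph either as GraphML or as a node-link JSON
#' document (`nodes`: term, cluster_id, n_genes; `links`: source, target,
#' weight) suitable for interactive network viewers.
#'
#' @param graph Term graph from [build_term_graph].
#' @param assignment Matching `cluster_assignment` (optional; cluster ids
#'   default to 0 when absent).
#' @param path Output path.
#' @param format `"graphml"` or `"json"`.
#' @return Invisibly, `path`.
#' @export
export_graph <- function(graph, assignment = NULL, path,
                         format = c("graphml", "json")) {
  format <- match.arg(format)
  stopifnot(inherits(graph, "igraph"))
  vnames <- igraph::V(graph)$name
  cluster_id <- if (is.null(assignment)) {
    rep(0L, length(vnames))
  } else {
    membership <- if (inherits(assignment, "cluster_assignment")) {
      assignment$membership
    } else assignment
    if (!all(vnames %in% names(membership))) {
      stop("assignment does not cover every graph node", call. = FALSE)
    }
    as.integer(membership[vnames])
  }
  if (format == "graphml") {
    g <- igraph::set_vertex_attr(graph, "cluster_id", value = cluster_id)
    igraph::write_graph(g, path, format = "graphml")
  } else {
    ends <- igraph::ends(graph, igraph::E(graph), names = TRUE)
    doc <- list(
      nodes = data.frame(term = vnames, cluster_id = cluster_id,
                         n_genes = igraph::V(graph)$n_genes,
                         stringsAsFactors = FALSE),
      links = if (nrow(ends)) {
        data.frame(source = ends[, 1], target = ends[, 2],
                   weight = igraph::E(graph)$weight, stringsAsFactors = FALSE)
      } else {
        data.frame(source = character(0), target = character(0),
                   weight = numeric(0))
      }
    )
    jsonlite::write_json(doc, path, dataframe = "rows", digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}
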