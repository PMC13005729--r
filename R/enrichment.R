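#' Split a condition's genes by regulation direction
#'
#' Divides a gene list into up- and downregulated subsets using a log2
#' fold-change threshold `t`: up takes genes with log2FC >= +t, down takes
#' genes with log2FC <= -t. With `t = 0` a gene at exactly 0 goes to the up
#' subset. Genes strictly inside (-t, +t) belong to neither subset and are
#' dropped; their count is reported via `message()`.
#'
#' @param cgl A [condition_genes] object whose `log2fc` covers every gene.
#' @param logfc_threshold Non-negative log2 fold-change threshold.
#' @return List with elements `up` and `down`, both [condition_genes]
#'   (possibly with empty gene sets), and `n_dropped`, the number of genes
#'   inside the open band.
#' @export
split_by_regulation <- function(cgl, logfc_threshold) {
  stopifnot(inherits(cgl, "condition_genes"))
  if (!is.numeric(logfc_threshold) || length(logfc_threshold) != 1L ||
      is.na(logfc_threshold) || logfc_threshold < 0) {
    stop("'logfc_threshold' must be a single non-negative number", call. = FALSE)
  }
  lfc <- cgl$log2fc
  if (is.null(lfc) || !all(cgl$genes %in% names(lfc))) {
    missing <- if (is.null(lfc)) cgl$genes else setdiff(cgl$genes, names(lfc))
    stop("log2 fold-change missing for gene(s): ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  up <- names(lfc)[lfc >= logfc_threshold]
  down <- setdiff(names(lfc)[lfc <= -logfc_threshold], up)
  n_dropped <- length(cgl$genes) - length(up) - length(down)
  if (n_dropped > 0L) {
    message(sprintf("condition '%s': %d gene(s) with |log2FC| < %g dropped from both subsets",
                    cgl$condition, n_dropped, logfc_threshold))
  }
  list(up = condition_genes_allow_empty(cgl$condition, up, lfc[up]),
       down = condition_genes_allow_empty(cgl$condition, down, lfc[down]),
       n_dropped = n_dropped)
}

# split_by_regulation may legitimately produce an empty subset; bypass the
# non-empty validation used for user input.
condition_genes_allow_empty <- function(condition, genes, log2fc) {
  if (length(genes) == 0L) {
    structure(list(condition = condition, genes = character(0), log2fc = NULL),
              class = "condition_genes")
  } else {
    condition_genes(condition, genes, log2fc)
  }
}

#' Upper-tail hypergeometric p-value
#'
#' Probability of observing `k` or more query genes inside a gene set of
#' size `K` when `n` genes are drawn without replacement from a background
#' universe of size `N`: `P(X >= k)` with
#' `X ~ Hypergeometric(N, K, n)`. This is the one-sided over-representation
#' test used throughout the package (equivalent to a one-sided Fisher exact
#' test on the 2x2 overlap table). Arguments are recycled to a common
#' length.
#'
#' @param k Observed overlap count(s).
#' @param n Query size(s).
#' @param K Gene-set size(s) within the background.
#' @param N Background universe size(s).
#' @return Numeric vector of upper-tail probabilities in (0, 1].
#' @examples
#' hypergeom_pvalue(3, 5, 5, 10)   # 0.5
#' @export
hypergeom_pvalue <- function(k, n, K, N) {
  len <- max(length(k), length(n), length(K), length(N))
  k <- rep_len(as.numeric(k), len)
  n <- rep_len(as.numeric(n), len)
  K <- rep_len(as.numeric(K), len)
  N <- rep_len(as.numeric(N), len)
  if (any(is.na(c(k, n, K, N))) || any(c(k, n, K, N) != floor(c(k, n, K, N)))) {
    stop("all arguments must be integers", call. = FALSE)
  }
  if (any(N < 1) || any(K < 0) || any(K > N) || any(n < 0) || any(n > N)) {
    stop("require N >= 1, 0 <= K <= N and 0 <= n <= N", call. = FALSE)
  }
  lo <- pmax(0, n + K - N)
  if (any(k < lo) || any(k > pmin(n, K))) {
    stop("infeasible overlap: require max(0, n + K - N) <= k <= min(n, K)",
         call. = FALSE)
  }
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment of a p-value vector, order-aligned
#' with the input. A thin validated front-end to [stats::p.adjust()].
#'
#' @param p_values Numeric vector with values in (0, 1].
#' @return Adjusted p-values, same length and order as the input.
#' @export
adjust_bh <- function(p_values) {
  if (!length(p_values)) stop("empty p-value vector", call. = FALSE)
  if (any(is.na(p_values)) || any(p_values <= 0 | p_values > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Over-representation analysis of one gene list against one library
#'
#' Tests every term of the library with the upper-tail hypergeometric test,
#' restricting the query to genes present in the library background (the
#' number of genes dropped by the restriction is reported via `message()`).
#' Adjusted p-values are computed over all tested terms of the library
#' before any size filter, so the multiple-testing family is the whole
#' library; terms with fewer than `min_genes` overlapping genes are then
#' removed from the output.
#'
#' @param genes Character vector of query gene symbols, or a
#'   [condition_genes] object.
#' @param library A [gene_set_library].
#' @param min_genes Minimum overlap count for a term to be reported
#'   (at least 1).
#' @param condition,regulation Labels copied onto every output row;
#'   `regulation` is one of `"all"`, `"up"`, `"down"`.
#' @param adjust_method Multiplicity adjustment, `"BH"` (default) or
#'   `"bonferroni"`.
#' @return Data frame of enrichment hits with columns `term`, `database`,
#'   `condition`, `regulation`, `overlap_genes` (list column), `k`, `n`,
#'   `K`, `N`, `p_raw`, `p_adj`, `rank` (`NA` until [filter_and_rank]).
#' @export
enrich_condition <- function(genes, library, min_genes = 2L,
                             condition = "query", regulation = "all",
                             adjust_method = c("BH", "bonferroni")) {
  adjust_method <- match.arg(adjust_method)
  stopifnot(inherits(library, "gene_set_library"))
  if (inherits(genes, "condition_genes")) {
    condition <- genes$condition
    genes <- genes$genes
  }
  if (!is_count(min_genes, min = 1L)) {
    stop("'min_genes' must be a positive integer", call. = FALSE)
  }
  regulation <- match.arg(regulation, c("all", "up", "down"))
  q <- sort(unique(normalize_symbols(as.character(genes))))
  q <- q[q != ""]
  if (!length(q)) stop("empty query gene list", call. = FALSE)
  q_bg <- intersect(q, library$background)
  n_outside <- length(q) - length(q_bg)
  if (n_outside > 0L) {
    message(sprintf("library '%s': %d of %d query gene(s) outside the background were dropped",
                    library$name, n_outside, length(q)))
  }
  if (!length(q_bg)) {
    stop(sprintf("no query gene overlaps the background of library '%s'",
                 library$name), call. = FALSE)
  }
  N <- length(library$background)
  n <- length(q_bg)
  overlap <- lapply(library$sets, function(s) intersect(q_bg, s))
  k <- lengths(overlap)
  K <- lengths(library$sets)
  p_raw <- hypergeom_pvalue(k, n, K, N)
  p_adj <- if (adjust_method == "BH") adjust_bh(p_raw) else
    stats::p.adjust(p_raw, method = "bonferroni")
  out <- data.frame(
    term = names(library$sets),
    database = library$name,
    condition = condition,
    regulation = regulation,
    overlap_genes = I(unname(overlap)),
    k = unname(k),
    n = n,
    K = unname(K),
    N = N,
    p_raw = unname(p_raw),
    p_adj = unname(p_adj),
    rank = NA_integer_,
    stringsAsFactors = FALSE
  )
  out <- out[out$k >= min_genes, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Significance filter and top-N ranking
#'
#' Within each (condition, regulation, database) stratum, keeps hits with
#' adjusted p-value strictly below `padj_max`, orders them by ascending
#' adjusted p-value (ties: larger overlap `k` first, then term name), keeps
#' the first `top_n` and assigns ranks 1..`top_n`.
#'
#' @param hits Enrichment hit table from [enrich_condition] /
#'   [aggregate_conditions].
#' @param padj_max Adjusted p-value cut-off (default 0.05, strict `<`).
#' @param top_n Maximum number of terms retained per stratum.
#' @return Filtered, ranked hit table ordered by condition, regulation,
#'   database, rank.
#' @export
filter_and_rank <- function(hits, padj_max = 0.05, top_n = 5L) {
  if (!is_count(top_n, min = 1L)) {
    stop("'top_n' must be a positive integer", call. = FALSE)
  }
  if (!is.numeric(padj_max) || length(padj_max) != 1L || padj_max <= 0 || padj_max > 1) {
    stop("'padj_max' must be a single value in (0, 1]", call. = FALSE)
  }
  if (nrow(hits) == 0L) return(hits)
  strata <- interaction(hits$condition, hits$regulation, hits$database,
                        drop = TRUE, lex.order = TRUE)
  pieces <- lapply(split(seq_len(nrow(hits)), strata), function(idx) {
    sub <- hits[idx, , drop = FALSE]
    sub <- sub[sub$p_adj < padj_max, , drop = FALSE]
    if (nrow(sub) == 0L) return(sub)
    ord <- order(sub$p_adj, -sub$k, sub$term)
    sub <- sub[utils::head(ord, top_n), , drop = FALSE]
    sub$rank <- seq_len(nrow(sub))
    sub
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' Aggregate enrichment tables across conditions and libraries
#'
#' Concatenates several hit tables into one, enforcing that the composite
#' key (term, database, condition, regulation) stays unique across the
#' union.
#'
#' @param tables List of hit tables (or several tables given as `...`).
#' @param ... Additional hit tables.
#' @return One combined hit table.
#' @export
aggregate_conditions <- function(tables, ...) {
  if (is.data.frame(tables)) tables <- list(tables)
  tables <- c(tables, list(...))
  tables <- tables[vapply(tables, function(t) is.data.frame(t) && nrow(t) > 0L,
                          logical(1))]
  if (!length(tables)) {
    stop("no non-empty enrichment tables to aggregate", call. = FALSE)
  }
  out <- do.call(rbind, tables)
  rownames(out) <- NULL
  key <- paste(out$term, out$database, out$condition, out$regulation, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- out[duplicated(key), c("term", "database", "condition", "regulation")]
    stop("duplicate (term, database, condition, regulation) row(s), e.g. ",
         paste(unlist(dup[1, ]), collapse = " / "), call. = FALSE)
  }
  out
}

#' Run enrichment for every condition, regulation subset and library
#'
#' Convenience driver: applies [enrich_condition] to each condition (split
#' into up/down subsets when `logfc_threshold` is given) against each
#' library, aggregates the results and applies [filter_and_rank].
#'
#' @param condition_lists Named list of [condition_genes] (as returned by
#'   [read_condition_table]).
#' @param libraries A [gene_set_library] or list of them.
#' @param logfc_threshold Optional log2 fold-change threshold; when given,
#'   each condition is analysed separately for up- and downregulated genes.
#' @inheritParams enrich_condition
#' @inheritParams filter_and_rank
#' @return Filtered, ranked hit table across all strata.
#' @export
run_enrichment <- function(condition_lists, libraries, logfc_threshold = NULL,
                           min_genes = 2L, padj_max = 0.05, top_n = 5L,
                           adjust_method = "BH") {
  if (inherits(libraries, "gene_set_library")) libraries <- list(libraries)
  if (inherits(condition_lists, "condition_genes")) {
    condition_lists <- list(condition_lists)
  }
  tables <- list()
  for (cgl in condition_lists) {
    subsets <- if (is.null(logfc_threshold)) {
      list(all = cgl)
    } else {
      sp <- split_by_regulation(cgl, logfc_threshold)
      list(up = sp$up, down = sp$down)
    }
    for (reg in names(subsets)) {
      sub <- subsets[[reg]]
      if (length(sub$genes) == 0L) next
      for (lib in libraries) {
        tab <- enrich_condition(sub$genes, lib, min_genes = min_genes,
                                condition = cgl$condition, regulation = reg,
                                adjust_method = adjust_method)
        if (nrow(tab)) tables[[length(tables) + 1L]] <- tab
      }
    }
  }
  if (!length(tables)) {
    stop("no enrichment hit passed the overlap filter in any stratum", call. = FALSE)
  }
  filter_and_rank(aggregate_conditions(tables), padj_max = padj_max, top_n = top_n)
}
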