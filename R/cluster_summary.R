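#' Combine p-values within a cluster
#'
#' Pools a vector of p-values with one of four classical combination
#' methods:
#' \describe{
#'   \item{fisher}{survival function of chi-squared(2k) at `-2 * sum(log p)`.}
#'   \item{stouffer}{upper tail of the standard normal at `sum(z) / sqrt(k)`
#'     with `z_i = qnorm(1 - p_i)`.}
#'   \item{weighted_z}{upper tail at `sum(w * z) / sqrt(sum(w^2))` (Liptak).}
#'   \item{cauchy}{`0.5 - atan(T) / pi` with
#'     `T = sum(w * tan((0.5 - p) * pi)) / sum(w)`; robust under dependence
#'     between the combined tests.}
#' }
#' All methods return exactly `p` for a single input. The result is clamped
#' into (0, 1].
#'
#' @param ps Numeric vector of p-values in (0, 1]; exact zeros are rejected
#'   (floor them first, see [cap_pvalue]).
#' @param method One of `"cauchy"`, `"fisher"`, `"stouffer"`, `"weighted_z"`.
#' @param weights Optional positive weights, same length as `ps`; used by
#'   `weighted_z` and `cauchy`, ignored by the unweighted methods. Default:
#'   equal weights.
#' @return A single pooled p-value in (0, 1].
#' @examples
#' pool_pvalues(c(0.5, 0.5), method = "fisher")   # 0.5965735
#' @export
pool_pvalues <- function(ps, method = c("cauchy", "fisher", "stouffer", "weighted_z"),
                         weights = NULL) {
  method <- match.arg(method)
  if (!length(ps)) stop("at least one p-value is required", call. = FALSE)
  if (any(is.na(ps)) || any(ps <= 0 | ps > 1)) {
    stop("p-values must lie in (0, 1]; floor exact zeros before pooling",
         call. = FALSE)
  }
  k <- length(ps)
  if (is.null(weights)) weights <- rep(1, k)
  if (length(weights) != k || any(is.na(weights)) || any(weights <= 0)) {
    stop("'weights' must be positive and match the length of 'ps'", call. = FALSE)
  }
  p <- switch(
    method,
    fisher = stats::pchisq(-2 * sum(log(ps)), df = 2 * k, lower.tail = FALSE),
    stouffer = {
      z <- stats::qnorm(ps, lower.tail = FALSE)
      stats::pnorm(sum(z) / sqrt(k), lower.tail = FALSE)
    },
    weighted_z = {
      z <- stats::qnorm(ps, lower.tail = FALSE)
      stats::pnorm(sum(weights * z) / sqrt(sum(weights^2)), lower.tail = FALSE)
    },
    cauchy = {
      t_stat <- sum(weights * tan((0.5 - ps) * pi)) / sum(weights)
      0.5 - atan(t_stat) / pi
    }
  )
  min(max(p, .Machine$double.xmin), 1)
}

#' Floor a p-value for display and numerical safety
#'
#' @param p Numeric vector of p-values.
#' @param floor Lower cap in (0, 1).
#' @return `pmax(p, floor)`.
#' @export
cap_pvalue <- function(p, floor) {
  if (!is.numeric(floor) || length(floor) != 1L || is.na(floor) ||
      floor <= 0 || floor >= 1) {
    stop("'floor' must be a single value in (0, 1)", call. = FALSE)
  }
  pmax(p, floor)
}

#' Pool enrichment evidence per cluster, condition and regulation
#'
#' Produces one summary row per (cluster, condition, regulation) cell with
#' at least one contributing hit. Within a cell, duplicate rows for the
#' same term (e.g. the same term retained from several databases) are
#' collapsed to the term's smallest p-value before pooling; genes are the
#' union over all rows of the cell. P-values are floored at `p_floor`
#' before pooling so the combination methods never see zero, and the pooled
#' value is capped at the same floor.
#'
#' @param hits Filtered hit table ([filter_and_rank]); every term must
#'   appear in `assignment`.
#' @param assignment A `cluster_assignment` from [walktrap_cluster].
#' @param method Pooling method, see [pool_pvalues]; default `"cauchy"`.
#' @param weights_rule `"overlap_size"` (weights = per-term overlap count
#'   `k`, the default) or `"equal"`; only `weighted_z` and `cauchy` are
#'   weight-sensitive.
#' @param p_floor Display floor applied before and after pooling.
#' @param use_adjusted Pool adjusted p-values (default) or raw ones.
#' @return Data frame with one row per cell: `cluster_id`, `annotation`
#'   (`NA` until [apply_annotations]), `condition`, `regulation`,
#'   `pooled_p`, `n_terms_total` (unique terms in the cluster),
#'   `n_terms_here` (terms contributing in this cell), `n_genes`, `genes`
#'   (list column of the cell's gene union).
#' @export
summarize_clusters <- function(hits, assignment,
                               method = c("cauchy", "fisher", "stouffer", "weighted_z"),
                               weights_rule = c("overlap_size", "equal"),
                               p_floor = 1e-10, use_adjusted = TRUE) {
  method <- match.arg(method)
  weights_rule <- match.arg(weights_rule)
  stopifnot(inherits(assignment, "cluster_assignment"))
  if (!is.data.frame(hits) || nrow(hits) == 0L) {
    stop("'hits' must be a non-empty hit table", call. = FALSE)
  }
  membership <- assignment$membership
  missing <- setdiff(unique(hits$term), names(membership))
  if (length(missing)) {
    stop("term(s) missing from the cluster assignment: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  cluster_sizes <- table(membership)
  hits$cluster_id <- as.integer(membership[hits$term])
  hits$p_use <- if (use_adjusted) hits$p_adj else hits$p_raw
  cells <- split(seq_len(nrow(hits)),
                 list(hits$cluster_id, hits$condition, hits$regulation),
                 drop = TRUE)
  rows <- lapply(cells, function(idx) {
    sub <- hits[idx, , drop = FALSE]
    # collapse duplicate term rows (same term kept from several databases)
    ord <- order(sub$p_use, -sub$k, sub$term)
    sub_best <- sub[ord, , drop = FALSE]
    sub_best <- sub_best[!duplicated(sub_best$term), , drop = FALSE]
    ps <- cap_pvalue(sub_best$p_use, p_floor)
    w <- if (weights_rule == "overlap_size") sub_best$k else NULL
    pooled <- cap_pvalue(pool_pvalues(ps, method = method, weights = w), p_floor)
    genes <- sort(unique(unlist(sub$overlap_genes, use.names = FALSE)))
    cl <- sub$cluster_id[[1]]
    data.frame(
      cluster_id = cl,
      annotation = NA_character_,
      condition = sub$condition[[1]],
      regulation = sub$regulation[[1]],
      pooled_p = pooled,
      n_terms_total = as.integer(cluster_sizes[[as.character(cl)]]),
      n_terms_here = nrow(sub_best),
      n_genes = length(genes),
      genes = I(list(genes)),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$cluster_id, out$condition, out$regulation), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build an annotation prompt for a language model
#'
#' Enumerates every cluster with its member terms (and, in the detailed
#' style, the databases each term came from) and asks for one short
#' biological label per cluster, to be returned as `cluster_id<TAB>label`
#' lines. The text is fully deterministic. When the clustering holds more
#' than `chunk_size` terms the prompt is split into numbered parts of at
#' most `chunk_size` terms each, since very long prompts tend to come back
#' incomplete.
#'
#' @param assignment A `cluster_assignment`.
#' @param hits Optional hit table used to attach database labels to terms
#'   (detailed style only).
#' @param style `"terse"` (one line per cluster) or `"detailed"` (one line
#'   per term with databases).
#' @param chunk_size Maximum number of terms per prompt part (default 200).
#' @return A single character string containing the prompt (all parts).
#' @export
build_annotation_prompt <- function(assignment, hits = NULL,
                                    style = c("terse", "detailed"),
                                    chunk_size = 200L) {
  style <- match.arg(style)
  stopifnot(inherits(assignment, "cluster_assignment"))
  if (!is_count(chunk_size, min = 1L)) {
    stop("'chunk_size' must be a positive integer", call. = FALSE)
  }
  membership <- assignment$membership
  clusters <- sort(unique(membership))
  term_db <- NULL
  if (!is.null(hits)) {
    term_db <- vapply(split(hits$database, hits$term),
                      function(d) paste(sort(unique(d)), collapse = ", "),
                      character(1))
  }
  entries <- do.call(rbind, lapply(clusters, function(cl) {
    data.frame(cluster_id = cl, term = sort(names(membership)[membership == cl]),
               stringsAsFactors = FALSE)
  }))
  n_chunks <- ceiling(nrow(entries) / chunk_size)
  entries$chunk <- ceiling(seq_len(nrow(entries)) / chunk_size)
  instruction <- paste(
    "You are given clusters of enriched gene-set terms from a transcriptomics analysis.",
    "For each cluster, reply with one short biological label summarizing its terms.",
    "Answer with one line per cluster, formatted exactly as 'cluster_id<TAB>label',",
    "using the numeric cluster id, and nothing else.", sep = "\n")
  parts <- vapply(seq_len(n_chunks), function(ch) {
    sub <- entries[entries$chunk == ch, , drop = FALSE]
    blocks <- vapply(unique(sub$cluster_id), function(cl) {
      terms <- sub$term[sub$cluster_id == cl]
      cont <- if (ch > 1L && cl %in% entries$cluster_id[entries$chunk < ch]) {
        " (continued)"
      } else ""
      if (style == "terse") {
        sprintf("Cluster %d%s: %s", cl, cont, paste(terms, collapse = "; "))
      } else {
        lines <- vapply(terms, function(t) {
          db <- if (!is.null(term_db) && t %in% names(term_db)) {
            sprintf(" [%s]", term_db[[t]])
          } else ""
          sprintf("  - %s%s", t, db)
        }, character(1))
        paste(c(sprintf("Cluster %d%s:", cl, cont), lines), collapse = "\n")
      }
    }, character(1))
    header <- if (n_chunks > 1L) {
      sprintf("Prompt part %d of %d.\n\n", ch, n_chunks)
    } else ""
    paste0(header, instruction, "\n\n", paste(blocks, collapse = "\n"))
  }, character(1))
  paste(parts, collapse = "\n\n")
}

#' Parse a language-model annotation reply
#'
#' Extracts `cluster_id<TAB>label` lines from a reply. Blank and
#' non-matching lines are ignored; a reply without any parseable line is an
#' error. When `assignment` is supplied, ids absent from the clustering are
#' reported with a warning and attached as attribute `unknown_ids`.
#'
#' @param text Character scalar or vector of reply lines.
#' @param assignment Optional `cluster_assignment` used to validate ids.
#' @return Named character vector, cluster id -> label.
#' @export
parse_annotation_reply <- function(text, assignment = NULL) {
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  m <- regmatches(lines, regexec("^[[:space:]]*([0-9]+)[[:space:]]*\t[[:space:]]*(.+?)[[:space:]]*$", lines))
  hits <- Filter(function(x) length(x) == 3L, m)
  if (!length(hits)) {
    stop("no 'cluster_id<TAB>label' line found in the reply", call. = FALSE)
  }
  ids <- vapply(hits, `[[`, character(1), 2L)
  labels <- vapply(hits, `[[`, character(1), 3L)
  if (anyDuplicated(ids)) {
    warning("duplicate cluster id(s) in reply; keeping the first occurrence",
            call. = FALSE)
    labels <- labels[!duplicated(ids)]
    ids <- ids[!duplicated(ids)]
  }
  map <- stats::setNames(labels, ids)
  if (!is.null(assignment)) {
    known <- as.character(sort(unique(assignment$membership)))
    unknown <- setdiff(ids, known)
    if (length(unknown)) {
      warning("reply contains unknown cluster id(s): ",
              paste(unknown, collapse = ", "), call. = FALSE)
    }
    attr(map, "unknown_ids") <- as.integer(unknown)
  }
  map
}

#' Apply cluster annotations to summary rows
#'
#' Fills the `annotation` column from a cluster id -> label map; clusters
#' without a label get the placeholder `"Cluster <id>"`. Re-applying with a
#' new map overwrites previous labels.
#'
#' @param rows Summary rows from [summarize_clusters] (or any data frame
#'   with a `cluster_id` column).
#' @param map Named character vector (names = cluster ids) as returned by
#'   [parse_annotation_reply], or an empty map.
#' @return `rows` with the `annotation` column filled.
#' @export
apply_annotations <- function(rows, map = character(0)) {
  stopifnot(is.data.frame(rows), "cluster_id" %in% names(rows))
  ids <- as.character(rows$cluster_id)
  rows$annotation <- ifelse(ids %in% names(map), unname(map[ids]),
                            sprintf("Cluster %s", ids))
  rows
}

#' Per-term cluster coherence
#'
#' For every term in a cluster of two or more terms, computes the Jaccard
#' similarity between the term's gene set and the union of the gene sets of
#' the other members of its cluster. Singleton terms have no defined value.
#' The mean over defined values summarizes how gene-coherent a clustering
#' is and allows comparison between alternative partitions of the same
#' terms.
#'
#' @param map Term -> gene map from [build_term_gene_map].
#' @param assignment A `cluster_assignment` (or named membership vector)
#'   covering every term in `map`.
#' @return Object of class `coherence_report`: list with `per_term` (data
#'   frame `term`, `cluster_id`, `jaccard_vs_rest`; `NA` for singletons)
#'   and `mean_jaccard` (`NA` when every cluster is a singleton).
#' @export
term_coherence <- function(map, assignment) {
  membership <- if (inherits(assignment, "cluster_assignment")) {
    assignment$membership
  } else assignment
  missing <- setdiff(names(map), names(membership))
  if (length(missing)) {
    stop("assignment does not cover term(s): ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  terms <- names(map)
  cl <- membership[terms]
  jac <- vapply(seq_along(terms), function(i) {
    others <- terms[cl == cl[[i]] & terms != terms[[i]]]
    if (!length(others)) return(NA_real_)
    jaccard_similarity(map[[i]], unique(unlist(map[others], use.names = FALSE)))
  }, numeric(1))
  per_term <- data.frame(term = terms, cluster_id = as.integer(cl),
                         jaccard_vs_rest = jac, stringsAsFactors = FALSE)
  defined <- jac[!is.na(jac)]
  structure(list(per_term = per_term,
                 mean_jaccard = if (length(defined)) mean(defined) else NA_real_),
            class = "coherence_report")
}

#' @export
print.coherence_report <- function(x, ...) {
  n_def <- sum(!is.na(x$per_term$jaccard_vs_rest))
  cat(sprintf("<coherence_report> %d term(s), %d in multi-term clusters; mean Jaccard %s\n",
              nrow(x$per_term), n_def,
              if (is.na(x$mean_jaccard)) "undefined" else
                sprintf("%.4f", x$mean_jaccard)))
  invisible(x)
}
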