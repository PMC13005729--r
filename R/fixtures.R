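#' Synthetic benchmark with planted cluster structure
#'
#' Generates a gene-set library and per-condition gene lists in which the
#' true term clustering is known, so that every pipeline stage can be
#' validated offline. Terms are organized in `n_blocks` blocks of
#' `terms_per_block` terms. Each term holds `genes_per_term` genes composed
#' of (i) a small globally shared pool sized so that cross-block term pairs
#' have Jaccard similarity close to `between_block_overlap`, (ii) a
#' block-core shared by all terms of the block, and (iii) term-unique genes
#' sized so that within-block pairs have Jaccard similarity close to
#' `within_block_overlap`. Blocks are assigned to conditions round-robin;
#' each condition's gene list is the union of its blocks' genes plus
#' `noise_genes` random genes outside the library background, with random
#' log2 fold-changes attached.
#'
#' The same seed always produces byte-identical output.
#'
#' @param n_blocks Number of planted blocks (true clusters).
#' @param terms_per_block Terms per block.
#' @param genes_per_term Genes per term.
#' @param within_block_overlap Target Jaccard similarity of term pairs in
#'   the same block (must exceed `between_block_overlap`).
#' @param between_block_overlap Target Jaccard similarity of term pairs in
#'   different blocks (0 gives fully disjoint blocks).
#' @param n_conditions Number of conditions; condition `i` is assigned
#'   block `((i - 1) mod n_blocks) + 1`.
#' @param noise_genes Number of random off-library genes added to each
#'   condition's list.
#' @param seed Integer seed; the generator calls `set.seed(seed)`.
#' @return List with `library` (a [gene_set_library]), `conditions` (data
#'   frame with columns `gene`, `condition`, `log2fc`) and `truth` (list
#'   with `blocks` = block name -> term names, `term_block` = named vector
#'   term -> block index, `condition_blocks`, and the generator `params`).
#' @export
generate_fixture <- function(n_blocks = 3L, terms_per_block = 4L,
                             genes_per_term = 30L,
                             within_block_overlap = 0.8,
                             between_block_overlap = 0.05,
                             n_conditions = 4L, noise_genes = 25L,
                             seed = 1L) {
  stopifnot(is_count(n_blocks), is_count(terms_per_block),
            is_count(genes_per_term), is_count(n_conditions),
            is_count(noise_genes, min = 0L))
  if (!is_prob(within_block_overlap) || !is_prob(between_block_overlap)) {
    stop("overlap fractions must lie in [0, 1]", call. = FALSE)
  }
  if (within_block_overlap <= between_block_overlap) {
    stop("'within_block_overlap' must exceed 'between_block_overlap'",
         call. = FALSE)
  }
  g <- genes_per_term
  # term = shared pool (s) + block core (c) + unique tail (u); within-block
  # Jaccard = (g - u) / (g + u), cross-block Jaccard = s / (2g - s)
  u <- round(g * (1 - within_block_overlap) / (1 + within_block_overlap))
  s <- round(2 * g * between_block_overlap / (1 + between_block_overlap))
  c_core <- g - u - s
  if (c_core < 1L) {
    stop("overlap fractions incompatible with 'genes_per_term': no room for a block core",
         call. = FALSE)
  }
  set.seed(seed)
  shared <- if (s > 0L) sprintf("SHARED%03d", seq_len(s)) else character(0)
  sets <- list()
  blocks <- list()
  term_block <- integer(0)
  for (b in seq_len(n_blocks)) {
    core <- sprintf("B%02dCORE%03d", b, seq_len(c_core))
    terms <- character(terms_per_block)
    for (t in seq_len(terms_per_block)) {
      term <- sprintf("B%02d_T%02d", b, t)
      uniq <- if (u > 0L) sprintf("B%02dT%02dU%03d", b, t, seq_len(u)) else character(0)
      sets[[term]] <- c(shared, core, uniq)
      terms[[t]] <- term
    }
    blocks[[sprintf("block%02d", b)]] <- terms
    term_block <- c(term_block, stats::setNames(rep(b, terms_per_block), terms))
  }
  library <- gene_set_library(sets, name = "synthetic_db")
  noise_pool <- sprintf("NOISE%04d", seq_len(max(10L * noise_genes, 1L)))
  condition_blocks <- stats::setNames(
    ((seq_len(n_conditions) - 1L) %% n_blocks) + 1L,
    sprintf("cond%d", seq_len(n_conditions)))
  cond_rows <- lapply(names(condition_blocks), function(cond) {
    b <- condition_blocks[[cond]]
    genes <- sort(unique(unlist(sets[blocks[[sprintf("block%02d", b)]]],
                                use.names = FALSE)))
    if (noise_genes > 0L) {
      genes <- c(genes, sort(sample(noise_pool, noise_genes)))
    }
    lfc <- round(stats::runif(length(genes), 0.5, 3), 3) *
      sample(c(-1, 1), length(genes), replace = TRUE)
    data.frame(gene = genes, condition = cond, log2fc = lfc,
               stringsAsFactors = FALSE)
  })
  conditions <- do.call(rbind, cond_rows)
  rownames(conditions) <- NULL
  list(
    library = library,
    conditions = conditions,
    truth = list(
      blocks = blocks,
      term_block = term_block,
      condition_blocks = condition_blocks,
      params = list(n_blocks = n_blocks, terms_per_block = terms_per_block,
                    genes_per_term = genes_per_term,
                    within_block_overlap = within_block_overlap,
                    between_block_overlap = between_block_overlap,
                    n_conditions = n_conditions, noise_genes = noise_genes,
                    seed = seed)
    )
  )
}

#' Write a generated fixture to disk
#'
#' Writes the condition table as CSV and the library as GMT, so the
#' file-based pipeline entry points can be exercised.
#'
#' @param fixture Result of [generate_fixture].
#' @param dir Output directory (created if needed).
#' @return Named character vector with elements `conditions` and `gmt`.
#' @export
write_fixture <- function(fixture, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cond_path <- file.path(dir, "conditions.csv")
  utils::write.table(fixture$conditions, cond_path, sep = ",",
                     row.names = FALSE, qmethod = "double")
  gmt_path <- file.path(dir, paste0(fixture$library$name, ".gmt"))
  write_gmt(fixture$library, gmt_path)
  c(conditions = cond_path, gmt = gmt_path)
}
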