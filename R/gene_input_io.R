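#' Per-condition gene list
#'
#' Lightweight container for one experimental condition's input genes and,
#' optionally, their log2 fold-changes. Gene symbols are normalized (trimmed,
#' upper-cased) and deduplicated; the stored set is sorted so that equal sets
#' compare equal regardless of input row order.
#'
#' @param condition Condition label (non-empty string).
#' @param genes Character vector of gene symbols.
#' @param log2fc Optional named numeric vector of log2 fold-changes; every
#'   name must be one of `genes` (after normalization).
#'
#' @return An object of class `condition_genes` with fields `condition`,
#'   `genes` (sorted unique symbols) and `log2fc` (named numeric or `NULL`).
#' @export
condition_genes <- function(condition, genes, log2fc = NULL) {
  condition <- trim_ws(as.character(condition))
  if (length(condition) != 1L || is.na(condition) || condition == "") {
    stop("'condition' must be a single non-empty label", call. = FALSE)
  }
  genes <- normalize_symbols(as.character(genes))
  genes <- genes[genes != ""]
  genes <- sort(unique(genes))
  if (!is.null(log2fc)) {
    if (is.null(names(log2fc))) {
      stop("'log2fc' must be a named numeric vector", call. = FALSE)
    }
    names(log2fc) <- normalize_symbols(names(log2fc))
    log2fc <- log2fc[!duplicated(names(log2fc))]
    extra <- setdiff(names(log2fc), genes)
    if (length(extra)) {
      stop("log2fc given for genes absent from the list: ",
           paste(utils::head(extra, 5), collapse = ", "), call. = FALSE)
    }
    log2fc <- log2fc[intersect(genes, names(log2fc))]
  }
  structure(list(condition = condition, genes = genes, log2fc = log2fc),
            class = "condition_genes")
}

#' @export
print.condition_genes <- function(x, ...) {
  cat(sprintf("<condition_genes> '%s': %d gene(s)%s\n", x$condition,
              length(x$genes),
              if (is.null(x$log2fc)) "" else " with log2 fold-changes"))
  invisible(x)
}

#' Gene-set library
#'
#' A named collection of gene sets (term name -> set of gene symbols) with a
#' background universe, as used by over-representation analysis. The
#' background defaults to the union of all member sets and may be widened by
#' the caller; it can never be narrower than that union.
#'
#' @param sets Named list of character vectors (term name -> gene symbols).
#' @param name Database label attached to every result derived from this
#'   library (e.g. `"GO_Biological_Process"`).
#' @param background Optional character vector of background gene symbols;
#'   must contain every gene appearing in `sets`.
#'
#' @return An object of class `gene_set_library` with fields `name`, `sets`
#'   and `background`.
#' @export
gene_set_library <- function(sets, name = "custom", background = NULL) {
  if (!is.list(sets) || length(sets) == 0L) {
    stop("'sets' must be a non-empty named list of gene vectors", call. = FALSE)
  }
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    stop("every gene set must be named", call. = FALSE)
  }
  if (anyDuplicated(names(sets))) {
    stop("duplicate term name(s): ",
         paste(unique(names(sets)[duplicated(names(sets))]), collapse = ", "),
         call. = FALSE)
  }
  sets <- lapply(sets, function(g) sort(unique(normalize_symbols(as.character(g)))))
  if (any(lengths(sets) == 0L)) {
    empty <- names(sets)[lengths(sets) == 0L]
    stop("term(s) with empty gene set: ", paste(empty, collapse = ", "),
         call. = FALSE)
  }
  auto_bg <- sort(unique(unlist(sets, use.names = FALSE)))
  if (is.null(background)) {
    background <- auto_bg
  } else {
    background <- sort(unique(normalize_symbols(as.character(background))))
    missing <- setdiff(auto_bg, background)
    if (length(missing)) {
      stop("background must contain every library gene; missing: ",
           paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
    }
  }
  structure(list(name = as.character(name), sets = sets, background = background),
            class = "gene_set_library")
}

#' @export
print.gene_set_library <- function(x, ...) {
  cat(sprintf("<gene_set_library> '%s': %d term(s), background of %d gene(s)\n",
              x$name, length(x$sets), length(x$background)))
  invisible(x)
}

# Split a validated data frame of (gene, condition[, log2fc]) rows into one
# condition_genes object per distinct condition label, keeping the first
# log2FC on duplicate genes (with a warning).
condition_lists_from_frame <- function(df, gene_col = "gene",
                                       condition_col = "condition",
                                       logfc_col = NULL) {
  needed <- c(gene_col, condition_col, logfc_col)
  absent <- setdiff(needed, names(df))
  if (length(absent)) {
    stop("missing column(s): ", paste(absent, collapse = ", "), call. = FALSE)
  }
  if (nrow(df) == 0L) stop("input table has no data rows", call. = FALSE)
  genes <- normalize_symbols(as.character(df[[gene_col]]))
  conds <- trim_ws(as.character(df[[condition_col]]))
  bad_gene <- which(is.na(genes) | genes == "")
  if (length(bad_gene)) {
    stop("empty gene symbol in row(s): ",
         paste(utils::head(bad_gene, 5), collapse = ", "), call. = FALSE)
  }
  bad_cond <- which(is.na(conds) | conds == "")
  if (length(bad_cond)) {
    stop("empty condition label in row(s): ",
         paste(utils::head(bad_cond, 5), collapse = ", "), call. = FALSE)
  }
  lfc <- NULL
  if (!is.null(logfc_col)) {
    raw <- trim_ws(as.character(df[[logfc_col]]))
    lfc <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(lfc))
    if (length(bad)) {
      stop("non-numeric log2 fold-change in row(s): ",
           paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
    }
  }
  out <- list()
  for (cond in unique(conds)) {
    idx <- which(conds == cond)
    dup <- duplicated(genes[idx])
    if (any(dup)) {
      warning(sprintf("condition '%s': %d duplicate gene(s) collapsed, first log2FC kept",
                      cond, sum(dup)), call. = FALSE)
    }
    keep <- idx[!dup]
    out[[cond]] <- condition_genes(
      condition = cond,
      genes = genes[keep],
      log2fc = if (!is.null(lfc)) stats::setNames(lfc[keep], genes[keep])
    )
  }
  out
}

#' Read a gene/condition input table
#'
#' Reads a delimited text table with one row per (gene, condition) pair and
#' an optional log2 fold-change column, and partitions it into one
#' [condition_genes] list per distinct condition. The delimiter (comma or
#' tab) is auto-detected from the header line. Duplicate genes within a
#' condition are collapsed with a warning, keeping the first log2FC seen.
#'
#' @param path Path to a CSV or TSV file with a header row.
#' @param gene_col,condition_col Names of the gene-symbol and condition-label
#'   columns.
#' @param logfc_col Optional name of the log2 fold-change column; when given
#'   every cell must be numeric.
#'
#' @return Named list of [condition_genes], one element per condition.
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' writeLines(c("gene,condition,lfc", "TNF,stim,2.1", "IL6,stim,-1.4"), tf)
#' read_condition_table(tf, logfc_col = "lfc")
#' @export
read_condition_table <- function(path, gene_col = "gene",
                                 condition_col = "condition",
                                 logfc_col = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  header <- readLines(path, n = 1L, warn = FALSE)
  if (length(header) == 0L || !nzchar(trim_ws(header))) {
    stop("empty input file: ", path, call. = FALSE)
  }
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character", comment.char = "")
  condition_lists_from_frame(df, gene_col, condition_col, logfc_col)
}

#' Read a GMT gene-set library
#'
#' Parses the standard GMT format: one tab-separated line per gene set with
#' fields name, description (ignored) and one or more member genes. Gene
#' symbols are normalized to trimmed upper case; the background defaults to
#' the union of all sets.
#'
#' @param path Path to a GMT file.
#' @param name Database label for the resulting library; defaults to the
#'   file name without extension.
#' @param background Optional wider background universe (see
#'   [gene_set_library]).
#'
#' @return A [gene_set_library].
#' @export
read_gmt <- function(path, name = NULL, background = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trim_ws(lines))]
  if (!length(lines)) stop("empty GMT file: ", path, call. = FALSE)
  sets <- list()
  for (i in seq_along(lines)) {
    # sentinel keeps trailing empty fields visible to strsplit
    fields <- strsplit(paste0(lines[[i]], "\x01"), "\t", fixed = TRUE)[[1]]
    fields[length(fields)] <- sub("\x01$", "", fields[length(fields)])
    if (length(fields) < 3L) {
      stop(sprintf("GMT format error at line %d: expected >= 3 tab-separated fields", i),
           call. = FALSE)
    }
    term <- trim_ws(fields[[1]])
    genes <- trim_ws(fields[-(1:2)])
    if (any(genes == "")) {
      stop(sprintf("GMT format error at line %d: empty gene field", i),
           call. = FALSE)
    }
    if (term %in% names(sets)) {
      stop(sprintf("duplicate term name '%s' at line %d", term, i), call. = FALSE)
    }
    sets[[term]] <- genes
  }
  if (is.null(name)) name <- tools::file_path_sans_ext(basename(path))
  gene_set_library(sets, name = name, background = background)
}

#' Write a gene-set library in GMT format
#'
#' @param library A [gene_set_library].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(library, path) {
  stopifnot(inherits(library, "gene_set_library"))
  lines <- vapply(names(library$sets), function(term) {
    paste(c(term, library$name, library$sets[[term]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

results_table_columns <- c("cluster_id", "annotation", "term", "database",
                           "condition", "regulation", "overlap_genes",
                           "p_raw", "p_adj", "pooled_p")

#' Write the full results table
#'
#' Serializes the per-term results table (cluster membership, annotation,
#' enrichment statistics and pooled cluster p-value) as CSV. Gene sets are
#' joined with `";"` in sorted order and numeric columns are printed with
#' full precision so that [read_results_table] round-trips exactly.
#'
#' @param rows Data frame with columns `cluster_id`, `annotation`, `term`,
#'   `database`, `condition`, `regulation`, `overlap_genes` (list column or
#'   `";"`-joined strings), `p_raw`, `p_adj`, `pooled_p`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_results_table <- function(rows, path) {
  if (!is.data.frame(rows) || nrow(rows) == 0L) {
    stop("'rows' must be a non-empty data frame", call. = FALSE)
  }
  absent <- setdiff(results_table_columns, names(rows))
  if (length(absent)) {
    stop("missing result column(s): ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  out <- rows[results_table_columns]
  if (is.list(out$overlap_genes)) {
    out$overlap_genes <- vapply(out$overlap_genes,
                                function(g) paste(sort(unique(g)), collapse = ";"),
                                character(1))
  }
  for (col in c("p_raw", "p_adj", "pooled_p")) {
    out[[col]] <- sprintf("%.17g", rows[[col]])
  }
  out$cluster_id <- as.integer(rows$cluster_id)
  ok <- tryCatch({
    utils::write.table(out, path, sep = ",", row.names = FALSE, qmethod = "double")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write results table to ", path, ": ",
                        conditionMessage(ok), call. = FALSE)
  invisible(path)
}

#' Read back a results table written by [write_results_table]
#'
#' @param path Path to a results CSV.
#' @return Data frame with the same columns and types as the in-memory
#'   results table (`overlap_genes` as a list column of sorted symbols).
#' @export
read_results_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = ",", quote = "\"",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character", comment.char = "")
  absent <- setdiff(results_table_columns, names(df))
  if (length(absent)) {
    stop("not a results table, missing column(s): ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  df$cluster_id <- as.integer(df$cluster_id)
  for (col in c("p_raw", "p_adj", "pooled_p")) df[[col]] <- as.numeric(df[[col]])
  df$overlap_genes <- I(lapply(strsplit(df$overlap_genes, ";", fixed = TRUE),
                               function(g) sort(g[nzchar(g)])))
  df
}

#' Fetch a library from the Enrichr web service (optional, needs network)
#'
#' Thin adapter that downloads one Enrichr library in GMT text form and
#' returns it through the same [gene_set_library] interface as [read_gmt].
#' It is a convenience for interactive use only: it requires network access
#' and is deliberately not exercised by the automated tests; the offline GMT
#' path is the supported contract.
#'
#' @param library_name Enrichr library identifier, e.g.
#'   `"GO_Biological_Process_2023"`.
#' @param base_url Service endpoint returning tab-separated gene-set lines.
#' @return A [gene_set_library].
#' @export
fetch_enrichr_library <- function(library_name,
                                  base_url = "https://maayanlab.cloud/Enrichr/geneSetLibrary?mode=text&libraryName=") {
  url <- paste0(base_url, utils::URLencode(library_name, reserved = TRUE))
  tmp <- tempfile(fileext = ".gmt")
  on.exit(unlink(tmp), add = TRUE)
  utils::download.file(url, tmp, quiet = TRUE)
  read_gmt(tmp, name = library_name)
}
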