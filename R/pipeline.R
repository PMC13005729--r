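#' Pipeline configuration
#'
#' Collects and validates every knob of the end-to-end workflow. Input may
#' be given as file paths (`conditions_file`, `gmt_files`) or as in-memory
#' objects (`conditions` data frame, `libraries` list), which is what the
#' synthetic benchmark uses.
#'
#' @param conditions_file Path to a gene/condition table (CSV or TSV).
#' @param conditions In-memory data frame alternative to `conditions_file`.
#' @param gmt_files Character vector of GMT paths.
#' @param libraries List of [gene_set_library] objects (alternative to
#'   `gmt_files`).
#' @param gene_col,condition_col,logfc_col Column names of the input table.
#' @param logfc_threshold Optional log2FC threshold enabling the up/down
#'   split; `NULL` analyses each condition as a single list.
#' @param min_genes,padj_max,top_n,adjust_method Enrichment filters, see
#'   [enrich_condition] and [filter_and_rank].
#' @param ts Jaccard pruning threshold, see [build_term_graph].
#' @param walk_length Walktrap walk length.
#' @param pool_method,weights_rule,p_floor,use_adjusted Pooling options, see
#'   [summarize_clusters].
#' @param annotations_file Optional path to a `cluster_id<TAB>label` reply
#'   file applied to the summary.
#' @param ts_grid Optional numeric vector; when given, a threshold profile
#'   is computed and written.
#' @param out_dir Output directory for all result files.
#' @param make_plots Render heatmap/bubble (and profile) figures.
#' @param seed Non-negative integer recorded in the manifest and used for
#'   any randomized step.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(conditions_file = NULL, conditions = NULL,
                            gmt_files = NULL, libraries = NULL,
                            gene_col = "gene", condition_col = "condition",
                            logfc_col = NULL, logfc_threshold = NULL,
                            min_genes = 2L, padj_max = 0.05, top_n = 5L,
                            adjust_method = "BH", ts = 0.3, walk_length = 4L,
                            pool_method = "cauchy",
                            weights_rule = "overlap_size", p_floor = 1e-10,
                            use_adjusted = TRUE, annotations_file = NULL,
                            ts_grid = NULL, out_dir = tempfile("enrichclust_run_"),
                            make_plots = TRUE, seed = 1L) {
  if (is.null(conditions_file) && is.null(conditions)) {
    stop("one of 'conditions_file' or 'conditions' is required", call. = FALSE)
  }
  if (is.null(gmt_files) && is.null(libraries)) {
    stop("one of 'gmt_files' or 'libraries' is required", call. = FALSE)
  }
  if (!is_prob(ts)) stop("'ts' must lie in [0, 1]", call. = FALSE)
  if (!is.numeric(p_floor) || p_floor <= 0 || p_floor >= 1) {
    stop("'p_floor' must lie in (0, 1)", call. = FALSE)
  }
  if (!is_count(seed, min = 0L)) {
    stop("'seed' must be a non-negative integer", call. = FALSE)
  }
  structure(list(
    conditions_file = conditions_file, conditions = conditions,
    gmt_files = gmt_files, libraries = libraries,
    gene_col = gene_col, condition_col = condition_col,
    logfc_col = logfc_col, logfc_threshold = logfc_threshold,
    min_genes = min_genes, padj_max = padj_max, top_n = top_n,
    adjust_method = adjust_method, ts = ts, walk_length = walk_length,
    pool_method = pool_method, weights_rule = weights_rule,
    p_floor = p_floor, use_adjusted = use_adjusted,
    annotations_file = annotations_file, ts_grid = ts_grid,
    out_dir = out_dir, make_plots = make_plots, seed = as.integer(seed)
  ), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys match the arguments of
#'   [pipeline_config].
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(pipeline_config, vals)
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[stage %s] %s", stage, conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full enrichment-clustering workflow
#'
#' Executes read -> enrich -> filter/rank -> similarity graph -> Walktrap
#' -> pooling -> annotation -> export. All outputs land in
#' `config$out_dir`:
#' `results_table.csv` (per-term rows with cluster ids and pooled
#' p-values), `cluster_summary.csv`, `term_graph.graphml`,
#' `term_graph.json`, `annotation_prompt.txt`, optional
#' `threshold_profile.csv`, optional figures, and `manifest.json`
#' recording every parameter, per-stage counts and output checksums. On
#' error, files already written for this run are removed.
#'
#' @param config A [pipeline_config].
#' @return Invisibly, a list with `hits`, `term_gene_map`, `graph`,
#'   `assignment`, `summary`, `profile` (or `NULL`) and `files` (named
#'   vector of output paths).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  set.seed(config$seed)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  ok <- FALSE
  on.exit(if (!ok) unlink(written), add = TRUE)
  out <- function(name) file.path(config$out_dir, name)

  cond_lists <- with_stage("read_input", {
    if (!is.null(config$conditions)) {
      condition_lists_from_frame(config$conditions, config$gene_col,
                                 config$condition_col, config$logfc_col)
    } else {
      read_condition_table(config$conditions_file, config$gene_col,
                           config$condition_col, config$logfc_col)
    }
  })
  libraries <- with_stage("read_libraries", {
    if (!is.null(config$libraries)) {
      libs <- config$libraries
      if (inherits(libs, "gene_set_library")) libs <- list(libs)
      libs
    } else {
      lapply(config$gmt_files, read_gmt)
    }
  })
  message(sprintf("read %d condition(s) and %d librar%s",
                  length(cond_lists), length(libraries),
                  if (length(libraries) == 1L) "y" else "ies"))

  hits <- with_stage("enrichment", {
    run_enrichment(cond_lists, libraries,
                   logfc_threshold = config$logfc_threshold,
                   min_genes = config$min_genes, padj_max = config$padj_max,
                   top_n = config$top_n, adjust_method = config$adjust_method)
  })
  message(sprintf("retained %d hit(s) over %d unique term(s)",
                  nrow(hits), length(unique(hits$term))))

  map <- with_stage("term_graph", build_term_gene_map(hits))
  graph <- with_stage("term_graph", build_term_graph(map, ts = config$ts))
  assignment <- with_stage("clustering",
                           walktrap_cluster(graph, walk_length = config$walk_length))
  message(sprintf("found %d cluster(s) at ts = %g", max(assignment$membership),
                  config$ts))

  summary_rows <- with_stage("pooling", {
    summarize_clusters(hits, assignment, method = config$pool_method,
                       weights_rule = config$weights_rule,
                       p_floor = config$p_floor,
                       use_adjusted = config$use_adjusted)
  })
  ann_map <- character(0)
  if (!is.null(config$annotations_file)) {
    ann_map <- with_stage("annotation", {
      parse_annotation_reply(readLines(config$annotations_file, warn = FALSE),
                             assignment)
    })
  }
  summary_rows <- apply_annotations(summary_rows, ann_map)

  files <- c()
  emit <- function(name, writer) {
    path <- out(name)
    writer(path)
    written <<- c(written, path)
    files[[name]] <<- path
    path
  }

  with_stage("export", {
    prompt <- build_annotation_prompt(assignment, hits, style = "detailed")
    emit("annotation_prompt.txt", function(p) writeLines(prompt, p))

    ann_by_cluster <- stats::setNames(summary_rows$annotation,
                                      summary_rows$cluster_id)
    results <- hits
    results$cluster_id <- as.integer(assignment$membership[results$term])
    results$annotation <- unname(ann_by_cluster[as.character(results$cluster_id)])
    pooled_key <- paste(summary_rows$cluster_id, summary_rows$condition,
                        summary_rows$regulation, sep = "\r")
    res_key <- paste(results$cluster_id, results$condition,
                     results$regulation, sep = "\r")
    results$pooled_p <- summary_rows$pooled_p[match(res_key, pooled_key)]
    emit("results_table.csv", function(p) write_results_table(results, p))

    sum_out <- summary_rows
    sum_out$genes <- vapply(sum_out$genes,
                            function(g) paste(g, collapse = ";"), character(1))
    emit("cluster_summary.csv", function(p) {
      utils::write.table(sum_out, p, sep = ",", row.names = FALSE,
                         qmethod = "double")
    })
    emit("term_graph.graphml",
         function(p) export_graph(graph, assignment, p, format = "graphml"))
    emit("term_graph.json",
         function(p) export_graph(graph, assignment, p, format = "json"))
  })

  profile <- NULL
  if (!is.null(config$ts_grid)) {
    profile <- with_stage("threshold_profile", {
      evaluate_thresholds(map, config$ts_grid,
                          walk_length = config$walk_length)
    })
    emit("threshold_profile.csv", function(p) {
      utils::write.table(as.data.frame(profile), p, sep = ",",
                         row.names = FALSE, qmethod = "double")
    })
  }

  if (isTRUE(config$make_plots)) {
    with_stage("figures", {
      emit("heatmap.png", function(p) {
        render_figure(heatmap_bundle(summary_rows), p)
      })
      emit("bubble.png", function(p) {
        render_figure(bubble_table(summary_rows), p)
      })
      if (!is.null(profile)) {
        emit("threshold_profile.png", function(p) render_figure(profile, p))
      }
    })
  }

  with_stage("manifest", {
    params <- config[setdiff(names(config), c("conditions", "libraries"))]
    params <- params[!vapply(params, is.null, logical(1))]
    manifest <- list(
      package = "enrichclust",
      version = as.character(utils::packageVersion("enrichclust")),
      parameters = params,
      counts = list(
        conditions = length(cond_lists),
        libraries = length(libraries),
        hits_retained = nrow(hits),
        unique_terms = length(unique(hits$term)),
        clusters = max(assignment$membership)
      ),
      library_checksums = if (!is.null(config$gmt_files)) {
        as.list(tools::md5sum(config$gmt_files))
      } else {
        lapply(libraries, function(l) length(l$sets))
      },
      output_checksums = as.list(tools::md5sum(unname(unlist(files))))
    )
    emit("manifest.json", function(p) {
      jsonlite::write_json(manifest, p, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE)
    })
  })

  ok <- TRUE
  invisible(list(hits = hits, term_gene_map = map, graph = graph,
                 assignment = assignment, summary = summary_rows,
                 profile = profile, files = unlist(files)))
}
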