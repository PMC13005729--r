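#' Plot-ready heatmap structure
#'
#' Builds the clusters x condition-cells matrix of `-log10(pooled_p)` (0
#' where a cluster has no evidence in a cell), together with optional
#' hierarchical orderings of rows and columns (average linkage on Euclidean
#' distance) and a per-cluster bar of total term counts. Column cells are
#' labeled `condition` or `condition (up)` / `condition (down)` when a
#' regulation split is present.
#'
#' @param rows Summary rows from [summarize_clusters], annotated via
#'   [apply_annotations] (placeholders are fine).
#' @param cluster_rows,cluster_cols Reorder rows/columns by hierarchical
#'   clustering (identity order when a dimension has fewer than 3 entries).
#' @return Object of class `heatmap_bundle`: list with `matrix`,
#'   `row_order`, `col_order` (integer permutations), `row_bar` (term count
#'   per cluster, aligned with matrix rows) and `cluster_id`.
#' @export
heatmap_bundle <- function(rows, cluster_rows = TRUE, cluster_cols = TRUE) {
  if (!is.data.frame(rows) || nrow(rows) == 0L) {
    stop("'rows' must be non-empty summary rows", call. = FALSE)
  }
  if (!"annotation" %in% names(rows) || anyNA(rows$annotation)) {
    rows <- apply_annotations(rows)
  }
  col_label <- ifelse(rows$regulation == "all", rows$condition,
                      sprintf("%s (%s)", rows$condition, rows$regulation))
  # one display label per cluster, made unique defensively
  lab_by_cluster <- tapply(rows$annotation, rows$cluster_id, `[[`, 1L)
  cluster_ids <- sort(as.integer(names(lab_by_cluster)))
  row_labels <- make.unique(unname(lab_by_cluster[as.character(cluster_ids)]))
  col_labels <- sort(unique(col_label))
  mat <- matrix(0, nrow = length(cluster_ids), ncol = length(col_labels),
                dimnames = list(row_labels, col_labels))
  ri <- match(rows$cluster_id, cluster_ids)
  ci <- match(col_label, col_labels)
  mat[cbind(ri, ci)] <- -log10(rows$pooled_p)
  row_bar <- stats::setNames(
    vapply(cluster_ids, function(cl) {
      as.integer(rows$n_terms_total[rows$cluster_id == cl][[1]])
    }, integer(1)),
    row_labels)
  order_of <- function(m, enabled) {
    if (!enabled || nrow(m) < 3L) return(seq_len(nrow(m)))
    stats::hclust(stats::dist(m, method = "euclidean"), method = "average")$order
  }
  structure(list(matrix = mat,
                 row_order = order_of(mat, cluster_rows),
                 col_order = order_of(t(mat), cluster_cols),
                 row_bar = row_bar,
                 cluster_id = cluster_ids),
            class = "heatmap_bundle")
}

#' Bubble-plot table
#'
#' One bubble per summary row: position (condition-cell x annotation),
#' size `-log10(pooled_p)` and color the number of enriched genes.
#'
#' @param rows Annotated summary rows (see [heatmap_bundle]).
#' @return Data frame of class `bubble_table` with columns `condition`,
#'   `regulation`, `annotation`, `size`, `n_genes`.
#' @export
bubble_table <- function(rows) {
  if (!is.data.frame(rows) || nrow(rows) == 0L) {
    stop("'rows' must be non-empty summary rows", call. = FALSE)
  }
  if (!"annotation" %in% names(rows) || anyNA(rows$annotation)) {
    rows <- apply_annotations(rows)
  }
  out <- data.frame(condition = rows$condition,
                    regulation = rows$regulation,
                    annotation = rows$annotation,
                    size = -log10(rows$pooled_p),
                    n_genes = rows$n_genes,
                    stringsAsFactors = FALSE)
  class(out) <- c("bubble_table", "data.frame")
  out
}

heatmap_long_table <- function(bundle) {
  mat <- bundle$matrix
  data.frame(
    cluster = rep(rownames(mat), times = ncol(mat)),
    cell = rep(colnames(mat), each = nrow(mat)),
    neg_log10_p = as.vector(mat),
    stringsAsFactors = FALSE
  )
}

plot_heatmap <- function(bundle) {
  long <- heatmap_long_table(bundle)
  row_levels <- rownames(bundle$matrix)[bundle$row_order]
  col_levels <- colnames(bundle$matrix)[bundle$col_order]
  long$cluster <- factor(long$cluster, levels = rev(row_levels))
  long$cell <- factor(long$cell, levels = col_levels)
  tiles <- ggplot2::ggplot(long, ggplot2::aes(x = .data$cell, y = .data$cluster,
                                              fill = .data$neg_log10_p)) +
    ggplot2::geom_tile(color = "grey85") +
    ggplot2::scale_fill_gradient(low = "white", high = "#b2182b",
                                 name = expression(-log[10] ~ "pooled" ~ italic(P))) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal(base_size = 10) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
  bars <- data.frame(cluster = factor(names(bundle$row_bar),
                                      levels = rev(row_levels)),
                     n_terms = as.integer(bundle$row_bar))
  bar_panel <- ggplot2::ggplot(bars, ggplot2::aes(x = .data$n_terms,
                                                  y = .data$cluster)) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::labs(x = "terms", y = NULL) +
    ggplot2::theme_minimal(base_size = 10) +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
  patchwork::wrap_plots(tiles, bar_panel, widths = c(4, 1))
}

plot_bubble <- function(tbl) {
  tbl$cell <- ifelse(tbl$regulation == "all", tbl$condition,
                     sprintf("%s (%s)", tbl$condition, tbl$regulation))
  ggplot2::ggplot(tbl, ggplot2::aes(x = .data$cell, y = .data$annotation,
                                    size = .data$size, color = .data$n_genes)) +
    ggplot2::geom_point() +
    ggplot2::scale_size_continuous(name = expression(-log[10] ~ "pooled" ~ italic(P)),
                                   range = c(1, 10)) +
    ggplot2::scale_color_gradient(low = "#2166ac", high = "#b2182b",
                                  name = "genes") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal(base_size = 10) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

plot_threshold_profile <- function(profile) {
  long <- rbind(
    data.frame(ts = profile$ts, value = profile$n_clusters, metric = "clusters"),
    data.frame(ts = profile$ts, value = profile$n_components, metric = "connected components"),
    data.frame(ts = profile$ts, value = profile$modularity, metric = "modularity")
  )
  long$metric <- factor(long$metric,
                        levels = c("clusters", "connected components", "modularity"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$ts, y = .data$value)) +
    ggplot2::geom_line(color = "#2166ac") +
    ggplot2::geom_point(size = 1.2) +
    ggplot2::facet_wrap(~metric, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "similarity threshold (ts)", y = NULL) +
    ggplot2::theme_minimal(base_size = 10)
}

#' Render a figure with its side-car data table
#'
#' Renders a [heatmap_bundle], [bubble_table] or threshold profile (from
#' [evaluate_thresholds]) to PNG, SVG or PDF, and writes the underlying
#' data as a CSV next to the figure (`<path>_data.csv`) so plots can be
#' rebuilt and customized outside the package.
#'
#' @param x A `heatmap_bundle`, `bubble_table` or `threshold_profile`.
#' @param path Output figure path.
#' @param format `"png"`, `"svg"` or `"pdf"`; inferred from the file
#'   extension when `NULL`.
#' @param width,height Figure size in inches.
#' @return Invisibly, the side-car table path.
#' @export
render_figure <- function(x, path, format = NULL, width = 8, height = 6) {
  if (is.null(format)) format <- tolower(tools::file_ext(path))
  if (!format %in% c("png", "svg", "pdf")) {
    stop("unknown figure format: '", format, "' (use png, svg or pdf)",
         call. = FALSE)
  }
  if (inherits(x, "heatmap_bundle")) {
    plt <- plot_heatmap(x)
    side <- heatmap_long_table(x)
  } else if (inherits(x, "bubble_table")) {
    plt <- plot_bubble(x)
    side <- as.data.frame(x)
  } else if (inherits(x, "threshold_profile")) {
    plt <- plot_threshold_profile(x)
    side <- as.data.frame(x)
  } else {
    stop("don't know how to render an object of class ",
         paste(class(x), collapse = "/"), call. = FALSE)
  }
  switch(format,
         png = grDevices::png(path, width = width, height = height,
                              units = "in", res = 150),
         svg = grDevices::svg(path, width = width, height = height),
         pdf = grDevices::pdf(path, width = width, height = height))
  print(plt)
  grDevices::dev.off()
  side_path <- paste0(tools::file_path_sans_ext(path), "_data.csv")
  utils::write.table(side, side_path, sep = ",", row.names = FALSE,
                     qmethod = "double")
  invisible(side_path)
}
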