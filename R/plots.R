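# ggplot2 views of the pipeline's objects.

#' Plot a rendered scene
#'
#' Grayscale raster of the image, optionally overlaid with ground-truth
#' colony outlines coloured by morphology class.
#'
#' @param rendered list with `image` and `truth` from [render_scene()].
#' @param outlines overlay ground-truth boundaries (default `TRUE`).
#' @return a ggplot.
#' @export
plot_scene <- function(rendered, outlines = TRUE) {
  img <- rendered$image
  df <- tidyr::expand_grid(row = seq_len(nrow(img)), col = seq_len(ncol(img)))
  df$intensity <- img[cbind(df$row, df$col)]
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$col, -.data$row,
                                        fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 limits = c(0, 255)) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL, fill = "intensity") +
    ggplot2::theme_void()
  if (outlines && length(rendered$truth$class_of_label)) {
    lab <- rendered$truth$label_image
    edge <- lab > 0 & (lab != rbind(lab[-1, ], lab[nrow(lab), ]) |
                         lab != cbind(lab[, -1], lab[, ncol(lab)]))
    idx <- which(edge)
    bd <- tibble::tibble(
      row = ((idx - 1L) %% nrow(lab)) + 1L,
      col = ((idx - 1L) %/% nrow(lab)) + 1L,
      class = rendered$truth$class_of_label[as.character(lab[idx])])
    p <- p + ggplot2::geom_point(
      data = bd, ggplot2::aes(.data$col, -.data$row, colour = .data$class),
      inherit.aes = FALSE, size = 0.1)
  }
  p
}

#' Cluster composition of a colony database
#'
#' Cluster sizes (major clusters highlighted), faceted by cell line when
#' the database is annotated.
#'
#' @param object a `colony_db`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.colony_db <- function(object, ...) {
  d <- tidy(object)
  p <- ggplot2::ggplot(d, ggplot2::aes(.data$cluster, fill = .data$is_major)) +
    ggplot2::geom_bar() +
    ggplot2::labs(x = "cluster", y = "colonies", fill = "major") +
    ggplot2::theme_minimal()
  if ("line" %in% names(d))
    p <- p + ggplot2::facet_wrap(~line)
  p
}

#' Dendrogram of a cluster tree
#'
#' Merge heights drawn as 1 - similarity; an optional horizontal line marks
#' a pruning threshold.
#'
#' @param object a `cluster_tree`.
#' @param r_threshold optional similarity threshold to mark.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.cluster_tree <- function(object, r_threshold = NULL, ...) {
  hc <- object$hclust
  n <- length(object$labels)
  # leaf x-positions in dendrogram order
  xpos <- stats::setNames(seq_len(n), hc$order)
  node_x <- numeric(n - 1); node_y <- 1 - object$similarity
  segs <- list()
  pos_of <- function(k) if (k < 0) c(xpos[as.character(-k)], 0)
                        else c(node_x[k], node_y[k])
  for (i in seq_len(n - 1)) {
    a <- pos_of(hc$merge[i, 1]); b <- pos_of(hc$merge[i, 2])
    node_x[i] <- (a[1] + b[1]) / 2
    segs[[i]] <- tibble::tibble(
      x = c(a[1], a[1], b[1]), xend = c(a[1], b[1], b[1]),
      y = c(a[2], node_y[i], node_y[i]), yend = c(node_y[i], node_y[i], b[2]))
  }
  d <- dplyr::bind_rows(segs)
  p <- ggplot2::ggplot(d) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$x, xend = .data$xend,
                                       y = .data$y, yend = .data$yend)) +
    ggplot2::scale_y_continuous("1 - similarity") +
    ggplot2::labs(x = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
  if (!is.null(r_threshold))
    p <- p + ggplot2::geom_hline(yintercept = 1 - r_threshold,
                                 linetype = "dashed", colour = "red")
  p
}

#' Volcano plot of a differential-expression result
#'
#' @param object a `diff_exp` tibble from [cluster_vs_rest()].
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.diff_exp <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(log2(.data$fold_change),
                               -log10(.data$p_adjusted),
                               colour = .data$significant)) +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::labs(x = "log2 fold change (target / rest)",
                  y = "-log10 adjusted p", colour = "significant") +
    ggplot2::theme_minimal()
}
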