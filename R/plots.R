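#' Diagnostics plot for a path fit
#'
#' Average standard error of the clustered slopes against the penalty, with
#' the selected penalty highlighted - the curve used to tune the model.
#'
#' @param object A `genejam_path` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot genejam_path
#' @export
autoplot.genejam_path <- function(object, ...) {
  df <- dplyr::filter(object$path, !is.na(.data$avg_se))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$rho, y = .data$avg_se)) +
    ggplot2::geom_line(colour = "grey30") +
    ggplot2::geom_point(size = 1, colour = "grey30") +
    ggplot2::labs(x = expression(rho), y = "average SE of clustered slopes") +
    ggplot2::theme_minimal()
  if (!object$fallback) {
    sel <- dplyr::filter(df, .data$rho == object$rho_min)
    p <- p + ggplot2::geom_point(data = sel, colour = "darkorange", size = 3)
  }
  p
}

#' Adjacency heat map
#'
#' Tile plot of an estimated trait adjacency matrix; edges present in a true
#' adjacency (if supplied) are outlined, so estimation errors are visible at
#' a glance.
#'
#' @param adjacency q x q binary adjacency matrix (or a `genejam_path`, in
#'   which case the selected clustering is plotted).
#' @param truth Optional q x q true adjacency to outline.
#' @return A ggplot object.
#' @export
plot_adjacency <- function(adjacency, truth = NULL) {
  if (inherits(adjacency, "genejam_path")) adjacency <- adjacency$clusters$adjacency
  A <- as_num_matrix(adjacency, "adjacency")
  q <- ncol(A)
  ids <- colnames(A) %||% default_ids(q, "trait")
  df <- tidyr::expand_grid(row = factor(ids, levels = ids),
                           col = factor(ids, levels = rev(ids)))
  df$edge <- as.vector(t(A)) == 1
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$row, y = .data$col)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$edge), colour = "white") +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey95", `TRUE` = "grey40"),
                               guide = "none") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
  if (!is.null(truth)) {
    Tm <- as_num_matrix(truth, "truth")
    df$true_edge <- as.vector(t(Tm)) == 1
    p <- p + ggplot2::geom_tile(
      data = dplyr::filter(df, .data$true_edge),
      fill = NA, colour = "darkorange", linewidth = 0.8
    )
  }
  p
}
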