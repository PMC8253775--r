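# ggplot2 views of the pipeline's objects. These are quick-look diagnostics
# (raster plots, GNA traces with burst markers, degree CDFs, score matrices,
# network geometry), not publication figures.

#' @export
autoplot.spike_raster <- function(object, ...) {
  df <- tidy(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$neuron_id))
  if ("label" %in% names(df))
    p <- p + ggplot2::geom_point(ggplot2::aes(colour = .data$label),
                                 shape = "|", size = 1.5)
  else
    p <- p + ggplot2::geom_point(shape = "|", size = 1.5)
  p + ggplot2::labs(x = "time (s)", y = "neuron",
                    title = sprintf("%d neurons, %d events",
                                    object$n_neurons, nrow(df))) +
    ggplot2::theme_minimal()
}

#' Plot a GNA series with optional burst markers
#'
#' @param gna A `gna_series`.
#' @param catalog Optional `burst_catalog`; peaks are marked, extreme events
#'   (if flagged) in a different colour.
#' @return A ggplot object.
#' @export
plot_gna <- function(gna, catalog = NULL) {
  stopifnot(inherits(gna, "gna_series"))
  p <- ggplot2::ggplot(as_tibble(unclass(gna)),
                       ggplot2::aes(x = .data$time, y = .data$gna)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "time (s)", y = "GNA") +
    ggplot2::theme_minimal()
  if (!is.null(catalog) && nrow(catalog) > 0) {
    df <- tidy(catalog)
    df$extreme <- ifelse(is.na(df$extreme), FALSE, df$extreme)
    p <- p + ggplot2::geom_point(
      data = df,
      ggplot2::aes(x = .data$time, y = .data$amplitude,
                   colour = .data$extreme)) +
      ggplot2::scale_colour_manual(values = c(`FALSE` = "#3366cc",
                                              `TRUE` = "#cc3333"),
                                   name = "extreme") +
      ggplot2::geom_hline(yintercept = attr(catalog, "threshold"),
                          linetype = "dashed", colour = "grey40")
  }
  p
}

#' @export
autoplot.gna_series <- function(object, ...) plot_gna(object)

#' @export
autoplot.degree_distribution <- function(object, ...) {
  xl <- if (isTRUE(attr(object, "percent")))
    "functional connections (% of network)" else "connections k"
  ggplot2::ggplot(as_tibble(unclass(object)),
                  ggplot2::aes(x = .data$k, y = .data$cdf)) +
    ggplot2::geom_step() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = xl, y = "CDF(k)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.effective_network <- function(object, order_by_community = TRUE,
                                       ...) {
  mat <- if (!is.null(object$adjacency)) object$adjacency else object$scores
  ord <- seq_len(nrow(mat))
  if (order_by_community && !is.null(object$adjacency)) {
    part <- tryCatch(detect_communities(object$adjacency),
                     error = function(e) NULL)
    if (!is.null(part)) {
      comp_order <- community_order(part)
      ord <- c(comp_order, setdiff(ord, comp_order))
    }
  }
  m <- mat[ord, ord]
  df <- tibble(
    source = rep(seq_len(nrow(m)), times = ncol(m)),
    target = rep(seq_len(ncol(m)), each = nrow(m)),
    value = as.vector(m)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$target, y = .data$source,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient(low = "white", high = "black") +
    ggplot2::labs(x = "target", y = "source") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.spatial_network <- function(object, edges = TRUE, max_edges = 2000,
                                     ...) {
  p <- ggplot2::ggplot()
  if (edges && nrow(object$edges) > 0) {
    ed <- object$edges
    if (nrow(ed) > max_edges) ed <- ed[seq_len(max_edges), ]
    seg <- tibble(
      x = object$neurons$x[ed$source], y = object$neurons$y[ed$source],
      xend = object$neurons$x[ed$target], yend = object$neurons$y[ed$target])
    p <- p + ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                   yend = .data$yend),
      alpha = 0.1, linewidth = 0.2)
  }
  p + ggplot2::geom_point(
    data = object$neurons,
    ggplot2::aes(x = .data$x, y = .data$y, colour = .data$type,
                 size = .data$dendrite_radius)) +
    ggplot2::scale_size_continuous(range = c(0.5, 2.5), guide = "none") +
    ggplot2::scale_colour_manual(values = c(excitatory = "#3366cc",
                                            da = "#cc3333",
                                            inhibitory = "#33a02c")) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (um)", y = "y (um)") +
    ggplot2::theme_minimal()
}
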