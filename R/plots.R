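#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

# segment coordinates for a dendrogram: classic rectangular layout
dendro_segments <- function(t) {
  n <- length(t$labels)
  xpos <- numeric(n + length(t$height))    # leaf and node x positions
  xpos[seq_len(n)] <- match(seq_len(n), t$order)
  segs <- list()
  node_x <- function(code) if (code < 0) xpos[-code] else xpos[n + code]
  node_h <- function(code) if (code < 0) 0 else t$height[code]
  for (s in seq_along(t$height)) {
    l <- t$merge[s, 1]; r <- t$merge[s, 2]
    xl <- node_x(l); xr <- node_x(r); h <- t$height[s]
    xpos[n + s] <- (xl + xr) / 2
    segs[[s]] <- tibble::tibble(
      x = c(xl, xl, xr),
      xend = c(xl, xr, xr),
      y = c(node_h(l), h, h),
      yend = c(h, h, node_h(r)),
      node = s
    )
  }
  dplyr::bind_rows(segs)
}

#' Plot a dendrogram
#'
#' Rectangular dendrogram with merge heights on the dissimilarity scale;
#' bootstrap supports (when attached) are printed at the internal nodes.
#'
#' @param object an `archipel_dendro`
#' @param support_digits digits for node support labels
#' @param ... unused
#' @return a ggplot
#' @method autoplot archipel_dendro
#' @export
autoplot.archipel_dendro <- function(object, support_digits = 0, ...) {
  segs <- dendro_segments(object)
  n <- length(object$labels)
  leaf_df <- tibble::tibble(
    x = seq_len(n),
    label = object$labels[object$order]
  )
  p <- ggplot2::ggplot(segs) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$x, xend = .data$xend,
                                       y = .data$y, yend = .data$yend)) +
    ggplot2::scale_x_continuous(breaks = leaf_df$x, labels = leaf_df$label) +
    ggplot2::labs(x = NULL,
                  y = sprintf("%s dissimilarity (%s)",
                              object$index %||% "", object$method)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1),
                   panel.grid.major.x = ggplot2::element_blank())
  if (!is.null(object$support)) {
    nodes <- segs |>
      dplyr::group_by(.data$node) |>
      dplyr::summarise(x = mean(range(c(.data$x, .data$xend))),
                       y = max(.data$y), .groups = "drop") |>
      dplyr::mutate(support = object$support[.data$node])
    p <- p + ggplot2::geom_text(
      data = nodes[nodes$node < max(nodes$node), ],
      ggplot2::aes(x = .data$x, y = .data$y,
                   label = sprintf(paste0("%.", support_digits, "f"),
                                   .data$support)),
      vjust = -0.4, size = 3)
  }
  p
}

#' Plot a dissimilarity matrix as a heatmap
#'
#' @param object an `archipel_dissim` matrix
#' @param ... unused
#' @return a ggplot
#' @method autoplot archipel_dissim
#' @export
autoplot.archipel_dissim <- function(object, ...) {
  df <- tidy.archipel_dissim(object)
  df2 <- dplyr::rename(df, region1 = "region2", region2 = "region1")
  long <- dplyr::bind_rows(df, df2)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$region1, y = .data$region2,
                                     fill = .data$dissimilarity)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL,
                  fill = paste(attr(object, "index"), "dissimilarity")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot an optimal-k score profile
#'
#' @param object an `archipel_optimal_k`
#' @param ... unused
#' @return a ggplot
#' @method autoplot archipel_optimal_k
#' @export
autoplot.archipel_optimal_k <- function(object, ...) {
  ggplot2::ggplot(object$profile, ggplot2::aes(x = .data$k, y = .data$score)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$k_best, linetype = "dashed") +
    ggplot2::labs(x = "number of clusters k",
                  y = switch(object$criterion,
                             silhouette = "mean silhouette width",
                             mantel = "Mantel r")) +
    ggplot2::theme_minimal()
}

#' Plot a shared-endemics occupancy distribution
#'
#' @param object an `archipel_shared_endemics`
#' @param ... unused
#' @return a ggplot
#' @method autoplot archipel_shared_endemics
#' @export
autoplot.archipel_shared_endemics <- function(object, ...) {
  ggplot2::ggplot(object$occupancy,
                  ggplot2::aes(x = factor(.data$occupancy), y = .data$n)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "number of archipelagos occupied",
                  y = "shared endemic species") +
    ggplot2::theme_minimal()
}
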