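#' Plot a central-vector clustering on an MDS map
#'
#' Classical MDS of the population distance matrix, points coloured by
#' cluster, with the central vectors overlaid as crosses.
#'
#' @param object An `hg_soc` fit.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot hg_soc
#' @export
autoplot.hg_soc <- function(object, ...) {
  emb <- mds_embedding(euclidean_matrix(object$data), dims = 2L)
  emb$cluster <- factor(object$assignment[emb$label])
  cv <- mds_project(object$data, object$centers, emb)
  ggplot2::ggplot(emb, ggplot2::aes(.data$dim1, .data$dim2,
                                    colour = .data$cluster)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_point(data = cv, shape = 4, size = 4, stroke = 1.5,
                        colour = "black") +
    ggplot2::labs(x = "MDS 1", y = "MDS 2", colour = "cluster",
                  title = sprintf("%d central vectors over %d populations",
                                  object$n_clusters, nrow(object$data))) +
    ggplot2::theme_minimal()
}

# Project extra rows (the centers) into an existing 2-D MDS of `m` by
# joint re-embedding; approximate but adequate for display.
mds_project <- function(m, centers, emb) {
  all <- rbind(m, centers)
  d <- as_hg_dist(as.matrix(stats::dist(all)))
  e2 <- suppressWarnings(mds_embedding(d, dims = 2L))
  cvpts <- e2[-seq_len(nrow(m)), ]
  # align signs with the population-only embedding
  for (ax in c("dim1", "dim2")) {
    if (stats::cor(e2[[ax]][seq_len(nrow(m))], emb[[ax]]) < 0)
      cvpts[[ax]] <- -cvpts[[ax]]
  }
  cvpts
}

#' Plot admixture weight profiles
#'
#' Weights of every central vector in every population, as a tile map.
#'
#' @param object An `hg_admix` table from [fit_admixture()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot hg_admix
#' @export
autoplot.hg_admix <- function(object, ...) {
  long <- tidy(object)
  long$cv <- factor(long$cv, levels = attr(object, "cv_names"))
  ggplot2::ggplot(long, ggplot2::aes(.data$cv, .data$population,
                                     fill = .data$weight)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "central vector", y = "population",
                  title = sprintf("admixture weights (mean J = %.3f)",
                                  attr(object, "mean_J"))) +
    ggplot2::theme_minimal()
}

#' Relationship graph of central vectors (or populations)
#'
#' MDS map of a distance matrix with two edge layers: thin edges between
#' pairs closer than `fraction` of the maximal distance, thick edges for
#' the minimum spanning tree.
#'
#' @param d An `hg_dist` matrix (e.g. distances between central vectors).
#' @param fraction Threshold-edge fraction of the maximal distance,
#'   default 0.35.
#' @return A ggplot object.
#' @export
plot_cv_graph <- function(d, fraction = 0.35) {
  d <- as_hg_dist(d)
  emb <- suppressWarnings(mds_embedding(d, dims = 2L))
  coords <- function(edges) {
    dplyr::mutate(edges,
                  x = emb$dim1[match(.data$from, emb$label)],
                  y = emb$dim2[match(.data$from, emb$label)],
                  xend = emb$dim1[match(.data$to, emb$label)],
                  yend = emb$dim2[match(.data$to, emb$label)])
  }
  thin <- coords(threshold_edges(d, fraction))
  thick <- coords(minimum_spanning_tree(d))
  ggplot2::ggplot(emb, ggplot2::aes(.data$dim1, .data$dim2)) +
    ggplot2::geom_segment(
      data = thin, colour = "grey70", linewidth = 0.3,
      ggplot2::aes(x = .data$x, y = .data$y,
                   xend = .data$xend, yend = .data$yend)) +
    ggplot2::geom_segment(
      data = thick, colour = "black", linewidth = 0.9,
      ggplot2::aes(x = .data$x, y = .data$y,
                   xend = .data$xend, yend = .data$yend)) +
    ggplot2::geom_point(size = 2, colour = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$label), vjust = -0.8,
                       size = 3) +
    ggplot2::labs(x = "MDS 1", y = "MDS 2") +
    ggplot2::theme_minimal()
}
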