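#' Plot a lineage tree against cumulative SHM distance
#'
#' Nodes are unique sequences (point size scaled to template count, colour
#' by CDR3 nt sequence), placed at their cumulative SHM distance from the
#' root; segments join parents to children.
#'
#' @param clusters A `clone_clusters` object.
#' @param cluster_id Cluster to draw.
#' @returns A ggplot object.
#' @export
plot_lineage_tree <- function(clusters, cluster_id) {
  edges <- export_tree(clusters, cluster_id, format = "tabular")
  ids <- edges$child_id
  depth <- stats::setNames(rep(NA_real_, length(ids)), ids)
  root <- edges$child_id[is.na(edges$parent_id)][1]
  depth[root] <- 0
  while (anyNA(depth)) {
    todo <- which(is.na(depth))
    for (i in todo) {
      p <- edges$parent_id[match(ids[i], edges$child_id)]
      if (!is.na(depth[p])) {
        depth[ids[i]] <- depth[p] + edges$distance[match(ids[i], edges$child_id)]
      }
    }
  }
  # leaves get consecutive y positions; internal nodes sit at the mean of
  # their children
  kids_of <- split(edges$child_id, edges$parent_id)
  ypos <- stats::setNames(rep(NA_real_, length(ids)), ids)
  leaf_counter <- 0
  assign_y <- function(id) {
    kids <- kids_of[[id]]
    if (is.null(kids)) {
      leaf_counter <<- leaf_counter + 1
      ypos[id] <<- leaf_counter
    } else {
      for (k in sort(kids)) assign_y(k)
      ypos[id] <<- mean(ypos[kids])
    }
  }
  assign_y(root)
  nodes <- tibble(id = ids, x = depth[ids], y = ypos[ids],
                  template_count = edges$template_count,
                  cdr3 = edges$cdr3)
  segs <- edges[!is.na(edges$parent_id), , drop = FALSE]
  segs <- tibble(x = depth[segs$parent_id], y = ypos[segs$parent_id],
                 xend = depth[segs$child_id], yend = ypos[segs$child_id])
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = segs,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend, yend = .data$yend),
                          colour = "grey50") +
    ggplot2::geom_point(data = nodes,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     size = .data$template_count,
                                     colour = .data$cdr3)) +
    ggplot2::labs(x = "cumulative SHM distance", y = NULL,
                  title = paste("Lineage tree:", cluster_id)) +
    ggplot2::guides(colour = "none") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a propensity matrix as per-parent substitution frequencies
#'
#' @param object A `propensity_matrix` tibble.
#' @param ... Unused.
#' @returns A ggplot object.
#' @method autoplot propensity_matrix
#' @export
autoplot.propensity_matrix <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$to, y = .data$freq)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~from, nrow = 1,
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = "child nt (X1)", y = "normalized frequency",
                  title = paste0("SHM propensities (",
                                 attr(object, "scope"), " segments)")) +
    ggplot2::theme_minimal()
}

#' Scatter plot of V versus DJ SHM propensities
#'
#' @param v,dj `propensity_matrix` tibbles.
#' @returns A ggplot object annotated with the Pearson correlation and
#'   regression slope.
#' @export
plot_propensity_correlation <- function(v, dj) {
  m <- dplyr::inner_join(as_tibble(v)[c("from", "to", "freq")],
                         as_tibble(dj)[c("from", "to", "freq")],
                         by = c("from", "to"), suffix = c("_v", "_dj"))
  cs <- v_dj_correlation(v, dj)
  lab <- sprintf("r = %.3f, slope = %.3f", cs$r_corr, cs$slope)
  ggplot2::ggplot(m, ggplot2::aes(x = .data$freq_v, y = .data$freq_dj,
                                  colour = .data$from,
                                  shape = .data$to)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_point(size = 3) +
    ggplot2::annotate("text", x = -Inf, y = Inf, hjust = -0.1, vjust = 1.5,
                      label = lab) +
    ggplot2::labs(x = "V-segment frequency", y = "DJ-segment frequency") +
    ggplot2::theme_minimal()
}

#' Bar chart of gene-family usage
#'
#' @param usage Output of [usage_frequencies()].
#' @returns A ggplot object.
#' @export
plot_usage <- function(usage) {
  ggplot2::ggplot(usage$family,
                  ggplot2::aes(x = .data$family, y = .data$freq)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~segment, scales = "free_x") +
    ggplot2::labs(x = NULL, y = "usage frequency") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Composition profile around mutated positions
#'
#' @param profile Output of [hotspot_profile()].
#' @returns A ggplot object (mutated-centred vs all-position background).
#' @export
plot_hotspot <- function(profile) {
  ggplot2::ggplot(profile, ggplot2::aes(x = .data$offset, y = .data$freq,
                                        fill = .data$nt)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::facet_wrap(~center) +
    ggplot2::labs(x = "offset from centre position", y = "composition") +
    ggplot2::theme_minimal()
}
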