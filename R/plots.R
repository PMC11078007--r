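# ggplot2 displays for the main result types.

#' Island presence/absence heatmap
#'
#' Genomes by islands; full carriers, partial carriers and absences are
#' distinguished, mirroring the usual island-distribution map.
#'
#' @param islands Result of [find_islands()].
#' @param genomes Character vector of genome ids (row order).
#' @return A ggplot object.
#' @export
plot_island_matrix <- function(islands, genomes) {
  m <- island_presence_matrix(islands, genomes)
  long <- tidyr::pivot_longer(m, -"genome_id", names_to = "island",
                              values_to = "state") |>
    dplyr::mutate(state = factor(c("absent", "carrier", "partial")[.data$state + 1],
                                 levels = c("absent", "carrier", "partial")))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$island, y = .data$genome_id,
                                     fill = .data$state)) +
    ggplot2::geom_tile(colour = "grey80") +
    ggplot2::scale_fill_manual(values = c(absent = "white",
                                          carrier = "#2166ac",
                                          partial = "grey40")) +
    ggplot2::labs(x = "genomic island", y = "genome", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, hjust = 1))
}

#' Normalized DTL rates, islands vs core
#'
#' @param dtl Tibble from [dtl_analysis()] with a `class` column
#'   (`"island"` / `"core"`).
#' @return A ggplot object (boxplots of transfer/loss/duplication rates).
#' @export
plot_dtl_rates <- function(dtl) {
  long <- tidyr::pivot_longer(dtl, dplyr::all_of(c("rate_d", "rate_t", "rate_l")),
                              names_to = "event", values_to = "rate") |>
    dplyr::mutate(event = c(rate_d = "duplication", rate_t = "transfer",
                            rate_l = "loss")[.data$event])
  ggplot2::ggplot(long, ggplot2::aes(x = .data$event, y = .data$rate,
                                     fill = .data$class)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::facet_wrap(~scheme) +
    ggplot2::labs(x = NULL, y = "events / (internode x total branch length)",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a tANI phylogeny with bootstrap supports
#'
#' A simple rectangular layout drawn with ggplot2 segments; internal edges
#' are labelled with their bootstrap support.
#'
#' @param object A `tani_phylo`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot tani_phylo
#' @export
autoplot.tani_phylo <- function(object, ...) {
  tr <- object$tree
  n_tip <- length(tr$tip.label)
  root <- n_tip + 1L
  n_node <- n_tip + tr$Nnode
  kids <- vector("list", n_node)
  for (r in seq_len(nrow(tr$edge))) {
    kids[[tr$edge[r, 1]]] <- c(kids[[tr$edge[r, 1]]], tr$edge[r, 2])
  }
  elen <- setNames(tr$edge.length, tr$edge[, 2])
  x <- numeric(n_node); y <- numeric(n_node)
  tip_counter <- 0
  assign_xy <- function(node, depth) {
    x[node] <<- depth
    if (node <= n_tip) {
      tip_counter <<- tip_counter + 1
      y[node] <<- tip_counter
    } else {
      for (ch in kids[[node]]) assign_xy(ch, depth + elen[[as.character(ch)]])
      y[node] <<- mean(y[kids[[node]]])
    }
  }
  assign_xy(root, 0)
  segs <- dplyr::bind_rows(lapply(seq_len(nrow(tr$edge)), function(r) {
    p <- tr$edge[r, 1]; c <- tr$edge[r, 2]
    dplyr::bind_rows(
      tibble(x = x[p], xend = x[p], y = y[p], yend = y[c]),
      tibble(x = x[p], xend = x[c], y = y[c], yend = y[c]))
  }))
  tips <- tibble(x = x[seq_len(n_tip)], y = y[seq_len(n_tip)],
                 label = tr$tip.label)
  nodes <- tibble(x = x[(n_tip + 2):n_node], y = y[(n_tip + 2):n_node],
                  support = object$supports[-1])
  p <- ggplot2::ggplot() +
    ggplot2::geom_segment(data = segs,
                          ggplot2::aes(x = .data$x, xend = .data$xend,
                                       y = .data$y, yend = .data$yend)) +
    ggplot2::geom_text(data = tips,
                       ggplot2::aes(x = .data$x, y = .data$y,
                                    label = .data$label),
                       hjust = -0.05, size = 3) +
    ggplot2::labs(x = "tANI distance", y = NULL) +
    ggplot2::scale_x_continuous(expand = ggplot2::expansion(mult = c(0.02, 0.2))) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   panel.grid.major.y = ggplot2::element_blank())
  if (nrow(nodes)) {
    p <- p + ggplot2::geom_text(data = nodes,
                                ggplot2::aes(x = .data$x, y = .data$y,
                                             label = .data$support),
                                hjust = 1.1, vjust = -0.4, size = 2.7,
                                colour = "grey30")
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
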