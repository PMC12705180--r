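# ggplot2 figure methods for the package's result types

#' Plot a document landscape
#'
#' Scatter of the 2-D embedding colored by cluster. The embedding is a
#' visualization aid only; cluster labels come from the PCA-space graph.
#'
#' @param object A `litscape_landscape`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.litscape_landscape <- function(object, ...) {
  df <- tidy.litscape_landscape(object)
  df$cluster <- factor(df$cluster)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$dim1, y = .data$dim2,
                                   colour = .data$cluster)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.7) +
    ggplot2::labs(x = "dim 1", y = "dim 2", colour = "cluster") +
    ggplot2::theme_minimal()
}

#' Plot a coherence scan
#'
#' Coherence against candidate topic count, with the selected `k_star`
#' marked.
#'
#' @param object A `litscape_coherence`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.litscape_coherence <- function(object, ...) {
  ggplot2::ggplot(object$report, ggplot2::aes(x = .data$k, y = .data$coherence)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$k_star, linetype = "dashed") +
    ggplot2::labs(x = "number of topics", y = "c_v coherence") +
    ggplot2::theme_minimal()
}

#' Topic-proportion trajectories
#'
#' Smoothed yearly topic proportions as one line per topic.
#'
#' @param proportions Output of [yearly_topic_proportions()].
#' @param smoothed Plot the smoothed series (default) or the raw one.
#' @return A ggplot.
#' @export
plot_topic_trends <- function(proportions, smoothed = TRUE) {
  y <- if (smoothed) "smoothed" else "proportion"
  df <- proportions[!is.na(proportions[[y]]), ]
  df$topic <- factor(df$topic)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$year, y = .data[[y]],
                                   colour = .data$topic)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "year", y = "topic proportion", colour = "topic") +
    ggplot2::theme_minimal()
}

#' Entropy trajectory
#'
#' Yearly mean Shannon entropy of document topic mixtures with its rolling
#' mean.
#'
#' @param entropy Output of [shannon_entropy_series()].
#' @return A ggplot.
#' @export
plot_entropy_trend <- function(entropy) {
  ggplot2::ggplot(entropy, ggplot2::aes(x = .data$year)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$mean_entropy), alpha = 0.4) +
    ggplot2::geom_line(
      data = entropy[!is.na(entropy$smoothed), ],
      ggplot2::aes(y = .data$smoothed), linewidth = 1
    ) +
    ggplot2::labs(x = "year", y = "mean Shannon entropy (nats)") +
    ggplot2::theme_minimal()
}

#' Co-occurrence heatmap
#'
#' Tile map of the topic co-occurrence matrix (the table behind a chord
#' diagram).
#'
#' @param m Output of [topic_cooccurrence()].
#' @return A ggplot.
#' @export
plot_cooccurrence <- function(m) {
  K <- nrow(m)
  df <- tibble(
    topic_i = factor(rep(seq_len(K), times = K)),
    topic_j = factor(rep(seq_len(K), each = K)),
    weight = as.vector(unclass(m)[seq_len(K), seq_len(K)])
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$topic_i, y = .data$topic_j,
                                   fill = .data$weight)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "topic", y = "topic", fill = "co-occurrence") +
    ggplot2::theme_minimal()
}

#' Hallmark-presence dot plot
#'
#' Proportion of documents containing each stem, per cluster, as a dot plot
#' (dot size and color encode the proportion).
#'
#' @param presence Clusters x stems matrix from [hallmark_presence()] or
#'   [word_presence()].
#' @return A ggplot.
#' @export
plot_hallmark_presence <- function(presence) {
  df <- tibble(
    cluster = factor(rep(rownames(presence), times = ncol(presence))),
    stem = factor(rep(colnames(presence), each = nrow(presence)),
                  levels = colnames(presence)),
    proportion = as.vector(presence)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$stem, y = .data$cluster,
                                   size = .data$proportion,
                                   colour = .data$proportion)) +
    ggplot2::geom_point() +
    ggplot2::scale_colour_viridis_c() +
    ggplot2::labs(x = "stem", y = "cluster") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Semantic-overlap heatmap
#'
#' Source-by-target tile map of mean TF-IDF of each source cluster's top
#' words within every target cluster.
#'
#' @param overlap A `litscape_overlap` from [semantic_overlap()].
#' @return A ggplot.
#' @export
plot_semantic_overlap <- function(overlap) {
  m <- overlap$matrix
  df <- tibble(
    source = factor(rep(rownames(m), times = ncol(m)), levels = rownames(m)),
    target = factor(rep(colnames(m), each = nrow(m)), levels = colnames(m)),
    score = as.vector(m)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$target, y = .data$source,
                                   fill = .data$score)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "target cluster", y = "source cluster",
                  fill = "mean TF-IDF") +
    ggplot2::theme_minimal()
}
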