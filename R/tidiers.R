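# broom-style tidiers for the package's fitted objects

#' Tidy a fitted topic model
#'
#' Returns the topic-word matrix in long form, one row per (topic, token)
#' pair, optionally restricted to each topic's top terms.
#'
#' @param x A `litscape_lda`.
#' @param n_terms Optional cap: keep only the `n_terms` highest-probability
#'   tokens per topic.
#' @param ... Unused.
#' @return Tibble with columns `topic`, `token`, `phi`.
#' @export
tidy.litscape_lda <- function(x, n_terms = NULL, ...) {
  tokens <- colnames(x$phi)
  out <- tibble(
    topic = rep(seq_len(x$K), times = ncol(x$phi)),
    token = rep(tokens, each = x$K),
    phi = as.vector(x$phi)
  )
  if (!is.null(n_terms)) {
    out <- out |>
      group_by(.data$topic) |>
      arrange(desc(.data$phi), .data$token, .by_group = TRUE) |>
      slice(seq_len(n_terms)) |>
      ungroup()
  }
  out
}

#' @rdname tidy.litscape_lda
#' @export
glance.litscape_lda <- function(x, ...) {
  tibble(
    k = x$K, n_docs = nrow(x$theta), n_tokens = ncol(x$phi),
    passes = x$passes, seed = x$seed,
    mean_token_loglik = x$log_likelihood,
    mean_entropy = mean(shannon_entropy(x$theta))
  )
}

#' Augment documents with topic-model quantities
#'
#' @param x A `litscape_lda`.
#' @param ... Unused.
#' @return Tibble with `doc_id`, `year`, `dominant_topic`, `max_theta`,
#'   `entropy`.
#' @export
augment.litscape_lda <- function(x, ...) {
  tibble(
    doc_id = x$doc_id, year = x$year,
    dominant_topic = dominant_topic(x$theta),
    max_theta = apply(x$theta, 1, max),
    entropy = shannon_entropy(x$theta)
  )
}

#' Tidy a coherence scan
#'
#' @param x A `litscape_coherence`.
#' @param ... Unused.
#' @return The scan report tibble (`k`, `coherence`).
#' @export
tidy.litscape_coherence <- function(x, ...) x$report

#' @rdname tidy.litscape_coherence
#' @export
glance.litscape_coherence <- function(x, ...) {
  tibble(k_star = x$k_star, n_candidates = nrow(x$report),
         best_coherence = max(x$report$coherence))
}

#' Tidy a document landscape
#'
#' @param x A `litscape_landscape`.
#' @param ... Unused.
#' @return Tibble with `doc_id`, `year`, `cluster`, `dim1`, `dim2`.
#' @export
tidy.litscape_landscape <- function(x, ...) {
  tibble(
    doc_id = x$doc_id, year = x$year, cluster = x$labels,
    dim1 = x$embedding[, 1], dim2 = x$embedding[, 2]
  )
}

#' @rdname tidy.litscape_landscape
#' @export
glance.litscape_landscape <- function(x, ...) {
  tibble(
    n_docs = length(x$doc_id), n_features = length(x$features),
    n_pcs = ncol(x$pca), n_clusters = length(unique(x$labels)),
    resolution = x$params$resolution, seed = x$params$seed
  )
}

#' Tidy a stability-trend result
#'
#' @param x A `litscape_stability`.
#' @param ... Unused.
#' @return The per-cluster slope table (`cluster`, `slope`, `n_points`,
#'   `rank`).
#' @export
tidy.litscape_stability <- function(x, ...) x$slopes

#' Tidy a topic-enrichment result
#'
#' @param x A `litscape_enrichment`.
#' @param ... Unused.
#' @return Long tibble with `cluster`, `topic`, `log2_enrichment`.
#' @export
tidy.litscape_enrichment <- function(x, ...) {
  tibble(
    cluster = rep(rownames(x$scores), times = ncol(x$scores)),
    topic = rep(seq_len(ncol(x$scores)), each = nrow(x$scores)),
    log2_enrichment = as.vector(x$scores)
  )
}
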