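# Cluster-level statistics: profiles, cosine similarity, topic enrichment,
# temporal evolution, thematic-stability trends, stem presence, and
# semantic-overlap gap discovery.

#' Per-cluster TF-IDF profiles
#'
#' Mean TF-IDF vector, size, and mean publication year of each cluster.
#'
#' @param tfidf Documents x features TF-IDF matrix.
#' @param labels Per-document cluster labels.
#' @param years Optional per-document publication years.
#' @return A `litscape_profiles` list: `clusters`, `mean_tfidf` (clusters x
#'   features), `size`, `mean_year`.
#' @export
cluster_profiles <- function(tfidf, labels, years = NULL) {
  cl <- sort(unique(labels))
  mean_tfidf <- do.call(rbind, lapply(cl, function(c) {
    Matrix::colMeans(tfidf[labels == c, , drop = FALSE])
  }))
  rownames(mean_tfidf) <- as.character(cl)
  structure(
    list(clusters = cl,
         mean_tfidf = mean_tfidf,
         size = vapply(cl, function(c) sum(labels == c), integer(1)),
         mean_year = if (is.null(years)) NULL else
           vapply(cl, function(c) mean(years[labels == c]), numeric(1))),
    class = "litscape_profiles"
  )
}

#' Cosine similarity between cluster profiles
#'
#' Pairwise cosine similarity of the clusters' mean TF-IDF vectors. Zero
#' mean vectors (flagged) have similarity 0 against everything, including
#' themselves.
#'
#' @param profiles A [cluster_profiles()] result.
#' @return Symmetric clusters x clusters matrix; diagonal 1 for non-zero
#'   profiles.
#' @export
cluster_cosine_matrix <- function(profiles) {
  m <- profiles$mean_tfidf
  if (nrow(m) < 2) abort("Need at least 2 clusters.")
  norms <- sqrt(rowSums(m^2))
  zero <- norms == 0
  if (any(zero)) {
    warn(sprintf("%d cluster(s) have a zero mean TF-IDF vector.", sum(zero)))
  }
  norms[zero] <- 1
  sim <- (m / norms) %*% t(m / norms)
  sim[zero, ] <- 0
  sim[, zero] <- 0
  dimnames(sim) <- list(rownames(m), rownames(m))
  sim
}

#' Topic enrichment of clusters
#'
#' Compares each cluster's observed topic mass (the sum of `theta[, k]` over
#' its documents) to the mass expected from the corpus-wide topic
#' distribution scaled by cluster size:
#' `expected(c, k) = sum_d theta[d, k] * |c| / N`. The score is
#' `log2((observed + eps) / (expected + eps))`; the pseudocount keeps all
#' scores finite.
#'
#' @param theta N x K document-topic matrix (or `litscape_lda` fit).
#' @param labels Per-document cluster labels.
#' @param eps Pseudocount (default 1e-9).
#' @return A `litscape_enrichment` list: `scores` (clusters x topics log2
#'   enrichment), `observed`, `expected`, `eps`.
#' @export
topic_enrichment <- function(theta, labels, eps = 1e-9) {
  if (inherits(theta, "litscape_lda")) theta <- theta$theta
  if (nrow(theta) != length(labels)) abort("`theta` and `labels` must align.")
  cl <- sort(unique(labels))
  n_docs <- nrow(theta)
  topic_mass <- colSums(theta)
  observed <- do.call(rbind, lapply(cl, function(c) {
    colSums(theta[labels == c, , drop = FALSE])
  }))
  size <- vapply(cl, function(c) sum(labels == c), integer(1))
  expected <- outer(size / n_docs, topic_mass)
  scores <- log2((observed + eps) / (expected + eps))
  dimnames(scores) <- list(as.character(cl), colnames(theta))
  structure(list(scores = scores, observed = observed, expected = expected,
                 eps = eps, clusters = cl),
            class = "litscape_enrichment")
}

#' Hierarchical clustering of enrichment profiles
#'
#' Standardizes each cluster's enrichment row (z-score across topics, so
#' clusters are compared by enrichment shape rather than magnitude) and
#' applies agglomerative clustering with Euclidean distance and average
#' (UPGMA) linkage.
#'
#' @param enrichment A [topic_enrichment()] result (or a plain score matrix).
#' @return An [stats::hclust] tree over clusters, with the standardized
#'   matrix attached as attribute `"scaled"`.
#' @export
enrichment_hclust <- function(enrichment) {
  scores <- if (inherits(enrichment, "litscape_enrichment")) enrichment$scores else enrichment
  if (nrow(scores) < 2) abort("Need at least 2 clusters to build a tree.")
  z <- t(apply(scores, 1, function(r) {
    s <- stats::sd(r)
    if (s == 0) r * 0 else (r - mean(r)) / s
  }))
  tree <- stats::hclust(stats::dist(z, method = "euclidean"), method = "average")
  attr(tree, "scaled") <- z
  tree
}

#' Temporal evolution of clusters
#'
#' Mean publication year per cluster, plus the yearly share of documents in
#' each cluster (cluster counts normalized by the total documents published
#' that year, so per-year proportions sum to 1) with a trailing moving
#' average attached. Years with zero documents are omitted.
#'
#' @param labels Per-document cluster labels.
#' @param years Per-document publication years.
#' @param window Smoothing window (default 5).
#' @return A list: `mean_year` (tibble `cluster`, `mean_year`, `size`) and
#'   `proportions` (tibble `year`, `cluster`, `proportion`, `smoothed`).
#' @export
cluster_evolution <- function(labels, years, window = 5L) {
  if (length(labels) != length(years)) abort("`labels` and `years` must align.")
  cl <- sort(unique(labels))
  mean_year <- tibble(
    cluster = cl,
    mean_year = vapply(cl, function(c) mean(years[labels == c]), numeric(1)),
    size = vapply(cl, function(c) sum(labels == c), integer(1))
  )
  yrs <- sort(unique(years))
  grid <- expand.grid(year = yrs, cluster = cl, KEEP.OUT.ATTRS = FALSE)
  grid$proportion <- mapply(function(y, c) {
    sum(labels == c & years == y) / sum(years == y)
  }, grid$year, grid$cluster)
  proportions <- as_tibble(grid) |>
    group_by(.data$cluster) |>
    arrange(.data$year, .by_group = TRUE) |>
    mutate(smoothed = trailing_mean(.data$proportion, window)) |>
    ungroup()
  list(mean_year = mean_year, proportions = proportions)
}

#' Thematic-stability trend per cluster
#'
#' For each cluster, averages `theta` over each year's documents, computes
#' the cosine similarity between consecutive years' mean topic vectors
#' (pairs spanning a year with no documents are skipped), applies a trailing
#' moving average, and fits an ordinary-least-squares slope of the smoothed
#' series against year. Clusters are ranked by slope (rank 1 = steepest
#' increase in stability); clusters with fewer than 3 smoothed points have
#' an undefined slope and are excluded from the ranking.
#'
#' @param theta N x K document-topic matrix (or `litscape_lda` fit).
#' @param labels Per-document cluster labels.
#' @param years Per-document publication years.
#' @param window Smoothing window (default 5).
#' @return A `litscape_stability` list: `series` (tibble `cluster`, `year`,
#'   `cosine`, `smoothed`) and `slopes` (tibble `cluster`, `slope`,
#'   `n_points`, `rank`).
#' @export
stability_trend <- function(theta, labels, years, window = 5L) {
  if (inherits(theta, "litscape_lda")) theta <- theta$theta
  cl <- sort(unique(labels))
  series <- bind_rows(lapply(cl, function(c) {
    in_c <- labels == c
    yrs <- sort(unique(years[in_c]))
    if (length(yrs) < 2) return(NULL)
    vecs <- lapply(yrs, function(y) {
      colMeans(theta[in_c & years == y, , drop = FALSE])
    })
    consecutive <- yrs[-1] == yrs[-length(yrs)] + 1L
    cosines <- vapply(seq_len(length(yrs) - 1L), function(i) {
      if (!consecutive[i]) return(NA_real_)   # gap year: pair skipped
      cosine_sim(vecs[[i]], vecs[[i + 1L]])
    }, numeric(1))
    keep <- !is.na(cosines)
    if (!any(keep)) return(NULL)
    tibble(cluster = c, year = yrs[-1][keep], cosine = cosines[keep])
  }))
  if (is.null(series) || nrow(series) == 0) {
    series <- tibble(cluster = cl[0], year = integer(0), cosine = numeric(0))
  }
  series <- series |>
    group_by(.data$cluster) |>
    arrange(.data$year, .by_group = TRUE) |>
    mutate(smoothed = trailing_mean(.data$cosine, window)) |>
    ungroup()
  slopes <- series |>
    filter(!is.na(.data$smoothed)) |>
    group_by(cluster = .data$cluster) |>
    summarise(
      slope = {
        d <- data.frame(x = .data$year, y = .data$smoothed)
        if (nrow(d) >= 3) unname(coef(lm(y ~ x, data = d))[2]) else NA_real_
      },
      n_points = n(), .groups = "drop"
    )
  all_slopes <- tibble(cluster = cl) |>
    left_join(slopes, by = "cluster")
  defined <- !is.na(all_slopes$slope)
  all_slopes$rank <- NA_integer_
  all_slopes$rank[defined] <- as.integer(rank(-all_slopes$slope[defined],
                                              ties.method = "first"))
  structure(list(series = series, slopes = all_slopes),
            class = "litscape_stability")
}

#' Hallmark-stem presence per cluster
#'
#' Proportion of documents in each cluster containing each stem (prefix
#' match on stemmed tokens, as in [word_presence()]). The default stems are
#' the fourteen hallmark-of-aging word stems used to map hallmark concepts
#' onto document clusters.
#'
#' @param docs Tokenized-document tibble aligned with `labels`.
#' @param labels Per-document cluster labels.
#' @param stems Character vector of stems.
#' @return Clusters x stems numeric matrix of proportions.
#' @export
hallmark_presence <- function(docs, labels,
                              stems = c("oxid", "inflamm", "senesc",
                                        "mitochondri", "genom", "stem",
                                        "insulin", "metabol", "telomer",
                                        "epigenet", "autophagi", "nutrient",
                                        "microbi", "intercellular")) {
  if (length(stems) == 0) abort("`stems` must be non-empty.")
  word_presence(docs, labels, setNames(as.list(stems), stems))
}

#' Semantic overlap between clusters
#'
#' For each source cluster, takes its `top_n` words by mean TF-IDF (ties
#' lexicographic) and measures their mean TF-IDF within every target
#' cluster, including the source itself on the diagonal. Off-diagonal
#' entries, symmetrized by averaging the two directions, rank the unordered
#' cluster pairs from most- to least-studied connection.
#'
#' @param tfidf Documents x features TF-IDF matrix.
#' @param labels Per-document cluster labels.
#' @param top_n Words per source cluster (default 20; capped at the number
#'   of features).
#' @param n_pairs How many top/bottom pairs to report (default 3).
#' @return A `litscape_overlap` list: `matrix` (source x target), `top_words`
#'   (list per source cluster), `pairs` (tibble `cluster_a`, `cluster_b`,
#'   `score`, `rank`, `extreme` marking the `n_pairs` most and least studied
#'   pairs).
#' @export
semantic_overlap <- function(tfidf, labels, top_n = 20L, n_pairs = 3L) {
  if (is.null(colnames(tfidf))) {
    colnames(tfidf) <- sprintf("t%04d", seq_len(ncol(tfidf)))
  }
  profiles <- cluster_profiles(tfidf, labels)
  m <- profiles$mean_tfidf
  if (nrow(m) < 2) abort("Need at least 2 clusters.")
  zero <- rowSums(m^2) == 0
  if (any(zero)) {
    warn(sprintf("%d cluster(s) have all-zero TF-IDF profiles; their overlap is 0.",
                 sum(zero)))
  }
  tokens <- colnames(m)
  top_n <- min(top_n, ncol(m))
  top_words <- lapply(seq_len(nrow(m)), function(i) {
    tokens[order(-m[i, ], tokens, method = "radix")[seq_len(top_n)]]
  })
  names(top_words) <- rownames(m)
  overlap <- matrix(0, nrow(m), nrow(m), dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(nrow(m))) {
    if (zero[i]) next
    cols <- match(top_words[[i]], tokens)
    overlap[i, ] <- rowMeans(m[, cols, drop = FALSE])
  }
  overlap[, zero] <- 0
  sym <- (overlap + t(overlap)) / 2
  ut <- which(upper.tri(sym), arr.ind = TRUE)
  pairs <- tibble(
    cluster_a = rownames(m)[ut[, 1]],
    cluster_b = rownames(m)[ut[, 2]],
    score = sym[ut]
  ) |>
    arrange(desc(.data$score), .data$cluster_a, .data$cluster_b) |>
    mutate(rank = row_number())
  n_off <- nrow(pairs)
  pairs$extreme <- ""
  pairs$extreme[seq_len(min(n_pairs, n_off))] <- "most_studied"
  if (n_off > n_pairs) {
    lo <- seq(max(n_off - n_pairs + 1L, n_pairs + 1L), n_off)
    pairs$extreme[lo] <- "least_studied"
  }
  structure(list(matrix = overlap, top_words = top_words, pairs = pairs),
            class = "litscape_overlap")
}
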