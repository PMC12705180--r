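#' TF-IDF weighting of a bag-of-words corpus
#'
#' Computes term weights under one fixed convention used throughout the
#' package: `weight(t, d) = tf(t, d) * log2(N / df_t)` with rows then
#' L2-normalized. Tokens present in every document get weight 0; documents
#' whose tokens all have `df = N` end up with an all-zero row and are
#' flagged.
#'
#' @param bow A `litscape_bow`, or a plain (sparse or dense) document-term
#'   count matrix.
#' @return A sparse `dgCMatrix` of TF-IDF weights, same dimnames as the
#'   counts, each non-empty row of unit L2 norm.
#' @export
compute_tfidf <- function(bow) {
  counts <- if (inherits(bow, "litscape_bow")) bow$counts else Matrix::Matrix(bow, sparse = TRUE)
  n_docs <- nrow(counts)
  if (n_docs == 0) abort("Empty corpus.")
  df <- Matrix::colSums(counts > 0)
  idf <- ifelse(df > 0, log2(n_docs / df), 0)
  w <- counts %*% Matrix::Diagonal(x = idf)
  w <- l2_normalize_rows(w)
  zero <- Matrix::rowSums(w^2) == 0 & Matrix::rowSums(counts) > 0
  if (any(zero)) {
    inform(sprintf("%d document(s) have an all-zero TF-IDF row (all tokens ubiquitous).",
                   sum(zero)))
  }
  dimnames(w) <- dimnames(counts)
  methods::as(w, "CsparseMatrix")
}

#' Topic-weighted word importance
#'
#' Aggregates per-document TF-IDF weights into a K x V matrix of
#' topic-specific word importance: `score(k, t) = sum_d theta[d, k] *
#' tfidf[d, t]`. Top-n per-topic word lists follow by sorting each row
#' (descending score, ties lexicographic).
#'
#' @param tfidf Document-term TF-IDF matrix from [compute_tfidf()].
#' @param theta N x K document-topic matrix (or `litscape_lda` fit).
#' @return K x V dense matrix, column names from `tfidf`.
#' @export
topic_word_importance <- function(tfidf, theta) {
  if (inherits(theta, "litscape_lda")) theta <- theta$theta
  if (nrow(tfidf) != nrow(theta)) {
    abort(sprintf("Row mismatch: %d documents in `tfidf` vs %d in `theta`.",
                  nrow(tfidf), nrow(theta)))
  }
  out <- as.matrix(Matrix::crossprod(Matrix::Matrix(theta, sparse = FALSE), tfidf))
  rownames(out) <- NULL
  out
}

#' Top words per topic by importance score
#'
#' @param importance K x V matrix from [topic_word_importance()].
#' @param n Words per topic.
#' @return Tibble with columns `topic`, `rank`, `token`, `score`.
#' @export
top_important_words <- function(importance, n = 10L) {
  tokens <- colnames(importance)
  bind_rows(lapply(seq_len(nrow(importance)), function(k) {
    ord <- order(-importance[k, ], tokens, method = "radix")[seq_len(min(n, ncol(importance)))]
    tibble(topic = k, rank = seq_along(ord), token = tokens[ord],
           score = importance[k, ord])
  }))
}

#' Yearly topic proportions with trailing smoothing
#'
#' The proportion of topic `k` in year `y` is the mean of `theta[d, k]` over
#' documents published in `y`; per-year proportions therefore sum to 1. A
#' trailing moving average over `window` years is attached (`NA` until a
#' full window exists); years with zero documents are omitted, leaving a gap
#' rather than an interpolation, and the trailing window is taken over the
#' observed years in order.
#'
#' @param theta N x K document-topic matrix (or `litscape_lda` fit).
#' @param years Length-N integer publication years.
#' @param window Smoothing window in years (default 5).
#' @return Tibble with columns `year`, `topic`, `proportion`, `smoothed`.
#' @export
yearly_topic_proportions <- function(theta, years, window = 5L) {
  if (inherits(theta, "litscape_lda")) {
    years <- theta$year
    theta <- theta$theta
  }
  if (nrow(theta) != length(years)) abort("`theta` rows and `years` must align.")
  yrs <- sort(unique(years))
  prop <- t(vapply(yrs, function(y) colMeans(theta[years == y, , drop = FALSE]),
                   numeric(ncol(theta))))
  out <- tibble(
    year = rep(yrs, times = ncol(theta)),
    topic = rep(seq_len(ncol(theta)), each = length(yrs)),
    proportion = as.vector(prop)
  )
  out <- out |>
    group_by(.data$topic) |>
    mutate(smoothed = trailing_mean(.data$proportion, window)) |>
    ungroup() |>
    arrange(.data$topic, .data$year)
  out
}

#' Shannon-entropy diversity of topic mixtures over time
#'
#' Per-document entropy `H(d) = -sum_k theta[d, k] * ln(theta[d, k])`
#' (natural log, `0 ln 0 := 0`), averaged per publication year, with a
#' trailing rolling mean attached (default 10 years). Higher values indicate
#' more diverse topic mixtures; `H` ranges from 0 (pure documents) to
#' `ln(K)` (uniform mixtures).
#'
#' @param theta N x K document-topic matrix (or `litscape_lda` fit).
#' @param years Length-N integer publication years.
#' @param roll Rolling-window length in years (default 10).
#' @return Tibble with columns `year`, `mean_entropy`, `smoothed`.
#' @export
shannon_entropy_series <- function(theta, years, roll = 10L) {
  if (inherits(theta, "litscape_lda")) {
    years <- theta$year
    theta <- theta$theta
  }
  H <- shannon_entropy(theta)
  yrs <- sort(unique(years))
  mean_H <- vapply(yrs, function(y) mean(H[years == y]), numeric(1))
  tibble(year = yrs, mean_entropy = mean_H,
         smoothed = trailing_mean(mean_H, roll))
}

#' Shannon entropy of probability rows (natural log)
#'
#' @param theta Probability vector or row-stochastic matrix.
#' @return Numeric vector of entropies in nats.
#' @export
shannon_entropy <- function(theta) {
  if (is.null(dim(theta))) theta <- matrix(theta, nrow = 1L)
  p <- theta
  terms <- ifelse(p > 0, p * log(p), 0)
  0 - rowSums(terms)   # 0 - x keeps an exact-zero entropy positively signed
}

#' Topic co-occurrence across documents
#'
#' For each document the `top_n` highest-probability topics are identified
#' (ties toward the lower index; all topics when `K < top_n`) and every
#' unordered pair among them is counted as one co-occurrence. Counts are
#' normalized by the total number of documents, giving a symmetric K x K
#' matrix of relative co-occurrence frequencies with a zero diagonal.
#'
#' @param theta N x K document-topic matrix (or `litscape_lda` fit).
#' @param top_n Number of top topics per document (default 5).
#' @return K x K symmetric numeric matrix, entries in `[0, 1]`, zero
#'   diagonal, with attribute `n_docs`.
#' @export
topic_cooccurrence <- function(theta, top_n = 5L) {
  if (inherits(theta, "litscape_lda")) theta <- theta$theta
  K <- ncol(theta)
  if (K < 2) abort("Co-occurrence needs at least 2 topics.")
  n_docs <- nrow(theta)
  m <- min(top_n, K)
  counts <- matrix(0, K, K)
  for (d in seq_len(n_docs)) {
    top <- order(-theta[d, ])[seq_len(m)]   # stable: ties toward lower index
    counts[top, top] <- counts[top, top] + 1
  }
  diag(counts) <- 0
  out <- counts / n_docs
  attr(out, "n_docs") <- n_docs
  attr(out, "top_n") <- as.integer(top_n)
  out
}

#' Chord-diagram edge list from a co-occurrence matrix
#'
#' Unordered topic pairs whose relative co-occurrence strictly exceeds
#' `threshold`, sorted by descending weight. These are the links a chord
#' diagram would draw; the package emits the table rather than the figure.
#'
#' @param m Symmetric co-occurrence matrix from [topic_cooccurrence()].
#' @param threshold Strict lower bound on the edge weight (default 0.033).
#' @return Tibble with columns `topic_i`, `topic_j`, `weight`.
#' @export
chord_links <- function(m, threshold = 0.033) {
  K <- nrow(m)
  pairs <- which(upper.tri(m) & m > threshold, arr.ind = TRUE)
  out <- tibble(
    topic_i = as.integer(pairs[, 1]),
    topic_j = as.integer(pairs[, 2]),
    weight = m[pairs]
  )
  arrange(out, desc(.data$weight), .data$topic_i, .data$topic_j)
}

#' Default valence lexicon
#'
#' Loads the compact general-purpose valence lexicon shipped with the
#' package (tab-separated `token`, `valence` in `[-4, 4]`, Porter-stemmed
#' tokens). Any lexicon with the same layout can be substituted, e.g. a
#' published sentiment dictionary, via the `lexicon` argument of
#' [sentiment_analysis()].
#'
#' @param path Optional path to an alternative lexicon file.
#' @return Named numeric vector (token -> valence).
#' @export
default_lexicon <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "valence_lexicon.tsv", package = "litscape")
  }
  tab <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  setNames(tab$valence, tab$token)
}

#' Lexicon-based sentiment of a corpus
#'
#' Scores each document with the standard valence-normalization form: with
#' `S` the sum of matched token valences, the compound score is
#' `S / sqrt(S^2 + 15)`, clipped to `[-1, 1]`; documents with no lexicon
#' matches score 0. Keywords are the top `max_keywords` corpus features
#' (the same frequency-based selection used for TF-IDF vectorization); each
#' keyword's score is the mean compound over the documents containing it.
#' A yearly mean-compound series is attached.
#'
#' @param docs Tokenized-document tibble.
#' @param bow The matching `litscape_bow` (used for keyword extraction).
#' @param lexicon Named numeric vector token -> valence (default
#'   [default_lexicon()]).
#' @param max_keywords Maximum number of keywords (default 500).
#' @return A list: `document` (tibble `doc_id`, `year`, `compound`),
#'   `keyword` (tibble `keyword`, `mean_compound`, `n_docs`), `yearly`
#'   (tibble `year`, `mean_compound`).
#' @export
sentiment_analysis <- function(docs, bow, lexicon = default_lexicon(),
                               max_keywords = 500L) {
  if (length(lexicon) == 0) abort("`lexicon` must be non-empty.")
  compound <- vapply(docs$tokens, function(toks) {
    v <- lexicon[toks]
    s <- sum(v, na.rm = TRUE)
    max(min(s / sqrt(s^2 + 15), 1), -1)
  }, numeric(1))
  document <- tibble(doc_id = docs$doc_id, year = docs$year, compound = compound)

  keywords <- select_features(bow$counts, max_keywords)
  keyword <- bind_rows(lapply(keywords, function(kw) {
    has <- vapply(docs$tokens, function(toks) kw %in% toks, logical(1))
    tibble(keyword = kw,
           mean_compound = if (any(has)) mean(compound[has]) else NA_real_,
           n_docs = sum(has))
  }))

  yearly <- document |>
    group_by(year = .data$year) |>
    summarise(mean_compound = mean(.data$compound), .groups = "drop") |>
    arrange(.data$year)

  list(document = document, keyword = keyword, yearly = yearly)
}
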