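#' Default English stopword list
#'
#' Loads the stopword list shipped with the package (one token per line,
#' plain text). Any list with the same format can be supplied instead, e.g.
#' a study-specific list, via the `stopwords` arguments downstream.
#'
#' @param path Optional path to an alternative stopword file.
#' @return Character vector of stopwords.
#' @export
default_stopwords <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "stopwords_en.txt", package = "litscape")
  }
  words <- readLines(path, encoding = "UTF-8", warn = FALSE)
  words[nzchar(words)]
}

#' Tokenize free text into stems
#'
#' Applies the preprocessing pipeline in a fixed order: strip markup tags,
#' strip punctuation, collapse whitespace, strip numerics, lowercase, remove
#' stopwords, drop tokens shorter than three characters, and Porter-stem each
#' surviving token (see [porter_stem()]).
#'
#' @param text Character vector of raw texts.
#' @param stopwords Character vector of stopwords (default:
#'   [default_stopwords()]).
#' @param min_chars Minimum token length before stemming (default 3).
#' @return For a single text, a character vector of stems; for several texts,
#'   a list of such vectors.
#' @examples
#' tokenize("The 25 cells, aging!")
#' @export
tokenize <- function(text, stopwords = default_stopwords(), min_chars = 3L) {
  one <- function(x) {
    if (is.na(x) || !nzchar(x)) return(character(0))
    x <- gsub("<[^>]*>", " ", x)              # markup
    x <- gsub("[[:punct:]]", " ", x)          # punctuation
    x <- gsub("\\s+", " ", trimws(x))         # whitespace
    x <- gsub("\\b[0-9]+\\b", " ", x)         # standalone numerics
    x <- tolower(x)
    toks <- strsplit(x, " ", fixed = TRUE)[[1]]
    toks <- toks[nzchar(toks)]
    toks <- toks[!(toks %in% stopwords)]
    toks <- toks[nchar(toks) >= min_chars]
    porter_stem(toks)
  }
  if (length(text) == 1L) one(text) else lapply(text, one)
}

#' Tokenize a corpus
#'
#' Maps [tokenize()] over a corpus, producing a tokenized-document tibble
#' with columns `doc_id`, `year`, and a `tokens` list-column of stems.
#'
#' @param corpus A corpus tibble (see [as_corpus()]).
#' @param stopwords Stopword list.
#' @return Tibble with columns `doc_id`, `year`, `tokens`.
#' @export
tokenize_corpus <- function(corpus, stopwords = default_stopwords()) {
  # same pipeline as tokenize(), vectorized over the corpus with a single
  # corpus-wide stemming pass
  x <- corpus$abstract
  x[is.na(x)] <- ""
  x <- gsub("<[^>]*>", " ", x)
  x <- gsub("[[:punct:]]", " ", x)
  x <- gsub("\\s+", " ", trimws(x))
  x <- gsub("\\b[0-9]+\\b", " ", x)
  x <- tolower(x)
  toks <- strsplit(x, " ", fixed = TRUE)
  flat <- unlist(toks, use.names = FALSE)
  doc_ix <- rep.int(seq_along(toks), lengths(toks))
  keep <- nzchar(flat) & !(flat %in% stopwords) & nchar(flat) >= 3L
  flat <- porter_stem(flat[keep])
  doc_ix <- doc_ix[keep]
  tibble(
    doc_id = corpus$doc_id,
    year = corpus$year,
    tokens = unname(split(flat, factor(doc_ix, levels = seq_along(toks))))
  )
}

#' Retain documents by post-preprocessing token count
#'
#' A document survives iff `min_tokens <= length(tokens) <= max_tokens`
#' (inclusive bounds); order is preserved and the counts of dropped-short and
#' dropped-long documents are reported.
#'
#' @param docs Tokenized-document tibble from [tokenize_corpus()].
#' @param min_tokens,max_tokens Inclusive bounds (defaults 30 and 500).
#' @return The retained subset of `docs`.
#' @export
filter_by_length <- function(docs, min_tokens = 30L, max_tokens = 500L) {
  if (min_tokens > max_tokens) {
    abort("`min_tokens` must not exceed `max_tokens`.")
  }
  n_tok <- lengths(docs$tokens)
  short <- n_tok < min_tokens
  long <- n_tok > max_tokens
  if (any(short) || any(long)) {
    inform(sprintf("Length filter [%d, %d]: dropped %d short and %d long; %d retained.",
                   min_tokens, max_tokens, sum(short), sum(long),
                   sum(!short & !long)))
  }
  docs[!short & !long, , drop = FALSE]
}

#' Build a pruned token vocabulary
#'
#' Maps tokens to contiguous integer ids (from 0, in lexicographic token
#' order) after frequency pruning: a token is retained iff its document
#' frequency is at least `ceiling(min_doc_fraction * n_docs)` (or at least
#' `min_doc_count` when that absolute override is given) and at most
#' `max_doc_fraction * n_docs`. The fractional floor generalizes an absolute
#' cutoff (e.g. 5,000 documents on a ~460k corpus is a fraction of ~0.011)
#' so that small corpora prune sensibly.
#'
#' @param docs Tokenized-document tibble.
#' @param min_doc_fraction Minimum document-frequency fraction (default 0.011).
#' @param max_doc_fraction Maximum document-frequency fraction (default 0.30).
#' @param min_doc_count Optional absolute floor overriding the fraction.
#' @return A `litscape_vocabulary`: tibble with columns `token`, `id`,
#'   `doc_freq`, and attribute `n_docs`.
#' @export
build_vocabulary <- function(docs, min_doc_fraction = 0.011,
                             max_doc_fraction = 0.30, min_doc_count = NULL) {
  if (nrow(docs) == 0) abort("Cannot build a vocabulary from zero documents.")
  n_docs <- nrow(docs)
  df <- table(unlist(lapply(docs$tokens, unique)))
  floor_count <- if (is.null(min_doc_count)) {
    ceiling(min_doc_fraction * n_docs)
  } else {
    min_doc_count
  }
  keep <- as.integer(df) >= floor_count &
    as.integer(df) / n_docs <= max_doc_fraction
  tokens <- names(df)[keep]
  if (length(tokens) == 0) {
    abort(paste0(
      "Vocabulary is empty after frequency pruning; relax `min_doc_fraction`/",
      "`min_doc_count` or raise `max_doc_fraction`."
    ))
  }
  ord <- order(tokens, method = "radix")   # deterministic lexicographic ids
  tokens <- tokens[ord]
  out <- tibble(
    token = tokens,
    id = seq_along(tokens) - 1L,
    doc_freq = as.integer(df[tokens])
  )
  attr(out, "n_docs") <- n_docs
  class(out) <- c("litscape_vocabulary", class(out))
  out
}

#' Convert tokenized documents to a bag-of-words corpus
#'
#' Produces the sparse document-term count matrix over a vocabulary.
#' Out-of-vocabulary tokens are silently dropped; documents left with no
#' in-vocabulary tokens are counted and reported.
#'
#' @param docs Tokenized-document tibble.
#' @param vocab A [build_vocabulary()] result.
#' @return A `litscape_bow` list: `counts` (sparse `dgCMatrix`, documents x
#'   tokens, dimnames `doc_id` x `token`), `doc_id`, `year`, `vocab`.
#' @export
to_bow <- function(docs, vocab) {
  if (!inherits(vocab, "litscape_vocabulary")) {
    abort("`vocab` must be created with build_vocabulary().")
  }
  n_docs <- nrow(docs)
  V <- nrow(vocab)
  tok_all <- unlist(docs$tokens, use.names = FALSE)
  doc_ix <- rep.int(seq_len(n_docs), lengths(docs$tokens))
  col_ix <- match(tok_all, vocab$token)
  ok <- !is.na(col_ix)
  counts <- Matrix::sparseMatrix(
    i = doc_ix[ok], j = col_ix[ok], x = 1,
    dims = c(n_docs, V),
    dimnames = list(docs$doc_id, vocab$token)
  )                                  # duplicate (i, j) entries are summed
  empty <- Matrix::rowSums(counts) == 0
  if (any(empty)) {
    inform(sprintf("%d document(s) have no in-vocabulary tokens.", sum(empty)))
  }
  structure(
    list(counts = counts, doc_id = docs$doc_id, year = docs$year, vocab = vocab),
    class = "litscape_bow"
  )
}

#' @export
print.litscape_bow <- function(x, ...) {
  cat(sprintf("<litscape_bow> %d documents x %d tokens, %d nonzero counts\n",
              nrow(x$counts), ncol(x$counts), Matrix::nnzero(x$counts)))
  invisible(x)
}

#' Preprocess a corpus end to end
#'
#' Convenience wrapper chaining [tokenize_corpus()], [filter_by_length()],
#' [build_vocabulary()] and [to_bow()].
#'
#' @inheritParams tokenize_corpus
#' @inheritParams filter_by_length
#' @inheritParams build_vocabulary
#' @return A list with `docs` (retained tokenized documents), `vocab`, `bow`.
#' @export
preprocess_corpus <- function(corpus, stopwords = default_stopwords(),
                              min_tokens = 30L, max_tokens = 500L,
                              min_doc_fraction = 0.011, max_doc_fraction = 0.30,
                              min_doc_count = NULL) {
  docs <- tokenize_corpus(corpus, stopwords)
  docs <- filter_by_length(docs, min_tokens, max_tokens)
  vocab <- build_vocabulary(docs, min_doc_fraction, max_doc_fraction, min_doc_count)
  list(docs = docs, vocab = vocab, bow = to_bow(docs, vocab))
}
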