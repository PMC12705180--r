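# Small fixture builders shared across test files.

make_corpus <- function(ids, titles, abstracts, years) {
  as_corpus(tibble::tibble(
    doc_id = ids, title = titles, abstract = abstracts, year = years
  ))
}

# tokenized-document tibble built directly from token lists
make_token_docs <- function(token_lists, years = NULL) {
  n <- length(token_lists)
  tibble::tibble(
    doc_id = sprintf("d%03d", seq_len(n)),
    year = if (is.null(years)) rep(2000L, n) else as.integer(years),
    tokens = token_lists
  )
}

# bag-of-words straight from a dense count matrix (columns = tokens)
make_bow <- function(counts, years = NULL) {
  counts <- as.matrix(counts)
  if (is.null(colnames(counts))) {
    colnames(counts) <- sprintf("tok%02d", seq_len(ncol(counts)))
  }
  docs <- make_token_docs(
    lapply(seq_len(nrow(counts)), function(d) {
      rep(colnames(counts), times = counts[d, ])
    }),
    years = years
  )
  vocab <- build_vocabulary(docs, min_doc_fraction = 0, max_doc_fraction = 1)
  to_bow(docs, vocab)
}

# quick synthetic corpus -> preprocessed pieces, pruning disabled
quick_prep <- function(spec) {
  gen <- generate_corpus(spec)
  prep <- suppressMessages(
    preprocess_corpus(gen$corpus, min_doc_fraction = 0, max_doc_fraction = 1)
  )
  list(gen = gen, docs = prep$docs, vocab = prep$vocab, bow = prep$bow,
       truth = gen$truth)
}

# align a learned phi's columns with the truth matrix's vocabulary
align_phi <- function(phi_learned, phi_true) {
  common <- intersect(colnames(phi_learned), colnames(phi_true))
  list(learned = phi_learned[, common, drop = FALSE],
       true = phi_true[, common, drop = FALSE])
}
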