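#' c_v topic coherence
#'
#' Scores a set of topics (given as top-word lists) against a tokenized
#' corpus with the c_v measure: boolean sliding-window co-occurrence counts
#' (window size 110), NPMI context vectors (epsilon 1e-12), and indirect
#' cosine similarity under one-set segmentation (each top word against the
#' full top-word set), averaged over words and then over topics. Documents
#' shorter than the window contribute a single window.
#'
#' @param top_words List of character vectors, one per topic (the top-M
#'   words of each topic).
#' @param docs Tokenized-document tibble (see [tokenize_corpus()]).
#' @param window Sliding-window length in tokens (default 110).
#' @param eps Pseudo-probability guarding the NPMI logarithms.
#' @return A list: `coherence` (scalar mean over topics) and `per_topic`.
#' @export
cv_coherence <- function(top_words, docs, window = 110L, eps = 1e-12) {
  words <- unique(unlist(top_words))
  m <- length(words)
  if (m == 0) abort("`top_words` is empty.")
  joint <- matrix(0, m, m, dimnames = list(words, words))
  n_windows <- 0

  for (tokens in docs$tokens) {
    L <- length(tokens)
    if (L == 0) next
    idx <- match(tokens, words)          # position -> word index or NA
    present_pos <- which(!is.na(idx))
    if (L <= window) {
      n_windows <- n_windows + 1
      if (length(present_pos) == 0) next
      pw <- unique(idx[present_pos])
      joint[pw, pw] <- joint[pw, pw] + 1
    } else {
      W <- L - window + 1L
      n_windows <- n_windows + W
      if (length(present_pos) == 0) next
      pw <- sort(unique(idx[present_pos]))
      # boolean windows x present-words matrix: word w occupies windows
      # [pos - window + 1, pos] for each occurrence position
      occ <- matrix(0L, W, length(pw))
      for (j in seq_along(pw)) {
        pos <- present_pos[idx[present_pos] == pw[j]]
        starts <- pmax(pos - window + 1L, 1L)
        ends <- pmin(pos, W)
        ok <- starts <= ends
        cover <- tabulate(starts[ok], nbins = W + 1L) -
          tabulate(ends[ok] + 1L, nbins = W + 1L)
        occ[, j] <- as.integer(cumsum(cover[seq_len(W)]) > 0L)
      }
      joint[pw, pw] <- joint[pw, pw] + crossprod(occ)
    }
  }
  if (n_windows == 0) abort("No tokens available to form co-occurrence windows.")

  p_joint <- joint / n_windows
  p_word <- diag(p_joint)
  # NPMI with epsilon guard
  lj <- log(p_joint + eps)
  npmi <- (lj - log(outer(p_word, p_word) + eps)) / (-lj)
  npmi[lj == 0] <- 1

  per_topic <- vapply(top_words, function(tw) {
    ix <- match(unique(tw), words)
    ctx <- npmi[ix, ix, drop = FALSE]      # context vectors over topic words
    v_set <- colSums(ctx)
    sims <- vapply(seq_along(ix), function(i) cosine_sim(ctx[i, ], v_set),
                   numeric(1))
    mean(sims)
  }, numeric(1))

  list(coherence = mean(per_topic), per_topic = per_topic)
}

# top-M words per topic from a topic-word matrix, ties lexicographic
top_topic_words <- function(phi, top_m = 20L) {
  tokens <- colnames(phi)
  if (is.null(tokens)) tokens <- as.character(seq_len(ncol(phi)))
  lapply(seq_len(nrow(phi)), function(k) {
    ord <- order(-phi[k, ], tokens, method = "radix")
    tokens[head(ord, top_m)]
  })
}

#' Select the topic count by c_v coherence
#'
#' Trains one LDA model per candidate topic count (with a reduced number of
#' passes for tractability) and scores each with [cv_coherence()] over the
#' tokenized corpus. The selected `k_star` is the argmax of coherence, ties
#' broken toward the smaller topic count. Candidates with `k >= n_docs` are
#' skipped with a warning.
#'
#' @param bow A `litscape_bow`.
#' @param docs The matching tokenized-document tibble.
#' @param k_values Candidate topic counts (default `seq(5, 50, by = 5)`).
#' @param seed Integer seed used for every candidate fit.
#' @param scan_passes Sampler sweeps per candidate model (default 20).
#'   Collapsed-Gibbs sweeps are cheap, and under-converged scan models bias
#'   c_v toward larger topic counts (fragments of true topics remain
#'   coherent), so the scan uses full sweeps by default; lower this for very
#'   large corpora.
#' @param top_m Top words per topic entering the coherence computation.
#' @param window Sliding-window length.
#' @return A `litscape_coherence` list: `report` (tibble `k`, `coherence`)
#'   and `k_star`.
#' @export
coherence_scan <- function(bow, docs, k_values = seq(5L, 50L, by = 5L),
                           seed = 1L, scan_passes = 20L, top_m = 20L,
                           window = 110L) {
  n_docs <- nrow(bow$counts)
  if (n_docs < 2 || ncol(bow$counts) < 2) {
    abort("Coherence scan needs at least 2 documents and 2 vocabulary tokens.")
  }
  usable <- k_values[k_values < n_docs]
  skipped <- setdiff(k_values, usable)
  if (length(skipped) > 0) {
    warn(sprintf("Skipping k >= number of documents: %s.",
                 paste(skipped, collapse = ", ")))
  }
  scores <- vapply(usable, function(k) {
    fit <- train_lda(bow, K = k, passes = scan_passes, seed = seed)
    cv_coherence(top_topic_words(fit$phi, top_m), docs, window = window)$coherence
  }, numeric(1))
  report <- tibble(k = as.integer(usable), coherence = scores)
  k_star <- report$k[order(-report$coherence, report$k)][1]
  structure(list(report = report, k_star = k_star),
            class = "litscape_coherence")
}

#' @export
print.litscape_coherence <- function(x, ...) {
  cat(sprintf("<litscape_coherence> k_star = %d\n", x$k_star))
  print(x$report)
  invisible(x)
}
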