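# Brute-force reference implementations used as independent oracles.
# Deliberately naive (explicit loops), sharing no code with the package
# internals they check.

oracle_tfidf <- function(counts) {
  counts <- as.matrix(counts)
  n <- nrow(counts)
  out <- matrix(0, n, ncol(counts), dimnames = dimnames(counts))
  df <- sapply(seq_len(ncol(counts)), function(j) sum(counts[, j] > 0))
  for (d in seq_len(n)) {
    for (t in seq_len(ncol(counts))) {
      if (counts[d, t] > 0 && df[t] > 0) {
        out[d, t] <- counts[d, t] * log2(n / df[t])
      }
    }
    nrm <- sqrt(sum(out[d, ]^2))
    if (nrm > 0) out[d, ] <- out[d, ] / nrm
  }
  out
}

oracle_importance <- function(tfidf, theta) {
  tfidf <- as.matrix(tfidf)
  K <- ncol(theta)
  out <- matrix(0, K, ncol(tfidf), dimnames = list(NULL, colnames(tfidf)))
  for (k in seq_len(K)) {
    for (t in seq_len(ncol(tfidf))) {
      s <- 0
      for (d in seq_len(nrow(tfidf))) s <- s + theta[d, k] * tfidf[d, t]
      out[k, t] <- s
    }
  }
  out
}

oracle_cooccurrence <- function(theta, top_n = 5) {
  K <- ncol(theta)
  m <- min(top_n, K)
  counts <- matrix(0, K, K)
  for (d in seq_len(nrow(theta))) {
    top <- order(-theta[d, ])[seq_len(m)]
    for (a in seq_along(top)) {
      for (b in seq_along(top)) {
        if (a < b) {
          counts[top[a], top[b]] <- counts[top[a], top[b]] + 1
          counts[top[b], top[a]] <- counts[top[b], top[a]] + 1
        }
      }
    }
  }
  counts / nrow(theta)
}

oracle_enrichment <- function(theta, labels, eps = 1e-9) {
  cl <- sort(unique(labels))
  K <- ncol(theta)
  out <- matrix(0, length(cl), K)
  for (i in seq_along(cl)) {
    members <- which(labels == cl[i])
    for (k in seq_len(K)) {
      obs <- sum(theta[members, k])
      exp_ <- sum(theta[, k]) * length(members) / nrow(theta)
      out[i, k] <- log2((obs + eps) / (exp_ + eps))
    }
  }
  rownames(out) <- as.character(cl)
  out
}

oracle_differential <- function(tfidf, labels) {
  tfidf <- as.matrix(tfidf)
  cl <- sort(unique(labels))
  out <- matrix(0, length(cl), ncol(tfidf),
                dimnames = list(as.character(cl), colnames(tfidf)))
  for (i in seq_along(cl)) {
    for (t in seq_len(ncol(tfidf))) {
      own <- mean(tfidf[labels == cl[i], t])
      best_other <- max(sapply(cl[cl != cl[i]], function(c2) {
        mean(tfidf[labels == c2, t])
      }))
      out[i, t] <- own - best_other
    }
  }
  out
}

oracle_overlap <- function(tfidf, labels, top_n = 20) {
  tfidf <- as.matrix(tfidf)
  cl <- sort(unique(labels))
  tokens <- colnames(tfidf)
  means <- t(sapply(cl, function(c) colMeans(tfidf[labels == c, , drop = FALSE])))
  top_n <- min(top_n, ncol(tfidf))
  out <- matrix(0, length(cl), length(cl),
                dimnames = list(as.character(cl), as.character(cl)))
  for (i in seq_along(cl)) {
    ord <- order(-means[i, ], tokens)[seq_len(top_n)]
    for (j in seq_along(cl)) {
      out[i, j] <- mean(means[j, ord])
    }
  }
  out
}

# sequential-scan duplicate count: a document is a duplicate if its id or its
# normalized text key has been seen before (both keys become "seen" either way)
oracle_dedup_count <- function(corpus) {
  seen_id <- character(0)
  seen_text <- character(0)
  kept <- 0L
  norm <- function(x) tolower(gsub("\\s+", " ", trimws(x)))
  for (i in seq_len(nrow(corpus))) {
    id <- corpus$doc_id[i]
    key <- paste(norm(corpus$title[i]), norm(corpus$abstract[i]), sep = "|")
    if (!(id %in% seen_id) && !(key %in% seen_text)) kept <- kept + 1L
    seen_id <- c(seen_id, id)
    seen_text <- c(seen_text, key)
  }
  kept
}

# optimal assignment by exhaustive permutation search (square case, K <= 6)
oracle_assignment <- function(sim) {
  K <- nrow(sim)
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    }
    out
  }
  best <- NULL
  best_score <- -Inf
  for (p in perms(seq_len(K))) {
    s <- sum(sim[cbind(seq_len(K), p)])
    if (s > best_score) {
      best_score <- s
      best <- p
    }
  }
  list(perm = best, score = best_score)
}
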