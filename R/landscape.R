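# Document-landscape construction: capped TF-IDF features, PCA, kNN graph,
# Leiden communities, and a 2-D layout for visualization only.

# top max_features tokens by corpus-wide total count, ties lexicographic
select_features <- function(counts, max_features) {
  totals <- Matrix::colSums(counts)
  tokens <- colnames(counts)
  ord <- order(-totals, tokens, method = "radix")
  tokens[head(ord, max_features)]
}

#' Capped TF-IDF vectorization
#'
#' Restricts the vocabulary to the `max_features` tokens with the highest
#' corpus-wide total count (ties broken lexicographically), recomputes
#' document frequencies on the restricted vocabulary, and applies the
#' package-wide TF-IDF convention with L2 row normalization. Documents with
#' no retained tokens become zero rows and are flagged.
#'
#' @param bow A `litscape_bow`.
#' @param max_features Feature cap (default 500). When the vocabulary is
#'   smaller, all tokens are used and a note is emitted.
#' @return A list: `features` (character), `tfidf` (sparse documents x
#'   features matrix).
#' @export
vectorize_features <- function(bow, max_features = 500L) {
  counts <- bow$counts
  if (ncol(counts) < max_features) {
    inform(sprintf("Vocabulary (%d) smaller than max_features (%d); using all tokens.",
                   ncol(counts), max_features))
  }
  features <- select_features(counts, max_features)
  restricted <- counts[, features, drop = FALSE]
  w <- suppressMessages(compute_tfidf(restricted))
  zero <- Matrix::rowSums(restricted) == 0
  if (any(zero)) {
    inform(sprintf("%d document(s) contain none of the %d selected features.",
                   sum(zero), length(features)))
  }
  list(features = features, tfidf = w)
}

#' PCA reduction with a fixed sign convention
#'
#' Mean-centered principal-component scores of a document-feature matrix.
#' For reproducibility each component's sign is fixed so that its
#' largest-magnitude loading is positive.
#'
#' @param x Matrix (sparse accepted; densified internally).
#' @param n_pcs Number of components; clamped with a warning when it exceeds
#'   `min(n_docs - 1, n_features)`.
#' @return Score matrix (documents x components) with attributes `rotation`
#'   and `sdev`.
#' @export
pca_reduce <- function(x, n_pcs) {
  x <- as.matrix(x)
  limit <- min(nrow(x) - 1L, ncol(x))
  if (n_pcs > limit) {
    warn(sprintf("n_pcs = %d clamped to %d.", n_pcs, limit))
    n_pcs <- limit
  }
  fit <- stats::prcomp(x, center = TRUE, scale. = FALSE, rank. = n_pcs)
  rot <- fit$rotation
  flip <- vapply(seq_len(ncol(rot)), function(j) {
    l <- rot[which.max(abs(rot[, j])), j]
    if (l < 0) -1 else 1
  }, numeric(1))
  scores <- sweep(fit$x, 2, flip, `*`)
  structure(scores,
            rotation = sweep(rot, 2, flip, `*`),
            sdev = fit$sdev[seq_len(ncol(rot))])
}

# symmetric (union) k-nearest-neighbor graph in Euclidean space
knn_graph <- function(coords, n_neighbors) {
  n <- nrow(coords)
  if (n < 2) abort("Need at least 2 documents to build a neighbor graph.")
  k <- min(n_neighbors, n - 1L)
  d <- as.matrix(stats::dist(coords))
  edges <- vector("list", n)
  for (i in seq_len(n)) {
    nb <- order(d[i, ])[2:(k + 1L)]
    edges[[i]] <- cbind(i, nb)
  }
  e <- do.call(rbind, edges)
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  e <- unique(e)                        # union symmetrization
  g <- igraph::make_empty_graph(n, directed = FALSE)
  g <- igraph::add_edges(g, t(e))
  igraph::E(g)$distance <- d[e]
  g
}

#' 2-D document embedding for visualization
#'
#' Projects documents to two dimensions by a seeded force-directed
#' (Fruchterman-Reingold) layout of the symmetrized k-nearest-neighbor graph
#' built in PCA space, with edges weighted by inverse distance; disconnected
#' graph components are laid out separately and tiled side by side. The
#' embedding is stochastic but fully reproducible for a fixed seed. It is
#' used for visualization only: no downstream statistic reads these
#' coordinates.
#'
#' @param pca_coords Documents x components score matrix.
#' @param n_neighbors Neighbors for the graph (default 5).
#' @param seed Integer seed.
#' @return Documents x 2 coordinate matrix.
#' @export
embed_2d <- function(pca_coords, n_neighbors = 5L, seed = 1L) {
  n <- nrow(pca_coords)
  if (n < n_neighbors + 1L) {
    abort(sprintf("Need at least n_neighbors + 1 = %d documents.", n_neighbors + 1L))
  }
  g <- knn_graph(pca_coords, n_neighbors)
  w <- 1 / (1 + igraph::E(g)$distance)
  with_seed(seed, {
    comps <- igraph::components(g)
    coords <- matrix(0, n, 2)
    x_offset <- 0
    for (c_id in seq_len(comps$no)) {
      members <- which(comps$membership == c_id)
      sub <- igraph::induced_subgraph(g, members)
      xy <- if (length(members) == 1L) {
        matrix(0, 1, 2)
      } else {
        igraph::layout_with_fr(sub, weights = 1 / (1 + igraph::E(sub)$distance))
      }
      xy[, 1] <- xy[, 1] - min(xy[, 1]) + x_offset
      x_offset <- max(xy[, 1]) + diff(range(xy[, 1])) * 0.5 + 3
      coords[members, ] <- xy
    }
    colnames(coords) <- c("dim1", "dim2")
    coords
  })
}

#' Leiden clustering of documents in PCA space
#'
#' Builds the union-symmetrized k-nearest-neighbor graph (Euclidean metric
#' in PCA space) and partitions it with the Leiden algorithm optimizing
#' RB-configuration modularity at the given resolution. Cluster labels are
#' relabeled by descending cluster size, starting at 0. Clustering reads
#' only PCA coordinates, never the 2-D embedding.
#'
#' @param pca_coords Documents x components score matrix.
#' @param n_neighbors Neighbors for the graph (default 5).
#' @param resolution Leiden resolution parameter (default 0.7).
#' @param seed Integer seed.
#' @param n_iterations Leiden refinement iterations (default 10).
#' @return Integer vector of 0-based cluster labels.
#' @export
leiden_cluster <- function(pca_coords, n_neighbors = 5L, resolution = 0.7,
                           seed = 1L, n_iterations = 10L) {
  n <- nrow(pca_coords)
  if (n < 2) abort("Need at least 2 documents to cluster.")
  # degenerate input: identical documents form a single cluster by definition
  if (all(abs(sweep(pca_coords, 2, pca_coords[1, ])) < 1e-12)) {
    return(rep(0L, n))
  }
  g <- knn_graph(pca_coords, n_neighbors)
  membership <- with_seed(seed, {
    igraph::cluster_leiden(
      g, objective_function = "modularity",
      resolution = resolution, n_iterations = n_iterations
    )$membership
  })
  relabel_by_size(membership)
}

# relabel integer memberships as 0-based labels in descending size order,
# ties broken by first appearance
relabel_by_size <- function(membership) {
  tab <- table(membership)
  first_seen <- vapply(names(tab), function(l) match(l, as.character(membership)),
                       integer(1))
  ord <- names(tab)[order(-as.integer(tab), first_seen)]
  as.integer(match(as.character(membership), ord)) - 1L
}

#' Build the full document landscape
#'
#' Chains [vectorize_features()], [pca_reduce()], [embed_2d()] and
#' [leiden_cluster()] into a single landscape object.
#'
#' @param bow A `litscape_bow`.
#' @param max_features TF-IDF feature cap (default 500).
#' @param n_pcs Principal components (default 50).
#' @param n_neighbors kNN graph neighbors (default 5).
#' @param resolution Leiden resolution (default 0.7).
#' @param seed Integer seed (drives embedding and clustering).
#' @return A `litscape_landscape` list: `doc_id`, `year`, `features`,
#'   `tfidf`, `pca`, `embedding`, `labels` (0-based), `params`.
#' @export
build_landscape <- function(bow, max_features = 500L, n_pcs = 50L,
                            n_neighbors = 5L, resolution = 0.7, seed = 1L) {
  vec <- vectorize_features(bow, max_features)
  pca <- pca_reduce(vec$tfidf, n_pcs)
  emb <- embed_2d(pca, n_neighbors, seed)
  labels <- leiden_cluster(pca, n_neighbors, resolution, seed)
  structure(
    list(doc_id = bow$doc_id, year = bow$year, features = vec$features,
         tfidf = vec$tfidf, pca = pca, embedding = emb, labels = labels,
         params = list(max_features = max_features, n_pcs = n_pcs,
                       n_neighbors = n_neighbors, resolution = resolution,
                       seed = seed)),
    class = "litscape_landscape"
  )
}

#' @export
print.litscape_landscape <- function(x, ...) {
  cat(sprintf("<litscape_landscape> %d documents, %d features, %d PCs, %d clusters\n",
              length(x$doc_id), length(x$features), ncol(x$pca),
              length(unique(x$labels))))
  invisible(x)
}

#' Differential words per cluster
#'
#' For every token and cluster, the differential score is the token's mean
#' TF-IDF within the cluster minus the maximum of its mean TF-IDF over all
#' other clusters. Positive scores mark tokens specific to the cluster.
#'
#' @param tfidf Documents x features TF-IDF matrix.
#' @param labels Per-document cluster labels.
#' @param top_k Top words per cluster to list (default 3).
#' @return A list: `scores` (clusters x features matrix, rownames are
#'   labels) and `top` (tibble `cluster`, `rank`, `token`, `score`; ties
#'   lexicographic).
#' @export
differential_words <- function(tfidf, labels, top_k = 3L) {
  cl <- sort(unique(labels))
  if (length(cl) < 2) abort("Differential words need at least 2 clusters.")
  if (is.null(colnames(tfidf))) {
    colnames(tfidf) <- sprintf("t%04d", seq_len(ncol(tfidf)))
  }
  means <- do.call(rbind, lapply(cl, function(c) {
    Matrix::colMeans(tfidf[labels == c, , drop = FALSE])
  }))
  rownames(means) <- as.character(cl)
  scores <- means
  for (i in seq_along(cl)) {
    others <- means[-i, , drop = FALSE]
    scores[i, ] <- means[i, ] - apply(others, 2, max)
  }
  tokens <- colnames(tfidf)
  top <- bind_rows(lapply(seq_along(cl), function(i) {
    ord <- order(-scores[i, ], tokens, method = "radix")[seq_len(min(top_k, ncol(scores)))]
    tibble(cluster = cl[i], rank = seq_along(ord), token = tokens[ord],
           score = scores[i, ord])
  }))
  list(scores = scores, top = top)
}

#' Presence of word groups per cluster
#'
#' A document "contains" a word group iff any stem in the group is a prefix
#' of any of the document's stemmed tokens (case-insensitive). The
#' proportion of containing documents is reported per cluster and group.
#'
#' @param docs Tokenized-document tibble aligned with `labels`.
#' @param labels Per-document cluster labels.
#' @param word_groups Named list of character stem vectors.
#' @return Clusters x groups numeric matrix of proportions.
#' @export
word_presence <- function(docs, labels, word_groups) {
  if (length(word_groups) == 0) abort("`word_groups` must be non-empty.")
  if (is.null(names(word_groups))) {
    names(word_groups) <- vapply(word_groups, function(g) g[1], character(1))
  }
  cl <- sort(unique(labels))
  has_group <- vapply(word_groups, function(stems) {
    stems <- tolower(stems)
    vapply(docs$tokens, function(toks) {
      any(vapply(stems, function(s) any(startsWith(tolower(toks), s)), logical(1)))
    }, logical(1))
  }, logical(nrow(docs)))
  if (nrow(docs) == 1L) has_group <- matrix(has_group, nrow = 1L,
                                            dimnames = list(NULL, names(word_groups)))
  out <- do.call(rbind, lapply(cl, function(c) {
    in_c <- labels == c
    if (!any(in_c)) {
      warn(sprintf("Cluster %s is empty; reporting zeros.", c))
      return(rep(0, ncol(has_group)))
    }
    colMeans(has_group[in_c, , drop = FALSE])
  }))
  dimnames(out) <- list(as.character(cl), names(word_groups))
  out
}

#' Refocus the landscape on a dominant-topic subcorpus
#'
#' Retains the documents whose dominant topic (argmax of `theta`) falls in
#' `topic_ids` and reruns the full vectorize / PCA / embed / cluster
#' pipeline on the subcorpus with its own parameters; features and document
#' frequencies are recomputed on the subcorpus. This is the mechanism used
#' to zoom into a thematic branch of a corpus (e.g. the molecular/cell
#' biology documents of an aging-literature corpus).
#'
#' @param bow The full `litscape_bow`.
#' @param theta N x K document-topic matrix (or `litscape_lda` fit).
#' @param topic_ids Topic indices (1-based) defining the subcorpus.
#' @param max_features,n_pcs,n_neighbors,resolution,seed Landscape
#'   parameters for the subcorpus (PCA defaults to 30 components here).
#' @return A list: `landscape` (the subcorpus `litscape_landscape`), `bow`
#'   (subcorpus bag-of-words), `keep` (logical selector on the full corpus).
#' @export
refocus_subcorpus <- function(bow, theta, topic_ids, max_features = 500L,
                              n_pcs = 30L, n_neighbors = 5L, resolution = 0.7,
                              seed = 1L) {
  if (length(topic_ids) == 0) abort("`topic_ids` must be non-empty.")
  if (inherits(theta, "litscape_lda")) theta <- theta$theta
  dom <- dominant_topic(theta)
  keep <- dom %in% topic_ids
  if (!any(keep)) {
    abort(sprintf("No document has a dominant topic in {%s}.",
                  paste(topic_ids, collapse = ", ")))
  }
  sub_bow <- structure(
    list(counts = bow$counts[keep, , drop = FALSE],
         doc_id = bow$doc_id[keep], year = bow$year[keep], vocab = bow$vocab),
    class = "litscape_bow"
  )
  land <- build_landscape(sub_bow, max_features = max_features, n_pcs = n_pcs,
                          n_neighbors = n_neighbors, resolution = resolution,
                          seed = seed)
  list(landscape = land, bow = sub_bow, keep = keep)
}
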