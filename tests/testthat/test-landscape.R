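test_that("feature selection keeps the most frequent tokens with df recomputed", {
  counts <- rbind(c(5, 1, 0), c(4, 0, 2), c(3, 1, 1))
  colnames(counts) <- c("big", "mid", "sml")
  bow <- make_bow(counts)
  vec <- suppressMessages(vectorize_features(bow, max_features = 2))
  expect_identical(sort(vec$features), c("big", "sml"))   # totals 12 and 3 beat 2
  # weighting equals TF-IDF computed on the restricted count matrix
  expect_equal(as.matrix(vec$tfidf),
               oracle_tfidf(counts[, vec$features]), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("PCA scores match an eigendecomposition oracle up to sign", {
  set.seed(51)
  x <- matrix(rnorm(30 * 10), 30, 10)
  scores <- pca_reduce(x, 5)
  expect_true(all(diff(apply(scores, 2, var)) < 1e-12))
  xc <- scale(x, center = TRUE, scale = FALSE)
  eig <- eigen(crossprod(xc) / (nrow(x) - 1))
  oracle <- xc %*% eig$vectors[, 1:5]
  for (j in 1:5) {
    expect_equal(abs(scores[, j]), abs(oracle[, j]), tolerance = 1e-8)
  }
  # sign convention: the largest-magnitude loading of each component is positive
  rot <- attr(scores, "rotation")
  for (j in 1:5) expect_gt(rot[which.max(abs(rot[, j])), j], 0)
})

test_that("rank-deficient data is reconstructed exactly with matching rank", {
  set.seed(52)
  base <- matrix(rnorm(20 * 2), 20, 2)
  x <- base %*% matrix(rnorm(2 * 8), 2, 8)    # rank 2
  scores <- pca_reduce(x, 2)
  recon <- scores %*% t(attr(scores, "rotation"))
  xc <- scale(x, center = TRUE, scale = FALSE)
  expect_equal(recon, unclass(xc), tolerance = 1e-8, ignore_attr = TRUE)
  expect_warning(pca_reduce(x[1:4, ], 10), "clamped")
})

test_that("the 2-D embedding is seeded, shaped, and separates planted groups", {
  set.seed(53)
  g1 <- matrix(rnorm(20 * 5), 20, 5)
  g2 <- matrix(rnorm(20 * 5, mean = 30), 20, 5)
  coords <- rbind(g1, g2)
  e1 <- embed_2d(coords, n_neighbors = 5, seed = 9)
  e2 <- embed_2d(coords, n_neighbors = 5, seed = 9)
  expect_identical(e1, e2)
  expect_identical(dim(e1), c(40L, 2L))
  d <- as.matrix(dist(e1))
  intra <- mean(d[1:20, 1:20][upper.tri(d[1:20, 1:20])])
  inter <- mean(d[1:20, 21:40])
  expect_gt(inter, intra)
  expect_error(embed_2d(coords[1:3, ], n_neighbors = 5), "n_neighbors")
})

test_that("leiden clustering recovers planted marker clusters", {
  spec <- synthetic_spec(K_true = 1, V = 300, years = 2000:2003,
                         docs_per_year = setNames(rep(100L, 4), 2000:2003),
                         n_clusters = 4, marker_rate = 0.25, seed = 54L)
  prep <- quick_prep(spec)
  land <- suppressMessages(build_landscape(prep$bow, seed = 54))
  expect_identical(length(unique(land$labels)), 4L)
  expect_gt(adjusted_rand_index(land$labels, prep$truth$cluster_true), 0.9)
  # labels are 0-based and size-ordered
  expect_identical(sort(unique(land$labels)), 0:3)
  sizes <- as.integer(table(land$labels))
  expect_true(all(diff(sizes) <= 0))
})

test_that("resolution near zero collapses a connected graph to one cluster", {
  # equally spaced points: the 5-NN union graph is a connected chain
  x <- cbind(seq_len(30), 0)
  labels <- leiden_cluster(x, n_neighbors = 5, resolution = 1e-6, seed = 1)
  expect_identical(unique(labels), 0L)
  # identical documents: one cluster
  same <- matrix(1, 10, 3)
  expect_identical(unique(leiden_cluster(same, n_neighbors = 3,
                                         resolution = 0.7, seed = 1)), 0L)
})

test_that("clustering reads PCA coordinates only, never the embedding", {
  spec <- synthetic_spec(K_true = 1, V = 80, years = 2000:2001,
                         docs_per_year = setNames(rep(40L, 2), 2000:2001),
                         n_clusters = 2, marker_rate = 0.25, seed = 56L)
  prep <- quick_prep(spec)
  land <- suppressMessages(build_landscape(prep$bow, n_pcs = 15, seed = 56))
  direct <- leiden_cluster(land$pca, n_neighbors = land$params$n_neighbors,
                           resolution = land$params$resolution,
                           seed = land$params$seed)
  expect_identical(land$labels, direct)
})

test_that("differential word scores match the brute-force oracle", {
  set.seed(57)
  counts <- matrix(rpois(30 * 12, 1.2), 30, 12,
                   dimnames = list(NULL, sprintf("w%02d", 1:12)))
  counts[1:10, 1] <- counts[1:10, 1] + 5     # token exclusive-ish to cluster 0
  tfidf <- compute_tfidf(counts)
  labels <- rep(0:2, each = 10)
  dw <- differential_words(tfidf, labels, top_k = 3)
  expect_equal(dw$scores, oracle_differential(tfidf, labels), tolerance = 1e-12)
  # exclusive token: positive in its cluster, non-positive elsewhere
  counts2 <- rbind(matrix(c(4, 1, 1), 5, 3, byrow = TRUE),
                   matrix(c(0, 2, 2), 5, 3, byrow = TRUE))
  colnames(counts2) <- c("excl", "sh1", "sh2")
  tf2 <- compute_tfidf(counts2)
  dw2 <- differential_words(tf2, rep(0:1, each = 5), top_k = 1)
  expect_gt(dw2$scores["0", "excl"], 0)
  expect_lte(dw2$scores["1", "excl"], 0)
  # identical means everywhere: score 0
  tf3 <- compute_tfidf(rbind(c(1, 1), c(1, 1), c(1, 1), c(1, 1)))
  dw3 <- differential_words(tf3, c(0, 0, 1, 1), top_k = 1)
  expect_true(all(abs(dw3$scores) < 1e-12))
})

test_that("word-group presence uses prefix matching on stems", {
  docs <- make_token_docs(list(
    c("telomeras", "w0001"),     # "telomer" prefix-matches "telomeras"
    c("telomer", "w0002"),
    c("w0003", "w0004"),
    c("senesc", "w0005")
  ))
  labels <- c(0, 0, 1, 1)
  pres <- word_presence(docs, labels,
                        list(telo = "telomer", sen = "senesc", none = "zzz"))
  expect_equal(pres["0", "telo"], 1)
  expect_equal(pres["1", "telo"], 0)
  expect_equal(pres["1", "sen"], 0.5)
  expect_true(all(pres[, "none"] == 0))
})

test_that("hand-placed stems give exact presence proportions", {
  docs <- make_token_docs(lapply(1:10, function(d) {
    toks <- c("w0001", "w0002")
    if (d %in% c(1, 2, 3)) toks <- c(toks, "oxidativestress")
    if (d %in% c(6, 7)) toks <- c(toks, "mitochondrion")
    toks
  }))
  labels <- rep(0:1, each = 5)
  pres <- word_presence(docs, labels, list(oxid = "oxid", mito = "mitochondri"))
  expect_equal(pres["0", "oxid"], 3 / 5)
  expect_equal(pres["1", "oxid"], 0)
  expect_equal(pres["1", "mito"], 2 / 5)
})

test_that("refocusing filters by dominant topic and reruns the pipeline", {
  spec <- synthetic_spec(K_true = 3, V = 80, beta = 0.05, years = 2000:2003,
                         docs_per_year = setNames(rep(60L, 4), 2000:2003),
                         n_clusters = 2, marker_rate = 0.15, seed = 58L)
  prep <- quick_prep(spec)
  fit <- train_lda(prep$bow, K = 3, passes = 15, seed = 58)
  ref_all <- suppressMessages(
    refocus_subcorpus(prep$bow, fit, topic_ids = 1:3, n_pcs = 15, seed = 58)
  )
  expect_identical(ref_all$landscape$doc_id, prep$bow$doc_id)
  ref_one <- suppressMessages(
    refocus_subcorpus(prep$bow, fit, topic_ids = 2, n_pcs = 10, seed = 58)
  )
  expect_true(all(dominant_topic(fit$theta[ref_one$keep, , drop = FALSE]) == 2))
  expect_error(refocus_subcorpus(prep$bow, fit, integer(0)), "topic_ids")
})
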