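test_that("cluster cosine matrix hits its analytic anchors", {
  prof <- structure(list(
    clusters = 0:2,
    mean_tfidf = rbind(c(1, 1), c(1, 0), c(1, 1)),
    size = c(1L, 1L, 1L), mean_year = NULL
  ), class = "litscape_profiles")
  rownames(prof$mean_tfidf) <- 0:2
  sim <- cluster_cosine_matrix(prof)
  expect_equal(sim["0", "2"], 1, tolerance = 1e-12)
  expect_equal(sim["0", "1"], 1 / sqrt(2), tolerance = 1e-12)
  expect_identical(sim, t(sim))
  # disjoint supports are orthogonal
  prof$mean_tfidf <- rbind(c(1, 0), c(0, 2), c(1, 1))
  rownames(prof$mean_tfidf) <- 0:2
  expect_equal(cluster_cosine_matrix(prof)["0", "1"], 0, tolerance = 1e-12)
})

test_that("topic enrichment is null at the corpus mix and exact at 2x", {
  # every document identical: each cluster's mix equals the corpus mix
  theta <- matrix(rep(c(0.6, 0.3, 0.1), each = 12), 12, 3)
  labels <- rep(0:2, each = 4)
  enr <- topic_enrichment(theta, labels)
  expect_true(all(abs(enr$scores) < 1e-6))
  # observed exactly twice expected: score 1 (pseudocount-free check)
  theta2 <- rbind(
    matrix(c(1, 0), 2, 2, byrow = TRUE),   # cluster 0: pure topic 1
    matrix(c(0, 1), 2, 2, byrow = TRUE)    # cluster 1: pure topic 2
  )
  enr2 <- topic_enrichment(theta2, c(0, 0, 1, 1), eps = 0)
  expect_equal(unname(enr2$scores["0", 1]), 1, tolerance = 1e-9)
})

test_that("enrichment conserves mass and matches the brute-force oracle", {
  for (s in 1:3) {
    set.seed(s)
    theta <- matrix(rgamma(40 * 5, 0.7), 40, 5)
    theta <- theta / rowSums(theta)
    labels <- sample(0:3, 40, replace = TRUE)
    enr <- topic_enrichment(theta, labels)
    expect_true(all(abs(colSums(enr$observed) - colSums(enr$expected)) < 1e-9))
    expect_equal(enr$scores, oracle_enrichment(theta, labels),
                 ignore_attr = TRUE, tolerance = 1e-9)
  }
})

test_that("enrichment trees follow UPGMA with z-scored rows", {
  scores <- rbind(a = c(2, 0, -1), b = c(2, 0, -1), c = c(-3, 1, 5))
  tree <- enrichment_hclust(scores)
  expect_equal(tree$height[1], 0, tolerance = 1e-12)   # identical rows first
  expect_setequal(tree$order, 1:3)
  # 3-row fixture against hand-computed UPGMA heights
  z <- attr(tree, "scaled")
  d <- as.matrix(dist(z))
  expect_equal(tree$height[2], mean(c(d[1, 3], d[2, 3])), tolerance = 1e-12)
})

test_that("cluster evolution reports mean years and conserving proportions", {
  labels <- c(0, 0, 1, 1, 1)
  years <- c(2000L, 2010L, 2000L, 2001L, 2001L)
  evo <- cluster_evolution(labels, years, window = 2)
  expect_equal(evo$mean_year$mean_year[evo$mean_year$cluster == 0], 2005)
  sums <- tapply(evo$proportions$proportion, evo$proportions$year, sum)
  expect_true(all(abs(sums - 1) < 1e-12))
  # single cluster: proportion 1 every year
  evo1 <- cluster_evolution(rep(0, 5), years, window = 2)
  expect_true(all(evo1$proportions$proportion == 1))
})

test_that("a cluster with a linearly rising share shows a monotone smoothed curve", {
  years <- rep(2000:2009, times = 10 * (1:10))
  n <- length(years)
  set.seed(61)
  labels <- integer(n)
  for (y in 2000:2009) {
    in_y <- which(years == y)
    share <- 0.1 + 0.08 * (y - 2000)
    labels[in_y] <- c(rep(1L, round(share * length(in_y))),
                      rep(0L, length(in_y) - round(share * length(in_y))))
  }
  evo <- cluster_evolution(labels, years, window = 3)
  rising <- evo$proportions[evo$proportions$cluster == 1 &
                              !is.na(evo$proportions$smoothed), ]
  expect_true(all(diff(rising$smoothed) > 0))
})

test_that("stationary clusters have unit cosines and zero slope", {
  years <- rep(2000:2009, each = 4)
  theta <- matrix(rep(c(0.7, 0.2, 0.1), each = 40), 40, 3)
  stab <- stability_trend(theta, rep(0, 40), years, window = 5)
  expect_true(all(abs(stab$series$cosine - 1) < 1e-12))
  expect_lt(abs(stab$slopes$slope[1]), 1e-9)
})

test_that("orthogonal alternation gives zero consecutive cosines", {
  years <- rep(2000:2005, each = 2)
  theta <- matrix(0, 12, 2)
  theta[, 1] <- rep(c(1, 0), each = 2, times = 3)
  theta[, 2] <- 1 - theta[, 1]
  stab <- stability_trend(theta, rep(0, 12), years, window = 2)
  expect_true(all(stab$series$cosine == 0))
})

test_that("gap years break the consecutive-year cosine chain", {
  years <- c(2000, 2000, 2003, 2003)
  theta <- matrix(0.5, 4, 2)
  stab <- stability_trend(theta, rep(0, 4), years, window = 2)
  expect_identical(nrow(stab$series), 0L)
  expect_true(is.na(stab$slopes$slope[1]))
  expect_true(is.na(stab$slopes$rank[1]))
})

test_that("converging clusters outrank diverging ones by stability slope", {
  years <- 2000:2014
  make_theta <- function(kind, seed) {
    spec <- synthetic_spec(
      K_true = 4, V = 40, marker_rate = 0, seed = seed,
      alpha_by_year = alpha_trajectory(4, years, kind),
      docs_per_year = setNames(rep(150L, length(years)), years)
    )
    generate_corpus(spec)
  }
  conv <- make_theta("converge", 62L)
  # diverging analogue: reverse the converging trajectory over years
  alpha_div <- rev(alpha_trajectory(4, years, "converge"))
  names(alpha_div) <- as.character(years)
  spec_div <- synthetic_spec(K_true = 4, V = 40, marker_rate = 0, seed = 63L,
                             alpha_by_year = alpha_div,
                             docs_per_year = setNames(rep(150L, length(years)),
                                                      years))
  div <- generate_corpus(spec_div)
  theta <- rbind(conv$truth$theta_true, div$truth$theta_true)
  labels <- rep(c("conv", "div"), times = c(nrow(conv$truth$theta_true),
                                            nrow(div$truth$theta_true)))
  yrs <- c(conv$truth$year, div$truth$year)
  stab <- stability_trend(theta, labels, yrs, window = 5)
  s <- setNames(stab$slopes$slope, stab$slopes$cluster)
  expect_gt(s["conv"], s["div"])
  expect_identical(stab$slopes$cluster[stab$slopes$rank == 1], "conv")
})

test_that("hallmark presence reproduces hand-enumerated proportions", {
  docs <- make_token_docs(lapply(1:12, function(d) {
    toks <- c("w0001")
    if (d <= 6) toks <- c(toks, "senescenc")          # cluster 0 docs
    if (d %in% c(7, 8)) toks <- c(toks, "telomeras")
    if (d == 9) toks <- c(toks, "oxidativ")
    toks
  }))
  labels <- rep(0:1, each = 6)
  pres <- hallmark_presence(docs, labels, stems = c("senesc", "telomer", "oxid"))
  expect_equal(pres["0", "senesc"], 1)
  expect_equal(pres["1", "senesc"], 0)
  expect_equal(pres["1", "telomer"], 2 / 6)
  expect_equal(pres["1", "oxid"], 1 / 6)
  # saturation and absence
  expect_true(all(hallmark_presence(docs, labels, stems = "w000")[, 1] == 1))
  expect_true(all(hallmark_presence(docs, labels, stems = "zzz")[, 1] == 0))
})

test_that("semantic overlap separates disjoint vocabularies and finds bridges", {
  # two clusters with disjoint vocabularies
  counts <- rbind(
    matrix(c(3, 2, 0, 0), 4, 4, byrow = TRUE),
    matrix(c(0, 0, 2, 3), 4, 4, byrow = TRUE)
  )
  colnames(counts) <- c("a1", "a2", "b1", "b2")
  tfidf <- compute_tfidf(counts)
  labels <- rep(0:1, each = 4)
  ovl <- semantic_overlap(tfidf, labels, top_n = 2)
  expect_equal(ovl$matrix["0", "1"], 0, tolerance = 1e-12)
  expect_equal(ovl$matrix["1", "0"], 0, tolerance = 1e-12)
  expect_gt(ovl$matrix["0", "0"], 0)
  expect_equal(ovl$matrix, oracle_overlap(tfidf, labels, 2), tolerance = 1e-12)
})

test_that("a single bridging token raises exactly the bridged pair", {
  # clusters 0 and 1 share token "bridge"; cluster 2 is fully disjoint and
  # has three exclusive tokens so its top-3 list stays inside its vocabulary
  counts <- rbind(
    matrix(rep(c(3, 2, 1, 0, 0, 0, 0, 0), 4), 4, 8, byrow = TRUE),
    matrix(rep(c(0, 0, 1, 3, 2, 0, 0, 0), 4), 4, 8, byrow = TRUE),
    matrix(rep(c(0, 0, 0, 0, 0, 3, 2, 1), 4), 4, 8, byrow = TRUE)
  )
  colnames(counts) <- c("a1", "a2", "bridge", "b1", "b2", "c1", "c2", "c3")
  tfidf <- compute_tfidf(counts)
  labels <- rep(0:2, each = 4)
  ovl <- semantic_overlap(tfidf, labels, top_n = 3)
  expect_equal(ovl$matrix, oracle_overlap(tfidf, labels, 3), tolerance = 1e-12)
  pair_01 <- ovl$pairs$score[ovl$pairs$cluster_a == "0" & ovl$pairs$cluster_b == "1"]
  pair_02 <- ovl$pairs$score[ovl$pairs$cluster_a == "0" & ovl$pairs$cluster_b == "2"]
  pair_12 <- ovl$pairs$score[ovl$pairs$cluster_a == "1" & ovl$pairs$cluster_b == "2"]
  expect_gt(pair_01, pair_02)
  expect_gt(pair_01, pair_12)
  expect_identical(ovl$pairs$cluster_b[ovl$pairs$rank == 1], "1")
})
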