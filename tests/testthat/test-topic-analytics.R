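test_that("TF-IDF follows the tf * log2(N/df) convention with unit rows", {
  # token in every document gets zero weight
  counts <- rbind(c(2, 1), c(3, 0))
  colnames(counts) <- c("ubiq", "rare")
  w <- as.matrix(compute_tfidf(counts))
  expect_identical(w[, "ubiq"], c(0, 0))
  # two disjoint single-token docs: each row is exactly 1 on its token
  counts2 <- rbind(c(1, 0), c(0, 1))
  colnames(counts2) <- c("a", "b")
  w2 <- as.matrix(compute_tfidf(counts2))
  expect_equal(w2, diag(2), ignore_attr = TRUE, tolerance = 1e-15)
})

test_that("TF-IDF matches a brute-force two-loop oracle", {
  set.seed(41)
  counts <- matrix(rpois(20 * 50, 0.8), 20, 50,
                   dimnames = list(NULL, sprintf("w%02d", 1:50)))
  w <- as.matrix(compute_tfidf(counts))
  expect_equal(w, oracle_tfidf(counts), tolerance = 1e-12)
})

test_that("topic word importance aggregates TF-IDF by topic weight", {
  set.seed(42)
  counts <- matrix(rpois(10 * 15, 1.5), 10, 15,
                   dimnames = list(NULL, sprintf("w%02d", 1:15)))
  tfidf <- compute_tfidf(counts)
  # pure documents: topic row equals the sum of its documents' rows
  theta_pure <- diag(2)[rep(1:2, each = 5), ]
  imp <- topic_word_importance(tfidf, theta_pure)
  expect_equal(imp[1, ], Matrix::colSums(tfidf[1:5, ]), tolerance = 1e-12)
  # uniform mixtures: all topic rows identical
  theta_unif <- matrix(1 / 3, 10, 3)
  imp_u <- topic_word_importance(tfidf, theta_unif)
  expect_equal(imp_u[1, ], imp_u[3, ], tolerance = 1e-12)
  # random mixtures: brute-force triple loop
  theta <- matrix(rgamma(10 * 4, 1), 10, 4)
  theta <- theta / rowSums(theta)
  expect_equal(topic_word_importance(tfidf, theta),
               oracle_importance(tfidf, theta), tolerance = 1e-12)
  expect_error(topic_word_importance(tfidf, theta[1:3, ]), "mismatch")
})

test_that("yearly topic proportions conserve mass and smooth correctly", {
  set.seed(43)
  theta <- matrix(rgamma(40 * 3, 1), 40, 3)
  theta <- theta / rowSums(theta)
  years <- rep(2001:2004, each = 10)
  props <- yearly_topic_proportions(theta, years, window = 2)
  sums <- tapply(props$proportion, props$year, sum)
  expect_true(all(abs(sums - 1) < 1e-8))
  # constant series: smoothing is the identity where defined
  theta_c <- matrix(1 / 3, 40, 3)
  props_c <- yearly_topic_proportions(theta_c, years, window = 2)
  expect_true(all(abs(props_c$smoothed[!is.na(props_c$smoothed)] - 1 / 3) < 1e-12))
})

test_that("a planted rising topic yields a monotone smoothed series", {
  years <- 2000:2014
  spec <- synthetic_spec(
    K_true = 3, V = 60, marker_rate = 0, seed = 44L,
    alpha_by_year = alpha_trajectory(3, years, "drift"),
    docs_per_year = setNames(rep(300L, length(years)), years)
  )
  gen <- generate_corpus(spec)
  props <- yearly_topic_proportions(gen$truth$theta_true, gen$truth$year,
                                    window = 5)
  rising <- props[props$topic == 3 & !is.na(props$smoothed), ]
  expect_true(all(diff(rising$smoothed) > 0))
})

test_that("Shannon entropy hits its analytic anchors", {
  expect_identical(shannon_entropy(c(1, 0, 0)), 0)
  expect_equal(shannon_entropy(rep(1 / 30, 30)), log(30), tolerance = 1e-12)
  expect_equal(shannon_entropy(c(0.5, 0.5)), log(2), tolerance = 1e-12)
  series <- shannon_entropy_series(rbind(c(1, 0), c(0.5, 0.5)),
                                   c(2000L, 2001L), roll = 1)
  expect_equal(series$mean_entropy, c(0, log(2)), tolerance = 1e-12)
})

test_that("topic co-occurrence counts unordered top-n pairs exactly", {
  # single document, K = 5, top-5 covers all topics
  theta1 <- matrix(c(0.4, 0.3, 0.15, 0.1, 0.05), 1)
  m1 <- topic_cooccurrence(theta1, top_n = 5)
  expect_true(all(m1[upper.tri(m1)] == 1))
  expect_true(all(diag(m1) == 0))
  # two documents with known top-5 sets {1..5} and {1,2,6,7,8}
  t2 <- rbind(
    c(0.3, 0.25, 0.2, 0.15, 0.07, 0.01, 0.01, 0.01),
    c(0.3, 0.25, 0.01, 0.01, 0.01, 0.2, 0.15, 0.07)
  )
  m2 <- topic_cooccurrence(t2, top_n = 5)
  expect_identical(m2[1, 2], 1)
  expect_identical(m2[1, 3], 0.5)
  expect_identical(m2[3, 6], 0)
  expect_identical(m2, t(m2))
})

test_that("co-occurrence matches brute force and conserves pair mass", {
  for (s in 1:3) {
    set.seed(s)
    theta <- matrix(rgamma(50 * 8, 0.5), 50, 8)
    theta <- theta / rowSums(theta)
    m <- topic_cooccurrence(theta, top_n = 5)
    expect_identical(unclass(m)[1:8, 1:8], oracle_cooccurrence(theta, 5))
    expect_true(all(m >= 0 & m <= 1))
    raw_pairs <- sum(m) / 2 * 50
    expect_equal(raw_pairs, 50 * choose(5, 2), tolerance = 1e-9)
  }
})

test_that("chord links apply a strict threshold in descending order", {
  m <- matrix(0, 3, 3)
  expect_identical(nrow(chord_links(m)), 0L)
  m[1, 2] <- m[2, 1] <- 0.033     # boundary: excluded
  m[1, 3] <- m[3, 1] <- 0.5
  m[2, 3] <- m[3, 2] <- 0.04
  links <- chord_links(m, threshold = 0.033)
  expect_identical(links$topic_i, c(1L, 2L))
  expect_identical(links$topic_j, c(3L, 3L))
  expect_identical(links$weight, c(0.5, 0.04))
})

test_that("sentiment compound follows the valence-normalization form", {
  docs <- make_token_docs(list(
    c("w0001", "w0002"),                 # no lexicon matches
    "benefit",                           # single positive token
    "cancer"                             # single negative token
  ))
  bow <- to_bow(docs, build_vocabulary(docs, 0, 1))
  lex <- c(benefit = 1.9, cancer = -2.7)
  sent <- sentiment_analysis(docs, bow, lexicon = lex)
  expect_identical(sent$document$compound[1], 0)
  expect_equal(sent$document$compound[2], 1.9 / sqrt(1.9^2 + 15),
               tolerance = 1e-12)
  expect_equal(sent$document$compound[3], -2.7 / sqrt(2.7^2 + 15),
               tolerance = 1e-12)
  expect_error(sentiment_analysis(docs, bow, lexicon = numeric(0)), "lexicon")
})

test_that("keyword sentiment orders planted positive and negative markers", {
  set.seed(45)
  docs <- make_token_docs(lapply(1:20, function(d) {
    base <- sample(sprintf("w%02d", 1:10), 20, replace = TRUE)
    if (d <= 10) c(base, "goodmark") else c(base, "badmark")
  }))
  bow <- to_bow(docs, build_vocabulary(docs, 0, 1))
  lex <- c(goodmark = 2, badmark = -2)
  sent <- sentiment_analysis(docs, bow, lexicon = lex, max_keywords = 50)
  kw <- sent$keyword
  expect_gt(kw$mean_compound[kw$keyword == "goodmark"],
            kw$mean_compound[kw$keyword == "badmark"])
})
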