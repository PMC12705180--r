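test_that("generation is deterministic given the seed", {
  spec <- synthetic_spec(K_true = 3, V = 50, years = 2000:2004,
                         docs_per_year = setNames(rep(20L, 5), 2000:2004),
                         duplicate_rate = 0.1, seed = 9L)
  g1 <- generate_corpus(spec)
  g2 <- generate_corpus(spec)
  expect_identical(as.data.frame(g1$corpus), as.data.frame(g2$corpus))
  expect_identical(g1$truth$theta_true, g2$truth$theta_true)
  expect_identical(g1$truth$phi_true, g2$truth$phi_true)
})

test_that("ground-truth matrices are row-stochastic and clusters cover all docs", {
  spec <- synthetic_spec(K_true = 4, V = 80, years = 2000:2003, seed = 2L,
                         docs_per_year = setNames(rep(25L, 4), 2000:2003))
  gen <- generate_corpus(spec)
  expect_true(all(abs(rowSums(gen$truth$phi_true) - 1) < 1e-9))
  expect_true(all(abs(rowSums(gen$truth$theta_true) - 1) < 1e-9))
  expect_identical(length(gen$truth$cluster_true), nrow(gen$corpus))
  expect_true(all(gen$truth$cluster_true %in% 1:4))
})

test_that("a single-topic spec yields pure topic mixtures", {
  spec <- synthetic_spec(K_true = 1, V = 40, years = 2000, marker_rate = 0,
                         docs_per_year = c("2000" = 10L), seed = 3L)
  gen <- generate_corpus(spec)
  expect_true(all(gen$truth$theta_true == 1))
  toks <- unique(unlist(strsplit(gen$corpus$abstract, " ")))
  expect_true(all(toks %in% colnames(gen$truth$phi_true)))
})

test_that("duplicate injection emits the exact count and dedup removes it", {
  spec <- synthetic_spec(K_true = 2, V = 40, years = 2000,
                         docs_per_year = c("2000" = 100L),
                         duplicate_rate = 0.1, seed = 4L)
  gen <- generate_corpus(spec)
  expect_identical(nrow(gen$truth$duplicate_map), 10L)
  expect_identical(nrow(gen$corpus), 110L)
  # duplicates share text but not ids, exercising the text half of the rule
  out <- suppressMessages(dedup_corpus(gen$corpus))
  expect_identical(nrow(out), 100L)
  expect_false(any(gen$truth$duplicate_map$dup_id %in% out$doc_id))
})

test_that("marker stems appear only in documents of their planted cluster", {
  spec <- synthetic_spec(K_true = 2, V = 60, years = 2000:2001,
                         docs_per_year = setNames(rep(40L, 2), 2000:2001),
                         n_clusters = 3, marker_rate = 0.3,
                         stem_plan = c(telomer = 1L, senesc = 3L), seed = 5L)
  gen <- generate_corpus(spec)
  toks <- strsplit(gen$corpus$abstract, " ")
  for (c_id in 1:3) {
    markers <- gen$truth$marker_vocab[[c_id]]
    in_c <- gen$truth$cluster_true == c_id
    outside <- unlist(toks[!in_c])
    expect_false(any(markers %in% outside))
  }
  expect_true("telomer" %in% unlist(toks[gen$truth$cluster_true == 1]))
  expect_true("senesc" %in% unlist(toks[gen$truth$cluster_true == 3]))
})

test_that("invalid specs fail with the offending field named", {
  expect_error(synthetic_spec(marker_rate = 1.2), "marker_rate")
  expect_error(synthetic_spec(duplicate_rate = -0.1), "duplicate_rate")
  expect_error(synthetic_spec(length_range = c(10, 5)), "length_range")
  expect_error(
    synthetic_spec(stem_plan = c(telomer = 9L), n_clusters = 4),
    "stem_plan"
  )
  expect_error(
    synthetic_spec(K_true = 3, alpha_by_year = list("2000" = c(1, 1)),
                   docs_per_year = c("2000" = 5L)),
    "alpha_by_year"
  )
})

test_that("empirical yearly topic proportions converge to the Dirichlet means", {
  alpha <- c(2, 1, 0.5)
  spec <- synthetic_spec(K_true = 3, V = 60, marker_rate = 0,
                         alpha_by_year = list("2005" = alpha),
                         docs_per_year = c("2005" = 2000L), seed = 6L)
  gen <- generate_corpus(spec)
  emp <- colMeans(gen$truth$theta_true)
  expect_true(all(abs(emp - alpha / sum(alpha)) < 0.02))
})

test_that("converging concentrations shrink topic-mixture entropy over years", {
  years <- 2000:2014
  spec <- synthetic_spec(
    K_true = 5, V = 60, marker_rate = 0, seed = 7L,
    alpha_by_year = alpha_trajectory(5, years, "converge"),
    docs_per_year = setNames(rep(200L, length(years)), years)
  )
  gen <- generate_corpus(spec)
  H <- shannon_entropy(gen$truth$theta_true)
  first <- mean(H[gen$truth$year == 2000])
  last <- mean(H[gen$truth$year == 2014])
  expect_lt(last, first)
})

test_that("match_topics recovers a planted row permutation exactly", {
  set.seed(8)
  phi <- matrix(rgamma(5 * 30, 0.3), 5, 30)
  phi <- phi / rowSums(phi)
  colnames(phi) <- sprintf("w%02d", 1:30)
  perm <- c(3L, 5L, 1L, 2L, 4L)
  m <- match_topics(phi[perm, ], phi)
  expect_identical(m$assignment$true, perm)
  expect_true(all(m$assignment$cosine > 1 - 1e-12))
})

test_that("match_topics equals exhaustive assignment search under noise", {
  for (s in 1:5) {
    set.seed(s)
    K <- sample(3:6, 1)
    phi <- matrix(rgamma(K * 40, 0.2), K, 40)
    phi <- phi / rowSums(phi)
    colnames(phi) <- sprintf("w%02d", 1:40)
    noisy <- phi + matrix(runif(K * 40, 0, 0.01), K, 40)
    noisy <- noisy / rowSums(noisy)
    m <- match_topics(noisy, phi)
    sim <- (noisy / sqrt(rowSums(noisy^2))) %*% t(phi / sqrt(rowSums(phi^2)))
    brute <- oracle_assignment(sim)
    expect_equal(m$total, brute$score, tolerance = 1e-9)
    expect_identical(m$assignment$true[order(m$assignment$learned)], brute$perm)
  }
})

test_that("orthogonal two-topic case scores a total of 2", {
  phi <- rbind(c(1, 0, 0, 0), c(0, 0, 1, 0))
  colnames(phi) <- letters[1:4]
  m <- match_topics(phi, phi)
  expect_equal(m$total, 2, tolerance = 1e-12)
  expect_error(match_topics(phi, phi[, 1:3]), "mismatch")
})

test_that("adjusted Rand index agrees with an independent implementation", {
  for (s in 1:5) {
    set.seed(s)
    a <- sample(1:4, 50, replace = TRUE)
    b <- sample(1:3, 50, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b), mclust::adjustedRandIndex(a, b),
                 tolerance = 1e-12)
  }
  expect_equal(adjusted_rand_index(rep(1:2, 10), rep(1:2, 10)), 1)
})
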