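#' Specify a synthetic Dirichlet-multinomial corpus
#'
#' Defines the generative model behind [generate_corpus()]: `K_true` latent
#' topics over a base vocabulary of `V` synthetic stems (`"w0001"`, ...),
#' per-year document-topic Dirichlet concentrations (encoding prevalence
#' drift or convergence), planted document clusters with cluster-exclusive
#' marker stems, optional hallmark-style stems targeted at specific clusters,
#' and injected duplicates. Because tokens are synthetic stems, the Porter
#' stemmer downstream is a no-op on them, isolating later stages from stemmer
#' behavior.
#'
#' @param K_true Number of latent topics.
#' @param V Base vocabulary size.
#' @param beta Topic-word Dirichlet concentration (small values give sparse,
#'   well-separated topics).
#' @param alpha_by_year Named list mapping year (as character) to a length-
#'   `K_true` positive Dirichlet concentration vector. Defaults to a constant
#'   symmetric 0.3 over `years`.
#' @param docs_per_year Named integer vector mapping year to document count.
#'   Defaults to 100 per year over `years`.
#' @param years Convenience for the defaults above (default 2000:2019).
#' @param length_range Inclusive token-count range, drawn uniformly
#'   (default `c(40, 200)`, inside the 30-500 retention window).
#' @param n_clusters Number of planted document clusters.
#' @param marker_rate Probability that a token is replaced by one of its
#'   document's cluster marker stems.
#' @param duplicate_rate Fraction of base documents re-emitted under fresh
#'   ids with identical title and abstract.
#' @param stem_plan Optional named integer vector mapping marker stems (e.g.
#'   `c(telomer = 1)`) to target clusters; these stems are added to the
#'   target cluster's marker vocabulary.
#' @param seed Integer seed; generation is fully reproducible from it.
#' @return A `litscape_synthetic_spec` list.
#' @export
synthetic_spec <- function(K_true = 5L, V = 300L, beta = 0.05,
                           alpha_by_year = NULL, docs_per_year = NULL,
                           years = 2000:2019, length_range = c(40L, 200L),
                           n_clusters = 4L, marker_rate = 0.1,
                           duplicate_rate = 0, stem_plan = NULL, seed = 1L) {
  check_number(K_true, "K_true", lower = 1)
  check_number(V, "V", lower = 2)
  check_number(beta, "beta", lower = 1e-12)
  check_number(n_clusters, "n_clusters", lower = 1)
  check_number(marker_rate, "marker_rate", lower = 0, upper = 1 - 1e-12)
  check_number(duplicate_rate, "duplicate_rate", lower = 0, upper = 1 - 1e-12)
  check_number(seed, "seed")
  if (is.null(docs_per_year)) {
    docs_per_year <- setNames(rep(100L, length(years)), as.character(years))
  }
  if (any(docs_per_year < 0)) abort("`docs_per_year` must be non-negative.")
  yrs <- names(docs_per_year)
  if (is.null(alpha_by_year)) {
    alpha_by_year <- setNames(
      rep(list(rep(0.3, K_true)), length(yrs)), yrs
    )
  }
  if (!setequal(names(alpha_by_year), yrs)) {
    abort("`alpha_by_year` must cover exactly the years in `docs_per_year`.")
  }
  for (y in yrs) {
    a <- alpha_by_year[[y]]
    if (length(a) != K_true || any(a <= 0)) {
      abort(sprintf("`alpha_by_year[['%s']]` must be %d positive concentrations.",
                    y, K_true))
    }
  }
  if (length(length_range) != 2L || length_range[1] > length_range[2] ||
      length_range[1] < 1) {
    abort("`length_range` must be an increasing pair of positive token counts.")
  }
  if (!is.null(stem_plan)) {
    if (is.null(names(stem_plan)) || any(!nzchar(names(stem_plan)))) {
      abort("`stem_plan` must be a named vector (stem -> target cluster).")
    }
    if (any(stem_plan < 1 | stem_plan > n_clusters)) {
      abort("`stem_plan` targets must be cluster indices in 1..n_clusters.")
    }
  }
  structure(
    list(K_true = as.integer(K_true), V = as.integer(V), beta = beta,
         alpha_by_year = alpha_by_year, docs_per_year = docs_per_year,
         length_range = as.integer(length_range),
         n_clusters = as.integer(n_clusters), marker_rate = marker_rate,
         duplicate_rate = duplicate_rate, stem_plan = stem_plan,
         seed = as.integer(seed)),
    class = "litscape_synthetic_spec"
  )
}

#' Dirichlet concentration trajectories for the synthetic generator
#'
#' Convenience builders for `alpha_by_year`: `"constant"` keeps a symmetric
#' concentration; `"drift"` linearly shifts mean prevalence from the first
#' topic toward the last across years; `"converge"` keeps the total
#' concentration fixed while progressively tilting mass toward the first
#' topic, so per-document topic mixtures grow more peaked (monotonically
#' lower expected Shannon entropy) over the years.
#'
#' @param K_true Number of topics.
#' @param years Integer years.
#' @param kind One of `"constant"`, `"drift"`, `"converge"`.
#' @param base Baseline concentration scale.
#' @return A named list suitable for [synthetic_spec()]'s `alpha_by_year`.
#' @export
alpha_trajectory <- function(K_true, years, kind = c("constant", "drift", "converge"),
                             base = 0.3) {
  kind <- match.arg(kind)
  n <- length(years)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    t <- if (n == 1L) 0 else (i - 1) / (n - 1)
    out[[i]] <- switch(
      kind,
      constant = rep(base, K_true),
      drift = {
        w <- (1 - t) * rev(seq_len(K_true)) + t * seq_len(K_true)
        base * K_true * w / sum(w)
      },
      converge = {
        w <- rep(1, K_true)
        w[1] <- 1 + 15 * t          # mass tilts toward topic 1, total fixed
        base * K_true * w / sum(w)
      }
    )
  }
  setNames(out, as.character(years))
}

#' Generate a synthetic corpus with known ground truth
#'
#' Draws documents from the Dirichlet-multinomial model in `spec` under an
#' explicit, documented draw order (years, then per-document topic mixtures,
#' then lengths, then tokens, then marker replacement, then duplicates), so
#' regeneration from the same seed is byte-identical. Abstracts are
#' space-joined token strings; titles are the first five tokens.
#'
#' @param spec A [synthetic_spec()].
#' @return A list with elements `corpus` (a corpus tibble) and `truth`, a
#'   `litscape_ground_truth` list with `phi_true` (`K_true` x `V`, rows sum
#'   to 1), `theta_true` (one row per emitted document, duplicates included),
#'   `cluster_true`, `year`, and `duplicate_map` (tibble of original and
#'   duplicate ids).
#' @export
generate_corpus <- function(spec) {
  if (!inherits(spec, "litscape_synthetic_spec")) {
    abort("`spec` must be created with synthetic_spec().")
  }
  K <- spec$K_true
  V <- spec$V
  vocab <- sprintf("w%04d", seq_len(V))
  marker_vocab <- lapply(seq_len(spec$n_clusters), function(c) {
    auto <- sprintf("clustmark%d", c)
    extra <- names(spec$stem_plan)[spec$stem_plan == c]
    c(auto, extra)
  })

  with_seed(spec$seed, {
    # 1. years
    years <- rep(as.integer(names(spec$docs_per_year)), spec$docs_per_year)
    n_base <- length(years)
    if (n_base == 0) abort("`docs_per_year` yields an empty corpus.")
    # topic-word matrix
    phi <- rdirichlet(K, rep(spec$beta, V))
    if (K == 1L) phi <- matrix(phi, nrow = 1L)
    # planted clusters, uniform
    clusters <- sample.int(spec$n_clusters, n_base, replace = TRUE)
    # 2. per-document topic mixtures
    theta <- matrix(0, n_base, K)
    for (y in unique(years)) {
      idx <- which(years == y)
      theta[idx, ] <- rdirichlet(length(idx), spec$alpha_by_year[[as.character(y)]])
    }
    # 3. lengths
    lens <- sample(spec$length_range[1]:spec$length_range[2], n_base, replace = TRUE)
    # 4. tokens, 5. marker replacement
    phi_cum <- t(apply(phi, 1, cumsum))
    abstracts <- character(n_base)
    titles <- character(n_base)
    for (d in seq_len(n_base)) {
      z <- sample.int(K, lens[d], replace = TRUE, prob = theta[d, ])
      u <- stats::runif(lens[d])
      w <- vocab[max.col(u < phi_cum[z, , drop = FALSE] |
                           col(matrix(0, lens[d], V)) == V,
                         ties.method = "first")]
      if (spec$marker_rate > 0) {
        repl <- stats::runif(lens[d]) < spec$marker_rate
        if (any(repl)) {
          mv <- marker_vocab[[clusters[d]]]
          w[repl] <- mv[sample.int(length(mv), sum(repl), replace = TRUE)]
        }
      }
      abstracts[d] <- paste(w, collapse = " ")
      titles[d] <- paste(head(w, 5L), collapse = " ")
    }
    # 6. duplicates
    n_dup <- floor(spec$duplicate_rate * n_base + 1e-9)
    dup_idx <- if (n_dup > 0) sort(sample.int(n_base, n_dup)) else integer(0)

    base_ids <- sprintf("syn%06d", seq_len(n_base))
    dup_ids <- sprintf("dup%06d", seq_along(dup_idx))
    docs <- tibble(
      doc_id = c(base_ids, dup_ids),
      title = c(titles, titles[dup_idx]),
      abstract = c(abstracts, abstracts[dup_idx]),
      year = c(years, years[dup_idx])
    )
    corpus <- as_corpus(docs, provenance = sprintf("synthetic seed %d", spec$seed),
                        year_range = range(years))
    truth <- structure(
      list(
        phi_true = `dimnames<-`(phi, list(NULL, vocab)),
        theta_true = rbind(theta, theta[dup_idx, , drop = FALSE]),
        cluster_true = c(clusters, clusters[dup_idx]),
        year = c(years, years[dup_idx]),
        duplicate_map = tibble(orig_id = base_ids[dup_idx], dup_id = dup_ids),
        marker_vocab = marker_vocab,
        spec = spec
      ),
      class = "litscape_ground_truth"
    )
    list(corpus = corpus, truth = truth)
  })
}

#' Match learned topics to reference topics
#'
#' Finds the one-to-one assignment between the rows of two topic-word
#' matrices that maximizes total cosine similarity (optimal assignment on the
#' pairwise cosine matrix, solved as a maximum-weight bipartite matching).
#'
#' @param phi_learned K x V matrix of learned topic-word probabilities.
#' @param phi_true K_true x V reference matrix over the same vocabulary.
#' @return A list with `assignment` (tibble: `learned`, `true`, `cosine`) and
#'   `total` (sum of matched cosines). When the matrices are rectangular the
#'   matching covers `min(K, K_true)` pairs.
#' @export
match_topics <- function(phi_learned, phi_true) {
  if (ncol(phi_learned) != ncol(phi_true)) {
    abort(sprintf("Vocabulary mismatch: %d vs %d columns.",
                  ncol(phi_learned), ncol(phi_true)))
  }
  K <- nrow(phi_learned)
  Kt <- nrow(phi_true)
  norm_l <- sqrt(rowSums(phi_learned^2))
  norm_t <- sqrt(rowSums(phi_true^2))
  sim <- (phi_learned %*% t(phi_true)) / outer(pmax(norm_l, 1e-300),
                                               pmax(norm_t, 1e-300))
  # weighted bipartite matching; small offset keeps zero-cosine edges present
  g <- igraph::make_bipartite_graph(
    types = c(rep(FALSE, K), rep(TRUE, Kt)),
    edges = as.vector(rbind(rep(seq_len(K), each = Kt),
                            K + rep(seq_len(Kt), times = K)))
  )
  m <- igraph::max_bipartite_match(g, weights = as.vector(t(sim)) + 1e-9)
  matched <- m$matching[seq_len(K)]
  pairs <- tibble(
    learned = seq_len(K),
    true = as.integer(matched) - K,
    cosine = NA_real_
  )
  pairs <- pairs[!is.na(pairs$true) & pairs$true >= 1, , drop = FALSE]
  pairs$cosine <- sim[cbind(pairs$learned, pairs$true)]
  list(assignment = pairs, total = sum(pairs$cosine))
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same documents;
#' 1 for identical partitions (up to label permutation), ~0 for independent
#' ones. Used to score recovery of planted cluster structure.
#'
#' @param a,b Two label vectors of equal length.
#' @return The adjusted Rand index.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) abort("`a` and `b` must have equal length.")
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}
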