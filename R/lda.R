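#' Fit latent Dirichlet allocation by collapsed Gibbs sampling
#'
#' Trains an LDA model on a bag-of-words corpus. Each document is modeled as
#' a mixture over `K` topics (row-stochastic `theta`, N x K) and each topic
#' as a distribution over the vocabulary (row-stochastic `phi`, K x V), with
#' symmetric Dirichlet priors `alpha` (document-topic) and `eta`
#' (topic-word), both defaulting to `1/K`. Inference is collapsed Gibbs
#' sampling with a package-internal RNG, so a fit is bit-reproducible for a
#' fixed `seed`, corpus order, and single-threaded execution. One pass is one
#' full sweep of the sampler over the token stream; `phi` and `theta` are
#' posterior-mean estimates from the final state. Entries of `theta` below
#' `1e-8` are floored and rows renormalized so downstream logarithms are
#' finite. Documents with no in-vocabulary tokens receive the prior-mean
#' (uniform) topic distribution and are flagged.
#'
#' @param bow A `litscape_bow` from [to_bow()].
#' @param K Number of topics (>= 2).
#' @param passes Sampler sweeps over the corpus (default 20).
#' @param seed Integer seed.
#' @param alpha,eta Symmetric prior concentrations (default `1/K`).
#' @return A `litscape_lda` list: `K`, `phi` (K x V, rows sum to 1), `theta`
#'   (N x K, rows sum to 1), `alpha`, `eta`, `passes`, `seed`, `doc_id`,
#'   `year`, `vocab`, `log_likelihood` (in-sample per-token mean).
#' @export
train_lda <- function(bow, K, passes = 20L, seed = 1L,
                      alpha = 1 / K, eta = 1 / K) {
  if (!inherits(bow, "litscape_bow")) abort("`bow` must come from to_bow().")
  check_number(K, "K", lower = 2)
  check_number(passes, "passes", lower = 1)
  V <- ncol(bow$counts)
  if (V < 1) abort("Vocabulary is empty.")
  if (K > V) warn(sprintf("K = %d exceeds vocabulary size %d.", K, V))

  trip <- Matrix::summary(bow$counts)  # i, j, x triplets
  ord <- order(trip$i, trip$j)         # fixed token-stream order
  trip <- trip[ord, , drop = FALSE]
  doc <- rep.int(trip$i, trip$x) - 1L
  word <- rep.int(trip$j, trip$x) - 1L

  fit <- lda_gibbs_cpp(doc, word, n_docs = nrow(bow$counts), vocab_size = V,
                       n_topics = as.integer(K), alpha = alpha, beta = eta,
                       n_sweeps = as.integer(passes), seed = as.double(seed))
  phi <- fit$phi
  theta <- fit$theta
  # floor and renormalize so entropies/logs are finite
  theta[theta < 1e-8] <- 1e-8
  theta <- theta / rowSums(theta)
  colnames(phi) <- colnames(bow$counts)

  empty <- Matrix::rowSums(bow$counts) == 0
  if (any(empty)) {
    inform(sprintf("%d empty document(s) assigned the prior-mean topic distribution.",
                   sum(empty)))
  }

  ll <- lda_token_loglik(bow$counts, theta, phi)
  structure(
    list(K = as.integer(K), phi = phi, theta = theta, alpha = alpha, eta = eta,
         passes = as.integer(passes), seed = as.integer(seed),
         doc_id = bow$doc_id, year = bow$year, vocab = bow$vocab,
         log_likelihood = ll),
    class = "litscape_lda"
  )
}

# mean per-token log-likelihood of counts under (theta, phi)
lda_token_loglik <- function(counts, theta, phi) {
  trip <- Matrix::summary(counts)
  probs <- rowSums(theta[trip$i, , drop = FALSE] * t(phi)[trip$j, , drop = FALSE])
  sum(trip$x * log(pmax(probs, 1e-300))) / sum(trip$x)
}

#' @export
print.litscape_lda <- function(x, ...) {
  cat(sprintf("<litscape_lda> K = %d topics, %d documents, %d tokens; %d passes, seed %d\n",
              x$K, nrow(x$theta), ncol(x$phi), x$passes, x$seed))
  cat(sprintf("  mean per-token log-likelihood: %.4f\n", x$log_likelihood))
  invisible(x)
}

#' Dominant topic of each document
#'
#' The argmax of each row of the document-topic matrix, with ties broken
#' toward the lowest topic index.
#'
#' @param theta An N x K document-topic matrix, a single row, or a
#'   `litscape_lda` fit.
#' @return Integer vector of topic indices (1-based).
#' @examples
#' dominant_topic(c(0.1, 0.7, 0.2))  # 2
#' dominant_topic(c(0.5, 0.5))       # 1 (tie toward lowest index)
#' @export
dominant_topic <- function(theta) {
  if (inherits(theta, "litscape_lda")) theta <- theta$theta
  if (is.null(dim(theta))) theta <- matrix(theta, nrow = 1L)
  max.col(theta, ties.method = "first")
}
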