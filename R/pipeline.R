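#' Pipeline configuration
#'
#' Assembles and validates the configuration for [run_pipeline()]. Every
#' tunable of the analysis is surfaced here with its default. The
#' configuration can be round-tripped through JSON with [write_config()] /
#' [read_config()].
#'
#' @param corpus Path to a JSONL corpus.
#' @param out_dir Output directory for artifacts and the manifest.
#' @param stopwords Optional path to a stopword file (default: bundled list).
#' @param min_tokens,max_tokens Inclusive token-count retention window.
#' @param min_doc_fraction,max_doc_fraction,min_doc_count Vocabulary pruning.
#' @param k_values Coherence-scan candidates (used when `K` is `NULL`).
#' @param scan_passes Sampler sweeps per scan candidate.
#' @param K Fixed topic count; skips the coherence scan when given.
#' @param passes Sampler sweeps for the final topic model.
#' @param top_n_cooccurrence Top topics per document for co-occurrence.
#' @param chord_threshold Strict threshold for chord edges.
#' @param max_features,n_pcs,n_neighbors,resolution Landscape parameters.
#' @param refocus_topics Optional topic ids for the dominant-topic refocus.
#' @param refocus_n_pcs PCA dimension of the refocused landscape.
#' @param hallmark_stems Stems for the presence matrix.
#' @param entropy_roll Entropy rolling window (years).
#' @param smoothing_window Moving-average window (years).
#' @param seed Integer seed for every stochastic stage.
#' @return A validated `litscape_config` list.
#' @export
pipeline_config <- function(corpus, out_dir, stopwords = NULL,
                            min_tokens = 30L, max_tokens = 500L,
                            min_doc_fraction = 0.011, max_doc_fraction = 0.30,
                            min_doc_count = NULL,
                            k_values = seq(5L, 50L, by = 5L), scan_passes = 20L,
                            K = NULL, passes = 20L,
                            top_n_cooccurrence = 5L, chord_threshold = 0.033,
                            max_features = 500L, n_pcs = 50L, n_neighbors = 5L,
                            resolution = 0.7, refocus_topics = NULL,
                            refocus_n_pcs = 30L,
                            hallmark_stems = c("oxid", "inflamm", "senesc",
                                               "mitochondri", "genom", "stem",
                                               "insulin", "metabol", "telomer",
                                               "epigenet", "autophagi",
                                               "nutrient", "microbi",
                                               "intercellular"),
                            entropy_roll = 10L, smoothing_window = 5L,
                            seed = 1L) {
  cfg <- list(
    corpus = corpus, out_dir = out_dir, stopwords = stopwords,
    min_tokens = as.integer(min_tokens), max_tokens = as.integer(max_tokens),
    min_doc_fraction = min_doc_fraction, max_doc_fraction = max_doc_fraction,
    min_doc_count = min_doc_count,
    k_values = as.integer(k_values), scan_passes = as.integer(scan_passes),
    K = if (is.null(K)) NULL else as.integer(K), passes = as.integer(passes),
    top_n_cooccurrence = as.integer(top_n_cooccurrence),
    chord_threshold = chord_threshold,
    max_features = as.integer(max_features), n_pcs = as.integer(n_pcs),
    n_neighbors = as.integer(n_neighbors), resolution = resolution,
    refocus_topics = if (is.null(refocus_topics)) NULL else as.integer(refocus_topics),
    refocus_n_pcs = as.integer(refocus_n_pcs),
    hallmark_stems = hallmark_stems,
    entropy_roll = as.integer(entropy_roll),
    smoothing_window = as.integer(smoothing_window),
    seed = as.integer(seed)
  )
  validate_config(cfg)
  structure(cfg, class = "litscape_config")
}

validate_config <- function(cfg) {
  if (cfg$min_tokens > cfg$max_tokens) {
    abort("Invalid configuration: `min_tokens` exceeds `max_tokens`.")
  }
  check_number(cfg$min_doc_fraction, "min_doc_fraction", 0, 1)
  check_number(cfg$max_doc_fraction, "max_doc_fraction", 0, 1)
  check_number(cfg$resolution, "resolution", lower = 1e-9)
  check_number(cfg$chord_threshold, "chord_threshold", lower = 0)
  if (!is.null(cfg$K)) check_number(cfg$K, "K", lower = 2)
  check_number(cfg$passes, "passes", lower = 1)
  check_number(cfg$n_pcs, "n_pcs", lower = 1)
  check_number(cfg$n_neighbors, "n_neighbors", lower = 1)
  invisible(cfg)
}

#' @rdname pipeline_config
#' @param config A `litscape_config` (or plain list).
#' @param path JSON file path.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_config <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  raw$k_values <- as.integer(raw$k_values)
  raw$hallmark_stems <- as.character(raw$hallmark_stems)
  do.call(pipeline_config, raw[!vapply(raw, is.null, logical(1))])
}

#' Run the full analysis pipeline
#'
#' Executes dedup, preprocessing, coherence scan (unless `K` is fixed),
#' topic-model fitting, topic analytics, landscape construction, cluster
#' analytics, and the optional dominant-topic refocus with its own
#' analytics. Every stage writes tidy CSV artifacts into `out_dir` and is
#' recorded in a JSON manifest (inputs, outputs, parameters, wall time,
#' seed, config hash). Stages whose configuration hash matches a previous
#' manifest and whose outputs still exist are skipped, making reruns cheap;
#' outputs are byte-stable across reruns with the same configuration and
#' seed under single-threaded execution.
#'
#' @param config A [pipeline_config()] (or path to its JSON form).
#' @return The run manifest, invisibly (also written to
#'   `out_dir/manifest.json`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_config(config)
  validate_config(config)
  if (!file.exists(config$corpus)) {
    abort(sprintf("Corpus file not found: %s", config$corpus))
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest_path <- file.path(config$out_dir, "manifest.json")
  previous <- if (file.exists(manifest_path)) {
    jsonlite::fromJSON(manifest_path, simplifyVector = FALSE)
  } else {
    list(stages = list())
  }
  manifest <- list(seed = config$seed, stages = list())
  state <- new.env(parent = emptyenv())

  run_stage <- function(name, params, outputs, inputs, compute) {
    hash <- rlang::hash(list(name = name, params = params, seed = config$seed))
    prev <- NULL
    for (st in previous$stages) if (identical(st$name, name)) prev <- st
    state$current_stage <- name
    out_paths <- file.path(config$out_dir, outputs)
    cached <- !is.null(prev) && identical(prev$hash, hash) &&
      all(file.exists(out_paths)) && !is.null(prev$cacheable) && isTRUE(prev$cacheable)
    t0 <- Sys.time()
    if (cached) {
      inform(sprintf("[%s] cached, skipping.", name))
      compute(recompute_only = TRUE)
    } else {
      compute(recompute_only = FALSE)
    }
    wall <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    manifest$stages[[length(manifest$stages) + 1L]] <<- list(
      name = name, hash = hash, inputs = as.list(inputs),
      outputs = as.list(outputs), params = params,
      wall_time_s = round(wall, 3), seed = config$seed,
      cached = cached, cacheable = TRUE
    )
  }
  fail_stage <- function(name, err) {
    manifest$stages[[length(manifest$stages) + 1L]] <- list(
      name = name, error = conditionMessage(err)
    )
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA)
    abort(sprintf("Pipeline failed at stage '%s': %s", name,
                  conditionMessage(err)))
  }
  write_csv_out <- function(df, file) {
    readr::write_csv(df, file.path(config$out_dir, file), progress = FALSE)
    file
  }

  tryCatch({
    # -- dedup ---------------------------------------------------------------
    run_stage(
      "dedup",
      params = list(corpus = config$corpus),
      outputs = "corpus_dedup.jsonl",
      inputs = config$corpus,
      compute = function(recompute_only) {
        raw <- read_corpus(config$corpus)
        state$corpus <- dedup_corpus(raw)
        if (!recompute_only) {
          write_corpus(state$corpus, file.path(config$out_dir, "corpus_dedup.jsonl"))
        }
      }
    )

    # -- preprocess ----------------------------------------------------------
    run_stage(
      "preprocess",
      params = config[c("stopwords", "min_tokens", "max_tokens",
                        "min_doc_fraction", "max_doc_fraction", "min_doc_count")],
      outputs = c("vocabulary.tsv", "documents.csv"),
      inputs = "corpus_dedup.jsonl",
      compute = function(recompute_only) {
        sw <- if (is.null(config$stopwords)) default_stopwords() else
          default_stopwords(config$stopwords)
        prep <- preprocess_corpus(
          state$corpus, stopwords = sw,
          min_tokens = config$min_tokens, max_tokens = config$max_tokens,
          min_doc_fraction = config$min_doc_fraction,
          max_doc_fraction = config$max_doc_fraction,
          min_doc_count = config$min_doc_count
        )
        state$docs <- prep$docs
        state$vocab <- prep$vocab
        state$bow <- prep$bow
        if (!recompute_only) {
          readr::write_tsv(as_tibble(prep$vocab),
                           file.path(config$out_dir, "vocabulary.tsv"),
                           progress = FALSE)
          write_csv_out(
            tibble(doc_id = prep$docs$doc_id, year = prep$docs$year,
                   n_tokens = lengths(prep$docs$tokens)),
            "documents.csv"
          )
        }
      }
    )

    # -- coherence scan ------------------------------------------------------
    if (is.null(config$K)) {
      run_stage(
        "coherence_scan",
        params = config[c("k_values", "scan_passes")],
        outputs = "coherence.csv",
        inputs = "documents.csv",
        compute = function(recompute_only) {
          scan <- coherence_scan(state$bow, state$docs,
                                 k_values = config$k_values,
                                 seed = config$seed,
                                 scan_passes = config$scan_passes)
          state$K <- scan$k_star
          if (!recompute_only) {
            write_csv_out(scan$report, "coherence.csv")
          }
        }
      )
    } else {
      state$K <- config$K
    }

    # -- topic model ---------------------------------------------------------
    run_stage(
      "topic_model",
      params = list(K = state$K, passes = config$passes),
      outputs = c("phi.tsv", "theta.tsv", "topic_top_words.csv"),
      inputs = "documents.csv",
      compute = function(recompute_only) {
        fit <- train_lda(state$bow, K = state$K, passes = config$passes,
                         seed = config$seed)
        state$lda <- fit
        state$tfidf_full <- compute_tfidf(state$bow)
        state$importance <- topic_word_importance(state$tfidf_full, fit)
        if (!recompute_only) {
          readr::write_tsv(as_tibble(as.data.frame(fit$phi)),
                           file.path(config$out_dir, "phi.tsv"), progress = FALSE)
          theta_df <- as.data.frame(fit$theta)
          names(theta_df) <- paste0("topic_", seq_len(fit$K))
          readr::write_tsv(as_tibble(cbind(doc_id = fit$doc_id, theta_df)),
                           file.path(config$out_dir, "theta.tsv"), progress = FALSE)
          write_csv_out(top_important_words(state$importance, n = 10L),
                        "topic_top_words.csv")
        }
      }
    )

    # -- topic analytics -----------------------------------------------------
    run_stage(
      "topic_analytics",
      params = config[c("top_n_cooccurrence", "chord_threshold",
                        "entropy_roll", "smoothing_window", "max_features")],
      outputs = c("topic_proportions.csv", "entropy.csv", "cooccurrence.csv",
                  "chord_edges.csv", "sentiment_keywords.csv",
                  "sentiment_yearly.csv"),
      inputs = "theta.tsv",
      compute = function(recompute_only) {
        if (recompute_only) return(invisible())
        fit <- state$lda
        props <- yearly_topic_proportions(fit$theta, fit$year,
                                          window = config$smoothing_window)
        ent <- shannon_entropy_series(fit$theta, fit$year,
                                      roll = config$entropy_roll)
        cooc <- topic_cooccurrence(fit$theta, top_n = config$top_n_cooccurrence)
        links <- chord_links(cooc, threshold = config$chord_threshold)
        sent <- sentiment_analysis(state$docs, state$bow,
                                   max_keywords = config$max_features)
        write_csv_out(props, "topic_proportions.csv")
        write_csv_out(ent, "entropy.csv")
        write_csv_out(as_tibble(as.data.frame(unclass(cooc))), "cooccurrence.csv")
        write_csv_out(links, "chord_edges.csv")
        write_csv_out(sent$keyword, "sentiment_keywords.csv")
        write_csv_out(sent$yearly, "sentiment_yearly.csv")
      }
    )

    # -- landscape -----------------------------------------------------------
    run_stage(
      "landscape",
      params = config[c("max_features", "n_pcs", "n_neighbors", "resolution")],
      outputs = c("labels.csv", "embedding.csv", "differential_words.csv"),
      inputs = "documents.csv",
      compute = function(recompute_only) {
        land <- build_landscape(state$bow, max_features = config$max_features,
                                n_pcs = config$n_pcs,
                                n_neighbors = config$n_neighbors,
                                resolution = config$resolution,
                                seed = config$seed)
        state$landscape <- land
        if (!recompute_only) {
          write_csv_out(tibble(doc_id = land$doc_id, cluster = land$labels),
                        "labels.csv")
          write_csv_out(tibble(doc_id = land$doc_id,
                               dim1 = land$embedding[, 1],
                               dim2 = land$embedding[, 2]),
                        "embedding.csv")
          dw <- differential_words(land$tfidf, land$labels, top_k = 3L)
          write_csv_out(dw$top, "differential_words.csv")
        }
      }
    )

    # -- cluster analytics ---------------------------------------------------
    run_stage(
      "cluster_analytics",
      params = config[c("smoothing_window", "hallmark_stems")],
      outputs = c("cluster_cosine.csv", "enrichment.csv",
                  "cluster_evolution.csv", "cluster_mean_year.csv",
                  "stability.csv", "hallmark_presence.csv",
                  "overlap.csv", "overlap_pairs.csv"),
      inputs = "labels.csv",
      compute = function(recompute_only) {
        if (recompute_only) return(invisible())
        land <- state$landscape
        fit <- state$lda
        prof <- cluster_profiles(land$tfidf, land$labels, land$year)
        cos <- cluster_cosine_matrix(prof)
        enr <- topic_enrichment(fit$theta, land$labels)
        evo <- cluster_evolution(land$labels, land$year,
                                 window = config$smoothing_window)
        stab <- stability_trend(fit$theta, land$labels, land$year,
                                window = config$smoothing_window)
        hall <- hallmark_presence(state$docs, land$labels,
                                  stems = config$hallmark_stems)
        ovl <- semantic_overlap(land$tfidf, land$labels)
        write_csv_out(mat_to_tibble(cos, "cluster"), "cluster_cosine.csv")
        write_csv_out(mat_to_tibble(enr$scores, "cluster"), "enrichment.csv")
        write_csv_out(evo$proportions, "cluster_evolution.csv")
        write_csv_out(evo$mean_year, "cluster_mean_year.csv")
        write_csv_out(stab$slopes, "stability.csv")
        write_csv_out(mat_to_tibble(hall, "cluster"), "hallmark_presence.csv")
        write_csv_out(mat_to_tibble(ovl$matrix, "cluster"), "overlap.csv")
        write_csv_out(ovl$pairs, "overlap_pairs.csv")
      }
    )

    # -- refocus -------------------------------------------------------------
    if (!is.null(config$refocus_topics)) {
      run_stage(
        "refocus",
        params = config[c("refocus_topics", "refocus_n_pcs", "max_features",
                          "n_neighbors", "resolution", "hallmark_stems")],
        outputs = c("refocus_labels.csv", "refocus_differential_words.csv",
                    "refocus_hallmark_presence.csv", "refocus_stability.csv"),
        inputs = "labels.csv",
        compute = function(recompute_only) {
          if (recompute_only) return(invisible())
          ref <- refocus_subcorpus(state$bow, state$lda, config$refocus_topics,
                                   max_features = config$max_features,
                                   n_pcs = config$refocus_n_pcs,
                                   n_neighbors = config$n_neighbors,
                                   resolution = config$resolution,
                                   seed = config$seed)
          land <- ref$landscape
          write_csv_out(tibble(doc_id = land$doc_id, cluster = land$labels),
                        "refocus_labels.csv")
          dw <- differential_words(land$tfidf, land$labels, top_k = 3L)
          write_csv_out(dw$top, "refocus_differential_words.csv")
          sub_docs <- state$docs[ref$keep, , drop = FALSE]
          hall <- hallmark_presence(sub_docs, land$labels,
                                    stems = config$hallmark_stems)
          write_csv_out(mat_to_tibble(hall, "cluster"),
                        "refocus_hallmark_presence.csv")
          stab <- stability_trend(state$lda$theta[ref$keep, , drop = FALSE],
                                  land$labels, land$year,
                                  window = config$smoothing_window)
          write_csv_out(stab$slopes, "refocus_stability.csv")
        }
      )
    }
  }, error = function(e) fail_stage(state$current_stage %||% "(setup)", e))

  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

# matrix -> tibble with a leading label column
mat_to_tibble <- function(m, label_col) {
  df <- as.data.frame(m)
  out <- cbind(setNames(tibble(rownames(m) %||% as.character(seq_len(nrow(m)))),
                        label_col), df)
  as_tibble(out)
}
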