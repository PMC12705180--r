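#' Corpus construction and validation
#'
#' A corpus is a tibble with one row per document and columns `doc_id`
#' (unique character id), `title`, `abstract` (non-empty), and `year`
#' (integer). Row order is meaningful and is preserved by all corpus
#' operations and by the JSONL reader/writer. Free-text provenance (query,
#' retrieval date, or synthetic seed) is carried in the `"provenance"`
#' attribute.
#'
#' @param docs A data frame with columns `doc_id`, `title`, `abstract`, `year`.
#' @param provenance Free-text description of where the corpus came from.
#' @param year_range Permitted publication-year range (inclusive).
#' @return A corpus tibble.
#' @export
as_corpus <- function(docs, provenance = "unspecified",
                      year_range = c(1925L, 2023L)) {
  required <- c("doc_id", "title", "abstract", "year")
  missing <- setdiff(required, names(docs))
  if (length(missing) > 0) {
    abort(sprintf("Corpus is missing required column(s): %s.",
                  paste(missing, collapse = ", ")))
  }
  out <- as_tibble(docs)[required]
  out$doc_id <- as.character(out$doc_id)
  out$title <- as.character(out$title)
  out$abstract <- as.character(out$abstract)
  if (is.character(out$year)) {
    suppressWarnings(yr <- as.integer(out$year))
    if (anyNA(yr) && !anyNA(out$year)) {
      abort("`year` contains values that cannot be coerced to integer.")
    }
    inform("Coerced character `year` values to integer.")
    out$year <- yr
  } else {
    out$year <- as.integer(out$year)
  }
  if (anyDuplicated(out$doc_id)) {
    abort("`doc_id` values must be unique within a corpus.")
  }
  if (any(!is.na(out$year) &
          (out$year < year_range[1] | out$year > year_range[2]))) {
    warn(sprintf("Some `year` values fall outside [%d, %d].",
                 year_range[1], year_range[2]))
  }
  attr(out, "provenance") <- provenance
  out
}

#' Read and write JSONL corpora
#'
#' The canonical on-disk corpus format is UTF-8 JSON Lines: one JSON object
#' per line with keys `doc_id`, `title`, `abstract`, `year` (in that order on
#' write, so writes are byte-stable). `write_corpus()` followed by
#' `read_corpus()` round-trips a corpus exactly, including row order.
#'
#' @param path File path.
#' @param corpus A corpus tibble (see [as_corpus()]).
#' @return `read_corpus()` returns a corpus tibble; `write_corpus()` returns
#'   `path` invisibly.
#' @export
read_corpus <- function(path) {
  if (!file.exists(path)) abort(sprintf("Corpus file not found: %s", path))
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  required <- c("doc_id", "title", "abstract", "year")
  n_coerced <- 0L
  parse_line <- function(i) {
    rec <- tryCatch(
      jsonlite::fromJSON(lines[i], simplifyVector = TRUE),
      error = function(e) {
        abort(sprintf("Malformed JSON on line %d of %s: %s",
                      i, path, conditionMessage(e)))
      }
    )
    missing <- setdiff(required, names(rec))
    if (length(missing) > 0) {
      abort(sprintf("Document %d is missing required field(s): %s.",
                    i, paste(missing, collapse = ", ")))
    }
    if (is.character(rec$year)) n_coerced <<- n_coerced + 1L
    year <- suppressWarnings(as.integer(rec$year))
    if (is.na(year)) {
      abort(sprintf("Document %d has a `year` that is not interpretable as an integer.", i))
    }
    tibble(
      doc_id = as.character(rec$doc_id),
      title = as.character(rec$title %||% ""),
      abstract = as.character(rec$abstract),
      year = year
    )
  }
  docs <- bind_rows(lapply(seq_along(lines), parse_line))
  if (n_coerced > 0) {
    inform(sprintf("Coerced %d character `year` value(s) to integer in %s.",
                   n_coerced, path))
  }
  as_corpus(docs, provenance = sprintf("read from %s", path))
}

#' @rdname read_corpus
#' @export
write_corpus <- function(corpus, path) {
  corpus <- as_corpus(corpus, provenance = attr(corpus, "provenance") %||% "unspecified")
  lines <- vapply(seq_len(nrow(corpus)), function(i) {
    jsonlite::toJSON(
      list(doc_id = corpus$doc_id[i], title = corpus$title[i],
           abstract = corpus$abstract[i], year = corpus$year[i]),
      auto_unbox = TRUE
    )
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Remove duplicate documents
#'
#' Two documents are duplicates when they share a `doc_id`, or when their
#' normalized (lowercased, whitespace-collapsed) `title` + `abstract` pair is
#' identical. The first occurrence in corpus order survives. The operation is
#' idempotent.
#'
#' @param corpus A corpus tibble.
#' @return The deduplicated corpus, original order preserved. The number of
#'   removed documents is reported via a message.
#' @export
dedup_corpus <- function(corpus) {
  if (nrow(corpus) == 0) return(corpus)
  norm <- function(x) tolower(gsub("\\s+", " ", trimws(x)))
  text_key <- paste(norm(corpus$title), norm(corpus$abstract), sep = "\x1f")
  keep <- !duplicated(corpus$doc_id) & !duplicated(text_key)
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    inform(sprintf("Removed %d duplicate document(s); %d retained.",
                   n_dropped, sum(keep)))
  }
  out <- corpus[keep, , drop = FALSE]
  attr(out, "provenance") <- attr(corpus, "provenance")
  out
}

#' Fetch abstracts from PubMed via the Entrez API
#'
#' Optional, network-dependent corpus acquisition. Queries PubMed through the
#' NCBI E-utilities (`esearch` + `efetch`), retrieving title, abstract, and
#' publication year for every match. Records without an abstract or year are
#' dropped and counted. All downstream stages consume only the JSONL corpus
#' format, so the rest of the pipeline is fully usable offline.
#'
#' @param query Entrez search expression, e.g.
#'   `"aging[Title/Abstract] OR aging[MeSH Terms]"`.
#' @param year_start,year_end Publication-year range (inclusive).
#' @param contact E-mail address supplied to the API, required by NCBI's
#'   usage policy.
#' @param batch_size Records per `efetch` request.
#' @param max_records Optional cap on total records (useful for testing).
#' @param retries Retry attempts per failed HTTP request.
#' @return A corpus tibble with provenance recording the query and date.
#' @export
fetch_pubmed <- function(query, year_start, year_end, contact,
                         batch_size = 500L, max_records = Inf, retries = 3L) {
  if (missing(contact) || !nzchar(contact)) {
    abort("`contact` e-mail is required by the Entrez usage policy.")
  }
  base <- "https://eutils.ncbi.nlm.nih.gov/entrez/eutils"
  term <- sprintf("(%s) AND (%d:%d[pdat])", query, year_start, year_end)
  get_xml <- function(url) {
    for (attempt in seq_len(retries)) {
      res <- tryCatch(xml2::read_xml(url), error = function(e) e)
      if (!inherits(res, "error")) return(res)
      if (attempt == retries) {
        abort(sprintf("Entrez request failed after %d attempt(s): %s",
                      retries, conditionMessage(res)))
      }
      Sys.sleep(2^attempt)
    }
  }
  search_url <- paste0(
    base, "/esearch.fcgi?db=pubmed&retmax=100000000&term=",
    utils::URLencode(term, reserved = TRUE), "&email=",
    utils::URLencode(contact, reserved = TRUE)
  )
  search <- get_xml(search_url)
  ids <- xml2::xml_text(xml2::xml_find_all(search, ".//IdList/Id"))
  if (is.finite(max_records)) ids <- head(ids, max_records)
  provenance <- sprintf("PubMed query '%s' (%d-%d), retrieved %s",
                        query, year_start, year_end, format(Sys.Date()))
  if (length(ids) == 0) {
    return(as_corpus(
      tibble(doc_id = character(), title = character(),
             abstract = character(), year = integer()),
      provenance = provenance
    ))
  }
  batches <- split(ids, ceiling(seq_along(ids) / batch_size))
  n_dropped <- 0L
  docs <- lapply(batches, function(batch) {
    fetch_url <- paste0(
      base, "/efetch.fcgi?db=pubmed&retmode=xml&id=", paste(batch, collapse = ","),
      "&email=", utils::URLencode(contact, reserved = TRUE)
    )
    xml <- get_xml(fetch_url)
    parsed <- parse_pubmed_xml(xml)
    n_dropped <<- n_dropped + attr(parsed, "n_dropped")
    parsed
  })
  docs <- bind_rows(docs)
  if (n_dropped > 0) {
    inform(sprintf("Dropped %d record(s) lacking an abstract or year.", n_dropped))
  }
  as_corpus(docs, provenance = provenance)
}

#' Parse a PubMed efetch XML document
#'
#' Extracts `doc_id` (PMID), `title`, `abstract`, and `year` from a
#' `PubmedArticleSet` XML document. Records missing an abstract or a
#' resolvable year are dropped; the count of dropped records is attached as
#' the `"n_dropped"` attribute. Malformed article nodes are skipped with a
#' warning, never aborting the batch.
#'
#' @param xml An `xml2` document (or path/string accepted by
#'   [xml2::read_xml()]).
#' @return A tibble of parsed records.
#' @export
parse_pubmed_xml <- function(xml) {
  if (!inherits(xml, "xml_document")) xml <- xml2::read_xml(xml)
  articles <- xml2::xml_find_all(xml, ".//PubmedArticle")
  n_dropped <- 0L
  rows <- lapply(articles, function(node) {
    rec <- tryCatch({
      pmid <- xml2::xml_text(xml2::xml_find_first(node, ".//MedlineCitation/PMID"))
      title <- xml2::xml_text(xml2::xml_find_first(node, ".//ArticleTitle"))
      abst_nodes <- xml2::xml_find_all(node, ".//Abstract/AbstractText")
      abstract <- paste(xml2::xml_text(abst_nodes), collapse = " ")
      year <- xml2::xml_text(xml2::xml_find_first(
        node, ".//JournalIssue/PubDate/Year"
      ))
      if (is.na(year) || !nzchar(year)) {
        medline <- xml2::xml_text(xml2::xml_find_first(
          node, ".//JournalIssue/PubDate/MedlineDate"
        ))
        year <- regmatches(medline, regexpr("[0-9]{4}", medline))
        if (length(year) == 0) year <- NA_character_
      }
      list(pmid = pmid, title = title, abstract = abstract, year = year)
    }, error = function(e) {
      warn(sprintf("Skipping malformed PubMed record: %s", conditionMessage(e)))
      NULL
    })
    if (is.null(rec) || is.na(rec$pmid) || !nzchar(trimws(rec$abstract)) ||
        is.na(rec$year)) {
      n_dropped <<- n_dropped + 1L
      return(NULL)
    }
    tibble(doc_id = rec$pmid, title = rec$title %||% "",
           abstract = rec$abstract, year = as.integer(rec$year))
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble(doc_id = character(), title = character(),
                  abstract = character(), year = integer())
  }
  attr(out, "n_dropped") <- n_dropped
  out
}
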