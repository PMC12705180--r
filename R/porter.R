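#' Porter stemmer
#'
#' Reduces English words to stems with the classic Porter (1980) suffix
#' stripping algorithm: five ordered rule steps driven by the consonant-vowel
#' "measure" of the candidate stem. Within each step the longest matching
#' suffix is selected; if its condition fails no other rule in that step is
#' tried. Words of one or two letters are returned unchanged. Input is
#' expected to be lowercase; tokens containing no alphabetic suffix patterns
#' (e.g. synthetic stems such as `"w0001"`) pass through unchanged.
#'
#' @param words Character vector of lowercase words.
#' @return Character vector of stems, same length as `words`.
#' @examples
#' porter_stem(c("cells", "aging", "generalizations", "oscillators"))
#' @export
porter_stem <- function(words) {
  if (!is.character(words)) abort("`words` must be a character vector.")
  uw <- unique(words)
  stems <- vapply(uw, porter_stem_word, character(1), USE.NAMES = FALSE)
  stems[match(words, uw)]
}

# -- internals ---------------------------------------------------------------

# TRUE where the letter at each position is a consonant. 'y' is a consonant
# at word start or after a vowel, a vowel after a consonant.
porter_types <- function(chars) {
  n <- length(chars)
  cons <- logical(n)
  for (i in seq_len(n)) {
    ch <- chars[i]
    if (ch %in% c("a", "e", "i", "o", "u")) {
      cons[i] <- FALSE
    } else if (ch == "y") {
      cons[i] <- if (i == 1L) TRUE else !cons[i - 1L]
    } else {
      cons[i] <- TRUE
    }
  }
  cons
}

# m in the [C](VC)^m[V] decomposition
porter_measure <- function(word) {
  if (nchar(word) == 0L) return(0L)
  cons <- porter_types(strsplit(word, "", fixed = TRUE)[[1]])
  runs <- rle(cons)$values           # TRUE = consonant run
  sum(runs[-length(runs)] == FALSE & runs[-1] == TRUE)
}

porter_has_vowel <- function(word) {
  if (nchar(word) == 0L) return(FALSE)
  any(!porter_types(strsplit(word, "", fixed = TRUE)[[1]]))
}

porter_double_cons <- function(word) {
  n <- nchar(word)
  if (n < 2L) return(FALSE)
  chars <- strsplit(word, "", fixed = TRUE)[[1]]
  if (chars[n] != chars[n - 1L]) return(FALSE)
  porter_types(chars)[n]
}

# *o: stem ends consonant-vowel-consonant and the final consonant is not w/x/y
porter_cvc <- function(word) {
  n <- nchar(word)
  if (n < 3L) return(FALSE)
  chars <- strsplit(word, "", fixed = TRUE)[[1]]
  cons <- porter_types(chars)
  cons[n] && !cons[n - 1L] && cons[n - 2L] && !(chars[n] %in% c("w", "x", "y"))
}

ends_with <- function(word, suffix) {
  nw <- nchar(word); ns <- nchar(suffix)
  nw >= ns && substring(word, nw - ns + 1L, nw) == suffix
}

drop_suffix <- function(word, suffix) {
  substring(word, 1L, nchar(word) - nchar(suffix))
}

# Apply the longest matching (suffix -> replacement) rule whose measure
# condition holds; rules with a matching suffix but failing condition end the
# step with no change (Porter's semantics).
porter_rule_step <- function(word, suffixes, replacements, min_measure) {
  lens <- nchar(suffixes)
  ord <- order(lens, decreasing = TRUE)
  for (i in ord) {
    if (ends_with(word, suffixes[i])) {
      stem <- drop_suffix(word, suffixes[i])
      if (porter_measure(stem) > min_measure) {
        return(paste0(stem, replacements[i]))
      }
      return(word)
    }
  }
  word
}

porter_stem_word <- function(word) {
  if (nchar(word) <= 2L) return(word)

  # Step 1a
  if (ends_with(word, "sses")) {
    word <- paste0(drop_suffix(word, "sses"), "ss")
  } else if (ends_with(word, "ies")) {
    word <- paste0(drop_suffix(word, "ies"), "i")
  } else if (!ends_with(word, "ss") && ends_with(word, "s")) {
    word <- drop_suffix(word, "s")
  }

  # Step 1b
  fixup <- FALSE
  if (ends_with(word, "eed")) {
    stem <- drop_suffix(word, "eed")
    if (porter_measure(stem) > 0L) word <- paste0(stem, "ee")
  } else if (ends_with(word, "ed") && porter_has_vowel(drop_suffix(word, "ed"))) {
    word <- drop_suffix(word, "ed")
    fixup <- TRUE
  } else if (ends_with(word, "ing") && porter_has_vowel(drop_suffix(word, "ing"))) {
    word <- drop_suffix(word, "ing")
    fixup <- TRUE
  }
  if (fixup) {
    if (ends_with(word, "at") || ends_with(word, "bl") || ends_with(word, "iz")) {
      word <- paste0(word, "e")
    } else if (porter_double_cons(word) &&
               !ends_with(word, "l") && !ends_with(word, "s") && !ends_with(word, "z")) {
      word <- substring(word, 1L, nchar(word) - 1L)
    } else if (porter_measure(word) == 1L && porter_cvc(word)) {
      word <- paste0(word, "e")
    }
  }

  # Step 1c
  if (ends_with(word, "y") && porter_has_vowel(drop_suffix(word, "y"))) {
    word <- paste0(drop_suffix(word, "y"), "i")
  }

  # Step 2 (m > 0)
  word <- porter_rule_step(
    word,
    c("ational", "tional", "enci", "anci", "izer", "abli", "alli", "entli",
      "eli", "ousli", "ization", "ation", "ator", "alism", "iveness",
      "fulness", "ousness", "aliti", "iviti", "biliti"),
    c("ate", "tion", "ence", "ance", "ize", "able", "al", "ent",
      "e", "ous", "ize", "ate", "ate", "al", "ive",
      "ful", "ous", "al", "ive", "ble"),
    min_measure = 0L
  )

  # Step 3 (m > 0)
  word <- porter_rule_step(
    word,
    c("icate", "ative", "alize", "iciti", "ical", "ful", "ness"),
    c("ic", "", "al", "ic", "ic", "", ""),
    min_measure = 0L
  )

  # Step 4 (m > 1); "ion" additionally requires the stem to end in s or t
  step4 <- c("al", "ance", "ence", "er", "ic", "able", "ible", "ant",
             "ement", "ment", "ent", "ion", "ou", "ism", "ate", "iti",
             "ous", "ive", "ize")
  lens <- nchar(step4)
  for (i in order(lens, decreasing = TRUE)) {
    suf <- step4[i]
    if (ends_with(word, suf)) {
      stem <- drop_suffix(word, suf)
      ok <- porter_measure(stem) > 1L
      if (suf == "ion") {
        ok <- ok && (ends_with(stem, "s") || ends_with(stem, "t"))
      }
      if (ok) word <- stem
      break
    }
  }

  # Step 5a
  if (ends_with(word, "e")) {
    stem <- drop_suffix(word, "e")
    m <- porter_measure(stem)
    if (m > 1L || (m == 1L && !porter_cvc(stem))) word <- stem
  }

  # Step 5b
  if (porter_measure(word) > 1L && porter_double_cons(word) && ends_with(word, "l")) {
    word <- substring(word, 1L, nchar(word) - 1L)
  }

  word
}
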