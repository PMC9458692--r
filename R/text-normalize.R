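# Keyword normalization shared by the indexer and the question lookup:
# lowercase, split on punctuation and camel case, Porter-stem each word.
# The same normalization must be applied on both sides or longest-match
# tokenization cannot work.

#' Default English stopword list
#'
#' A compact list of function words plus interrogative scaffolding ("what",
#' "which", "show", "give", "list"); stopwords are stripped from questions at
#' lookup time, never from the index itself, so multi-word keys keep their
#' inner words.
#'
#' @return Character vector of lowercase words.
#' @export
default_stopwords <- function() {
  c(
    "a", "an", "the", "this", "that", "these", "those", "some", "any", "all",
    "is", "are", "was", "were", "be", "been", "being", "am", "do", "does",
    "did", "have", "has", "had", "can", "could", "will", "would", "shall",
    "should", "may", "might", "must",
    "of", "in", "on", "at", "by", "for", "with", "to", "from", "into", "as",
    "about", "between", "through", "over", "under", "up", "down", "out",
    "and", "or", "not", "no", "nor", "but", "if", "then", "than", "so",
    "there", "here", "where", "when", "how", "why", "what", "which", "who",
    "whom", "whose",
    "i", "you", "he", "she", "it", "we", "they", "me", "him", "her", "us",
    "them", "my", "your", "his", "its", "our", "their",
    "show", "give", "list", "find", "get", "tell", "display", "retrieve",
    "please", "use", "used", "uses", "using"
  )
}

#' Split a URI fragment or identifier into normalized keywords
#'
#' Splits camel-case humps and punctuation, keeping runs of uppercase letters
#' and digits together (so `"BRCA1_gene"` becomes `"brca1 gene"` and
#' `"possibleDiseaseTarget"` becomes `"possible disease target"`), then
#' lowercases. Stemming is applied separately by [normalize_words()].
#'
#' @param fragment Character vector of local names / identifiers.
#' @param splitters Characters treated as word separators.
#' @return Character vector of space-separated lowercase keywords (empty
#'   string when nothing survives).
#' @export
split_fragment <- function(fragment, splitters = c("_", "-", ".", ":", "/", ",", ";")) {
  x <- fragment
  for (s in splitters) x <- gsub(s, " ", x, fixed = TRUE)
  # camel humps: aB -> a B; also split a trailing capitalized word off an
  # uppercase run (BRCAGene -> BRCA Gene), keeping upper+digit runs whole.
  x <- gsub("([a-z0-9])([A-Z])", "\\1 \\2", x)
  x <- gsub("([A-Z]+)([A-Z][a-z])", "\\1 \\2", x)
  x <- gsub("[[:space:]]+", " ", trimws(x))
  tolower(x)
}

#' Normalize free text to stemmed keyword words
#'
#' @param text Character vector.
#' @param stopwords Words to drop (applied before stemming); use
#'   `character(0)` to keep everything, as the indexer does.
#' @return List of character vectors of stemmed words, one per input string.
#' @export
normalize_words <- function(text, stopwords = character(0)) {
  lapply(text, function(s) {
    s <- tolower(s)
    s <- gsub("[^a-z0-9]+", " ", s)
    words <- strsplit(trimws(s), " +")[[1]]
    words <- words[nzchar(words)]
    words <- words[!words %in% stopwords]
    porter_stem(words)
  })
}

normalize_key <- function(text) {
  vapply(
    normalize_words(text),
    function(w) paste(w, collapse = " "), ""
  )
}

#' Porter stemmer
#'
#' The classic five-step suffix-stripping algorithm, reproduced in full
#' (including its known quirks: "gaseous" does not reduce to "gas").
#'
#' @param words Character vector of lowercase words.
#' @return Character vector of stems.
#' @export
porter_stem <- function(words) {
  vapply(words, porter_stem_one, "", USE.NAMES = FALSE)
}

porter_stem_one <- function(w) {
  if (nchar(w) <= 2 || grepl("[^a-z]", w)) {
    return(w)
  }

  is_cons <- function(chars, i) {
    ch <- chars[i]
    if (ch %in% c("a", "e", "i", "o", "u")) {
      return(FALSE)
    }
    if (ch == "y") {
      return(if (i == 1) TRUE else !is_cons(chars, i - 1))
    }
    TRUE
  }
  measure <- function(stem) {
    chars <- strsplit(stem, "")[[1]]
    if (length(chars) == 0) {
      return(0L)
    }
    types <- vapply(seq_along(chars), function(i) is_cons(chars, i), TRUE)
    runs <- rle(types)$values
    sum(runs[-1] == TRUE) # VC transitions after the optional initial C run
  }
  has_vowel <- function(stem) {
    chars <- strsplit(stem, "")[[1]]
    any(!vapply(seq_along(chars), function(i) is_cons(chars, i), TRUE))
  }
  ends_double_cons <- function(stem) {
    n <- nchar(stem)
    if (n < 2) {
      return(FALSE)
    }
    chars <- strsplit(stem, "")[[1]]
    chars[n] == chars[n - 1] && is_cons(chars, n)
  }
  ends_cvc <- function(stem) {
    n <- nchar(stem)
    if (n < 3) {
      return(FALSE)
    }
    chars <- strsplit(stem, "")[[1]]
    is_cons(chars, n) && !is_cons(chars, n - 1) && is_cons(chars, n - 2) &&
      !chars[n] %in% c("w", "x", "y")
  }
  ends_with <- function(w, suf) {
    nchar(w) > nchar(suf) && substring(w, nchar(w) - nchar(suf) + 1) == suf
  }
  chop <- function(w, suf) substring(w, 1, nchar(w) - nchar(suf))

  # Step 1a
  if (ends_with(w, "sses")) {
    w <- paste0(chop(w, "sses"), "ss")
  } else if (ends_with(w, "ies")) {
    w <- paste0(chop(w, "ies"), "i")
  } else if (!ends_with(w, "ss") && ends_with(w, "s")) w <- chop(w, "s")

  # Step 1b
  fired <- FALSE
  if (ends_with(w, "eed")) {
    if (measure(chop(w, "eed")) > 0) w <- chop(w, "d")
  } else if (ends_with(w, "ed") && has_vowel(chop(w, "ed"))) {
    w <- chop(w, "ed")
    fired <- TRUE
  } else if (ends_with(w, "ing") && has_vowel(chop(w, "ing"))) {
    w <- chop(w, "ing")
    fired <- TRUE
  }
  if (fired) {
    if (ends_with(w, "at") || ends_with(w, "bl") || ends_with(w, "iz")) {
      w <- paste0(w, "e")
    } else if (ends_double_cons(w) &&
      !substring(w, nchar(w)) %in% c("l", "s", "z")) {
      w <- substring(w, 1, nchar(w) - 1)
    } else if (measure(w) == 1 && ends_cvc(w)) {
      w <- paste0(w, "e")
    }
  }

  # Step 1c
  if (ends_with(w, "y") && has_vowel(chop(w, "y"))) {
    w <- paste0(chop(w, "y"), "i")
  }

  apply_rules <- function(w, rules, cond) {
    for (r in rules) {
      if (ends_with(w, r[1])) {
        stem <- chop(w, r[1])
        if (cond(stem)) w <- paste0(stem, r[2])
        return(w)
      }
    }
    w
  }

  # Step 2
  w <- apply_rules(w, list(
    c("ational", "ate"), c("tional", "tion"), c("enci", "ence"),
    c("anci", "ance"), c("izer", "ize"), c("abli", "able"), c("alli", "al"),
    c("entli", "ent"), c("eli", "e"), c("ousli", "ous"), c("ization", "ize"),
    c("ation", "ate"), c("ator", "ate"), c("alism", "al"), c("iveness", "ive"),
    c("fulness", "ful"), c("ousness", "ous"), c("aliti", "al"),
    c("iviti", "ive"), c("biliti", "ble")
  ), function(stem) measure(stem) > 0)

  # Step 3
  w <- apply_rules(w, list(
    c("icate", "ic"), c("ative", ""), c("alize", "al"), c("iciti", "ic"),
    c("ical", "ic"), c("ful", ""), c("ness", "")
  ), function(stem) measure(stem) > 0)

  # Step 4
  step4 <- list(
    c("al", ""), c("ance", ""), c("ence", ""), c("er", ""), c("ic", ""),
    c("able", ""), c("ible", ""), c("ant", ""), c("ement", ""), c("ment", ""),
    c("ent", ""), c("ion", ""), c("ou", ""), c("ism", ""), c("ate", ""),
    c("iti", ""), c("ous", ""), c("ive", ""), c("ize", "")
  )
  for (r in step4) {
    if (ends_with(w, r[1])) {
      stem <- chop(w, r[1])
      ok <- measure(stem) > 1 &&
        (r[1] != "ion" || substring(stem, nchar(stem)) %in% c("s", "t"))
      if (ok) w <- stem
      break
    }
  }

  # Step 5a
  if (ends_with(w, "e")) {
    stem <- chop(w, "e")
    m <- measure(stem)
    if (m > 1 || (m == 1 && !ends_cvc(stem))) w <- stem
  }
  # Step 5b
  if (measure(w) > 1 && ends_double_cons(w) && ends_with(w, "l")) {
    w <- substring(w, 1, nchar(w) - 1)
  }
  w
}

# All contiguous word n-grams of a word vector, up to max_len words.
word_ngrams <- function(words, max_len) {
  n <- length(words)
  if (n == 0) {
    return(character(0))
  }
  out <- character(0)
  for (len in seq_len(min(max_len, n))) {
    for (start in seq_len(n - len + 1L)) {
      out <- c(out, paste(words[start:(start + len - 1L)], collapse = " "))
    }
  }
  unique(out)
}
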