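# Turtle / N-Triples reader.
#
# Covers the Turtle subset in which fixtures and typical instance data are
# written: @prefix/PREFIX and @base/BASE directives, IRIREFs, prefixed names,
# `a`, predicate-object lists with `;` and `,`, string literals (short and
# long quoted forms, escapes, @lang and ^^datatype), numeric and boolean
# shorthand, labelled and anonymous blank nodes. Blank nodes are skolemized
# deterministically per file. Collections `( ... )` are not supported.

parse_turtle_file <- function(path) {
  text <- paste(readLines(path, warn = FALSE, encoding = "UTF-8"), collapse = "\n")
  st <- new.env(parent = emptyenv())
  st$text <- text
  st$pos <- 1L
  st$n <- nchar(text)
  st$path <- path
  st$prefixes <- stats::setNames("", "") # default (empty) prefix
  st$base <- ""
  st$bnode_counter <- 0L
  st$file_tag <- gsub("[^A-Za-z0-9]", "-", basename(path))
  rows <- list()
  st$emit <- function(s, p, o, kind, dt, lang) {
    rows[[length(rows) + 1L]] <<- list(
      subject = s, predicate = p, object = o,
      object_kind = kind, datatype = dt, lang = lang
    )
  }
  repeat {
    ttl_skip_ws(st)
    if (st$pos > st$n) break
    ttl_statement(st)
  }
  triples <- if (length(rows) == 0) {
    NULL
  } else {
    tibble::tibble(
      subject = vapply(rows, `[[`, "", "subject"),
      predicate = vapply(rows, `[[`, "", "predicate"),
      object = vapply(rows, `[[`, "", "object"),
      object_kind = vapply(rows, `[[`, "", "object_kind"),
      datatype = vapply(rows, `[[`, NA_character_, "datatype"),
      lang = vapply(rows, `[[`, NA_character_, "lang")
    )
  }
  prefixes <- st$prefixes[names(st$prefixes) != ""]
  list(triples = triples, prefixes = prefixes)
}

ttl_line <- function(st) {
  1L + nchar(gsub("[^\n]", "", substr(st$text, 1L, st$pos - 1L)))
}

ttl_fail <- function(st, why) {
  stop(
    "Turtle parse error in ", st$path, " line ", ttl_line(st), ": ", why,
    call. = FALSE
  )
}

ttl_skip_ws <- function(st) {
  repeat {
    m <- regmatches(
      substr(st$text, st$pos, st$n),
      regexpr("^([ \t\r\n]+|#[^\n]*)", substr(st$text, st$pos, st$n))
    )
    if (length(m) == 0) break
    st$pos <- st$pos + nchar(m)
  }
}

ttl_peek <- function(st, k = 1L) substr(st$text, st$pos, st$pos + k - 1L)

ttl_take_re <- function(st, re) {
  rest <- substr(st$text, st$pos, st$n)
  m <- regmatches(rest, regexpr(re, rest, perl = TRUE))
  if (length(m) == 0) {
    return(NULL)
  }
  st$pos <- st$pos + nchar(m)
  m
}

ttl_expect <- function(st, ch) {
  ttl_skip_ws(st)
  if (ttl_peek(st, nchar(ch)) != ch) ttl_fail(st, paste0("expected '", ch, "'"))
  st$pos <- st$pos + nchar(ch)
}

ttl_statement <- function(st) {
  rest <- substr(st$text, st$pos, st$n)
  if (grepl("^@prefix\\b", rest) || grepl("^PREFIX\\b", rest, ignore.case = TRUE)) {
    at <- grepl("^@", rest)
    st$pos <- st$pos + (if (at) 7L else 6L)
    ttl_skip_ws(st)
    label <- ttl_take_re(st, "^[A-Za-z0-9_.-]*:")
    if (is.null(label)) ttl_fail(st, "expected prefix label")
    ttl_skip_ws(st)
    iri <- ttl_iriref(st)
    st$prefixes[sub(":$", "", label)] <- iri
    if (at) ttl_expect(st, ".")
    return(invisible())
  }
  if (grepl("^@base\\b", rest) || grepl("^BASE\\b", rest, ignore.case = TRUE)) {
    at <- grepl("^@", rest)
    st$pos <- st$pos + (if (at) 5L else 4L)
    ttl_skip_ws(st)
    st$base <- ttl_iriref(st)
    if (at) ttl_expect(st, ".")
    return(invisible())
  }
  subj <- ttl_subject(st)
  ttl_predicate_object_list(st, subj)
  ttl_expect(st, ".")
}

ttl_iriref <- function(st) {
  ttl_skip_ws(st)
  m <- ttl_take_re(st, "^<[^<>\"{}|^`\\\\ ]*>")
  if (is.null(m)) ttl_fail(st, "expected IRIREF")
  iri <- substr(m, 2L, nchar(m) - 1L)
  if (!grepl("^[A-Za-z][A-Za-z0-9+.-]*:", iri) && nzchar(st$base)) {
    iri <- paste0(st$base, iri)
  }
  iri
}

ttl_pname_or_null <- function(st) {
  m <- ttl_take_re(st, "^[A-Za-z0-9_.-]*:[A-Za-z0-9_.%-]*")
  if (is.null(m)) {
    return(NULL)
  }
  colon <- regexpr(":", m, fixed = TRUE)
  prefix <- substr(m, 1L, colon - 1L)
  local <- substr(m, colon + 1L, nchar(m))
  if (!prefix %in% names(st$prefixes)) {
    ttl_fail(st, paste0("undeclared prefix '", prefix, ":'"))
  }
  paste0(st$prefixes[[prefix]], local)
}

ttl_blank_label <- function(st) {
  m <- ttl_take_re(st, "^_:[A-Za-z0-9_.-]+")
  if (is.null(m)) {
    return(NULL)
  }
  skolem_iri(st, sub("^_:", "", m))
}

skolem_iri <- function(st, label) {
  paste0("urn:skolem:", st$file_tag, ":", label)
}

ttl_subject <- function(st) {
  ttl_skip_ws(st)
  ch <- ttl_peek(st)
  if (ch == "<") {
    return(ttl_iriref(st))
  }
  if (ch == "_") {
    b <- ttl_blank_label(st)
    if (!is.null(b)) {
      return(b)
    }
  }
  if (ch == "[") {
    return(ttl_anon_bnode(st))
  }
  p <- ttl_pname_or_null(st)
  if (is.null(p)) ttl_fail(st, "expected subject")
  p
}

ttl_anon_bnode <- function(st) {
  ttl_expect(st, "[")
  st$bnode_counter <- st$bnode_counter + 1L
  node <- skolem_iri(st, paste0("anon", st$bnode_counter))
  ttl_skip_ws(st)
  if (ttl_peek(st) != "]") ttl_predicate_object_list(st, node)
  ttl_expect(st, "]")
  node
}

ttl_predicate <- function(st) {
  ttl_skip_ws(st)
  if (ttl_peek(st) == "a" && grepl("^a[ \t\r\n<]", ttl_peek(st, 2L))) {
    st$pos <- st$pos + 1L
    return(RDF_TYPE)
  }
  if (ttl_peek(st) == "<") {
    return(ttl_iriref(st))
  }
  p <- ttl_pname_or_null(st)
  if (is.null(p)) ttl_fail(st, "expected predicate")
  p
}

ttl_predicate_object_list <- function(st, subj) {
  repeat {
    pred <- ttl_predicate(st)
    repeat {
      ttl_object(st, subj, pred)
      ttl_skip_ws(st)
      if (ttl_peek(st) == ",") {
        st$pos <- st$pos + 1L
      } else {
        break
      }
    }
    ttl_skip_ws(st)
    if (ttl_peek(st) == ";") {
      st$pos <- st$pos + 1L
      ttl_skip_ws(st)
      # trailing ';' before '.' or ']'
      if (ttl_peek(st) %in% c(".", "]")) break
    } else {
      break
    }
  }
}

ttl_object <- function(st, subj, pred) {
  ttl_skip_ws(st)
  ch <- ttl_peek(st)
  if (ch == "<") {
    st$emit(subj, pred, ttl_iriref(st), "iri", NA_character_, NA_character_)
    return(invisible())
  }
  if (ch == "_") {
    b <- ttl_blank_label(st)
    if (!is.null(b)) {
      st$emit(subj, pred, b, "iri", NA_character_, NA_character_)
      return(invisible())
    }
  }
  if (ch == "[") {
    node <- ttl_anon_bnode(st)
    st$emit(subj, pred, node, "iri", NA_character_, NA_character_)
    return(invisible())
  }
  if (ch == "\"" || ch == "'") {
    lit <- ttl_literal(st)
    st$emit(subj, pred, lit$value, "literal", lit$datatype, lit$lang)
    return(invisible())
  }
  num <- ttl_take_re(st, "^[+-]?[0-9]+\\.[0-9]*(?=[ \t\r\n,;.\\]])|^[+-]?[0-9]+(?=[ \t\r\n,;\\]]|\\.[ \t\r\n])")
  if (!is.null(num)) {
    dt <- if (grepl("\\.", num)) XSD_DECIMAL else XSD_INTEGER
    st$emit(subj, pred, num, "literal", dt, NA_character_)
    return(invisible())
  }
  bool <- ttl_take_re(st, "^(true|false)(?![A-Za-z0-9_:-])")
  if (!is.null(bool)) {
    st$emit(subj, pred, bool, "literal", XSD_BOOLEAN, NA_character_)
    return(invisible())
  }
  p <- ttl_pname_or_null(st)
  if (is.null(p)) ttl_fail(st, "expected object term")
  st$emit(subj, pred, p, "iri", NA_character_, NA_character_)
}

ttl_literal <- function(st) {
  q <- ttl_peek(st)
  long <- ttl_peek(st, 3L) %in% c("\"\"\"", "'''")
  quote_str <- if (long) ttl_peek(st, 3L) else q
  st$pos <- st$pos + nchar(quote_str)
  start <- st$pos
  repeat {
    if (st$pos > st$n) ttl_fail(st, "unterminated string literal")
    ch <- ttl_peek(st)
    if (ch == "\\") {
      st$pos <- st$pos + 2L
      next
    }
    if (substr(st$text, st$pos, st$pos + nchar(quote_str) - 1L) == quote_str) break
    st$pos <- st$pos + 1L
  }
  raw <- substr(st$text, start, st$pos - 1L)
  st$pos <- st$pos + nchar(quote_str)
  value <- unescape_nt_string(raw)
  lang <- NA_character_
  datatype <- NA_character_
  langm <- ttl_take_re(st, "^@[A-Za-z]+(-[A-Za-z0-9]+)*")
  if (!is.null(langm)) {
    lang <- sub("^@", "", langm)
  } else if (ttl_peek(st, 2L) == "^^") {
    st$pos <- st$pos + 2L
    datatype <- if (ttl_peek(st) == "<") ttl_iriref(st) else ttl_pname_or_null(st)
    if (is.null(datatype)) ttl_fail(st, "expected datatype IRI")
  }
  list(value = value, lang = lang, datatype = datatype)
}
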