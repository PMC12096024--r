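#' Tokenize a document and count readability inputs
#'
#' Produces the token statistics that feed all four readability indices:
#' sentences, words, syllables, letters, polysyllables (>= 3 syllables) and
#' Fog-complex words (polysyllables surviving the exclusion rules).
#'
#' Sentence segmentation is deterministic: `.`, `!`, `?` end a sentence,
#' except a period inside a decimal number, a period followed by a lower-case
#' letter, or a period closing a known abbreviation ("Dr.", "e.g.", ...).
#' Words are maximal runs of alphanumerics with internal hyphens or
#' apostrophes; purely numeric tokens count one syllable. A Fog-complex word
#' is a polysyllable that is neither a capitalized non-sentence-initial token
#' (proper-noun proxy) nor a hyphenated compound.
#'
#' @param text Non-empty character scalar.
#' @param exceptions Syllable exception table, see [syllable_exceptions()].
#' @return A `token_stats` object: list with `n_sentences`, `n_words`,
#'   `n_syllables`, `n_complex`, `n_polysyllables`, `n_letters`.
#' @examples
#' compute_token_stats("The knee hurts. Rest it.")
#' @export
compute_token_stats <- function(text, exceptions = syllable_exceptions()) {
  if (length(text) != 1L || is.na(text) || !is.character(text)) {
    stop("`text` must be a single character string", call. = FALSE)
  }
  norm <- gsub("[[:space:]]+", " ", trimws(text))
  if (!nzchar(norm)) stop("text is empty after whitespace normalization",
                          call. = FALSE)

  sentences <- segment_sentences(norm)
  word_re <- "[[:alnum:]]+(?:['’-][[:alnum:]]+)*"

  n_words <- 0L; n_syll <- 0L; n_poly <- 0L; n_complex <- 0L; n_letters <- 0L
  for (s in sentences) {
    toks <- regmatches(s, gregexpr(word_re, s))[[1L]]
    if (length(toks) == 0L) next
    for (j in seq_along(toks)) {
      tok <- toks[j]
      n_words <- n_words + 1L
      n_letters <- n_letters + nchar(gsub("[^A-Za-z]", "", tok))
      syll <- if (grepl("[A-Za-z]", tok)) {
        count_syllables(tok, exceptions)
      } else 1L
      n_syll <- n_syll + syll
      if (syll >= 3L) {
        n_poly <- n_poly + 1L
        capitalized_midsentence <- j > 1L && grepl("^[A-Z]", tok)
        hyphenated <- grepl("-", tok, fixed = TRUE)
        if (!capitalized_midsentence && !hyphenated) {
          n_complex <- n_complex + 1L
        }
      }
    }
  }
  if (n_words == 0L) stop("text contains no words", call. = FALSE)

  token_stats(n_sentences = length(sentences), n_words = n_words,
              n_syllables = n_syll, n_complex = n_complex,
              n_polysyllables = n_poly, n_letters = n_letters)
}

#' Construct a token_stats object
#'
#' @param n_sentences,n_words,n_syllables,n_complex,n_polysyllables,n_letters
#'   Non-negative integer counts. Invariants checked: complex <= polysyllables,
#'   and when words are present, syllables >= words and letters >= words.
#' @return A `token_stats` list object.
#' @export
token_stats <- function(n_sentences, n_words, n_syllables, n_complex,
                        n_polysyllables, n_letters) {
  x <- list(n_sentences = as.integer(n_sentences),
            n_words = as.integer(n_words),
            n_syllables = as.integer(n_syllables),
            n_complex = as.integer(n_complex),
            n_polysyllables = as.integer(n_polysyllables),
            n_letters = as.integer(n_letters))
  if (any(vapply(x, function(v) is.na(v) || v < 0L, logical(1L)))) {
    stop("token counts must be non-negative", call. = FALSE)
  }
  if (x$n_complex > x$n_polysyllables) {
    stop("complex-word count cannot exceed polysyllable count", call. = FALSE)
  }
  if (x$n_words > 0L && (x$n_syllables < x$n_words || x$n_letters < x$n_words)) {
    stop("every word contributes at least one syllable and one letter",
         call. = FALSE)
  }
  structure(x, class = "token_stats")
}

#' @export
print.token_stats <- function(x, ...) {
  cat("Token statistics:",
      sprintf("S=%d W=%d Syll=%d C=%d P=%d L=%d",
              x$n_sentences, x$n_words, x$n_syllables,
              x$n_complex, x$n_polysyllables, x$n_letters), "\n")
  invisible(x)
}

# abbreviations whose trailing period does not end a sentence
sentence_abbreviations <- c("dr", "mr", "mrs", "ms", "prof", "fig", "e.g",
                            "i.e", "etc", "vs", "approx", "dept")

# split normalized text into sentences; always returns >= 1 sentence
segment_sentences <- function(norm) {
  chars <- strsplit(norm, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  bounds <- integer(0)
  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    if (ch %in% c("!", "?")) {
      # absorb a run of terminal punctuation
      while (i < n && chars[i + 1L] %in% c("!", "?", ".")) i <- i + 1L
      bounds <- c(bounds, i)
    } else if (ch == ".") {
      while (i < n && chars[i + 1L] %in% c("!", "?", ".")) i <- i + 1L
      prev <- if (i > 1L) chars[i - 1L] else ""
      nxt <- next_nonspace(chars, i)
      is_decimal <- grepl("[0-9]", prev) && grepl("[0-9]", nxt)
      followed_lower <- grepl("[a-z]", nxt)
      abbrev <- is_abbreviation(norm, i)
      if (!is_decimal && !followed_lower && !abbrev) bounds <- c(bounds, i)
    }
    i <- i + 1L
  }
  starts <- c(1L, bounds + 1L)
  ends <- c(bounds, n)
  keep <- starts <= ends
  sent <- trimws(substring(norm, starts[keep], ends[keep]))
  sent <- sent[nzchar(gsub("[^[:alnum:]]", "", sent))]
  if (length(sent) == 0L) sent <- norm
  sent
}

next_nonspace <- function(chars, i) {
  j <- i + 1L
  while (j <= length(chars) && chars[j] == " ") j <- j + 1L
  if (j <= length(chars)) chars[j] else ""
}

# does the period at character position i close a listed abbreviation?
is_abbreviation <- function(norm, i) {
  head_txt <- substr(norm, 1L, i - 1L)
  m <- regmatches(head_txt, regexpr("[A-Za-z]+(?:\\.[A-Za-z]+)*$", head_txt))
  if (length(m) == 0L || !nzchar(m)) return(FALSE)
  tolower(m) %in% sentence_abbreviations
}
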