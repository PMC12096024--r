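#' Grade-level readability indices
#'
#' The four classic grade-level formulas, computed from a [token_stats()]
#' object with words W, sentences S, syllables Syll, Fog-complex words C,
#' polysyllables P and letters L:
#'
#' * Flesch-Kincaid grade: `0.39 * W/S + 11.8 * Syll/W - 15.59`
#' * Gunning Fog index:    `0.4 * (W/S + 100 * C/W)`
#' * Coleman-Liau index:   `0.0588 * 100*L/W - 0.296 * 100*S/W - 15.8`
#' * SMOG index:           `1.0430 * sqrt(P * 30/S) + 3.1291`
#'
#' All return a US school-grade estimate; lower means easier to read. SMOG was
#' calibrated on 30-sentence health-education samples, so a warning is issued
#' when S < 30 (the general scaling formula is still applied).
#'
#' @param stats A `token_stats` object (or list with the same fields).
#' @return Numeric grade level.
#' @name readability
NULL

req_counts <- function(stats, fields) {
  for (f in fields) {
    v <- stats[[f]]
    if (is.null(v) || is.na(v) || v <= 0) {
      stop(sprintf("readability formula requires %s > 0", f), call. = FALSE)
    }
  }
}

#' @rdname readability
#' @export
flesch_kincaid_grade <- function(stats) {
  req_counts(stats, c("n_words", "n_sentences"))
  with(stats, 0.39 * n_words / n_sentences +
         11.8 * n_syllables / n_words - 15.59)
}

#' @rdname readability
#' @export
gunning_fog_index <- function(stats) {
  req_counts(stats, c("n_words", "n_sentences"))
  with(stats, 0.4 * (n_words / n_sentences + 100 * n_complex / n_words))
}

#' @rdname readability
#' @export
coleman_liau_index <- function(stats) {
  req_counts(stats, "n_words")
  with(stats, 0.0588 * 100 * n_letters / n_words -
         0.296 * 100 * n_sentences / n_words - 15.8)
}

#' @rdname readability
#' @export
smog_index <- function(stats) {
  req_counts(stats, "n_sentences")
  if (stats$n_sentences < 30) {
    warning("SMOG formula was designed for samples of 30 sentences; S = ",
            stats$n_sentences, call. = FALSE)
  }
  1.0430 * sqrt(stats$n_polysyllables * 30 / stats$n_sentences) + 3.1291
}

#' Authoring efficiency in words per minute
#'
#' @param stats A `token_stats` object for the document.
#' @param authoring_minutes Positive time taken to author the document, in
#'   minutes.
#' @return Words per minute (W / minutes).
#' @examples
#' words_per_minute(token_stats(30, 600, 900, 50, 60, 3000), 2) # 300
#' @export
words_per_minute <- function(stats, authoring_minutes) {
  if (!is.numeric(authoring_minutes) || length(authoring_minutes) != 1L ||
      is.na(authoring_minutes) || authoring_minutes <= 0) {
    stop("`authoring_minutes` must be a positive number", call. = FALSE)
  }
  stats$n_words / authoring_minutes
}

#' Per-document text metrics table
#'
#' Tokenizes each document and returns one row per document with the raw
#' token counts, the four readability grades and words per minute.
#'
#' @param docs Data frame of documents with columns `doc_id`, `text`,
#'   `authoring_minutes` (and any others, carried through is not attempted).
#' @return Data frame with columns `doc_id, W, S, Syll, C, P, L, fk, fog,
#'   cli, smog, wpm`.
#' @export
document_metrics <- function(docs) {
  stopifnot(is.data.frame(docs),
            all(c("doc_id", "text", "authoring_minutes") %in% names(docs)))
  rows <- lapply(seq_len(nrow(docs)), function(i) {
    st <- compute_token_stats(docs$text[i])
    data.frame(doc_id = docs$doc_id[i],
               W = st$n_words, S = st$n_sentences, Syll = st$n_syllables,
               C = st$n_complex, P = st$n_polysyllables, L = st$n_letters,
               fk = flesch_kincaid_grade(st),
               fog = gunning_fog_index(st),
               cli = coleman_liau_index(st),
               smog = suppressWarnings(smog_index(st)),
               wpm = words_per_minute(st, docs$authoring_minutes[i]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
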