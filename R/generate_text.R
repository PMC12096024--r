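#' Generate a synthetic document with an exact token ledger
#'
#' Assembles sentences from a [word_bank()] so that the emitted text has a
#' known, exact set of token statistics (the "ledger"). Words are drawn
#' uniformly among bank entries whose syllable counts keep the per-sentence
#' syllable target feasible; the first word of each sentence is capitalized
#' and each sentence ends with a period. `compute_token_stats()` on the text
#' reproduces the ledger exactly (round-trip property), which makes the
#' generator an oracle for the readability formulas.
#'
#' @param n_sentences Number of sentences S, >= 1.
#' @param words_per_sentence Words per sentence, >= 1.
#' @param syllables_per_word Target mean syllables per word; must lie within
#'   the bank's achievable range `[1, max(bank$syllables)]`.
#' @param bank Word bank, default [word_bank()].
#' @param seed Optional integer seed (uses the current RNG state when
#'   `NULL`).
#' @return List with `text` and `stats` (a `token_stats` ledger).
#' @examples
#' g <- generate_text(10, 10, 1.5, seed = 1)
#' flesch_kincaid_grade(g$stats) # 6.01 by the formula on the ledger
#' @export
generate_text <- function(n_sentences, words_per_sentence,
                          syllables_per_word, bank = word_bank(),
                          seed = NULL) {
  stopifnot(n_sentences >= 1, words_per_sentence >= 1)
  if (!is.null(seed)) set.seed(seed)
  max_syl <- max(bank$syllables)
  if (syllables_per_word < 1 || syllables_per_word > max_syl) {
    stop(sprintf("syllable target %.2f per word unsatisfiable from bank (range 1..%d)",
                 syllables_per_word, max_syl), call. = FALSE)
  }
  w_per <- as.integer(words_per_sentence)
  total_target <- round(n_sentences * w_per * syllables_per_word)
  # distribute the syllable budget over sentences as evenly as possible
  base <- total_target %/% n_sentences
  extra <- total_target %% n_sentences
  sentence_targets <- rep(base, n_sentences) +
    rep(c(1L, 0L), c(extra, n_sentences - extra))
  sentence_targets <- pmin(pmax(sentence_targets, w_per), w_per * max_syl)

  words <- character(0); syls <- integer(0); hyph <- logical(0)
  sentences <- character(n_sentences)
  for (s in seq_len(n_sentences)) {
    t_rem <- sentence_targets[s]
    picked <- character(w_per); psyl <- integer(w_per); phyp <- logical(w_per)
    for (k in seq_len(w_per)) {
      left <- w_per - k          # words still to place after this one
      lo <- max(1L, t_rem - left * max_syl)
      hi <- min(max_syl, t_rem - left)
      ok <- which(bank$syllables >= lo & bank$syllables <= hi)
      if (length(ok) == 0L) {
        stop("syllable mix unsatisfiable from bank", call. = FALSE)
      }
      j <- ok[sample.int(length(ok), 1L)]
      picked[k] <- bank$word[j]; psyl[k] <- bank$syllables[j]
      phyp[k] <- bank$hyphenated[j]
      t_rem <- t_rem - psyl[k]
    }
    first <- picked[1L]
    substr(first, 1L, 1L) <- toupper(substr(first, 1L, 1L))
    sentences[s] <- paste0(paste(c(first, picked[-1L]), collapse = " "), ".")
    words <- c(words, picked); syls <- c(syls, psyl); hyph <- c(hyph, phyp)
  }
  poly <- syls >= 3L
  ledger <- token_stats(
    n_sentences = n_sentences,
    n_words = length(words),
    n_syllables = sum(syls),
    n_complex = sum(poly & !hyph),
    n_polysyllables = sum(poly),
    n_letters = sum(nchar(gsub("[^A-Za-z]", "", words))))
  list(text = paste(sentences, collapse = " "), stats = ledger)
}
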