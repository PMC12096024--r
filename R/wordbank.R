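#' Knee-osteoarthritis word bank for synthetic documents
#'
#' A curated vocabulary of treatment, lifestyle and disease-management words
#' from which synthetic education documents are assembled. Syllable and
#' letter counts are computed with the package's own counter at build time,
#' so a generated document's ledger is exact by construction. The bank covers
#' every syllable count from 1 to 5 and includes hyphenated compounds (which
#' exercise the Fog complex-word exclusion).
#'
#' @param words Optional character vector to build a custom bank from.
#' @return Data frame with columns `word`, `syllables`, `letters`,
#'   `hyphenated`.
#' @export
word_bank <- function(words = NULL) {
  if (is.null(words)) {
    words <- c(
      # 1-2 syllables: everyday self-management vocabulary
      "knee", "joint", "pain", "walk", "rest", "ice", "heat", "strength",
      "swelling", "brace", "stairs", "stretch", "squat", "mild", "flare",
      "doctor", "muscle", "tissue", "stiffness", "balance", "tablet",
      "walking", "cycling", "posture", "footwear", "morning", "daily",
      "gentle", "body", "weight", "sleep", "mood", "stress", "support",
      # 3+ syllables: clinical vocabulary
      "exercise", "therapy", "arthritis", "cartilage", "remedy", "physical",
      "injection", "managing", "recovery", "energy",
      "medication", "inflammation", "activity", "education", "ability",
      "mobility", "community", "paracetamol", "capability",
      "physiotherapy", "osteoarthritis",
      # hyphenated compounds
      "self-care", "low-impact", "long-term", "anti-inflammatory")
  }
  syl <- vapply(words, count_syllables, integer(1L))
  bank <- data.frame(word = words,
                     syllables = syl,
                     letters = nchar(gsub("[^A-Za-z]", "", words)),
                     hyphenated = grepl("-", words, fixed = TRUE),
                     stringsAsFactors = FALSE, row.names = NULL)
  span <- seq_len(max(bank$syllables))
  covered <- span %in% bank$syllables
  if (!all(covered[1:5]) || !all(covered)) {
    stop("word bank must cover every syllable count 1..",
         max(bank$syllables), "; missing: ",
         paste(span[!covered], collapse = ", "), call. = FALSE)
  }
  bank
}

#' Treatment labels for synthetic guideline tables
#'
#' @return Character vector of plausible knee-osteoarthritis treatment names
#'   (synthetic scaffolding; not an authoritative guideline extract).
#' @keywords internal
treatment_labels <- function() {
  c("land-based exercise", "weight management", "topical NSAIDs",
    "oral NSAIDs", "acetaminophen", "intraarticular corticosteroids",
    "hyaluronic acid injection", "glucosamine", "opioids",
    "arthroscopic lavage", "acupuncture", "TENS", "knee bracing",
    "aquatic exercise", "cane or walking aid", "patient education program",
    "heat therapy", "mindfulness training")
}
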