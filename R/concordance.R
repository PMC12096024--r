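#' Guideline-concordance (accuracy) scoring
#'
#' A document's accuracy is scored against a table of treatments, each
#' carrying an endorsement stance from up to five professional societies
#' (ACR, OARSI, ESCEO, AAOS, NICE). Stances are consolidated to a modal
#' category, scored strongly recommended +2 / conditionally recommended +1 /
#' inconclusive 0 / conditionally against -1 / strongly against -2, and
#' weighted by how many societies agree: >=4 societies -> 1, 3 -> 0.75,
#' 2 -> 0.5, 1 -> 0.25. A document's raw accuracy is the sum of
#' score x weight over the distinct treatments it mentions.
#'
#' @name concordance
NULL

guideline_societies <- c("ACR", "OARSI", "ESCEO", "AAOS", "NICE")
stance_levels <- c("SR", "CR", "INC", "CRA", "SRA")

#' Score of a consolidated endorsement category
#'
#' @param category One of `"SR"`, `"CR"`, `"INC"`, `"CRA"`, `"SRA"`.
#' @return Integer in -2..2. `NOT_ADDRESSED` is rejected: a treatment no
#'   society addresses has no consolidated category.
#' @export
category_score <- function(category) {
  scores <- c(SR = 2L, CR = 1L, INC = 0L, CRA = -1L, SRA = -2L)
  if (length(category) != 1L || is.na(category) ||
      !category %in% names(scores)) {
    stop("no recommendation score for category: ", category, call. = FALSE)
  }
  unname(scores[category])
}

#' Consensus weight from the number of agreeing societies
#'
#' @param consensus_n Number of societies sharing the consolidated category,
#'   1 to 5.
#' @return 1 for >= 4 societies, 0.75 for 3, 0.5 for 2, 0.25 for 1.
#' @export
consensus_weight <- function(consensus_n) {
  if (length(consensus_n) != 1L || is.na(consensus_n) ||
      consensus_n != round(consensus_n) ||
      consensus_n < 1 || consensus_n > 5) {
    stop("`consensus_n` must be an integer in 1..5", call. = FALSE)
  }
  if (consensus_n >= 4) 1 else c(0.25, 0.5, 0.75)[consensus_n]
}

#' Consolidate per-society stances into one category
#'
#' The consolidated category is the modal category among societies that
#' address the treatment; `consensus_n` is the size of that modal bloc.
#' When two or more categories tie for the modal size, the result is
#' `INC` with the tied bloc size: disagreement among societies is treated
#' as inconclusive.
#'
#' @param stances Character vector of per-society categories (`"SR"`, `"CR"`,
#'   `"INC"`, `"CRA"`, `"SRA"`, with `"NOT_ADDRESSED"` or `NA` for societies
#'   that do not address the treatment). At most 5 entries.
#' @return List with `category` and `consensus_n`.
#' @export
consolidate_stances <- function(stances) {
  stances <- as.character(stances)
  if (length(stances) > 5L) stop("at most 5 society stances", call. = FALSE)
  stances[stances %in% c("NA", "NOT_ADDRESSED")] <- NA_character_
  addressed <- stances[!is.na(stances)]
  if (length(addressed) == 0L) {
    stop("all societies NOT_ADDRESSED: no consolidated category",
         call. = FALSE)
  }
  bad <- setdiff(addressed, stance_levels)
  if (length(bad)) stop("unknown stance category: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  tab <- table(addressed)
  m <- max(tab)
  modal <- names(tab)[tab == m]
  category <- if (length(modal) == 1L) modal else "INC"
  list(category = category, consensus_n = as.integer(m))
}

#' Weighted score of a consolidated treatment
#'
#' @param treatment List or one-row data frame with fields `category` and
#'   `consensus_n` (as produced by [consolidate_stances()]).
#' @return `category_score * consensus_weight`, in \[-2, 2\].
#' @export
treatment_weighted_score <- function(treatment) {
  if (is.null(treatment$category) || is.null(treatment$consensus_n)) {
    stop("treatment is not consolidated (needs category and consensus_n)",
         call. = FALSE)
  }
  category_score(as.character(treatment$category)) *
    consensus_weight(treatment$consensus_n)
}

#' Read and consolidate a guideline table
#'
#' Reads a CSV with columns `treatment_id`, `name` and one column per
#' society (`ACR, OARSI, ESCEO, AAOS, NICE`; values SR/CR/INC/CRA/SRA/NA),
#' and derives `category`, `consensus_n`, `score`, `weight` and
#' `weighted_score` per treatment. If the file already carries `category` or
#' `consensus_n` columns they are validated against the recomputation.
#'
#' @param path CSV path, or a data frame already in that layout.
#' @return Data frame with the derived columns appended.
#' @export
read_guidelines <- function(path) {
  tab <- if (is.data.frame(path)) path else
    utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(c("treatment_id", guideline_societies), names(tab))
  if (length(missing_cols)) {
    stop("guideline table lacks columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(tab$treatment_id)) {
    stop("duplicate treatment_id in guideline table", call. = FALSE)
  }
  cons <- lapply(seq_len(nrow(tab)), function(i) {
    consolidate_stances(unlist(tab[i, guideline_societies]))
  })
  cat_new <- vapply(cons, `[[`, character(1L), "category")
  n_new <- vapply(cons, `[[`, integer(1L), "consensus_n")
  for (col in c("category", "consensus_n")) {
    if (col %in% names(tab)) {
      given <- tab[[col]]
      want <- if (col == "category") cat_new else n_new
      if (!isTRUE(all(given == want))) {
        stop("precomputed `", col, "` disagrees with recomputation for: ",
             paste(tab$treatment_id[given != want], collapse = ", "),
             call. = FALSE)
      }
    }
  }
  tab$category <- cat_new
  tab$consensus_n <- n_new
  tab$score <- vapply(cat_new, category_score, integer(1L))
  tab$weight <- vapply(n_new, consensus_weight, numeric(1L))
  tab$weighted_score <- tab$score * tab$weight
  tab
}

#' Raw accuracy score of one document's treatment mentions
#'
#' Sums the weighted scores of the distinct treatments a document mentions.
#' In the default `"literal"` mode the mention polarity is ignored, matching
#' the instrument's rule of summing over all treatments mentioned. The
#' `"polarity_aware"` extension flips the sign of the contribution for
#' treatments the document argues against.
#'
#' @param mentions Data frame with columns `treatment_id` and optionally
#'   `polarity` (`"ADVISED"` or `"DISCOURAGED"`); duplicates of one treatment
#'   are collapsed to a single mention.
#' @param table Consolidated guideline table from [read_guidelines()].
#' @param mode `"literal"` (default) or `"polarity_aware"`.
#' @return Numeric raw score.
#' @export
document_accuracy_score <- function(mentions, table,
                                    mode = c("literal", "polarity_aware")) {
  mode <- match.arg(mode)
  if (is.null(table$weighted_score)) {
    stop("`table` must be a consolidated guideline table", call. = FALSE)
  }
  if (nrow(mentions) == 0L) return(0)
  if (is.null(mentions$polarity)) mentions$polarity <- "ADVISED"
  mentions <- mentions[!duplicated(mentions$treatment_id), , drop = FALSE]
  unknown <- setdiff(mentions$treatment_id, table$treatment_id)
  if (length(unknown)) {
    stop("unknown treatment_id: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  idx <- match(mentions$treatment_id, table$treatment_id)
  contrib <- table$weighted_score[idx]
  if (mode == "polarity_aware") {
    contrib <- ifelse(mentions$polarity == "DISCOURAGED", -contrib, contrib)
  }
  sum(contrib)
}

#' Rescale a raw accuracy score onto a bounded reporting scale
#'
#' The raw weighted sum is unbounded above by the sum of all positive
#' weighted scores in the table; this anchor maps to `scale_max` and the
#' result is clipped to `[0, scale_max]` (e.g. a 6-point reporting scale).
#'
#' @param raw Raw accuracy score.
#' @param table Consolidated guideline table.
#' @param scale_max Top of the reporting scale, default 6.
#' @return Scaled score in `[0, scale_max]`.
#' @export
normalize_accuracy <- function(raw, table, scale_max = 6) {
  stopifnot(scale_max > 0)
  max_achievable <- sum(pmax(table$weighted_score, 0))
  if (max_achievable <= 0) {
    stop("guideline table has no positively weighted treatment", call. = FALSE)
  }
  pmin(pmax(raw / max_achievable * scale_max, 0), scale_max)
}

#' Accuracy scores for a set of documents
#'
#' @param mentions Long data frame: `doc_id`, `treatment_id`, optional
#'   `polarity`.
#' @param table Consolidated guideline table.
#' @param mode Passed to [document_accuracy_score()].
#' @param scale_max If non-`NULL`, also report the normalized score.
#' @return Data frame `doc_id`, `accuracy_raw` and (optionally)
#'   `accuracy_scaled`.
#' @export
accuracy_scores <- function(mentions, table, mode = "literal",
                            scale_max = NULL) {
  ids <- unique(mentions$doc_id)
  raw <- vapply(ids, function(d) {
    document_accuracy_score(mentions[mentions$doc_id == d, , drop = FALSE],
                            table, mode)
  }, numeric(1L))
  out <- data.frame(doc_id = ids, accuracy_raw = raw,
                    stringsAsFactors = FALSE)
  if (!is.null(scale_max)) {
    out$accuracy_scaled <- normalize_accuracy(raw, table, scale_max)
  }
  out
}
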