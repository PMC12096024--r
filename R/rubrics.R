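#' Rubric instrument definitions
#'
#' Three 100-point instruments score each document:
#'
#' * personalization: relevance (30), individual_relevance (40),
#'   detail_level (30);
#' * comprehensiveness and safety: five 20-point dimensions each
#'   (medication_treatment, nonmedication_treatment, lifestyle_advice,
#'   psychological_support, disease_management).
#'
#' The qualitative band anchors used by raters (e.g. 17-20 "complete
#' coverage" for comprehensiveness, 16-20 "very safe" for safety) are carried
#' as documentation strings, not enforced logic.
#'
#' @param instrument `"PERSONALIZATION"`, `"COMPREHENSIVENESS"` or
#'   `"SAFETY"`.
#' @return List with `instrument`, `dimensions` (named vector of per-dimension
#'   maxima), `total_max` (100) and `anchors` (free-text band description).
#' @export
instrument_definition <- function(instrument = c("PERSONALIZATION",
                                                 "COMPREHENSIVENESS",
                                                 "SAFETY")) {
  instrument <- match.arg(instrument)
  five20 <- c(medication_treatment = 20, nonmedication_treatment = 20,
              lifestyle_advice = 20, psychological_support = 20,
              disease_management = 20)
  def <- switch(instrument,
    PERSONALIZATION = list(
      dimensions = c(relevance = 30, individual_relevance = 40,
                     detail_level = 30),
      anchors = "each dimension scored 0..max by fit to the patient profile"),
    COMPREHENSIVENESS = list(
      dimensions = five20,
      anchors = "per category: 17-20 complete coverage, 13-16 mostly covered"),
    SAFETY = list(
      dimensions = five20,
      anchors = "per domain: 16-20 very safe, 0 unsafe"))
  stopifnot(sum(def$dimensions) == 100)
  list(instrument = instrument, dimensions = def$dimensions,
       total_max = 100, anchors = def$anchors)
}

#' Construct one rater's score sheet
#'
#' @param doc_id Document identifier.
#' @param instrument Instrument name, see [instrument_definition()].
#' @param rater_id Rater identifier.
#' @param points Named numeric vector, one integer entry per instrument
#'   dimension.
#' @return A `score_sheet` list.
#' @export
score_sheet <- function(doc_id, instrument, rater_id, points) {
  structure(list(doc_id = doc_id, instrument = instrument,
                 rater_id = rater_id, points = points),
            class = "score_sheet")
}

#' Validate a score sheet against its instrument definition
#'
#' @param sheet A [score_sheet()].
#' @param def Instrument definition; defaults to the sheet's instrument.
#' @return List with `valid` (logical) and `problems` (character vector,
#'   empty when valid).
#' @export
validate_sheet <- function(sheet, def = instrument_definition(sheet$instrument)) {
  problems <- character(0)
  dims <- names(def$dimensions)
  missing <- setdiff(dims, names(sheet$points))
  if (length(missing)) {
    problems <- c(problems, paste0("missing dimension: ", missing))
  }
  extra <- setdiff(names(sheet$points), dims)
  if (length(extra)) {
    problems <- c(problems, paste0("unknown dimension: ", extra))
  }
  for (d in intersect(dims, names(sheet$points))) {
    v <- sheet$points[[d]]
    if (is.na(v) || v != round(v)) {
      problems <- c(problems, paste0("non-integer points in ", d))
    } else if (v < 0 || v > def$dimensions[[d]]) {
      problems <- c(problems, sprintf("%s = %s out of range [0, %d]",
                                      d, v, def$dimensions[[d]]))
    }
  }
  list(valid = length(problems) == 0L, problems = problems)
}

#' Total points of a valid score sheet
#'
#' @param sheet A valid [score_sheet()].
#' @return Sum of dimension points, in 0..100.
#' @export
sheet_total <- function(sheet) {
  chk <- validate_sheet(sheet)
  if (!chk$valid) {
    stop("invalid score sheet: ", paste(chk$problems, collapse = "; "),
         call. = FALSE)
  }
  sum(sheet$points)
}

#' Dimensions needing adjudication between two raters
#'
#' A dimension is flagged when the two raters differ by strictly more than
#' `threshold` points ("more than 10" excludes a difference of exactly 10).
#'
#' @param r1,r2 Score sheets for the same document and instrument.
#' @param threshold Disagreement threshold in points, default 10.
#' @return Character vector of flagged dimension names (possibly empty).
#' @export
needs_adjudication <- function(r1, r2, threshold = 10) {
  if (!identical(r1$doc_id, r2$doc_id) ||
      !identical(r1$instrument, r2$instrument)) {
    stop("sheets are for different documents or instruments", call. = FALSE)
  }
  dims <- names(r1$points)
  flagged <- dims[abs(r1$points[dims] - r2$points[dims]) > threshold]
  unname(flagged)
}

#' Adjudicated final score sheet
#'
#' Dimensions where the two primary raters agree (within the threshold) are
#' averaged; half-points are allowed. Flagged dimensions are resolved either
#' by an agreed consensus value (`resolution = "CONSENSUS_VALUE"`, supplied
#' via `consensus`) or by the per-dimension median of the two raters and a
#' third independent rater (`resolution = "THIRD_RATER"`). The result does
#' not depend on rater order.
#'
#' @param r1,r2 Primary rater sheets (same document and instrument).
#' @param r3 Third rater's sheet, required for `THIRD_RATER` resolution when
#'   any dimension is flagged.
#' @param resolution `"THIRD_RATER"` (default) or `"CONSENSUS_VALUE"`.
#' @param consensus Named numeric vector of agreed values for flagged
#'   dimensions (for `CONSENSUS_VALUE`).
#' @param threshold Disagreement threshold, default 10.
#' @return List with `points` (final per-dimension values), `flagged`
#'   (dimension names that required adjudication) and `total`.
#' @export
final_score <- function(r1, r2, r3 = NULL,
                        resolution = c("THIRD_RATER", "CONSENSUS_VALUE"),
                        consensus = NULL, threshold = 10) {
  resolution <- match.arg(resolution)
  flagged <- needs_adjudication(r1, r2, threshold)
  dims <- names(r1$points)
  final <- (r1$points[dims] + r2$points[dims]) / 2
  for (d in flagged) {
    if (resolution == "CONSENSUS_VALUE") {
      if (is.null(consensus) || is.na(consensus[d])) {
        stop("flagged dimension '", d, "' has no consensus value and no ",
             "third rater", call. = FALSE)
      }
      final[d] <- consensus[[d]]
    } else {
      if (is.null(r3)) {
        stop("flagged dimension '", d, "' requires a third rater",
             call. = FALSE)
      }
      final[d] <- stats::median(c(r1$points[[d]], r2$points[[d]],
                                  r3$points[[d]]))
    }
  }
  list(points = final, flagged = flagged, total = sum(final))
}

#' Adjudicate a long-format ratings table
#'
#' Expects columns `doc_id, instrument, rater_id, dimension, points` with two
#' primary raters per (document, instrument) and an optional third rater used
#' only for flagged dimensions. Rater roles are taken from the sorted order
#' of rater ids within each group (third rater = third id); results are
#' order-invariant between the two primary raters.
#'
#' @param ratings Long-format data frame of ratings.
#' @param threshold Disagreement threshold, default 10.
#' @return Data frame `doc_id, instrument, dimension, final_points,
#'   adjudication_flag` plus a `total` attribute-free summary obtainable by
#'   aggregation.
#' @export
adjudicate_ratings <- function(ratings, threshold = 10) {
  need <- c("doc_id", "instrument", "rater_id", "dimension", "points")
  if (!all(need %in% names(ratings))) {
    stop("ratings table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  groups <- unique(ratings[c("doc_id", "instrument")])
  out <- vector("list", nrow(groups))
  for (g in seq_len(nrow(groups))) {
    sub <- ratings[ratings$doc_id == groups$doc_id[g] &
                     ratings$instrument == groups$instrument[g], ]
    raters <- sort(unique(sub$rater_id))
    if (length(raters) < 2L) {
      stop("document ", groups$doc_id[g], " / ", groups$instrument[g],
           " has fewer than 2 raters", call. = FALSE)
    }
    as_sheet <- function(r) {
      s <- sub[sub$rater_id == r, ]
      score_sheet(groups$doc_id[g], groups$instrument[g], r,
                  stats::setNames(s$points, s$dimension))
    }
    r1 <- as_sheet(raters[1L]); r2 <- as_sheet(raters[2L])
    for (s in list(r1, r2)) {
      chk <- validate_sheet(s)
      if (!chk$valid) {
        stop("invalid sheet (doc ", s$doc_id, ", rater ", s$rater_id, "): ",
             paste(chk$problems, collapse = "; "), call. = FALSE)
      }
    }
    r3 <- if (length(raters) >= 3L) as_sheet(raters[3L]) else NULL
    fs <- final_score(r1, r2, r3, threshold = threshold)
    out[[g]] <- data.frame(doc_id = groups$doc_id[g],
                           instrument = groups$instrument[g],
                           dimension = names(fs$points),
                           final_points = unname(fs$points),
                           adjudication_flag = names(fs$points) %in% fs$flagged,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Adjudicated instrument totals per document
#'
#' @param adjudicated Output of [adjudicate_ratings()].
#' @return Data frame `doc_id, instrument, total`.
#' @export
rubric_totals <- function(adjudicated) {
  agg <- stats::aggregate(final_points ~ doc_id + instrument,
                          data = adjudicated, FUN = sum)
  names(agg)[names(agg) == "final_points"] <- "total"
  agg
}
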