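#' Blind and randomize a document set
#'
#' Strips arm labels, shuffles document order with the given seed and
#' assigns opaque evaluation codes. The returned key is a bijection from
#' code back to (doc_id, arm) and is meant to be stored separately from the
#' blinded documents until unblinding.
#'
#' @param documents Data frame with at least `doc_id` and `arm`.
#' @param seed Integer seed for the permutation.
#' @return List with `blinded` (documents, arm removed, in shuffled order,
#'   with a `code` column) and `key` (data frame `code, doc_id, arm`).
#' @export
blind_and_randomize <- function(documents, seed = 1) {
  if (nrow(documents) < 1L) stop("no documents to blind", call. = FALSE)
  if (anyDuplicated(documents$doc_id)) {
    stop("duplicate doc_id: blinding requires unique documents",
         call. = FALSE)
  }
  set.seed(substream_seed(seed, "blinding"))
  perm <- sample.int(nrow(documents))
  blinded <- documents[perm, , drop = FALSE]
  codes <- sprintf("DOC-%04d", seq_len(nrow(blinded)))
  key <- data.frame(code = codes, doc_id = blinded$doc_id,
                    arm = blinded$arm, stringsAsFactors = FALSE)
  blinded$arm <- NULL
  blinded <- cbind(code = codes, blinded, stringsAsFactors = FALSE)
  rownames(blinded) <- NULL
  list(blinded = blinded, key = key)
}

#' Recover arm labels from a blinding key
#'
#' @param blinded Blinded document set (with `code`).
#' @param key Blinding key from [blind_and_randomize()].
#' @return Data frame with `arm` restored.
#' @export
unblind <- function(blinded, key) {
  idx <- match(blinded$code, key$code)
  if (anyNA(idx)) stop("codes missing from the blinding key", call. = FALSE)
  blinded$arm <- key$arm[idx]
  blinded
}

#' Run the full blinded evaluation
#'
#' Validates all inputs up front (no statistics are computed if any file is
#' malformed), computes per-document text metrics and accuracy, adjudicates
#' the rubric ratings, forms per-profile paired samples for each metric and
#' runs the paired arm comparison with normality-driven test selection.
#'
#' @param docs Documents: a data frame or a path to `docs.jsonl`. Must carry
#'   `profile_id` and `arm` (used only after metric computation, at the
#'   pairing stage).
#' @param guidelines Guideline table (data frame or CSV path).
#' @param mentions Treatment mentions (data frame or CSV path).
#' @param ratings Rubric ratings, long format (data frame or CSV path).
#' @param policy Test-selection policy, see [compare_paired()].
#' @param alpha Significance level, default 0.05.
#' @param scale_max Reporting scale for accuracy, default 6.
#' @param threshold Adjudication threshold, default 10.
#' @return An `edu_report`: list with `table` (one row per metric),
#'   `comparisons` (named list of `paired_comparison` objects),
#'   `per_document` metrics and `provenance`.
#' @export
run_evaluation <- function(docs, guidelines, mentions, ratings,
                           policy = "AUTO", alpha = 0.05, scale_max = 6,
                           threshold = 10) {
  documents <- if (is.character(docs)) read_docs_jsonl(docs) else
    validate_documents(docs)
  if (!all(c("profile_id", "arm") %in% names(documents))) {
    stop("documents need `profile_id` and `arm` for the paired analysis",
         call. = FALSE)
  }
  gtab <- read_guidelines(guidelines)
  men <- if (is.character(mentions))
    utils::read.csv(mentions, stringsAsFactors = FALSE) else mentions
  rat <- if (is.character(ratings))
    utils::read.csv(ratings, stringsAsFactors = FALSE) else ratings
  validate_ratings(rat)
  unknown <- setdiff(men$treatment_id, gtab$treatment_id)
  if (length(unknown)) {
    stop("mentions reference unknown treatment_id: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  extra_docs <- setdiff(unique(c(men$doc_id, rat$doc_id)), documents$doc_id)
  if (length(extra_docs)) {
    stop("mentions/ratings reference unknown doc_id: ",
         paste(extra_docs, collapse = ", "), call. = FALSE)
  }

  message(sprintf("validated %d documents, %d treatments, %d mention rows, %d rating rows",
                  nrow(documents), nrow(gtab), nrow(men), nrow(rat)))

  metrics <- document_metrics(documents)
  acc <- accuracy_scores(men, gtab, scale_max = scale_max)
  metrics <- merge(metrics, acc, by = "doc_id", all.x = TRUE)
  metrics$accuracy_raw[is.na(metrics$accuracy_raw)] <- 0
  metrics$accuracy_scaled[is.na(metrics$accuracy_scaled)] <-
    normalize_accuracy(0, gtab, scale_max)

  adjudicated <- adjudicate_ratings(rat, threshold = threshold)
  totals <- rubric_totals(adjudicated)
  for (inst in unique(totals$instrument)) {
    col <- tolower(inst)
    sub <- totals[totals$instrument == inst, c("doc_id", "total")]
    names(sub)[2L] <- col
    metrics <- merge(metrics, sub, by = "doc_id", all.x = TRUE)
  }

  info <- documents[c("doc_id", "profile_id", "arm")]
  metrics <- merge(metrics, info, by = "doc_id")

  metric_cols <- c(wpm = "wpm", fk = "fk", fog = "fog", cli = "cli",
                   smog = "smog", accuracy = "accuracy_scaled",
                   personalization = "personalization",
                   comprehensiveness = "comprehensiveness",
                   safety = "safety")
  metric_cols <- metric_cols[metric_cols %in% names(metrics)]

  comparisons <- list()
  rows <- list()
  for (m in names(metric_cols)) {
    col <- metric_cols[[m]]
    ai <- metrics[metrics$arm == "AI", c("profile_id", col)]
    cl <- metrics[metrics$arm == "CLIN", c("profile_id", col)]
    merged <- merge(ai, cl, by = "profile_id", suffixes = c("_ai", "_clin"))
    ps <- paired_sample(m, merged$profile_id,
                        merged[[paste0(col, "_ai")]],
                        merged[[paste0(col, "_clin")]])
    res <- compare_paired(ps, policy = policy, alpha = alpha)
    comparisons[[m]] <- res
    rows[[m]] <- data.frame(
      metric = m, test = res$test, n = res$n,
      ai_mean = res$summary_ai$mean, ai_sd = res$summary_ai$sd,
      ai_median = res$summary_ai$median,
      ai_q1 = res$summary_ai$q1, ai_q3 = res$summary_ai$q3,
      clin_mean = res$summary_clin$mean, clin_sd = res$summary_clin$sd,
      clin_median = res$summary_clin$median,
      clin_q1 = res$summary_clin$q1, clin_q3 = res$summary_clin$q3,
      statistic = res$statistic, p_value = res$p_value,
      significant = res$significant, stringsAsFactors = FALSE)
    message(sprintf("metric %-17s %-8s P = %s", m, res$test,
                    format_p(res$p_value)))
  }
  table <- do.call(rbind, rows)
  rownames(table) <- NULL

  structure(list(table = table, comparisons = comparisons,
                 per_document = metrics, adjudicated = adjudicated,
                 provenance = list(
                   n_documents = nrow(documents),
                   n_profiles = length(unique(documents$profile_id)),
                   policy = policy, alpha = alpha,
                   scale_max = scale_max, threshold = threshold)),
            class = "edu_report")
}

#' @export
print.edu_report <- function(x, ...) {
  cat(sprintf("Blinded paired evaluation: %d documents, %d profiles\n\n",
              x$provenance$n_documents, x$provenance$n_profiles))
  for (i in seq_len(nrow(x$table))) {
    r <- x$table[i, ]
    desc <- if (r$test == "PAIRED_T") {
      sprintf("AI %.2f (SD %.2f) vs clinician %.2f (SD %.2f)",
              r$ai_mean, r$ai_sd, r$clin_mean, r$clin_sd)
    } else {
      sprintf("AI %.2f (IQR %.2f-%.2f) vs clinician %.2f (IQR %.2f-%.2f)",
              r$ai_median, r$ai_q1, r$ai_q3,
              r$clin_median, r$clin_q1, r$clin_q3)
    }
    cat(sprintf("%-17s %-9s %s, P = %s%s\n", r$metric, r$test, desc,
                format_p(r$p_value), if (r$significant) " *" else ""))
  }
  invisible(x)
}

#' @export
summary.edu_report <- function(object, ...) {
  print(object)
  invisible(object$table)
}

#' Write an evaluation report to CSV
#'
#' @param report An `edu_report`.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_report <- function(report, path) {
  utils::write.csv(report$table, path, row.names = FALSE)
  invisible(path)
}
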