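#' Read documents from JSON-lines
#'
#' One JSON object per line with fields `doc_id`, `text`,
#' `authoring_minutes`, and optionally `arm` and `profile_id`.
#'
#' @param path Path to a `.jsonl` file.
#' @return Data frame of documents.
#' @export
read_docs_jsonl <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("no documents in ", path, call. = FALSE)
  rows <- lapply(lines, function(l) {
    obj <- jsonlite::fromJSON(l)
    as.data.frame(obj, stringsAsFactors = FALSE)
  })
  docs <- do.call(rbind, rows)
  validate_documents(docs)
  docs
}

#' Write documents as JSON-lines
#'
#' @param docs Data frame of documents.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_docs_jsonl <- function(docs, path) {
  lines <- vapply(seq_len(nrow(docs)), function(i) {
    jsonlite::toJSON(as.list(docs[i, , drop = FALSE]), auto_unbox = TRUE,
                     digits = NA)
  }, character(1L))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

# schema checks shared by readers and the pipeline (fail fast, itemized)
validate_documents <- function(docs) {
  need <- c("doc_id", "text", "authoring_minutes")
  missing_cols <- setdiff(need, names(docs))
  if (length(missing_cols)) {
    stop("documents lack fields: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(docs$doc_id)) {
    stop("duplicate doc_id: ",
         paste(unique(docs$doc_id[duplicated(docs$doc_id)]), collapse = ", "),
         call. = FALSE)
  }
  blank <- !nzchar(trimws(docs$text))
  if (any(blank)) {
    stop("empty text for doc_id: ",
         paste(docs$doc_id[blank], collapse = ", "), call. = FALSE)
  }
  bad_min <- !is.finite(docs$authoring_minutes) | docs$authoring_minutes <= 0
  if (any(bad_min)) {
    stop("non-positive authoring_minutes for doc_id: ",
         paste(docs$doc_id[bad_min], collapse = ", "), call. = FALSE)
  }
  invisible(docs)
}

validate_ratings <- function(ratings) {
  need <- c("doc_id", "instrument", "rater_id", "dimension", "points")
  missing_cols <- setdiff(need, names(ratings))
  if (length(missing_cols)) {
    stop("ratings lack columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  bad <- which(!is.finite(ratings$points) |
                 ratings$points != round(ratings$points) |
                 ratings$points < 0)
  if (length(bad)) {
    stop("invalid points in ratings rows: ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  }
  invisible(ratings)
}
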