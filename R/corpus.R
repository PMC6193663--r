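#' Read a forum-post corpus from JSONL
#'
#' Reads one post per line from a JSON-lines file. Each line must be a JSON
#' object with fields `post_id`, `patient_id`, `thread_id`, `forum`,
#' `timestamp` (ISO-8601) and `text`. Lines that fail the schema (missing
#' fields, unparseable timestamp, duplicate `post_id`) are not silently
#' dropped: they are collected into a rejection report available via
#' [corpus_rejects()].
#'
#' @param path Path to a JSONL file.
#' @return A tibble with columns `post_id`, `patient_id`, `thread_id`,
#'   `forum`, `timestamp` (POSIXct, UTC) and `text`, one row per accepted
#'   post, with the rejection report attached as the `"rejects"` attribute.
#' @seealso [write_posts()], [collocate_by_patient()]
#' @export
read_posts <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("posts file not found: ", path), class = "osgminer_io")
  }
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    warn("empty posts file; returning an empty corpus")
    out <- empty_corpus()
    attr(out, "rejects") <- empty_rejects()
    return(out)
  }
  required <- c("post_id", "patient_id", "thread_id", "forum", "timestamp", "text")
  rows <- vector("list", length(lines))
  rejects <- list()
  seen <- new.env(parent = emptyenv())
  for (i in seq_along(lines)) {
    rec <- tryCatch(jsonlite::fromJSON(lines[[i]]), error = function(e) NULL)
    if (is.null(rec) || !is.list(rec)) {
      rejects[[length(rejects) + 1L]] <- tibble(line = i, reason = "malformed JSON")
      next
    }
    missing <- setdiff(required, names(rec))
    if (length(missing) > 0L) {
      rejects[[length(rejects) + 1L]] <-
        tibble(line = i, reason = paste0("missing field(s): ",
                                         paste(missing, collapse = ", ")))
      next
    }
    ts <- parse_timestamp(as.character(rec$timestamp))
    if (is.na(ts)) {
      rejects[[length(rejects) + 1L]] <-
        tibble(line = i, reason = paste0("malformed timestamp: ", rec$timestamp))
      next
    }
    id <- as.character(rec$post_id)
    if (!is.null(seen[[id]])) {
      rejects[[length(rejects) + 1L]] <-
        tibble(line = i, reason = paste0("duplicate post_id: ", id))
      next
    }
    seen[[id]] <- TRUE
    rows[[i]] <- tibble(
      post_id = id,
      patient_id = as.character(rec$patient_id),
      thread_id = as.character(rec$thread_id),
      forum = as.character(rec$forum),
      timestamp = ts,
      text = if (is.null(rec$text) || is.na(rec$text)) "" else as.character(rec$text)
    )
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) out <- empty_corpus()
  attr(out, "rejects") <- if (length(rejects)) dplyr::bind_rows(rejects) else empty_rejects()
  out
}

parse_timestamp <- function(x) {
  x <- sub("Z$", "", x)
  x <- sub("T", " ", x, fixed = TRUE)
  fmts <- c("%Y-%m-%d %H:%M:%S", "%Y-%m-%d %H:%M", "%Y-%m-%d")
  for (f in fmts) {
    ts <- as.POSIXct(x, format = f, tz = "UTC")
    if (!is.na(ts)) return(ts)
  }
  as.POSIXct(NA)
}

empty_corpus <- function() {
  tibble(post_id = character(), patient_id = character(),
         thread_id = character(), forum = character(),
         timestamp = as.POSIXct(character(), tz = "UTC"), text = character())
}

empty_rejects <- function() tibble(line = integer(), reason = character())

#' Rejection report from corpus ingestion
#'
#' @param posts A corpus tibble returned by [read_posts()].
#' @return A tibble with columns `line` and `reason`.
#' @export
corpus_rejects <- function(posts) {
  attr(posts, "rejects") %||% empty_rejects()
}

#' Write a forum-post corpus to JSONL
#'
#' Inverse of [read_posts()]: `read_posts(write_posts(x, f))` reproduces `x`
#' field for field (timestamps are serialized at second precision, UTC).
#'
#' @param posts A corpus tibble (see [read_posts()] for the schema).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_posts <- function(posts, path) {
  validate_corpus(posts)
  con <- tryCatch(file(path, open = "wb"), error = function(e) {
    abort(paste0("cannot write posts file: ", path), class = "osgminer_io")
  })
  on.exit(close(con))
  if (nrow(posts) > 0L) {
    df <- posts
    df$timestamp <- format(df$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
    lines <- vapply(seq_len(nrow(df)), function(i) {
      jsonlite::toJSON(as.list(df[i, c("post_id", "patient_id", "thread_id",
                                       "forum", "timestamp", "text")]),
                       auto_unbox = TRUE)
    }, character(1))
    writeLines(lines, con, useBytes = TRUE)
  }
  invisible(path)
}

validate_corpus <- function(posts) {
  required <- c("post_id", "patient_id", "thread_id", "forum", "timestamp", "text")
  missing <- setdiff(required, names(posts))
  if (length(missing) > 0L) {
    abort(paste0("corpus is missing column(s): ", paste(missing, collapse = ", ")),
          class = "osgminer_bad_corpus")
  }
  if (anyDuplicated(posts$post_id)) {
    abort("corpus has duplicate post_id values", class = "osgminer_bad_corpus")
  }
  if (any(is.na(posts$timestamp))) {
    abort("corpus has missing timestamps", class = "osgminer_bad_corpus")
  }
  invisible(posts)
}

#' Collocate posts into chronological per-patient threads
#'
#' Gathers all posts by each patient (scattered across discussion threads)
#' into a single chronological stream, ordered by timestamp with ties broken
#' by lexicographic `post_id` so the result is fully deterministic.
#'
#' @param posts A corpus tibble.
#' @return The same rows, ordered by `patient_id`, `timestamp`, `post_id`,
#'   with an additional `post_seq` column giving each post's 1-based position
#'   within its patient's stream.
#' @export
collocate_by_patient <- function(posts) {
  validate_corpus(posts)
  posts |>
    dplyr::arrange(.data$patient_id, .data$timestamp, .data$post_id) |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::mutate(post_seq = dplyr::row_number()) |>
    dplyr::ungroup()
}
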