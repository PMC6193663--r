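# Text normalization: URLs are stripped before anything else, text is
# lower-cased, sentences are split on terminal punctuation with a small
# abbreviation guard, and tokens keep intra-word apostrophes and hyphens.
# Multi-word lexicon entries are handled downstream by contiguous-run
# matching, so the tokenizer itself stays minimal.

TOKEN_RE <- "[a-z0-9]+(?:['’-][a-z0-9]+)*"

strip_urls <- function(text) {
  gsub("(?i)\\b(?:https?://|www\\.)[^[:space:]]+", " ", text, perl = TRUE)
}

ABBREV_RE <- "(?i)\\b(dr|mr|mrs|ms|prof|st|vs|etc|e\\.g|i\\.e)\\."

split_sentences_one <- function(text) {
  if (is.na(text) || !nzchar(trimws(text))) return(character())
  protected <- gsub(ABBREV_RE, "\\1\x01", text, perl = TRUE)
  parts <- strsplit(protected, "(?<=[.!?])\\s+", perl = TRUE)[[1]]
  parts <- gsub("\x01", ".", parts, fixed = TRUE)
  parts[nzchar(trimws(parts))]
}

sentence_tokens <- function(sentences) {
  stringr::str_extract_all(tolower(sentences), TOKEN_RE)
}

#' Tokenize free text into lower-cased word tokens and sentences
#'
#' URLs are removed first, then the text is segmented into sentences (split
#' on terminal `.`/`!`/`?` with common abbreviations protected), lower-cased
#' and tokenized. Tokens keep internal apostrophes and hyphens; everything
#' else is a separator. The result is deterministic and idempotent on
#' already-normalized text.
#'
#' @param text A single character string.
#' @return A list with `tokens` (character vector) and `sentences`, a tibble
#'   of 1-based token index ranges (`start`, `end`) that partition the token
#'   sequence; sentences with no alphanumeric tokens are dropped.
#' @examples
#' tokenize("I am Happy.")$tokens
#' @export
tokenize <- function(text) {
  stopifnot(length(text) == 1L)
  sents <- split_sentences_one(strip_urls(text))
  toks <- sentence_tokens(sents)
  keep <- lengths(toks) > 0L
  toks <- toks[keep]
  n <- lengths(toks)
  ends <- cumsum(n)
  starts <- ends - n + 1L
  list(tokens = unlist(toks, use.names = FALSE) %||% character(),
       sentences = tibble(start = as.integer(starts), end = as.integer(ends)))
}

# Batched tokenization over a corpus: one row per sentence, with the poster's
# id, a question-mark flag (used by the advice classifier) and the sentence's
# token vector as a list column.
tokenize_posts <- function(posts) {
  validate_corpus(posts)
  if (nrow(posts) == 0L) {
    return(tibble(post_id = character(), sent_idx = integer(),
                  ends_q = logical(), tokens = list()))
  }
  clean <- strip_urls(posts$text)
  sent_lists <- lapply(clean, split_sentences_one)
  n_sent <- lengths(sent_lists)
  flat <- unlist(sent_lists, use.names = FALSE) %||% character()
  tok_lists <- sentence_tokens(flat)
  out <- tibble(
    post_id = rep(posts$post_id, n_sent),
    sent_idx = unlist(lapply(n_sent, seq_len), use.names = FALSE) %||% integer(),
    ends_q = grepl("\\?\\s*$", flat),
    tokens = tok_lists
  )
  out[lengths(out$tokens) > 0L | out$ends_q, , drop = FALSE]
}

# Post-level token streams (sentence tokens concatenated in order).
post_token_table <- function(sent_table) {
  n <- lengths(sent_table$tokens)
  tibble(
    post_id = rep(sent_table$post_id, n),
    token = unlist(sent_table$tokens, use.names = FALSE) %||% character()
  ) |>
    dplyr::group_by(.data$post_id) |>
    dplyr::mutate(pos = dplyr::row_number()) |>
    dplyr::ungroup()
}
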