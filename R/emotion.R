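# Per-post 16-dimensional emotion scoring. The intensity of emotion e in a
# post is the weighted count of un-negated lexicon matches of category e
# divided by the post's total word-token count N. Each match starts with
# weight 1; every booster fully inside the 3-token window before the match
# multiplies it by the booster multiplier, every dampener by the dampener
# multiplier, and any negator in that window zeroes it. Multi-word lexicon
# phrases are matched longest-first and count as one match regardless of
# length; the denominator is the raw token count, so without modifiers each
# dimension is bounded by 1.

MODIFIER_WINDOW <- 3L

#' Compute the 16-dimensional emotion vector of a post
#'
#' @param tokens A character vector of post tokens, or a [tokenize()]
#'   result; an empty post gives the zero vector.
#' @param lexicon An [emotion_lexicon()].
#' @param modifiers A [modifier_lexicon()].
#' @param window Number of tokens before a match scanned for modifiers.
#' @param compiled Optional precompiled lexicon structure (internal use).
#' @return A named non-negative numeric vector over the 16 categories of
#'   [emotion_categories()]; zero exactly when the post has no un-negated
#'   lexicon match.
#' @examples
#' compute_emotion_vector(c("i", "am", "happy"))
#' @export
compute_emotion_vector <- function(tokens, lexicon = emotion_lexicon(),
                                   modifiers = modifier_lexicon(),
                                   window = MODIFIER_WINDOW,
                                   compiled = NULL) {
  if (is.list(tokens) && !is.null(tokens$tokens)) tokens <- tokens$tokens
  stopifnot(is.character(tokens))
  cats <- emotion_categories()
  out <- setNames(numeric(length(cats)), cats)
  n <- length(tokens)
  if (n == 0L) return(out)

  matches <- emotion_matches(tokens, lexicon, compiled = compiled)
  if (nrow(matches) == 0L) return(out)
  w <- match_weights(tokens, matches$start, modifiers, window)
  contrib <- tapply(w, matches$category, sum)
  out[names(contrib)] <- as.numeric(contrib) / n
  out
}

# Term structures are precompiled once per lexicon: single-token terms are
# matched with a set lookup, multi-word terms by contiguous-run search.
compile_emotion_lexicon <- function(lexicon) {
  terms <- unique(lexicon$term)
  tt <- split_terms(terms)
  len <- lengths(tt)
  list(uni = terms[len == 1L],
       multi = terms[len > 1L],
       multi_tokens = tt[len > 1L],
       cat_map = split(lexicon$category, lexicon$term),
       first_words = unique(vapply(tt, `[`, character(1), 1)))
}

# Longest-first consuming match of lexicon terms over one token vector.
# A term listed under k categories yields k rows for its span.
emotion_matches <- function(tokens, lexicon, compiled = NULL) {
  cl <- compiled %||% compile_emotion_lexicon(lexicon)
  uni_idx <- which(tokens %in% cl$uni)
  uni_runs <- data.frame(start = uni_idx, end = uni_idx,
                         label = tokens[uni_idx], stringsAsFactors = FALSE)
  multi_runs <- find_term_runs(tokens, cl$multi_tokens, cl$multi)
  runs <- greedy_longest_first(rbind(multi_runs, uni_runs))
  if (nrow(runs) == 0L) {
    return(data.frame(start = integer(), end = integer(),
                      category = character()))
  }
  expanded <- lapply(seq_len(nrow(runs)), function(i) {
    data.frame(start = runs$start[i], end = runs$end[i],
               category = cl$cat_map[[runs$label[i]]], stringsAsFactors = FALSE)
  })
  do.call(rbind, expanded)
}

# Weight for each match start position given the modifier window rule.
match_weights <- function(tokens, starts, modifiers, window = MODIFIER_WINDOW) {
  boost1 <- modifiers$boosters[!grepl("\\s", modifiers$boosters)]
  boost2 <- split_terms(modifiers$boosters[grepl("\\s", modifiers$boosters)])
  damp1 <- modifiers$dampeners[!grepl("\\s", modifiers$dampeners)]
  damp2 <- split_terms(modifiers$dampeners[grepl("\\s", modifiers$dampeners)])
  neg1 <- modifiers$negators

  bigram_end_hits <- function(pairs) {
    # logical over positions: a two-token modifier ends here
    hit <- logical(length(tokens))
    for (bt in pairs) {
      if (length(bt) != 2L) {
        abort("modifier phrases longer than two tokens are not supported")
      }
      idx <- which(tokens == bt[2])
      idx <- idx[idx > 1L & tokens[idx - 1L] == bt[1]]
      hit[idx] <- TRUE
    }
    hit
  }
  b1 <- tokens %in% boost1
  d1 <- tokens %in% damp1
  ng <- tokens %in% neg1
  b2 <- bigram_end_hits(boost2)
  d2 <- bigram_end_hits(damp2)

  vapply(starts, function(p) {
    lo <- max(1L, p - window)
    if (lo > p - 1L) return(1)
    win <- lo:(p - 1L)
    if (any(ng[win])) return(0)
    # a two-token modifier must lie fully inside the window
    win2 <- win[win - 1L >= lo]
    nb <- sum(b1[win]) + sum(b2[win2])
    nd <- sum(d1[win]) + sum(d2[win2])
    modifiers$booster_multiplier^nb * modifiers$dampener_multiplier^nd
  }, numeric(1))
}

#' Score emotions for every post in a corpus
#'
#' Vectorized application of [compute_emotion_vector()] over a corpus.
#'
#' @param posts A corpus tibble.
#' @param lexicon An [emotion_lexicon()].
#' @param modifiers A [modifier_lexicon()].
#' @param tokens Optionally, a precomputed sentence table (internal use).
#' @return A tibble with `post_id`, `n_tokens`, one column per emotion
#'   category, and `positive`/`negative` composites (the mean over the 8
#'   positive and 8 negative dimensions respectively).
#' @export
score_emotions <- function(posts, lexicon = emotion_lexicon(),
                           modifiers = modifier_lexicon(), tokens = NULL) {
  validate_corpus(posts)
  sent <- tokens %||% tokenize_posts(posts)
  token_tab <- post_token_table(sent)
  toks <- split(token_tab$token, token_tab$post_id)
  cl <- compile_emotion_lexicon(lexicon)
  cats <- emotion_categories()
  base <- tibble(post_id = posts$post_id)
  vecs <- matrix(0, nrow = nrow(posts), ncol = length(cats),
                 dimnames = list(NULL, cats))
  n_tokens <- integer(nrow(posts))
  for (i in seq_len(nrow(posts))) {
    tk <- toks[[posts$post_id[i]]] %||% character()
    n_tokens[i] <- length(tk)
    # only posts containing some lexicon first word can score non-zero
    if (length(tk) == 0L || !any(tk %in% cl$first_words)) next
    vecs[i, ] <- compute_emotion_vector(tk, lexicon, modifiers, compiled = cl)
  }
  out <- dplyr::bind_cols(base, tibble(n_tokens = n_tokens), as_tibble(vecs))
  out$positive <- rowMeans(out[, POSITIVE_EMOTIONS])
  out$negative <- rowMeans(out[, NEGATIVE_EMOTIONS])
  out
}

#' Aggregate per-post emotion vectors
#'
#' Arithmetic mean of post emotion vectors per group, with positive and
#' negative composites (mean over the 8 positive / 8 negative dimensions).
#' Groups with no posts are simply absent from the result rather than
#' reported as zero.
#'
#' @param scores A tibble from [score_emotions()], optionally joined with
#'   grouping columns.
#' @param by Character vector of grouping column names present in `scores`
#'   (empty for a single overall mean).
#' @return A tibble with the grouping columns, `n_posts`, the 16 category
#'   means, and `positive`/`negative` composite means.
#' @export
aggregate_emotions <- function(scores, by = character()) {
  cats <- emotion_categories()
  missing <- setdiff(by, names(scores))
  if (length(missing) > 0L) {
    abort(paste0("grouping column(s) not in scores: ",
                 paste(missing, collapse = ", ")))
  }
  scores |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise(n_posts = dplyr::n(),
                     dplyr::across(dplyr::all_of(cats), mean),
                     .groups = "drop") |>
    dplyr::mutate(
      positive = rowMeans(dplyr::pick(dplyr::all_of(POSITIVE_EMOTIONS))),
      negative = rowMeans(dplyr::pick(dplyr::all_of(NEGATIVE_EMOTIONS))))
}
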