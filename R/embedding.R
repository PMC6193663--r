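#' Train a skip-gram word embedding
#'
#' Trains dense word vectors on tokenized sentences with the skip-gram
#' negative-sampling objective (single-threaded, with an internal RNG, so a
#' fixed seed gives bitwise-identical vectors across runs on the same
#' machine). Frequent bigrams can optionally be joined into `a_b` phrase
#' tokens before training so multi-word lexicon entries can exist in the
#' vocabulary.
#'
#' @param sentences A list of character token vectors, or a character vector
#'   of raw sentences (tokenized with the package tokenizer).
#' @param dim Embedding dimension (>= 2).
#' @param window Maximum context window either side (the effective window is
#'   sampled uniformly in 1..window per position, as is standard).
#' @param negative Number of negative samples per positive pair.
#' @param epochs Training passes over the corpus.
#' @param min_count Minimum token frequency for vocabulary inclusion.
#' @param alpha,min_alpha Initial and floor learning rates (linear decay).
#' @param sample Sub-sampling threshold for frequent words (0 disables).
#' @param phrase_threshold When non-`NULL`, frequent bigrams with
#'   `(count(ab) - min_count) * V / (count(a) * count(b))` above this value
#'   are joined into single `a_b` tokens before training.
#' @param seed Integer seed for the internal RNG.
#' @return An object of class `osg_embedding`: a list with `terms`,
#'   `vectors` (terms x dim matrix with rownames), `dim` and `params`.
#' @export
train_embedding <- function(sentences, dim = 100L, window = 5L,
                            negative = 5L, epochs = 5L, min_count = 2L,
                            alpha = 0.025, min_alpha = 1e-4, sample = 0,
                            phrase_threshold = NULL, seed = 1L) {
  stopifnot(dim >= 2L, window >= 1L, negative >= 1L, epochs >= 1L)
  if (is.character(sentences)) {
    sentences <- lapply(sentences, function(s) tokenize(s)$tokens)
  }
  sentences <- lapply(sentences, tolower)
  sentences <- sentences[lengths(sentences) > 0L]
  if (length(sentences) == 0L) {
    abort("cannot train an embedding on an empty corpus",
          class = "osgminer_empty_corpus")
  }
  if (!is.null(phrase_threshold)) {
    sentences <- join_phrases(sentences, min_count = min_count,
                              threshold = phrase_threshold)
  }
  all_tokens <- unlist(sentences, use.names = FALSE)
  counts <- table(all_tokens)
  counts <- counts[counts >= min_count]
  if (length(counts) == 0L) {
    abort("no token reaches min_count; lower min_count or supply more text")
  }
  # deterministic vocabulary order: frequency desc, then term
  ord <- order(-as.integer(counts), names(counts))
  vocab <- names(counts)[ord]
  freq <- as.numeric(counts)[ord]
  idx <- setNames(seq_along(vocab) - 1L, vocab)

  coded <- lapply(sentences, function(s) {
    v <- idx[s]
    as.integer(v[!is.na(v)])
  })
  coded <- coded[lengths(coded) > 0L]

  mat <- sgns_train(coded, length(vocab), freq, as.integer(dim),
                    as.integer(window), as.integer(negative),
                    as.integer(epochs), alpha, min_alpha, sample,
                    as.numeric(seed))
  rownames(mat) <- vocab
  structure(list(terms = vocab, vectors = mat, dim = as.integer(dim),
                 params = list(window = window, negative = negative,
                               epochs = epochs, min_count = min_count,
                               alpha = alpha, sample = sample,
                               phrase_threshold = phrase_threshold,
                               seed = seed)),
            class = "osg_embedding")
}

# Greedy left-to-right joining of high-scoring bigrams with "_".
join_phrases <- function(sentences, min_count = 2L, threshold = 10) {
  all_tokens <- unlist(sentences, use.names = FALSE)
  uni <- table(all_tokens)
  n_vocab <- length(uni)
  bi <- table(unlist(lapply(sentences, function(s) {
    if (length(s) < 2L) return(character())
    paste(s[-length(s)], s[-1L], sep = "\t")
  }), use.names = FALSE))
  if (length(bi) == 0L) return(sentences)
  parts <- stringr::str_split_fixed(names(bi), "\t", 2)
  score <- (as.numeric(bi) - min_count) * n_vocab /
    (as.numeric(uni[parts[, 1]]) * as.numeric(uni[parts[, 2]]))
  good <- names(bi)[score >= threshold & as.numeric(bi) >= min_count]
  if (length(good) == 0L) return(sentences)
  good_set <- gsub("\t", " ", good, fixed = TRUE)
  lapply(sentences, function(s) {
    if (length(s) < 2L) return(s)
    out <- character(0)
    i <- 1L
    while (i <= length(s)) {
      if (i < length(s) && paste(s[i], s[i + 1L]) %in% good_set) {
        out <- c(out, paste(s[i], s[i + 1L], sep = "_"))
        i <- i + 2L
      } else {
        out <- c(out, s[i])
        i <- i + 1L
      }
    }
    out
  })
}

#' @export
print.osg_embedding <- function(x, ...) {
  cat("<osg_embedding> ", length(x$terms), " terms, ", x$dim,
      " dimensions\n", sep = "")
  invisible(x)
}

embedding_vector <- function(embedding, term) {
  if (!term %in% embedding$terms) return(NULL)
  embedding$vectors[term, ]
}

#' Nearest terms by cosine similarity
#'
#' @param embedding An `osg_embedding` (or word2vec file read with
#'   [read_word2vec()]).
#' @param term A vocabulary term (multi-word phrases use `_` joining).
#' @param k Number of neighbours.
#' @return A tibble `term`, `similarity`, ranked by decreasing similarity
#'   (ties broken alphabetically for determinism), excluding `term` itself.
#' @export
nearest_terms <- function(embedding, term, k = 10L) {
  v <- embedding_vector(embedding, term)
  if (is.null(v)) {
    abort(paste0("term not in embedding vocabulary: ", term),
          class = "osgminer_oov")
  }
  m <- embedding$vectors
  norms <- sqrt(rowSums(m^2))
  norms[norms == 0] <- NA_real_
  sims <- unname(as.numeric(m %*% v) / (norms * sqrt(sum(v^2))))
  df <- tibble(term = embedding$terms, similarity = sims) |>
    dplyr::filter(.data$term != !!term, !is.na(.data$similarity)) |>
    dplyr::arrange(dplyr::desc(.data$similarity), .data$term)
  head(df, k)
}

#' Expand an emotion lexicon by embedding nearest neighbours
#'
#' For each lexicon term present in the embedding vocabulary, finds the `k`
#' most cosine-similar terms. Candidates are deliberately NOT auto-accepted:
#' distributional neighbours often carry the opposite emotional sense (a
#' neighbour of a sadness word can be a joy word), so acceptance is a
#' separate review step ([apply_review()]).
#'
#' @param lexicon An [emotion_lexicon()].
#' @param embedding An `osg_embedding`.
#' @param k Number of candidates per seed term (default 25).
#' @return A candidate report tibble: `category`, `seed_term`, `candidate`,
#'   `similarity` (non-increasing within each seed), `rank`, `accepted`
#'   (all `NA` pending review). Seed terms missing from the vocabulary are
#'   skipped with a warning.
#' @export
expand_lexicon <- function(lexicon, embedding, k = 25L) {
  stopifnot(k >= 1L)
  if (!all(c("category", "term") %in% names(lexicon))) {
    abort("lexicon needs columns category and term",
          class = "osgminer_bad_lexicon")
  }
  seeds <- lexicon |>
    dplyr::mutate(lookup = gsub(" ", "_", .data$term, fixed = TRUE))
  missing <- setdiff(unique(seeds$lookup), embedding$terms)
  if (length(missing) > 0L) {
    warn(paste0("seed term(s) not in embedding vocabulary, skipped: ",
                paste(gsub("_", " ", missing, fixed = TRUE), collapse = ", ")))
  }
  present <- seeds[seeds$lookup %in% embedding$terms, , drop = FALSE]
  rows <- lapply(seq_len(nrow(present)), function(i) {
    nn <- nearest_terms(embedding, present$lookup[i], k)
    if (nrow(nn) == 0L) return(NULL)
    tibble(category = present$category[i], seed_term = present$term[i],
           candidate = nn$term, similarity = nn$similarity,
           rank = seq_len(nrow(nn)), accepted = NA)
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) {
    out <- tibble(category = character(), seed_term = character(),
                  candidate = character(), similarity = numeric(),
                  rank = integer(), accepted = logical())
  }
  class(out) <- c("osg_candidates", class(out))
  out
}

#' Apply review decisions to an expansion candidate report
#'
#' Merges reviewed candidates into the lexicon: accepted candidates are
#' added under their seed's category with provenance `expanded-accepted`
#' (underscore-joined phrases become spaced phrases); rejected candidates
#' are discarded. Every distinct (category, candidate) pair in the report
#' must be covered by a decision, otherwise the uncovered candidates are
#' listed in a fatal error — expansion is never silently auto-accepted.
#'
#' @param report A candidate report from [expand_lexicon()].
#' @param decisions A tibble (or path to a TSV) with columns `category`,
#'   `candidate`, `accept` (logical or "true"/"false").
#' @param lexicon The lexicon the candidates expand (defaults to the
#'   packaged [emotion_lexicon()]).
#' @return The merged lexicon tibble, with the audit trail in the
#'   `"audit"` attribute.
#' @export
apply_review <- function(report, decisions, lexicon = emotion_lexicon()) {
  if (is.character(decisions) && length(decisions) == 1L) {
    decisions <- readr::read_tsv(decisions,
                                 col_types = readr::cols(.default = "c"),
                                 progress = FALSE)
  }
  decisions <- as_tibble(decisions)
  if (!all(c("category", "candidate", "accept") %in% names(decisions))) {
    abort("decisions need columns category, candidate, accept")
  }
  decisions$accept <- as.logical(decisions$accept)
  need <- dplyr::distinct(as_tibble(report)[, c("category", "candidate")])
  covered <- dplyr::semi_join(need, decisions, by = c("category", "candidate"))
  if (nrow(covered) < nrow(need)) {
    miss <- dplyr::anti_join(need, decisions, by = c("category", "candidate"))
    abort(paste0("review decisions missing for: ",
                 paste(paste0(miss$category, "/", miss$candidate),
                       collapse = ", ")),
          class = "osgminer_review_incomplete")
  }
  accepted <- decisions |>
    dplyr::semi_join(need, by = c("category", "candidate")) |>
    dplyr::filter(.data$accept) |>
    dplyr::transmute(category = .data$category,
                     term = gsub("_", " ", .data$candidate, fixed = TRUE),
                     provenance = "expanded-accepted")
  out <- validate_emotion_lexicon(dplyr::bind_rows(lexicon, accepted))
  attr(out, "audit") <- decisions |>
    dplyr::semi_join(need, by = c("category", "candidate"))
  out
}

#' Read and write embeddings in word2vec text format
#'
#' The standard text format: a header line `"V D"` followed by one line per
#' term with the term and `D` space-separated values.
#'
#' @param embedding An `osg_embedding`.
#' @param path File path.
#' @return `read_word2vec()` returns an `osg_embedding`; `write_word2vec()`
#'   returns `path` invisibly.
#' @export
write_word2vec <- function(embedding, path) {
  m <- embedding$vectors
  header <- paste(nrow(m), ncol(m))
  body <- vapply(seq_len(nrow(m)), function(i) {
    paste(rownames(m)[i], paste(format(m[i, ], digits = 17, scientific = TRUE,
                                       trim = TRUE), collapse = " "))
  }, character(1))
  writeLines(c(header, body), path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_word2vec
#' @export
read_word2vec <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  hdr <- as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]])
  v <- hdr[1]; d <- hdr[2]
  if (is.na(v) || is.na(d) || length(lines) < v + 1L) {
    abort("malformed word2vec text file", class = "osgminer_io")
  }
  terms <- character(v)
  mat <- matrix(NA_real_, nrow = v, ncol = d)
  for (i in seq_len(v)) {
    parts <- strsplit(trimws(lines[i + 1L]), "\\s+")[[1]]
    terms[i] <- parts[1]
    mat[i, ] <- as.numeric(parts[-1])
  }
  rownames(mat) <- terms
  structure(list(terms = terms, vectors = mat, dim = d,
                 params = list(source = path)),
            class = "osg_embedding")
}
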