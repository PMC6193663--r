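# Shared fixtures and independent oracles. Oracles deliberately use naive
# exhaustive strategies so they share no code with the implementation.

make_posts <- function(texts, patient_id = "pA", thread_id = NULL,
                       start = "2009-05-01 10:00:00", step_days = 40) {
  n <- length(texts)
  patient_id <- rep_len(patient_id, n)
  tibble::tibble(
    post_id = sprintf("x%03d", seq_len(n)),
    patient_id = patient_id,
    thread_id = thread_id %||% sprintf("th%03d", seq_len(n)),
    forum = "fixture",
    timestamp = as.POSIXct(start, tz = "UTC") + (seq_len(n) - 1) * step_days * 86400,
    text = texts
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Exhaustive subsequence checker for the decision templates: tries every
# (subject, verb, treatment) occurrence triple directly.
oracle_occurrences <- function(tokens, terms) {
  out <- list()
  for (tm in terms) {
    tt <- strsplit(tolower(tm), "\\s+")[[1]]
    L <- length(tt)
    if (L > length(tokens)) next
    for (s in seq_len(length(tokens) - L + 1)) {
      if (all(tokens[s:(s + L - 1)] == tt)) {
        out[[length(out) + 1L]] <- c(start = s, end = s + L - 1L)
      }
    }
  }
  out
}

oracle_template_fires <- function(tokens, subjects, verbs, treatments,
                                  negators, window = 3) {
  subj <- oracle_occurrences(tokens, subjects)
  verb <- oracle_occurrences(tokens, verbs)
  cats <- character()
  for (cat in names(treatments)) {
    for (tr in oracle_occurrences(tokens, treatments[[cat]])) {
      for (sv in subj) {
        for (vb in verb) {
          if (sv["start"] >= vb["start"] || tr["start"] <= vb["end"]) next
          if (vb["start"] > 1) {
            win <- seq(max(1, vb["start"] - window), vb["start"] - 1)
            if (any(tokens[win] %in% negators)) next
          }
          cats <- c(cats, cat)
        }
      }
    }
  }
  unique(cats)
}

# Plain-loop cosine ranking oracle over an embedding matrix.
oracle_nearest <- function(vectors, term, k) {
  v <- vectors[term, ]
  others <- setdiff(rownames(vectors), term)
  sims <- vapply(others, function(t) {
    u <- vectors[t, ]
    sum(u * v) / (sqrt(sum(u^2)) * sqrt(sum(v^2)))
  }, numeric(1))
  ord <- order(-sims, others)
  data.frame(term = others[ord], similarity = sims[ord],
             stringsAsFactors = FALSE)[seq_len(min(k, length(others))), ]
}

# Closed-form 2x2 Pearson chi-squared from the margins.
oracle_chisq_2x2 <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  n <- a + b + c + d
  n * (a * d - b * c)^2 /
    ((a + b) * (c + d) * (a + c) * (b + d))
}
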