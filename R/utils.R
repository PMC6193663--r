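# Calendar months are handled as "YYYY-MM" labels backed by a flat integer
# index (year * 12 + month - 1) so month arithmetic is exact.

month_to_idx <- function(m) {
  ok <- grepl("^\\d{4}-\\d{2}$", m)
  if (any(!ok & !is.na(m))) {
    abort(paste0("invalid calendar month label(s): ",
                 paste(unique(m[!ok & !is.na(m)]), collapse = ", ")),
          class = "osgminer_bad_month")
  }
  y <- as.integer(substr(m, 1, 4))
  mo <- as.integer(substr(m, 6, 7))
  if (any(!is.na(mo) & (mo < 1L | mo > 12L))) {
    abort("calendar month outside 01..12", class = "osgminer_bad_month")
  }
  y * 12L + (mo - 1L)
}

idx_to_month <- function(i) {
  ifelse(is.na(i), NA_character_, sprintf("%04d-%02d", i %/% 12L, i %% 12L + 1L))
}

post_month <- function(timestamp) {
  format(timestamp, "%Y-%m", tz = "UTC")
}

extdata_path <- function(file) {
  path <- system.file("extdata", file, package = "osgminer")
  if (!nzchar(path)) abort(paste0("packaged data file not found: ", file))
  path
}

read_role_tsv <- function(path, key = "role") {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                        progress = FALSE)
  if (!all(c(key, "term") %in% names(df))) {
    abort(paste0("lexicon file must have columns '", key, "' and 'term': ", path))
  }
  df
}

`%||%` <- rlang::`%||%`
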