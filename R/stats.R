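new_osg_test <- function(statistic, df, p_value, method) {
  structure(list(statistic = statistic, df = df, p_value = p_value,
                 method = method),
            class = "osg_test")
}

#' Pearson chi-squared test of independence
#'
#' Pearson statistic over a contingency table of counts, with expected
#' counts from the row/column margins, df = (r-1)(c-1) and the p-value from
#' the upper tail of the chi-squared distribution. No continuity correction
#' is applied (the 2x2 closed form is the uncorrected statistic).
#'
#' @param table A matrix (or table) of non-negative counts, at least 2x2.
#' @return An `osg_test` with `statistic`, `df`, `p_value`, `method`;
#'   use [tidy()] for a one-row tibble.
#' @export
chi_squared_test <- function(table) {
  m <- as.matrix(table)
  if (nrow(m) < 2L || ncol(m) < 2L) {
    abort("contingency table must be at least 2x2", class = "osgminer_bad_table")
  }
  if (any(is.na(m)) || any(m < 0)) {
    abort("contingency table must contain non-negative counts",
          class = "osgminer_bad_table")
  }
  rs <- rowSums(m); cs <- colSums(m)
  if (any(rs == 0)) {
    abort(paste0("empty row margin: ",
                 paste(which(rs == 0), collapse = ", ")),
          class = "osgminer_zero_margin")
  }
  if (any(cs == 0)) {
    abort(paste0("empty column margin: ",
                 paste(which(cs == 0), collapse = ", ")),
          class = "osgminer_zero_margin")
  }
  ht <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  new_osg_test(unname(ht$statistic), unname(ht$parameter),
               unname(ht$p.value), "Pearson chi-squared")
}

#' Two-sample Student's t-test
#'
#' Two-sided pooled-variance Student's t-test by default
#' (df = n_a + n_b - 2); Welch's unequal-variance form is available with
#' `var_equal = FALSE`. When both samples are constant with equal means the
#' statistic is 0 with p = 1; constant samples with unequal means have no
#' finite t statistic and are a fatal error.
#'
#' @param a,b Numeric samples, each of size >= 2, finite values.
#' @param var_equal Pool the variances (Student) or not (Welch).
#' @return An `osg_test`.
#' @export
two_sample_t_test <- function(a, b, var_equal = TRUE) {
  stopifnot(length(a) >= 2L, length(b) >= 2L)
  if (any(!is.finite(a)) || any(!is.finite(b))) {
    abort("samples must be finite", class = "osgminer_bad_sample")
  }
  method <- if (var_equal) "Student's t-test (pooled)" else "Welch's t-test"
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (mean(a) == mean(b)) {
      return(new_osg_test(0, length(a) + length(b) - 2L, 1, method))
    }
    abort("zero pooled variance with unequal means: t is undefined",
          class = "osgminer_degenerate_t")
  }
  ht <- stats::t.test(a, b, var.equal = var_equal)
  new_osg_test(unname(ht$statistic), unname(ht$parameter),
               unname(ht$p.value), method)
}

#' @export
print.osg_test <- function(x, ...) {
  cat("<osg_test> ", x$method, ": statistic = ",
      format(x$statistic, digits = 6), ", df = ",
      format(x$df, digits = 6), ", p = ",
      format(x$p_value, digits = 6), "\n", sep = "")
  invisible(x)
}

#' Tidy an osg_test
#'
#' @param x An `osg_test`.
#' @param ... Unused.
#' @return A one-row tibble with `method`, `statistic`, `df`, `p.value`.
#' @export
tidy.osg_test <- function(x, ...) {
  tibble(method = x$method, statistic = x$statistic, df = x$df,
         p.value = x$p_value)
}

#' @rdname tidy.osg_test
#' @export
glance.osg_test <- function(x, ...) tidy.osg_test(x)
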