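# Agreement between two pattern classifications, and paired tests between
# two methods' SES distributions.

#' Classify agreement between two phylogenetic pattern calls
#'
#' Vectorized five-way taxonomy of (dis)agreement between two pattern
#' classifications of the same community:
#' \itemize{
#'   \item `significant_match` - both show the same significant pattern;
#'   \item `nonsignificant_match` - both random;
#'   \item `significant_mismatch` - one clustered, the other overdispersed;
#'   \item `nonsignificant_mismatch` - exactly one of the two is random;
#'   \item `NA` - either input is `NA` (community uncomputable on one side).
#' }
#' The map is symmetric in its arguments.
#'
#' @param a,b Character vectors among `"clustered"`, `"overdispersed"`,
#'   `"random"`, `NA` (recycled to a common length).
#' @return Character vector of categories.
#' @export
compare_patterns <- function(a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(as.character(a), n)
  b <- rep_len(as.character(b), n)
  valid <- c("clustered", "overdispersed", "random")
  if (!all(is.na(a) | a %in% valid) || !all(is.na(b) | b %in% valid)) {
    stop("patterns must be clustered/overdispersed/random or NA")
  }
  out <- character(n)
  for (i in seq_len(n)) {
    out[i] <- if (is.na(a[i]) || is.na(b[i])) {
      NA_character_
    } else if (a[i] == b[i]) {
      if (a[i] == "random") "nonsignificant_match" else "significant_match"
    } else if (a[i] != "random" && b[i] != "random") {
      "significant_mismatch"
    } else {
      "nonsignificant_mismatch"
    }
  }
  out
}

#' Paired test between two methods' SES values
#'
#' Two-sided Wilcoxon signed-rank test (default) or paired t-test on
#' replicate-aligned SES pairs; pairs with any `NA` are dropped.  When every
#' difference is zero the test is degenerate and reported as `p_value = 1`
#' with `degenerate = TRUE`.
#'
#' @param a,b Numeric vectors of SES values aligned by replicate.
#' @param method `"wilcoxon"` (default) or `"t"`.
#' @return A list: `statistic`, `p_value`, `n` (non-NA pairs), `method`,
#'   `degenerate`.
#' @export
paired_method_test <- function(a, b, method = c("wilcoxon", "t")) {
  method <- match.arg(method)
  stopifnot(length(a) == length(b))
  ok <- is.finite(a) & is.finite(b)
  a <- a[ok]; b <- b[ok]
  if (length(a) < 5L) stop("fewer than 5 non-NA pairs")
  d <- b - a
  if (all(d == 0)) {
    return(list(statistic = NA_real_, p_value = 1, n = length(a),
                method = method, degenerate = TRUE))
  }
  ht <- if (method == "wilcoxon") {
    suppressWarnings(stats::wilcox.test(b, a, paired = TRUE, exact = FALSE))
  } else {
    stats::t.test(b, a, paired = TRUE)
  }
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       n = length(a), method = method, degenerate = FALSE)
}

#' Proportions of pattern classes
#'
#' Shares of `clustered`, `overdispersed`, and `random` among the non-`NA`
#' entries of a vector of pattern calls; they sum to one.  The number of
#' excluded `NA` entries is reported in the `n_na` attribute.
#'
#' @param patterns Character vector of pattern calls.
#' @return Named numeric vector `(clustered, overdispersed, random)` with
#'   attributes `n` (entries used) and `n_na`.
#' @export
proportions_table <- function(patterns) {
  patterns <- as.character(patterns)
  n_na <- sum(is.na(patterns))
  used <- patterns[!is.na(patterns)]
  if (!length(used)) stop("all patterns are NA")
  classes <- c("clustered", "overdispersed", "random")
  if (!all(used %in% classes)) stop("unknown pattern value")
  out <- vapply(classes, function(cl) mean(used == cl), numeric(1))
  attr(out, "n") <- length(used)
  attr(out, "n_na") <- n_na
  out
}

#' Benjamini-Hochberg adjustment for a paired-test table
#'
#' Off by default in the experiment runners (per-community results are
#' reported the way field studies usually report them); apply it explicitly
#' when many community-by-size cells are screened.
#'
#' @param tests A data frame with a `p_value` column (e.g. the `tests`
#'   element of [run_q4()] / [run_q5()] output).
#' @return The data frame with an added `p_adj` column.
#' @export
adjust_test_table <- function(tests) {
  stopifnot(is.data.frame(tests), "p_value" %in% names(tests))
  tests$p_adj <- stats::p.adjust(tests$p_value, method = "BH")
  tests
}
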