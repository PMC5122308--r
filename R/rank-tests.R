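#' Rank-based two-group and paired tests
#'
#' Thin, tibble-returning wrappers around the Wilcoxon family used for
#' breeding-status comparisons and within-pair age contrasts. The exact
#' null distribution (full enumeration) is used when there are no ties
#' and the smaller sample has at most `exact_threshold` observations;
#' otherwise the normal approximation with tie-corrected variance and no
#' continuity correction is used. Degenerate inputs (all values
#' identical, or all paired differences zero) return p = 1 with a flag
#' rather than an error.
#'
#' `wmw_test()` is the two-sample Wilcoxon-Mann-Whitney test; its W is
#' the Mann-Whitney statistic of the first group (rank sum of `x` minus
#' its minimum). `signed_rank_test()` is the Wilcoxon matched-pairs
#' signed-rank test on a vector of differences; zeros are dropped and W
#' is the sum of positive ranks.
#'
#' @param x,y Numeric samples (first and second group).
#' @param sides `"two"`, `"greater"` or `"less"`.
#' @param exact_threshold Largest min-group size for the exact path
#'   (default 12).
#' @return A one-row tibble: `statistic`, `p_value`, `method`
#'   (`"exact"` or `"normal-approx"`), `sides`, `degenerate`.
#' @examples
#' wmw_test(c(1, 2), c(3, 4)) # exact two-sided p = 1/3
#' signed_rank_test(c(1, 2, 3, 4, 5), sides = "greater") # p = 1/32
#' @export
wmw_test <- function(x, y, sides = c("two", "greater", "less"),
                     exact_threshold = 12) {
  sides <- match.arg(sides)
  if (length(x) == 0 || length(y) == 0) {
    abort("Both groups must be non-empty.")
  }
  if (length(unique(c(x, y))) == 1) {
    return(tibble::tibble(
      statistic = length(x) * length(y) / 2, p_value = 1,
      method = "degenerate", sides = sides, degenerate = TRUE
    ))
  }
  ties <- anyDuplicated(c(x, y)) > 0
  use_exact <- !ties && min(length(x), length(y)) <= exact_threshold
  alt <- switch(sides, two = "two.sided", greater = "greater", less = "less")
  ht <- suppressWarnings(
    wilcox.test(x, y,
      alternative = alt, exact = use_exact, correct = FALSE
    )
  )
  tibble::tibble(
    statistic = unname(ht$statistic),
    p_value = min(1, ht$p.value),
    method = if (use_exact) "exact" else "normal-approx",
    sides = sides,
    degenerate = FALSE
  )
}

#' @rdname wmw_test
#' @param d Numeric vector of paired differences.
#' @export
signed_rank_test <- function(d, sides = c("two", "greater", "less"),
                             exact_threshold = 12) {
  sides <- match.arg(sides)
  if (length(d) == 0) {
    abort("Need at least one difference.")
  }
  nz <- d[d != 0]
  if (length(nz) == 0) {
    return(tibble::tibble(
      statistic = 0, p_value = 1,
      method = "degenerate", sides = sides, degenerate = TRUE
    ))
  }
  ties <- anyDuplicated(abs(nz)) > 0
  use_exact <- !ties && length(nz) <= exact_threshold
  alt <- switch(sides, two = "two.sided", greater = "greater", less = "less")
  ht <- suppressWarnings(
    wilcox.test(nz, alternative = alt, exact = use_exact, correct = FALSE)
  )
  tibble::tibble(
    statistic = unname(ht$statistic),
    p_value = min(1, ht$p.value),
    method = if (use_exact) "exact" else "normal-approx",
    sides = sides,
    degenerate = FALSE
  )
}

#' Compare display complexity between breeders and non-breeders
#'
#' Joins SDC scores to breeding status, runs a two-sided
#' Wilcoxon-Mann-Whitney test of SDC by status, and summarizes each group
#' by mean and standard error — the standard presentation for a
#' breeder/non-breeder contrast.
#'
#' @param scores Tibble with `subject_id` and a score column.
#' @param status Tibble with `subject_id` and a logical/0-1 `breeder`
#'   column.
#' @param score_col Name of the score column (default `"sdc"`).
#' @return A list of class `sdc_breeding_comparison`: `test` (tibble from
#'   [wmw_test()], first group = breeders), `groups` (tibble: `breeder`,
#'   `n`, `mean`, `se`), `score_col`.
#' @export
breeding_comparison <- function(scores, status, score_col = "sdc") {
  stopifnot(score_col %in% names(scores), "breeder" %in% names(status))
  d <- dplyr::inner_join(
    scores[, c("subject_id", score_col)], status,
    by = "subject_id"
  )
  d$breeder <- as.logical(d$breeder)
  if (anyNA(d$breeder)) {
    abort("`breeder` must be logical or 0/1 without missing values.")
  }
  v <- d[[score_col]]
  if (!any(d$breeder) || all(d$breeder)) {
    abort("Both breeding groups must be non-empty.")
  }
  groups <- d |>
    dplyr::group_by(.data$breeder) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean(.data[[score_col]]),
      se = sd(.data[[score_col]]) / sqrt(dplyr::n()),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$breeder)
  structure(
    list(
      test = wmw_test(v[d$breeder], v[!d$breeder]),
      groups = groups,
      score_col = score_col
    ),
    class = "sdc_breeding_comparison"
  )
}

#' @export
print.sdc_breeding_comparison <- function(x, ...) {
  cat("Breeding-status comparison of `", x$score_col, "` (first group = breeders)\n", sep = "")
  print(x$test)
  print(x$groups)
  invisible(x)
}
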