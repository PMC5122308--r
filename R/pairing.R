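#' Mean absolute within-pair difference
#'
#' The assortative-mating statistic: the arithmetic mean over pairs of
#' the absolute difference between the male's and the female's value of
#' some attribute (age, predicted display complexity, ...). Small values
#' mean partners resemble each other.
#'
#' @param pairs Tibble with one row per pair.
#' @param male_col,female_col Names of the male and female attribute
#'   columns (defaults `male_age` / `female_age`).
#' @return A single number.
#' @examples
#' p <- tibble::tibble(male_age = c(10, 20), female_age = c(12, 15))
#' mean_abs_pair_diff(p) # 3.5
#' @export
mean_abs_pair_diff <- function(pairs, male_col = "male_age",
                               female_col = "female_age") {
  if (nrow(pairs) == 0) {
    abort("Need at least one pair.")
  }
  m <- pairs[[male_col]]
  f <- pairs[[female_col]]
  if (anyNA(m) || anyNA(f)) {
    abort("Attribute missing for some pair members.")
  }
  mean(abs(m - f))
}

#' Randomization test of assortative mating
#'
#' Tests whether observed partners are more (or less) similar than
#' expected under random pairing. Each simulation permutes the female
#' attribute vector against the fixed male vector — i.e. re-pairs the
#' observed individuals at random, identity permutation allowed — and
#' recomputes the mean absolute within-pair difference. The null
#' interval is the 2.5th-97.5th percentile band of the simulated means
#' (linear interpolation between order statistics); an observed mean
#' below it (`"outside-low"`) indicates assortment (homogamy), above it
#' (`"outside-high"`) disassortment.
#'
#' @inheritParams mean_abs_pair_diff
#' @param n_sim Number of random re-pairings (default 1000; fewer than
#'   100 triggers a warning about unstable percentiles).
#' @param seed Integer seed; the result is fully reproducible given the
#'   seed and leaves the global RNG state untouched.
#' @param conf_level Width of the percentile band (default 0.95).
#' @param attribute Label stored with the result (default derived from
#'   the column names).
#' @return An object of class `sdc_randomization`: a list with
#'   `attribute`, `observed`, `null_draws`, `conf_low`, `conf_high`,
#'   `verdict` (`"inside"`, `"outside-low"`, `"outside-high"`),
#'   `n_sim`, `n_pairs`, `seed`, `conf_level`.
#' @examples
#' p <- tibble::tibble(male_age = c(4, 12, 30), female_age = c(5, 13, 28))
#' random_pairing_null(p, n_sim = 200, seed = 1)
#' @export
random_pairing_null <- function(pairs, male_col = "male_age",
                                female_col = "female_age",
                                n_sim = 1000, seed = 1,
                                conf_level = 0.95, attribute = NULL) {
  if (nrow(pairs) < 2) {
    abort("Need at least two pairs to permute.")
  }
  if (n_sim < 100) {
    warn("Fewer than 100 simulations: percentile interval will be unstable.")
  }
  if (is.null(attribute)) {
    attribute <- sub("^male_", "", male_col)
  }
  m <- pairs[[male_col]]
  f <- pairs[[female_col]]
  if (anyNA(m) || anyNA(f)) {
    abort("Attribute missing for some pair members.")
  }
  observed <- mean(abs(m - f))
  draws <- withr::with_seed(seed, {
    vapply(seq_len(n_sim), function(i) {
      mean(abs(m - sample(f)))
    }, numeric(1))
  })
  alpha <- (1 - conf_level) / 2
  ci <- unname(quantile(draws, c(alpha, 1 - alpha)))
  verdict <- if (observed < ci[1]) {
    "outside-low"
  } else if (observed > ci[2]) {
    "outside-high"
  } else {
    "inside"
  }
  structure(
    list(
      attribute = attribute,
      observed = observed,
      null_draws = draws,
      conf_low = ci[1],
      conf_high = ci[2],
      verdict = verdict,
      n_sim = n_sim,
      n_pairs = nrow(pairs),
      seed = seed,
      conf_level = conf_level
    ),
    class = "sdc_randomization"
  )
}

#' @export
print.sdc_randomization <- function(x, ...) {
  cat(
    "Random-pairing null for `", x$attribute, "` (", x$n_pairs,
    " pairs, ", x$n_sim, " simulations, seed ", x$seed, ")\n",
    "  observed mean |difference| = ", format(x$observed, digits = 4),
    "\n  ", 100 * x$conf_level, "% null interval = [",
    format(x$conf_low, digits = 4), "; ",
    format(x$conf_high, digits = 4), "]  ->  ", x$verdict, "\n",
    sep = ""
  )
  invisible(x)
}

#' Assign model-predicted display complexity to pair members
#'
#' When display complexity was not measured on the paired individuals
#' themselves, each member receives the complexity predicted from its
#' age by a fitted display model (date held fixed for everyone, so the
#' predicted score is a pure function of age). The resulting columns
#' feed [random_pairing_null()] for the complexity-homogamy test.
#'
#' @param pairs Tibble with `male_age` and `female_age` columns.
#' @param object A fitted `sdc_average` or `sdc_candidate` for the
#'   display-complexity response.
#' @param fixed_date Date (days since season start, Nov 1 = 0) at which
#'   to predict; default 94 (Feb 3).
#' @param scaling Scaling record if not stored in `object`.
#' @return `pairs` with added `male_sdc_pred` and `female_sdc_pred`.
#' @export
predicted_sdc_for_pairs <- function(pairs, object, fixed_date = 94,
                                    scaling = NULL) {
  stopifnot(all(c("male_age", "female_age") %in% names(pairs)))
  if (anyNA(pairs$male_age) || anyNA(pairs$female_age)) {
    abort("Ages missing for some pair members.")
  }
  pred_for <- function(ages) {
    nd <- tibble::tibble(age = ages, date = fixed_date)
    predict_response(object, nd, scaling = scaling)$.pred
  }
  pairs$male_sdc_pred <- pred_for(pairs$male_age)
  pairs$female_sdc_pred <- pred_for(pairs$female_age)
  pairs
}
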