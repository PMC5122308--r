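#' Zero-method (full-average) model averaging
#'
#' Averages coefficients across a set of models using their Akaike
#' weights, substituting 0 for a coefficient in every model that excludes
#' its term (the "zero method" or full average). The unconditional
#' standard error follows Burnham & Anderson:
#' `SE(term) = sum_i w_i * sqrt(var_i + (beta_i - est)^2)`, with
#' `var_i = 0` and `beta_i = 0` where the term is absent, so model
#' selection uncertainty inflates the SE. Confidence intervals are
#' normal-theory `estimate +/- 1.96 SE`. A term's importance is the sum
#' of the weights of the models containing it.
#'
#' @param x An `sdc_model_selection` (its delta AICc <= threshold top set
#'   is averaged with renormalized weights), or a list of
#'   `sdc_candidate` fits.
#' @param weights Weights for the fits when `x` is a list; must sum to 1
#'   after renormalization (renormalized internally).
#' @param conf_level Confidence level for the normal-theory interval
#'   (default 0.95).
#' @return An object of class `sdc_average`: a list with `coefficients`
#'   (tibble: `term`, `estimate`, `se`, `conf_low`, `conf_high`,
#'   `sum_of_weights`), `weights`, `labels`, `family`, `response`, `n`,
#'   `scaling` and `age_range`-style term ranges (`term_ranges`) for
#'   extrapolation flagging.
#' @examples
#' d <- tibble::tibble(x = rnorm(40), y = rnorm(40))
#' model_average(model_selection(d, "y", terms = "x"))
#' @export
model_average <- function(x, weights = NULL, conf_level = 0.95) {
  if (inherits(x, "sdc_model_selection")) {
    tm <- top_models(x)
    fits <- tm$fits
    weights <- tm$weights
    scaling <- x$scaling
    response <- x$response
  } else {
    fits <- x
    if (is.null(weights)) {
      weights <- akaike_weights(vapply(fits, function(f) f$aicc, numeric(1)))
    }
    scaling <- NULL
    fml <- fits[[1]]$fit$formula
    response <- if (is.null(fml)) NA_character_ else as.character(fml[[2]])
  }
  stopifnot(length(fits) >= 1, length(weights) == length(fits))
  weights <- weights / sum(weights)

  all_terms <- unique(unlist(purrr::map(fits, function(f) names(f$coef))))
  # keep intercept first, then the order terms first appear
  all_terms <- c(
    intersect("(Intercept)", all_terms),
    setdiff(all_terms, "(Intercept)")
  )
  rows <- purrr::map(all_terms, function(tm) {
    beta <- vapply(fits, function(f) {
      if (tm %in% names(f$coef)) unname(f$coef[[tm]]) else 0
    }, numeric(1))
    vr <- vapply(fits, function(f) {
      if (tm %in% names(f$coef)) f$vcov[tm, tm] else 0
    }, numeric(1))
    present <- vapply(fits, function(f) tm %in% names(f$coef), logical(1))
    est <- sum(weights * beta)
    se <- sum(weights * sqrt(vr + (beta - est)^2))
    tibble::tibble(
      term = tm, estimate = est, se = se,
      sum_of_weights = sum(weights[present])
    )
  })
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  coefs <- purrr::list_rbind(rows) |>
    dplyr::mutate(
      conf_low = .data$estimate - z * .data$se,
      conf_high = .data$estimate + z * .data$se
    ) |>
    dplyr::select(
      "term", "estimate", "se", "conf_low", "conf_high", "sum_of_weights"
    )

  # observed range of each model column, for extrapolation flags at predict time
  mf <- fits[[1]]$fit$model
  num <- names(mf)[vapply(mf, is.numeric, logical(1))]
  term_ranges <- purrr::map(setNames(num, num), function(cl) range(mf[[cl]]))

  structure(
    list(
      coefficients = coefs,
      weights = weights,
      labels = vapply(fits, function(f) f$label, character(1)),
      family = fits[[1]]$family,
      response = response,
      n = fits[[1]]$n,
      conf_level = conf_level,
      scaling = scaling,
      term_ranges = term_ranges
    ),
    class = "sdc_average"
  )
}

#' @export
print.sdc_average <- function(x, ...) {
  cat("Zero-method model average over ", length(x$weights), " model(s): ",
    paste(x$labels, collapse = "; "), "\n",
    sep = ""
  )
  print(x$coefficients)
  invisible(x)
}

#' Predict the response over a grid of predictor values
#'
#' Computes model-averaged (or single-model) predictions on the original
#' response scale. New predictor values are given on their *original*
#' scale and standardized internally with the stored scaling record, so a
#' prediction at age 20 means age 20 in years. Any model column absent
#' from `newdata` is held at its standardized mean (0); for a quadratic
#' column `x2` present in the scaling record, the square is derived from
#' `x` automatically. Binomial predictions are inverse-logit transformed.
#'
#' @param object An `sdc_average` or `sdc_candidate`.
#' @param newdata Data frame of predictor values on the original scale
#'   (e.g. `tibble(age = 4:37, date = 94)`).
#' @param scaling Scaling record; defaults to the one stored in `object`.
#' @return `newdata` with columns `.pred` (response scale) and
#'   `.extrapolated` (`TRUE` where any supplied predictor falls outside
#'   the range seen when fitting).
#' @examples
#' d <- tibble::tibble(x = rnorm(40), y = rnorm(40))
#' avg <- model_average(model_selection(d, "y", terms = "x"))
#' predict_response(avg, tibble::tibble(x = c(-1, 0, 1)))
#' @export
predict_response <- function(object, newdata, scaling = NULL) {
  if (inherits(object, "sdc_candidate")) {
    coefs <- tibble::tibble(
      term = names(object$coef), estimate = unname(object$coef)
    )
    family <- object$family
    mf <- object$fit$model
    num <- names(mf)[vapply(mf, is.numeric, logical(1))]
    term_ranges <- purrr::map(setNames(num, num), function(cl) range(mf[[cl]]))
  } else if (inherits(object, "sdc_average")) {
    coefs <- object$coefficients
    family <- object$family
    term_ranges <- object$term_ranges
    if (is.null(scaling)) scaling <- object$scaling
  } else {
    abort("`object` must be an sdc_average or sdc_candidate.")
  }
  newdata <- tibble::as_tibble(newdata)
  raw <- newdata

  slope_terms <- setdiff(coefs$term, "(Intercept)")
  main_cols <- unique(unlist(strsplit(slope_terms, ":", fixed = TRUE)))

  # derive quadratic columns from their base before standardizing
  if (!is.null(scaling)) {
    scaling <- scaling_record(scaling)
    for (cl in intersect(main_cols, scaling$term)) {
      base <- sub("2$", "", cl)
      if (grepl("2$", cl) && !cl %in% names(newdata) && base %in% names(newdata)) {
        newdata[[cl]] <- newdata[[base]]^2
      }
    }
    newdata <- standardize_new(newdata, scaling)
  }
  for (cl in setdiff(main_cols, names(newdata))) {
    newdata[[cl]] <- 0 # standardized mean
  }

  eta <- rep(0, nrow(newdata))
  for (i in seq_len(nrow(coefs))) {
    tm <- coefs$term[i]
    if (tm == "(Intercept)") {
      eta <- eta + coefs$estimate[i]
    } else {
      parts <- strsplit(tm, ":", fixed = TRUE)[[1]]
      val <- rep(1, nrow(newdata))
      for (p in parts) val <- val * newdata[[p]]
      eta <- eta + coefs$estimate[i] * val
    }
  }
  pred <- if (identical(family, "binomial")) plogis(eta) else eta

  extrap <- rep(FALSE, nrow(newdata))
  for (cl in intersect(names(newdata), names(term_ranges))) {
    if (!cl %in% names(raw) &&
        !(!is.null(scaling) && cl %in% scaling$term && grepl("2$", cl))) {
      next # column defaulted to the mean, not user input
    }
    rg <- term_ranges[[cl]]
    extrap <- extrap | newdata[[cl]] < rg[1] | newdata[[cl]] > rg[2]
  }
  raw$.pred <- pred
  raw$.extrapolated <- extrap
  raw
}
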