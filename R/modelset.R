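#' Generate an all-subsets candidate model set
#'
#' Enumerates every subset of the full term list, subject to marginality
#' (hierarchy) and collinearity constraints, and always includes the
#' intercept-only model. Marginality means a quadratic term is only
#' allowed together with its linear term, and an interaction only with
#' both main effects. Collinearity exclusions drop any subset containing
#' a forbidden pair of terms jointly — the classic case being group size
#' and date of season, which are strongly correlated in communal display
#' data because display groups swell as the season advances.
#'
#' @param terms Character vector of term names. Interactions are written
#'   `"a:b"`; a quadratic of `x` is a column named `x2` (see
#'   [standardize_predictors()] for the square-then-standardize rule) and
#'   is auto-detected as depending on `x`.
#' @param exclusions List of length-2 character vectors; no returned set
#'   contains both members of a pair. Default: none.
#' @param marginality Enforce hierarchy? Default `TRUE`.
#' @param hierarchy Optional named list mapping a term to the terms it
#'   requires, overriding/extending auto-detection.
#' @param max_terms Maximum number of terms per model (e.g. from a 10:1
#'   observations-to-predictors rule). Default unlimited.
#' @return A list of character vectors (term sets); the first is
#'   `character(0)`, the intercept-only model.
#' @examples
#' generate_model_set(c("age", "age2")) # null; age; age + age2
#' @export
generate_model_set <- function(terms, exclusions = list(),
                               marginality = TRUE, hierarchy = list(),
                               max_terms = Inf) {
  terms <- unique(as.character(terms))
  if (length(terms) == 0) {
    return(list(character(0)))
  }
  deps <- hierarchy
  if (marginality) {
    for (tm in terms) {
      auto <- character(0)
      if (grepl(":", tm, fixed = TRUE)) {
        auto <- strsplit(tm, ":", fixed = TRUE)[[1]]
      } else if (grepl("2$", tm)) {
        base <- sub("2$", "", tm)
        if (base %in% terms) auto <- base
      }
      deps[[tm]] <- union(deps[[tm]], intersect(auto, terms))
    }
  }
  for (pair in exclusions) {
    if (!all(pair %in% terms)) {
      abort(paste0(
        "Exclusion pair contains unknown term(s): ",
        paste(setdiff(pair, terms), collapse = ", ")
      ))
    }
  }
  n <- length(terms)
  keep <- list()
  for (mask in 0:(2^n - 1)) {
    inc <- terms[bitwAnd(mask, 2^(seq_len(n) - 1)) > 0]
    if (length(inc) > max_terms) next
    ok <- TRUE
    if (marginality || length(deps) > 0) {
      for (tm in inc) {
        if (!all(deps[[tm]] %in% inc)) {
          ok <- FALSE
          break
        }
      }
    }
    if (ok && length(exclusions) > 0) {
      for (pair in exclusions) {
        if (all(pair %in% inc)) {
          ok <- FALSE
          break
        }
      }
    }
    if (ok) keep[[length(keep) + 1]] <- inc
  }
  # deterministic order: by size, then lexicographic label
  labels <- vapply(keep, model_label, character(1))
  keep[order(lengths(keep), labels)]
}

#' Human-readable label for a term set
#' @param terms Character vector of terms (possibly empty).
#' @return A single string, `"1"` for the intercept-only model.
#' @export
model_label <- function(terms) {
  if (length(terms) == 0) "1" else paste(terms, collapse = " + ")
}

#' Small-sample corrected Akaike information criterion
#'
#' `AICc = -2 logLik + 2k + 2k(k+1)/(n - k - 1)`. The parameter count `k`
#' includes the intercept, all slope terms, and — for gaussian models —
#' the residual variance. The correction is undefined when
#' `n <= k + 1`.
#'
#' @param loglik Maximized log-likelihood.
#' @param k Number of estimated parameters.
#' @param n Number of observations.
#' @return The AICc value, unrounded.
#' @examples
#' aicc(-479.75, 5, 100) # 970.14 to 2 dp
#' @export
aicc <- function(loglik, k, n) {
  if (any(n <= k + 1)) {
    abort("AICc undefined: need n > k + 1.")
  }
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Akaike weights
#'
#' `w_i = exp(-0.5 * delta_i) / sum_j exp(-0.5 * delta_j)` with deltas
#' relative to the smallest criterion value in the supplied set. Weights
#' are interpreted as model probabilities over that set; renormalizing
#' over a top subset is just calling this on the subset.
#'
#' @param ic Vector of AICc (or AIC) values.
#' @return Numeric vector of weights summing to 1.
#' @examples
#' akaike_weights(c(0, 1.3, 1.9)) # 0.52, 0.27, 0.20
#' @export
akaike_weights <- function(ic) {
  if (length(ic) == 0) {
    abort("Need at least one criterion value.")
  }
  rel <- exp(-0.5 * (ic - min(ic)))
  rel / sum(rel)
}

#' Fit one candidate GLM
#'
#' Maximum-likelihood fit of `response ~ terms` by [stats::glm()].
#' Gaussian fits count the residual variance in `k`; binomial fits do
#' not. Binomial fits showing complete separation (fitted probabilities
#' numerically 0 or 1, or non-convergence) are flagged so that model
#' averaging can drop them.
#'
#' @param data Data frame holding the response and all term columns
#'   (standardized or not — fitting does not care).
#' @param response Name of the response column.
#' @param terms Character vector of term names (`character(0)` for the
#'   intercept-only model). Interaction terms `"a:b"` use the usual
#'   formula semantics.
#' @param family `"gaussian"` or `"binomial"`.
#' @return An object of class `sdc_candidate`: a list with `terms`,
#'   `label`, `family`, `fit` (the glm), `coef`, `vcov`, `loglik`, `k`,
#'   `n`, `aicc`, `converged`.
#' @export
fit_candidate <- function(data, response, terms,
                          family = c("gaussian", "binomial")) {
  family <- match.arg(family)
  rhs <- if (length(terms) == 0) "1" else paste(terms, collapse = " + ")
  fml <- as.formula(paste(response, "~", rhs))
  separated <- FALSE
  fit <- withCallingHandlers(
    glm(fml, data = data, family = family),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)) ||
          grepl("algorithm did not converge", conditionMessage(w))) {
        separated <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  ll <- logLik(fit)
  k <- attr(ll, "df") # glm: p for binomial, p + 1 (sigma^2) for gaussian
  n <- length(fit$residuals)
  structure(
    list(
      terms = terms,
      label = model_label(terms),
      family = family,
      fit = fit,
      coef = coef(fit),
      vcov = vcov(fit),
      loglik = as.numeric(ll),
      k = k,
      n = n,
      aicc = aicc(as.numeric(ll), k, n),
      converged = fit$converged && !separated
    ),
    class = "sdc_candidate"
  )
}

#' @export
print.sdc_candidate <- function(x, ...) {
  cat("<candidate model ", x$family, ": ", x$label,
    " | k = ", x$k, ", logLik = ", round(x$loglik, 2),
    ", AICc = ", round(x$aicc, 2), ">\n",
    sep = ""
  )
  invisible(x)
}

#' AICc model selection over an all-subsets candidate set
#'
#' Fits every candidate term set, ranks by AICc (ties broken by fewer
#' parameters, then label), and identifies the top set of models within
#' `delta_top` AICc units of the best. Weights are reported both over the
#' full candidate set and renormalized within the top set; the latter
#' drive zero-method averaging. Binomial candidates flagged for complete
#' separation are excluded from ranking with a warning.
#'
#' @inheritParams fit_candidate
#' @param model_set List of term sets from [generate_model_set()], or
#'   `NULL` to generate it from `terms`.
#' @param terms Full term list (used when `model_set` is `NULL`).
#' @param exclusions,marginality,max_terms Passed to
#'   [generate_model_set()].
#' @param delta_top AICc window defining the top model set (default 2).
#' @return An object of class `sdc_model_selection` with elements
#'   `table` (tibble: `model`, `df`, `logLik`, `AICc`, `delta`, `weight`,
#'   `weight_top`, `top`), `fits` (list of `sdc_candidate` in table
#'   order), `response`, `family`, `n`, `delta_top`, and `scaling` (the
#'   scaling record of `data` if one is attached).
#' @examples
#' d <- tibble::tibble(x = rnorm(30), y = rnorm(30))
#' model_selection(d, "y", terms = "x")
#' @export
model_selection <- function(data, response, terms = NULL, model_set = NULL,
                            family = c("gaussian", "binomial"),
                            exclusions = list(), marginality = TRUE,
                            max_terms = Inf, delta_top = 2) {
  family <- match.arg(family)
  if (is.null(model_set)) {
    if (is.null(terms)) {
      abort("Supply either `terms` or `model_set`.")
    }
    model_set <- generate_model_set(
      terms,
      exclusions = exclusions,
      marginality = marginality, max_terms = max_terms
    )
  }
  fits <- purrr::map(model_set, function(tm) {
    fit_candidate(data, response, tm, family = family)
  })
  ok <- vapply(fits, function(f) f$converged, logical(1))
  if (any(!ok)) {
    warn(paste0(
      sum(!ok), " candidate model(s) dropped (non-convergence/separation): ",
      paste(vapply(fits[!ok], function(f) f$label, character(1)),
        collapse = "; "
      )
    ))
    fits <- fits[ok]
  }
  if (length(fits) == 0) {
    abort("No candidate model converged.")
  }
  aiccs <- vapply(fits, function(f) f$aicc, numeric(1))
  ks <- vapply(fits, function(f) f$k, numeric(1))
  labels <- vapply(fits, function(f) f$label, character(1))
  ord <- order(aiccs, ks, labels)
  fits <- fits[ord]
  aiccs <- aiccs[ord]
  delta <- aiccs - aiccs[1]
  weight <- akaike_weights(aiccs)
  top <- delta <= delta_top
  weight_top <- rep(NA_real_, length(fits))
  weight_top[top] <- akaike_weights(aiccs[top])
  table <- tibble::tibble(
    model = vapply(fits, function(f) f$label, character(1)),
    df = vapply(fits, function(f) as.integer(f$k), integer(1)),
    logLik = vapply(fits, function(f) f$loglik, numeric(1)),
    AICc = aiccs,
    delta = delta,
    weight = weight,
    weight_top = weight_top,
    top = top
  )
  structure(
    list(
      table = table,
      fits = fits,
      response = response,
      family = family,
      n = fits[[1]]$n,
      delta_top = delta_top,
      scaling = attr(data, "sdc_scaling")
    ),
    class = "sdc_model_selection"
  )
}

#' @export
print.sdc_model_selection <- function(x, n = 10, ...) {
  cat("AICc model selection for `", x$response, "` (", x$family,
    ", n = ", x$n, "): ", nrow(x$table), " candidate models, ",
    sum(x$table$top), " within dAICc <= ", x$delta_top, "\n",
    sep = ""
  )
  print(utils::head(x$table, n))
  invisible(x)
}

#' Extract the top (delta AICc <= threshold) models
#'
#' @param selection An `sdc_model_selection`.
#' @return A list with `fits` (the top candidates) and `weights`
#'   (their renormalized Akaike weights, summing to 1).
#' @export
top_models <- function(selection) {
  stopifnot(inherits(selection, "sdc_model_selection"))
  idx <- which(selection$table$top)
  list(
    fits = selection$fits[idx],
    weights = selection$table$weight_top[idx]
  )
}
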