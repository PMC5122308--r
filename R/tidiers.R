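#' Tidiers for fitted objects
#'
#' broom-style `tidy()` and `glance()` methods so pipeline results drop
#' straight into dplyr chains.
#'
#' @param x The fitted object.
#' @param ... Unused.
#' @return A tibble.
#' @name sdc-tidiers
NULL

#' @rdname sdc-tidiers
#' @export
tidy.sdc_model_selection <- function(x, ...) {
  x$table
}

#' @rdname sdc-tidiers
#' @export
glance.sdc_model_selection <- function(x, ...) {
  tibble::tibble(
    response = x$response,
    family = x$family,
    n = x$n,
    n_models = nrow(x$table),
    n_top = sum(x$table$top),
    best_model = x$table$model[1],
    best_aicc = x$table$AICc[1]
  )
}

#' @rdname sdc-tidiers
#' @export
tidy.sdc_average <- function(x, ...) {
  x$coefficients
}

#' @rdname sdc-tidiers
#' @export
glance.sdc_average <- function(x, ...) {
  tibble::tibble(
    response = as.character(x$response),
    family = x$family,
    n = x$n,
    n_models = length(x$weights),
    conf_level = x$conf_level
  )
}

#' @rdname sdc-tidiers
#' @export
tidy.sdc_randomization <- function(x, ...) {
  tibble::tibble(
    attribute = x$attribute,
    observed = x$observed,
    conf_low = x$conf_low,
    conf_high = x$conf_high,
    verdict = x$verdict,
    n_pairs = x$n_pairs,
    n_sim = x$n_sim,
    seed = x$seed
  )
}

#' @rdname sdc-tidiers
#' @export
glance.sdc_randomization <- function(x, ...) {
  tibble::tibble(
    null_mean = mean(x$null_draws),
    null_sd = sd(x$null_draws),
    conf_level = x$conf_level,
    n_sim = x$n_sim
  )
}

#' @rdname sdc-tidiers
#' @export
tidy.sdc_breeding_comparison <- function(x, ...) {
  x$groups
}

#' @rdname sdc-tidiers
#' @export
glance.sdc_breeding_comparison <- function(x, ...) {
  x$test
}
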