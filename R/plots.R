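#' Plot methods
#'
#' `autoplot()` methods for the main result types, plus
#' [plot_age_curve()] for the predicted complexity-by-age relationship.
#'
#' @param object The result object.
#' @param ... Unused.
#' @return A ggplot.
#' @name sdc-plots
NULL

#' @rdname sdc-plots
#' @param bins Histogram bins for the null distribution.
#' @export
autoplot.sdc_randomization <- function(object, bins = 30, ...) {
  d <- tibble::tibble(draw = object$null_draws)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$draw)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey70", color = "white") +
    ggplot2::geom_vline(
      xintercept = c(object$conf_low, object$conf_high), linetype = 1
    ) +
    ggplot2::geom_vline(xintercept = object$observed, linetype = 2) +
    ggplot2::labs(
      x = paste0("mean |pair difference| in ", object$attribute),
      y = "simulations",
      title = paste0(
        "Random-pairing null (", object$verdict, "), ",
        object$n_sim, " simulations"
      )
    ) +
    ggplot2::theme_minimal()
}

#' @rdname sdc-plots
#' @export
autoplot.sdc_model_selection <- function(object, ...) {
  d <- dplyr::slice_min(object$table, .data$AICc, n = 15)
  d$model <- factor(d$model, levels = rev(d$model))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$delta, y = .data$model, fill = .data$top)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::geom_vline(xintercept = object$delta_top, linetype = 2) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "grey30", `FALSE` = "grey70")) +
    ggplot2::labs(
      x = expression(Delta * AICc), y = NULL,
      title = paste0("Model selection for ", object$response)
    ) +
    ggplot2::theme_minimal()
}

#' @rdname sdc-plots
#' @export
autoplot.sdc_breeding_comparison <- function(object, ...) {
  d <- object$groups |>
    dplyr::mutate(group = ifelse(.data$breeder, "breeder", "non-breeder"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$group, y = .data$mean)) +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$mean - .data$se, ymax = .data$mean + .data$se
    )) +
    ggplot2::labs(
      x = NULL, y = paste0("mean ", object$score_col, " (+/- SE)"),
      title = "Display complexity by subsequent breeding status"
    ) +
    ggplot2::theme_minimal()
}

#' Predicted display complexity across ages
#'
#' Draws the model-averaged prediction curve over an age grid at a fixed
#' date, optionally overlaying per-age observed means.
#'
#' @param object An `sdc_average` (or `sdc_candidate`) for a display
#'   response.
#' @param ages Age grid (default 4-37 by 0.25).
#' @param fixed_date Date held fixed (default 94 = Feb 3).
#' @param observed Optional score table; per-age mean +/- SE points are
#'   overlaid for its response column.
#' @param response_col Column of `observed` to summarize (default
#'   `"sdc"`).
#' @return A ggplot.
#' @export
plot_age_curve <- function(object, ages = seq(4, 37, by = 0.25),
                           fixed_date = 94, observed = NULL,
                           response_col = "sdc") {
  curve <- predict_response(
    object, tibble::tibble(age = ages, date = fixed_date)
  )
  p <- ggplot2::ggplot(curve, ggplot2::aes(x = .data$age, y = .data$.pred)) +
    ggplot2::geom_line(linewidth = 1) +
    ggplot2::labs(
      x = "age (years)", y = paste0("predicted ", response_col),
      title = paste0(
        "Predicted ", response_col, " by age (date fixed at day ",
        fixed_date, ")"
      )
    ) +
    ggplot2::theme_minimal()
  if (!is.null(observed)) {
    pts <- observed |>
      dplyr::group_by(.data$age) |>
      dplyr::summarise(
        mean = mean(.data[[response_col]]),
        se = sd(.data[[response_col]]) / sqrt(dplyr::n()),
        .groups = "drop"
      )
    p <- p +
      ggplot2::geom_pointrange(
        data = pts,
        ggplot2::aes(
          x = .data$age, y = .data$mean,
          ymin = .data$mean - ifelse(is.na(.data$se), 0, .data$se),
          ymax = .data$mean + ifelse(is.na(.data$se), 0, .data$se)
        ),
        inherit.aes = FALSE, color = "grey40"
      )
  }
  p
}
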