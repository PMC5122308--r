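#' Standardize predictors by two standard deviations
#'
#' Centers each predictor and divides by twice its sample standard
#' deviation, so that a one-unit change corresponds to a two-SD change and
#' coefficients of continuous and binary inputs are directly comparable
#' across models and studies. Binary indicators (e.g. sex coded 0/1) are
#' treated like any other column under this rule. A quadratic term must be
#' squared on the raw scale *first* and then standardized as its own
#' column (see the example).
#'
#' @param data A data frame of predictors (and possibly other columns).
#' @param cols Character vector of columns to standardize. Defaults to all
#'   numeric columns.
#' @return `data` with the chosen columns replaced by their standardized
#'   versions (mean 0, SD 0.5) and an attached scaling record: a tibble
#'   with columns `term`, `center`, `scale` (`scale` = 2 x sample SD),
#'   retrievable with [scaling_record()] and reusable on new data via
#'   [standardize_new()].
#' @examples
#' d <- tibble::tibble(age = c(4, 10, 20, 35))
#' d$age2 <- d$age^2 # square first ...
#' s <- standardize_predictors(d) # ... then standardize both columns
#' scaling_record(s)
#' @export
standardize_predictors <- function(data, cols = NULL) {
  if (is.null(cols)) {
    cols <- names(data)[vapply(data, is.numeric, logical(1))]
  }
  missing <- setdiff(cols, names(data))
  if (length(missing) > 0) {
    abort(paste0("Column(s) not in data: ", paste(missing, collapse = ", ")))
  }
  centers <- vapply(cols, function(cl) mean(data[[cl]]), numeric(1))
  sds <- vapply(cols, function(cl) sd(data[[cl]]), numeric(1))
  degenerate <- cols[is.na(sds) | sds == 0]
  if (length(degenerate) > 0) {
    abort(paste0(
      "Cannot standardize constant column(s): ",
      paste(degenerate, collapse = ", ")
    ))
  }
  scaling <- tibble::tibble(term = cols, center = centers, scale = 2 * sds)
  for (cl in cols) {
    data[[cl]] <- (data[[cl]] - centers[[cl]]) / (2 * sds[[cl]])
  }
  attr(data, "sdc_scaling") <- scaling
  data
}

#' @rdname standardize_predictors
#' @param x A data frame returned by `standardize_predictors()`, or a
#'   scaling tibble itself.
#' @export
scaling_record <- function(x) {
  if (is.data.frame(x) && all(c("term", "center", "scale") %in% names(x)) &&
      is.null(attr(x, "sdc_scaling"))) {
    return(x)
  }
  rec <- attr(x, "sdc_scaling")
  if (is.null(rec)) {
    abort("No scaling record attached; did this come from standardize_predictors()?")
  }
  rec
}

#' @rdname standardize_predictors
#' @param newdata New observations on the original scale.
#' @param scaling A scaling record (or an object carrying one).
#' @export
standardize_new <- function(newdata, scaling) {
  scaling <- scaling_record(scaling)
  for (i in seq_len(nrow(scaling))) {
    cl <- scaling$term[i]
    if (cl %in% names(newdata)) {
      newdata[[cl]] <- (newdata[[cl]] - scaling$center[i]) / scaling$scale[i]
    }
  }
  newdata
}
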