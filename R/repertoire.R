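#' Display repertoires
#'
#' A repertoire is the ethogram of discrete display postures against which
#' focal event logs are validated. The built-in default is the nine-posture
#' ritualized display repertoire of the greater flamingo (*Phoenicopterus
#' roseus*): group displays cycle through a small set of highly stereotyped
#' movements, and every scored sequence is a walk over this set.
#'
#' @param labels Character vector of unique, non-empty posture codes.
#' @param display_names Optional character vector of human-readable names,
#'   same length as `labels`. Defaults to the labels themselves.
#'
#' @return A tibble of class `sdc_repertoire` with columns `label` and
#'   `display_name`, one row per posture.
#' @examples
#' default_repertoire()
#' repertoire(c("A", "B", "C"))
#' @export
repertoire <- function(labels, display_names = labels) {
  labels <- as.character(labels)
  if (length(labels) == 0) {
    abort("A repertoire needs at least one posture label.")
  }
  if (anyNA(labels) || any(!nzchar(trimws(labels)))) {
    abort("Posture labels must be non-empty strings.")
  }
  if (anyDuplicated(labels)) {
    dup <- unique(labels[duplicated(labels)])
    abort(paste0(
      "Duplicate posture label(s): ", paste(dup, collapse = ", ")
    ))
  }
  if (length(display_names) != length(labels)) {
    abort("`display_names` must match `labels` in length.")
  }
  out <- tibble::tibble(
    label = labels,
    display_name = as.character(display_names)
  )
  class(out) <- c("sdc_repertoire", class(out))
  out
}

#' @rdname repertoire
#' @details
#' The default labels follow the classical flamingo display catalogue:
#' head-flagging, wing-salute, twist-preen, inverted-wing-salute,
#' wing-leg-stretch, marching, false-feeding, hooking and broken-neck.
#' @export
default_repertoire <- function() {
  repertoire(
    c(
      "HF", "WS", "TP", "IWS", "WLS", "MA", "FF", "HO", "BN"
    ),
    c(
      "head-flagging", "wing-salute", "twist-preen", "inverted-wing-salute",
      "wing-leg-stretch", "marching", "false-feeding", "hooking",
      "broken-neck"
    )
  )
}

#' Read a repertoire from a configuration file
#'
#' Accepts either a YAML file (a plain list of codes, or a mapping of
#' code to display name) or a plain-text file with one code per line.
#' With no path, returns [default_repertoire()].
#'
#' @param path Path to a YAML or plain-text repertoire file, or `NULL`.
#' @return An `sdc_repertoire` tibble.
#' @examples
#' read_repertoire() # built-in nine-posture repertoire
#' @export
read_repertoire <- function(path = NULL) {
  if (is.null(path)) {
    return(default_repertoire())
  }
  if (!file.exists(path)) {
    abort(paste0("Repertoire file not found: ", path))
  }
  parsed <- tryCatch(
    yaml::read_yaml(path),
    error = function(e) abort(paste0("Cannot parse repertoire file: ", conditionMessage(e)))
  )
  if (is.null(parsed)) {
    abort("Repertoire file is empty.")
  }
  if (!is.null(names(parsed)) && all(nzchar(names(parsed)))) {
    repertoire(names(parsed), vapply(parsed, as.character, character(1)))
  } else {
    repertoire(unlist(parsed, use.names = FALSE))
  }
}

#' @export
print.sdc_repertoire <- function(x, ...) {
  cat("<display repertoire: ", nrow(x), " postures>\n", sep = "")
  NextMethod()
}
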