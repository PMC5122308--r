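#' Display richness, versatility and the SDC score
#'
#' Richness is the number of distinct postures an individual used in a
#' sequence (its realized repertoire size); versatility counts the
#' transitions between *different* postures; sexual display complexity
#' (SDC) is their product. A complex display is therefore a sequence with
#' many switches among many postures, while a monotonous sequence (one
#' posture repeated) scores richness 1, versatility 0, SDC 0.
#'
#' Adjacent duplicate events (the same state re-logged) are collapsed
#' before counting, so a re-logged identical posture never counts as a
#' transition. Two versatility definitions are supported:
#' `"change-count"` (default) counts every adjacent pair of different
#' postures, i.e. the total number of posture changes;
#' `"distinct-ordered"` counts the number of *unique* ordered pairs
#' observed at least once.
#'
#' @param posture Character vector: the posture codes of one sequence in
#'   temporal order.
#' @param mode Versatility definition, `"change-count"` or
#'   `"distinct-ordered"`.
#' @return `richness()` and `versatility()` return a single integer.
#' @examples
#' richness(c("A", "A", "B"))            # 2
#' versatility(c("A", "B", "A", "B", "A"))  # 4 changes
#' versatility(c("A", "B", "A", "B", "A"), mode = "distinct-ordered") # 2
#' @export
richness <- function(posture) {
  posture <- as.character(posture)
  if (length(posture) == 0 || anyNA(posture)) {
    abort("Cannot score an empty sequence.")
  }
  length(unique(posture))
}

#' @rdname richness
#' @export
versatility <- function(posture, mode = c("change-count", "distinct-ordered")) {
  mode <- match.arg(mode)
  posture <- as.character(posture)
  if (length(posture) == 0 || anyNA(posture)) {
    abort("Cannot score an empty sequence.")
  }
  # collapse re-logged identical states
  p <- rle(posture)$values
  if (length(p) < 2) {
    return(0L)
  }
  from <- p[-length(p)]
  to <- p[-1]
  switch(mode,
    "change-count" = length(from),
    "distinct-ordered" = nrow(unique(cbind(from, to)))
  )
}

#' Score one sequence
#'
#' @param events A sequence tibble (see [behavior_sequence()]) for a
#'   single subject, or a character vector of postures.
#' @param repertoire Repertoire used for validation and the richness
#'   upper bound.
#' @inheritParams richness
#' @return A one-row tibble: `subject_id`, `richness`, `versatility`,
#'   `sdc`, `mode`.
#' @examples
#' sdc_score(c("A", "B", "A"))
#' @export
sdc_score <- function(events, repertoire = default_repertoire(),
                      mode = c("change-count", "distinct-ordered")) {
  mode <- match.arg(mode)
  if (is.character(events)) {
    events <- behavior_sequence(
      "seq", seq_along(events) - 1, events,
      repertoire = repertoire,
      window_length = length(events) + 1
    )
  }
  bad <- setdiff(unique(events$posture), repertoire$label)
  if (length(bad) > 0) {
    abort(paste0("Posture code(s) outside repertoire: ", paste(bad, collapse = ", ")))
  }
  r <- richness(events$posture)
  v <- versatility(events$posture, mode = mode)
  tibble::tibble(
    subject_id = events$subject_id[1],
    richness = as.integer(r),
    versatility = as.integer(v),
    sdc = as.integer(r * v),
    mode = mode
  )
}

#' Score a batch of sequences and join focal metadata
#'
#' @param events Long event tibble covering any number of subjects.
#' @param metadata Focal metadata tibble with one row per `subject_id`
#'   (columns such as `sex`, `age`, `date`, `hour`, `group_size`, `year`).
#'   Every scored subject must be present.
#' @inheritParams sdc_score
#' @return A tibble with one row per subject, ordered by `subject_id`:
#'   scores joined to metadata.
#' @export
score_sequences <- function(events, metadata = NULL,
                            repertoire = default_repertoire(),
                            mode = c("change-count", "distinct-ordered")) {
  mode <- match.arg(mode)
  if (nrow(events) == 0) {
    out <- tibble::tibble(
      subject_id = character(), richness = integer(),
      versatility = integer(), sdc = integer(), mode = character()
    )
    if (!is.null(metadata)) out <- dplyr::left_join(out, metadata, by = "subject_id")
    return(out)
  }
  scores <- events |>
    dplyr::arrange(.data$subject_id, .data$t) |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::group_modify(function(d, key) {
      sdc_score(
        dplyr::bind_cols(tibble::tibble(subject_id = key$subject_id), d),
        repertoire = repertoire, mode = mode
      )[, -1]
    }) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$subject_id)
  if (!is.null(metadata)) {
    missing <- setdiff(scores$subject_id, metadata$subject_id)
    if (length(missing) > 0) {
      abort(paste0(
        "No metadata for subject(s): ", paste(missing, collapse = ", ")
      ))
    }
    scores <- dplyr::left_join(scores, metadata, by = "subject_id")
  }
  scores
}
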