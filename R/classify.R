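#' Classify a single syllable
#'
#' Assigns exactly one of the 11 syllable types to an annotated syllable
#' by a fixed precedence ladder over its spectro-temporal measurements.
#' All frequency thresholds are in kHz and inclusive where stated:
#'
#' 1. **lfh** — harmonic stack with fundamental below 5 kHz;
#' 2. **noisy** — warbled broadband harmonic sound (annotation flag);
#' 3. **short** — duration at most 5 ms;
#' 4. **two_freq_step** — three elements, both inter-element steps at
#'    least 10 kHz in magnitude;
#' 5. **one_freq_step** — two elements, step at least 10 kHz;
#' 6. **complex** — two or more directional frequency changes > 6 kHz
#'    (the annotated reversal count);
#' 7. **chevron** — the track's highest frequency at least 6 kHz above
#'    both the starting and ending frequencies (inverted U);
#' 8. **reverse_chevron** — lowest frequency at least 6 kHz below both
#'    (U shape);
#' 9. **up_fm** — net upward modulation of at least 6 kHz;
#' 10. **down_fm** — net downward modulation of at least 6 kHz;
#' 11. **flat** — everything else (modulation below 6 kHz).
#'
#' Structural rules precede shape rules so that the ladder is a total
#' partition of valid records. Multi-element records whose steps are all
#' below 10 kHz are treated as a single concatenated track and fall
#' through to the shape rules. Classification depends only on duration
#' and frequencies, never on absolute onset time.
#'
#' @param record A `usv_syllable` (see [syllable_record()]).
#' @return A list of class `usv_classified` with fields `record`,
#'   `syll_type`, `bandwidth` (kHz, max minus min over the whole
#'   syllable), `step_sizes` (signed kHz between consecutive element
#'   center frequencies) and `dominant_freq` (center frequency of the
#'   primary element: the only element for simple syllables, the first
#'   element for stepped syllables).
#' @export
#' @examples
#' rec <- syllable_record("s1", 0, 19, "74/76/75/73/77")
#' classify_syllable(rec)$syll_type   # "flat"
classify_syllable <- function(record) {
  validate_syllable_record(record)
  el <- record$elements
  k <- nrow(el)
  steps <- if (k > 1L) diff(el[, "center"]) else numeric(0)
  # the frequency track in time order: start, center, end of each element
  track <- as.vector(t(el[, c("start", "center", "end"), drop = FALSE]))

  type <-
    if (!is.na(record$fundamental) && record$fundamental < 5) "lfh"
    else if (record$is_noisy_broadband) "noisy"
    else if (record$duration <= 5) "short"
    else if (k == 3L && all(abs(steps) >= 10)) "two_freq_step"
    else if (k == 2L && abs(steps[1L]) >= 10) "one_freq_step"
    else if (record$reversals >= 2L) "complex"
    else {
      s <- track[1L]; e <- track[length(track)]
      peak <- max(track); trough <- min(track)
      if (peak - s >= 6 && peak - e >= 6) "chevron"
      else if (s - trough >= 6 && e - trough >= 6) "reverse_chevron"
      else if (e - s >= 6) "up_fm"
      else if (s - e >= 6) "down_fm"
      else "flat"
    }

  structure(
    list(record = record,
         syll_type = type,
         bandwidth = max(el[, "max"]) - min(el[, "min"]),
         step_sizes = steps,
         dominant_freq = el[1L, "center"]),
    class = "usv_classified")
}

#' Classify an annotation table
#'
#' Order-preserving, vectorised application of [classify_syllable()] to
#' every row of an annotation data.frame. Malformed rows are collected
#' and reported together with their row indices.
#'
#' @param records Annotation data.frame in the dialect of
#'   [read_annotations()]; may be empty.
#' @return The input data.frame with added columns `syll_type`,
#'   `bandwidth_khz`, `step_sizes` (semicolon-joined signed kHz),
#'   `dominant_khz`, `min_khz`, `max_khz`, `n_elements` and
#'   `duration_ms`. A per-age type-count table is attached as attribute
#'   `"type_counts"`.
#' @export
classify_table <- function(records) {
  if (nrow(records) == 0L) {
    out <- records
    out$syll_type <- character(0); out$bandwidth_khz <- numeric(0)
    out$step_sizes <- character(0); out$dominant_khz <- numeric(0)
    out$min_khz <- numeric(0); out$max_khz <- numeric(0)
    out$n_elements <- integer(0); out$duration_ms <- numeric(0)
    attr(out, "type_counts") <- table(age_group = character(0),
                                      syll_type = character(0))
    return(out)
  }
  n <- nrow(records)
  type <- character(n); bw <- numeric(n); dom <- numeric(n)
  mn <- numeric(n); mx <- numeric(n); ne <- integer(n)
  stp <- character(n); dur <- numeric(n)
  errors <- character(0)
  missing <- setdiff(ANNOTATION_COLUMNS, names(records))
  if (length(missing)) {
    usv_error(sprintf("annotation table missing columns: %s",
                      paste(missing, collapse = ", ")), "usvrep_io")
  }
  col <- as.list(records[ANNOTATION_COLUMNS])
  for (i in seq_len(n)) {
    res <- tryCatch({
      rec <- syllable_record(
        id = col$id[i], onset = col$onset_ms[i], offset = col$offset_ms[i],
        elements = col$elements[i],
        reversals = if (is.na(col$reversals[i])) 0L else col$reversals[i],
        purity = col$purity[i],
        fundamental = suppressWarnings(as.numeric(col$fundamental_khz[i])),
        is_noisy_broadband = isTRUE(as.logical(col$is_noisy_broadband[i])),
        age_group = col$age_group[i], animal_id = col$animal_id[i])
      cl <- classify_syllable(rec)
      type[i] <- cl$syll_type
      bw[i] <- cl$bandwidth
      dom[i] <- cl$dominant_freq
      mn[i] <- min(cl$record$elements[, "min"])
      mx[i] <- max(cl$record$elements[, "max"])
      ne[i] <- nrow(cl$record$elements)
      stp[i] <- paste(round(cl$step_sizes, 3), collapse = ";")
      dur[i] <- cl$record$duration
      NULL
    }, usvrep_malformed = function(e) conditionMessage(e))
    if (!is.null(res)) errors <- c(errors, sprintf("row %d: %s", i, res))
  }
  if (length(errors)) {
    usv_error(paste0("malformed annotation rows:\n",
                     paste(errors, collapse = "\n")), "usvrep_malformed")
  }
  out <- records
  out$syll_type <- type; out$bandwidth_khz <- bw; out$step_sizes <- stp
  out$dominant_khz <- dom; out$min_khz <- mn; out$max_khz <- mx
  out$n_elements <- ne; out$duration_ms <- dur
  attr(out, "type_counts") <- table(age_group = out$age_group,
                                    syll_type = out$syll_type)
  out
}
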