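#' Inter-syllable interval statistics
#'
#' Computes silent inter-syllable intervals (next onset minus current
#' offset) within each animal/session — never across animals — and
#' summarises all intervals shorter than the analysis window. The
#' standard deviation is the sample (n-1) estimator.
#'
#' @param records Annotation or classified data.frame, time-ordered by
#'   onset within each animal.
#' @param window Inclusion cutoff in ms; only intervals strictly below
#'   it contribute (default 5000 ms).
#' @return List of class `usv_interval_stats`: `mean`, `sd`, `median`,
#'   `window`, `n` (intervals used).
#' @export
interval_stats <- function(records, window = 5000) {
  iv <- .intervals_by_animal(records)
  iv <- iv[iv < window]
  if (length(iv) < 1L) {
    usv_error("no inter-syllable intervals available (need >= 2 syllables in some session)",
              "usvrep_empty_stats")
  }
  structure(list(mean = mean(iv),
                 sd = if (length(iv) > 1L) sd(iv) else 0,
                 median = median(iv),
                 window = window, n = length(iv)),
            class = "usv_interval_stats")
}

.intervals_by_animal <- function(records) {
  if (nrow(records) < 2L) return(numeric(0))
  unlist(lapply(split(records, records$animal_id), function(d) {
    if (nrow(d) < 2L) return(numeric(0))
    if (is.unsorted(d$onset_ms)) {
      usv_error(sprintf("records for animal '%s' are not sorted by onset",
                        d$animal_id[1L]), "usvrep_unsorted")
    }
    d$onset_ms[-1L] - d$offset_ms[-nrow(d)]
  }), use.names = FALSE)
}

#' Bout-separation threshold from interval statistics
#'
#' The bout criterion is a silence threshold `k` standard deviations
#' above the mean inter-syllable interval; with the pooled all-age
#' statistics (mean 337.8 ms, SD 616.0 ms) and the default `k = 2`, the
#' threshold is 1569.8 ms.
#'
#' @param stats A `usv_interval_stats` (or any list with `mean`, `sd`).
#' @param k SD multiplier (default 2).
#' @return Threshold in ms.
#' @export
#' @examples
#' bout_threshold(list(mean = 337.8, sd = 616.0))   # 1569.8
bout_threshold <- function(stats, k = 2) {
  if (!is.finite(stats$mean) || !is.finite(stats$sd) || stats$sd < 0) {
    usv_error("invalid interval statistics", "usvrep_empty_stats")
  }
  stats$mean + k * stats$sd
}

#' Segment a syllable stream into bouts
#'
#' A bout is a maximal run of successive syllables whose silent gaps are
#' all strictly below the threshold; runs with fewer than `min_len`
#' syllables are returned as discards (counted, not silently dropped).
#' Runs never span animal/session boundaries.
#'
#' @param records Classified data.frame, time-ordered by onset within
#'   each animal (a `syll_type` column is required for downstream
#'   sequence analyses; segmentation itself only uses timing).
#' @param threshold Silence threshold in ms (> 0); see [bout_threshold()].
#' @param min_len Minimum syllables per bout (default 3).
#' @return List of class `usv_segmentation`: `bouts` (list of
#'   `usv_bout`), `discards` (list of short runs, same structure),
#'   `threshold`, `min_len`, `n_syllables_in_bouts`,
#'   `n_syllables_discarded`.
#' @export
segment_bouts <- function(records, threshold, min_len = 3) {
  if (!is.numeric(threshold) || threshold <= 0) {
    usv_error("threshold must be positive", "usvrep_parameter")
  }
  bouts <- list(); discards <- list()
  for (d in split(records, records$animal_id)) {
    if (is.unsorted(d$onset_ms)) {
      usv_error(sprintf("records for animal '%s' are not sorted by onset",
                        d$animal_id[1L]), "usvrep_unsorted")
    }
    gaps <- if (nrow(d) > 1L) d$onset_ms[-1L] - d$offset_ms[-nrow(d)] else numeric(0)
    run_id <- cumsum(c(1L, as.integer(gaps >= threshold)))
    for (idx in split(seq_len(nrow(d)), run_id)) {
      run <- .new_bout(d[idx, , drop = FALSE])
      if (length(idx) >= min_len) bouts[[length(bouts) + 1L]] <- run
      else discards[[length(discards) + 1L]] <- run
    }
  }
  structure(list(bouts = bouts, discards = discards,
                 threshold = threshold, min_len = min_len,
                 n_syllables_in_bouts = sum(vapply(bouts, function(b) nrow(b$syllables), 0L)),
                 n_syllables_discarded = sum(vapply(discards, function(b) nrow(b$syllables), 0L))),
            class = "usv_segmentation")
}

.new_bout <- function(d) {
  n <- nrow(d)
  structure(list(
    syllables = d,
    types = if ("syll_type" %in% names(d)) d$syll_type else NULL,
    intervals = if (n > 1L) d$onset_ms[-1L] - d$offset_ms[-n] else numeric(0),
    bout_duration = d$offset_ms[n] - d$onset_ms[1L],
    age_group = d$age_group[1L],
    animal_id = d$animal_id[1L]),
    class = "usv_bout")
}

#' @export
print.usv_segmentation <- function(x, ...) {
  cat(sprintf("usv_segmentation: %d bouts (%d syllables), %d discarded runs (%d syllables), threshold %.1f ms\n",
              length(x$bouts), x$n_syllables_in_bouts,
              length(x$discards), x$n_syllables_discarded, x$threshold))
  invisible(x)
}

#' Per-age bout summary statistics
#'
#' @param bouts A `usv_segmentation` or a list of `usv_bout`.
#' @return data.frame, one row per age group: number of bouts, mean
#'   syllables per bout, median inter-syllable interval (pooled over the
#'   age's within-bout gaps), mean bout duration, and mean number of
#'   distinct syllable types per bout.
#' @export
bout_stats <- function(bouts) {
  bouts <- .as_bout_list(bouts)
  if (!length(bouts)) usv_error("no bouts to summarise", "usvrep_empty_stats")
  ages <- vapply(bouts, function(b) b$age_group, "")
  do.call(rbind, lapply(split(bouts, ages), function(bs) {
    data.frame(
      age_group = bs[[1L]]$age_group,
      n_bouts = length(bs),
      mean_syllables_per_bout = mean(vapply(bs, function(b) nrow(b$syllables), 0L)),
      median_interval_ms = median(unlist(lapply(bs, function(b) b$intervals))),
      mean_bout_duration_ms = mean(vapply(bs, function(b) b$bout_duration, 0)),
      mean_distinct_types = mean(vapply(bs, function(b) length(unique(b$types)), 0L)),
      row.names = NULL)
  }))
}

.as_bout_list <- function(bouts) {
  if (inherits(bouts, "usv_segmentation")) return(bouts$bouts)
  if (inherits(bouts, "usv_bout")) return(list(bouts))
  bouts
}

# extract per-bout type sequences; accepts usv_segmentation, list of
# usv_bout, or a plain list of character vectors (generated sequences)
.bout_sequences <- function(bouts) {
  bouts <- .as_bout_list(bouts)
  lapply(bouts, function(b) {
    if (inherits(b, "usv_bout")) {
      if (is.null(b$types)) {
        usv_error("bout lacks syllable types; classify the table first",
                  "usvrep_parameter")
      }
      b$types
    } else if (inherits(b, "usv_generated_bout")) b$types
    else as.character(b)
  })
}
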