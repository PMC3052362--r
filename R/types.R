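#' The closed syllable-type taxonomy
#'
#' Eleven syllable types are recognised in CBA/CaJ mouse vocalizations:
#' complex, 1-frequency-step, 2-frequency-step, upward FM, downward FM,
#' flat, short, chevron, reverse chevron, low-frequency harmonic (LFH)
#' and noisy. Harmonic content and nonlinearities (subharmonics,
#' deterministic chaos) are recorded as a per-syllable *purity*
#' attribute, not as types of their own.
#'
#' @return Character vector of the 11 type labels, in canonical order.
#' @export
#' @examples
#' syllable_types()
syllable_types <- function() {
  c("complex", "one_freq_step", "two_freq_step", "up_fm", "down_fm",
    "flat", "short", "chevron", "reverse_chevron", "lfh", "noisy")
}

#' Recognised age groups
#'
#' Postnatal days 5 through 13 (isolation calls) plus adult (social calls).
#'
#' @return Character vector of age-group labels.
#' @export
age_groups <- function() {
  c("p5", "p7", "p9", "p11", "p13", "adult")
}

#' Spectral purity classes
#'
#' @return Character vector: tonal, harmonic, nonlinear.
#' @export
purity_levels <- function() {
  c("tonal", "harmonic", "nonlinear")
}

# ---- element tracks ---------------------------------------------------------

# Elements are the step-separated components of a syllable (1-3 per
# syllable). Each carries five dominant-frequency measurements in kHz:
# start (+2 ms), center, end (-2 ms), and the min/max over the element.
ELEMENT_FIELDS <- c("start", "center", "end", "min", "max")

#' Parse an element string into a measurement matrix
#'
#' The annotation dialect encodes elements as semicolon-separated blocks
#' of `start/center/end/min/max` dominant frequencies in kHz, e.g.
#' `"70/90/72/68/92"` for one element.
#'
#' @param x A single element string.
#' @return Numeric matrix, one row per element, columns
#'   `start,center,end,min,max` (kHz).
#' @export
parse_elements <- function(x) {
  if (length(x) != 1L || is.na(x) || !nzchar(x)) {
    usv_error("empty element string", "usvrep_malformed")
  }
  blocks <- strsplit(x, ";", fixed = TRUE)[[1]]
  vals <- lapply(blocks, function(b) {
    v <- suppressWarnings(as.numeric(strsplit(b, "/", fixed = TRUE)[[1]]))
    if (length(v) != 5L || anyNA(v)) {
      usv_error(sprintf("malformed element block '%s'", b), "usvrep_malformed")
    }
    v
  })
  m <- do.call(rbind, vals)
  colnames(m) <- ELEMENT_FIELDS
  m
}

#' Format an element measurement matrix as an element string
#'
#' @param m Matrix as returned by [parse_elements()].
#' @param digits Number of decimal places kept.
#' @return Single string in the annotation dialect.
#' @export
format_elements <- function(m, digits = 3) {
  m <- round(m, digits)
  paste(apply(m, 1L, paste, collapse = "/"), collapse = ";")
}

# ---- syllable records -------------------------------------------------------

#' Construct a syllable record
#'
#' One manually annotated syllable: timing, element-wise dominant
#' frequency measurements, reversal count, purity class, optional
#' fundamental frequency (harmonic stacks) and the broadband-noise flag.
#'
#' @param id Record identifier.
#' @param onset,offset Onset/offset in ms from the recording start.
#' @param elements Numeric matrix (1-3 rows) with columns
#'   `start,center,end,min,max` in kHz, or an element string.
#' @param reversals Count of directional frequency changes > 6 kHz within
#'   the track (annotated, not recomputed; three samples per element
#'   cannot resolve two reversals).
#' @param purity One of [purity_levels()].
#' @param fundamental Fundamental frequency in kHz for harmonic-stack
#'   sounds, `NA` otherwise.
#' @param is_noisy_broadband `TRUE` for warbled noisy harmonic sounds in
#'   the 10-120 kHz range.
#' @param age_group One of [age_groups()].
#' @param animal_id Animal/session identifier (intervals are never formed
#'   across animals).
#' @return A list of class `usv_syllable`.
#' @export
syllable_record <- function(id, onset, offset, elements,
                            reversals = 0L,
                            purity = "tonal",
                            fundamental = NA_real_,
                            is_noisy_broadband = FALSE,
                            age_group = "adult",
                            animal_id = "unknown") {
  if (is.character(elements)) elements <- parse_elements(elements)
  rec <- structure(
    list(id = as.character(id), onset = as.numeric(onset),
         offset = as.numeric(offset),
         duration = as.numeric(offset) - as.numeric(onset),
         elements = elements, reversals = as.integer(reversals),
         purity = purity, fundamental = as.numeric(fundamental),
         is_noisy_broadband = isTRUE(is_noisy_broadband),
         age_group = age_group, animal_id = as.character(animal_id)),
    class = "usv_syllable")
  validate_syllable_record(rec)
  rec
}

#' Validate a syllable record
#'
#' Checks the structural invariants: positive duration, 1-3 elements,
#' positive frequencies with `min <= start,center,end <= max` per
#' element, a single purity value, and a known age group.
#'
#' @param rec A `usv_syllable`.
#' @return The record, invisibly; signals a condition of class
#'   `usvrep_malformed` otherwise.
#' @export
validate_syllable_record <- function(rec) {
  el <- rec$elements
  if (!is.matrix(el) || nrow(el) < 1L) {
    usv_error(sprintf("record '%s': elements must be a non-empty matrix", rec$id),
              "usvrep_malformed")
  }
  if (nrow(el) > 3L) {
    usv_error(sprintf("record '%s': more than 3 elements", rec$id),
              "usvrep_malformed")
  }
  if (any(!is.finite(el)) || any(el <= 0)) {
    usv_error(sprintf("record '%s': non-positive or missing frequency", rec$id),
              "usvrep_malformed")
  }
  bad <- el[, "min"] > pmin(el[, "start"], el[, "center"], el[, "end"]) |
    el[, "max"] < pmax(el[, "start"], el[, "center"], el[, "end"])
  if (any(bad)) {
    usv_error(sprintf("record '%s': min/max do not bound start/center/end", rec$id),
              "usvrep_malformed")
  }
  if (!is.finite(rec$duration) || rec$duration <= 0) {
    usv_error(sprintf("record '%s': offset must exceed onset", rec$id),
              "usvrep_malformed")
  }
  if (!(rec$purity %in% purity_levels())) {
    usv_error(sprintf("record '%s': unknown purity '%s'", rec$id, rec$purity),
              "usvrep_malformed")
  }
  if (!(rec$age_group %in% age_groups())) {
    usv_error(sprintf("record '%s': unknown age group '%s'", rec$id, rec$age_group),
              "usvrep_malformed")
  }
  invisible(rec)
}

# ---- annotation table IO ----------------------------------------------------

ANNOTATION_COLUMNS <- c("id", "animal_id", "age_group", "onset_ms", "offset_ms",
                        "purity", "is_noisy_broadband", "fundamental_khz",
                        "reversals", "elements")

#' Read a syllable annotation table
#'
#' CSV or TSV (by file extension), UTF-8, header row, one row per
#' syllable. Required columns: `id, animal_id, age_group, onset_ms,
#' offset_ms, purity, is_noisy_broadband, fundamental_khz, reversals,
#' elements`; `fundamental_khz` may be blank. Extra columns (e.g. the
#' classifier's outputs) are preserved.
#'
#' @param path File path.
#' @return data.frame of annotations.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) {
    usv_error(sprintf("annotation file '%s' not found", path), "usvrep_io")
  }
  reader <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) read.delim else read.csv
  df <- reader(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  missing <- setdiff(ANNOTATION_COLUMNS, names(df))
  if (length(missing)) {
    usv_error(sprintf("annotation table missing columns: %s",
                      paste(missing, collapse = ", ")), "usvrep_io")
  }
  df$fundamental_khz <- suppressWarnings(as.numeric(df$fundamental_khz))
  df$is_noisy_broadband <- as.logical(df$is_noisy_broadband)
  df
}

#' Write a syllable annotation table
#'
#' Emits the same dialect read by [read_annotations()]; classified
#' tables additionally carry `syll_type`, `bandwidth_khz`, `step_sizes`
#' and the derived per-syllable frequency summaries.
#'
#' @param df Annotation (or classified) data.frame.
#' @param path Output path; `.tsv` extension selects tab separation.
#' @export
write_annotations <- function(df, path) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}
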