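#' Rank-frequency table of syllable types
#'
#' Counts syllable-type usage and ranks types by descending count,
#' breaking ties alphabetically by label. Types with zero count are
#' excluded (their log-count is undefined in the Zipf regression).
#'
#' @param x A classified data.frame (uses `syll_type`), a character
#'   vector of types, or a named numeric vector of counts.
#' @return List of class `usv_rank_frequency`: `counts` (named, in rank
#'   order) and `rank` (1-based).
#' @export
rank_frequency <- function(x) {
  counts <-
    if (is.data.frame(x)) table(x$syll_type)
    else if (is.character(x)) table(x)
    else x
  counts <- counts[counts > 0]
  cv <- as.numeric(counts)
  nm <- names(counts)
  ord <- order(-cv, nm)
  structure(list(counts = setNames(cv[ord], nm[ord]),
                 rank = seq_along(ord)),
            class = "usv_rank_frequency")
}

#' Zipf rank-frequency regression slope
#'
#' Ordinary least-squares slope of log(count) on log(rank) over the
#' types with nonzero counts (natural logs; the slope is base
#' invariant). A slope of -1 is the canonical balance between
#' repertoire diversity and repetition; steeper (more negative) slopes
#' indicate a more repetitious repertoire.
#'
#' @param rf A `usv_rank_frequency`, or anything accepted by
#'   [rank_frequency()].
#' @return List of class `usv_zipf`: `slope`, `intercept`, `r_squared`,
#'   `n_types_used`.
#' @export
#' @examples
#' zipf_slope(c(a = 12, b = 6, c = 4, d = 3))$slope   # exactly -1
zipf_slope <- function(rf) {
  if (!inherits(rf, "usv_rank_frequency")) rf <- rank_frequency(rf)
  if (length(rf$counts) < 2L) {
    usv_error("Zipf regression needs at least 2 types with nonzero counts",
              "usvrep_insufficient_diversity")
  }
  y <- log(as.numeric(rf$counts))
  fit <- lm(y ~ log(rf$rank))
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - sum(fit$residuals^2) / ss_tot else NA_real_
  structure(list(slope = unname(coef(fit)[2L]),
                 intercept = unname(coef(fit)[1L]),
                 r_squared = r2,
                 n_types_used = length(rf$counts)),
            class = "usv_zipf")
}

#' Goodness-of-fit test of type proportions against a uniform model
#'
#' Chi-squared goodness-of-fit of observed per-type counts against the
#' random (uniform over observed types) model; tests whether some
#' syllable types are produced more commonly than others.
#'
#' @param counts Named non-negative counts, at least 2 categories.
#' @return List: `statistic`, `df` (c - 1), `p_value`, `n`.
#' @export
proportion_test <- function(counts) {
  counts <- counts[!is.na(counts)]
  if (length(counts) < 2L) {
    usv_error("need at least 2 categories", "usvrep_parameter")
  }
  n <- sum(counts)
  if (n <= 0) usv_error("all expected counts are zero", "usvrep_degenerate")
  ht <- suppressWarnings(chisq.test(as.numeric(counts)))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = unname(ht$p.value), n = n)
}

#' Two-syllable (pair) transition count table
#'
#' Counts overlapping consecutive syllable-type pairs within each bout;
#' pairs never cross bout boundaries, and only bouts with **more than 3**
#' syllables contribute.
#'
#' @param bouts A `usv_segmentation`, list of `usv_bout`, or list of
#'   character type sequences.
#' @param min_bout_len Minimum bout length + 1 for inclusion; default 4
#'   (the "more than 3 syllables" rule).
#' @return List of class `usv_pair_table`: `counts` (square matrix,
#'   first syllable in rows), `total`, `n_bouts_used`.
#' @export
pair_table <- function(bouts, min_bout_len = 4L) {
  seqs <- .bout_sequences(bouts)
  seqs <- seqs[lengths(seqs) >= min_bout_len]
  if (!length(seqs)) {
    usv_error("no bouts with more than 3 syllables", "usvrep_empty_table")
  }
  lev <- .type_levels(unlist(seqs, use.names = FALSE))
  m <- matrix(0L, length(lev), length(lev), dimnames = list(from = lev, to = lev))
  for (s in seqs) {
    from <- s[-length(s)]; to <- s[-1L]
    t2 <- table(factor(from, lev), factor(to, lev))
    m <- m + unclass(t2)
  }
  structure(list(counts = m, total = sum(m), n_bouts_used = length(seqs)),
            class = "usv_pair_table")
}

# keep the canonical taxonomy ordering when possible; otherwise sort
.type_levels <- function(types) {
  u <- unique(types)
  if (all(u %in% syllable_types())) intersect(syllable_types(), u)
  else sort(u)
}

#' Chi-squared independence test on a syllable-pair table
#'
#' Tests whether consecutive syllables are independent: observed pair
#' counts against expected counts from the product of the first- and
#' second-position marginals. Zero marginal rows/columns are dropped
#' with a warning; df = (r-1)(s-1) over the retained table.
#'
#' @param pt A `usv_pair_table`.
#' @return List: `statistic`, `df`, `p_value`, `n` (pair total).
#' @export
pair_independence_test <- function(pt) {
  m <- pt$counts
  if (sum(m) <= 0) usv_error("empty pair table", "usvrep_empty_table")
  keep_r <- rowSums(m) > 0; keep_c <- colSums(m) > 0
  if (!all(keep_r) || !all(keep_c)) {
    warning("dropping zero-marginal rows/columns from pair table")
    m <- m[keep_r, keep_c, drop = FALSE]
  }
  n <- sum(m)
  expected <- outer(rowSums(m), colSums(m)) / n
  stat <- sum((m - expected)^2 / expected)
  df <- (nrow(m) - 1L) * (ncol(m) - 1L)
  list(statistic = stat, df = df,
       p_value = pchisq(stat, df, lower.tail = FALSE), n = n)
}

#' Probability of switching between syllable types
#'
#' One minus the repetition probability: repetitions (same type twice in
#' a row, any type) summed and divided by the total number of
#' two-syllable pairings.
#'
#' @param pt A `usv_pair_table`.
#' @return Switching probability in \[0, 1\].
#' @export
switching_probability <- function(pt) {
  if (pt$total <= 0) usv_error("empty pair table", "usvrep_empty_table")
  1 - sum(diag(pt$counts)) / pt$total
}

#' Empirical distribution of bout-initial syllable types
#'
#' @param bouts A `usv_segmentation`, list of `usv_bout`, or list of
#'   character sequences; all bouts contribute their first syllable.
#' @return Named numeric vector of probabilities summing to 1, in
#'   decreasing order.
#' @export
initial_syllable_probs <- function(bouts) {
  seqs <- .bout_sequences(bouts)
  if (!length(seqs)) usv_error("no bouts", "usvrep_empty_table")
  first <- vapply(seqs, `[`, "", 1L)
  sort(table(first) / length(first), decreasing = TRUE)
}

#' Audibility census: syllables above 100 kHz
#'
#' Adult mice hear little above roughly 100 kHz, so syllables whose
#' dominant frequency exceeds 100 kHz are of special interest, and
#' syllables with *all* energy above 100 kHz would be inaudible to
#' adults entirely.
#'
#' @param classified Classified data.frame (needs `dominant_khz`,
#'   `min_khz`, `age_group`).
#' @param cutoff_khz Audibility cutoff (default 100).
#' @return data.frame per age group: `n`, `n_dominant_above`,
#'   `frac_dominant_above`, `n_all_energy_above`, `frac_all_energy_above`.
#'   Fractions are reported at full precision; round for presentation.
#' @export
audibility_census <- function(classified, cutoff_khz = 100) {
  do.call(rbind, lapply(split(classified, classified$age_group), function(d) {
    data.frame(age_group = d$age_group[1L], n = nrow(d),
               n_dominant_above = sum(d$dominant_khz > cutoff_khz),
               frac_dominant_above = mean(d$dominant_khz > cutoff_khz),
               n_all_energy_above = sum(d$min_khz > cutoff_khz),
               frac_all_energy_above = mean(d$min_khz > cutoff_khz),
               row.names = NULL)
  }))
}

#' Spectral purity census
#'
#' Per-age fractions of tonal, harmonic and nonlinear syllables
#' (fractions sum to 1 within each age).
#'
#' @param classified Classified (or raw annotation) data.frame.
#' @return data.frame per age group with `n` and one fraction column per
#'   purity class.
#' @export
purity_census <- function(classified) {
  do.call(rbind, lapply(split(classified, classified$age_group), function(d) {
    p <- table(factor(d$purity, purity_levels())) / nrow(d)
    data.frame(age_group = d$age_group[1L], n = nrow(d),
               frac_tonal = as.numeric(p["tonal"]),
               frac_harmonic = as.numeric(p["harmonic"]),
               frac_nonlinear = as.numeric(p["nonlinear"]),
               row.names = NULL)
  }))
}

#' Descriptive statistics of duration and dominant frequency
#'
#' Mean, sample SD, median, normal-approximation 95% CI of the mean, and
#' Fisher excess kurtosis (sample-moment estimator; normal
#' distributions score 0) for syllable duration and dominant frequency,
#' per grouping cell. Kurtosis is reported as `NA` for groups with fewer
#' than 4 observations or zero variance rather than fabricated.
#'
#' @param classified Classified data.frame.
#' @param by Grouping columns (default age group and syllable type).
#' @return data.frame, one row per group x variable.
#' @export
descriptive_stats <- function(classified, by = c("age_group", "syll_type")) {
  groups <- split(classified, classified[by], drop = TRUE)
  out <- lapply(groups, function(d) {
    do.call(rbind, lapply(c(duration_ms = "duration_ms",
                            dominant_khz = "dominant_khz"), function(v) {
      x <- d[[v]]
      n <- length(x); m <- mean(x)
      s <- if (n > 1L) sd(x) else NA_real_
      se <- if (n > 1L) s / sqrt(n) else NA_real_
      cbind(d[1L, by, drop = FALSE],
            data.frame(variable = v, n = n, mean = m, sd = s,
                       median = median(x),
                       ci95_lo = m - 1.96 * se, ci95_hi = m + 1.96 * se,
                       excess_kurtosis = excess_kurtosis(x),
                       row.names = NULL))
    }))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Fisher excess kurtosis (sample-moment estimator)
#'
#' `m4 / m2^2 - 3` with central sample moments; `NA` for fewer than 4
#' observations or constant samples.
#'
#' @param x Numeric vector.
#' @return Excess kurtosis, or `NA`.
#' @export
#' @examples
#' excess_kurtosis(c(0, 0, 1, 1))   # -2, the Bernoulli(1/2) closed form
excess_kurtosis <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 4L) return(NA_real_)
  m2 <- mean((x - mean(x))^2)
  if (m2 == 0) return(NA_real_)
  mean((x - mean(x))^4) / m2^2 - 3
}
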