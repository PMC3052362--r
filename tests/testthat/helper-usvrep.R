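# shared fixture builders (all fixtures are constructed in code)

# one annotation row in the standard dialect
ann_row <- function(id, onset, offset, elements,
                    reversals = 0L, purity = "tonal",
                    fundamental = NA_real_, noisy = FALSE,
                    age = "adult", animal = "m1") {
  data.frame(id = id, animal_id = animal, age_group = age,
             onset_ms = onset, offset_ms = offset, purity = purity,
             is_noisy_broadband = noisy, fundamental_khz = fundamental,
             reversals = reversals, elements = elements,
             stringsAsFactors = FALSE)
}

# a timed annotation table from durations and silent gaps (single animal)
ann_stream <- function(durations, gaps, elements = "74/76/75/72/78",
                       age = "adult", animal = "m1") {
  onset <- cumsum(c(0, gaps + durations[-length(durations)]))
  do.call(rbind, lapply(seq_along(durations), function(i) {
    ann_row(sprintf("s%03d", i), onset[i], onset[i] + durations[i],
            elements, age = age, animal = animal)
  }))
}

# random valid single-element record for fuzzing the classifier
random_record <- function(id = "r") {
  track <- runif(3, 20, 120)
  el <- matrix(c(track, min(track) - runif(1, 0, 3), max(track) + runif(1, 0, 3)),
               1, dimnames = list(NULL, c("start", "center", "end", "min", "max")))
  n_el <- sample(1:3, 1)
  if (n_el > 1) {
    el <- do.call(rbind, lapply(seq_len(n_el), function(i) {
      tr <- runif(3, 20, 120)
      matrix(c(tr, min(tr) - 1, max(tr) + 1), 1,
             dimnames = list(NULL, colnames(el)))
    }))
  }
  syllable_record(id, 0, runif(1, 1, 120), el,
                  reversals = sample(0:3, 1),
                  purity = sample(purity_levels(), 1),
                  fundamental = if (runif(1) < 0.15) runif(1, 1, 60) else NA_real_,
                  is_noisy_broadband = runif(1) < 0.1)
}

# independent brute-force entropy oracle: enumerate observed
# (order)-grams from raw sequences and sum -p log2 p terms directly
oracle_entropy <- function(seqs, order) {
  if (order == 0) return(log2(length(unique(unlist(seqs)))))
  collect <- function(len) {
    unlist(lapply(seqs, function(s) {
      L <- length(s)
      if (L < len) return(character(0))
      vapply(seq_len(L - len + 1L),
             function(i) paste(s[i:(i + len - 1L)], collapse = "\x01"), "")
    }))
  }
  H <- function(keys) {
    p <- as.numeric(table(keys)) / length(keys)
    -sum(p * log2(p))
  }
  if (order == 1) return(H(collect(1L)))
  H(collect(order)) - H(vapply(strsplit(collect(order), "\x01", fixed = TRUE),
                               function(v) paste(v[-length(v)], collapse = "\x01"), ""))
}

# G statistic (2 sum O ln(O/E)) of independence on a pair-count matrix
g_statistic <- function(m) {
  n <- sum(m)
  e <- outer(rowSums(m), colSums(m)) / n
  keep <- m > 0
  2 * sum(m[keep] * log(m[keep] / e[keep]))
}
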