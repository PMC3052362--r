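#' Fit an age profile from bouts
#'
#' Estimates the generative parameters of the virtual vocal organ for
#' one age group: the bout-initial type distribution (from first-in-bout
#' counts over all bouts), the overall type probabilities (all tokens),
#' and maximum-likelihood transition tables conditioning on the previous
#' 1, 2 and 3 syllables (pairs/triplets/quadruples from bouts with more
#' than 3 syllables). Unseen contexts are handled at generation time by
#' backing off to the next-shorter context and finally to the type
#' probabilities.
#'
#' @param bouts Bouts or type sequences from a single age group.
#' @param templates Named list of [syllable_template()]s, one per type
#'   used; defaults to [default_templates()] for `age_group` when that
#'   is supplied.
#' @param mean_interval Inter-syllable silence for synthesis, ms. When
#'   `NULL` and the bouts carry timing, the median within-bout interval
#'   is used (the robust location for right-skewed intervals).
#' @param age_group Optional age label (one of [age_groups()]).
#' @return List of class `usv_profile`: `age_group`, `initial_probs`,
#'   `type_probs`, `trans1` (matrix, contexts in rows), `trans2`,
#'   `trans3` (matrices with `"a|b"`-style context rownames),
#'   `templates`, `mean_interval`, `types`.
#' @export
fit_profile <- function(bouts, templates = NULL, mean_interval = NULL,
                        age_group = NULL) {
  seqs <- .bout_sequences(bouts)
  if (!length(seqs)) usv_error("no bouts to fit", "usvrep_unfittable")
  qual <- seqs[lengths(seqs) >= 4L]
  if (!length(qual)) {
    usv_error("no bouts with more than 3 syllables; profile is unfittable",
              "usvrep_unfittable")
  }
  types <- .type_levels(unlist(seqs, use.names = FALSE))
  first <- vapply(seqs, `[`, "", 1L)
  initial <- table(factor(first, types)) / length(first)
  tokens <- unlist(seqs, use.names = FALSE)
  type_probs <- table(factor(tokens, types)) / length(tokens)

  if (is.null(mean_interval)) {
    blist <- .as_bout_list(bouts)
    ivs <- unlist(lapply(blist, function(b)
      if (inherits(b, "usv_bout")) b$intervals else numeric(0)))
    if (length(ivs)) mean_interval <- median(ivs)
  }
  if (is.null(templates) && !is.null(age_group)) {
    templates <- default_templates(age_group)
  }
  prof <- structure(list(
    age_group = age_group,
    initial_probs = .as_prob_vector(initial),
    type_probs = .as_prob_vector(type_probs),
    trans1 = .context_table(qual, 1L, types),
    trans2 = .context_table(qual, 2L, types),
    trans3 = .context_table(qual, 3L, types),
    templates = templates,
    mean_interval = mean_interval,
    types = types), class = "usv_profile")
  validate_profile(prof)
  prof
}

.as_prob_vector <- function(tab) {
  v <- as.numeric(tab)
  names(v) <- names(tab)
  v
}

# row-stochastic table of P(next | previous `k` types); rows are only
# the observed contexts, named "a|b|..." for k > 1
.context_table <- function(seqs, k, types) {
  ctx <- character(0); nxt <- character(0)
  for (s in seqs) {
    L <- length(s)
    if (L < k + 1L) next
    pos <- seq_len(L - k)
    cols <- lapply(seq_len(k) - 1L, function(o) s[pos + o])
    ctx <- c(ctx, do.call(paste, c(cols, sep = "|")))
    nxt <- c(nxt, s[pos + k])
  }
  if (!length(ctx)) return(NULL)
  counts <- unclass(table(ctx, factor(nxt, types)))
  dimnames(counts) <- list(rownames(counts), colnames(counts))
  counts / rowSums(counts)
}

#' Validate an age profile
#'
#' Every stored distribution must sum to 1 within 1e-9, and every type
#' with nonzero probability must have a template when templates are
#' present.
#'
#' @param profile A `usv_profile`.
#' @return The profile, invisibly.
#' @export
validate_profile <- function(profile) {
  chk <- function(p, what) {
    if (length(p) && abs(sum(p) - 1) > 1e-9) {
      usv_error(sprintf("%s does not sum to 1", what), "usvrep_profile")
    }
    if (any(p < 0)) usv_error(sprintf("%s has negative entries", what), "usvrep_profile")
  }
  chk(profile$initial_probs, "initial_probs")
  chk(profile$type_probs, "type_probs")
  for (nm in c("trans1", "trans2", "trans3")) {
    m <- profile[[nm]]
    if (!is.null(m)) apply(m, 1L, chk, what = nm)
  }
  if (!is.null(profile$templates)) {
    need <- names(profile$type_probs)[profile$type_probs > 0]
    missing <- setdiff(need, names(profile$templates))
    if (length(missing)) {
      usv_error(sprintf("types without a template: %s",
                        paste(missing, collapse = ", ")), "usvrep_profile")
    }
  }
  invisible(profile)
}

# distribution over next type for a context vector, with back-off:
# full context -> shorter context -> type_probs
.next_distribution <- function(profile, context) {
  k <- length(context)
  while (k > 0L) {
    tab <- profile[[paste0("trans", k)]]
    if (!is.null(tab)) {
      key <- paste(utils::tail(context, k), collapse = "|")
      if (key %in% rownames(tab)) {
        p <- setNames(tab[key, ], colnames(tab))
        if (sum(p) > 0) return(p)
      }
    }
    k <- k - 1L
  }
  profile$type_probs
}

#' Generate a syllable sequence from a profile
#'
#' Pseudo-random Markov generation: the first syllable is drawn from the
#' bout-initial probabilities; each later syllable is drawn from the
#' transition distribution of the requested order given the most recent
#' `min(order, t - 1)` syllables, backing off to shorter contexts (and
#' finally the type probabilities) when a context was never observed.
#' Identical `(profile, order, length, seed)` give identical sequences.
#'
#' @param profile A `usv_profile`.
#' @param order Conditioning-context length, 1, 2 or 3.
#' @param length Number of syllables (>= 1).
#' @param seed Integer seed.
#' @return List of class `usv_generated_bout`: `types`, `order`, `seed`,
#'   `age_group`.
#' @export
generate_sequence <- function(profile, order, length, seed) {
  if (!(order %in% 1:3)) usv_error("order must be 1, 2 or 3", "usvrep_parameter")
  if (length < 1) usv_error("length must be >= 1", "usvrep_parameter")
  validate_profile(profile)
  set.seed(as.integer(seed))
  types <- names(profile$type_probs)
  out <- character(length)
  out[1L] <- sample(types, 1L, prob = profile$initial_probs[types])
  t <- 2L
  while (t <= length) {
    ctx <- out[max(1L, t - order):(t - 1L)]
    p <- .next_distribution(profile, ctx)
    out[t] <- sample(names(p), 1L, prob = p)
    t <- t + 1L
  }
  structure(list(types = out, order = as.integer(order),
                 seed = as.integer(seed), age_group = profile$age_group),
            class = "usv_generated_bout")
}

#' Most probable bout under the greedy rule
#'
#' Greedy argmax chain mirroring the construction of the most probable
#' 10-syllable bouts: the first syllable is the most probable
#' bout-initial type; the second maximises the transition probability
#' given the first; every later syllable maximises the probability of
#' following the previous *two* syllables. Ties break alphabetically;
#' unseen contexts back off to shorter contexts.
#'
#' @param profile A `usv_profile`.
#' @param length Bout length (default 10).
#' @return Character vector of syllable types.
#' @export
most_probable_bout <- function(profile, length = 10) {
  validate_profile(profile)
  out <- character(length)
  out[1L] <- .argmax_alpha(profile$initial_probs)
  if (length >= 2L) {
    out[2L] <- .argmax_alpha(.next_distribution(profile, out[1L]))
  }
  t <- 3L
  while (t <= length) {
    out[t] <- .argmax_alpha(.next_distribution(profile, out[c(t - 2L, t - 1L)]))
    t <- t + 1L
  }
  out
}

# alphabetical tie-break: among maxima, the alphabetically first name
.argmax_alpha <- function(p) {
  nm <- names(p)[p == max(p)]
  sort(nm)[1L]
}
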