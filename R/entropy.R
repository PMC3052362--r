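#' Harvest n-grams from bout sequences
#'
#' Collects all (order + 1)-grams of syllable types lying fully inside
#' single bouts; contexts never span bout boundaries, and bouts shorter
#' than order + 1 are skipped for that order.
#'
#' @param bouts A `usv_segmentation`, list of `usv_bout`, or list of
#'   character type sequences.
#' @param order Context length k (0-4); grams are (k+1)-tuples.
#' @return List of class `usv_ngram_model`: `order`, `grams`
#'   (data.frame with symbol columns `s1..s(k+1)` and count `n`),
#'   `n_grams` (total grams harvested), `n_tokens` (total syllables in
#'   the bouts), `types` (sorted inventory over all tokens), `c`.
#' @export
ngram_model <- function(bouts, order) {
  if (!is.numeric(order) || length(order) != 1L || order < 0 || order > 4) {
    usv_error("order must be in 0..4", "usvrep_parameter")
  }
  order <- as.integer(order)
  seqs <- .bout_sequences(bouts)
  if (!length(seqs)) usv_error("no bouts", "usvrep_insufficient_sequence")
  tokens <- unlist(seqs, use.names = FALSE)
  g <- order + 1L
  keys <- unlist(lapply(seqs, function(s) {
    L <- length(s)
    if (L < g) return(character(0))
    if (g == 1L) return(s)
    pos <- seq_len(L - g + 1L)
    cols <- lapply(seq_len(g) - 1L, function(o) s[pos + o])
    do.call(paste, c(cols, sep = "\r"))
  }), use.names = FALSE)
  if (!length(keys)) {
    usv_error(sprintf("no bout long enough for order %d", order),
              "usvrep_insufficient_sequence")
  }
  tab <- table(keys)
  sym <- do.call(rbind, strsplit(names(tab), "\r", fixed = TRUE))
  grams <- as.data.frame(sym, stringsAsFactors = FALSE)
  names(grams) <- paste0("s", seq_len(g))
  grams$n <- as.integer(tab)
  structure(list(order = order, grams = grams,
                 n_grams = sum(grams$n), n_tokens = length(tokens),
                 types = sort(unique(tokens)), c = length(unique(tokens))),
            class = "usv_ngram_model")
}

# plug-in Shannon entropy (bits) of a count vector; zero counts
# contribute 0 by the limit convention
.shannon_bits <- function(n) {
  n <- n[n > 0]
  p <- n / sum(n)
  -sum(p * log2(p))
}

#' Plug-in sequence entropy at a given order
#'
#' Orders are defined by the length of the conditioning context plus
#' one: `H0 = log2(c)` with `c` the number of syllable types observed;
#' `H1` is the Shannon entropy of type frequencies; for `m >= 2`, `Hm`
#' is the conditional entropy (bits) of a syllable given its `m - 1`
#' predecessors. All estimates are plug-in (maximum likelihood), with
#' zero-probability terms contributing 0.
#'
#' When `order < model$order + 1`, the entropy is computed by
#' marginalising the model's gram table onto the final `order` symbol
#' positions, i.e. conditioning on the *suffix* of the stored context.
#' Entropies of successive orders taken from the same model therefore
#' share one joint sample and are exactly non-increasing. For an
#' order-0 model, `H1` is the unigram entropy over all harvested
#' tokens.
#'
#' @param model A `usv_ngram_model`.
#' @param order Requested entropy order, `0 <= order <= model$order + 1`.
#' @return Entropy in bits.
#' @export
#' @examples
#' m <- ngram_model(list(rep(c("a", "b"), 10)), order = 1)
#' seq_entropy(m, 2)   # 0 bits: deterministic alternation
seq_entropy <- function(model, order) {
  if (!inherits(model, "usv_ngram_model")) {
    usv_error("model must be a usv_ngram_model", "usvrep_parameter")
  }
  if (model$n_grams < 1L) usv_error("empty model", "usvrep_undefined_entropy")
  g <- model$order + 1L
  if (order < 0 || order > g) {
    usv_error(sprintf("order %d not available from an order-%d model",
                      order, model$order), "usvrep_parameter")
  }
  if (order == 0) return(log2(model$c))
  grams <- model$grams
  # joint over the last `order` symbols; context over the last `order - 1`
  joint_cols <- paste0("s", seq(g - order + 1L, g))
  joint_n <- .collapse_counts(grams, joint_cols)
  h_joint <- .shannon_bits(joint_n)
  if (order == 1L) return(h_joint)
  ctx_n <- .collapse_counts(grams, joint_cols[-length(joint_cols)])
  h_joint - .shannon_bits(ctx_n)
}

.collapse_counts <- function(grams, cols) {
  key <- do.call(paste, c(grams[cols], sep = "\r"))
  as.numeric(rowsum(grams$n, key))
}

#' Full entropy report for a set of bouts
#'
#' Computes H0 through `max_order`, each from its own per-order n-gram
#' harvest (H1 from all tokens), the adjacent-order entropy drops, and
#' the chi-squared drop tests. Monotonicity H0 >= H1 >= ... is asserted.
#'
#' @param bouts Bouts or type sequences (see [ngram_model()]).
#' @param max_order Highest entropy order (default 4).
#' @return List of class `usv_entropy_report`: `H` (named numeric,
#'   orders 0..max_order), `deltas`, `tests` (data.frame: comparison,
#'   statistic, df, p_value), `c`, `n_tokens`.
#' @export
entropy_report <- function(bouts, max_order = 4) {
  if (max_order < 1 || max_order > 4) {
    usv_error("max_order must be in 1..4", "usvrep_parameter")
  }
  models <- lapply(seq_len(max_order) - 1L, function(k) ngram_model(bouts, k))
  H <- numeric(max_order + 1L)
  names(H) <- paste0("H", 0:max_order)
  H[1L] <- seq_entropy(models[[1L]], 0)
  for (m in seq_len(max_order)) H[m + 1L] <- seq_entropy(models[[m]], m)
  if (any(diff(H) > 1e-9)) {
    usv_error("entropy estimates are not non-increasing in order; sequences are too sparse for the requested orders",
              "usvrep_undefined_entropy")
  }
  tests <- do.call(rbind, lapply(seq_len(max_order), function(m) {
    tt <- entropy_drop_test(models[[m]], m - 1L, m)
    data.frame(comparison = sprintf("H%d-H%d", m - 1L, m),
               statistic = tt$statistic, df = tt$df, p_value = tt$p_value,
               n = tt$n, row.names = NULL)
  }))
  structure(list(H = H, deltas = setNames(-diff(H),
                                          sprintf("H%d-H%d", 0:(max_order - 1L), 1:max_order)),
                 tests = tests, c = models[[1L]]$c,
                 n_tokens = models[[1L]]$n_tokens),
            class = "usv_entropy_report")
}

#' @export
print.usv_entropy_report <- function(x, ...) {
  cat("usv_entropy_report (", x$n_tokens, " syllables, ", x$c, " types)\n", sep = "")
  print(round(x$H, 4))
  invisible(x)
}

# degrees of freedom for the drop from H_level to H_{level+1}
# (Chatfield & Lemon): level 0 -> c-1, level j>=1 -> c^(j-1) (c-1)^2
.df_level <- function(level, c) {
  if (level == 0L) c - 1 else c^(level - 1) * (c - 1)^2
}

#' Chi-squared test of an entropy drop between orders
#'
#' Tests whether entropy decreases significantly between two orders:
#' `T = 2 * N * ln(2) * (H_lower - H_higher)`, chi-squared with df
#' summed over the levels spanned (level j contributes `c - 1` for
#' j = 0 and `c^(j-1) * (c-1)^2` for j >= 1). Both entropies are
#' computed from the *same* n-gram table (suffix-context
#' marginalisation, see [seq_entropy()]), so for adjacent orders T is
#' exactly the G statistic (2 * sum O log(O/E)) of the corresponding
#' conditional-independence test, and a non-adjacent T is the sum of
#' the adjacent Ts it spans. `N` is the number of harvested n-grams
#' (the sequence positions entering the table; equal to the token count
#' for an order-0 model).
#'
#' @param model A `usv_ngram_model` with `model$order >= higher - 1`.
#' @param lower,higher Entropy orders to compare, `lower < higher`.
#' @return List: `statistic` (T), `df`, `p_value`, `drop_bits`, `n`.
#' @export
entropy_drop_test <- function(model, lower, higher) {
  if (lower >= higher) usv_error("need lower < higher", "usvrep_parameter")
  h_lo <- seq_entropy(model, lower)
  h_hi <- seq_entropy(model, higher)
  drop <- h_lo - h_hi
  note <- NULL
  if (drop < 0) {   # cannot occur for shared-table entropies; kept as a guard
    note <- "non-positive entropy drop floored at 0"
    drop <- 0
  }
  stat <- 2 * model$n_grams * log(2) * drop
  df <- sum(vapply(seq(lower, higher - 1L), .df_level, 0, c = model$c))
  out <- list(statistic = stat, df = df,
              p_value = pchisq(stat, df, lower.tail = FALSE),
              drop_bits = drop, n = model$n_grams)
  if (!is.null(note)) out$note <- note
  out
}

#' Compare an entropy drop between two repertoires
#'
#' Heterogeneity test of whether the entropy reduction between two
#' orders differs between repertoires (e.g. ages). Two variants are
#' provided, since the classical formulation admits more than one
#' reading:
#'
#' * `"difference"` (default): `T = 2 * ln(2) * |N_a * dH_a - N_b * dH_b|`
#'   with df the sum of the two drops' dfs — the scaled difference of
#'   the two repertoires' drop statistics.
#' * `"pooled"`: the likelihood-ratio heterogeneity statistic
#'   `(T_a + T_b) - T_pooled`, where `T_pooled` is the drop statistic of
#'   the combined gram table; df uses the pooled type inventory.
#'
#' Larger repertoires with more syllable types yield larger T, so the
#' comparison presumes comparable type inventories; a warning is issued
#' when they differ by more than `margin` types.
#'
#' @param model_a,model_b `usv_ngram_model`s of equal order covering the
#'   requested orders.
#' @param lower,higher Entropy orders of the drop.
#' @param method `"difference"` or `"pooled"`.
#' @param margin Comparability margin on the type-inventory sizes.
#' @return List: `statistic`, `df`, `p_value`, `drop_a`, `drop_b`,
#'   `method`.
#' @export
cross_group_test <- function(model_a, model_b, lower, higher,
                             method = c("difference", "pooled"), margin = 2) {
  method <- match.arg(method)
  if (model_a$order != model_b$order) {
    usv_error("models must have the same order", "usvrep_parameter")
  }
  if (abs(model_a$c - model_b$c) > margin) {
    warning(sprintf("type inventories differ by more than %d types (%d vs %d); T is inflated by inventory size",
                    margin, model_a$c, model_b$c))
  }
  ta <- entropy_drop_test(model_a, lower, higher)
  tb <- entropy_drop_test(model_b, lower, higher)
  if (method == "difference") {
    stat <- abs(ta$statistic - tb$statistic)
    df <- ta$df + tb$df
  } else {
    pooled <- .pool_models(model_a, model_b)
    tp <- entropy_drop_test(pooled, lower, higher)
    stat <- max(ta$statistic + tb$statistic - tp$statistic, 0)
    df <- sum(vapply(seq(lower, higher - 1L), .df_level, 0, c = pooled$c))
  }
  list(statistic = stat, df = df,
       p_value = pchisq(stat, df, lower.tail = FALSE),
       drop_a = ta$drop_bits, drop_b = tb$drop_bits, method = method)
}

.pool_models <- function(a, b) {
  grams <- rbind(a$grams, b$grams)
  cols <- setdiff(names(grams), "n")
  key <- do.call(paste, c(grams[cols], sep = "\r"))
  n <- rowsum(grams$n, key)
  sym <- do.call(rbind, strsplit(rownames(n), "\r", fixed = TRUE))
  gd <- as.data.frame(sym, stringsAsFactors = FALSE)
  names(gd) <- cols
  gd$n <- as.integer(n)
  types <- sort(unique(c(a$types, b$types)))
  structure(list(order = a$order, grams = gd, n_grams = sum(gd$n),
                 n_tokens = a$n_tokens + b$n_tokens,
                 types = types, c = length(types)),
            class = "usv_ngram_model")
}
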