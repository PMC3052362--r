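#' Calibrate a transition matrix to a target switching probability
#'
#' Constructs a first-order transition matrix whose stationary
#' distribution equals `type_probs` and whose expected repetition
#' probability `sum_i pi_i P(i->i)` equals `1 - switch_target`. The
#' matrix is a diagonal loading of the product-form (i.i.d.) kernel:
#' `P(i->j) = (1 - a) p_j + a 1[i == j]`, which leaves the stationary
#' distribution at `p` for every admissible `a`; `a` is solved in
#' closed form from the switch target and the construction is verified
#' against the stationarity condition to 1e-9.
#'
#' @param type_probs Named probability vector (>= 2 types, sums to 1).
#' @param switch_target Desired probability of a type switch between
#'   consecutive syllables, in (0, 1).
#' @return Row-stochastic matrix with attributes `stationary` and
#'   `switch_target`.
#' @export
#' @examples
#' calibrate_transitions(c(a = 0.5, b = 0.5), 0.5)   # the i.i.d. matrix
calibrate_transitions <- function(type_probs, switch_target) {
  p <- type_probs / sum(type_probs)
  if (length(p) < 2L) usv_error("need at least 2 types", "usvrep_parameter")
  if (switch_target <= 0 || switch_target >= 1) {
    usv_error("switch_target must be in (0, 1)", "usvrep_parameter")
  }
  rep_target <- 1 - switch_target
  s2 <- sum(p^2)
  a <- (rep_target - s2) / (1 - s2)
  a_min <- -min(p) / (1 - min(p))
  if (a > 1 || a < a_min) {
    lo <- 1 - (s2 + a_min * (1 - s2))   # largest feasible switch
    usv_error(sprintf(
      "switch_target %.3f infeasible for these proportions: achievable range is (0, %.3f]",
      switch_target, lo), "usvrep_calibration")
  }
  k <- length(p)
  P <- (1 - a) * matrix(p, k, k, byrow = TRUE) + a * diag(k)
  dimnames(P) <- list(names(p), names(p))
  stat_err <- max(abs(as.numeric(p %*% P) - p))
  if (stat_err > 1e-9) {
    usv_error(sprintf("stationarity violated (err %.2e)", stat_err),
              "usvrep_calibration")
  }
  attr(P, "stationary") <- p
  attr(P, "switch_target") <- switch_target
  P
}

#' Rank-frequency power-law type probabilities
#'
#' Probabilities proportional to `rank^exponent` (exponent <= 0 for a
#' Zipf-like profile). Fitting [zipf_slope()] to the exact expected
#' counts of such a profile recovers the exponent to machine precision.
#'
#' @param n_types Number of types (>= 2).
#' @param exponent Power-law exponent (-1 is the canonical Zipf
#'   balance; more negative is more repetitious).
#' @return Numeric probability vector in rank order (unnamed).
#' @export
#' @examples
#' calibrate_zipf(4, -1)   # 12/25, 6/25, 4/25, 3/25
calibrate_zipf <- function(n_types, exponent) {
  if (n_types < 2L) usv_error("need at least 2 types", "usvrep_parameter")
  w <- seq_len(n_types)^exponent
  w / sum(w)
}
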