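#' Shannon entropy of a whole histogram
#'
#' `J = -sum_o q_o log_base(q_o)` over all gray levels, with the convention
#' `0 * log 0 = 0`.  Base 2 gives bits (default); base 10 hartleys; base
#' `exp(1)` nats.  The maximizing threshold vector of the segmentation
#' criterion is invariant to the base.
#'
#' @param hist A [gray_histogram()].
#' @param base Logarithm base: 2, `exp(1)` or 10.
#' @return Non-negative numeric scalar.
#' @examples
#' h <- gray_histogram(c(0.5, 0.25, 0, 0.25))
#' total_entropy(h)           # 1.5 bits
#' total_entropy(h, base = 10)
#' @export
total_entropy <- function(hist, base = 2) {
  if (!is_gray_histogram(hist)) abort_domain("`hist` must be a gray_histogram")
  check_base(base)
  p <- hist$probs[hist$probs > 0]
  -sum(p * log(p)) / log(base)
}

check_base <- function(base) {
  if (!is.numeric(base) || length(base) != 1L || base <= 0 || base == 1) {
    abort_domain("`base` must be a single positive number != 1 (2, exp(1), or 10)")
  }
  invisible(base)
}

#' Entropy of one histogram class
#'
#' Entropy of the sub-histogram over gray levels `[lo, hi)` normalized by
#' the class probability mass `e = sum_{lo <= o < hi} q_o`:
#' `-sum (q_o / e) log(q_o / e)`.  An empty class (`e = 0`) is infeasible
#' and returns `NA`.
#'
#' @inheritParams total_entropy
#' @param lo,hi Gray-level bounds, `0 <= lo < hi <= Z`; the class covers
#'   levels `lo .. hi - 1`.
#' @return Numeric scalar, or `NA` for an empty class.
#' @export
class_entropy <- function(hist, lo, hi, base = 2) {
  if (!is_gray_histogram(hist)) abort_domain("`hist` must be a gray_histogram")
  check_base(base)
  Z <- hist$n_levels
  if (lo < 0 || hi > Z || lo >= hi) {
    abort_domain(sprintf("invalid class range [%s, %s) for Z = %d", lo, hi, Z))
  }
  q <- hist$probs[(lo + 1):hi]
  e <- sum(q)
  if (e <= 0) {
    return(NA_real_)
  }
  p <- q[q > 0] / e
  -sum(p * log(p)) / log(base)
}

#' Maximum-entropy (Kapur) segmentation objective
#'
#' Total criterion `J(u) = sum_{i=0}^{m} J_i`: the sum of the within-class
#' entropies of the `m + 1` classes induced by the threshold vector.  A
#' vector that leaves any class with zero probability mass is infeasible
#' and returns `NA`; without this rule the criterion degenerately prefers
#' piling all mass into one class.
#'
#' @inheritParams total_entropy
#' @param thresholds A [threshold_vector()] (or integer vector of cuts).
#' @return Numeric scalar `J`, or `NA` if any induced class is empty.
#' @examples
#' h <- gray_histogram(rep(0.25, 4))
#' kapur_objective(h, threshold_vector(2L, n_levels = 4))  # 2 bits
#' @export
kapur_objective <- function(hist, thresholds, base = 2) {
  if (!is_gray_histogram(hist)) abort_domain("`hist` must be a gray_histogram")
  check_base(base)
  if (!is_threshold_vector(thresholds)) {
    thresholds <- threshold_vector(thresholds, n_levels = hist$n_levels)
  }
  if (thresholds$n_levels != hist$n_levels) {
    abort_domain("threshold vector and histogram disagree on Z")
  }
  tab <- entropy_tables(hist$probs)
  kapur_eval(tab, matrix(thresholds$cuts, ncol = 1L), hist$n_levels) / log(base)
}

# Prefix tables for O(1) class-entropy evaluation:
# S0[k + 1] = sum of q over levels 0..k-1, T0 likewise for q*log(q) (nats).
entropy_tables <- function(probs) {
  ql <- ifelse(probs > 0, probs * log(probs), 0)
  list(S = c(0, cumsum(probs)), T = c(0, cumsum(ql)))
}

# Vectorized objective in nats over a matrix of cut vectors (m x K).
# Returns NA for infeasible columns (any zero-mass class).
kapur_eval <- function(tab, cuts, n_levels) {
  m <- nrow(cuts)
  K <- ncol(cuts)
  bounds <- rbind(0L, cuts, n_levels)
  J <- numeric(K)
  feasible <- rep(TRUE, K)
  for (i in seq_len(m + 1L)) {
    lo <- bounds[i, ]
    hi <- bounds[i + 1L, ]
    e <- tab$S[hi + 1L] - tab$S[lo + 1L]
    t <- tab$T[hi + 1L] - tab$T[lo + 1L]
    ok <- e > 1e-300
    feasible <- feasible & ok
    J <- J + ifelse(ok, log(pmax(e, 1e-300)) - t / pmax(e, 1e-300), 0)
  }
  J[!feasible] <- NA_real_
  J
}

#' Exhaustive objective landscape
#'
#' Enumerates every threshold vector for `m` cuts over `Z` levels and
#' tabulates the objective.  Guarded: refuses enumerations larger than
#' `max_evals` (reduce `Z` or `m` for diagnostics).
#'
#' @inheritParams kapur_objective
#' @param m Number of thresholds.
#' @param max_evals Enumeration guard (default 2e6 vectors).
#' @return `data.frame` with columns `u_1..u_m`, `objective`, `feasible`.
#' @export
objective_landscape <- function(hist, m, base = 2, max_evals = 2e6) {
  if (!is_gray_histogram(hist)) abort_domain("`hist` must be a gray_histogram")
  check_base(base)
  m <- as.integer(m)
  Z <- hist$n_levels
  if (m < 1L || m > Z - 1L) abort_domain("need 1 <= m <= Z - 1")
  n_comb <- choose(Z - 1L, m)
  if (n_comb > max_evals) {
    abort_resource(sprintf(
      "enumeration of %g threshold vectors exceeds guard %g; reduce Z (e.g. to %d) or m",
      n_comb, max_evals, max(2L, as.integer(2^floor(log2(Z / 2))))
    ))
  }
  cuts <- utils::combn(seq_len(Z - 1L), m)
  J <- kapur_eval(entropy_tables(hist$probs), cuts, Z) / log(base)
  out <- as.data.frame(t(cuts))
  names(out) <- paste0("u_", seq_len(m))
  out$objective <- J
  out$feasible <- !is.na(J)
  out
}
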