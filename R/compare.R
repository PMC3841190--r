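# Profile-column and fragment-level similarity scores.
# All divergences use log base 2, so the Jensen-Shannon divergence of
# two probability rows lies in [0, 1] (0 = identical columns).

check_prob_vector <- function(p, arg, tol = 1e-6) {
  if (any(p < -tol)) abort(sprintf("`%s` has negative entries.", arg))
  if (abs(sum(p) - 1) > tol) {
    abort(sprintf("`%s` is not normalized (sums to %.8f).", arg, sum(p)))
  }
}

#' Kullback-Leibler divergence between two letter distributions
#'
#' Computed in bits: `sum(P * log2(P / Q))` with the convention
#' `0 * log(0 / q) = 0`.  Infinite when `P` puts mass where `Q` has
#' none; inside the package `Q` is always a Jensen-Shannon mixture, so
#' this never occurs downstream.
#'
#' @param p,q probability vectors over the same letters (sums within
#'   1e-6 of 1).
#' @return nonnegative scalar (bits); 0 iff `p == q`.
#' @export
#' @examples
#' kl_divergence(c(1, rep(0, 26)), rep(1 / 27, 27))  # log2(27)
kl_divergence <- function(p, q) {
  if (length(p) != length(q)) abort("`p` and `q` must have equal length.")
  check_prob_vector(p, "p"); check_prob_vector(q, "q")
  pos <- p > 0
  if (any(pos & q == 0)) return(Inf)
  sum(p[pos] * log2(p[pos] / q[pos]))
}

#' Jensen-Shannon divergence between two letter distributions
#'
#' `0.5 * KL(P, M) + 0.5 * KL(Q, M)` with `M = (P + Q) / 2`, in bits.
#' Symmetric, always finite, and bounded in \[0, 1\].
#'
#' @inheritParams kl_divergence
#' @return scalar in \[0, 1\]; 0 iff `p == q`.
#' @export
js_distance <- function(p, q) {
  if (length(p) != length(q)) abort("`p` and `q` must have equal length.")
  check_prob_vector(p, "p"); check_prob_vector(q, "q")
  # entropy identity H(M) - (H(P) + H(Q)) / 2: equal to the KL form but
  # immune to denormal underflow in P / M
  m <- rbind((p + q) / 2)
  unname(row_entropy(m) - (row_entropy(rbind(p)) + row_entropy(rbind(q))) / 2)
}

# row entropies in bits, 0 log 0 := 0 (NA rows stay NA)
row_entropy <- function(m) {
  -rowSums(m * log2(pmax(m, .Machine$double.xmin)))
}

# Jensen-Shannon between matched rows of A and B (vectorized)
js_rows <- function(A, B) {
  M <- (A + B) / 2
  row_entropy(M) - (row_entropy(A) + row_entropy(B)) / 2
}

# full nq x nb Jensen-Shannon matrix between rows of A and rows of B;
# NA rows (chain-break windows) propagate to NA scores
js_cross <- function(A, B) {
  ha <- row_entropy(A)
  hb <- row_entropy(B)
  out <- matrix(NA_real_, nrow(A), nrow(B))
  for (i in seq_len(nrow(A))) {
    if (is.na(ha[i])) next
    M <- (matrix(A[i, ], nrow(B), ncol(B), byrow = TRUE) + B) / 2
    out[i, ] <- row_entropy(M) - (ha[i] + hb) / 2
  }
  out
}

#' A window over consecutive profile columns
#'
#' A fragment of `n` amino acids corresponds to `n - 3` consecutive
#' profile columns; `fragment_window()` marks such a span on a
#' profile.
#'
#' @param profile an [sa_profile()].
#' @param start 1-based index of the first profile column.
#' @param n_cols number of columns (fragment length minus 3).
#' @return list of class `fragment_window`.
#' @export
fragment_window <- function(profile, start, n_cols) {
  if (n_cols < 1L) abort("`n_cols` must be at least 1.")
  if (start < 1L || start + n_cols - 1L > nrow(profile)) {
    abort("window exceeds the profile bounds.")
  }
  structure(list(profile = profile, start = as.integer(start),
                 n_cols = as.integer(n_cols)),
            class = "fragment_window")
}

window_matrix <- function(w) {
  profile_matrix(w$profile)[w$start:(w$start + w$n_cols - 1L), , drop = FALSE]
}

#' Maximum Jensen-Shannon score between two fragment windows
#'
#' The dissimilarity of two equal-length fragments is the maximum,
#' over their paired profile columns, of the per-column Jensen-Shannon
#' divergence.  0 means every paired column is identical.  `NA` when a
#' window covers a chain-break column.
#'
#' @param a,b [fragment_window()]s of equal `n_cols`.
#' @return scalar in \[0, 1\] (or `NA`).
#' @export
mjs <- function(a, b) {
  if (!inherits(a, "fragment_window") || !inherits(b, "fragment_window")) {
    abort("`a` and `b` must be fragment_window objects.")
  }
  if (a$n_cols != b$n_cols) abort("windows must have the same number of columns.")
  A <- window_matrix(a)
  B <- window_matrix(b)
  if (anyNA(A) || anyNA(B)) return(NA_real_)
  max(js_rows(A, B))
}
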