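#' Initialize the online detector state
#'
#' The state carries, for every (coordinate j, signed scale b) pair, the
#' residual tail length `t[j, b]` and the tail partial-sum vector
#' `A[, j, b]` holding the sum of the last `t[j, b]` observation vectors.
#' Storage is `p^2 |B u B0|` reals plus `p |B u B0|` integers, independent
#' of how many observations have been processed.
#'
#' This is the reference implementation of the recursion; the simulation
#' harness and calibration use a compiled engine that is checked against it
#' in the test suite.
#'
#' @param p stream dimension.
#' @param grid an [scale_grid()] object (its `p` must match).
#' @return An object of class `ocd_state`.
#' @export
detector_state <- function(p, grid) {
  stopifnot(inherits(grid, "ocd_scale_grid"), grid$p == p)
  K <- length(grid$scales)
  j <- rep(seq_len(p), K)
  k <- rep(seq_len(K), each = p)
  structure(
    list(n = 0L, p = as.integer(p), grid = grid,
         t = matrix(0L, p, K),
         A = matrix(0, p, p * K),
         # precomputed index helpers
         Bmat = matrix(grid$scales, p, K, byrow = TRUE),
         diag_idx = cbind(j, (k - 1L) * p + j),
         colmat = matrix(seq_len(p * K), p, K)),
    class = "ocd_state")
}

#' Feed one observation through the reset recursion
#'
#' For every (j, b): the tail length is incremented, the new observation is
#' added to the tail partial sums, and the pair is reset to zero whenever
#' \eqn{b A^{j,j}_b - b^2 t^j_b / 2 \le 0}. The `<= 0` realizes the
#' smallest-maximizer convention of the residual tail length: `t[j, b]`
#' always equals the smallest `h` maximizing the tail likelihood-ratio sum
#' \eqn{\sum_{i=n-h+1}^n (b X_i^j - b^2/2)} (see [residual_tail_oracle()]).
#' Floating-point equality at the boundary is taken as-is, no tolerance.
#'
#' @param state an `ocd_state`.
#' @param x length-`p` numeric observation.
#' @return the updated state.
#' @export
update_state <- function(state, x) {
  if (length(x) != state$p) stop("'x' must have length p")
  state$n <- state$n + 1L
  state$t <- state$t + 1L
  state$A <- state$A + x  # x recycles down the rows of each (j, b) column
  Adiag <- matrix(state$A[state$diag_idx], state$p)
  G <- state$Bmat * Adiag - state$Bmat^2 * state$t / 2
  reset <- G <= 0
  if (any(reset)) {
    state$t[reset] <- 0L
    state$A[, state$colmat[reset]] <- 0
  }
  state
}

#' Brute-force residual tail length
#'
#' Quadratic-cost test oracle: the smallest `h` in `0..n` maximizing
#' \eqn{\sum_{i=n-h+1}^n (b x_i - b^2/2)}, with the empty sum equal to 0.
#'
#' @param history numeric vector of past observations of one coordinate.
#' @param b signed scale.
#' @return nonnegative integer tail length.
#' @export
residual_tail_oracle <- function(history, b) {
  n <- length(history)
  if (n == 0L) return(0L)
  cs <- c(0, cumsum(history))
  vals <- b * (cs[n + 1L] - cs[n + 1L - (0:n)]) - b^2 * (0:n) / 2
  as.integer(which.max(vals) - 1L)  # which.max takes the first = smallest h
}

#' Diagonal (per-coordinate) declaration statistic
#'
#' \eqn{\max_{j, b \in B \cup B_0} (b A^{j,j}_b - b^2 t^j_b / 2)}: the best
#' single-coordinate likelihood-ratio evidence over all residual tails.
#' Zero on a fresh state.
#'
#' @param state an `ocd_state`.
#' @return nonnegative real.
#' @export
diag_statistic <- function(state) {
  Adiag <- matrix(state$A[state$diag_idx], state$p)
  G <- state$Bmat * Adiag - state$Bmat^2 * state$t / 2
  max(G, 0)
}

#' Off-diagonal (cross-coordinate) declaration statistic
#'
#' For tail lengths anchored at (j, b), the other coordinates' tail sums are
#' standardized, hard-thresholded at `a_tilde` and aggregated:
#' \deqn{\max_{j, b} \sum_{j' \ne j} (E_b^{j',j})^2 1\{|E_b^{j',j}| \ge
#' \tilde a\}, \quad E_b^{j',j} = A_b^{j',j} / \sqrt{t_b^j \vee 1}.}
#' The maximum runs over `b` in `B` for the default ocd detector and over
#' the `B0` tail lengths for the ocd' variant.
#'
#' @param state an `ocd_state`.
#' @param a_tilde nonnegative hard threshold.
#' @param variant `"ocd"` or `"ocd_prime"`.
#' @return nonnegative real.
#' @export
offdiag_statistic <- function(state, a_tilde, variant = c("ocd", "ocd_prime")) {
  variant <- match.arg(variant)
  use <- if (variant == "ocd") state$grid$in_B else !state$grid$in_B
  p <- state$p
  cols <- as.vector(state$colmat[, use, drop = FALSE])
  tsel <- as.vector(state$t[, use, drop = FALSE])
  E <- state$A[, cols, drop = FALSE] /
    rep(sqrt(pmax(tsel, 1)), each = p)
  contrib <- E^2 * (abs(E) >= a_tilde)
  tot <- colSums(contrib)
  own <- contrib[cbind(rep(seq_len(p), sum(use)), seq_along(cols))]
  max(tot - own, 0)
}
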