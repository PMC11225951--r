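#' Post-declaration statistics
#'
#' Combines the frozen detector state at the declaration time N with the
#' (optional) l extra observations: for every (j', j, b),
#' \deqn{E_b^{j',j} = (A_b^{j',j} + \textstyle\sum_{i=N+1}^{N+l} X_i^{j'})
#'   / \sqrt{(t_b^j + l) \vee 1},}
#' and for every (j, b in B) the hard-thresholded aggregation
#' \eqn{Q_b^j = \sum_{j' \ne j} (E_b^{j',j})^2 1\{|E_b^{j',j}| \ge a\}}.
#' The extra observations update nothing in the state; only their
#' coordinate-wise sum enters.
#'
#' @param decl an [run_detector()] declaration (trigger must not be
#'   `"none"`).
#' @param extra optional l x p matrix of post-declaration observations; by
#'   default the extra sum already collected by the declaration is used.
#' @param a hard threshold for Q (defaults to the declaration's tuning
#'   `a`).
#' @return An object of class `ocd_poststats` with fields `E` (p x pK),
#'   `Q` (p x |B|), `l`, `t`, `grid`, `N`.
#' @export
collect_extra <- function(decl, extra = NULL, a = decl$tuning$a) {
  stopifnot(inherits(decl, "ocd_declaration"))
  if (decl$trigger == "none")
    stop("no declaration was made; refusing to run inference")
  p <- decl$grid$p
  if (is.null(extra)) {
    extra_sum <- decl$extra_sum
    l <- decl$l
  } else {
    extra <- as.matrix(extra)
    if (ncol(extra) != p) stop("'extra' must have p columns")
    extra_sum <- colSums(extra)
    l <- nrow(extra)
  }
  K <- length(decl$grid$scales)
  denom <- sqrt(pmax(as.vector(decl$t) + l, 1))      # one per (j, b) column
  E <- (decl$A + extra_sum) / rep(denom, each = p)
  useB <- decl$grid$in_B
  colsB <- as.vector(matrix(seq_len(p * K), p, K)[, useB])
  contrib <- E[, colsB, drop = FALSE]^2 *
    (abs(E[, colsB, drop = FALSE]) >= a)
  tot <- colSums(contrib)
  own <- contrib[cbind(rep(seq_len(p), sum(useB)), seq_along(colsB))]
  Q <- matrix(tot - own, p, sum(useB))
  structure(list(E = E, Q = Q, l = l, t = decl$t, grid = decl$grid,
                 N = decl$N, a = a),
            class = "ocd_poststats")
}

#' Anchor coordinate and signed anchor scale
#'
#' The (j, b) pair in `[p] x B` maximizing Q: the tail whose
#' cross-coordinate evidence against the null is strongest. Ties are broken
#' deterministically: smallest coordinate index first, then the grid's
#' fixed scale ordering.
#'
#' @param stats an [collect_extra()] object.
#' @return list with `j_hat`, `b_hat` (signed scale), `k_hat` (column index
#'   of `b_hat` in the full grid) and the attained `q_max`.
#' @export
select_anchor <- function(stats) {
  stopifnot(inherits(stats, "ocd_poststats"))
  Q <- stats$Q
  best <- max(Q)
  hit <- which(Q == best, arr.ind = TRUE)
  # smallest j, then earliest scale in the fixed ordering
  hit <- hit[order(hit[, 1L], hit[, 2L]), , drop = FALSE]
  j_hat <- as.integer(hit[1L, 1L])
  kB <- as.integer(hit[1L, 2L])
  k_hat <- which(stats$grid$in_B)[kB]
  list(j_hat = j_hat, b_hat = stats$grid$scales[k_hat], k_hat = k_hat,
       q_max = best)
}

#' Estimated set of coordinates with large mean change
#'
#' \eqn{\hat S = \{j \ne \hat j : |E_{\hat b}^{j,\hat j}| - b_{min}
#' \sqrt{t_{\hat b}^{\hat j} + l} \ge d_1\}}. All coordinates are judged
#' along the anchor's tail length; the anchor itself is never a member.
#'
#' @param stats an [collect_extra()] object.
#' @param anchor a [select_anchor()] result.
#' @param d1 positive threshold.
#' @return sorted integer vector of coordinate indices.
#' @export
estimate_support <- function(stats, anchor, d1) {
  if (d1 <= 0) stop("'d1' must be positive")
  p <- stats$grid$p
  e <- abs(stats$E[, (anchor$k_hat - 1L) * p + anchor$j_hat])
  tj <- stats$t[anchor$j_hat, anchor$k_hat]
  keep <- which(e - stats$grid$b_min * sqrt(tj + stats$l) >= d1)
  setdiff(keep, anchor$j_hat)
}

#' Shrunken per-coordinate scale estimates
#'
#' For each j in the support estimate, the largest positive grid scale b
#' with \eqn{|E_{\hat b}^{j,\hat j}| - b\sqrt{t_{\hat b}^{\hat j} + l} \ge
#' d_1}, signed to match \eqn{E_{\hat b}^{j,\hat j}}. Membership of
#' \eqn{\hat S} guarantees the smallest scale qualifies, so the maximum is
#' over a nonempty set.
#'
#' @inheritParams estimate_support
#' @param S_hat support estimate from [estimate_support()] (with the same
#'   `d1`).
#' @return named numeric vector of signed scales, one per element of
#'   `S_hat`.
#' @export
shrunken_scales <- function(stats, anchor, S_hat, d1) {
  p <- stats$grid$p
  Ecol <- stats$E[, (anchor$k_hat - 1L) * p + anchor$j_hat]
  tj <- stats$t[anchor$j_hat, anchor$k_hat]
  root <- sqrt(tj + stats$l)
  lv <- stats$grid$levels
  out <- vapply(S_hat, function(j) {
    ok <- which(abs(Ecol[j]) - lv * root >= d1)
    if (length(ok) == 0L)
      stop("coordinate ", j, " violates the support-estimate inequality")
    sign(Ecol[j]) * lv[max(ok)]
  }, numeric(1))
  names(out) <- S_hat
  out
}

#' Confidence interval for the changepoint location
#'
#' \deqn{C = [\max\{N - \min_{j \in \hat S}(t_{\tilde b_j}^j +
#'   d_2/\tilde b_j^2), 0\}, N],}
#' where \eqn{t_{\tilde b_j}^j} is read from the state frozen at N at the
#' signed scale \eqn{\tilde b_j}. An empty support estimate gives
#' \eqn{[0, N]} (empty min is infinite). The left endpoint is the raw value
#' of the formula (real-valued); containment of a changepoint z means
#' `left <= z <= N`.
#'
#' @param decl the [run_detector()] declaration (supplies the frozen tail
#'   lengths).
#' @param S_hat support estimate.
#' @param b_tilde shrunken scales from [shrunken_scales()].
#' @param d2 positive slack parameter.
#' @return numeric `c(left, right)` with `0 <= left <= right = N`.
#' @export
confidence_interval <- function(decl, S_hat, b_tilde, d2) {
  N <- decl$N
  if (length(S_hat) == 0L) return(c(0, N))
  scales <- decl$grid$scales
  reach <- vapply(seq_along(S_hat), function(i) {
    j <- S_hat[i]
    k <- which(scales == b_tilde[i])
    decl$t[j, k] + d2 / b_tilde[i]^2
  }, numeric(1))
  c(max(N - min(reach), 0), N)
}

#' Full post-declaration inference pipeline
#'
#' Runs the base detector to declaration, folds in the l extra
#' observations, then computes the anchor, the support estimate, the
#' shrunken scales and the confidence interval.
#'
#' @inheritParams run_detector
#' @return An object of class `ocd_inference`: `declared`, `N`, `trigger`,
#'   `j_hat`, `b_hat`, `S_hat`, `b_tilde`, `interval` (`c(left, N)`), plus
#'   the declaration in `$declaration`. When the horizon is exhausted
#'   without a declaration, `declared` is `FALSE` and the inference fields
#'   are `NULL`.
#' @examples
#' g <- scale_grid(p = 5, beta = 2)
#' tn <- default_tuning(p = 5, beta = 2, gamma = 500)
#' tn <- calibrate_thresholds(5, 500, tn, g, n_runs = 20, seed = 1)
#' set.seed(7)
#' x <- rbind(matrix(rnorm(50 * 5), 50, 5),
#'            matrix(rnorm(100 * 5), 100, 5) +
#'              rep(c(3, 0, 0, 0, 0), each = 100))
#' ocd_ci(x, g, tn)
#' @export
ocd_ci <- function(x, grid, tuning, variant = c("ocd", "ocd_prime"),
                   l = tuning$l, engine = c("cpp", "r")) {
  variant <- match.arg(variant)
  decl <- run_detector(x, grid, tuning, variant, l = l, engine = engine)
  if (decl$trigger == "none") {
    return(structure(list(declared = FALSE, N = decl$N, trigger = "none",
                          j_hat = NULL, b_hat = NULL, S_hat = NULL,
                          b_tilde = NULL, interval = NULL,
                          declaration = decl),
                     class = "ocd_inference"))
  }
  stats <- collect_extra(decl)
  anchor <- select_anchor(stats)
  S_hat <- estimate_support(stats, anchor, tuning$d1)
  b_tilde <- shrunken_scales(stats, anchor, S_hat, tuning$d1)
  ci <- confidence_interval(decl, S_hat, b_tilde, tuning$d2)
  structure(list(declared = TRUE, N = decl$N, trigger = decl$trigger,
                 j_hat = anchor$j_hat, b_hat = anchor$b_hat, S_hat = S_hat,
                 b_tilde = b_tilde, interval = ci, declaration = decl),
            class = "ocd_inference")
}

#' @export
print.ocd_inference <- function(x, ...) {
  if (!x$declared) {
    cat("no change declared within the stream\n")
    return(invisible(x))
  }
  cat(sprintf("change declared at N = %d (%s trigger)\n", x$N, x$trigger))
  cat(sprintf("  confidence interval: [%.2f, %d]\n", x$interval[1], x$N))
  cat(sprintf("  anchor: coordinate %d at scale %.4f\n", x$j_hat, x$b_hat))
  if (length(x$S_hat)) {
    cat("  support estimate:", x$S_hat, "\n")
  } else {
    cat("  support estimate: empty\n")
  }
  invisible(x)
}
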