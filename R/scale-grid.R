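#' Dyadic grid of signed scales for the multiscale detector
#'
#' Builds the signed scale sets \eqn{B} and \eqn{B_0} used by the ocd
#' detectors and the post-declaration inference. The standard grid anchors at
#' \deqn{b_{min} = \beta / \sqrt{2^{\lfloor\log_2(2p)\rfloor} \log_2(2p)},}
#' and takes \eqn{B = \{\pm 2^{m/2} b_{min} : m = 1, \dots,
#' \lfloor\log_2(2p)\rfloor\}}, \eqn{B_0 = \{\pm b_{min}\}}, so that the
#' largest magnitude in \eqn{B} is exactly \eqn{\beta/\sqrt{\log_2(2p)}}.
#'
#' With `modified = TRUE` (for an arbitrarily loose lower bound \eqn{\beta}
#' on the signal norm), \eqn{b_{min}} is capped at 1/2 and the number of
#' dyadic levels becomes \eqn{M = \lceil 2\log_2(1/b_{min})\rceil}, so the
#' largest scale lies in \eqn{[1, 2)} regardless of how small \eqn{\beta} is.
#'
#' The full set \eqn{B \cup B_0} is stored in a fixed order -- increasing
#' magnitude, positive sign before negative at equal magnitude -- which
#' downstream tie-breaking (anchor selection, shrunken scales) relies on.
#'
#' @param p stream dimension (at least 2).
#' @param beta positive lower bound on the Euclidean norm of the mean change.
#' @param modified logical; use the capped grid for unknown signal size.
#' @return An object of class `ocd_scale_grid`: a list with elements `p`,
#'   `beta`, `modified`, `b_min`, `M` (number of dyadic levels in `B`),
#'   `scales` (all of \eqn{B \cup B_0}, signed, in the fixed order), `in_B`
#'   (logical marking members of \eqn{B}), and `levels` (the positive
#'   magnitudes, smallest first).
#' @examples
#' g <- scale_grid(p = 100, beta = 2)
#' max(g$scales) * sqrt(log2(2 * 100))  # recovers beta exactly
#' @export
scale_grid <- function(p, beta, modified = FALSE) {
  if (!is.numeric(p) || length(p) != 1L || p < 2)
    stop("'p' must be a single integer >= 2")
  p <- as.integer(p)
  if (!is.numeric(beta) || length(beta) != 1L || beta <= 0)
    stop("'beta' must be a single positive number")
  L <- floor(log2(2 * p))
  b_min <- beta / sqrt(2^L * log2(2 * p))
  if (modified) {
    b_min <- min(b_min, 0.5)
    M <- as.integer(ceiling(2 * log2(1 / b_min)))
  } else {
    M <- as.integer(L)
  }
  levels <- b_min * 2^((0:M) / 2)
  scales <- as.vector(rbind(levels, -levels)) # +b, -b, by increasing magnitude
  in_B <- rep(c(FALSE, rep(TRUE, M)), each = 2L)
  structure(
    list(p = p, beta = beta, modified = modified, b_min = b_min, M = M,
         scales = scales, in_B = in_B, levels = levels),
    class = "ocd_scale_grid")
}

#' @export
print.ocd_scale_grid <- function(x, ...) {
  cat(sprintf("ocd scale grid (%s): p = %d, beta = %g\n",
              if (x$modified) "modified" else "standard", x$p, x$beta))
  cat(sprintf("  b_min = %g, M = %d levels, |B u B0| = %d\n",
              x$b_min, x$M, length(x$scales)))
  cat("  positive magnitudes:", format(x$levels, digits = 4), "\n")
  invisible(x)
}

#' Practical tuning parameters for the ocd_CI procedure
#'
#' Assembles the default tuning used throughout the numerical studies:
#' hard thresholds \eqn{a = \tilde a = \sqrt{2\log p}} on the standardized
#' cross-coordinate statistics, support threshold \eqn{d_1 =
#' c\sqrt{\log(p/\alpha)}} with \eqn{c = 0.5} as the safe default, interval
#' slack \eqn{d_2 = 4 d_1^2}, and no extra post-declaration sampling
#' (\eqn{l = 0}). The declaration thresholds `T_diag` and `T_off` are left
#' uncalibrated (`NA`); set them with [calibrate_thresholds()] or, for the
#' ocd' theory variant, with [ocd_prime_thresholds()].
#'
#' Since \eqn{|E|}-type statistics are standardized (approximately standard
#' normal under the null), all hard thresholds on them live on the
#' \eqn{\sqrt{\log}} scale; the declaration thresholds, by contrast, live on
#' the likelihood-ratio scale and are plain logarithms.
#'
#' For sub-exponential data (regime `"sub_exponential"` with `r`, `s` and
#' rate `A` supplied), `a` becomes
#' \eqn{\max\{\sqrt{\log(rp/\alpha)}, \log(rp/\alpha)/A\}} and `d1` the
#' maximum of the Gaussian-theory form \eqn{5r\beta^2/(9 s \log_2(2p))} and
#' its \eqn{\sqrt{A}}-scaled counterpart; the active branch is recorded in
#' the `d1_branch` field.
#'
#' @param p stream dimension.
#' @param alpha nominal non-coverage level, in (0, 1).
#' @param beta lower bound on the Euclidean norm of the mean change.
#' @param gamma patience (target average run length to false alarm).
#' @param c multiplier for `d1`; 0.5 is the recommended default.
#' @param regime one of `"gaussian"`, `"sub_gaussian"`, `"sub_exponential"`.
#' @param r,s theory-mode delay bound and effective sparsity (optional; only
#'   used for the sub-exponential adjustments).
#' @param A sub-exponential rate parameter.
#' @param l number of extra post-declaration observations.
#' @return An object of class `ocd_tuning`.
#' @export
default_tuning <- function(p, alpha = 0.05, beta = 1, gamma = 30000,
                           c = 0.5,
                           regime = c("gaussian", "sub_gaussian",
                                      "sub_exponential"),
                           r = NULL, s = NULL, A = NULL, l = 0) {
  regime <- match.arg(regime)
  if (!is.numeric(p) || p < 2) stop("'p' must be >= 2")
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("'alpha' must be in (0, 1)")
  if (!is.numeric(c) || c <= 0) stop("'c' must be positive")
  if (l < 0) stop("'l' must be nonnegative")
  a <- sqrt(2 * log(p))
  d1 <- c * sqrt(log(p / alpha))
  d1_branch <- "practical"
  if (regime == "sub_exponential" && !is.null(r) && !is.null(s)) {
    if (is.null(A) || A <= 0) stop("sub-exponential regime needs rate A > 0")
    a <- max(sqrt(log(r * p / alpha)), log(r * p / alpha) / A)
    d1_g <- 5 * r * beta^2 / (9 * s * log2(2 * p))
    d1_e <- 5 * r * beta^2 / (9 * sqrt(A) * s * log2(2 * p))
    d1 <- max(d1_g, d1_e)
    d1_branch <- if (d1_e > d1_g) "sub_exponential" else "gaussian"
  }
  structure(
    list(p = as.integer(p), alpha = alpha, beta = beta, gamma = gamma,
         a = a, a_tilde = a, d1 = d1, d2 = 4 * d1^2, l = as.integer(l),
         T_diag = NA_real_, T_off = NA_real_, c = c, regime = regime,
         d1_branch = d1_branch),
    class = "ocd_tuning")
}

#' @export
print.ocd_tuning <- function(x, ...) {
  cat(sprintf("ocd tuning: p = %d, alpha = %g, beta = %g, gamma = %g\n",
              x$p, x$alpha, x$beta, x$gamma))
  cat(sprintf("  a = atilde = %.4f, d1 = %.4f, d2 = %.4f, l = %d\n",
              x$a, x$d1, x$d2, x$l))
  if (is.na(x$T_diag)) {
    cat("  thresholds: uncalibrated (run calibrate_thresholds())\n")
  } else {
    cat(sprintf("  thresholds: T_diag = %.3f, T_off = %.3f\n",
                x$T_diag, x$T_off))
  }
  invisible(x)
}

#' Theoretical declaration thresholds for the ocd' base procedure
#'
#' The patience-\eqn{\gamma} thresholds for which ocd' carries its average
#' run length and detection-delay guarantees:
#' \eqn{\tilde a = \sqrt{2\log(16 p^2 \gamma \log_2(2p))}},
#' \eqn{T_{diag} = \log(16 p \gamma \log_2(4p))} and
#' \eqn{T_{off} = 8\log(16 p \gamma \log_2(2p))}. With `modified = TRUE`
#' the \eqn{\log_2} factors are replaced by the level count `M` of the
#' capped scale grid (which must then be supplied).
#'
#' These are known to be conservative in practice; Monte-Carlo calibration
#' via [calibrate_thresholds()] is preferred for data analysis.
#'
#' @param p stream dimension.
#' @param gamma patience.
#' @param modified logical; thresholds for the capped grid of
#'   [scale_grid()] with `modified = TRUE`.
#' @param M number of dyadic levels (required when `modified = TRUE`).
#' @return A list with `a_tilde`, `T_diag`, `T_off`.
#' @export
ocd_prime_thresholds <- function(p, gamma, modified = FALSE, M = NULL) {
  if (p < 2) stop("'p' must be >= 2")
  if (gamma <= 0) stop("'gamma' must be positive")
  if (modified) {
    if (is.null(M)) stop("supply the grid level count M for the modified grid")
    list(a_tilde = sqrt(2 * log(16 * p^2 * gamma * M)),
         T_diag = log(16 * p * gamma * (M + 1)),
         T_off = 8 * log(16 * p * gamma * M))
  } else {
    list(a_tilde = sqrt(2 * log(16 * p^2 * gamma * log2(2 * p))),
         T_diag = log(16 * p * gamma * log2(4 * p)),
         T_off = 8 * log(16 * p * gamma * log2(2 * p)))
  }
}

#' Theory-mode support threshold
#'
#' The coverage-theory pair \eqn{d_1 = 5 r \beta^2 / (9 s \log_2(2p))},
#' \eqn{d_2 = 4 d_1^2}, where `r` bounds the detection delay of the base
#' procedure. Used only for theory-mode experiments; practical runs use
#' [default_tuning()].
#'
#' @param r delay bound (at least 1).
#' @param beta lower bound on the signal norm.
#' @param s effective sparsity (at least 1).
#' @param p stream dimension.
#' @return A list with `d1` and `d2`.
#' @export
theoretical_d1 <- function(r, beta, s, p) {
  if (r < 1 || s < 1) stop("'r' and 's' must be at least 1")
  d1 <- 5 * r * beta^2 / (9 * s * log2(2 * p))
  list(d1 = d1, d2 = 4 * d1^2)
}
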