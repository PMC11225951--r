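#' Data-generating model for a mean-change stream
#'
#' Describes independent p-variate observations with mean 0 up to the
#' changepoint `z` (1-based; `X_z` is the last pre-change observation) and
#' mean `theta` afterwards. The cross-sectional covariance has unit diagonal
#' and can be the identity, Toeplitz with entries \eqn{\rho^{|j-k|}}, or an
#' explicit unit-diagonal positive semi-definite matrix. Marginals are
#' Gaussian by default; a bounded sub-Gaussian family (centered uniform on
#' \eqn{[-\sqrt3, \sqrt3]}) and a sub-exponential family (centered Laplace
#' scaled to unit variance) are available. For non-Gaussian families with a
#' non-identity covariance, the iid draws are mixed through the Cholesky
#' factor, which preserves the moment class and the covariance but not the
#' exact marginal shape.
#'
#' @param p dimension.
#' @param z changepoint (nonnegative integer; `z = 0` means every
#'   observation is post-change).
#' @param theta length-`p` post-change mean vector.
#' @param covariance `"identity"`, `"toeplitz"` (supply `rho`), or an
#'   explicit p x p unit-diagonal matrix.
#' @param rho Toeplitz parameter in (-1, 1).
#' @param noise one of `"gaussian"`, `"bounded_subgaussian"`,
#'   `"subexponential"`.
#' @param rate sub-exponential rate parameter (recorded; the Laplace
#'   default has rate \eqn{\sqrt 2}).
#' @param seed optional integer; if set, [generate_stream()] is
#'   bit-reproducible.
#' @return An object of class `ocd_stream_model`.
#' @export
stream_model <- function(p, z, theta, covariance = "identity", rho = NULL,
                         noise = c("gaussian", "bounded_subgaussian",
                                   "subexponential"),
                         rate = sqrt(2), seed = NULL) {
  noise <- match.arg(noise)
  p <- as.integer(p)
  if (p < 1) stop("'p' must be positive")
  if (z < 0) stop("'z' must be nonnegative")
  if (length(theta) != p) stop("'theta' must have length p")
  R <- NULL
  if (is.matrix(covariance)) {
    if (!all(dim(covariance) == c(p, p)))
      stop("explicit covariance must be p x p")
    if (max(abs(diag(covariance) - 1)) > 1e-8)
      stop("explicit covariance must have unit diagonal")
    R <- tryCatch(chol(covariance),
                  error = function(e)
                    stop("explicit covariance is not positive semi-definite: ",
                         conditionMessage(e)))
    cov_kind <- "explicit"
  } else {
    cov_kind <- match.arg(covariance, c("identity", "toeplitz"))
    if (cov_kind == "toeplitz") {
      if (is.null(rho) || abs(rho) >= 1)
        stop("Toeplitz covariance needs 'rho' in (-1, 1)")
      Sigma <- rho^abs(outer(seq_len(p), seq_len(p), "-"))
      R <- chol(Sigma)
    }
  }
  structure(
    list(p = p, z = as.integer(z), theta = as.numeric(theta),
         covariance = cov_kind, rho = rho, chol = R, noise = noise,
         rate = rate, seed = seed),
    class = "ocd_stream_model")
}

#' Simulate observations from a stream model
#'
#' Returns a `horizon` x p matrix; rows `1..z` have mean zero, later rows
#' have mean `theta`. Unit-variance marginals from the model's noise family
#' are drawn row-by-row conceptually but filled by row so that a longer
#' horizon extends a shorter one draw-for-draw under the same seed.
#'
#' @param model an [stream_model()] object.
#' @param horizon number of observations (at least 1).
#' @return numeric matrix with `horizon` rows and `model$p` columns.
#' @export
generate_stream <- function(model, horizon) {
  stopifnot(inherits(model, "ocd_stream_model"))
  if (horizon < 1) stop("'horizon' must be at least 1")
  if (!is.null(model$seed)) set.seed(model$seed)
  p <- model$p
  m <- horizon * p
  eps <- switch(model$noise,
    gaussian = stats::rnorm(m),
    bounded_subgaussian = stats::runif(m, -sqrt(3), sqrt(3)),
    subexponential = {
      u <- stats::runif(m, -0.5, 0.5)
      # centered Laplace with scale 1/sqrt(2) => unit variance
      -sign(u) * log(1 - 2 * abs(u)) / sqrt(2)
    })
  X <- matrix(eps, nrow = horizon, ncol = p, byrow = TRUE)
  if (!is.null(model$chol)) X <- X %*% model$chol
  post <- seq_len(horizon) > model$z
  if (any(post)) X[post, ] <- sweep(X[post, , drop = FALSE], 2L,
                                    model$theta, "+")
  X
}

#' Draw a sparse post-change mean vector
#'
#' Produces `theta` with exactly `s` nonzero entries and Euclidean norm
#' `vartheta`. `"sphere_uniform"` picks the support uniformly at random and
#' the direction uniformly on the s-sparse unit sphere; the deterministic
#' shapes place the signal on coordinates `1..s` with nonzeros proportional
#' to 1 (`"uniform"`), \eqn{j^{-1/2}} (`"inv_sqrt"`) or \eqn{j^{-1}}
#' (`"harmonic"`), rescaled to norm `vartheta`.
#'
#' @param p dimension.
#' @param s sparsity, `1 <= s <= p`.
#' @param vartheta positive target norm.
#' @param shape signal shape.
#' @param seed optional integer seed (only used by `"sphere_uniform"`).
#' @return length-`p` numeric vector.
#' @export
sample_theta <- function(p, s, vartheta,
                         shape = c("sphere_uniform", "uniform", "inv_sqrt",
                                   "harmonic"),
                         seed = NULL) {
  shape <- match.arg(shape)
  if (s < 1 || s > p) stop("'s' must satisfy 1 <= s <= p")
  if (vartheta <= 0) stop("'vartheta' must be positive")
  theta <- numeric(p)
  if (shape == "sphere_uniform") {
    if (!is.null(seed)) set.seed(seed)
    supp <- sample.int(p, s)
    u <- stats::rnorm(s)
    while (all(u == 0)) u <- stats::rnorm(s)
    theta[supp] <- u / sqrt(sum(u^2)) * vartheta
  } else {
    w <- switch(shape,
                uniform = rep(1, s),
                inv_sqrt = seq_len(s)^(-1 / 2),
                harmonic = seq_len(s)^(-1))
    theta[seq_len(s)] <- w / sqrt(sum(w^2)) * vartheta
  }
  theta
}

#' Effective sparsity of a mean-change vector
#'
#' The smallest dyadic \eqn{s \in \{1, 2, 4, \dots, 2^{\lfloor\log_2
#' p\rfloor}\}} such that at least `s` coordinates satisfy \eqn{|\theta_j|
#' \ge \|\theta\|_2 / \sqrt{s \log_2(2p)}}. The coordinates exceeding the
#' threshold at `s(theta)` form the effective support: its sum of squares
#' captures \eqn{\|\theta\|_2^2} up to logarithmic factors.
#'
#' @param theta nonzero numeric vector.
#' @param p dimension (defaults to `length(theta)`).
#' @return integer power of two.
#' @export
effective_sparsity <- function(theta, p = length(theta)) {
  nrm <- sqrt(sum(theta^2))
  if (nrm == 0) stop("'theta' must be nonzero")
  for (s in 2^(0:floor(log2(p)))) {
    thr <- nrm / sqrt(s * log2(2 * p))
    if (sum(abs(theta) >= thr) >= s) return(as.integer(s))
  }
  stop("no candidate sparsity satisfies the defining inequality")
}

#' Effective support of a mean-change vector
#'
#' Coordinates whose magnitude reaches \eqn{\|\theta\|_2 /
#' \sqrt{s(\theta)\log_2(2p)}}, where \eqn{s(\theta)} is the
#' [effective_sparsity()]. Always a subset of the true support with
#' cardinality at least \eqn{s(\theta)}.
#'
#' @inheritParams effective_sparsity
#' @return sorted integer vector of coordinate indices.
#' @export
effective_support <- function(theta, p = length(theta)) {
  s <- effective_sparsity(theta, p)
  nrm <- sqrt(sum(theta^2))
  S <- which(abs(theta) >= nrm / sqrt(s * log2(2 * p)))
  stopifnot(length(S) >= s)
  S
}

#' Coordinates detectable at the smallest grid scale
#'
#' \eqn{S_\beta(\theta) = \{j : |\theta_j| \ge b_{min}\}}: the superset
#' against which false positives of the support estimate are judged.
#'
#' @param theta numeric vector.
#' @param b_min positive smallest grid scale (see [scale_grid()]).
#' @return sorted integer vector of coordinate indices.
#' @export
support_beta <- function(theta, b_min) {
  if (b_min <= 0) stop("'b_min' must be positive")
  which(abs(theta) >= b_min)
}

#' Read / write a stream as headerless delimited text
#'
#' One row per time point, one column per coordinate.
#'
#' @param x numeric matrix of observations.
#' @param path file path.
#' @param sep field separator (tab by default).
#' @param header logical; write/expect a header row of coordinate names.
#' @return `read_stream` returns a numeric matrix.
#' @export
write_stream <- function(x, path, sep = "\t", header = FALSE) {
  utils::write.table(x, path, sep = sep, row.names = FALSE,
                     col.names = header, quote = FALSE)
  invisible(path)
}

#' @rdname write_stream
#' @export
read_stream <- function(path, sep = "\t", header = FALSE) {
  as.matrix(utils::read.table(path, sep = sep, header = header))
}
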