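#' Run a base sequential detector over a stream
#'
#' Consumes observations one at a time and declares a change at the first
#' time the diagonal statistic reaches `T_diag` or the off-diagonal
#' statistic reaches `T_off`. If neither threshold is reached by the end of
#' the stream the trigger is `"none"` and no inference should follow.
#'
#' The declaration is a stopping time: the decision at time n depends on
#' the first n observations only. If `l > 0`, the l observations following
#' the declaration are summed into `extra_sum` for later inference; the
#' detector state itself stays frozen at N.
#'
#' @param x numeric matrix, one row per time point.
#' @param grid an [scale_grid()] object.
#' @param tuning an [default_tuning()] object with calibrated `T_diag`,
#'   `T_off`.
#' @param variant `"ocd"` (default) or `"ocd_prime"`.
#' @param l extra post-declaration observations to sum (taken from the
#'   rows of `x` after N).
#' @param engine `"cpp"` (compiled, default) or `"r"` (reference
#'   implementation; small problems only).
#' @return An object of class `ocd_declaration`: `N`, `trigger`
#'   (`"diag"`, `"offdiag"` or `"none"`), the statistics at N, the frozen
#'   tail lengths `t` (p x K) and tail partial sums `A` (p x pK), the
#'   extra-observation sum, and the grid/tuning used.
#' @export
run_detector <- function(x, grid, tuning, variant = c("ocd", "ocd_prime"),
                         l = tuning$l, engine = c("cpp", "r")) {
  variant <- match.arg(variant)
  engine <- match.arg(engine)
  stopifnot(inherits(grid, "ocd_scale_grid"), inherits(tuning, "ocd_tuning"))
  if (!is.matrix(x)) x <- matrix(x, ncol = grid$p)
  if (ncol(x) != grid$p) stop("'x' must have p = ", grid$p, " columns")
  if (is.na(tuning$T_diag) || is.na(tuning$T_off))
    stop("declaration thresholds are uncalibrated; ",
         "run calibrate_thresholds() (or ocd_prime_thresholds()) first")
  K <- length(grid$scales)
  p <- grid$p

  if (engine == "cpp") {
    res <- ocd_engine(x, grid$scales, grid$in_B, tuning$a_tilde,
                      tuning$T_diag, tuning$T_off, as.integer(l),
                      FALSE, variant == "ocd_prime")
    trigger <- c("none", "diag", "offdiag")[res$trigger + 1L]
    decl <- list(N = res$N, trigger = trigger, stat_diag = res$stat_diag,
                 stat_off = res$stat_off, t = res$t,
                 A = matrix(res$A, p, p * K), extra_sum = res$extra_sum,
                 l = res$l_avail, grid = grid, tuning = tuning,
                 variant = variant)
  } else {
    st <- detector_state(p, grid)
    trigger <- "none"
    N <- nrow(x)
    for (i in seq_len(nrow(x))) {
      st <- update_state(st, x[i, ])
      sd <- diag_statistic(st)
      so <- offdiag_statistic(st, tuning$a_tilde, variant)
      if (sd >= tuning$T_diag || so >= tuning$T_off) {
        trigger <- if (sd >= tuning$T_diag) "diag" else "offdiag"
        N <- i
        break
      }
    }
    l_avail <- min(l, nrow(x) - N)
    extra_sum <- if (l_avail > 0)
      colSums(x[N + seq_len(l_avail), , drop = FALSE]) else numeric(p)
    decl <- list(N = N, trigger = trigger,
                 stat_diag = diag_statistic(st),
                 stat_off = offdiag_statistic(st, tuning$a_tilde, variant),
                 t = st$t, A = st$A, extra_sum = extra_sum, l = l_avail,
                 grid = grid, tuning = tuning, variant = variant)
  }
  if (decl$trigger != "none" && decl$l < l)
    stop("stream exhausted before the ", l,
         " requested post-declaration observations")
  structure(decl, class = "ocd_declaration")
}

#' @export
print.ocd_declaration <- function(x, ...) {
  if (x$trigger == "none") {
    cat(sprintf("no declaration within %d observations (stats: diag %.3f, off %.3f)\n",
                x$N, x$stat_diag, x$stat_off))
  } else {
    cat(sprintf("change declared at N = %d (trigger: %s; diag %.3f, off %.3f)\n",
                x$N, x$trigger, x$stat_diag, x$stat_off))
  }
  invisible(x)
}

#' Monte-Carlo calibration of the declaration thresholds
#'
#' Simulates `n_runs` independent Gaussian null streams of length `gamma`,
#' records each run's maximum diagonal and off-diagonal statistic, and sets
#' the thresholds to the empirical `1 - q/2` quantiles of the two
#' run-maximum samples. The false-alarm budget `q` (probability of any
#' alarm within `gamma` null observations) is split evenly between the two
#' statistics; the default `q = 1/2` makes the patience interpretation --
#' expected run length to false alarm of order at least `gamma` -- hold
#' comfortably.
#'
#' Run `i` seeds the generator with `seed + i`, and each stream matrix is
#' filled row-by-row, so run maxima are weakly increasing in `gamma` under
#' the same seed schedule, and calibration is fully reproducible.
#'
#' @param p stream dimension.
#' @param gamma patience: null run length.
#' @param tuning an [default_tuning()] object (supplies `a_tilde`).
#' @param grid an [scale_grid()] object.
#' @param n_runs number of null runs (at least 2; 100 by default).
#' @param seed integer seed for the run schedule.
#' @param q target probability of any false alarm within `gamma` steps.
#' @param variant `"ocd"` or `"ocd_prime"`.
#' @return the `tuning` object with `T_diag`, `T_off` filled in; the run
#'   maxima samples are attached as attribute `"run_maxima"`.
#' @export
calibrate_thresholds <- function(p, gamma, tuning, grid, n_runs = 100,
                                 seed = 1, q = 0.5,
                                 variant = c("ocd", "ocd_prime")) {
  variant <- match.arg(variant)
  stopifnot(inherits(grid, "ocd_scale_grid"), grid$p == p)
  if (n_runs < 2) stop("'n_runs' must be at least 2")
  gamma <- as.integer(gamma)
  maxd <- maxo <- numeric(n_runs)
  for (i in seq_len(n_runs)) {
    set.seed(seed + i)
    X <- matrix(stats::rnorm(gamma * p), gamma, p, byrow = TRUE)
    m <- ocd_engine(X, grid$scales, grid$in_B, tuning$a_tilde,
                    Inf, Inf, 0L, TRUE, variant == "ocd_prime")
    maxd[i] <- m$max_diag
    maxo[i] <- m$max_off
  }
  tuning$T_diag <- as.numeric(stats::quantile(maxd, 1 - q / 2))
  tuning$T_off <- as.numeric(stats::quantile(maxo, 1 - q / 2))
  attr(tuning, "run_maxima") <- list(diag = maxd, off = maxo,
                                     gamma = gamma, n_runs = n_runs,
                                     seed = seed, q = q)
  tuning
}
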