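#' @keywords internal
split_seed <- function(seed, id) {
  # documented splitting rule: affine hash modulo a prime below 2^31
  as.integer((as.numeric(seed) %% 2147483629 * 48271 + id * 1664525) %%
               2147483629)
}

rep_seed <- function(seed, i) split_seed(seed, 1000L + i)

#' Coverage / length / delay experiment
#'
#' Repeats the full pipeline under the Gaussian (or Toeplitz) mean-change
#' model: each replication draws a fresh s-sparse direction for the mean
#' change (norm `vartheta`), simulates `z` pre-change and up to
#' `horizon_cap` post-change observations, runs [ocd_ci()] and records
#' whether the interval covers `z`, its length `N - left`, and the
#' detection delay `N - z`.
#'
#' Replications with a false alarm (`N <= z`) count as non-coverage and
#' are excluded from the delay and length averages, since delay is only
#' meaningful after the change; with the default patience they are rare.
#' Replications with no declaration inside the horizon (rarer still) are
#' counted as non-coverage and reported.
#'
#' @param p,s,vartheta,beta,z,gamma,alpha,c,l,rho experiment setting;
#'   `rho = 0` means identity covariance.
#' @param shape signal shape passed to [sample_theta()].
#' @param n_reps number of replications.
#' @param seed master seed; each replication derives its own stream seed.
#' @param thresholds optional pre-calibrated [calibrate_thresholds()]
#'   tuning (strongly recommended: calibrate once per (p, gamma, beta) and
#'   reuse); when `NULL` a calibration with `n_runs_cal` runs is performed.
#' @param n_runs_cal calibration runs when `thresholds` is `NULL`.
#' @param horizon_cap post-change observations simulated beyond `z`.
#' @param variant base detector variant.
#' @return a one-row `data.frame` of class `ocd_experiment` with the
#'   setting, the estimates and their Monte-Carlo standard errors; per-rep
#'   records are attached as attribute `"reps"`.
#' @export
run_coverage_experiment <- function(p = 100, s = 2, vartheta = 2, beta = 2,
                                    z = 1000, gamma = 30000, alpha = 0.05,
                                    c = 0.5, l = 0, rho = 0,
                                    shape = "sphere_uniform",
                                    n_reps = 300, seed = 1,
                                    thresholds = NULL, n_runs_cal = 100,
                                    horizon_cap = 2000, variant = "ocd") {
  grid <- scale_grid(p, beta)
  tuning <- default_tuning(p, alpha, beta, gamma, c = c, l = l)
  if (is.null(thresholds)) {
    tuning <- calibrate_thresholds(p, gamma, tuning, grid,
                                   n_runs = n_runs_cal,
                                   seed = split_seed(seed, 77L))
  } else {
    tuning$T_diag <- thresholds$T_diag
    tuning$T_off <- thresholds$T_off
  }
  covered <- logical(n_reps)
  len <- delay <- rep(NA_real_, n_reps)
  outcome <- character(n_reps)
  for (i in seq_len(n_reps)) {
    set.seed(rep_seed(seed, i))
    theta <- sample_theta(p, s, vartheta, shape)
    model <- stream_model(p, z, theta,
                          covariance = if (rho == 0) "identity" else "toeplitz",
                          rho = if (rho == 0) NULL else rho)
    x <- generate_stream(model, z + horizon_cap + l)
    fit <- ocd_ci(x, grid, tuning, variant, l = l)
    if (!fit$declared) {
      outcome[i] <- "none"
      covered[i] <- FALSE
    } else if (fit$N <= z) {
      outcome[i] <- "false_alarm"
      covered[i] <- FALSE
    } else {
      outcome[i] <- "detected"
      covered[i] <- fit$interval[1] <= z
      len[i] <- fit$N - fit$interval[1]
      delay[i] <- fit$N - z
    }
  }
  cov_hat <- mean(covered)
  det <- outcome == "detected"
  res <- data.frame(
    p = p, s = s, vartheta = vartheta, beta = beta, rho = rho, z = z,
    gamma = gamma, alpha = alpha, c = c, l = l, shape = shape,
    variant = variant, n_reps = n_reps,
    coverage = cov_hat,
    se_coverage = sqrt(cov_hat * (1 - cov_hat) / n_reps),
    mean_length = mean(len[det]),
    se_length = stats::sd(len[det]) / sqrt(sum(det)),
    mean_delay = mean(delay[det]),
    se_delay = stats::sd(delay[det]) / sqrt(sum(det)),
    n_false_alarm = sum(outcome == "false_alarm"),
    n_no_declaration = sum(outcome == "none"))
  attr(res, "reps") <- data.frame(covered = covered, length = len,
                                  delay = delay, outcome = outcome)
  class(res) <- c("ocd_experiment", "data.frame")
  res
}

#' Support-recovery experiment
#'
#' Fixed-shape signal on coordinates `1..s`; each replication records
#' whether the support estimate avoids every coordinate outside
#' \eqn{S_\beta} and whether, augmented with the anchor, it contains the
#' effective support. The default extra-sampling budget follows the
#' support-recovery theory:
#' \eqn{l = \lceil 2 s \log_2(2p) \log(p) / \beta^2 \rceil},
#' and the default support threshold is \eqn{d_1 = 2\sqrt{\log(p/\alpha)}}.
#'
#' @inheritParams run_coverage_experiment
#' @param shape `"uniform"`, `"inv_sqrt"` or `"harmonic"`.
#' @param d1 support threshold.
#' @return a one-row `data.frame` of class `ocd_experiment` with
#'   `p_subset` (\eqn{P(\hat S \subseteq S_\beta)}), `p_superset`
#'   (\eqn{P(\hat S \cup \{\hat j\} \supseteq S)}) and standard errors.
#' @export
run_support_experiment <- function(p = 100, s = 5, vartheta = 2,
                                   shape = c("uniform", "inv_sqrt",
                                             "harmonic"),
                                   beta = vartheta, z = 1000,
                                   gamma = 30000, alpha = 0.05,
                                   d1 = 2 * sqrt(log(p / alpha)),
                                   l = ceiling(2 * s * log2(2 * p) *
                                                 log(p) / beta^2),
                                   n_reps = 300, seed = 1,
                                   thresholds = NULL, n_runs_cal = 100,
                                   horizon_cap = 2000, variant = "ocd") {
  shape <- match.arg(shape)
  grid <- scale_grid(p, beta)
  tuning <- default_tuning(p, alpha, beta, gamma, l = l)
  tuning$d1 <- d1
  tuning$d2 <- 4 * d1^2
  if (is.null(thresholds)) {
    tuning <- calibrate_thresholds(p, gamma, tuning, grid,
                                   n_runs = n_runs_cal,
                                   seed = split_seed(seed, 77L))
  } else {
    tuning$T_diag <- thresholds$T_diag
    tuning$T_off <- thresholds$T_off
  }
  theta <- sample_theta(p, s, vartheta, shape)
  S <- effective_support(theta, p)
  Sb <- support_beta(theta, grid$b_min)
  subset_ok <- superset_ok <- logical(n_reps)
  for (i in seq_len(n_reps)) {
    set.seed(rep_seed(seed, i))
    model <- stream_model(p, z, theta)
    x <- generate_stream(model, z + horizon_cap + l)
    fit <- ocd_ci(x, grid, tuning, variant, l = l)
    if (!fit$declared) next
    subset_ok[i] <- all(fit$S_hat %in% Sb)
    superset_ok[i] <- all(S %in% union(fit$S_hat, fit$j_hat))
  }
  ps <- mean(subset_ok)
  pu <- mean(superset_ok)
  res <- data.frame(
    p = p, s = s, vartheta = vartheta, beta = beta, z = z, gamma = gamma,
    alpha = alpha, d1 = d1, l = l, shape = shape, variant = variant,
    n_reps = n_reps,
    p_subset = ps, se_subset = sqrt(ps * (1 - ps) / n_reps),
    p_superset = pu, se_superset = sqrt(pu * (1 - pu) / n_reps))
  attr(res, "reps") <- data.frame(subset_ok = subset_ok,
                                  superset_ok = superset_ok)
  class(res) <- c("ocd_experiment", "data.frame")
  res
}

#' Support-recovery operating characteristic over d1
#'
#' Runs the pipeline once per replication, then re-evaluates the support
#' estimate along a grid of `d1` values on the same post-declaration
#' statistics, so the points are replication-paired: as d1 grows,
#' \eqn{\hat S} shrinks, so the subset probability is nondecreasing and
#' the superset probability nonincreasing along the grid.
#'
#' @inheritParams run_support_experiment
#' @param d1_grid increasing vector of support thresholds.
#' @param l extra observations (0 in the operating-characteristic regime).
#' @return `data.frame` with one row per `d1`: `p_subset`, `p_superset`
#'   and standard errors.
#' @export
roc_curve <- function(p = 100, s = 5, vartheta = 2,
                      shape = c("uniform", "inv_sqrt", "harmonic"),
                      beta = vartheta, z = 1000, gamma = 30000,
                      alpha = 0.05, d1_grid, l = 0, n_reps = 300,
                      seed = 1, thresholds = NULL, n_runs_cal = 100,
                      horizon_cap = 2000) {
  shape <- match.arg(shape)
  sel <- selection_runs(p, s, vartheta, shape, beta, z, gamma, alpha, l,
                        n_reps, seed, thresholds, n_runs_cal, horizon_cap)
  out <- lapply(d1_grid, function(d1) {
    sub <- vapply(sel$runs, function(r) {
      if (is.null(r)) return(FALSE)
      Sh <- estimate_support(r$stats, r$anchor, d1)
      all(Sh %in% sel$Sb)
    }, logical(1))
    sup <- vapply(sel$runs, function(r) {
      if (is.null(r)) return(FALSE)
      Sh <- estimate_support(r$stats, r$anchor, d1)
      all(sel$S %in% union(Sh, r$anchor$j_hat))
    }, logical(1))
    data.frame(d1 = d1, p_subset = mean(sub),
               se_subset = sqrt(mean(sub) * (1 - mean(sub)) / n_reps),
               p_superset = mean(sup),
               se_superset = sqrt(mean(sup) * (1 - mean(sup)) / n_reps))
  })
  do.call(rbind, out)
}

#' Per-coordinate selection frequency
#'
#' Frequency, over replications, with which each coordinate belongs to
#' \eqn{\hat S \cup \{\hat j\}} at a fixed `d1`.
#'
#' @inheritParams roc_curve
#' @param d1 support threshold.
#' @return numeric vector of length `p` of frequencies in `[0, 1]`.
#' @export
selection_frequency <- function(p = 100, s = 20, vartheta = 2,
                                shape = "inv_sqrt", beta = vartheta,
                                z = 1000, gamma = 30000, alpha = 0.05,
                                d1 = 2 * sqrt(log(p)), l = 0, n_reps = 300,
                                seed = 1, thresholds = NULL,
                                n_runs_cal = 100, horizon_cap = 2000) {
  sel <- selection_runs(p, s, vartheta, shape, beta, z, gamma, alpha, l,
                        n_reps, seed, thresholds, n_runs_cal, horizon_cap)
  counts <- numeric(p)
  for (r in sel$runs) {
    if (is.null(r)) next
    Sh <- estimate_support(r$stats, r$anchor, d1)
    counts[union(Sh, r$anchor$j_hat)] <- counts[union(Sh, r$anchor$j_hat)] + 1
  }
  counts / n_reps
}

#' @keywords internal
selection_runs <- function(p, s, vartheta, shape, beta, z, gamma, alpha, l,
                           n_reps, seed, thresholds, n_runs_cal,
                           horizon_cap) {
  grid <- scale_grid(p, beta)
  tuning <- default_tuning(p, alpha, beta, gamma, l = l)
  if (is.null(thresholds)) {
    tuning <- calibrate_thresholds(p, gamma, tuning, grid,
                                   n_runs = n_runs_cal,
                                   seed = split_seed(seed, 77L))
  } else {
    tuning$T_diag <- thresholds$T_diag
    tuning$T_off <- thresholds$T_off
  }
  theta <- sample_theta(p, s, vartheta, shape)
  runs <- vector("list", n_reps)
  for (i in seq_len(n_reps)) {
    set.seed(rep_seed(seed, i))
    model <- stream_model(p, z, theta)
    x <- generate_stream(model, z + horizon_cap + l)
    decl <- tryCatch(run_detector(x, grid, tuning, l = l),
                     error = function(e) NULL)
    if (is.null(decl) || decl$trigger == "none") next
    stats <- collect_extra(decl)
    runs[[i]] <- list(stats = stats, anchor = select_anchor(stats))
  }
  list(runs = runs, S = effective_support(theta, p),
       Sb = support_beta(theta, grid$b_min), theta = theta)
}

#' Coverage as a function of the d1 multiplier c
#'
#' Sweeps `c` over a grid for one or more experiment settings, with paired
#' seeds across `c` values, returning one row per (setting, c).
#'
#' @param settings `data.frame` with columns `p`, `s`, `vartheta`, `beta`
#'   (optionally `z`, `gamma`, `alpha`).
#' @param c_grid increasing vector of multipliers.
#' @inheritParams run_coverage_experiment
#' @return `data.frame` of class `ocd_experiment` rows.
#' @export
tuning_curve <- function(settings, c_grid, n_reps = 300, seed = 1,
                         thresholds = NULL, n_runs_cal = 100,
                         horizon_cap = 2000) {
  rows <- list()
  for (i in seq_len(nrow(settings))) {
    st <- settings[i, ]
    z <- if ("z" %in% names(st)) st$z else 500
    gamma <- if ("gamma" %in% names(st)) st$gamma else 30000
    alpha <- if ("alpha" %in% names(st)) st$alpha else 0.05
    for (cc in c_grid) {
      rows[[length(rows) + 1L]] <- run_coverage_experiment(
        p = st$p, s = st$s, vartheta = st$vartheta, beta = st$beta,
        z = z, gamma = gamma, alpha = alpha, c = cc, n_reps = n_reps,
        seed = seed, thresholds = thresholds, n_runs_cal = n_runs_cal,
        horizon_cap = horizon_cap)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("ocd_experiment", "data.frame")
  out
}
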