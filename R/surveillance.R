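#' Weekly regional count panel
#'
#' A panel of weekly counts (e.g. deaths) per region: strictly increasing
#' week-ending dates exactly 7 days apart, nonnegative counts, and a
#' training cutoff. Weeks ending on or before `training_end` form the
#' training window used for the seasonal baseline and standardization.
#'
#' @param dates `Date` vector of week-ending dates.
#' @param counts numeric matrix, one row per week, one column per region
#'   (column names are the region names).
#' @param training_end `Date`; last week-ending date of the training
#'   window.
#' @return An object of class `ocd_weekly_panel`.
#' @export
weekly_panel <- function(dates, counts, training_end) {
  dates <- as.Date(dates)
  counts <- as.matrix(counts)
  if (nrow(counts) != length(dates))
    stop("'counts' must have one row per date")
  d <- diff(as.integer(dates))
  if (length(d) && any(d != 7L))
    stop("'dates' must be strictly increasing and exactly 7 days apart")
  if (any(counts < 0)) stop("counts must be nonnegative")
  training_end <- as.Date(training_end)
  if (!any(dates <= training_end)) stop("training window is empty")
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("region", seq_len(ncol(counts)))
  structure(list(dates = dates, counts = counts,
                 training_end = training_end),
            class = "ocd_weekly_panel")
}

# day-of-year on a circle of length 365; Feb-29 years put 31 Dec at 366,
# which is folded onto day 365's neighborhood
day_of_year <- function(dates) {
  doy <- as.POSIXlt(dates)$yday + 1L
  pmin(doy, 365L)
}

week_days <- function(date) date - 6:0  # the 7 days of a week-ending date

#' Seasonal daily baseline for one region
#'
#' Estimates the expected count for each day of the year from the training
#' window: weekly counts are split evenly across their 7 days (count/7 per
#' day), and the curve value at day d is a Gaussian-kernel weighted average
#' of these daily values, with circular day-of-year distance (wrap at year
#' end, so late December and early January borrow strength). The bandwidth
#' is the kernel's standard deviation in days. Kernel weights are
#' normalized to sum to 1 at every day, so a constant panel yields a
#' constant curve.
#'
#' @param panel an [weekly_panel()].
#' @param region region name or column index.
#' @param bandwidth Gaussian kernel standard deviation, in days.
#' @return numeric vector of length 366 (day 366 equals day 365).
#' @export
seasonal_curve <- function(panel, region, bandwidth = 20) {
  stopifnot(inherits(panel, "ocd_weekly_panel"))
  train <- panel$dates <= panel$training_end
  if (as.integer(panel$training_end - min(panel$dates)) < 358)
    stop("training window must cover at least one full year")
  wk_dates <- panel$dates[train]
  wk_counts <- panel$counts[train, region]
  days <- as.Date(unlist(lapply(wk_dates, week_days)), origin = "1970-01-01")
  daily <- rep(wk_counts / 7, each = 7L)
  doy <- day_of_year(days)
  curve <- numeric(365)
  for (d in 1:365) {
    dist <- abs(doy - d)
    dist <- pmin(dist, 365 - dist)
    w <- exp(-dist^2 / (2 * bandwidth^2))
    curve[d] <- sum(w * daily) / sum(w)
  }
  c(curve, curve[365])
}

#' Variance-stabilized weekly excess series for one region
#'
#' Predicted weekly deaths are the seasonal curve summed over the 7 days of
#' each week; the transformed excess is
#' \eqn{\sqrt{\mathrm{observed}} - \sqrt{\mathrm{predicted}}} (the square
#' root stabilizes the variance of approximately Poisson counts), and the
#' standardized series subtracts the training-window mean and divides by
#' the training-window standard deviation of the transformed excess.
#'
#' @inheritParams seasonal_curve
#' @param curve a [seasonal_curve()] for the same region.
#' @param standardize logical; set `FALSE` to stop before standardization
#'   (required when the training excess is constant).
#' @return `data.frame` with columns `date`, `observed`, `predicted`,
#'   `excess`, and (if standardizing) `standardized`.
#' @export
transform_weekly <- function(panel, region, curve, standardize = TRUE) {
  stopifnot(inherits(panel, "ocd_weekly_panel"), length(curve) == 366L)
  predicted <- vapply(panel$dates, function(d) {
    sum(curve[day_of_year(week_days(d))])
  }, numeric(1))
  observed <- panel$counts[, region]
  excess <- sqrt(observed) - sqrt(predicted)
  out <- data.frame(date = panel$dates, observed = observed,
                    predicted = predicted, excess = excess)
  if (standardize) {
    train <- panel$dates <= panel$training_end
    mu <- mean(excess[train])
    sdv <- stats::sd(excess[train])
    if (sdv == 0)
      stop("training excess has zero variance; cannot standardize ",
           "(use standardize = FALSE)")
    out$standardized <- (excess - mu) / sdv
  }
  out
}

#' Online surveillance of a weekly count panel
#'
#' The full preprocessing + detection pipeline: per-region seasonal
#' baseline from the training window, square-root variance stabilization,
#' training-window standardization, then the post-declaration inference
#' pipeline on the monitoring weeks. Declaration thresholds default to the
#' closed-form patience-\eqn{\gamma} values of [ocd_prime_thresholds()]
#' (with the practical hard threshold \eqn{a = \tilde a = \sqrt{2\log p}});
#' pass a calibrated tuning to override.
#'
#' @param panel an [weekly_panel()].
#' @param monitor_start `Date`; first monitored week-ending date (defaults
#'   to the first week after `training_end`).
#' @param beta lower bound on the aggregate standardized shift size.
#' @param gamma patience, in weeks.
#' @param alpha nominal non-coverage level.
#' @param c multiplier for `d1`.
#' @param bandwidth seasonal kernel bandwidth in days.
#' @param tuning optional pre-built [default_tuning()] with thresholds set.
#' @return list with the [ocd_ci()] result (`fit`), `declared_week`,
#'   `interval_weeks` (`Date` endpoints), `regions` (names in
#'   \eqn{\hat S \cup \{\hat j\}}), and the standardized monitoring matrix.
#' @export
run_surveillance <- function(panel, monitor_start = NULL, beta = 50,
                             gamma = 1000, alpha = 0.05, c = 0.5,
                             bandwidth = 20, tuning = NULL) {
  stopifnot(inherits(panel, "ocd_weekly_panel"))
  p <- ncol(panel$counts)
  if (is.null(monitor_start)) monitor_start <- panel$training_end + 7
  monitor <- panel$dates >= as.Date(monitor_start)
  if (!any(monitor)) stop("monitoring window is empty")
  std <- sapply(colnames(panel$counts), function(rg) {
    crv <- seasonal_curve(panel, rg, bandwidth)
    transform_weekly(panel, rg, crv)$standardized
  })
  xmon <- std[monitor, , drop = FALSE]
  grid <- scale_grid(p, beta)
  if (is.null(tuning)) {
    tuning <- default_tuning(p, alpha, beta, gamma, c = c)
    th <- ocd_prime_thresholds(p, gamma)
    tuning$T_diag <- th$T_diag
    tuning$T_off <- th$T_off
  }
  fit <- ocd_ci(xmon, grid, tuning)
  mon_dates <- panel$dates[monitor]
  if (!fit$declared) {
    return(list(fit = fit, declared_week = NULL, interval_weeks = NULL,
                regions = character(0), standardized = xmon,
                monitor_dates = mon_dates))
  }
  left_idx <- max(ceiling(fit$interval[1]), 1)
  list(fit = fit,
       declared_week = mon_dates[fit$N],
       interval_weeks = c(mon_dates[left_idx], mon_dates[fit$N]),
       interval_left_raw = fit$interval[1],
       regions = colnames(panel$counts)[sort(union(fit$S_hat, fit$j_hat))],
       standardized = xmon,
       monitor_dates = mon_dates)
}

#' Synthetic weekly-deaths panel
#'
#' Generates a toy panel emulating regional weekly death counts: each
#' region has a base weekly rate, a smooth multiplicative seasonal cycle
#' (winter peak), and Poisson sampling. Optionally a simultaneous
#' multiplicative level shift is injected in a subset of regions from a
#' given week onward.
#'
#' @param n_regions number of regions.
#' @param n_weeks number of weeks.
#' @param start first week-ending date.
#' @param base_rates weekly base rates (recycled to `n_regions`).
#' @param seasonal_amp amplitude of the seasonal cycle (fraction of base).
#' @param shift_regions indices of regions receiving the shift (possibly
#'   empty).
#' @param shift_week index of the first shifted week (`NA` for none).
#' @param shift_mult multiplicative size of the shift.
#' @param training_end training cutoff (defaults to 2/3 of the panel).
#' @param seed integer seed.
#' @return an [weekly_panel()].
#' @export
synth_weekly_panel <- function(n_regions = 20, n_weeks = 180,
                               start = as.Date("2017-01-07"),
                               base_rates = seq(300, 2000,
                                                length.out = n_regions),
                               seasonal_amp = 0.15,
                               shift_regions = integer(0),
                               shift_week = NA, shift_mult = 1.5,
                               training_end = NULL, seed = 1) {
  set.seed(seed)
  dates <- as.Date(start) + 7 * (seq_len(n_weeks) - 1L)
  base_rates <- rep_len(base_rates, n_regions)
  doy <- day_of_year(dates)
  season <- 1 + seasonal_amp * cos(2 * pi * (doy - 15) / 365)
  lam <- outer(season, base_rates)
  if (length(shift_regions) && !is.na(shift_week))
    lam[seq_len(n_weeks) >= shift_week, shift_regions] <-
      lam[seq_len(n_weeks) >= shift_week, shift_regions] * shift_mult
  counts <- matrix(stats::rpois(length(lam), lam), n_weeks, n_regions)
  colnames(counts) <- paste0("region", seq_len(n_regions))
  if (is.null(training_end)) training_end <- dates[floor(2 * n_weeks / 3)]
  weekly_panel(dates, counts, training_end)
}
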