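# build a declaration on a small stream for reuse across blocks
make_decl <- function(seed = 50, p = 4, z = 40, theta = c(2, -1.5, 0, 0),
                      beta = 1.5, extra_rows = 30) {
  g <- scale_grid(p, beta)
  tn <- default_tuning(p, beta = beta, gamma = 200)
  tn$T_diag <- 8; tn$T_off <- 20
  set.seed(seed)
  x <- rbind(matrix(rnorm(z * p), z, p),
             matrix(rnorm((60 + extra_rows) * p), 60 + extra_rows, p) +
               rep(theta, each = 60 + extra_rows))
  list(x = x, g = g, tn = tn,
       decl = run_detector(x, g, tn, l = 0))
}

test_that("post-declaration statistics honor the (t + l) v 1 normalization", {
  mk <- make_decl()
  decl <- mk$decl
  expect_true(decl$trigger != "none")
  st0 <- collect_extra(decl)           # l = 0
  expect_equal(st0$l, 0)
  denom <- sqrt(pmax(as.vector(decl$t), 1))
  expect_equal(st0$E, decl$A / rep(denom, each = 4), tolerance = 1e-12)
  # fresh pairs (t = 0, A = 0) give E = 0 through the v 1 guard
  zero_pairs <- which(decl$t == 0)
  if (length(zero_pairs)) {
    k <- zero_pairs[1]
    expect_true(all(st0$E[, (col(decl$t)[k] - 1) * 4 + row(decl$t)[k]] == 0))
  }
  # explicit extra observations shift E by their sum
  extra <- mk$x[decl$N + 1:5, , drop = FALSE]
  st5 <- collect_extra(decl, extra = extra)
  expect_equal(st5$l, 5)
  j <- 1; k <- which(decl$t[j, ] > 0)[1]
  colk <- (k - 1) * 4 + j
  expect_equal(st5$E[, colk],
               (decl$A[, colk] + colSums(extra)) /
                 sqrt(decl$t[j, k] + 5), tolerance = 1e-12)
  # hand value: t = 4, A = 6, l = 0 -> E = 3
  expect_equal(6 / sqrt(4), 3)
})

test_that("anchor selection matches exhaustive enumeration with tie rules", {
  mk <- make_decl()
  stats <- collect_extra(mk$decl)
  an <- select_anchor(stats)
  # brute force over all (j, b in B)
  best <- -Inf; bj <- NA; bk <- NA
  kB <- which(stats$grid$in_B)
  for (j in 1:4) {
    for (m in seq_along(kB)) {
      q <- stats$Q[j, m]
      if (q > best) { best <- q; bj <- j; bk <- kB[m] }
    }
  }
  expect_equal(an$j_hat, bj)
  expect_equal(an$k_hat, bk)
  expect_equal(an$q_max, best)
  expect_equal(an$b_hat, stats$grid$scales[bk])
  # all-zero Q: deterministic tie-break at the first coordinate/scale
  stats0 <- stats
  stats0$Q <- matrix(0, 4, length(kB))
  an0 <- select_anchor(stats0)
  expect_equal(an0$j_hat, 1L)
  expect_equal(an0$k_hat, kB[1])
})

test_that("support estimate applies the anchored threshold inequality", {
  mk <- make_decl()
  stats <- collect_extra(mk$decl)
  an <- select_anchor(stats)
  # independent recomputation of the rule
  p <- 4
  e <- abs(stats$E[, (an$k_hat - 1) * p + an$j_hat])
  tj <- stats$t[an$j_hat, an$k_hat]
  for (d1 in c(0.5, 2, 5, 50)) {
    Sh <- estimate_support(stats, an, d1)
    manual <- setdiff(which(e - stats$grid$b_min * sqrt(tj) >= d1), an$j_hat)
    expect_identical(Sh, manual)
    expect_false(an$j_hat %in% Sh)
  }
  # numeric example: |E| = 5, b_min = 0.1, t + l = 16, d1 = 4 -> included
  expect_true(5 - 0.1 * sqrt(16) >= 4)
  # huge d1 empties the estimate
  expect_length(estimate_support(stats, an, 1e6), 0)
})

test_that("shrunken scales pick the largest certified grid magnitude", {
  # crafted check: |E| = 5, t + l = 16, d1 = 3, positive levels .25/.5/1
  # => b <= (5-3)/4 = 0.5, so the certified scale is 0.5 with E's sign
  lv <- c(0.25, 0.5, 1)
  ok <- which(5 - lv * sqrt(16) >= 3)
  expect_equal(lv[max(ok)], 0.5)

  mk <- make_decl()
  stats <- collect_extra(mk$decl)
  an <- select_anchor(stats)
  Sh <- estimate_support(stats, an, 1.5)
  expect_gt(length(Sh), 0)
  bt <- shrunken_scales(stats, an, Sh, 1.5)
  p <- 4
  Ecol <- stats$E[, (an$k_hat - 1) * p + an$j_hat]
  root <- sqrt(stats$t[an$j_hat, an$k_hat])
  for (i in seq_along(Sh)) {
    j <- Sh[i]
    expect_equal(unname(sign(bt[i])), sign(Ecol[j]))
    b <- abs(bt[i])
    expect_true(b %in% stats$grid$levels)
    expect_gte(abs(Ecol[j]) - b * root, 1.5)
    # next level up (if any) must fail the inequality
    up <- stats$grid$levels[stats$grid$levels > b]
    if (length(up))
      expect_lt(abs(Ecol[j]) - min(up) * root, 1.5)
  }
  # a coordinate violating the support inequality is refused
  bad <- which(abs(Ecol) - stats$grid$b_min * root < 1e6)[1]
  expect_error(shrunken_scales(stats, an, bad, 1e6), "violates")
})

test_that("confidence interval follows the reach formula and conventions", {
  mk <- make_decl()
  decl <- mk$decl
  # empty support: [0, N]
  expect_equal(confidence_interval(decl, integer(0), numeric(0), 4),
               c(0, decl$N))
  # single-coordinate hand computation: N = 100, t = 5, b = 1, d2 = 4
  fake <- decl
  fake$N <- 100
  k1 <- which(fake$grid$scales == fake$grid$levels[1])
  fake$t[2, k1] <- 5L
  ci <- confidence_interval(fake, 2L, setNames(fake$grid$levels[1], 2),
                            4 * fake$grid$levels[1]^2)
  expect_equal(ci, c(100 - 5 - 4, 100))
  # clamping at zero when the reach exceeds N
  ci0 <- confidence_interval(fake, 2L, setNames(fake$grid$levels[1], 2), 1e9)
  expect_equal(ci0[1], 0)
})

test_that("support and scales shrink monotonically as d1 grows", {
  mk <- make_decl()
  stats <- collect_extra(mk$decl)
  an <- select_anchor(stats)
  d1s <- c(0.5, 1, 2, 4, 8, 16)
  prev <- NULL
  prev_bt <- NULL
  for (d1 in d1s) {
    Sh <- estimate_support(stats, an, d1)
    if (!is.null(prev)) expect_true(all(Sh %in% prev))
    if (length(Sh)) {
      bt <- shrunken_scales(stats, an, Sh, d1)
      if (!is.null(prev_bt)) {
        common <- intersect(names(bt), names(prev_bt))
        expect_true(all(abs(bt[common]) <= abs(prev_bt[common]) + 1e-12))
      }
      prev_bt <- bt
    }
    prev <- Sh
  }
})

test_that("the full pipeline returns a valid inference object", {
  g <- scale_grid(5, 2)
  tn <- cached_calibration(5, 500, 2, n_runs = 30, seed = 2)
  for (rep in 1:10) {
    set.seed(900 + rep)
    x <- rbind(matrix(rnorm(50 * 5), 50, 5),
               matrix(rnorm(100 * 5), 100, 5) +
                 rep(c(3, -2, 0, 0, 0), each = 100))
    fit <- ocd_ci(x, g, tn)
    expect_true(fit$declared)
    expect_equal(fit$interval[2], fit$N)
    expect_gte(fit$interval[1], 0)
    expect_lte(fit$interval[1], fit$N)
    expect_false(fit$j_hat %in% fit$S_hat)
    expect_true(fit$b_hat %in% g$scales[g$in_B])
  }
})

test_that("inference is refused when no declaration was made", {
  g <- scale_grid(2, 1)
  tn <- default_tuning(2, beta = 1)
  tn$T_diag <- Inf; tn$T_off <- Inf
  set.seed(1)
  fit <- ocd_ci(matrix(rnorm(40), 20, 2), g, tn)
  expect_false(fit$declared)
  expect_null(fit$interval)
  expect_error(collect_extra(fit$declaration), "no declaration")
})

test_that("inference pipeline is permutation-equivariant", {
  g <- scale_grid(4, 1.5)
  tn <- default_tuning(4, beta = 1.5, gamma = 200)
  tn$T_diag <- 8; tn$T_off <- 20
  set.seed(71)
  x <- rbind(matrix(rnorm(40 * 4), 40, 4),
             matrix(rnorm(60 * 4), 60, 4) + rep(c(2.5, -2, 0, 0), each = 60))
  perm <- c(3, 1, 4, 2)
  f1 <- ocd_ci(x, g, tn)
  f2 <- ocd_ci(x[, perm], g, tn)
  expect_equal(f1$N, f2$N)
  # coordinate labels map through the permutation: column perm[j] of the
  # permuted stream is original coordinate perm[j]
  expect_equal(perm[f2$j_hat], f1$j_hat)
  expect_equal(sort(perm[f2$S_hat]), sort(f1$S_hat))
  expect_equal(f1$interval, f2$interval)
})
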