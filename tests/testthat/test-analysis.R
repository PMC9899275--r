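test_that("power-law fits recover exact exponents and flag non-power laws", {
  # exact tau^{-3/2} curve
  x <- 10^seq(0, 4, length.out = 50)
  f <- suppressWarnings( # exact synthetic input: lm flags the perfect fit
    fit_power_law(list(x = x, y = 0.3 * x^-1.5), window = c(1, 1e4)))
  expect_lt(abs(f$exponent - 1.5), 0.02)
  expect_gt(f$r_squared, 0.999)
  # geometric samples are not a power law on any wide window
  g <- with_seed(1, stats::rgeom(50000, 0.2) + 1)
  fg <- fit_power_law(g, window = c(1, 50), n_boot = 20)
  expect_lt(fg$r_squared, 0.9)
  expect_error(fit_power_law(g, window = c(1e4, 1e6)), "100 samples")
})

test_that("bootstrap CI covers the true density exponent for Pareto samples", {
  # density p(x) ~ x^{-2} (continuous Pareto, shape 1)
  cover <- vapply(1:40, function(r) {
    x <- with_seed(100 + r, 1 / stats::runif(10000))
    f <- fit_power_law(x, window = c(1.5, 300), n_boot = 100, seed = r)
    abs(f$exponent - 2) <= 2 * f$stderr
  }, logical(1))
  expect_gte(mean(cover), 0.85)
})

test_that("tail-rate estimation recovers geometric rates, invariant to shifts", {
  x <- with_seed(3, stats::rgeom(40000, 0.5) + 1)
  tr <- estimate_tail_rate(x, quantile = 0.5)
  expect_lt(abs(tr$rate - log(2)) / log(2), 0.05)
  tr_shift <- estimate_tail_rate(x + 7, quantile = 0.5)
  expect_equal(tr$rate, tr_shift$rate, tolerance = 1e-10)
  expect_error(estimate_tail_rate(x[1:50], quantile = 0.95), "insufficient tail")
})

test_that("terminal decay rate theta_n grows as n^{1/mu} for the 1d walk", {
  s1 <- substrate_hypercubic(1)
  ns <- c(50, 100, 200)
  ths <- vapply(ns, function(n) {
    x <- tau_ensemble(walk_model("simple"), s1, n, reps = 30000, seed = 13)
    estimate_tail_rate(as.vector(x), n = n, quantile = 0.99)$theta_n
  }, numeric(1))
  slope <- unname(coef(stats::lm(log(ths) ~ log(ns)))[2])
  expect_lt(abs(slope - 2), 0.2)
})

test_that("scaling collapse scores identify the true exponents", {
  # identical curves collapse to score zero
  c0 <- list(data.frame(x = 1:50, y = (1:50)^-2),
             data.frame(x = 1:50, y = (1:50)^-2))
  expect_equal(scaling_collapse(c0, c(10, 10), 0, 0)$score, 0)
  # synthetic curves built from one psi at mu = 1/2: grid search lands on 1/2
  ns <- c(100, 400, 1600)
  curves <- synthetic_psi_curves(0.5, ns)
  grid <- seq(0.3, 0.9, by = 0.05)
  scores <- vapply(grid, function(m)
    scaling_collapse(curves, ns, x_exp = 1 / m, y_exp = 1 + 1 / m)$score,
    numeric(1))
  expect_equal(grid[which.min(scores)], 0.5)
  expect_error(scaling_collapse(list(data.frame(x = 1:10, y = 1:10),
                                     data.frame(x = 1e6 + 1:10, y = 1:10)),
                                c(2, 2), 0, 0), "disjoint")
})

test_that("marginal 2d data collapse under X = tau/sqrt(n)", {
  ns <- c(200, 800, 3200)
  tm <- tau_ensemble(walk_model("simple"), substrate_hypercubic(2), ns,
                     reps = 5000, seed = 53)
  curves <- lapply(seq_along(ns), function(i) {
    x <- tm[, i]
    log_bin_histogram(x[is.finite(x)])
  })
  right <- scaling_collapse(curves, ns, x_exp = 0.5, y_exp = 1)$score
  wrong <- scaling_collapse(curves, ns, x_exp = 0.7, y_exp = 1)$score
  expect_lt(right, wrong)
  expect_lt(right, 0.1)
})

test_that("covariance of N(t) behaves like a covariance", {
  N <- n_visited_ensemble(walk_model("levy", alpha = 1.5),
                          substrate_hypercubic(1), c(50, 100, 400),
                          reps = 2000, seed = 55)
  cv <- covariance_N(N, 100, 100)
  expect_equal(cv$cov, stats::var(N[, 2]))
  expect_gte(cv$cov, 0)
  # shuffling one column across an independent ensemble kills the covariance
  N2 <- N
  N2[, 3] <- N[with_seed(5, sample(nrow(N))), 3]
  cv0 <- covariance_N(N2, 100, 400)
  se <- stats::sd(N[, 2]) * stats::sd(N[, 3]) / sqrt(nrow(N))
  expect_lt(abs(cv0$cov), 3 * se)
  expect_error(covariance_N(N[1:10, ], 50, 100), "paths")
  expect_error(covariance_N(N, 400, 100), "t1 must be")
})

test_that("k-point moments reduce to the covariance at k = 2", {
  N <- n_visited_ensemble(walk_model("levy", alpha = 1.5),
                          substrate_hypercubic(1), c(20, 80), reps = 1500,
                          seed = 57)
  k2 <- kpoint_moment(N, c(20, 80))
  cv <- covariance_N(N, 20, 80)
  expect_equal(k2, cv$normalized, tolerance = 1e-10)
  expect_error(kpoint_moment(N, c(80, 20)), "ordered")
  expect_error(kpoint_moment(N, c(20, 40, 80)), "k = 2 and k = 4")
})

test_that("partial sums of independent synthetic taus are uncorrelated", {
  vt <- with_seed(7, {
    taus <- matrix(stats::rexp(2000 * 60), 2000, 60)
    t(apply(taus, 1, cumsum))
  })
  colnames(vt) <- 1:60
  cv <- partial_sum_covariance(vt, 30, 60)
  expect_lt(abs(cv), 4 * 30 / sqrt(2000)) # Var of each sum is ~30
  # n2 = n1 + 1: reduces to Cov(partial sum, single tau)
  one <- partial_sum_covariance(vt, 30, 31)
  direct <- stats::cov(vt[, 30], vt[, 31] - vt[, 30])
  expect_equal(one, direct, tolerance = 1e-12)
})

test_that("1d recurrent moments and giant fluctuations scale as predicted", {
  ns <- c(25, 50, 100, 200)
  tm <- tau_ensemble(walk_model("simple"), substrate_hypercubic(1), ns,
                     reps = 20000, seed = 9)
  m1 <- colMeans(tm)
  m2 <- colMeans(tm^2)
  vr <- apply(tm, 2, stats::var) / m1^2
  expect_lt(abs(unname(coef(stats::lm(log(m1) ~ log(ns)))[2]) - 1), 0.1)
  expect_lt(abs(unname(coef(stats::lm(log(m2) ~ log(ns)))[2]) - 3), 0.3)
  expect_lt(abs(unname(coef(stats::lm(log(vr) ~ log(ns)))[2]) - 1), 0.15)
})

test_that("marginal mean inter-visit time grows logarithmically", {
  ns <- round(10^seq(2, 4, by = 0.5))
  tm <- tau_ensemble(walk_model("simple"), substrate_hypercubic(2), ns,
                     reps = 20000, seed = 91)
  m <- colMeans(tm)
  fit <- stats::lm(m ~ log(ns))
  expect_gt(summary(fit)$r.squared, 0.95)
  expect_gt(unname(coef(fit)[2]), 0)
})

test_that("tau distributions age: n and 4n samples differ beyond resampling noise", {
  tm <- tau_ensemble(walk_model("simple"), substrate_hypercubic(1), c(8, 32),
                     reps = 30000, seed = 85)
  ks <- suppressWarnings(stats::ks.test(tm[, 1], tm[, 2])$statistic)
  base <- with_seed(5, replicate(100, {
    i <- sample(nrow(tm), nrow(tm) / 2)
    suppressWarnings(stats::ks.test(tm[i, 1], tm[-i, 1])$statistic)
  }))
  expect_gt(ks, stats::quantile(base, 0.99))
})

test_that("starving walk matches exact enumeration at S = 1 and lives >= S", {
  out <- starving_walk(S = 1, d = 2, reps = 80000, seed = 61)
  exact <- starving_s1_exact(4)
  for (t in 2:4) { # death at t = 1 is impossible; t = 2 is the first chance
    se <- sqrt(exact[t] * (1 - exact[t]) / nrow(out))
    expect_lt(abs(mean(out$lifetime == t) - exact[t]), 4 * se + 1e-12)
  }
  expect_equal(exact[1], 0)
  expect_true(all(out$lifetime >= 1))
  expect_true(all(out$sites_at_death >= 1))
  out8 <- starving_walk(S = 8, d = 2, reps = 500, seed = 63)
  expect_true(all(out8$lifetime >= 8))
})

test_that("1d forager lifetime grows linearly with the metabolic time", {
  sw <- starvation_sweep(c(8, 16, 32, 64), d = 1, reps = 1000, seed = 65)
  expect_lt(abs(attr(sw, "slope") - 1), 0.15)
})

test_that("plateau detection summarizes slowly varying rescaled curves", {
  x <- seq_len(100)
  flat <- detect_plateau(x, rep(2, 100) + 0.01 * sin(x))
  expect_lt(flat$rel_spread, 0.02)
  expect_equal(flat$level, 2, tolerance = 0.02)
  steep <- detect_plateau(x, x)
  expect_gt(steep$rel_spread, 0.2)
})
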