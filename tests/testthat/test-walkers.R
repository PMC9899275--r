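test_that("simple steps are uniform over neighbours", {
  # 1d: long-run fraction of right-steps = 1/2 within 3 binomial sigma
  tr <- simulate_trajectory(walk_model("simple"), substrate_hypercubic(1),
                            steps = 40000, seed = 1)
  inc <- diff(tr$sites[, 1])
  expect_lt(abs(mean(inc == 1) - 0.5), 3 * sqrt(0.25 / length(inc)))
  # 2d: single step from origin lands on each of the 4 neighbours w.p. 1/4
  firsts <- vapply(1:4000, function(k) {
    s <- simulate_trajectory(walk_model("simple"), substrate_hypercubic(2),
                             steps = 1, seed = 2, stream = k)$sites[2, ]
    paste(s, collapse = ",")
  }, character(1))
  cnt <- table(factor(firsts, levels = c("-1,0", "1,0", "0,-1", "0,1")))
  expect_gt(stats::chisq.test(cnt)$p.value, 1e-4)
})

test_that("graph walks choose uniformly among existing neighbours", {
  # a degree-3 junction of the T-tree: each neighbour visited w.p. 1/3
  sub <- substrate_ttree(2)
  expect_length(sub$adj[[sub$start]], 3)
  firsts <- vapply(1:3000, function(k) {
    cpp_walk_graph(sub$csr$indptr, sub$csr$indices, sub$start - 1L, 1, 3,
                   k)[2] + 1L
  }, integer(1))
  cnt <- table(factor(firsts, levels = sub$adj[[sub$start]]))
  expect_gt(stats::chisq.test(cnt)$p.value, 1e-4)
})

test_that("persistent steps follow the repeat/uniform-remainder rule", {
  p <- 0.3
  tr <- simulate_trajectory(walk_model("persistent", p = p),
                            substrate_hypercubic(2), steps = 60000, seed = 3)
  inc <- diff(tr$sites)
  key <- paste(inc[, 1], inc[, 2])
  rep_frac <- mean(key[-1] == key[-length(key)])
  expect_lt(abs(rep_frac - p), 3 * sqrt(p * (1 - p) / length(key)))
  # each non-repeat direction has probability (1-p)/3 ~ 0.2333
  dirs <- unique(key)
  for (d in dirs) {
    after <- key[-1][key[-length(key)] == d]
    others <- after[after != d]
    frac <- length(others) / length(after)
    expect_lt(abs(frac - (1 - p)), 4 * sqrt(p * (1 - p) / length(after)))
    # and uniform over the 3 remaining directions
    expect_gt(stats::chisq.test(table(others))$p.value, 1e-4)
  }
  expect_error(walk_model("persistent", p = 1.2), "p in \\(0, 1\\)")
  expect_error(walk_model("persistent"), "p in \\(0, 1\\)")
})

test_that("persistent walk at p = 1/(2d) reduces to the simple walk law", {
  # one-step displacement frequencies match between the two models
  step_of <- function(model, k)
    paste(simulate_trajectory(model, substrate_hypercubic(2), 2, seed = 5,
                              stream = k)$sites[3, ], collapse = ",")
  a <- vapply(1:3000, function(k) step_of(walk_model("persistent", p = 0.25), k),
              character(1))
  b <- vapply(1:3000, function(k) step_of(walk_model("simple"), k), character(1))
  tab <- rbind(table(factor(a, levels = unique(c(a, b)))),
               table(factor(b, levels = unique(c(a, b)))))
  expect_gt(stats::chisq.test(tab)$p.value, 1e-3)
})

test_that("discrete Levy law is normalized with the printed zeta constant", {
  for (alpha in c(1, 1.5)) {
    s <- c(-(2000:1), 1:2000)
    mass <- sum(levy_jump_pmf(s, alpha))
    # remaining tail mass: 2 * sum_{s>2000} s^{-(1+a)} / (2 zeta)
    tail <- 2000^(-alpha) / alpha / (2 * pracma::zeta(1 + alpha)) * 2
    expect_lt(abs(mass + tail - 1), 1e-4)
  }
  expect_equal(cpp_zeta(2), pi^2 / 6, tolerance = 1e-10)
  expect_equal(cpp_zeta(2.5), pracma::zeta(2.5), tolerance = 1e-8)
  expect_error(levy_jump_pmf(0, 1.5), "no mass")
  expect_error(walk_model("levy", alpha = 0.8), "alpha >= 1")
})

test_that("Levy sampler matches the closed-form law and is symmetric", {
  x <- sample_levy_jumps(200000, alpha = 1, seed = 11)
  # P(|s| = 1) = 1/zeta(2) = 6/pi^2
  p1 <- 6 / pi^2
  expect_lt(abs(mean(abs(x) == 1) - p1), 4 * sqrt(p1 * (1 - p1) / length(x)))
  expect_lt(abs(mean(sign(x))), 4 / sqrt(length(x)))
  # P(|s| = 2) = 1/(4 zeta(2))
  p2 <- 1 / (4 * pracma::zeta(2))
  expect_lt(abs(mean(abs(x) == 2) - p2), 4 * sqrt(p2 * (1 - p2) / length(x)))
})

test_that("2d Levy steps: uniform axes, magnitudes from the 1d law", {
  tr <- simulate_trajectory(walk_model("levy", alpha = 1.3),
                            substrate_hypercubic(2), steps = 40000, seed = 13)
  inc <- diff(tr$sites)
  ax <- ifelse(inc[, 1] != 0, ifelse(inc[, 1] > 0, "x+", "x-"),
               ifelse(inc[, 2] > 0, "y+", "y-"))
  expect_gt(stats::chisq.test(table(ax))$p.value, 1e-4)
  mag2d <- abs(inc[, 1] + inc[, 2])
  mag1d <- abs(sample_levy_jumps(40000, alpha = 1.3, seed = 14))
  for (m in 1:4) {
    pm <- mean(mag1d == m)
    expect_lt(abs(mean(mag2d == m) - pm), 4 * sqrt(pm / length(mag2d)))
  }
  # alpha = 1 in 2d is transient with mu = 2
  pred <- classify_walk(2, 1)
  expect_equal(pred$mu, 2)
  expect_equal(pred$walk_class, "transient")
})

test_that("TSAW jump probabilities follow the visit-count softmax", {
  # after one right step the start site holds C = 1, the site ahead C = 0:
  # P(continue right) = 1/(1 + e^{-1})
  second <- vapply(1:6000, function(k) {
    diff(simulate_trajectory(walk_model("tsaw"), substrate_hypercubic(1), 2,
                             seed = 17, stream = k)$sites[, 1])
  }, numeric(2))
  first_right <- second[1, ] == 1
  expect_lt(abs(mean(first_right) - 0.5), 4 * sqrt(0.25 / ncol(second)))
  p_cont <- 1 / (1 + exp(-1))
  cont <- second[2, first_right] == 1
  expect_lt(abs(mean(cont) - p_cont),
            4 * sqrt(p_cont * (1 - p_cont) / sum(first_right)))
  # the quoted law: equal counts give 1/2, counts (1, 0) give 1/(1+e)
  expect_equal(exp(-1) / (exp(-1) + exp(-1)), 0.5)
  expect_equal(exp(-1) / (exp(-1) + exp(0)), 1 / (1 + exp(1)), tolerance = 1e-12)
})

test_that("trajectories are bit-reproducible per (seed, stream)", {
  a <- simulate_trajectory(walk_model("levy", alpha = 1.4),
                           substrate_hypercubic(1), 500, seed = 19, stream = 2)
  b <- simulate_trajectory(walk_model("levy", alpha = 1.4),
                           substrate_hypercubic(1), 500, seed = 19, stream = 2)
  expect_identical(a$sites, b$sites)
  c <- simulate_trajectory(walk_model("levy", alpha = 1.4),
                           substrate_hypercubic(1), 500, seed = 19, stream = 3)
  expect_false(identical(a$sites, c$sites))
  ta <- simulate_tau(walk_model("simple"), substrate_gasket(5), 100, seed = 23)
  tb <- simulate_tau(walk_model("simple"), substrate_gasket(5), 100, seed = 23)
  expect_identical(ta$taus, tb$taus)
})

test_that("mean-square displacement exponents recover 2/d_w", {
  tg <- round(10^seq(1, 4, by = 0.25))
  m2 <- msd_ensemble(walk_model("simple"), substrate_hypercubic(2), tg,
                     reps = 1000, seed = 81)
  sl <- unname(coef(stats::lm(log10(colMeans(m2)) ~ log10(tg)))[2])
  expect_lt(abs(sl - 1), 0.05)
  mg <- msd_ensemble(walk_model("simple"), substrate_gasket(10), tg,
                     reps = 1000, seed = 83)
  slg <- unname(coef(stats::lm(log10(colMeans(mg)) ~ log10(tg)))[2])
  expect_lt(abs(slg - 2 * log(2) / log(5)), 0.05)
})

test_that("Hosking fGn has the exact stationary covariance structure", {
  # unit variance at every step
  v <- mean(vapply(1:40, function(k) stats::var(fbm_hosking(0.7, 400, seed = 2000 + k)),
                   numeric(1)))
  expect_lt(abs(v - 1), 0.05)
  # H = 1/2: independent increments
  ac0 <- mean(vapply(1:60, function(k) {
    x <- fbm_hosking(0.5, 500, seed = 3000 + k)
    mean(x[-1] * x[-length(x)])
  }, numeric(1)))
  expect_lt(abs(ac0), 0.02)
  # H = 0.75: lag-1 autocovariance (2^{1.5} - 2)/2 ~ 0.414
  ac1 <- mean(vapply(1:120, function(k) {
    x <- fbm_hosking(0.75, 500, seed = 4000 + k)
    mean(x[-1] * x[-length(x)])
  }, numeric(1)))
  expect_lt(abs(ac1 - 0.5 * (2^1.5 - 2)), 0.05)
  expect_error(fbm_hosking(1.2, 10, 1), "H must be")
  expect_error(fbm_visits(0, 10, 1), "H must be")
})

test_that("fbm visitation counts unit intervals at first entry", {
  fv <- fbm_visits(0.75, 1500, seed = 5)
  expect_true(all(fv$taus$tau >= 1))
  expect_lte(sum(fv$taus$tau), 1500)
  expect_false(any(duplicated(fv$sites)))
  # reconstruct from the path directly
  incr <- fbm_hosking(0.75, 1500, seed = 5)
  iv <- floor(c(0, cumsum(incr)))
  expect_equal(fv$taus$tau, as.numeric(diff(which(!duplicated(iv)) - 1L)))
})
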