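test_that("two-site 1d domain gives the geometric exit law exactly", {
  s1 <- substrate_hypercubic(1)
  dom <- visited_domain(matrix(c(0, 1), ncol = 1), s1)
  ed <- exit_time_distribution(dom, start = 2, tau_max = 40)
  expect_equal(ed$mass, 2^-(1:length(ed$mass)), tolerance = 1e-12)
  expect_lt(abs(sum(ed$mass) + ed$survival - 1), 1e-12)
  me <- mean_exit_time(dom)
  expect_equal(me$per_start, c(2, 2), tolerance = 1e-10)
  expect_equal(me$average, 2, tolerance = 1e-10)
  # single-site domain: every step exits
  dom1 <- visited_domain(matrix(0, 1, 1), s1)
  expect_equal(mean_exit_time(dom1)$average, 1, tolerance = 1e-12)
  ed1 <- exit_time_distribution(dom1, start = 1, tau_max = 5)
  expect_equal(ed1$mass[1], 1)
})

test_that("interval exit matches the spectral oracle and decays as tau^{-3/2}", {
  n <- 30
  s1 <- substrate_hypercubic(1)
  dom <- visited_domain(matrix(seq_len(n), ncol = 1), s1)
  ed <- exit_time_distribution(dom, start = 1, tau_max = 2000, tol = 0)
  oracle <- interval_exit_spectral(n, start = 1, t_max = 2000)
  expect_lt(max(abs(ed$mass - oracle)), 1e-10)
  # tail over 1 << tau << n^2 from a larger interval
  dom2 <- visited_domain(matrix(1:100, ncol = 1), s1)
  ed2 <- exit_time_distribution(dom2, start = 1, tau_max = 2000, tol = 0)
  f <- fit_power_law(bin_mass_curve(ed2$mass), window = c(5, 1000))
  expect_lt(abs(f$exponent - 1.5), 0.05)
})

test_that("mass is conserved and prefixes are stable for all Markov models", {
  s2 <- substrate_hypercubic(2)
  ts <- simulate_tau(walk_model("simple"), s2, n_max = 25, seed = 45)
  dom <- visited_domain(ts$sites, s2)
  for (model in list(walk_model("simple"), walk_model("persistent", p = 0.3))) {
    ed <- exit_time_distribution(dom, start = 25, tau_max = 3000, model = model,
                                 tol = 0)
    expect_lt(abs(sum(ed$mass) + ed$survival - 1), 1e-12)
    ed_short <- exit_time_distribution(dom, start = 25, tau_max = 100,
                                       model = model, tol = 0)
    expect_equal(ed_short$mass, ed$mass[1:100], tolerance = 1e-14)
  }
  s1 <- substrate_hypercubic(1)
  tl <- simulate_tau(walk_model("levy", alpha = 1.5), s1, n_max = 20, seed = 47)
  doml <- visited_domain(tl$sites, s1)
  edl <- exit_time_distribution(doml, start = 20, tau_max = 500,
                                model = walk_model("levy", alpha = 1.5), tol = 0)
  expect_lt(abs(sum(edl$mass) + edl$survival - 1), 1e-10)
  # graph substrate domain
  g <- substrate_gasket(5)
  tg <- simulate_tau(walk_model("simple"), g, n_max = 20, seed = 49)
  domg <- visited_domain(tg$sites, g)
  edg <- exit_time_distribution(domg, start = 20, tau_max = 1000, tol = 0)
  expect_lt(abs(sum(edg$mass) + edg$survival - 1), 1e-12)
})

test_that("enumeration agrees with Monte Carlo on small domains", {
  s2 <- substrate_hypercubic(2)
  ts <- simulate_tau(walk_model("simple"), s2, n_max = 12, seed = 71)
  dom <- visited_domain(ts$sites, s2)
  reps <- 100000
  # simple walk
  ed <- exit_time_distribution(dom, start = 12, tau_max = 300, tol = 0)
  mc <- cpp_mc_exit(0L, 2L, 0, dom$sites, 12L, reps, 73)
  for (k in 1:8) {
    se <- sqrt(ed$mass[k] * (1 - ed$mass[k]) / reps)
    expect_lt(abs(mean(mc == k) - ed$mass[k]), 4 * se + 1e-12)
  }
  # persistent walk on the same domain (direction-augmented enumeration)
  edp <- exit_time_distribution(dom, start = 12, tau_max = 300,
                                model = walk_model("persistent", p = 0.4),
                                tol = 0)
  mcp <- cpp_mc_exit(1L, 2L, 0.4, dom$sites, 12L, reps, 75)
  for (k in 1:8) {
    se <- sqrt(edp$mass[k] * (1 - edp$mass[k]) / reps)
    expect_lt(abs(mean(mcp == k) - edp$mass[k]), 4 * se + 1e-12)
  }
  # 1d Levy with long-range columns
  s1 <- substrate_hypercubic(1)
  tl <- simulate_tau(walk_model("levy", alpha = 1.5), s1, n_max = 10, seed = 77)
  doml <- visited_domain(tl$sites, s1)
  edl <- exit_time_distribution(doml, start = 10, tau_max = 300,
                                model = walk_model("levy", alpha = 1.5), tol = 0)
  mcl <- cpp_mc_exit(2L, 1L, 1.5, doml$sites, 10L, reps, 79)
  for (k in 1:6) {
    se <- sqrt(edl$mass[k] * (1 - edl$mass[k]) / reps)
    expect_lt(abs(mean(mcl == k) - edl$mass[k]), 4 * se + 2e-4)
  }
})

test_that("non-Markovian models and invalid starts are rejected", {
  s1 <- substrate_hypercubic(1)
  dom <- visited_domain(matrix(0:4, ncol = 1), s1)
  expect_error(exit_time_distribution(dom, start = 3, tau_max = 10,
                                      model = walk_model("tsaw")),
               "history-dependent")
  expect_error(exit_time_distribution(dom, start = 3, tau_max = 10,
                                      model = walk_model("fbm", H = 0.5)),
               "history-dependent")
  expect_error(exit_time_distribution(dom, start = 9, tau_max = 10),
               "start must index")
})

test_that("mean exit time tracks the domain surface", {
  s2 <- substrate_hypercubic(2)
  # at fixed n, small-surface (compact) domains hold the walker longest
  fixed <- t(vapply(1:30, function(k) {
    dom <- visited_domain(simulate_tau(walk_model("simple"), s2, 60,
                                       seed = 93, stream = k)$sites, s2)
    c(me = mean_exit_time(dom)$average, P = domain_perimeter(dom))
  }, numeric(2)))
  ft <- stats::lm(me ~ P, as.data.frame(fixed))
  expect_lt(unname(coef(ft)[2]), 0)
  expect_gt(summary(ft)$r.squared, 0.5)
  # across n, the start-averaged exit time grows with the surface
  across <- t(vapply(c(20, 40, 80, 160, 320), function(n) {
    v <- vapply(1:15, function(k) {
      dom <- visited_domain(simulate_tau(walk_model("simple"), s2, n,
                                         seed = 95, stream = k + n)$sites, s2)
      c(mean_exit_time(dom)$average, domain_perimeter(dom))
    }, numeric(2))
    rowMeans(v)
  }, numeric(2)))
  fa <- stats::lm(across[, 1] ~ across[, 2])
  expect_gt(unname(coef(fa)[2]), 0)
  expect_gt(summary(fa)$r.squared, 0.9)
})
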