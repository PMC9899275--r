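test_that("record_visitation counts first visits and inter-visit times", {
  # hand-enumerated 1d path 0, 1, 0, -1
  rv <- record_visitation(matrix(c(0, 1, 0, -1), ncol = 1),
                          substrate_hypercubic(1))
  expect_equal(rv$tau_series$tau, c(1, 2))
  expect_equal(rv$N, c(1, 2, 2, 3))
  expect_equal(rv$domain$n, 3)
  # Levy jump 0 -> 3: flown-over sites 1, 2 are not visited
  rv2 <- record_visitation(matrix(c(0, 3), ncol = 1), substrate_hypercubic(1))
  expect_equal(rv2$N, c(1, 2))
  expect_equal(rv2$domain$n, 2)
  # conservation on random trajectories: N(T) = 1 + number of taus
  for (k in 1:5) {
    tr <- simulate_trajectory(walk_model("simple"), substrate_hypercubic(2),
                              300, seed = 31, stream = k)
    rv3 <- record_visitation(tr)
    expect_equal(rv3$N[length(rv3$N)], 1 + nrow(rv3$tau_series))
    expect_true(all(diff(rv3$N) %in% c(0, 1)))
  }
})

test_that("fused tau recording agrees with trajectory-based recording", {
  for (spec in list(list(m = walk_model("simple"), d = 2),
                    list(m = walk_model("levy", alpha = 1.4), d = 1),
                    list(m = walk_model("tsaw"), d = 1))) {
    sub <- substrate_hypercubic(spec$d)
    ts <- simulate_tau(spec$m, sub, n_max = 60, seed = 33, stream = 4)
    tr <- simulate_trajectory(spec$m, sub, steps = ts$total_time, seed = 33,
                              stream = 4)
    rv <- record_visitation(tr)
    expect_equal(rv$tau_series$tau[seq_len(nrow(ts$taus))], ts$taus$tau)
  }
  # graph substrate path
  g <- substrate_gasket(6)
  ts <- simulate_tau(walk_model("simple"), g, n_max = 50, seed = 35)
  tr_sites <- cpp_walk_graph(g$csr$indptr, g$csr$indices, g$start - 1L,
                             ts$total_time, 35, 0) + 1L
  rv <- record_visitation(tr_sites, g)
  expect_equal(rv$tau_series$tau, ts$taus$tau)
})

test_that("boundary is exactly the unvisited nearest neighbours", {
  s2 <- substrate_hypercubic(2)
  expect_equal(nrow(boundary_of(visited_domain(matrix(c(0, 0), 1), s2))), 4)
  block <- as.matrix(expand.grid(0:1, 0:1))
  expect_equal(nrow(boundary_of(visited_domain(block, s2))), 8)
  s1 <- substrate_hypercubic(1)
  expect_equal(nrow(boundary_of(visited_domain(matrix(1:7, ncol = 1), s1))), 2)
  # invariants on random domains, against a brute-force scan
  for (k in 1:4) {
    ts <- simulate_tau(walk_model("simple"), s2, n_max = 40, seed = 37,
                       stream = k)
    dom <- visited_domain(ts$sites, s2)
    bd <- boundary_of(dom)
    vis_keys <- apply(dom$sites, 1, paste, collapse = ",")
    bd_keys <- apply(bd, 1, paste, collapse = ",")
    expect_length(intersect(bd_keys, vis_keys), 0)
    brute <- unique(unlist(lapply(seq_len(nrow(dom$sites)), function(i) {
      nb <- site_neighbors(s2, dom$sites[i, ])
      setdiff(apply(nb, 1, paste, collapse = ","), vis_keys)
    })))
    expect_setequal(bd_keys, brute)
  }
})

test_that("perimeter counts boundary bonds and is even on all small polyominoes", {
  s2 <- substrate_hypercubic(2)
  expect_equal(domain_perimeter(visited_domain(matrix(c(0, 0), 1), s2)), 4)
  expect_equal(domain_perimeter(visited_domain(rbind(c(0, 0), c(1, 0)), s2)), 6)
  polys <- enumerate_polyominoes(6)
  expect_gt(length(polys), 300) # all fixed polyominoes up to 6 cells
  peris <- vapply(polys, function(p)
    domain_perimeter(visited_domain(p, s2)), numeric(1))
  expect_true(all(peris %% 2 == 0))
  expect_true(all(peris >= 4))
})

test_that("perimeter series agrees with from-scratch recomputation", {
  tr <- simulate_trajectory(walk_model("simple"), substrate_hypercubic(2),
                            400, seed = 39)
  ps <- perimeter_series(tr)
  keys <- apply(tr$sites, 1, paste, collapse = ",")
  for (t in c(50, 200, 400)) {
    dom <- visited_domain(tr$sites[seq_len(t + 1), , drop = FALSE][!duplicated(keys[seq_len(t + 1)]), , drop = FALSE],
                          substrate_hypercubic(2))
    expect_equal(ps$P[t + 1], domain_perimeter(dom))
  }
  # level first-attainment times are non-decreasing in the level
  expect_true(all(diff(ps$level_times$t_first) >= 0))
})

test_that("island counting matches flood-fill geometry", {
  s2 <- substrate_hypercubic(2)
  ring <- rbind(c(-1, -1), c(0, -1), c(1, -1), c(-1, 0), c(1, 0),
                c(-1, 1), c(0, 1), c(1, 1))
  expect_equal(island_count(visited_domain(ring, s2)), 1)
  filled <- as.matrix(expand.grid(-1:1, -1:1))
  expect_equal(island_count(visited_domain(filled, s2)), 0)
  two_holes <- rbind(as.matrix(expand.grid(0:2, 0:2)),
                     as.matrix(expand.grid(4:6, 0:2)))
  two_holes <- two_holes[!(two_holes[, 1] %in% c(1, 5) & two_holes[, 2] == 1), ]
  expect_equal(island_count(visited_domain(two_holes, s2)), 2)
})

test_that("1d island level tracker agrees with a direct gap recount", {
  # same (seed, stream) reproduces the same Levy path as the level tracker
  path <- simulate_trajectory(walk_model("levy", alpha = 1.3),
                              substrate_hypercubic(1), 3000, seed = 41,
                              stream = 0)$sites[, 1]
  count_islands <- function(x) {
    v <- sort(unique(x))
    sum(diff(v) > 1)
  }
  lv <- island_level_times(alpha = 1.3, i_max = 12, reps = 1, seed = 41,
                           horizon = 3000)
  for (i in which(is.finite(lv[1, ]))) {
    t_i <- lv[1, i]
    expect_equal(count_islands(path[seq_len(t_i + 1)]), i)
    if (t_i > 0) expect_lt(count_islands(path[seq_len(t_i)]), i)
  }
})

test_that("largest trap-free radius matches definitions and brute force", {
  s1 <- substrate_hypercubic(1)
  for (n in c(4, 5, 9))
    expect_equal(largest_trapfree_radius(visited_domain(matrix(1:n, ncol = 1), s1)),
                 ceiling(n / 2))
  s2 <- substrate_hypercubic(2)
  expect_equal(largest_trapfree_radius(visited_domain(matrix(c(0, 0), 1), s2)), 1)
  # random small domains: equality with an all-pairs scan over a padded box
  for (k in 1:4) {
    ts <- simulate_tau(walk_model("simple"), s2, n_max = 30, seed = 43,
                       stream = k)
    dom <- visited_domain(ts$sites, s2)
    keys <- apply(dom$sites, 1, paste, collapse = ",")
    box <- as.matrix(expand.grid(
      (min(dom$sites[, 1]) - 2):(max(dom$sites[, 1]) + 2),
      (min(dom$sites[, 2]) - 2):(max(dom$sites[, 2]) + 2)))
    unvis <- box[!(apply(box, 1, paste, collapse = ",") %in% keys), , drop = FALSE]
    brute <- max(vapply(seq_len(nrow(dom$sites)), function(i)
      sqrt(min(colSums((t(unvis) - dom$sites[i, ])^2))), numeric(1)))
    expect_equal(largest_trapfree_radius(dom), brute)
  }
})

test_that("trap-free radius grows as n^{1/d_f} (1d) and n^{1/(2 d_f)} (2d)", {
  s1 <- substrate_hypercubic(1)
  ns1 <- c(50, 100, 200)
  med1 <- vapply(ns1, function(n) {
    stats::median(vapply(1:30, function(k)
      largest_trapfree_radius(visited_domain(
        simulate_tau(walk_model("simple"), s1, n, seed = 37, stream = k)$sites,
        s1)), numeric(1)))
  }, numeric(1))
  sl1 <- unname(coef(stats::lm(log(med1) ~ log(ns1)))[2])
  expect_lt(abs(sl1 - 1), 0.1)
  s2 <- substrate_hypercubic(2)
  ns2 <- c(200, 800, 3200)
  med2 <- vapply(ns2, function(n) {
    stats::median(vapply(1:40, function(k)
      largest_trapfree_radius(visited_domain(
        simulate_tau(walk_model("simple"), s2, n, seed = 31,
                     stream = k + n * 1000)$sites, s2)), numeric(1)))
  }, numeric(1))
  sl2 <- unname(coef(stats::lm(log(med2) ~ log(ns2)))[2])
  expect_lt(abs(sl2 - 0.25), 0.05)
})

test_that("bulk dimer increments share the tau_n statistics", {
  ev <- dimer_events(alpha = 1.5, n_events = 3000, seed = 87)
  td <- diff(ev$dimer_times)
  tn <- diff(ev$site_times)
  f_dimer <- fit_power_law(td[td >= 1], window = c(3, 300), n_boot = 30)
  f_tau <- fit_power_law(tn[tn >= 1], window = c(3, 300), n_boot = 30)
  expect_lt(abs(f_dimer$exponent - f_tau$exponent), 0.3)
})
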