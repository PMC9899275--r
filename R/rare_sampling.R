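#' Wang-Landau biased sampling of visited domains
#'
#' For transient walks the deep tail of \eqn{F_n(\tau)} is carried by rare
#' domains of atypically small boundary surface (equivalently, large
#' trap-free regions), far beyond the reach of plain Monte Carlo. The
#' sampler runs a Markov chain over *generating trajectories* — so every
#' sampled domain is guaranteed realizable by the walk — with suffix-regrowth
#' moves: pick a cut point uniformly along the current trajectory, keep the
#' prefix, and resimulate until n distinct sites are again reached. Moves
#' are accepted with Wang-Landau weights on the resulting boundary-surface
#' size (boundary-bond count), which drives the surface histogram flat and
#' so boosts the small-surface states. The modification factor ln f starts
#' at 1 and is halved whenever the histogram is flat (min/max >= the
#' flatness threshold over visited bins).
#'
#' @name rare_sampling
NULL

#' Generate a Wang-Landau ensemble of visited domains at fixed n
#'
#' @param d lattice dimension; the walk must be transient, so `d >= 3` for
#'   the simple walk (recurrent/marginal requests are refused: their surface
#'   coordinate is degenerate or the tail needs no biasing).
#' @param n number of distinct sites per domain, >= 10.
#' @param model a [walk_model()], simple or persistent.
#' @param moves Monte Carlo moves per histogram-flatness check.
#' @param n_halvings halvings of ln f to perform.
#' @param flatness histogram flatness threshold (min/max over the binned
#'   surface window).
#' @param max_sweeps bail-out bound on flatness checks; non-convergence
#'   returns the partial ensemble with a warning.
#' @param keep_every thinning interval for stored domains (final stage).
#' @param n_bins number of surface bins across the biasing window. The
#'   window spans from just below the minimal (sphere-like) surface
#'   `~4.5 n^{(d-1)/d}` to the maximal `2d n`; surfaces outside clamp into
#'   the edge bins.
#' @param seed integer seed.
#' @return A `domain_ensemble`: `domains` (site matrices in discovery
#'   order), `surface` (boundary-bond counts), `log_weights` (log
#'   density-of-states estimates g(s); unbiasing weights are
#'   `exp(log_weights)`), `wl` (schedule record), `converged`.
#' @export
wang_landau_domains <- function(d, n, model = walk_model("simple"),
                                moves = 2000, n_halvings = 16,
                                flatness = 0.8, max_sweeps = 400,
                                keep_every = 10, n_bins = 24, seed = 1) {
  if (n < 10) stop("n must be >= 10")
  dims <- model_dimensions(model, substrate_hypercubic(d))
  mu <- dims$d_f / dims$d_w
  if (mu <= 1)
    stop("Wang-Landau domain biasing requires a transient walk (mu > 1); ",
         "got mu = ", signif(mu, 3),
         " - for recurrent walks the surface coordinate is degenerate")
  mc <- model_code(model, d)
  horizon <- 1e7
  empty <- matrix(0, 1, d)
  traj <- cpp_prefix_extend(mc$code, d, mc$par, empty, n, horizon, seed, 0)
  surface_of <- function(tr) cpp_boundary_bonds(unique_sites(tr), d)
  # biasing window: from just below the minimal (sphere-like) surface to the
  # maximal possible boundary-bond count; values outside clamp to the edges
  s_min <- floor(4.5 * n^((d - 1) / d))
  s_max <- 2 * d * n
  bin_edges <- seq(s_min, s_max, length.out = n_bins + 1)
  bin_of <- function(s) min(max(findInterval(s, bin_edges), 1L), n_bins)
  s_cur <- surface_of(traj)
  b_cur <- bin_of(s_cur)
  g <- numeric(n_bins)  # log density-of-states estimate per bin
  h <- numeric(n_bins)  # histogram since the last halving
  lnf <- 1
  halvings <- 0
  sweep_i <- 0
  stream <- 0
  domains <- list()
  surfaces <- numeric(0)
  dom_g <- numeric(0)
  flat_hist <- numeric(0)
  move_rng <- function(k) with_seed((seed * 97 + k) %% 2147483647,
                                    stats::runif(2))
  move_i <- 0
  while (halvings < n_halvings && sweep_i < max_sweeps) {
    sweep_i <- sweep_i + 1
    for (m in seq_len(moves)) {
      move_i <- move_i + 1
      u <- move_rng(move_i)
      cut <- 1 + floor(u[1] * nrow(traj))
      stream <- stream + 1
      prop <- cpp_prefix_extend(mc$code, d, mc$par,
                                traj[seq_len(cut), , drop = FALSE], n,
                                horizon, seed, stream)
      s_new <- surface_of(prop)
      b_new <- bin_of(s_new)
      if (log(u[2]) < g[b_cur] - g[b_new]) {
        traj <- prop
        s_cur <- s_new
        b_cur <- b_new
      }
      g[b_cur] <- g[b_cur] + lnf
      h[b_cur] <- h[b_cur] + 1
      if (halvings == n_halvings - 1 && move_i %% keep_every == 0) {
        domains[[length(domains) + 1]] <- unique_sites(traj)
        surfaces <- c(surfaces, s_cur)
        dom_g <- c(dom_g, g[b_cur])
      }
    }
    # flatness over the contiguous span of bins reached so far
    span <- range(which(h > 0))
    counts <- h[span[1]:span[2]]
    flat <- min(counts) / max(counts)
    flat_hist <- c(flat_hist, flat)
    if (flat >= flatness) {
      lnf <- lnf / 2
      halvings <- halvings + 1
      h[] <- 0
    }
  }
  converged <- halvings >= n_halvings
  if (!converged)
    warning("Wang-Landau schedule did not complete ", n_halvings,
            " halvings within ", max_sweeps, " sweeps; returning the ",
            "partial ensemble")
  if (!length(domains)) {
    # schedule ended without a collection stage; collect from the final state
    domains <- list(unique_sites(traj))
    surfaces <- s_cur
    dom_g <- g[b_cur]
  }
  structure(list(domains = domains, surface = surfaces,
                 log_weights = dom_g, n = n, d = d, model = model,
                 wl = list(lnf_final = lnf, halvings = halvings,
                           flatness = flat_hist, moves = move_i),
                 converged = converged),
            class = "domain_ensemble")
}

unique_sites <- function(traj) {
  traj[!duplicated(site_keys(traj)), , drop = FALSE]
}

#' @export
print.domain_ensemble <- function(x, ...) {
  cat(sprintf("<domain_ensemble: %d domains at n = %d (d = %d), surfaces [%g, %g]>\n",
              length(x$domains), x$n, x$d, min(x$surface), max(x$surface)))
  invisible(x)
}

#' Unbias an ensemble average over a Wang-Landau ensemble
#'
#' Weights each stored domain by `exp(g(s))` (normalized), undoing the flat
#' surface histogram.
#'
#' @param ensemble a `domain_ensemble`.
#' @param values per-domain observable values.
#' @return The reweighted mean.
#' @export
reweighted_mean <- function(ensemble, values) {
  w <- exp(ensemble$log_weights - max(ensemble$log_weights))
  sum(w * values) / sum(w)
}

#' Reweighted deep-tail survival curve via exact enumeration
#'
#' For each domain of the ensemble, computes the exact exit-time
#' distribution from the last-visited site (enumeration) and averages the
#' survival curves with the unbiasing weights. The result resolves the
#' stretched-exponential and terminal-exponential tails at probabilities far
#' below plain-Monte-Carlo reach.
#'
#' @param ensemble a `domain_ensemble`.
#' @param tau_max survival horizon.
#' @param max_domains cap on enumerated domains (evenly thinned).
#' @return Data frame `tau`, `survival` (monotone non-increasing), plus the
#'   per-domain curves as an attribute.
#' @export
reweighted_tail <- function(ensemble, tau_max, max_domains = 200) {
  if (!length(ensemble$domains)) stop("empty ensemble")
  k <- length(ensemble$domains)
  pick <- if (k > max_domains) unique(round(seq(1, k, length.out = max_domains)))
          else seq_len(k)
  sub <- substrate_hypercubic(ensemble$d)
  w <- exp(ensemble$log_weights[pick] - max(ensemble$log_weights[pick]))
  w <- w / sum(w)
  surv <- numeric(tau_max)
  for (i in seq_along(pick)) {
    dom <- visited_domain(ensemble$domains[[pick[i]]], sub)
    ed <- exit_time_distribution(dom, start = dom$n, tau_max = tau_max,
                                 model = ensemble$model, tol = 0)
    s_i <- ed$survival_series # computed inside the propagation: exact in
                              # relative terms, no 1 - cumsum cancellation
    if (length(s_i) < tau_max) s_i <- c(s_i, rep(ed$survival, tau_max - length(s_i)))
    surv <- surv + w[i] * s_i
  }
  data.frame(tau = seq_len(tau_max), survival = surv)
}

#' Wang-Landau / Metropolis acceptance rule
#'
#' Accept a proposal with probability `min(1, exp(log_w_new - log_w_old))`.
#' Exposed so the acceptance rule itself can be validated against an exact
#' stationary distribution on toy state spaces.
#'
#' @param log_w_old,log_w_new log weights of current and proposed states.
#' @param u a uniform(0,1) draw.
#' @export
metropolis_accept <- function(log_w_old, log_w_new, u) {
  log(u) < log_w_new - log_w_old
}
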