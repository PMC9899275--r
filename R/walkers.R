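#' Walk model specifications
#'
#' A walk model bundles the one-step rule with its parameters:
#' \describe{
#'   \item{`simple`}{uniform choice among the present nearest neighbours
#'     (the "myopic ant" rule on irregular substrates).}
#'   \item{`persistent`}{repeats the previous displacement with probability
#'     `p`, otherwise chooses uniformly among the other `2d - 1` directions;
#'     the first step is uniform over all `2d` directions. At `p = 1/(2d)`
#'     this reduces to the simple walk.}
#'   \item{`levy`}{jump length drawn from the discrete symmetric law
#'     \eqn{p(s) = 1/[2\zeta(1+\alpha)|s|^{1+\alpha}]}, \eqn{s \in Z\setminus\{0\}}.
#'     Sites flown over are not visited. In 2d the magnitude follows the same
#'     1d law and the direction is uniform over the four lattice axes.}
#'   \item{`tsaw`}{true self-avoiding walk on the 1d line: steps right with
#'     probability \eqn{e^{-C_{i+1}}/(e^{-C_{i+1}} + e^{-C_{i-1}})} where
#'     `C_i` counts previous arrivals at site i (the start site counts as
#'     one arrival at t = 0).}
#'   \item{`fbm`}{fractional Brownian motion with Hurst exponent `H`,
#'     discretized to unit intervals of the line; see [fbm_visits()].}
#' }
#'
#' @param name one of `"simple"`, `"persistent"`, `"levy"`, `"tsaw"`, `"fbm"`.
#' @param p persistence probability in (0, 1) (persistent model).
#' @param alpha Levy index, `>= 1` (`alpha = 1` is the marginal case).
#' @param H Hurst exponent in (0, 1) (fbm model).
#' @return An object of class `walk_model`.
#' @export
walk_model <- function(name = c("simple", "persistent", "levy", "tsaw", "fbm"),
                       p = NULL, alpha = NULL, H = NULL) {
  name <- match.arg(name)
  params <- list()
  if (name == "persistent") {
    if (is.null(p) || p <= 0 || p >= 1) stop("persistent walks need p in (0, 1)")
    params$p <- p
  }
  if (name == "levy") {
    if (is.null(alpha) || alpha < 1)
      stop("Levy flights need alpha >= 1 (alpha < 1 is not normalizable here)")
    params$alpha <- alpha
  }
  if (name == "fbm") {
    if (is.null(H) || H <= 0 || H >= 1) stop("fbm needs H in (0, 1)")
    params$H <- H
  }
  structure(list(name = name, params = params), class = "walk_model")
}

#' @export
print.walk_model <- function(x, ...) {
  cat(sprintf("<walk_model: %s%s>\n", x$name,
              if (length(x$params))
                paste0("(", paste(names(x$params), unlist(x$params),
                                  sep = "=", collapse = ", "), ")")
              else ""))
  invisible(x)
}

# Internal: map a model + lattice dimension to the C++ model code and the
# scalar parameter slot.
model_code <- function(model, d) {
  switch(model$name,
         simple = list(code = 0L, par = 0),
         persistent = list(code = 1L, par = model$params$p),
         levy = if (d == 1) list(code = 2L, par = model$params$alpha)
                else if (d == 2) list(code = 3L, par = model$params$alpha)
                else stop("Levy flights are implemented in 1d and 2d"),
         tsaw = {
           if (d != 1) stop("the TSAW is defined on the 1d line")
           list(code = 4L, par = 0)
         },
         stop("model '", model$name, "' has no lattice stepper (use fbm_visits)"))
}

check_model_substrate <- function(model, substrate) {
  if (is_graph_substrate(substrate) && model$name != "simple")
    stop("only the simple (myopic-ant) walk is defined on graph substrates")
  if (model$name == "fbm")
    stop("fbm paths are generated wholesale; use fbm_visits()")
  invisible(TRUE)
}

#' Walk dimension of a model on a substrate
#'
#' For the simple walk this is the substrate's `d_w`; persistent walks share
#' the diffusive `d_w = 2`; 1d Levy flights of index `alpha` in `[1, 2)` have
#' `d_w = alpha` (and `d_f = 1`), 2d Levy flights `d_w = alpha` with
#' `d_f = 2`; the 1d TSAW has `d_w = 3/2`; fbm has `d_w = 1/H`.
#'
#' @param model a [walk_model()].
#' @param substrate an `rw_substrate` (used by the simple walk).
#' @return A list with `d_f` and `d_w`.
#' @export
model_dimensions <- function(model, substrate = substrate_hypercubic(1)) {
  switch(model$name,
         simple = list(d_f = substrate$d_f, d_w = substrate$d_w),
         persistent = list(d_f = substrate$d_f, d_w = 2),
         levy = {
           d <- if (substrate$kind == "hypercubic") substrate$params$d else
             stop("Levy flights live on hypercubic lattices")
           a <- model$params$alpha
           list(d_f = d, d_w = min(a, 2))
         },
         tsaw = list(d_f = 1, d_w = 3 / 2),
         fbm = list(d_f = 1, d_w = 1 / model$params$H))
}

#' Simulate a trajectory
#'
#' @param model a [walk_model()] (not fbm).
#' @param substrate an `rw_substrate`.
#' @param steps number of steps.
#' @param seed integer seed; with `stream`, selects a reproducible substream.
#' @param stream substream index (one per realization).
#' @return An `rw_trajectory`: for lattices a `(steps+1) x d` integer matrix
#'   of positions in the `sites` field; for graphs a vector of vertex ids.
#' @export
simulate_trajectory <- function(model, substrate, steps, seed, stream = 0) {
  check_model_substrate(model, substrate)
  if (is_graph_substrate(substrate)) {
    start <- if (!is.null(substrate$start)) substrate$start else 1L
    path <- cpp_walk_graph(substrate$csr$indptr, substrate$csr$indices,
                           start - 1L, steps, seed, stream) + 1L
    sites <- path
  } else {
    mc <- model_code(model, substrate$params$d)
    sites <- cpp_walk_lattice(mc$code, substrate$params$d, mc$par, steps,
                              seed, stream)
    storage.mode(sites) <- "double"
  }
  structure(list(sites = sites, model = model, substrate = substrate,
                 seed = seed, stream = stream),
            class = "rw_trajectory")
}

#' @export
print.rw_trajectory <- function(x, ...) {
  len <- if (is.matrix(x$sites)) nrow(x$sites) else length(x$sites)
  cat(sprintf("<rw_trajectory: %s on %s, %d positions>\n", x$model$name,
              x$substrate$kind, len))
  invisible(x)
}

#' Simulate one realization of the inter-visit time series
#'
#' Runs the walk until `n_max` distinct sites have been visited (or `horizon`
#' steps) and records every inter-visit time \eqn{\tau_n}, the elapsed steps
#' between the discovery of the n-th and (n+1)-st distinct sites. The start
#' site counts as the first distinct site at t = 0.
#'
#' @inheritParams simulate_trajectory
#' @param n_max target number of distinct sites.
#' @param horizon step budget.
#' @return A `tau_series`: data frame columns `n`, `tau`, plus the visited
#'   sites in discovery order, total steps and a `reached` flag.
#' @export
simulate_tau <- function(model, substrate, n_max, seed, horizon = Inf,
                         stream = 0) {
  check_model_substrate(model, substrate)
  if (!is.finite(horizon)) horizon <- 2^62
  if (is_graph_substrate(substrate)) {
    start <- if (!is.null(substrate$start)) substrate$start else 1L
    res <- cpp_tau_single_graph(substrate$csr$indptr, substrate$csr$indices,
                                start - 1L, n_max, horizon, seed, stream)
    res$sites <- res$sites + 1L
    if (!is.null(substrate$guard) && any(res$sites %in% substrate$guard))
      warning("trajectory reached the outer corner of the finite ",
              substrate$kind, "; increase the generation")
  } else {
    mc <- model_code(model, substrate$params$d)
    res <- cpp_tau_single(mc$code, substrate$params$d, mc$par, n_max, horizon,
                          seed, stream)
  }
  taus <- res$taus
  structure(list(taus = data.frame(n = seq_along(taus), tau = taus),
                 sites = res$sites, total_time = res$steps,
                 reached = res$reached, model = model,
                 substrate_kind = substrate$kind, seed = seed),
            class = "tau_series")
}

#' @export
print.tau_series <- function(x, ...) {
  cat(sprintf("<tau_series: %d taus, %g steps, model %s on %s>\n",
              nrow(x$taus), x$total_time, x$model$name, x$substrate_kind))
  invisible(x)
}

#' Ensemble of inter-visit times at chosen n
#'
#' Runs `reps` independent realizations (counter-based substreams of `seed`)
#' and records \eqn{\tau_n} for each requested `n` — one sample per
#' realization, so samples at fixed n are independent across rows.
#'
#' @inheritParams simulate_tau
#' @param n_record increasing integer vector of n values.
#' @param reps number of realizations.
#' @return A `reps x length(n_record)` matrix (NA where the horizon was hit
#'   first), with `n_record` as an attribute.
#' @export
tau_ensemble <- function(model, substrate, n_record, reps, seed,
                         horizon = Inf) {
  check_model_substrate(model, substrate)
  n_record <- as.integer(sort(n_record))
  if (!is.finite(horizon)) horizon <- 2^62
  if (is_graph_substrate(substrate)) {
    starts <- graph_start_pool(substrate)
    out <- cpp_tau_ensemble_graph(substrate$csr$indptr, substrate$csr$indices,
                                  starts - 1L, n_record, reps, horizon, seed)
  } else {
    mc <- model_code(model, substrate$params$d)
    out <- cpp_tau_ensemble(mc$code, substrate$params$d, mc$par, n_record,
                            reps, horizon, seed)
  }
  colnames(out) <- n_record
  attr(out, "n_record") <- n_record
  out
}

# Start vertices for graph substrates: the designated start site where one
# exists (gasket apex, ttree centre), else all cluster sites (percolation:
# uniform start over the cluster).
graph_start_pool <- function(substrate) {
  if (!is.null(substrate$start)) substrate$start
  else seq_len(substrate$n_vertices)
}

#' First-visit times of the n-th distinct site, across an ensemble
#'
#' The time of the n-th discovery equals the partial sum
#' \eqn{\sum_{k<n} \tau_k}; these are the jump times of N(t).
#'
#' @inheritParams tau_ensemble
#' @return A `reps x length(n_record)` matrix of discovery times.
#' @export
visit_time_ensemble <- function(model, substrate, n_record, reps, seed,
                                horizon = Inf) {
  check_model_substrate(model, substrate)
  if (is_graph_substrate(substrate)) stop("implemented for lattice models")
  if (!is.finite(horizon)) horizon <- 2^62
  n_record <- as.integer(sort(n_record))
  mc <- model_code(model, substrate$params$d)
  out <- cpp_visit_time_ensemble(mc$code, substrate$params$d, mc$par, n_record,
                                 reps, horizon, seed)
  colnames(out) <- n_record
  out
}

#' Number of distinct sites visited N(t), across an ensemble
#'
#' @inheritParams tau_ensemble
#' @param t_record increasing vector of times (steps).
#' @return A `reps x length(t_record)` matrix of N values; N(0) = 1.
#' @export
n_visited_ensemble <- function(model, substrate, t_record, reps, seed) {
  check_model_substrate(model, substrate)
  t_record <- sort(t_record)
  if (is_graph_substrate(substrate)) {
    starts <- graph_start_pool(substrate)
    out <- cpp_N_ensemble_graph(substrate$csr$indptr, substrate$csr$indices,
                                starts - 1L, t_record, reps, seed)
  } else {
    mc <- model_code(model, substrate$params$d)
    out <- cpp_N_ensemble(mc$code, substrate$params$d, mc$par, t_record, reps,
                          seed)
  }
  colnames(out) <- t_record
  attr(out, "t_record") <- t_record
  out
}

#' Mean-square displacement across an ensemble
#'
#' Squared Euclidean displacement from the start site at the recorded times
#' (graph substrates use their embedded coordinates). On guarded substrates
#' (finite gasket) a warning reports walks that touched the outer corners.
#'
#' @inheritParams n_visited_ensemble
#' @return A `reps x length(t_record)` matrix of squared displacements.
#' @export
msd_ensemble <- function(model, substrate, t_record, reps, seed) {
  check_model_substrate(model, substrate)
  t_record <- sort(t_record)
  if (is_graph_substrate(substrate)) {
    if (is.null(substrate$coords))
      stop("substrate has no coordinate embedding")
    starts <- graph_start_pool(substrate)
    guard <- if (!is.null(substrate$guard)) substrate$guard else integer(0)
    out <- cpp_msd_ensemble_graph(substrate$csr$indptr, substrate$csr$indices,
                                  substrate$coords, starts - 1L, guard - 1L,
                                  t_record, reps, seed)
    if (attr(out, "guard_hits") > 0)
      warning(attr(out, "guard_hits"), " walks reached the outer corner of ",
              "the finite ", substrate$kind)
  } else {
    mc <- model_code(model, substrate$params$d)
    out <- cpp_msd_ensemble(mc$code, substrate$params$d, mc$par, t_record,
                            reps, seed)
  }
  colnames(out) <- t_record
  out
}

#' Discrete Levy jump probability mass
#'
#' \eqn{p(s) = 1/[2\zeta(1+\alpha)|s|^{1+\alpha}]} for integer `s != 0`.
#'
#' @param s integer displacements (nonzero).
#' @param alpha Levy index `>= 1`.
#' @export
levy_jump_pmf <- function(s, alpha) {
  if (any(s == 0)) stop("s = 0 has no mass")
  if (alpha < 1) stop("alpha must be >= 1")
  1 / (2 * pracma::zeta(1 + alpha) * abs(s)^(1 + alpha))
}

#' Sample discrete Levy jumps
#'
#' Inverse-transform sampling of the law in [levy_jump_pmf()], with a Pareto
#' tail continuation beyond the tabulated range.
#'
#' @param n number of samples.
#' @param alpha Levy index `>= 1`.
#' @param seed,stream reproducible substream selectors.
#' @export
sample_levy_jumps <- function(n, alpha, seed, stream = 0) {
  cpp_levy_samples(alpha, n, seed, stream)
}

#' Exact fractional Gaussian noise via the Hosking recursion
#'
#' Generates `T` stationary increments of fractional Brownian motion with
#' Hurst exponent `H` and unit-variance increments, by the Durbin-Levinson
#' (Hosking) conditional recursion on the exact autocovariance
#' \eqn{\gamma(k) = (|k+1|^{2H} - 2|k|^{2H} + |k-1|^{2H})/2}.
#'
#' @param H Hurst exponent in (0, 1).
#' @param T number of increments.
#' @param seed integer seed (R RNG, restored afterwards).
#' @return Numeric vector of length `T`.
#' @export
fbm_hosking <- function(H, T, seed) {
  if (H <= 0 || H >= 1) stop("H must be in (0, 1)")
  if (T < 1) stop("T must be >= 1")
  k <- 0:T
  gamma <- 0.5 * (abs(k + 1)^(2 * H) - 2 * abs(k)^(2 * H) + abs(k - 1)^(2 * H))
  z <- with_seed(seed, stats::rnorm(T))
  x <- numeric(T)
  x[1] <- z[1]
  if (T == 1) return(x)
  phi <- numeric(T)      # AR coefficients of the current order
  v <- 1                 # prediction error variance
  phi[1] <- gamma[2]     # gamma(1) / gamma(0), gamma(0) = 1
  v <- v * (1 - phi[1]^2)
  x[2] <- phi[1] * x[1] + sqrt(v) * z[2]
  if (T == 2) return(x)
  for (t in 2:(T - 1)) {
    # extend the Durbin-Levinson recursion to order t
    kap <- (gamma[t + 1] - sum(phi[1:(t - 1)] * gamma[t:2])) / v
    phi_new <- phi[1:(t - 1)] - kap * phi[(t - 1):1]
    phi[1:(t - 1)] <- phi_new
    phi[t] <- kap
    v <- v * (1 - kap^2)
    x[t + 1] <- sum(phi[1:t] * x[t:1]) + sqrt(v) * z[t + 1]
  }
  x
}

#' Inter-visit times of fractional Brownian motion on unit intervals
#'
#' Builds the fBM position path from Hosking increments, discretizes the line
#' into unit intervals, marks an interval visited at the first time the
#' sampled position falls in it (no bridge interpolation between samples),
#' and records \eqn{\tau_n} between first entries of the n-th and (n+1)-st
#' distinct intervals. The interval containing the origin is visited at t = 0.
#'
#' @inheritParams fbm_hosking
#' @return A `tau_series` (sites are interval indices in discovery order).
#' @export
fbm_visits <- function(H, T, seed) {
  incr <- fbm_hosking(H, T, seed)
  pos <- c(0, cumsum(incr))
  iv <- floor(pos)
  first <- !duplicated(iv)
  disc <- which(first) - 1L # discovery times, 0-based
  taus <- diff(disc)
  structure(list(taus = data.frame(n = seq_along(taus), tau = as.numeric(taus)),
                 sites = iv[first], total_time = T, reached = NA,
                 model = walk_model("fbm", H = H), substrate_kind = "line",
                 seed = seed),
            class = "tau_series")
}
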