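#' Regime predictions for the inter-visit time distribution
#'
#' The ratio \eqn{\mu = d_f/d_w} fixes the walk class and, with it, the full
#' regime structure of \eqn{F_n(\tau)}:
#'
#' | class | \eqn{t_n} | \eqn{T_n} | early | intermediate | late |
#' |---|---|---|---|---|---|
#' | recurrent (\eqn{\mu<1}) | \eqn{n^{1/\mu}} | \eqn{n^{1/\mu}} | \eqn{\tau^{-(1+\mu)}} | — | \eqn{e^{-c\tau/n^{1/\mu}}} |
#' | marginal (\eqn{\mu=1}) | \eqn{\sqrt n} | \eqn{n^{3/2}} | \eqn{\tau^{-2}} | \eqn{e^{-c(\tau/t_n)^{1/2}}} | \eqn{e^{-c\tau/n}} |
#' | transient (\eqn{\mu>1}) | 1 | \eqn{n^{(\mu+1)/\mu}} | — | \eqn{e^{-c(\tau/t_n)^{\mu/(1+\mu)}}} | \eqn{e^{-c\tau/n^{1/\mu}}} |
#'
#' Crossovers are given as exponents of n with undetermined prefactors (and
#' up to logarithmic corrections); the constants a, b, A are fitted, never
#' assumed.
#'
#' @name theory
NULL

#' Classify a walk and derive its regime exponents
#'
#' @param d_f fractal dimension of the medium (> 0).
#' @param d_w walk dimension (> 0).
#' @return A `theory_prediction` with fields `mu`, `walk_class`, crossover
#'   exponents `rho_exp` (\eqn{\rho_n \sim n^{rho\_exp}}), `tn_exp`,
#'   `Tn_exp`, `early_exponent` (\eqn{1+\mu}), `stretched_exponent`
#'   (\eqn{\mu/(1+\mu)}), `terminal_rate_exp` (\eqn{\theta_n \sim n^{1/\mu}}),
#'   `d_T = 2 d_f - d_w`, persistence exponent `theta = 1 - mu`, and empty
#'   `fit_constants` slots.
#' @export
classify_walk <- function(d_f, d_w) {
  if (d_f <= 0 || d_w <= 0) stop("d_f and d_w must be positive")
  mu <- d_f / d_w
  walk_class <- if (mu < 1) "recurrent" else if (mu == 1) "marginal" else "transient"
  rho_exp <- switch(walk_class,
                    recurrent = 1 / d_f,
                    marginal = 1 / (2 * d_f),
                    transient = 0)
  tn_exp <- d_w * rho_exp # t_n = rho_n^{d_w}
  Tn_exp <- switch(walk_class,
                   recurrent = 1 / mu,
                   marginal = 3 / 2,
                   transient = (mu + 1) / mu)
  structure(list(
    d_f = d_f, d_w = d_w, mu = mu, walk_class = walk_class,
    rho_exp = rho_exp, tn_exp = tn_exp, Tn_exp = Tn_exp,
    early_exponent = if (walk_class == "transient") NA_real_ else 1 + mu,
    stretched_exponent = mu / (1 + mu),
    terminal_rate_exp = 1 / mu,
    d_T = 2 * d_f - d_w,
    theta = 1 - mu,
    fit_constants = list(a = NA_real_, b = NA_real_, A = NA_real_)),
    class = "theory_prediction")
}

#' @export
print.theory_prediction <- function(x, ...) {
  cat(sprintf("<theory_prediction: %s, mu = %.4f>\n", x$walk_class, x$mu))
  cat(sprintf("  t_n ~ n^%.3f, T_n ~ n^%.3f, rho_n ~ n^%.3f\n",
              x$tn_exp, x$Tn_exp, x$rho_exp))
  if (!is.na(x$early_exponent))
    cat(sprintf("  early decay tau^-%.3f, ", x$early_exponent))
  cat(sprintf("stretched exponent %.3f, theta_n ~ n^%.3f, d_T = %.3f\n",
              x$stretched_exponent, x$terminal_rate_exp, x$d_T))
  invisible(x)
}

#' Fractal dimension of the visited/unvisited interface
#'
#' \eqn{d_T = 2 d_f - d_w}. A negative value (outside the theory's regime)
#' triggers a warning.
#'
#' @inheritParams classify_walk
#' @export
trap_dimension <- function(d_f, d_w) {
  d_T <- 2 * d_f - d_w
  if (d_T < 0) warning("d_T < 0: outside the regime of the interface scaling")
  d_T
}

#' Growth exponent of the k-th moment of tau_n
#'
#' Recurrent: \eqn{\langle\tau_n^k\rangle \propto n^{k/\mu - 1}}. Marginal:
#' \eqn{\langle\tau_n\rangle \propto \ln n} (returned as the string `"log"`)
#' and \eqn{n^{(k-1)/2}} for k > 1. Transient: constant (exponent 0).
#'
#' @param k moment order, >= 1.
#' @param prediction a `theory_prediction`.
#' @return Numeric exponent, or `"log"` for the marginal mean.
#' @export
moment_exponent <- function(k, prediction) {
  if (k < 1) stop("k must be >= 1")
  switch(prediction$walk_class,
         recurrent = k / prediction$mu - 1,
         marginal = if (k == 1) "log" else (k - 1) / 2,
         transient = 0)
}

#' Solve the discrete renewal equation for the first-arrival series
#'
#' The probability P_trap(t) of occupying a trap at time t partitions over
#' the first arrival at time tau and a return over the remaining t - tau:
#' \deqn{P(t) = \delta_{t,0} + \sum_{\tau=1}^{t} F(\tau) P(t-\tau).}
#' Given P with P(0) = 1, deconvolves for F.
#'
#' @param p_trap numeric vector, `p_trap[1] = P(0) = 1`, `p_trap[t+1] = P(t)`.
#' @return Numeric vector F with `F[t]` the first-arrival mass at time t
#'   (length `length(p_trap) - 1`).
#' @export
renewal_solve <- function(p_trap) {
  if (abs(p_trap[1] - 1) > 1e-12)
    stop("p_trap[1] must be 1 (the delta term at t = 0)")
  T <- length(p_trap) - 1
  F <- numeric(T)
  for (t in seq_len(T)) {
    conv <- if (t > 1) sum(F[1:(t - 1)] * p_trap[t:2]) else 0
    F[t] <- p_trap[t + 1] - conv
  }
  F
}

#' Compose a first-arrival series back into the trap-occupation series
#'
#' Inverse of [renewal_solve()]: reconstructs P from F via the same
#' convolution; `renewal_compose(renewal_solve(P))` returns P to machine
#' precision.
#'
#' @param F numeric vector of first-arrival masses (index = time).
#' @return Numeric vector P of length `length(F) + 1` with `P[1] = 1`.
#' @export
renewal_compose <- function(F) {
  T <- length(F)
  P <- numeric(T + 1)
  P[1] <- 1
  for (t in seq_len(T)) P[t + 1] <- F[t] + if (t > 1) sum(F[1:(t - 1)] * P[t:2]) else 0
  P
}

#' Large-deviation survival bound and optimal trap-free radius
#'
#' Evaluates the lower bound on the survival probability inside the visited
#' domain,
#' \deqn{S_n(\tau) \ge \rho_n^{-1} \int_0^{n^{1/d_f}}
#'   \exp[-b\tau/r^{d_w} - a (r/\rho_n)^{d_f}] dr,}
#' together with its Laplace asymptote
#' \eqn{\exp[-\tau^{\mu/(1+\mu)} f(\rho^*)]} where
#' \eqn{f(\rho) = b/\rho^{d_w} + a(\rho/\rho_n)^{d_f}} is minimized at
#' \eqn{\rho^*}, the optimal radius
#' \eqn{r^*(\tau) = \rho^* \tau^{1/(d_f+d_w)}}, and the second crossover
#' \eqn{T_n} defined by \eqn{r^*(T_n) = n^{1/d_f}}.
#'
#' @param tau time(s), > 0.
#' @param n number of visited sites.
#' @param prediction a `theory_prediction`.
#' @param a,b fitted positive constants of the radius distribution
#'   \eqn{Q_n(r)} and of the spherical confinement law.
#' @return A list with `numeric` (the integral bound), `laplace` (the
#'   asymptote), `r_star`, `rho_star`, `rho_n` and `T_n`.
#' @export
survival_bound <- function(tau, n, prediction, a, b) {
  if (any(tau <= 0)) stop("tau must be positive")
  if (a <= 0 || b <= 0) stop("the fitted constants a, b must be positive")
  d_f <- prediction$d_f; d_w <- prediction$d_w
  rho_n <- n^prediction$rho_exp
  r_max <- n^(1 / d_f)
  num <- vapply(tau, function(tt) {
    stats::integrate(function(r)
      exp(-b * tt / r^d_w - a * (r / rho_n)^d_f),
      lower = 1e-9, upper = r_max, rel.tol = 1e-9,
      subdivisions = 500L)$value / rho_n
  }, numeric(1))
  rho_star <- (b * d_w * rho_n^d_f / (a * d_f))^(1 / (d_f + d_w))
  fmin <- b / rho_star^d_w + a * (rho_star / rho_n)^d_f
  expo <- prediction$stretched_exponent
  laplace <- exp(-tau^expo * fmin)
  r_star <- rho_star * tau^(1 / (d_f + d_w))
  T_n <- (r_max / rho_star)^(d_f + d_w)
  list(numeric = num, laplace = laplace, r_star = r_star,
       rho_star = rho_star, rho_n = rho_n, T_n = T_n)
}
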