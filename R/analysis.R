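#' Statistical estimation layer
#'
#' Estimators applied to simulated tau samples and N(t) ensembles: power-law
#' exponents on logarithmically binned histograms, exponential tail rates,
#' scaling collapses across n, multi-time covariances of N(t), and the
#' starving-forager experiment.
#'
#' @name analysis
NULL

#' Logarithmically binned probability mass
#'
#' @param x positive samples (tau values).
#' @param factor geometric bin growth factor.
#' @return Data frame `x` (geometric bin centre), `y` (probability density,
#'   bin mass / total / bin width), `count`.
#' @export
log_bin_histogram <- function(x, factor = 1.25) {
  x <- x[is.finite(x) & x > 0]
  if (!length(x)) stop("no positive samples")
  lo <- min(x)
  k_max <- ceiling(log(max(x) / lo) / log(factor)) + 1
  breaks <- lo * factor^(0:k_max)
  breaks[1] <- breaks[1] * (1 - 1e-9)
  idx <- findInterval(x, breaks, rightmost.closed = TRUE)
  cnt <- tabulate(idx, nbins = k_max)
  width <- diff(breaks)
  centre <- sqrt(breaks[-1] * breaks[-length(breaks)])
  keep <- cnt > 0
  data.frame(x = centre[keep], y = cnt[keep] / length(x) / width[keep],
             count = cnt[keep])
}

#' Logarithmically bin a discrete probability mass series
#'
#' Aggregates `mass[t]`, t = 1, 2, ... into geometric bins and returns the
#' bin density. Use on exact enumeration output, where parity effects on
#' bipartite lattices make individual masses oscillate.
#'
#' @param mass numeric vector, `mass[t]` = P(tau = t).
#' @param factor geometric bin growth factor.
#' @return Data frame `x` (bin centre), `y` (density: bin mass / width).
#' @export
bin_mass_curve <- function(mass, factor = 1.25) {
  t <- seq_along(mass)
  k_max <- ceiling(log(length(mass)) / log(factor)) + 1
  breaks <- factor^(0:k_max)
  breaks[1] <- 1 - 1e-9
  idx <- findInterval(t, breaks, rightmost.closed = TRUE)
  tot <- tapply(mass, idx, sum)
  width <- diff(breaks)
  centre <- sqrt(breaks[-1] * breaks[-length(breaks)])
  bins <- as.integer(names(tot))
  keep <- tot > 0
  data.frame(x = centre[bins[keep]], y = as.numeric(tot[keep]) / width[bins[keep]])
}

#' Fit a power-law exponent on a window
#'
#' Least squares on log-log axes of the logarithmically binned density of
#' `x` restricted to `window`; the reported exponent is the positive decay
#' exponent of \eqn{p(\tau) \propto \tau^{-exponent}}. The standard error
#' comes from bootstrap resampling of the samples.
#'
#' @param x positive samples, or a precomputed curve as a list/data.frame
#'   with fields `x` and `y` (no bootstrap then; `stderr` from the fit).
#' @param window `c(lo, hi)` in tau units.
#' @param n_boot bootstrap replicates.
#' @param factor log-binning factor.
#' @param seed seed for the bootstrap.
#' @return A `power_law_fit`: `exponent`, `stderr`, `window`, `r_squared`,
#'   `n_samples`.
#' @export
fit_power_law <- function(x, window, n_boot = 200, factor = 1.25, seed = 1) {
  fit_curve <- function(h) {
    h <- h[h$x >= window[1] & h$x <= window[2], ]
    if (nrow(h) < 3) return(NULL)
    fit <- stats::lm(log10(y) ~ log10(x), data = h)
    list(exponent = -unname(stats::coef(fit)[2]),
         r_squared = summary(fit)$r.squared,
         stderr = unname(summary(fit)$coefficients[2, 2]))
  }
  if (is.list(x) && !is.null(x$y)) {
    f <- fit_curve(as.data.frame(x))
    if (is.null(f)) stop("fewer than 3 histogram points in the window")
    return(structure(c(f, list(window = window, n_samples = NA_integer_)),
                     class = "power_law_fit"))
  }
  x <- x[is.finite(x)]
  n_in <- sum(x >= window[1] & x <= window[2])
  if (n_in < 100) stop("need >= 100 samples in the fit window, have ", n_in)
  f <- fit_curve(log_bin_histogram(x, factor))
  if (is.null(f)) stop("fewer than 3 histogram points in the window")
  boots <- with_seed(seed, vapply(seq_len(n_boot), function(b) {
    xb <- sample(x, length(x), replace = TRUE)
    fb <- fit_curve(log_bin_histogram(xb, factor))
    if (is.null(fb)) NA_real_ else fb$exponent
  }, numeric(1)))
  structure(list(exponent = f$exponent,
                 stderr = stats::sd(boots, na.rm = TRUE),
                 window = window, r_squared = f$r_squared,
                 n_samples = length(x), boot = boots),
            class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("<power_law_fit: exponent %.3f +- %.3f on [%g, %g], R2 = %.3f>\n",
              x$exponent, x$stderr, x$window[1], x$window[2], x$r_squared))
  invisible(x)
}

#' Exponential tail rate of a tau sample
#'
#' Fits the slope of the log empirical survival function beyond the
#' `quantile` threshold: \eqn{F_n(\tau) \sim e^{-\tau/\theta_n}} gives rate
#' \eqn{1/\theta_n}. Translation of all samples leaves the rate unchanged.
#'
#' @param x samples.
#' @param n the domain size the samples were taken at (metadata).
#' @param quantile tail threshold (default 0.9).
#' @param min_tail minimum number of tail points required.
#' @return A `tail_rate`: `rate` (= 1/theta_n), `theta_n`, `stderr`, `n`,
#'   `window`.
#' @export
estimate_tail_rate <- function(x, n = NA, quantile = 0.9, min_tail = 30) {
  x <- sort(x[is.finite(x)])
  thr <- stats::quantile(x, quantile, names = FALSE)
  tail_x <- x[x > thr]
  if (length(tail_x) < min_tail)
    stop("insufficient tail: ", length(tail_x), " samples beyond the ",
         quantile, " quantile (need ", min_tail, ")")
  m <- length(x)
  surv <- (m - match(tail_x, x) + 1) / m # P(X >= tail_x), ties resolved left
  # drop the extreme tail carried by fewer than 5 samples: its log-survival
  # noise would otherwise dominate the fit
  keep <- !duplicated(tail_x) & surv * m >= 5
  df <- data.frame(t = tail_x[keep], ls = log(surv[keep]))
  fit <- stats::lm(ls ~ t, data = df)
  rate <- -unname(stats::coef(fit)[2])
  if (rate <= 0) stop("tail is not exponentially decaying on this window")
  structure(list(rate = rate, theta_n = 1 / rate,
                 stderr = unname(summary(fit)$coefficients[2, 2]),
                 n = n, window = range(df$t), n_tail = length(tail_x)),
            class = "tail_rate")
}

#' @export
print.tail_rate <- function(x, ...) {
  cat(sprintf("<tail_rate: theta_n = %.4g (rate %.4g +- %.2g), n = %s>\n",
              x$theta_n, x$rate, x$stderr, format(x$n)))
  invisible(x)
}

#' Scaling collapse of F_n curves across n
#'
#' Rescales each curve as \eqn{X = \tau / n^{x\_exp}},
#' \eqn{Y = F_n(\tau) \, n^{y\_exp}}, interpolates all curves onto a common
#' logarithmic X grid restricted to the overlap of their supports, and
#' scores the collapse by the mean pairwise squared deviation of log10 Y.
#' A score of 0 means the rescaled curves coincide. For recurrent walks the
#' scaling form \eqn{F_n(\tau) = n^{-(1+1/\mu)} \psi(\tau/n^{1/\mu})}
#' corresponds to `x_exp = 1/mu`, `y_exp = 1 + 1/mu`.
#'
#' @param curves list of data frames with columns `x` (tau) and `y` (F)
#'   — e.g. from [log_bin_histogram()].
#' @param n_values the n of each curve.
#' @param x_exp,y_exp rescaling exponents.
#' @param grid_size number of common grid points.
#' @return A `collapse_result`: `score`, `grid`, `rescaled` curves.
#' @export
scaling_collapse <- function(curves, n_values, x_exp, y_exp, grid_size = 40) {
  stopifnot(length(curves) == length(n_values), length(curves) >= 2)
  resc <- lapply(seq_along(curves), function(i) {
    cc <- as.data.frame(curves[[i]])
    cc <- cc[cc$y > 0, ]
    data.frame(lx = log10(cc$x / n_values[i]^x_exp),
               ly = log10(cc$y * n_values[i]^y_exp))
  })
  lo <- max(vapply(resc, function(r) min(r$lx), numeric(1)))
  hi <- min(vapply(resc, function(r) max(r$lx), numeric(1)))
  if (lo >= hi) stop("rescaled curves have disjoint supports")
  grid <- seq(lo, hi, length.out = grid_size)
  ys <- vapply(resc, function(r) stats::approx(r$lx, r$ly, xout = grid)$y,
               numeric(grid_size))
  k <- ncol(ys)
  score <- 0
  pairs <- 0
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    score <- score + mean((ys[, i] - ys[, j])^2, na.rm = TRUE)
    pairs <- pairs + 1
  }
  structure(list(score = score / pairs, grid = grid, rescaled = resc,
                 x_exp = x_exp, y_exp = y_exp),
            class = "collapse_result")
}

#' @export
print.collapse_result <- function(x, ...) {
  cat(sprintf("<collapse_result: score %.4g with x_exp = %.3f, y_exp = %.3f>\n",
              x$score, x$x_exp, x$y_exp))
  invisible(x)
}

#' Two-time covariance of the number of distinct sites visited
#'
#' @param N a `reps x length(t_record)` matrix from [n_visited_ensemble()].
#' @param t1,t2 times (must be in the recorded grid), `t1 <= t2`.
#' @param min_paths minimum ensemble size.
#' @return List: `cov` (unbiased sample covariance of N(t1), N(t2)) and
#'   `normalized` (covariance over the product of means).
#' @export
covariance_N <- function(N, t1, t2, min_paths = 1000) {
  if (t1 > t2) stop("t1 must be <= t2")
  if (nrow(N) < min_paths)
    stop("need >= ", min_paths, " paths, have ", nrow(N))
  tr <- as.numeric(colnames(N))
  i1 <- match(t1, tr); i2 <- match(t2, tr)
  if (is.na(i1) || is.na(i2)) stop("t1/t2 not in the recorded time grid")
  cv <- stats::cov(N[, i1], N[, i2])
  list(cov = cv, normalized = cv / (mean(N[, i1]) * mean(N[, i2])))
}

#' Normalized central k-point moment of N(t)
#'
#' \eqn{\langle \prod_i (N(t_i) - \langle N(t_i)\rangle) \rangle /
#'   \prod_i \langle N(t_i) \rangle} for ordered times.
#'
#' @param N matrix as in [covariance_N()].
#' @param times ordered times within the recorded grid; k = 2 or 4.
#' @export
kpoint_moment <- function(N, times) {
  if (is.unsorted(times)) stop("times must be ordered")
  if (!length(times) %in% c(2, 4)) stop("k = 2 and k = 4 are supported")
  tr <- as.numeric(colnames(N))
  idx <- match(times, tr)
  if (anyNA(idx)) stop("times not in the recorded grid")
  cols <- N[, idx, drop = FALSE]
  centred <- sweep(cols, 2, colMeans(cols))
  r <- nrow(cols)
  # n/(n-1) normalization so that k = 2 coincides with the unbiased covariance
  sum(apply(centred, 1, prod)) / (r - 1) / prod(colMeans(cols))
}

#' Covariance of disjoint partial sums of the tau series
#'
#' \eqn{\mathrm{Cov}[\sum_{k<n_1}\tau_k, \sum_{n_1 \le k < n_2}\tau_k]}
#' across realizations, computed from first-visit times: the first sum is
#' the discovery time \eqn{T_{n_1}}, the second \eqn{T_{n_2} - T_{n_1}}.
#'
#' @param visit_times matrix from [visit_time_ensemble()] with columns
#'   containing `n1` and `n2`.
#' @param n1,n2 distinct-site counts, `n1 < n2`.
#' @param min_paths minimum ensemble size.
#' @export
partial_sum_covariance <- function(visit_times, n1, n2, min_paths = 100) {
  if (n1 >= n2) stop("n1 must be < n2")
  if (nrow(visit_times) < min_paths)
    stop("need >= ", min_paths, " realizations")
  nr <- as.numeric(colnames(visit_times))
  i1 <- match(n1, nr); i2 <- match(n2, nr)
  if (is.na(i1) || is.na(i2)) stop("n1/n2 not recorded")
  a <- visit_times[, i1]
  b <- visit_times[, i2] - visit_times[, i1]
  ok <- is.finite(a) & is.finite(b)
  stats::cov(a[ok], b[ok])
}

#' Starving random walk
#'
#' A forager on the d-dimensional lattice; every site initially holds one
#' food unit, consumed (instantaneously) at first visit, and the forager
#' dies once `S` consecutive steps pass without finding food. The clock
#' resets on every new-site visit; the start site is eaten at t = 0.
#'
#' @param S metabolic time (steps), >= 1.
#' @param d lattice dimension (1 or 2).
#' @param reps number of foragers.
#' @param seed integer seed.
#' @return A `starvation_outcome` data frame: `lifetime` (steps until death,
#'   always >= S) and `sites_at_death` (distinct sites visited, >= 1), with
#'   `S` as attribute.
#' @export
starving_walk <- function(S, d = 2, reps = 1, seed = 1) {
  if (S < 1) stop("S must be >= 1")
  m <- cpp_starving(as.integer(d), as.integer(S), as.integer(reps), seed)
  out <- data.frame(lifetime = m[, 1], sites_at_death = m[, 2])
  attr(out, "S") <- S
  class(out) <- c("starvation_outcome", "data.frame")
  out
}

#' Sweep of mean forager lifetime over the metabolic time
#'
#' @param S_values metabolic times to sweep.
#' @param d lattice dimension.
#' @param reps foragers per S.
#' @param seed integer seed (substreams derived per S).
#' @return Data frame `S`, `mean_lifetime`, `mean_sites`, `se_lifetime`,
#'   plus the fitted log-log `slope` of mean lifetime vs S as an attribute.
#' @export
starvation_sweep <- function(S_values, d = 2, reps = 1000, seed = 1) {
  rows <- lapply(seq_along(S_values), function(i) {
    out <- starving_walk(S_values[i], d = d, reps = reps,
                         seed = seed + 7919 * i)
    data.frame(S = S_values[i], mean_lifetime = mean(out$lifetime),
               mean_sites = mean(out$sites_at_death),
               se_lifetime = stats::sd(out$lifetime) / sqrt(reps))
  })
  df <- do.call(rbind, rows)
  fit <- stats::lm(log(mean_lifetime) ~ log(S), data = df)
  attr(df, "slope") <- unname(stats::coef(fit)[2])
  df
}

#' Detect a plateau of a slowly varying rescaled curve
#'
#' Used for the stretched-exponential diagnostic
#' \eqn{Y = -\ln F_n(\tau)/\tau^{\mu/(1+\mu)}}: on the intermediate window Y
#' approaches a constant. Reports the relative spread of Y over the central
#' portion of the curve.
#'
#' @param x ordered abscissa.
#' @param y curve values.
#' @param trim fraction trimmed from each end before scoring.
#' @return List with `level` (median Y on the window) and `rel_spread`
#'   (interquartile range over the median).
#' @export
detect_plateau <- function(x, y, trim = 0.25) {
  ok <- is.finite(y)
  x <- x[ok]; y <- y[ok]
  k <- length(y)
  if (k < 8) stop("too few points for plateau detection")
  idx <- seq(ceiling(k * trim), floor(k * (1 - trim)))
  level <- stats::median(y[idx])
  list(level = level,
       rel_spread = stats::IQR(y[idx]) / abs(level))
}
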