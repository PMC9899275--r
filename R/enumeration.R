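#' Exact first-exit enumeration on a frozen visited domain
#'
#' Deterministic propagation of the walker's occupation probability through
#' the transition matrix restricted to the visited sites. Probability flowing
#' to any unvisited neighbour is absorbed and recorded as exit mass at that
#' step, so the returned series is the exact distribution of the inter-visit
#' time \eqn{\tau_n} conditional on the frozen domain.
#'
#' Supported step rules: simple (lattice or graph substrates), persistent
#' (enumerated on the (site, incoming-direction) product space, which
#' restores the Markov property exactly), and 1d Levy flights (long-range
#' columns; jumps landing outside the domain are exits by definition, so
#' truncation at the domain extent is exact). Non-Markovian models (TSAW,
#' fBM) are rejected.
#'
#' @name enumeration
NULL

# Build the restricted transition structure. Returns list(M, e, n_states,
# start_state_weights(start_row) -> v0).
build_restricted_kernel <- function(domain, model) {
  sub <- domain$substrate
  if (model$name %in% c("tsaw", "fbm"))
    stop("exact enumeration requires a Markovian step rule; '", model$name,
         "' is history-dependent")
  if (is_graph_substrate(sub)) {
    if (model$name != "simple") stop("graph substrates use the simple walk")
    sites <- domain$sites
    n <- length(sites)
    loc <- integer(sub$n_vertices)
    loc[sites] <- seq_len(n)
    ii <- jj <- integer(0); xx <- numeric(0)
    e <- numeric(n)
    for (k in seq_len(n)) {
      nb <- sub$adj[[sites[k]]]
      p <- 1 / length(nb)
      ins <- loc[nb]
      stay <- ins > 0
      e[k] <- sum(!stay) * p
      if (any(stay)) {
        jj <- c(jj, rep(k, sum(stay)))
        ii <- c(ii, ins[stay])
        xx <- c(xx, rep(p, sum(stay)))
      }
    }
    v0 <- function(start_row) { v <- numeric(n); v[start_row] <- 1; v }
    list(ii = ii, jj = jj, xx = xx, e = e, n_states = n, v0 = v0)
  } else {
    d <- sub$params$d
    s <- domain$sites
    n <- nrow(s)
    keys <- site_keys(s)
    loc <- seq_len(n)
    names(loc) <- keys
    if (model$name == "simple") {
      ii <- jj <- integer(0); xx <- numeric(0)
      e <- numeric(n)
      p <- 1 / (2 * d)
      for (dir in seq_len(2 * d)) {
        nb <- s
        j <- (dir + 1) %/% 2
        nb[, j] <- nb[, j] + if (dir %% 2 == 1) -1 else 1
        tgt <- loc[site_keys(nb)]
        stay <- !is.na(tgt)
        e[!stay] <- e[!stay] + p
        ii <- c(ii, unname(tgt[stay]))
        jj <- c(jj, which(stay))
        xx <- c(xx, rep(p, sum(stay)))
      }
      v0 <- function(start_row) { v <- numeric(n); v[start_row] <- 1; v }
      list(ii = ii, jj = jj, xx = xx, e = e, n_states = n, v0 = v0)
    } else if (model$name == "persistent") {
      pp <- model$params$p
      nd <- 2 * d
      # state index: (site k, incoming direction dir) -> (k-1)*nd + dir
      deltas <- matrix(0L, nd, d)
      for (dir in seq_len(nd)) {
        j <- (dir + 1) %/% 2
        deltas[dir, j] <- if (dir %% 2 == 1) -1L else 1L
      }
      ii <- jj <- integer(0); xx <- numeric(0)
      e <- numeric(n * nd)
      for (k in seq_len(n)) for (dir in seq_len(nd)) {
        st <- (k - 1) * nd + dir
        for (dir2 in seq_len(nd)) {
          pr <- if (dir2 == dir) pp else (1 - pp) / (nd - 1)
          nb <- s[k, ] + deltas[dir2, ]
          tgt <- loc[paste(nb, collapse = ",")]
          if (is.na(tgt)) e[st] <- e[st] + pr
          else {
            ii <- c(ii, (unname(tgt) - 1) * nd + dir2)
            jj <- c(jj, st)
            xx <- c(xx, pr)
          }
        }
      }
      # the walker has no incoming direction at the frozen start: first step
      # uniform over the 2d directions
      v0 <- function(start_row) {
        v <- numeric(n * nd)
        # distribute over the states reached after the uniform first step is
        # folded into the product space: start as equal mixture of incoming
        # directions whose *next* step behaves uniformly requires p = 1/(2d);
        # instead represent the uniform first step directly: mixture over
        # (site, dir) with weight such that step one is uniform. A uniform
        # mixture over incoming directions gives each direction probability
        # p/(2d) + (1 - p)/(2d) = 1/(2d) for the next step, i.e. exactly the
        # uniform first step.
        v[(start_row - 1) * nd + seq_len(nd)] <- 1 / nd
        v
      }
      list(ii = ii, jj = jj, xx = xx, e = e, n_states = n * nd, v0 = v0)
    } else if (model$name == "levy") {
      if (d != 1) stop("Levy enumeration is implemented in 1d")
      alpha <- model$params$alpha
      xs <- as.numeric(s[, 1])
      n <- length(xs)
      ii <- jj <- integer(0); xx <- numeric(0)
      e <- numeric(n)
      for (k in seq_len(n)) {
        sdisp <- xs - xs[k]
        keep <- sdisp != 0
        pr <- levy_jump_pmf(sdisp[keep], alpha)
        ii <- c(ii, which(keep))
        jj <- c(jj, rep(k, sum(keep)))
        xx <- c(xx, pr)
        e[k] <- 1 - sum(pr)
      }
      v0 <- function(start_row) { v <- numeric(n); v[start_row] <- 1; v }
      list(ii = ii, jj = jj, xx = xx, e = e, n_states = n, v0 = v0)
    } else stop("unsupported model for enumeration: ", model$name)
  }
}

restricted_sparse <- function(kern) {
  # M[i, j] = P(j -> i) restricted to interior states (CSC, ready for the
  # column-sweep propagation loop)
  Matrix::sparseMatrix(i = kern$ii, j = kern$jj, x = kern$xx,
                       dims = c(kern$n_states, kern$n_states))
}

#' Exact exit-time distribution from a visited domain
#'
#' @param domain a `visited_domain`.
#' @param start the start site: row index into the domain's discovery-order
#'   site list (default: the last-visited site, the physical start of the
#'   \eqn{\tau_n} clock).
#' @param tau_max propagation horizon.
#' @param model a Markovian [walk_model()].
#' @param tol stop early once residual survival drops below `tol`.
#' @return An `exit_distribution`: `mass[t]` = P(first exit at step t),
#'   `survival` = residual mass, plus metadata. Masses already computed are
#'   unchanged by enlarging `tau_max` (prefix stability).
#' @export
exit_time_distribution <- function(domain, start = domain$n, tau_max,
                                   model = walk_model("simple"),
                                   tol = 1e-10) {
  if (start < 1 || start > domain$n) stop("start must index a visited site")
  kern <- build_restricted_kernel(domain, model)
  M <- restricted_sparse(kern)
  res <- cpp_exit_propagate(M@p, M@i, M@x, kern$e, kern$v0(start), tau_max,
                            tol)
  structure(list(mass = res$mass, survival = res$survival,
                 survival_series = res$survival_series, start = start,
                 n = domain$n, model = model, tau_max = tau_max),
            class = "exit_distribution")
}

#' @export
print.exit_distribution <- function(x, ...) {
  cat(sprintf("<exit_distribution: n = %d, %d steps computed, survival %.3g>\n",
              x$n, length(x$mass), x$survival))
  invisible(x)
}

#' Exact mean exit time from a visited domain
#'
#' Solves the linear first-moment system \eqn{(I - Q) m = 1} on the interior
#' states.
#'
#' @inheritParams exit_time_distribution
#' @return A list: `per_start` (mean exit time from each visited site) and
#'   `average` (start averaged uniformly over visited sites).
#' @export
mean_exit_time <- function(domain, model = walk_model("simple")) {
  kern <- build_restricted_kernel(domain, model)
  M <- restricted_sparse(kern) # t(Q)
  I <- Matrix::Diagonal(kern$n_states)
  m <- Matrix::solve(Matrix::t(I - M), rep(1, kern$n_states))
  m <- as.numeric(m)
  per_start <- vapply(seq_len(domain$n),
                      function(k) sum(kern$v0(k) * m), numeric(1))
  list(per_start = per_start, average = mean(per_start))
}

#' Serialize an exit distribution
#'
#' Writes a TSV of (tau, mass) plus a JSON sidecar with survival, start and
#' domain size.
#'
#' @param x an `exit_distribution`.
#' @param path TSV path; the sidecar gets extension `.json`.
#' @export
write_exit_distribution <- function(x, path) {
  utils::write.table(data.frame(tau = seq_along(x$mass), mass = x$mass),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(survival = x$survival, start = x$start, n = x$n),
                       paste0(tools::file_path_sans_ext(path), ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
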