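#' Visitation observables
#'
#' Functions that reduce a trajectory to the exploration observables: the
#' inter-visit times \eqn{\tau_n}, the step function N(t) of distinct sites
#' visited, the visited domain with its boundary (the unvisited nearest
#' neighbours, i.e. the traps), the domain perimeter and island count on the
#' square lattice, and the radius of the largest trap-free region.
#'
#' @name visitation
NULL

site_keys <- function(sites) {
  if (is.matrix(sites)) do.call(paste, c(as.data.frame(sites), sep = ","))
  else as.character(sites)
}

#' Record the visitation observables of a trajectory
#'
#' The start site counts as the first distinct site at t = 0; \eqn{\tau_n} is
#' the number of steps between the discoveries of the n-th and (n+1)-st
#' distinct sites. Levy jumps do not mark flown-over sites: only occupied
#' positions enter the visited set.
#'
#' @param traj an `rw_trajectory` from [simulate_trajectory()], or a position
#'   matrix / vertex-id vector.
#' @param substrate the substrate (required when `traj` is bare positions on
#'   a graph; inferred from an `rw_trajectory`).
#' @return A list with `tau_series` (data frame `n`, `tau`), `N` (vector of
#'   N(t) for t = 0..T), and `domain` (a `visited_domain`).
#' @export
record_visitation <- function(traj, substrate = NULL) {
  if (inherits(traj, "rw_trajectory")) {
    substrate <- traj$substrate
    sites <- traj$sites
  } else {
    sites <- traj
    if (is.null(substrate))
      substrate <- substrate_hypercubic(if (is.matrix(sites)) ncol(sites) else 1)
  }
  if (!is.matrix(sites) && !is_graph_substrate(substrate))
    sites <- matrix(sites, ncol = 1)
  keys <- site_keys(sites)
  first <- !duplicated(keys)
  N <- cumsum(first)
  disc <- which(first) - 1L
  taus <- diff(disc)
  dom_sites <- if (is.matrix(sites)) sites[first, , drop = FALSE] else sites[first]
  tau_df <- data.frame(n = seq_along(taus), tau = as.numeric(taus))
  list(tau_series = tau_df, N = N,
       domain = visited_domain(dom_sites, substrate))
}

#' Visited domain
#'
#' @param sites distinct visited sites (matrix of lattice coordinates in
#'   discovery order, or graph vertex ids).
#' @param substrate the substrate the walk moved on.
#' @return A `visited_domain` with fields `sites`, `n`, `substrate`.
#' @export
visited_domain <- function(sites, substrate) {
  if (!is_graph_substrate(substrate) && !is.matrix(sites))
    sites <- matrix(sites, ncol = 1)
  n <- if (is.matrix(sites)) nrow(sites) else length(sites)
  structure(list(sites = sites, n = n, substrate = substrate),
            class = "visited_domain")
}

#' @export
print.visited_domain <- function(x, ...) {
  cat(sprintf("<visited_domain: %d sites on %s>\n", x$n, x$substrate$kind))
  invisible(x)
}

#' Boundary of a visited domain
#'
#' The unvisited nearest neighbours of the visited sites — the traps whose
#' first hitting defines \eqn{\tau_n}.
#'
#' @param domain a `visited_domain`.
#' @return A matrix of boundary sites (lattice) or vector of vertex ids.
#' @export
boundary_of <- function(domain) {
  sub <- domain$substrate
  if (is_graph_substrate(sub)) {
    nb <- unlist(sub$adj[domain$sites], use.names = FALSE)
    sort(setdiff(unique(nb), domain$sites))
  } else {
    d <- sub$params$d
    s <- domain$sites
    n <- nrow(s)
    nb <- matrix(0, n * 2 * d, d)
    r <- 0
    for (j in seq_len(d)) for (sgn in c(-1, 1)) {
      blk <- s
      blk[, j] <- blk[, j] + sgn
      nb[r * n + seq_len(n), ] <- blk
      r <- r + 1
    }
    keys <- site_keys(nb)
    keep <- !duplicated(keys) & !(keys %in% site_keys(s))
    nb[keep, , drop = FALSE]
  }
}

#' Perimeter of a 2d visited domain
#'
#' Number of visited-unvisited nearest-neighbour bonds. On the square lattice
#' the perimeter changes in even steps, which is why perimeter levels are
#' compared at P and P + 2.
#'
#' @param domain a `visited_domain` on the 2d square lattice.
#' @return Integer bond count.
#' @export
domain_perimeter <- function(domain) {
  sub <- domain$substrate
  if (sub$kind != "hypercubic" || sub$params$d != 2)
    stop("the perimeter observable is defined on the square lattice")
  cpp_boundary_bonds(domain$sites, 2L)
}

#' Perimeter time series and level first-attainment times
#'
#' Follows the domain perimeter P(t) along a square-lattice trajectory and
#' records, for each even level, the first time P reaches it. Differences of
#' consecutive level times are the boundary inter-increment times
#' \eqn{\tau_P} between first observations of perimeter P and P + 2.
#'
#' @param traj an `rw_trajectory` on the 2d square lattice (or position
#'   matrix).
#' @return A list with `P` (perimeter after each step) and `level_times`
#'   (data frame `level`, `t_first`).
#' @export
perimeter_series <- function(traj) {
  sites <- if (inherits(traj, "rw_trajectory")) traj$sites else traj
  if (!is.matrix(sites) || ncol(sites) != 2)
    stop("perimeter_series needs a square-lattice trajectory")
  keys <- site_keys(sites)
  first <- !duplicated(keys)
  visited <- new.env(hash = TRUE, size = 4 * sum(first))
  P <- numeric(nrow(sites))
  cur <- 0
  for (t in seq_len(nrow(sites))) {
    if (first[t]) {
      x <- sites[t, 1]; y <- sites[t, 2]
      nvis <- 0
      for (nb in list(c(x + 1, y), c(x - 1, y), c(x, y + 1), c(x, y - 1)))
        if (!is.null(visited[[paste(nb[1], nb[2], sep = ",")]])) nvis <- nvis + 1
      cur <- cur + 4 - 2 * nvis
      assign(paste(x, y, sep = ","), TRUE, envir = visited)
    }
    P[t] <- cur
  }
  levels <- seq(4, max(P), by = 2)
  t_first <- vapply(levels, function(l) which(P >= l)[1] - 1, numeric(1))
  list(P = P, level_times = data.frame(level = levels, t_first = t_first))
}

#' Number of islands enclosed by a 2d visited domain
#'
#' Finite 4-connected components of unvisited sites that are not connected
#' to the infinite exterior, found by flood-filling the complement from a
#' frame surrounding the domain's bounding box.
#'
#' @param domain a `visited_domain` on the 2d square lattice.
#' @return Integer island count.
#' @export
island_count <- function(domain) {
  sub <- domain$substrate
  if (sub$kind != "hypercubic" || sub$params$d != 2)
    stop("island_count is defined on the square lattice")
  s <- domain$sites
  xr <- range(s[, 1]); yr <- range(s[, 2])
  nx <- xr[2] - xr[1] + 3; ny <- yr[2] - yr[1] + 3
  occ <- matrix(FALSE, nx, ny)
  occ[cbind(s[, 1] - xr[1] + 2, s[, 2] - yr[1] + 2)] <- TRUE
  ext <- matrix(FALSE, nx, ny)
  ext[1, ] <- ext[nx, ] <- TRUE
  ext[, 1] <- ext[, ny] <- TRUE
  ext <- ext & !occ
  repeat {
    grown <- ext
    grown[-1, ] <- grown[-1, ] | ext[-nx, ]
    grown[-nx, ] <- grown[-nx, ] | ext[-1, ]
    grown[, -1] <- grown[, -1] | ext[, -ny]
    grown[, -ny] <- grown[, -ny] | ext[, -1]
    grown <- grown & !occ
    if (identical(grown, ext)) break
    ext <- grown
  }
  hole <- !occ & !ext
  if (!any(hole)) return(0L)
  # count 4-connected components of the hole cells
  id <- matrix(0L, nx, ny)
  id[hole] <- seq_len(sum(hole))
  cells <- which(hole, arr.ind = TRUE)
  edges <- NULL
  for (shift in list(c(1, 0), c(0, 1))) {
    nb <- cells + rep(shift, each = nrow(cells))
    ok <- nb[, 1] >= 1 & nb[, 1] <= nx & nb[, 2] >= 1 & nb[, 2] <= ny
    ok[ok] <- hole[nb[ok, , drop = FALSE]]
    if (any(ok))
      edges <- rbind(edges, cbind(id[cells[ok, , drop = FALSE]],
                                  id[nb[ok, , drop = FALSE]]))
  }
  if (is.null(edges)) return(sum(hole))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0, sum(hole) - igraph::vcount(g)))
  igraph::components(g)$no
}

#' Island-count level attainment times for 1d Levy flights
#'
#' Tracks the number of enclosed unvisited gaps along 1d Levy trajectories
#' and records the first time the island count reaches each level 1..`i_max`
#' for every realization. Differences of consecutive level times are the
#' boundary inter-increment times \eqn{\tau_I}.
#'
#' @param alpha Levy index.
#' @param i_max largest island count tracked.
#' @param reps number of realizations.
#' @param seed integer seed.
#' @param horizon step budget per realization.
#' @return A `reps x i_max` matrix of first-attainment times (NA if never).
#' @export
island_level_times <- function(alpha, i_max, reps, seed, horizon = 1e7) {
  cpp_island_levels(alpha, as.integer(i_max), horizon, as.integer(reps), seed)
}

#' Perimeter level first-attainment times for 2d simple walks
#'
#' @param p_max largest perimeter level tracked (even).
#' @param reps number of realizations.
#' @param seed integer seed.
#' @param horizon step budget per realization.
#' @return A `reps x (p_max-4)/2` matrix; column k is the first time the
#'   perimeter reached level `4 + 2k`.
#' @export
perimeter_level_times <- function(p_max, reps, seed, horizon = 1e6) {
  out <- cpp_perimeter_levels(as.integer(p_max), horizon, as.integer(reps),
                              seed)
  colnames(out) <- seq(6, p_max, by = 2)
  out
}

#' Radius of the largest trap-free region
#'
#' The largest ball, centred on a visited site, containing no unvisited site:
#' the maximum over visited sites of the distance to the nearest unvisited
#' site. Lattice substrates use the Euclidean metric; graph substrates the
#' chemical (shortest-path) distance. The nearest unvisited site to any
#' visited site is always adjacent to the visited set, so only boundary sites
#' need to be scanned.
#'
#' @param domain a `visited_domain`.
#' @return The radius (real for lattices, integer for graphs).
#' @export
largest_trapfree_radius <- function(domain) {
  sub <- domain$substrate
  if (is_graph_substrate(sub)) {
    bd <- boundary_of(domain)
    inside <- rep(FALSE, sub$n_vertices)
    inside[domain$sites] <- TRUE
    dist <- rep(NA_integer_, sub$n_vertices)
    frontier <- bd
    dist[frontier] <- 0L
    lev <- 0L
    while (length(frontier)) {
      lev <- lev + 1L
      nb <- unique(unlist(sub$adj[frontier], use.names = FALSE))
      nb <- nb[inside[nb] & is.na(dist[nb])]
      dist[nb] <- lev
      frontier <- nb
    }
    max(dist[domain$sites])
  } else {
    bd <- boundary_of(domain)
    # max over visited sites of min Euclidean distance to a boundary site
    sqrt(cpp_max_min_dist2(domain$sites, bd))
  }
}

#' Inter-increment times of the dimer count for 1d Levy flights
#'
#' The dimer count (number of adjacent visited pairs, a bulk observable)
#' increments whenever a newly visited site touches the visited set. Returns
#' the event times of new-site discoveries and of dimer increments for one
#' realization, for distributional comparison of bulk and visitation
#' dynamics.
#'
#' @param alpha Levy index.
#' @param n_events number of new-site events to record.
#' @param seed,stream substream selectors.
#' @param horizon step budget.
#' @return List with `site_times` and `dimer_times`.
#' @export
dimer_events <- function(alpha, n_events, seed, stream = 0, horizon = 1e7) {
  cpp_levy1d_bulk_events(alpha, as.integer(n_events), horizon, seed, stream)
}
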