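#' Discrete media for random-walk exploration
#'
#' A substrate bundles the neighbour structure of the medium with its two
#' governing exponents: the fractal dimension `d_f` (scaling of the number of
#' sites within radius r) and the walk dimension `d_w` (mean-square
#' displacement \eqn{\langle r^2 \rangle \propto t^{2/d_w}}). Their ratio
#' \eqn{\mu = d_f/d_w} classifies the exploration as recurrent (\eqn{\mu<1}),
#' marginal (\eqn{\mu=1}) or transient (\eqn{\mu>1}).
#'
#' Two representations are used: hypercubic lattices are implicit (infinite,
#' neighbours computed on the fly), while the Sierpinski gasket, the T-fractal
#' tree and percolation clusters are finite graphs stored as adjacency lists.
#'
#' @name substrates
NULL

new_substrate <- function(kind, d_f, d_w, params, graph = NULL) {
  obj <- list(kind = kind, d_f = d_f, d_w = d_w, params = params)
  if (!is.null(graph)) obj <- c(obj, graph)
  structure(obj, class = "rw_substrate")
}

#' @export
print.rw_substrate <- function(x, ...) {
  cat(sprintf("<rw_substrate: %s>\n", x$kind))
  cat(sprintf("  d_f = %.4f, d_w = %.4f, mu = %.4f\n", x$d_f, x$d_w,
              x$d_f / x$d_w))
  if (!is.null(x$n_vertices))
    cat(sprintf("  %d vertices, %d edges\n", x$n_vertices, x$n_edges))
  if (length(x$params))
    cat("  params:", paste(names(x$params), unlist(x$params), sep = "=",
                           collapse = ", "), "\n")
  invisible(x)
}

is_graph_substrate <- function(s) !is.null(s$csr)

#' Hypercubic lattice substrate
#'
#' The implicit infinite d-dimensional integer lattice with nearest-neighbour
#' bonds; `d_f = d`, `d_w = 2`.
#'
#' @param d integer dimension, between 1 and 6.
#' @return An object of class `rw_substrate`.
#' @examples
#' site_neighbors(substrate_hypercubic(2), c(0, 0))
#' @export
substrate_hypercubic <- function(d) {
  if (!is.numeric(d) || length(d) != 1 || d != round(d) || d < 1 || d > 6)
    stop("d must be an integer between 1 and 6")
  new_substrate("hypercubic", d_f = d, d_w = 2, params = list(d = as.integer(d)))
}

# Build the adjacency-list representation used by the C++ graph walkers.
# edges: 2-column matrix of 1-based vertex ids.
graph_parts <- function(edges, n_vertices, coords = NULL) {
  adj <- vector("list", n_vertices)
  both <- rbind(edges, edges[, 2:1, drop = FALSE])
  sp <- split(both[, 2], both[, 1])
  adj[as.integer(names(sp))] <- lapply(sp, function(v) sort(unique(v)))
  deg <- lengths(adj)
  indptr <- c(0L, cumsum(deg))
  indices <- unlist(adj, use.names = FALSE) - 1L
  list(adj = adj, csr = list(indptr = as.integer(indptr),
                             indices = as.integer(indices)),
       coords = coords, n_vertices = n_vertices, n_edges = nrow(edges))
}

#' Sierpinski gasket substrate
#'
#' Finite-generation Sierpinski gasket with corner (apex) start site;
#' `d_f = ln3/ln2`, `d_w = ln5/ln2`, so `mu = ln3/ln5 ~ 0.683`. The gasket
#' proper is unbounded; here a large finite generation stands in for it and
#' trajectories that touch the two far corner vertices are flagged through
#' the `guard` vertex set (see [simulate_tau()]).
#'
#' @param generation integer >= 1; the default 10 gives 88575 vertices, large
#'   enough that desk-scale walks never approach the outer corners.
#' @return An `rw_substrate` with adjacency, triangular-lattice coordinates,
#'   a `start` vertex (the apex) and `guard` vertices (the far corners).
#' @export
substrate_gasket <- function(generation = 10) {
  if (generation < 1) stop("generation must be >= 1")
  # integer coordinates (a, b) on the triangular lattice; embedding is
  # x = a + b/2, y = b*sqrt(3)/2. Recursion: gasket(g) is three copies of
  # gasket(g-1) translated to the corners of a side-2^g triangle.
  edges <- rbind(c(0L, 0L, 1L, 0L), c(0L, 0L, 0L, 1L), c(1L, 0L, 0L, 1L))
  for (g in seq_len(generation)) {
    s <- 2L^(g - 1L)
    edges <- rbind(edges,
                   sweep(edges, 2, c(s, 0L, s, 0L), "+"),
                   sweep(edges, 2, c(0L, s, 0L, s), "+"))
  }
  keys <- unique(c(paste(edges[, 1], edges[, 2]), paste(edges[, 3], edges[, 4])))
  id <- seq_along(keys)
  names(id) <- keys
  em <- cbind(id[paste(edges[, 1], edges[, 2])],
              id[paste(edges[, 3], edges[, 4])])
  em <- unique(t(apply(em, 1, sort)))
  ab <- do.call(rbind, strsplit(keys, " "))
  ab <- matrix(as.numeric(ab), ncol = 2)
  coords <- cbind(ab[, 1] + ab[, 2] / 2, ab[, 2] * sqrt(3) / 2)
  gp <- graph_parts(em, length(keys), coords)
  side <- 2^generation
  start <- unname(id[paste(0L, 0L)])
  guard <- unname(id[c(paste(side, 0L), paste(0L, side))])
  sub <- new_substrate("gasket", d_f = log(3) / log(2), d_w = log(5) / log(2),
                       params = list(generation = as.integer(generation)),
                       graph = gp)
  sub$start <- start
  sub$guard <- guard
  sub
}

#' T-fractal tree substrate
#'
#' Standard T-fractal: each edge of the previous generation is replaced by a
#' "T" of three edges, so generation g has `3^g` edges. The tree has
#' `d_f = ln3/ln2` and `d_w = ln6/ln2`, hence `mu = ln3/ln6 ~ 0.613`. The
#' start site is the junction vertex created at the first subdivision.
#'
#' @param generation integer between 1 and 12.
#' @return An `rw_substrate` graph object.
#' @export
substrate_ttree <- function(generation = 9) {
  if (generation < 1 || generation > 12)
    stop("generation must be between 1 and 12")
  edges <- matrix(c(1L, 2L), ncol = 2)
  nv <- 2L
  for (g in seq_len(generation)) {
    ne <- nrow(edges)
    mid <- nv + seq_len(ne)            # midpoint of each old edge
    leaf <- nv + ne + seq_len(ne)      # new dangling vertex at each midpoint
    edges <- rbind(cbind(edges[, 1], mid),
                   cbind(mid, edges[, 2]),
                   cbind(mid, leaf))
    nv <- nv + 2L * ne
  }
  gp <- graph_parts(edges, nv)
  sub <- new_substrate("ttree", d_f = log(3) / log(2), d_w = log(6) / log(2),
                       params = list(generation = as.integer(generation)),
                       graph = gp)
  sub$start <- 3L # midpoint created when the initial edge was subdivided
  sub
}

#' Critical bond-percolation cluster substrate
#'
#' Retains each bond of an L x L periodic square lattice independently with
#' probability `keep_prob` (default 1/2, the bond-percolation threshold) and
#' returns the largest connected cluster. Site identity uses the wrapped
#' (torus) coordinates, so a revisit through the periodic boundary counts as
#' a revisit. The stored exponents are `d_f = 91/48` (2d percolation) and
#' `d_w = d_f / 0.659`, the walk dimension consistent with the measured
#' exploration exponent `mu ~ 0.659`.
#'
#' @param L lattice side, >= 4.
#' @param keep_prob bond retention probability in `[0, 1]`.
#' @param seed integer seed controlling bond dilution (bit-reproducible).
#' @return An `rw_substrate` with the cluster adjacency, integer coordinates
#'   of each cluster site, and `cluster_size`.
#' @export
substrate_percolation <- function(L, keep_prob = 0.5, seed = 1) {
  if (L < 4) stop("L must be >= 4")
  if (keep_prob < 0 || keep_prob > 1) stop("keep_prob must be in [0, 1]")
  x <- rep(seq_len(L), times = L)
  y <- rep(seq_len(L), each = L)
  idx <- function(x, y) (y - 1L) * L + x
  v <- idx(x, y)
  right <- idx(x %% L + 1L, y)
  up <- idx(x, y %% L + 1L)
  bonds <- rbind(cbind(v, right), cbind(v, up))
  keep <- with_seed(seed, stats::runif(nrow(bonds)) < keep_prob)
  bonds <- bonds[keep, , drop = FALSE]
  if (nrow(bonds) == 0) stop("no bonds retained: the cluster is empty")
  g <- igraph::graph_from_edgelist(bonds, directed = FALSE)
  g <- igraph::add_vertices(g, max(0, L^2 - igraph::vcount(g)))
  comp <- igraph::components(g)
  big <- which.max(comp$csize)
  members <- which(comp$membership == big)
  remap <- integer(L^2)
  remap[members] <- seq_along(members)
  on_cluster <- remap[bonds[, 1]] > 0 & remap[bonds[, 2]] > 0
  em <- cbind(remap[bonds[on_cluster, 1]], remap[bonds[on_cluster, 2]])
  coords <- cbind(x[members], y[members])
  gp <- graph_parts(em, length(members), coords)
  d_f <- 91 / 48
  sub <- new_substrate("percolation", d_f = d_f, d_w = d_f / 0.659,
                       params = list(L = as.integer(L), keep_prob = keep_prob,
                                     seed = as.integer(seed)),
                       graph = gp)
  sub$cluster_size <- length(members)
  sub
}

#' Neighbours of a site
#'
#' @param substrate an `rw_substrate`.
#' @param site integer coordinate vector (lattice substrates) or a vertex id
#'   (graph substrates).
#' @return For lattices, a matrix with one neighbour per row; for graphs, an
#'   ordered integer vector of vertex ids.
#' @export
site_neighbors <- function(substrate, site) {
  if (substrate$kind == "hypercubic") {
    d <- substrate$params$d
    if (length(site) != d) stop("site must have ", d, " coordinates")
    out <- matrix(rep(as.integer(site), each = 2 * d), nrow = 2 * d)
    for (j in seq_len(d)) {
      out[2 * j - 1, j] <- out[2 * j - 1, j] - 1L
      out[2 * j, j] <- out[2 * j, j] + 1L
    }
    out
  } else {
    substrate$adj[[site]]
  }
}

#' Substrate descriptor for serialization
#'
#' @param substrate an `rw_substrate`.
#' @return A plain list (kind, exponents, parameters) serializable to JSON.
#' @export
substrate_descriptor <- function(substrate) {
  list(kind = substrate$kind, d_f = substrate$d_f, d_w = substrate$d_w,
       params = substrate$params)
}

#' Write a graph substrate as an edge-list TSV
#'
#' @param substrate a graph `rw_substrate` (gasket, ttree or percolation).
#' @param path output file.
#' @export
write_substrate_edges <- function(substrate, path) {
  if (!is_graph_substrate(substrate)) stop("lattice substrates are implicit")
  ip <- substrate$csr$indptr
  ix <- substrate$csr$indices + 1L
  from <- rep(seq_len(substrate$n_vertices), diff(ip))
  keep <- from < ix
  utils::write.table(data.frame(from = from[keep], to = ix[keep]),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Evaluate an expression under a temporary R RNG seed, restoring state after.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
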