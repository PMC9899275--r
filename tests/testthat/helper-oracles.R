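# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Exact first-exit distribution of the 1d nearest-neighbour walk from an
# interval of n sites (absorbing at both ends), via the spectral
# decomposition of the tridiagonal chain: eigenvalues cos(k*pi/(n+1)).
interval_exit_spectral <- function(n, start, t_max) {
  k <- seq_len(n)
  lambda <- cos(k * pi / (n + 1))
  v <- sqrt(2 / (n + 1)) * outer(k, seq_len(n), function(k, j) sin(k * pi * j / (n + 1)))
  w <- v[, start] * rowSums(v) # spectral weight of survival from `start`
  surv <- vapply(0:t_max, function(t) sum(w * lambda^t), numeric(1))
  -diff(surv) # F(t) = S(t-1) - S(t), t = 1..t_max
}

# Largest connected component of a bond list by plain BFS flood fill
# (oracle for the igraph-based percolation construction).
flood_fill_largest <- function(bonds, n_vertices) {
  adj <- vector("list", n_vertices)
  for (r in seq_len(nrow(bonds))) {
    a <- bonds[r, 1]; b <- bonds[r, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  seen <- logical(n_vertices)
  best <- 0L
  for (s in seq_len(n_vertices)) {
    if (seen[s] || is.null(adj[[s]])) next
    queue <- s
    seen[s] <- TRUE
    size <- 0L
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      size <- size + 1L
      nb <- adj[[v]]
      new <- nb[!seen[nb]]
      seen[new] <- TRUE
      queue <- c(queue, new)
    }
    best <- max(best, size)
  }
  best
}

# All fixed polyominoes with up to `max_cells` cells (canonical form:
# translation-normalized sorted cell strings), grown cell by cell.
enumerate_polyominoes <- function(max_cells) {
  canon <- function(cells) {
    cells[, 1] <- cells[, 1] - min(cells[, 1])
    cells[, 2] <- cells[, 2] - min(cells[, 2])
    key <- paste(cells[, 1], cells[, 2], sep = ",")
    cells[order(cells[, 1], cells[, 2]), , drop = FALSE]
  }
  key_of <- function(cells) paste(t(cells), collapse = ";")
  out <- list(list(matrix(c(0L, 0L), 1)))
  for (size in 2:max_cells) {
    seen <- new.env(hash = TRUE)
    grown <- list()
    for (p in out[[size - 1]]) {
      keys <- paste(p[, 1], p[, 2], sep = ",")
      for (i in seq_len(nrow(p))) for (dxy in list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L))) {
        cell <- p[i, ] + dxy
        if (paste(cell[1], cell[2], sep = ",") %in% keys) next
        cand <- canon(rbind(p, cell))
        k <- key_of(cand)
        if (is.null(seen[[k]])) {
          seen[[k]] <- TRUE
          grown[[length(grown) + 1]] <- cand
        }
      }
    }
    out[[size]] <- grown
  }
  unlist(out, recursive = FALSE)
}

# Synthetic recurrent-class F_n curves from one scaling function psi:
# F_n(tau) = n^{-(1+1/mu)} psi(tau / n^{1/mu}).
synthetic_psi_curves <- function(mu, ns, psi = function(x) x^(-(1 + mu)) * exp(-x)) {
  lapply(ns, function(n) {
    x <- 10^seq(-2, 1.5, length.out = 60) * n^(1 / mu)
    data.frame(x = x, y = n^(-(1 + 1 / mu)) * psi(x / n^(1 / mu)))
  })
}

# Exact death-time distribution of the 2d starving walk with S = 1 over the
# first `depth` steps, by full path enumeration (4^depth paths): with S = 1
# the forager dies on the first step that lands on an already-eaten site.
starving_s1_exact <- function(depth) {
  dirs <- list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  probs <- numeric(depth)
  recurse <- function(pos, visited, t, p) {
    if (t > depth) return(invisible())
    for (d in dirs) {
      np <- pos + d
      key <- paste(np, collapse = ",")
      if (key %in% visited) {
        probs[t] <<- probs[t] + p / 4
      } else {
        recurse(np, c(visited, key), t + 1, p / 4)
      }
    }
  }
  recurse(c(0, 0), "0,0", 1, 1)
  probs
}
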