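# Independent oracles used across the suite: these deliberately avoid the
# code paths they check.

# brute-force minimum-image displacement: enumerate all 27 periodic images
brute_min_image <- function(a, b, L) {
  best <- NULL; bestn <- Inf
  for (ix in -1:1) for (iy in -1:1) for (iz in -1:1) {
    d <- (b + c(ix, iy, iz) * L) - a
    n <- sqrt(sum(d^2))
    if (n < bestn) { bestn <- n; best <- d }
  }
  best
}

# BFS shortest-path distances from src on an undirected edge list over 1..n
bfs_dist <- function(n, edges, src) {
  adj <- vector("list", n)
  if (nrow(edges)) {
    for (r in seq_len(nrow(edges))) {
      a <- edges[r, 1]; b <- edges[r, 2]
      adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
    }
  }
  dist <- rep(Inf, n); dist[src] <- 0; q <- src
  while (length(q)) {
    v <- q[1]; q <- q[-1]
    for (w in adj[[v]]) {
      if (!is.finite(dist[w])) { dist[w] <- dist[v] + 1; q <- c(q, w) }
    }
  }
  dist
}

closeness_oracle <- function(n, edges) {
  vapply(seq_len(n), function(v) {
    d <- bfs_dist(n, edges, v)[-v]
    reach <- d[is.finite(d)]
    r <- length(reach) + 1L
    if (r == 1L) 0 else ((r - 1) / (n - 1)) * ((r - 1) / sum(reach))
  }, 0)
}

degree_oracle <- function(n, edges) {
  deg <- integer(n)
  if (nrow(edges)) for (r in seq_len(nrow(edges))) {
    deg[edges[r, 1]] <- deg[edges[r, 1]] + 1L
    deg[edges[r, 2]] <- deg[edges[r, 2]] + 1L
  }
  deg
}

random_er_graph <- function(n, p) {
  all_pairs <- t(combn(n, 2))
  keep <- runif(nrow(all_pairs)) < p
  all_pairs[keep, , drop = FALSE]
}

# naive O(T^2) MSD over sliding origins (per-axis subset)
naive_msd <- function(a, axes, tau_max) {
  nT <- dim(a)[1]
  vapply(seq_len(tau_max), function(tau) {
    s <- 0; cnt <- 0
    for (t in seq_len(nT - tau)) {
      d <- a[t + tau, , axes, drop = FALSE] - a[t, , axes, drop = FALSE]
      s <- s + sum(d^2); cnt <- cnt + dim(a)[2]
    }
    s / cnt
  }, 0)
}

# brute-force O(N^2) pair-distance histogram counts (minimum image)
brute_pair_counts <- function(pos, L, edges_r) {
  n <- nrow(pos)
  dists <- c()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d <- pos[j, ] - pos[i, ]
    d <- d - L * round(d / L)
    dists <- c(dists, sqrt(sum(d^2)))
  }
  dists <- dists[dists <= max(edges_r)]
  hist(dists, breaks = edges_r, plot = FALSE)$counts * 2  # ordered pairs
}

# analytic surface area of z = A sin(2 pi p x / Lx) over the box via 1-D
# quadrature: Ly * integral sqrt(1 + (dz/dx)^2) dx
quadrature_area_sine <- function(A, p, lx, ly) {
  f <- function(x) sqrt(1 + (A * 2 * pi * p / lx * cos(2 * pi * p * x / lx))^2)
  ly * stats::integrate(f, 0, lx, rel.tol = 1e-10)$value
}
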