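# Scattered-data linear interpolation on a Delaunay triangulation,
# with periodic ghost images so the interpolant is defined on the whole
# primary cell. This is the grid-construction engine behind leaflet height
# fields; it is deliberately self-contained.

# circumcircle center + squared radius for triangles (rows of idx into x,y)
tri_circum <- function(x, y, idx) {
  ax <- x[idx[, 1]]; ay <- y[idx[, 1]]
  bx <- x[idx[, 2]]; by <- y[idx[, 2]]
  cx <- x[idx[, 3]]; cy <- y[idx[, 3]]
  d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
  d[abs(d) < 1e-300] <- NA_real_
  a2 <- ax^2 + ay^2; b2 <- bx^2 + by^2; c2 <- cx^2 + cy^2
  ux <- (a2 * (by - cy) + b2 * (cy - ay) + c2 * (ay - by)) / d
  uy <- (a2 * (cx - bx) + b2 * (ax - cx) + c2 * (bx - ax)) / d
  r2 <- (ux - ax)^2 + (uy - ay)^2
  # degenerate (collinear) triangles: treat circumcircle as all-containing
  ux[is.na(d)] <- 0; uy[is.na(d)] <- 0; r2[is.na(d)] <- Inf
  cbind(ux, uy, r2)
}

# Bowyer-Watson Delaunay triangulation of points (x, y).
# Returns an integer matrix of triangles (rows of vertex indices).
# Input is assumed to be free of exact duplicates; cocircular degeneracies
# are broken by the caller via a deterministic micro-jitter.
delaunay_triangulation <- function(x, y) {
  n <- length(x)
  if (n < 3L) stop("delaunay_triangulation: need >= 3 points", call. = FALSE)
  dx <- max(x) - min(x); dy <- max(y) - min(y)
  dmax <- max(dx, dy, 1)
  cx <- (min(x) + max(x)) / 2; cy <- (min(y) + max(y)) / 2
  # super-triangle far outside the data
  X <- c(cx - 30 * dmax, cx + 30 * dmax, cx, x)
  Y <- c(cy - 20 * dmax, cy - 20 * dmax, cy + 30 * dmax, y)
  tri <- matrix(c(1L, 2L, 3L), nrow = 1L)
  cc <- tri_circum(X, Y, tri)
  for (p in 4:(n + 3L)) {
    px <- X[p]; py <- Y[p]
    bad <- (px - cc[, 1])^2 + (py - cc[, 2])^2 < cc[, 3]
    if (!any(bad)) stop("delaunay_triangulation: point outside hull (internal)",
                        call. = FALSE)
    badtri <- tri[bad, , drop = FALSE]
    e1 <- c(badtri[, 1], badtri[, 2], badtri[, 3])
    e2 <- c(badtri[, 2], badtri[, 3], badtri[, 1])
    lo <- pmin(e1, e2); hi <- pmax(e1, e2)
    key <- lo * (n + 4) + hi
    dupkey <- unique(key[duplicated(key)])
    keep <- !(key %in% dupkey)      # boundary edges appear exactly once
    newtri <- cbind(e1[keep], e2[keep], p)
    tri <- rbind(tri[!bad, , drop = FALSE], newtri)
    cc <- rbind(cc[!bad, , drop = FALSE], tri_circum(X, Y, newtri))
  }
  keep <- tri[, 1] > 3L & tri[, 2] > 3L & tri[, 3] > 3L
  tri <- tri[keep, , drop = FALSE] - 3L
  if (!nrow(tri)) stop("delaunay_triangulation: all points collinear",
                       call. = FALSE)
  tri
}

# deterministic micro-jitter to break exact-lattice cocircularity;
# amplitude is ~1e-8 of the coordinate scale, far below GRO precision
degeneracy_jitter <- function(x, scale) {
  i <- seq_along(x)
  x + scale * 1e-8 * sin(i * 12.9898 + 78.233)
}

#' Evaluate a periodic piecewise-linear interpolant
#'
#' Builds a Delaunay triangulation of scattered `(x, y, z)` samples augmented
#' with periodic ghost images within `margin` of the box boundary, and
#' evaluates the piecewise-linear (barycentric) interpolant at query points.
#' Every query inside the primary cell is covered provided `margin` exceeds
#' the largest point spacing.
#'
#' @param x,y,z Sample coordinates; `x`, `y` are wrapped into the box.
#' @param lx,ly Periodic cell lengths (nm).
#' @param qx,qy Query coordinates (vectors of equal length), inside the cell.
#' @param margin Ghost-image margin (nm); default `2 * sqrt(lx * ly / n)`.
#' @return Numeric vector of interpolated `z` at the query points.
#' @export
periodic_linear_interp <- function(x, y, z, lx, ly, qx, qy, margin = NULL) {
  n <- length(x)
  stopifnot(length(y) == n, length(z) == n, length(qx) == length(qy))
  if (n < 3L) stop("periodic_linear_interp: need >= 3 points", call. = FALSE)
  if (is.null(margin)) margin <- 2 * sqrt(lx * ly / n)
  margin <- min(margin, lx, ly)
  sv <- svd(cbind(x - mean(x), y - mean(y)), nu = 0, nv = 0)$d
  if (sv[2] < 1e-9 * max(sv[1], 1)) {
    stop("periodic_linear_interp: points are collinear", call. = FALSE)
  }
  x <- x - lx * floor(x / lx)
  y <- y - ly * floor(y / ly)
  # ghost images: replicate points across each boundary they are close to
  gx <- x; gy <- y; gz <- z
  for (sx in c(-1, 0, 1)) for (sy in c(-1, 0, 1)) {
    if (sx == 0 && sy == 0) next
    xi <- x + sx * lx; yi <- y + sy * ly
    keep <- xi > -margin & xi < lx + margin & yi > -margin & yi < ly + margin
    if (any(keep)) {
      gx <- c(gx, xi[keep]); gy <- c(gy, yi[keep]); gz <- c(gz, z[keep])
    }
  }
  if (stats::sd(gx) < 1e-12 * lx || stats::sd(gy) < 1e-12 * ly) {
    stop("periodic_linear_interp: points are collinear", call. = FALSE)
  }
  tx <- degeneracy_jitter(gx, lx)
  ty <- degeneracy_jitter(gy, ly)
  tri <- delaunay_triangulation(tx, ty)
  interp_eval(tx, ty, gz, tri, qx, qy)
}

# evaluate barycentric linear interpolation; errors on uncovered queries
interp_eval <- function(x, y, z, tri, qx, qy) {
  nq <- length(qx)
  out <- rep(NA_real_, nq)
  # bin queries on a coarse grid, visit triangles and fill covered queries
  x1 <- x[tri[, 1]]; y1 <- y[tri[, 1]]
  x2 <- x[tri[, 2]]; y2 <- y[tri[, 2]]
  x3 <- x[tri[, 3]]; y3 <- y[tri[, 3]]
  det <- (y2 - y3) * (x1 - x3) + (x3 - x2) * (y1 - y3)
  ord <- order(qx)
  qxs <- qx[ord]
  eps <- 1e-9 * (max(x) - min(x) + 1)
  for (t in seq_len(nrow(tri))) {
    if (abs(det[t]) < 1e-300) next
    xmin <- min(x1[t], x2[t], x3[t]) - eps
    xmax <- max(x1[t], x2[t], x3[t]) + eps
    lo <- findInterval(xmin, qxs) + 1L
    hi <- findInterval(xmax, qxs)
    if (lo > hi) next
    cand <- ord[lo:hi]
    cand <- cand[is.na(out[cand])]
    if (!length(cand)) next
    l1 <- ((y2[t] - y3[t]) * (qx[cand] - x3[t]) +
           (x3[t] - x2[t]) * (qy[cand] - y3[t])) / det[t]
    l2 <- ((y3[t] - y1[t]) * (qx[cand] - x3[t]) +
           (x1[t] - x3[t]) * (qy[cand] - y3[t])) / det[t]
    l3 <- 1 - l1 - l2
    tol <- 1e-9
    inside <- l1 >= -tol & l2 >= -tol & l3 >= -tol
    if (any(inside)) {
      ci <- cand[inside]
      out[ci] <- l1[inside] * z[tri[t, 1]] + l2[inside] * z[tri[t, 2]] +
        l3[inside] * z[tri[t, 3]]
    }
  }
  if (anyNA(out)) {
    stop("interpolation hole: ", sum(is.na(out)),
         " query point(s) not covered; increase the ghost-image margin",
         call. = FALSE)
  }
  out
}
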