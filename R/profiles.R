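# Density and orientation profiles along the bilayer normal (the z axis),
# and radial distribution functions. The reaction coordinate xi is the
# signed z-distance from a bilayer midplane, negative toward the external
# solution.

bilayer_midplane <- function(surfaces, bilayer) {
  g <- surfaces$grids
  Lz <- surfaces$box[["lz"]]
  if (bilayer == 1L) {
    a <- mean(g[["b1_external"]]$heights); b <- mean(g[["b1_internal"]]$heights)
  } else {
    a <- mean(g[["b2_internal"]]$heights); b <- mean(g[["b2_external"]]$heights)
  }
  m <- a + periodic_offset(b, a, Lz) / 2
  m - Lz * floor(m / Lz)
}

# +1 if the external leaflet of the chosen bilayer lies above (+z of) the
# midplane, else -1: the sign s such that xi = -s * dz is negative external
external_direction <- function(surfaces, bilayer) {
  g <- surfaces$grids
  Lz <- surfaces$box[["lz"]]
  m <- bilayer_midplane(surfaces, bilayer)
  ext <- mean(g[[if (bilayer == 1L) "b1_external" else "b2_external"]]$heights)
  sign(periodic_offset(ext, m, Lz))
}

#' Signed reaction coordinate xi relative to a bilayer midplane
#'
#' `xi` is the periodic-minimum signed z-offset of a position from the
#' midplane of the chosen bilayer (mean of its two leaflet grid means),
#' with the sign fixed so that negative xi points toward the external
#' solution.
#'
#' @param positions Length-3 vector or n x 3 matrix (nm).
#' @param surfaces A `bilayer_surfaces`.
#' @param bilayer 1 or 2.
#' @return Numeric vector of xi (nm).
#' @export
xi_coordinate <- function(positions, surfaces, bilayer = 1L) {
  stopifnot(inherits(surfaces, "bilayer_surfaces"), bilayer %in% c(1L, 2L))
  p <- if (is.matrix(positions)) positions else matrix(positions, ncol = 3L,
                                                       byrow = TRUE)
  Lz <- surfaces$box[["lz"]]
  m <- bilayer_midplane(surfaces, bilayer)
  s <- external_direction(surfaces, bilayer)
  dz <- periodic_offset(p[, 3], m, Lz)
  -s * dz
}

#' Number-density profile along xi
#'
#' Bins the xi values of a group's reference sites per frame and normalizes
#' by the slab volume `Lx * Ly * bin_width` and the frame count, so that
#' `sum(values) * bin_volume` equals the mean per-frame site count.
#'
#' @param trajectory A `cg_trajectory`.
#' @param site_indices Either an integer vector of bead indices (applied to
#'   every frame) or a function `frame -> n x 3 matrix` of reference-site
#'   positions (e.g. per-molecule centroids).
#' @param surfaces_per_frame A single `bilayer_surfaces` (reused across
#'   frames) or a list, one per frame; or a function `frame ->
#'   bilayer_surfaces`.
#' @param bin_width Bin width, nm (default 0.05).
#' @param bilayer Which bilayer's midplane defines xi.
#' @param xi_range Profile extent (nm), default `c(-Lz/2, Lz/2)` clipped to
#'   whole bins.
#' @return An object of class `density_profile`: list with `xi`
#'   (bin centers), `density` (nm^-3), `counts`, `n_frames`, `bin_width`.
#' @export
density_profile <- function(trajectory, site_indices, surfaces_per_frame,
                            bin_width = 0.05, bilayer = 1L, xi_range = NULL) {
  stopifnot(bin_width > 0)
  if (inherits(trajectory, "cg_frame")) trajectory <- cg_trajectory(list(trajectory))
  box <- trajectory[[1]]$box
  Lz <- box[["lz"]]
  if (is.null(xi_range)) xi_range <- c(-Lz / 2, Lz / 2)
  edges <- seq(floor(xi_range[1] / bin_width) * bin_width,
               ceiling(xi_range[2] / bin_width) * bin_width, by = bin_width)
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  counts <- numeric(length(mids))
  nf <- 0L
  for (fi in seq_along(trajectory)) {
    fr <- trajectory[[fi]]
    surf <- resolve_surfaces(surfaces_per_frame, fr, fi)
    pos <- resolve_sites(site_indices, fr)
    if (!nrow(pos)) next
    xi <- xi_coordinate(pos, surf, bilayer)
    h <- graphics::hist(xi[xi >= edges[1] & xi <= edges[length(edges)]],
                        breaks = edges, plot = FALSE)
    counts <- counts + h$counts
    nf <- nf + 1L
  }
  if (nf == 0L) warning("density_profile: empty group; profile is all zero")
  nf <- max(nf, 1L)
  slab <- box[["lx"]] * box[["ly"]] * bin_width
  structure(list(xi = mids, density = counts / (nf * slab),
                 counts = counts, n_frames = nf, bin_width = bin_width),
            class = "density_profile")
}

resolve_surfaces <- function(spf, frame, i) {
  if (inherits(spf, "bilayer_surfaces")) return(spf)
  if (is.function(spf)) return(spf(frame))
  if (is.list(spf)) return(spf[[i]])
  stop("expected a bilayer_surfaces, a list of them, or a function",
       call. = FALSE)
}

resolve_sites <- function(sites, frame) {
  if (is.function(sites)) return(sites(frame))
  frame_positions(frame)[sites, , drop = FALSE]
}

#' Per-molecule centroids of a bead subset
#'
#' Centroid (center of geometry) of each molecule's beads among `idx`;
#' row names are the molecule ids.
#'
#' @param frame A `cg_frame`.
#' @param idx Integer bead indices (e.g. from [role_indices()]).
#' @return m x 3 matrix of centroids (nm).
#' @export
molecule_centroids <- function(frame, idx) {
  if (!length(idx)) return(matrix(numeric(), 0L, 3L))
  sp <- split(idx, frame$atoms$molecule_id[idx])
  pos <- frame_positions(frame)
  out <- t(vapply(sp, function(i) colMeans(pos[i, , drop = FALSE]),
                  numeric(3L)))
  rownames(out) <- names(sp)
  out
}

#' Cation orientation profile along xi
#'
#' For each cation, `cos(theta)` is the cosine of the angle between the
#' vector from its tail-site centroid to its head-site centroid and the
#' outward bilayer normal (+z flipped so that positive values mean the
#' head points away from the bilayer center). Values are binned by the
#' head-site xi and a trailing running mean of `smooth_window` bins is
#' applied to the reported profile (window 1 = no smoothing). Zero-count
#' bins are flagged `NA`, never interpolated.
#'
#' @param trajectory A `cg_trajectory`.
#' @param map A `role_map` resolving `cation_head` and `cation_tail` beads.
#' @param surfaces_per_frame As in [density_profile()].
#' @param bin_width Bin width along xi, nm (default 0.1).
#' @param smooth_window Running-mean window in bins (default 4).
#' @param bilayer Which bilayer's midplane defines xi.
#' @return An object of class `orientation_profile`: list with `xi`,
#'   `mean_cos_theta` (smoothed), `raw_mean_cos_theta`, `counts`,
#'   `n_skipped` (zero-length orientation vectors), `smooth_window`.
#' @export
orientation_profile <- function(trajectory, map, surfaces_per_frame,
                                bin_width = 0.1, smooth_window = 4,
                                bilayer = 1L) {
  stopifnot(bin_width > 0, smooth_window >= 1)
  if (inherits(trajectory, "cg_frame")) trajectory <- cg_trajectory(list(trajectory))
  Lz <- trajectory[[1]]$box[["lz"]]
  edges <- seq(-Lz / 2, Lz / 2 + bin_width, by = bin_width)
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  sums <- numeric(length(mids)); counts <- numeric(length(mids))
  skipped <- 0L
  for (fi in seq_along(trajectory)) {
    fr <- trajectory[[fi]]
    surf <- resolve_surfaces(surfaces_per_frame, fr, fi)
    heads <- molecule_centroids(fr, role_indices(fr, map, "cation_head"))
    tails <- molecule_centroids(fr, role_indices(fr, map, "cation_tail"))
    common <- intersect(rownames(heads), rownames(tails))
    if (!length(common)) next
    h <- heads[common, , drop = FALSE]
    t <- tails[common, , drop = FALSE]
    v <- min_image_disp(t, h, fr$box)        # tail centroid -> head centroid
    if (!is.matrix(v)) v <- matrix(v, ncol = 3L)
    vn <- sqrt(rowSums(v^2))
    ok <- vn > 1e-9
    skipped <- skipped + sum(!ok)
    if (!any(ok)) next
    xi <- xi_coordinate(h[ok, , drop = FALSE], surf, bilayer)
    # outward normal: sign of the periodic z-offset from the midplane
    m <- bilayer_midplane(surf, bilayer)
    dz <- periodic_offset(h[ok, 3], m, Lz)
    ct <- v[ok, 3] / vn[ok] * sign(dz)
    bin <- findInterval(xi, edges, rightmost.closed = TRUE)
    ok2 <- bin >= 1 & bin <= length(mids)
    for (b in unique(bin[ok2])) {
      sel <- ok2 & bin == b
      sums[b] <- sums[b] + sum(ct[sel])
      counts[b] <- counts[b] + sum(sel)
    }
  }
  raw <- ifelse(counts > 0, sums / counts, NA_real_)
  sm <- running_mean(raw, smooth_window)
  structure(list(xi = mids, mean_cos_theta = sm, raw_mean_cos_theta = raw,
                 counts = counts, n_skipped = skipped,
                 smooth_window = smooth_window),
            class = "orientation_profile")
}

#' Trailing running mean
#'
#' Mean of the current and previous `window - 1` values (shorter at the
#' start); `NA`s are dropped within each window, and windows with no data
#' stay `NA`.
#'
#' @param x Numeric vector.
#' @param window Window length in samples.
#' @return Numeric vector, same length.
#' @export
running_mean <- function(x, window) {
  window <- as.integer(window)
  if (window <= 1L) return(x)
  out <- rep(NA_real_, length(x))
  for (i in seq_along(x)) {
    w <- x[max(1L, i - window + 1L):i]
    if (any(!is.na(w))) out[i] <- mean(w, na.rm = TRUE)
  }
  out
}

#' Radial distribution function between two bead groups
#'
#' Minimum-image pair distances binned in shells of width `dr` and
#' normalized by the ideal-gas shell count `4 pi r^2 dr rho_B` per
#' reference site and frame. Self-pairs are excluded when the groups
#' overlap.
#'
#' @param trajectory A `cg_trajectory` (or single `cg_frame`).
#' @param group_a,group_b Integer bead indices of the two groups.
#' @param r_max Maximum distance, nm; must be <= half the smallest box
#'   edge.
#' @param dr Shell width, nm (default 0.01).
#' @return An object of class `rdf`: list with `r` (shell centers), `g`,
#'   `counts`, `dr`, `n_frames`.
#' @export
rdf <- function(trajectory, group_a, group_b, r_max, dr = 0.01) {
  stopifnot(dr > 0)
  if (inherits(trajectory, "cg_frame")) trajectory <- cg_trajectory(list(trajectory))
  box <- trajectory[[1]]$box
  if (r_max > min(unclass(box)) / 2 + 1e-9) {
    stop("rdf: r_max exceeds half the smallest box edge", call. = FALSE)
  }
  edges <- seq(0, r_max, by = dr)
  if (abs(edges[length(edges)] - r_max) > 1e-12) edges <- c(edges, r_max)
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  counts <- numeric(length(mids))
  nf <- length(trajectory)
  na <- length(group_a); nb <- length(group_b)
  overlap <- length(intersect(group_a, group_b)) > 0
  for (fr in trajectory) {
    pos <- frame_positions(fr)
    pa <- pos[group_a, , drop = FALSE]
    pb <- pos[group_b, , drop = FALSE]
    d <- cross_distances(pa, pb, fr$box)
    if (overlap) {
      same <- outer(group_a, group_b, `==`)
      d[same] <- NA_real_
    }
    dv <- d[!is.na(d) & d <= r_max & d > 0]
    h <- graphics::hist(dv, breaks = edges, plot = FALSE)
    counts <- counts + h$counts
  }
  V <- box_volume(box)
  nb_eff <- if (overlap) nb - 1 else nb
  rho_b <- nb_eff / V
  shell <- 4 * pi * mids^2 * dr
  g <- counts / (nf * na * shell * rho_b)
  structure(list(r = mids, g = g, counts = counts, dr = dr, n_frames = nf),
            class = "rdf")
}

#' Minimum-image distance matrix between two point sets
#'
#' @param a,b n x 3 and m x 3 position matrices (nm).
#' @param box A `sim_box`.
#' @return n x m matrix of minimum-image distances.
#' @export
cross_distances <- function(a, b, box) {
  L <- unclass(as_sim_box(box))
  d2 <- matrix(0, nrow(a), nrow(b))
  for (k in 1:3) {
    dk <- outer(a[, k], b[, k], `-`)
    dk <- dk - L[k] * round(dk / L[k])
    d2 <- d2 + dk^2
  }
  sqrt(d2)
}

#' First minimum of a radial distribution function
#'
#' Locates the first local minimum following the first prominent local
#' maximum of `g(r)` (the first coordination-shell peak), optionally after a
#' centered 3-bin running-mean smoothing, and returns its position as the
#' suggested contact cutoff. Prominence guards against noise wiggles in the
#' excluded-volume region: the peak must reach at least `prominence` times
#' the global maximum of `g`.
#'
#' @param x An `rdf` (>= 5 bins).
#' @param smooth Apply 3-bin smoothing before the search (default TRUE).
#' @param prominence Minimum height of the first peak relative to
#'   `max(g)` (default 0.5).
#' @return Position of the first minimum, nm.
#' @export
first_minimum <- function(x, smooth = TRUE, prominence = 0.5) {
  stopifnot(inherits(x, "rdf"))
  g <- x$g; r <- x$r
  if (length(g) < 5L) stop("first_minimum: need >= 5 bins", call. = FALSE)
  if (smooth) {
    g <- stats::filter(g, rep(1 / 3, 3), sides = 2)
    g[1] <- x$g[1]; g[length(g)] <- x$g[length(g)]
    g <- as.numeric(g)
  }
  n <- length(g)
  ipeak <- NA_integer_
  gmin <- prominence * max(g)
  for (i in 2:(n - 1)) {
    if (g[i] > g[i - 1] && g[i] >= g[i + 1] && g[i] >= gmin) {
      ipeak <- i; break
    }
  }
  if (is.na(ipeak)) stop("first_minimum: g(r) has no interior maximum",
                         call. = FALSE)
  for (i in (ipeak + 1L):(n - 1L)) {
    if (g[i] < g[i - 1] && g[i] <= g[i + 1]) return(r[i])
  }
  stop("first_minimum: no local minimum after the first peak", call. = FALSE)
}

#' Write a profile as two/three-column delimited text
#'
#' @param x A `density_profile`, `orientation_profile` or `rdf`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (inherits(x, "density_profile")) {
    writeLines(c("# memscope density profile",
                 sprintf("# n_frames= %d bin_width= %g nm", x$n_frames,
                         x$bin_width),
                 "# xi_nm\tdensity_nm3"), con)
    utils::write.table(data.frame(x$xi, x$density), con, sep = "\t",
                       row.names = FALSE, col.names = FALSE, quote = FALSE)
  } else if (inherits(x, "orientation_profile")) {
    writeLines(c("# memscope orientation profile",
                 sprintf("# smooth_window= %d", x$smooth_window),
                 "# xi_nm\tmean_cos_theta\tcount"), con)
    utils::write.table(data.frame(x$xi, x$mean_cos_theta, x$counts), con,
                       sep = "\t", row.names = FALSE, col.names = FALSE,
                       quote = FALSE)
  } else if (inherits(x, "rdf")) {
    writeLines(c("# memscope radial distribution function",
                 sprintf("# dr= %g nm n_frames= %d", x$dr, x$n_frames),
                 "# r_nm\tg_r"), con)
    utils::write.table(data.frame(x$r, x$g), con, sep = "\t",
                       row.names = FALSE, col.names = FALSE, quote = FALSE)
  } else stop("write_profile: unsupported object", call. = FALSE)
  invisible(path)
}
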