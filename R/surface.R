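#' Periodic leaflet height field
#'
#' A `leaflet_grid` stores a single-valued height field z(x, y) sampled on a
#' regular nx x ny grid over the periodic box cross-section. Grid nodes sit
#' at `x_i = (i-1) Lx / nx`, `y_j = (j-1) Ly / ny` (the last row/column
#' wraps onto the first).
#'
#' @param heights nx x ny numeric matrix of heights (nm).
#' @param box A `sim_box`.
#' @param label Leaflet label, one of `"b1_external"`, `"b1_internal"`,
#'   `"b2_internal"`, `"b2_external"` (or `""` for free-standing grids).
#' @return An object of class `leaflet_grid`.
#' @export
leaflet_grid <- function(heights, box, label = "") {
  stopifnot(is.matrix(heights), all(is.finite(heights)))
  structure(list(heights = heights, box = as_sim_box(box), label = label,
                 nx = nrow(heights), ny = ncol(heights)),
            class = "leaflet_grid")
}

#' @export
print.leaflet_grid <- function(x, ...) {
  cat(sprintf("<leaflet_grid> %s %d x %d, mean height %.3f nm\n",
              if (nzchar(x$label)) x$label else "(unlabelled)",
              x$nx, x$ny, mean(x$heights)))
  invisible(x)
}

#' Interpolate scattered leaflet points into a periodic height grid
#'
#' Builds a piecewise-linear interpolant of phosphate positions (Delaunay
#' triangulation with periodic ghost images) and samples it on a regular
#' grid. The default resolution is `ceiling(sqrt(2 n))` capped at 128,
#' about two grid nodes per data point; the default ghost margin
#' `2 sqrt(Lx Ly / n)` guarantees coverage for quasi-uniform points.
#'
#' @param points n x 3 matrix (or data.frame with x, y, z) of bead
#'   positions (nm); at least 3 non-collinear points.
#' @param box A `sim_box`.
#' @param nx,ny Grid resolution; defaults as above.
#' @param margin Ghost-image margin (nm).
#' @param label Passed to [leaflet_grid()].
#' @return A `leaflet_grid`.
#' @export
build_leaflet_grid <- function(points, box, nx = NULL, ny = NULL,
                               margin = NULL, label = "") {
  box <- as_sim_box(box)
  p <- as.matrix(as.data.frame(points)[, 1:3])
  n <- nrow(p)
  if (n < 3L) stop("build_leaflet_grid: need >= 3 points", call. = FALSE)
  if (is.null(nx)) nx <- min(128L, ceiling(sqrt(2 * n)))
  if (is.null(ny)) ny <- nx
  gx <- (seq_len(nx) - 1) * box[["lx"]] / nx
  gy <- (seq_len(ny) - 1) * box[["ly"]] / ny
  q <- expand.grid(x = gx, y = gy)   # column-major: x varies fastest
  # heights may straddle the periodic z boundary; interpolate offsets about
  # a circular-mean reference so the field is smooth
  zref <- p[1, 3]
  dz <- periodic_offset(p[, 3], zref, box[["lz"]])
  zi <- periodic_linear_interp(p[, 1], p[, 2], zref + dz,
                               box[["lx"]], box[["ly"]], q$x, q$y,
                               margin = margin)
  leaflet_grid(matrix(zi, nrow = nx, ncol = ny), box, label)
}

#' Surface area of a periodic height field
#'
#' Sums the areas of the `2 nx ny` triangles tiling the periodic height
#' field (each grid cell split along its diagonal). Always >= `Lx * Ly`,
#' with equality for a flat field.
#'
#' @param grid A `leaflet_grid`.
#' @return Surface area in nm^2.
#' @export
surface_area <- function(grid) {
  stopifnot(inherits(grid, "leaflet_grid"))
  h <- grid$heights
  nx <- grid$nx; ny <- grid$ny
  dx <- grid$box[["lx"]] / nx
  dy <- grid$box[["ly"]] / ny
  ip <- c(seq_len(nx)[-1], 1L)       # wrapped i+1
  jp <- c(seq_len(ny)[-1], 1L)
  z00 <- h
  z10 <- h[ip, , drop = FALSE]
  z01 <- h[, jp, drop = FALSE]
  z11 <- h[ip, jp, drop = FALSE]
  # triangles (00,10,11) and (00,11,01); cross products have constant xy parts
  a1 <- 0.5 * sqrt((dy * (z00 - z10))^2 + (dx * (z10 - z11))^2 + (dx * dy)^2)
  a2 <- 0.5 * sqrt((dy * (z01 - z11))^2 + (dx * (z00 - z01))^2 + (dx * dy)^2)
  sum(a1) + sum(a2)
}

#' Mean bilayer thickness from two leaflet grids
#'
#' Node-wise vertical (z) separation between the two leaflets, taken modulo
#' the box height (periodic minimum), averaged over grid nodes. This is the
#' vertical-distance convention; surface-normal distance is not used.
#'
#' @param grid_upper,grid_lower `leaflet_grid`s sharing resolution and box.
#' @return Mean thickness in nm.
#' @export
bilayer_thickness <- function(grid_upper, grid_lower) {
  stopifnot(inherits(grid_upper, "leaflet_grid"),
            inherits(grid_lower, "leaflet_grid"))
  if (grid_upper$nx != grid_lower$nx || grid_upper$ny != grid_lower$ny ||
      !isTRUE(all.equal(unclass(grid_upper$box), unclass(grid_lower$box)))) {
    stop("bilayer_thickness: grids must share resolution and box",
         call. = FALSE)
  }
  L <- grid_upper$box[["lz"]]
  d <- abs(periodic_offset(grid_upper$heights, grid_lower$heights, L))
  mean(d)
}

#' Partition phosphate beads into the four leaflets of a two-bilayer stack
#'
#' Sorts phosphate z-coordinates and cuts the circular (periodic) sequence
#' at the four largest gaps. The gap containing `external_z` is taken as the
#' external aqueous compartment; going +z from it the leaflets are labelled
#' `b1_external`, `b1_internal`, `b2_internal`, `b2_external`.
#'
#' @param frame A `cg_frame` with two stacked bilayers.
#' @param map A `role_map` resolving the phosphate beads.
#' @param external_z A z-coordinate (nm) known to lie in the external
#'   solution; default 0 (the box face).
#' @param gap_ratio Separability guard: the 4th largest gap must exceed
#'   `gap_ratio` times the 5th largest, otherwise the leaflets are not
#'   separable and an error with gap diagnostics is raised.
#' @return A list with `groups` (list of 4 integer vectors of bead indices,
#'   labelled), `labels`, and `gaps` (diagnostic: the sorted circular gaps).
#' @export
assign_leaflets <- function(frame, map, external_z = 0, gap_ratio = 2) {
  idx <- role_indices(frame, map, "phosphate")
  if (length(idx) < 12L) {
    stop("assign_leaflets: need >= 3 phosphates per leaflet (found ",
         length(idx), " total)", call. = FALSE)
  }
  Lz <- frame$box[["lz"]]
  z <- frame$atoms$z[idx]
  z <- z - Lz * floor(z / Lz)
  ord <- order(z)
  zs <- z[ord]
  nz <- length(zs)
  gaps <- c(diff(zs), zs[1] + Lz - zs[nz])   # gap i follows sorted point i
  gord <- order(gaps, decreasing = TRUE)
  if (gaps[gord[4]] < gap_ratio * gaps[gord[5]]) {
    stop(sprintf(paste0("assign_leaflets: cannot separate 4 leaflets: ",
                        "4th gap %.4f vs 5th gap %.4f nm ",
                        "(largest gaps: %s)"),
                 gaps[gord[4]], gaps[gord[5]],
                 paste(sprintf("%.3f", gaps[gord[1:6]]), collapse = ", ")),
         call. = FALSE)
  }
  cuts <- sort(gord[1:4])   # sorted indices after which a big gap opens
  # group g: sorted points (cuts[g-1]+1) .. cuts[g], circularly
  grp <- rep(NA_integer_, nz)
  bounds <- c(0L, cuts)
  for (g in 1:4) grp[(bounds[g] + 1L):bounds[g + 1L]] <- g
  # remaining points after cuts[4] wrap into group 1
  if (bounds[5] < nz) grp[(bounds[5] + 1L):nz] <- 1L
  # identify the gap holding external_z
  ez <- external_z - Lz * floor(external_z / Lz)
  gap_lo <- zs[gord[1:4]]
  gap_hi <- gap_lo + gaps[gord[1:4]]
  inside <- (ez >= gap_lo & ez <= gap_hi) |
    (ez + Lz >= gap_lo & ez + Lz <= gap_hi)
  if (!any(inside)) {
    stop("assign_leaflets: external_z = ", external_z,
         " does not fall in any inter-leaflet gap", call. = FALSE)
  }
  ext_gap_cut <- gord[1:4][which(inside)[1]]   # sorted-point index before gap
  # the group that STARTS just above the external gap
  first_group <- grp[if (ext_gap_cut == nz) 1L else ext_gap_cut + 1L]
  labels <- c("b1_external", "b1_internal", "b2_internal", "b2_external")
  groups <- vector("list", 4L)
  for (k in 1:4) {
    g <- ((first_group - 1L + k - 1L) %% 4L) + 1L
    groups[[k]] <- idx[ord[grp == g]]
  }
  names(groups) <- labels
  sizes <- lengths(groups)
  if (any(sizes < 3L)) {
    stop("assign_leaflets: leaflet group with < 3 phosphates (sizes: ",
         paste(sizes, collapse = ", "), ")", call. = FALSE)
  }
  list(groups = groups, labels = labels, gaps = sort(gaps, decreasing = TRUE),
       sizes = sizes)
}

#' Build the four leaflet surfaces and compartment volumes of a frame
#'
#' Runs [assign_leaflets()], interpolates each leaflet into a
#' [leaflet_grid()] (all four at a common resolution), and computes the four
#' compartment volumes. Column-wise, the four heights cut the periodic
#' z-extent into bilayer1, internal, bilayer2 and external slabs whose
#' volumes sum to the box volume exactly.
#'
#' @inheritParams assign_leaflets
#' @param nx,ny Common grid resolution (default from the smallest leaflet).
#' @param margin Ghost-image margin for the interpolation.
#' @return An object of class `bilayer_surfaces`: list with `grids` (named
#'   list of four `leaflet_grid`s, +z order from the external gap),
#'   `volumes` (named: external, bilayer1, internal, bilayer2, nm^3),
#'   `box`, and `assignment`.
#' @export
build_bilayer_surfaces <- function(frame, map, nx = NULL, ny = NULL,
                                   external_z = 0, margin = NULL,
                                   gap_ratio = 2) {
  asg <- assign_leaflets(frame, map, external_z = external_z,
                         gap_ratio = gap_ratio)
  nmin <- min(lengths(asg$groups))
  if (is.null(nx)) nx <- min(128L, ceiling(sqrt(2 * nmin)))
  if (is.null(ny)) ny <- nx
  grids <- lapply(names(asg$groups), function(lab) {
    i <- asg$groups[[lab]]
    build_leaflet_grid(frame$atoms[i, c("x", "y", "z")], frame$box,
                       nx = nx, ny = ny, margin = margin, label = lab)
  })
  names(grids) <- names(asg$groups)
  surf <- structure(list(grids = grids, box = frame$box, assignment = asg),
                    class = "bilayer_surfaces")
  surf$volumes <- compartment_volumes(surf)
  surf
}

#' @export
print.bilayer_surfaces <- function(x, ...) {
  cat("<bilayer_surfaces>", x$grids[[1]]$nx, "x", x$grids[[1]]$ny, "grids\n")
  v <- x$volumes
  cat(sprintf("  volumes (nm^3): external %.1f | bilayer1 %.1f | internal %.1f | bilayer2 %.1f\n",
              v[["external"]], v[["bilayer1"]], v[["internal"]], v[["bilayer2"]]))
  invisible(x)
}

# column heights of the 4 grids, circularly unwrapped so that the mean
# heights satisfy m1 < m2 < m3 < m4 < m1 + Lz (+z order from the external
# gap). Each grid's height field is already continuous by construction, so
# whole grids are shifted by multiples of Lz.
ordered_column_heights <- function(surfaces) {
  g <- surfaces$grids
  Lz <- surfaces$box[["lz"]]
  h <- vector("list", 4L)
  h[[1]] <- g[[1]]$heights
  ref <- mean(h[[1]])
  for (k in 2:4) {
    mk <- mean(g[[k]]$heights)
    shift <- (mk - ref) %% Lz            # in [0, Lz)
    h[[k]] <- g[[k]]$heights - mk + (ref + shift)
    ref <- ref + shift
  }
  h
}

#' Compartment volumes from a four-leaflet surface stack
#'
#' @param surfaces A `bilayer_surfaces`.
#' @return Named numeric vector of volumes (nm^3): `external`, `bilayer1`,
#'   `internal`, `bilayer2`; they sum to the box volume.
#' @export
compartment_volumes <- function(surfaces) {
  stopifnot(inherits(surfaces, "bilayer_surfaces"))
  h <- ordered_column_heights(surfaces)
  Lz <- surfaces$box[["lz"]]
  nx <- surfaces$grids[[1]]$nx; ny <- surfaces$grids[[1]]$ny
  cell <- surfaces$box[["lx"]] * surfaces$box[["ly"]] / (nx * ny)
  l1 <- h[[2]] - h[[1]]          # bilayer1
  l2 <- h[[3]] - h[[2]]          # internal
  l3 <- h[[4]] - h[[3]]          # bilayer2
  l4 <- Lz - (l1 + l2 + l3)      # external (wrap-around remainder)
  for (nm in list(list(l1, "bilayer1"), list(l2, "internal"),
                  list(l3, "bilayer2"), list(l4, "external"))) {
    if (any(nm[[1]] < 0)) {
      bad <- which(nm[[1]] < 0, arr.ind = TRUE)[1, ]
      stop(sprintf("compartment_volumes: surfaces cross in compartment %s at grid column (%d, %d)",
                   nm[[2]], bad[1], bad[2]), call. = FALSE)
    }
  }
  c(external = sum(l4) * cell, bilayer1 = sum(l1) * cell,
    internal = sum(l2) * cell, bilayer2 = sum(l3) * cell)
}

# bilinear interpolation of a periodic grid at arbitrary (x, y); vectorized
bilinear_at <- function(grid, x, y) {
  nx <- grid$nx; ny <- grid$ny
  lx <- grid$box[["lx"]]; ly <- grid$box[["ly"]]
  fx <- (x - lx * floor(x / lx)) / (lx / nx)
  fy <- (y - ly * floor(y / ly)) / (ly / ny)
  i0 <- floor(fx); j0 <- floor(fy)
  tx <- fx - i0; ty <- fy - j0
  i0 <- (as.integer(i0) %% nx) + 1L
  j0 <- (as.integer(j0) %% ny) + 1L
  i1 <- (i0 %% nx) + 1L
  j1 <- (j0 %% ny) + 1L
  h <- grid$heights
  # heights may straddle the z boundary: interpolate offsets about h[i0,j0]
  base <- h[cbind(i0, j0)]
  L <- grid$box[["lz"]]
  d10 <- periodic_offset(h[cbind(i1, j0)], base, L)
  d01 <- periodic_offset(h[cbind(i0, j1)], base, L)
  d11 <- periodic_offset(h[cbind(i1, j1)], base, L)
  base + (1 - tx) * (1 - ty) * 0 + tx * (1 - ty) * d10 +
    (1 - tx) * ty * d01 + tx * ty * d11
}

#' Locate positions among the four compartments
#'
#' For each position, the four leaflet heights are bilinearly interpolated
#' at its (x, y) and the z-interval containing the position (periodic in z)
#' names its compartment.
#'
#' @param positions Length-3 vector or n x 3 matrix of positions (nm).
#' @param surfaces A `bilayer_surfaces`.
#' @return Character vector of labels in
#'   `{external, bilayer1, internal, bilayer2}`.
#' @export
locate_compartment <- function(positions, surfaces) {
  stopifnot(inherits(surfaces, "bilayer_surfaces"))
  p <- if (is.matrix(positions)) positions else matrix(positions, ncol = 3L,
                                                       byrow = TRUE)
  Lz <- surfaces$box[["lz"]]
  hcol <- ordered_column_heights(surfaces)
  # interpolate each ordered sheet at the query (x, y)
  hs <- lapply(1:4, function(k) {
    g <- surfaces$grids[[k]]
    gk <- leaflet_grid(hcol[[k]], surfaces$box, g$label)
    bilinear_at(gk, p[, 1], p[, 2])
  })
  z <- p[, 3]
  zz <- hs[[1]] + (z - hs[[1]]) %% Lz     # fold into [h1, h1 + Lz)
  out <- rep("external", nrow(p))
  out[zz < hs[[2]]] <- "bilayer1"
  out[zz >= hs[[2]] & zz < hs[[3]]] <- "internal"
  out[zz >= hs[[3]] & zz < hs[[4]]] <- "bilayer2"
  out
}

#' Per-lipid morphology metrics
#'
#' Divides leaflet surface areas by per-leaflet lipid counts and bilayer
#' slab volumes by per-bilayer lipid counts.
#'
#' @param surfaces A `bilayer_surfaces`.
#' @param n_per_leaflet Lipid counts per leaflet: scalar or named vector
#'   over `b1_external`, `b1_internal`, `b2_internal`, `b2_external`.
#' @param n_per_bilayer Lipid counts per bilayer: scalar or named vector
#'   over `bilayer1`, `bilayer2`.
#' @return List with `area_per_lipid` (nm^2, one per leaflet side) and
#'   `volume_per_lipid` (nm^3, one per bilayer).
#' @export
per_lipid_metrics <- function(surfaces, n_per_leaflet, n_per_bilayer) {
  stopifnot(inherits(surfaces, "bilayer_surfaces"))
  labs <- names(surfaces$grids)
  if (length(n_per_leaflet) == 1L) {
    n_per_leaflet <- stats::setNames(rep(n_per_leaflet, 4L), labs)
  }
  if (length(n_per_bilayer) == 1L) {
    n_per_bilayer <- stats::setNames(rep(n_per_bilayer, 2L),
                                     c("bilayer1", "bilayer2"))
  }
  if (any(n_per_leaflet <= 0) || any(n_per_bilayer <= 0)) {
    stop("per_lipid_metrics: lipid counts must be > 0", call. = FALSE)
  }
  areas <- vapply(surfaces$grids, surface_area, 0)
  vols <- surfaces$volumes
  list(area_per_lipid = areas / n_per_leaflet[labs],
       volume_per_lipid = c(
         bilayer1 = unname(vols[["bilayer1"]] / n_per_bilayer[["bilayer1"]]),
         bilayer2 = unname(vols[["bilayer2"]] / n_per_bilayer[["bilayer2"]])))
}

#' Write morphology metrics for a trajectory as a delimited table
#'
#' One row per frame: time, leaflet areas, compartment volumes, bilayer
#' thicknesses. Columns are documented in a `#`-prefixed header.
#'
#' @param trajectory A `cg_trajectory`.
#' @param map A `role_map`.
#' @param path Output TSV path (optional).
#' @param ... Passed to [build_bilayer_surfaces()].
#' @return Data frame of per-frame metrics (invisibly written to `path`
#'   when given).
#' @export
morphology_table <- function(trajectory, map, path = NULL, ...) {
  rows <- lapply(trajectory, function(fr) {
    s <- build_bilayer_surfaces(fr, map, ...)
    a <- vapply(s$grids, surface_area, 0)
    th1 <- bilayer_thickness(s$grids[["b1_internal"]], s$grids[["b1_external"]])
    th2 <- bilayer_thickness(s$grids[["b2_external"]], s$grids[["b2_internal"]])
    data.frame(time = fr$time,
               area_b1_external = a[["b1_external"]],
               area_b1_internal = a[["b1_internal"]],
               area_b2_internal = a[["b2_internal"]],
               area_b2_external = a[["b2_external"]],
               vol_external = s$volumes[["external"]],
               vol_bilayer1 = s$volumes[["bilayer1"]],
               vol_internal = s$volumes[["internal"]],
               vol_bilayer2 = s$volumes[["bilayer2"]],
               thickness_b1 = th1, thickness_b2 = th2)
  })
  out <- do.call(rbind, rows)
  if (!is.null(path)) {
    con <- file(path, "w")
    writeLines(c("# memscope morphology table (nm, nm^2, nm^3, ps)",
                 paste0("# ", paste(names(out), collapse = "\t"))), con)
    utils::write.table(out, con, sep = "\t", row.names = FALSE,
                       col.names = FALSE, quote = FALSE)
    close(con)
  }
  invisible(out)
}
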