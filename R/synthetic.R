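# Synthetic configurations with known ground truth: bilayer stacks, ion
# placements, Brownian walkers and umbrella-biased samples. These exist so
# every analysis stage can be validated without running MD; no force field
# is evaluated anywhere.

#' Specification of one synthetic bilayer
#'
#' @param n_lipids_per_leaflet Lipid count per leaflet.
#' @param area_per_lipid Area per lipid, nm^2.
#' @param thickness Phosphate-to-phosphate distance, nm.
#' @param z_center Height of the bilayer midplane, nm.
#' @param undulation_amplitude Amplitude A of the leaflet undulation, nm.
#' @param undulation_periods Integer pair (px, py): full undulation periods
#'   along x and y, so the surface is exactly box-periodic. The surface
#'   term is `A sin(2 pi px x / Lx)` when `py = 0`, and
#'   `A sin(2 pi px x / Lx) cos(2 pi py y / Ly)` otherwise. Both leaflets
#'   of a bilayer share the undulation (parallel sheets).
#' @return An object of class `bilayer_spec`.
#' @export
bilayer_spec <- function(n_lipids_per_leaflet, area_per_lipid = 0.64,
                         thickness = 4.0, z_center,
                         undulation_amplitude = 0,
                         undulation_periods = c(1L, 0L)) {
  stopifnot(n_lipids_per_leaflet >= 4, area_per_lipid > 0, thickness > 0,
            undulation_amplitude >= 0, length(undulation_periods) == 2L)
  structure(list(n = as.integer(n_lipids_per_leaflet),
                 apl = area_per_lipid, thickness = thickness,
                 z_center = z_center, amp = undulation_amplitude,
                 periods = as.integer(undulation_periods)),
            class = "bilayer_spec")
}

undulation_height <- function(spec, x, y, lx, ly) {
  if (spec$amp == 0) return(rep(0, length(x)))
  u <- spec$amp * sin(2 * pi * spec$periods[1] * x / lx)
  if (spec$periods[2] > 0) u <- u * cos(2 * pi * spec$periods[2] * y / ly)
  u
}

# lay n points on a jittered nx x ny lattice covering the box cross-section
lattice_xy <- function(n, lx, ly, jitter_xy = 0) {
  nx <- max(2L, round(sqrt(n * lx / ly)))
  ny <- ceiling(n / nx)
  g <- expand.grid(i = seq_len(nx) - 1L, j = seq_len(ny) - 1L)[seq_len(n), ]
  x <- (g$i + 0.5) * lx / nx
  y <- (g$j + 0.5) * ly / ny
  if (jitter_xy > 0) {
    x <- x + stats::runif(n, -jitter_xy, jitter_xy)
    y <- y + stats::runif(n, -jitter_xy, jitter_xy)
  }
  cbind(x = x %% lx, y = y %% ly)
}

# one DPPC-like coarse lipid: PO4 head bead + two 4-bead tails pointing
# toward the bilayer midplane (direction = -1 for upper leaflet, +1 lower)
lipid_beads <- function(x, y, zp, direction, mol_id) {
  tails <- expand.grid(t = 1:4, chain = c("A", "B"))
  zt <- zp + direction * (0.25 + 0.35 * tails$t)
  xt <- x + ifelse(tails$chain == "A", -0.15, 0.15)
  data.frame(molecule_id = mol_id, residue_name = "DPPC",
             bead_name = c("PO4", paste0("C", tails$t, tails$chain)),
             x = c(x, xt), y = c(y, rep(y, 8L)), z = c(zp, zt))
}

#' Generate a two-bilayer stack with aqueous compartments
#'
#' Builds two DPPC-like bilayers in an orthorhombic periodic box: four
#' phosphate sheets at `z_center +/- thickness / 2` plus the undulation
#' term, each lipid carrying one phosphate bead and two 4-bead tails
#' pointing toward its bilayer midplane. Water beads fill the external and
#' internal aqueous compartments on a jittered lattice and never fall
#' inside a bilayer slab. The external compartment is the one spanning the
#' periodic z-boundary (z = 0).
#'
#' @param spec1,spec2 `bilayer_spec`s of the lower (bilayer 1) and upper
#'   (bilayer 2) bilayer; lipid lattices must fit the box cross-section at
#'   the given area per lipid within 1%.
#' @param box A `sim_box`.
#' @param seed Integer seed; the frame is bit-reproducible given it.
#' @param z_jitter Gaussian jitter (sd, nm) added to phosphate heights.
#' @param xy_jitter Uniform half-width (nm) of lipid lattice jitter.
#' @param water_spacing Water lattice spacing, nm (larger = fewer waters;
#'   waters exist to exercise selection/compartment logic only).
#' @param water_margin Clearance (nm) between water and phosphate sheets.
#' @return An object of class `cg_system`: list with `frame` (a
#'   [cg_frame()]) and `truth`, a sidecar list holding construction labels
#'   (`leaflets`: data.frame bead index / molecule / leaflet label;
#'   `water`: data.frame molecule / compartment; `ions` added by
#'   [place_ions()]).
#' @export
generate_two_bilayer_system <- function(spec1, spec2, box, seed = 1,
                                        z_jitter = 0, xy_jitter = 0,
                                        water_spacing = 1.2,
                                        water_margin = 0.45) {
  box <- as_sim_box(box)
  lx <- box[["lx"]]; ly <- box[["ly"]]; lz <- box[["lz"]]
  for (sp in list(spec1, spec2)) {
    if (abs(sp$n * sp$apl - lx * ly) > 0.01 * lx * ly) {
      stop(sprintf(paste0("generate_two_bilayer_system: lattice does not fit: ",
                          "n * apl = %.2f nm^2 vs Lx * Ly = %.2f nm^2"),
                   sp$n * sp$apl, lx * ly), call. = FALSE)
    }
  }
  set.seed(seed)
  atoms <- list(); leaf_rows <- list()
  mol <- 0L; bead_at <- 0L
  for (b in 1:2) {
    sp <- if (b == 1L) spec1 else spec2
    for (side in c("lower", "upper")) {
      xy <- lattice_xy(sp$n, lx, ly, xy_jitter)
      sgn <- if (side == "lower") -1 else 1
      zp <- sp$z_center + sgn * sp$thickness / 2 +
        undulation_height(sp, xy[, 1], xy[, 2], lx, ly)
      if (z_jitter > 0) zp <- zp + stats::rnorm(sp$n, 0, z_jitter)
      lab <- if (b == 1L) {
        if (side == "lower") "b1_external" else "b1_internal"
      } else {
        if (side == "lower") "b2_internal" else "b2_external"
      }
      for (i in seq_len(sp$n)) {
        mol <- mol + 1L
        atoms[[length(atoms) + 1L]] <-
          lipid_beads(xy[i, 1], xy[i, 2], zp[i], -sgn, mol)
        leaf_rows[[length(leaf_rows) + 1L]] <-
          data.frame(bead = bead_at + 1L, molecule_id = mol, leaflet = lab)
        bead_at <- bead_at + 9L
      }
    }
  }
  # aqueous compartments along z (external wraps across z = 0)
  top1 <- spec1$z_center + spec1$thickness / 2 + spec1$amp
  bot1 <- spec1$z_center - spec1$thickness / 2 - spec1$amp
  top2 <- spec2$z_center + spec2$thickness / 2 + spec2$amp
  bot2 <- spec2$z_center - spec2$thickness / 2 - spec2$amp
  zones <- list(
    internal = c(top1 + water_margin, bot2 - water_margin),
    external = c(top2 + water_margin, bot1 + lz - water_margin))
  water_rows <- list()
  for (zone in names(zones)) {
    zr <- zones[[zone]]
    depth <- zr[2] - zr[1]
    if (depth <= 0) next
    nzl <- max(1L, floor(depth / water_spacing))
    nxl <- max(1L, floor(lx / water_spacing))
    nyl <- max(1L, floor(ly / water_spacing))
    g <- expand.grid(i = seq_len(nxl), j = seq_len(nyl), k = seq_len(nzl))
    jit <- water_spacing * 0.12
    wx <- ((g$i - 0.5) * lx / nxl + stats::runif(nrow(g), -jit, jit)) %% lx
    wy <- ((g$j - 0.5) * ly / nyl + stats::runif(nrow(g), -jit, jit)) %% ly
    wz <- zr[1] + (g$k - 0.5) * depth / nzl +
      stats::runif(nrow(g), -min(jit, depth / (4 * nzl)),
                   min(jit, depth / (4 * nzl)))
    ids <- mol + seq_len(nrow(g))
    atoms[[length(atoms) + 1L]] <- data.frame(
      molecule_id = ids, residue_name = "W", bead_name = "W",
      x = wx, y = wy, z = wz %% lz)
    water_rows[[length(water_rows) + 1L]] <-
      data.frame(molecule_id = ids, compartment = zone)
    mol <- mol + nrow(g)
  }
  at <- do.call(rbind, atoms)
  at$x <- at$x %% lx; at$y <- at$y %% ly; at$z <- at$z %% lz
  frame <- cg_frame(at, box, time = 0)
  structure(list(
    frame = frame,
    spec = list(bilayer1 = spec1, bilayer2 = spec2),
    truth = list(leaflets = do.call(rbind, leaf_rows),
                 water = if (length(water_rows)) do.call(rbind, water_rows)
                         else data.frame(molecule_id = integer(),
                                         compartment = character()),
                 ions = NULL)),
    class = "cg_system")
}

#' @export
print.cg_system <- function(x, ...) {
  cat("<cg_system>\n  ")
  print(x$frame)
  if (!is.null(x$truth$ions) && nrow(x$truth$ions)) {
    cat("  ions:", nrow(x$truth$ions), "molecules (",
        paste(unique(x$truth$ions$mode), collapse = ", "), ")\n")
  }
  invisible(x)
}

#' Ion placement specification
#'
#' @param n_pairs Number of cation/anion pairs.
#' @param mode Placement regime: `dispersed_external` (isolated cations in
#'   the external solution, pairwise molecule separations > 1 nm),
#'   `internal_solution` (same, internal compartment), `micelle` (compact
#'   cluster in the external solution), `interfacial` (cations layered on
#'   the external leaflet surface of bilayer 1), `core_droplet` (compact
#'   cluster centered on the bilayer-1 midplane).
#' @param cluster_radius Cluster radius (nm) for `micelle` / `core_droplet`.
#' @param n_tail_beads Cation tail length in beads.
#' @return An object of class `ion_placement`.
#' @export
ion_placement <- function(n_pairs,
                          mode = c("dispersed_external", "micelle",
                                   "interfacial", "core_droplet",
                                   "internal_solution"),
                          cluster_radius = 2, n_tail_beads = 4) {
  mode <- match.arg(mode)
  stopifnot(n_pairs >= 0, cluster_radius > 0, n_tail_beads >= 1)
  structure(list(n_pairs = as.integer(n_pairs), mode = mode,
                 cluster_radius = cluster_radius,
                 n_tail = as.integer(n_tail_beads)),
            class = "ion_placement")
}

# sample n points in an axis-aligned periodic-z zone with min separation
poisson_disk_zone <- function(n, lx, ly, zlo, zhi, lz, min_sep, max_try = 5000L) {
  pts <- matrix(NA_real_, n, 3L)
  got <- 0L; tries <- 0L
  depth <- (zhi - zlo) %% lz
  if (depth == 0) depth <- lz
  while (got < n && tries < max_try) {
    tries <- tries + 1L
    cand <- c(stats::runif(1, 0, lx), stats::runif(1, 0, ly),
              (zlo + stats::runif(1, 0, depth)) %% lz)
    ok <- TRUE
    if (got > 0L) {
      d <- min_image_disp(pts[seq_len(got), , drop = FALSE],
                          matrix(cand, 1L, 3L), c(lx, ly, lz))
      if (!is.matrix(d)) d <- matrix(d, ncol = 3L)
      if (min(sqrt(rowSums(d^2))) <= min_sep) ok <- FALSE
    }
    if (ok) { got <- got + 1L; pts[got, ] <- cand }
  }
  if (got < n) {
    stop("place_ions: compartment too small to place ", n,
         " molecules at separation > ", min_sep, " nm", call. = FALSE)
  }
  pts
}

# cation bead chain: head (RNG) then tail beads along a direction
cation_beads <- function(head_pos, direction, n_tail, mol_id, spacing = 0.3) {
  u <- direction / sqrt(sum(direction^2))
  k <- 0:n_tail
  pos <- sweep(outer(k, u * spacing), 2, head_pos, `+`)
  data.frame(molecule_id = mol_id, residue_name = "IMI",
             bead_name = c("RNG", paste0("CT", seq_len(n_tail))),
             x = pos[, 1], y = pos[, 2], z = pos[, 3])
}

#' Place ions into a synthetic system
#'
#' Adds cation (head + tail-bead chain) and anion (single-bead) molecules
#' to a [generate_two_bilayer_system()] frame according to the placement
#' regime, and records ground-truth labels (compartment, cluster
#' membership) in the sidecar. Cluster modes lay tail-bead anchors on a
#' jittered compact lattice (spacing 0.55 nm) inside the cluster radius, so
#' a 0.7 nm contact cutoff is guaranteed to connect the cluster. May be
#' called repeatedly to combine regimes.
#'
#' @param system A `cg_system`.
#' @param placement An [ion_placement()].
#' @param seed Integer seed.
#' @return The updated `cg_system` (frame + `truth$ions` rows appended).
#' @export
place_ions <- function(system, placement, seed = 1) {
  stopifnot(inherits(system, "cg_system"), inherits(placement, "ion_placement"))
  if (placement$n_pairs == 0L) return(system)
  set.seed(seed)
  box <- system$frame$box
  lx <- box[["lx"]]; ly <- box[["ly"]]; lz <- box[["lz"]]
  sp1 <- system$spec$bilayer1; sp2 <- system$spec$bilayer2
  top1 <- sp1$z_center + sp1$thickness / 2 + sp1$amp
  bot1 <- sp1$z_center - sp1$thickness / 2 - sp1$amp
  top2 <- sp2$z_center + sp2$thickness / 2 + sp2$amp
  bot2 <- sp2$z_center - sp2$thickness / 2 - sp2$amp
  margin <- 0.5
  n <- placement$n_pairs
  mode <- placement$mode
  mol0 <- max(system$frame$atoms$molecule_id)
  chain_len <- 0.3 * placement$n_tail
  new_atoms <- list(); ion_rows <- list()
  add_cation <- function(head, dir, mol, compartment, cluster) {
    new_atoms[[length(new_atoms) + 1L]] <<-
      cation_beads(head, dir, placement$n_tail, mol)
    ion_rows[[length(ion_rows) + 1L]] <<- data.frame(
      molecule_id = mol, kind = "cation", mode = mode,
      compartment = compartment, cluster = cluster)
  }
  add_anion <- function(pos, mol, compartment) {
    new_atoms[[length(new_atoms) + 1L]] <<- data.frame(
      molecule_id = mol, residue_name = "BF4", bead_name = "ANI",
      x = pos[1], y = pos[2], z = pos[3])
    ion_rows[[length(ion_rows) + 1L]] <<- data.frame(
      molecule_id = mol, kind = "anion", mode = mode,
      compartment = compartment, cluster = NA_integer_)
  }
  solution_zone <- function(which) {
    if (which == "external") c(top2 + margin, (bot1 - margin) %% lz)
    else c(top1 + margin, bot2 - margin)
  }
  if (mode %in% c("dispersed_external", "internal_solution")) {
    comp <- if (mode == "dispersed_external") "external" else "internal"
    zr <- solution_zone(comp)
    depth <- (zr[2] - zr[1]) %% lz
    if (depth == 0) depth <- lz
    # rejection sampling at the bead level: every bead of a new ion must be
    # > 1 nm (minimum image) from every bead of the ions already placed, so
    # pairwise molecule separations exceed 1 nm by construction
    placed <- matrix(numeric(), 0L, 3L)
    min_sep <- 1.02
    tries <- 0L
    i <- 1L
    while (i <= n && tries < 20000L) {
      tries <- tries + 1L
      anchor <- c(stats::runif(1, 0, lx), stats::runif(1, 0, ly),
                  (zr[1] + stats::runif(1, chain_len, max(chain_len,
                                                          depth - chain_len))) %% lz)
      u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
      cat_b <- as.matrix(cation_beads(anchor, u, placement$n_tail,
                                      1L)[, c("x", "y", "z")])
      an_b <- matrix(c(stats::runif(1, 0, lx), stats::runif(1, 0, ly),
                       (zr[1] + stats::runif(1, 0, depth)) %% lz), 1L, 3L)
      cand <- rbind(cat_b, an_b)
      ok <- TRUE
      if (nrow(placed)) {
        ok <- min(cross_distances(placed, cand, box)) > min_sep
      }
      if (ok && min(cross_distances(cat_b, an_b, box)) <= min_sep) ok <- FALSE
      if (!ok) next
      add_cation(anchor, u, mol0 + 2L * i - 1L, comp, NA_integer_)
      add_anion(an_b[1, ], mol0 + 2L * i, comp)
      placed <- rbind(placed, cand)
      i <- i + 1L
    }
    if (i <= n) {
      stop("place_ions: compartment too small to place ", n,
           " ion pairs at molecule separation > 1 nm", call. = FALSE)
    }
  } else if (mode %in% c("micelle", "core_droplet")) {
    r <- placement$cluster_radius
    center <- if (mode == "core_droplet") {
      c(lx / 2, ly / 2, sp1$z_center)
    } else {
      zr <- solution_zone("external")
      depth <- (zr[2] - zr[1]) %% lz
      c(lx / 2, ly / 2, (zr[1] + depth / 2) %% lz)
    }
    # compact jittered lattice of head anchors; tails point inward, so any
    # tail bead is no farther from the center than max(anchor, chain) < r
    if (chain_len > r) {
      stop("place_ions: cation chain (", chain_len,
           " nm) longer than cluster_radius", call. = FALSE)
    }
    s <- 0.55
    reach <- max(0, r - 0.15)
    m <- ceiling(reach / s)
    g <- as.matrix(expand.grid(i = -m:m, j = -m:m, k = -m:m)) * s
    g <- g[sqrt(rowSums(g^2)) <= reach, , drop = FALSE]
    if (nrow(g) < n) {
      stop("place_ions: cluster_radius too small for ", n, " cations",
           call. = FALSE)
    }
    g <- g[order(rowSums(g^2))[seq_len(n)], , drop = FALSE]
    g <- g + matrix(stats::runif(3 * n, -0.05, 0.05), n, 3L)
    comp <- if (mode == "core_droplet") "bilayer1" else "external"
    for (i in seq_len(n)) {
      anchor <- center + g[i, ]
      dir <- center - anchor
      if (sqrt(sum(dir^2)) < 1e-6) dir <- c(0, 0, 1)
      # head sits at the anchor, tail extends inward: all tail beads stay
      # within |anchor - center| <= reach < r of the cluster center
      add_cation(anchor, dir, mol0 + 2L * i - 1L, comp, 1L)
    }
    zr <- solution_zone("external")
    anions <- poisson_disk_zone(n, lx, ly, zr[1], zr[2], lz, min_sep = 0.4)
    for (i in seq_len(n)) add_anion(anions[i, ], mol0 + 2L * i, "external")
  } else if (mode == "interfacial") {
    xy <- lattice_xy(n, lx, ly, jitter_xy = 0.1)
    zs <- (bot1 - 0.3) %% lz     # just below the b1 external leaflet sheet
    for (i in seq_len(n)) {
      head <- c(xy[i, 1], xy[i, 2], zs)
      add_cation(head, c(0, 0, -1), mol0 + 2L * i - 1L, "external", NA_integer_)
    }
    zr <- solution_zone("external")
    anions <- poisson_disk_zone(n, lx, ly, zr[1], zr[2], lz, min_sep = 0.4)
    for (i in seq_len(n)) add_anion(anions[i, ], mol0 + 2L * i, "external")
  }
  at <- do.call(rbind, new_atoms)
  at$x <- at$x %% lx; at$y <- at$y %% ly; at$z <- at$z %% lz
  frame <- cg_frame(rbind(system$frame$atoms, at), box,
                    time = system$frame$time)
  system$frame <- frame
  system$truth$ions <- rbind(system$truth$ions, do.call(rbind, ion_rows))
  system
}

#' Write the ground-truth sidecar tables of a synthetic system
#'
#' Tab-separated files `<prefix>_leaflets.tsv`, `<prefix>_water.tsv`,
#' `<prefix>_ions.tsv` with a `#` header line naming the columns.
#'
#' @param system A `cg_system`.
#' @param prefix Output path prefix.
#' @return Character vector of paths written, invisibly.
#' @export
write_ground_truth <- function(system, prefix) {
  stopifnot(inherits(system, "cg_system"))
  paths <- character()
  for (nm in c("leaflets", "water", "ions")) {
    d <- system$truth[[nm]]
    if (is.null(d) || !nrow(d)) next
    p <- paste0(prefix, "_", nm, ".tsv")
    con <- file(p, "w")
    writeLines(paste0("# ", paste(names(d), collapse = "\t")), con)
    utils::write.table(d, con, sep = "\t", row.names = FALSE,
                       col.names = FALSE, quote = FALSE)
    close(con)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Brownian (overdamped) walkers in a periodic box
#'
#' Per-step displacements are independent Gaussians with variance
#' `2 D dt` per axis. Both wrapped and unwrapped coordinates are retained,
#' the unwrapped ones serving as ground truth for [unwrap()] and [msd()].
#'
#' @param n_particles Number of walkers.
#' @param D Diffusion coefficient, nm^2/ps (>= 0).
#' @param dt Time step, ps.
#' @param n_steps Number of steps (frames = n_steps + 1).
#' @param box A `sim_box`.
#' @param seed Integer seed.
#' @return An object of class `brownian_traj`: list with `wrapped` and
#'   `unwrapped` arrays of dim `(n_steps + 1, n_particles, 3)`, `times`
#'   (ps), `box`, `D`.
#' @export
brownian_trajectory <- function(n_particles, D, dt, n_steps, box, seed = 1) {
  stopifnot(D >= 0, dt > 0, n_particles >= 1, n_steps >= 1)
  box <- as_sim_box(box)
  set.seed(seed)
  L <- unclass(box)
  sdstep <- sqrt(2 * D * dt)
  nT <- n_steps + 1L
  unwrapped <- array(0, c(nT, n_particles, 3L))
  start <- cbind(stats::runif(n_particles, 0, L[1]),
                 stats::runif(n_particles, 0, L[2]),
                 stats::runif(n_particles, 0, L[3]))
  for (k in 1:3) {
    steps <- matrix(stats::rnorm(n_steps * n_particles, 0, sdstep),
                    n_steps, n_particles)
    cs <- apply(steps, 2, cumsum)
    if (!is.matrix(cs)) cs <- matrix(cs, nrow = 1L)
    unwrapped[, , k] <- rbind(start[, k], sweep(cs, 2, start[, k], `+`))
  }
  wrapped <- unwrapped
  for (k in 1:3) wrapped[, , k] <- unwrapped[, , k] -
      L[k] * floor(unwrapped[, , k] / L[k])
  structure(list(wrapped = wrapped, unwrapped = unwrapped,
                 times = (0:n_steps) * dt, box = box, D = D),
            class = "brownian_traj")
}

#' @export
print.brownian_traj <- function(x, ...) {
  cat(sprintf("<brownian_traj> %d walkers x %d frames, D = %g nm^2/ps\n",
              dim(x$wrapped)[2], dim(x$wrapped)[1], x$D))
  invisible(x)
}
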