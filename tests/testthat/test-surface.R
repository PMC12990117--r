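test_that("grid interpolation reproduces constant and analytic fields", {
  box <- sim_box(20, 20, 20)
  # constant field: every grid height exactly the constant
  set.seed(1)
  pts <- cbind(runif(60, 0, 20), runif(60, 0, 20), 5.0)
  g <- build_leaflet_grid(pts, box, nx = 32, ny = 32)
  expect_equal(as.vector(g$heights), rep(5.0, 32 * 32), tolerance = 1e-12)
  # sinusoidal field sampled on a 50 x 50 lattice, evaluated at 64 x 64
  gg <- (seq_len(50) - 1) * 20 / 50
  lat <- expand.grid(x = gg, y = gg)
  pts <- cbind(lat$x, lat$y, 2 * sin(2 * pi * lat$x / 20))
  g <- build_leaflet_grid(pts, box, nx = 64, ny = 64)
  qx <- (seq_len(64) - 1) * 20 / 64
  ref <- outer(qx, rep(1, 64)) |> (\(m) 2 * sin(2 * pi * m / 20))()
  expect_lt(max(abs(g$heights - ref)), 0.05)
  # three points: single-triangle interpolation defined everywhere
  g3 <- build_leaflet_grid(cbind(c(1, 10, 15), c(2, 18, 7), c(1, 2, 3)),
                           box, nx = 16, ny = 16, margin = 20)
  expect_true(all(is.finite(g3$heights)))
  # collinear points cannot triangulate
  expect_error(build_leaflet_grid(cbind(1:5, 1:5, 1), box, nx = 8, ny = 8),
               "collinear")
})

test_that("surface area is exact for planes and matches quadrature for sines", {
  box <- sim_box(20, 20, 20)
  flat <- leaflet_grid(matrix(7, 64, 64), box)
  expect_identical(surface_area(flat), 400)
  # z = 2 sin(2 pi x / 20): compare with the 1-D quadrature oracle
  qx <- (seq_len(64) - 1) * 20 / 64
  h <- matrix(2 * sin(2 * pi * qx / 20), 64, 64)
  a <- surface_area(leaflet_grid(h, box))
  ref <- quadrature_area_sine(2, 1, 20, 20)
  expect_equal(a, ref, tolerance = 0.01)
  expect_gte(a, 400)
  # refinement convergence: doubling the resolution moves the area < 0.1%
  qx2 <- (seq_len(128) - 1) * 20 / 128
  h2 <- matrix(2 * sin(2 * pi * qx2 / 20), 128, 128)
  a2 <- surface_area(leaflet_grid(h2, box))
  expect_lt(abs(a2 - a) / a, 1e-3)
  expect_lte(abs(a2 - ref), abs(a - ref) + 1e-9)
})

test_that("thickness is the node-wise periodic vertical separation", {
  box <- sim_box(10, 10, 20)
  g <- function(z) leaflet_grid(matrix(z, 8, 8), box)
  expect_equal(bilayer_thickness(g(7), g(3)), 4)
  # parallel undulated leaflets keep the flat-case offset
  qx <- (seq_len(8) - 1) * 10 / 8
  u <- matrix(1.5 * sin(2 * pi * qx / 10), 8, 8)
  expect_equal(bilayer_thickness(leaflet_grid(3 + u, box),
                                 leaflet_grid(7 + u, box)), 4)
  # separation across the periodic boundary
  expect_equal(bilayer_thickness(g(19), g(1)), 2)
  expect_error(bilayer_thickness(g(3), leaflet_grid(matrix(7, 4, 4), box)),
               "share resolution")
})

test_that("leaflet assignment recovers construction labels under jitter", {
  sys <- make_small_system(seed = 13, z_jitter = 0.1)
  asg <- assign_leaflets(sys$frame, test_map)
  truth <- sys$truth$leaflets
  for (lab in names(asg$groups)) {
    mols <- sys$frame$atoms$molecule_id[asg$groups[[lab]]]
    expect_setequal(mols, truth$molecule_id[truth$leaflet == lab])
  }
  # heavy jitter (25% of the 2 nm inter-sheet half-gap) still separates
  sys2 <- make_small_system(seed = 14, z_jitter = 0.25)
  asg2 <- assign_leaflets(sys2$frame, test_map)
  expect_equal(sort(unname(asg2$sizes)), rep(64L, 4))
  # a single-bilayer frame has only 2 separable groups
  half <- sys$frame
  keep <- half$atoms$molecule_id %in%
    sys$truth$leaflets$molecule_id[sys$truth$leaflets$leaflet %in%
                                     c("b1_external", "b1_internal")] |
    half$atoms$residue_name != "DPPC"
  half <- cg_frame(half$atoms[keep, ], half$box)
  expect_error(assign_leaflets(half, test_map), "cannot separate")
})

test_that("compartment volumes follow slab arithmetic and conserve volume", {
  box <- sim_box(10, 10, 20)
  s <- flat_surfaces(c(4, 6, 14, 16), box)
  expect_equal(s$volumes[["bilayer1"]], 200)
  expect_equal(s$volumes[["bilayer2"]], 200)
  expect_equal(s$volumes[["internal"]], 800)
  expect_equal(s$volumes[["external"]], 800)
  expect_equal(sum(s$volumes), 2000)
  # undulated parallel leaflets leave the bilayer volume unchanged
  nx <- 16L
  qx <- (seq_len(nx) - 1) * 10 / nx
  u <- matrix(sin(2 * pi * qx / 10), nx, nx)
  labs <- c("b1_external", "b1_internal", "b2_internal", "b2_external")
  grids <- list(leaflet_grid(4 + u, box, labs[1]),
                leaflet_grid(6 + u, box, labs[2]),
                leaflet_grid(14 + u, box, labs[3]),
                leaflet_grid(16 + u, box, labs[4]))
  names(grids) <- labs
  su <- structure(list(grids = grids, box = box), class = "bilayer_surfaces")
  vu <- compartment_volumes(su)
  expect_equal(vu[["bilayer1"]], 200)
  expect_equal(sum(vu), 2000)
  # crossing surfaces raise a geometry error naming the column
  bad <- grids
  bad[["b1_internal"]] <- leaflet_grid(matrix(c(3.5, rep(6, nx * nx - 1)),
                                              nx, nx), box, labs[2])
  sb <- structure(list(grids = bad, box = box), class = "bilayer_surfaces")
  expect_error(compartment_volumes(sb), "cross")
})

test_that("volume closure holds on random undulated systems", {
  set.seed(21)
  for (i in 1:20) {
    amp <- runif(1, 0, 0.6)
    sys <- make_small_system(seed = 100 + i, z_jitter = 0.05, amp = amp,
                             periods = c(sample(1:2, 1), sample(0:2, 1)))
    surf <- build_bilayer_surfaces(sys$frame, test_map)
    expect_lt(abs(sum(surf$volumes) - box_volume(sys$frame$box)) /
                box_volume(sys$frame$box), 1e-3)
  }
})

test_that("locate_compartment reads the z-interval of the column", {
  box <- sim_box(10, 10, 20)
  s <- flat_surfaces(c(4, 6, 14, 16), box)
  expect_equal(locate_compartment(c(5, 5, 15), s), "bilayer2")
  expect_equal(locate_compartment(c(5, 5, 10), s), "internal")
  expect_equal(locate_compartment(c(5, 5, 2), s), "external")
  expect_equal(locate_compartment(c(5, 5, 18), s), "external")
  expect_equal(locate_compartment(c(5, 5, 5), s), "bilayer1")
  # planted ions agree with generator labels
  sys <- make_small_system(seed = 31)
  sys <- place_ions(sys, ion_placement(10, "dispersed_external"), seed = 5)
  surf <- build_bilayer_surfaces(sys$frame, test_map)
  heads <- molecule_centroids(sys$frame,
                              role_indices(sys$frame, test_map, "cation_head"))
  lab <- locate_compartment(heads, surf)
  expect_true(all(lab == "external"))
  w <- sys$truth$water
  wpos <- molecule_centroids(sys$frame,
                             which(sys$frame$atoms$residue_name == "W"))
  wlab <- locate_compartment(wpos, surf)
  expect_equal(unname(wlab), w$compartment[match(as.integer(rownames(wpos)),
                                                 w$molecule_id)])
})

test_that("per-lipid metrics divide by the stated counts", {
  box <- sim_box(20.2386, 20.2386, 30)
  s <- flat_surfaces(c(5, 9, 21, 25), box)
  m <- per_lipid_metrics(s, n_per_leaflet = 640, n_per_bilayer = 1280)
  expect_equal(unname(m$area_per_lipid[["b1_external"]]), 0.64, tolerance = 1e-4)
  expect_equal(length(unique(round(m$area_per_lipid, 12))), 1L)
  v1 <- s$volumes[["bilayer1"]]
  expect_equal(m$volume_per_lipid[["bilayer1"]], v1 / 1280)
  expect_error(per_lipid_metrics(s, 0, 10), "> 0")
})
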