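test_that("xi is the signed midplane offset, negative toward the external side", {
  box <- sim_box(10, 10, 20)
  s <- flat_surfaces(c(4, 6, 14, 16), box)   # bilayer 1 midplane at z = 5
  expect_equal(xi_coordinate(c(1, 1, 5), s, 1L), 0)
  expect_equal(xi_coordinate(c(1, 1, 2.2), s, 1L), -2.8)
  expect_equal(xi_coordinate(c(1, 1, 7), s, 1L), 2)
  # bilayer 2 (midplane 15): external side is +z
  expect_equal(xi_coordinate(c(1, 1, 17.8), s, 2L), -2.8)
  expect_equal(xi_coordinate(c(1, 1, 13), s, 2L), 2)
})

test_that("density profiles bin, normalize, and integrate to the group count", {
  box <- sim_box(10, 10, 20)
  s <- flat_surfaces(c(4, 6, 14, 16), box)
  n <- 40L
  at <- data.frame(molecule_id = seq_len(n), residue_name = "BF4",
                   bead_name = "ANI", x = runif(n, 0, 10),
                   y = runif(n, 0, 10), z = 2.2)
  fr <- cg_frame(at, box)
  prof <- density_profile(cg_trajectory(list(fr)), seq_len(n), s,
                          bin_width = 0.05)
  nonzero <- which(prof$density > 0)
  expect_length(nonzero, 1L)
  expect_equal(prof$xi[nonzero], -2.825, tolerance = 0.05)
  expect_equal(prof$density[nonzero], n / (10 * 10 * 0.05))
  # integral property: sum(density) * bin volume = mean count
  expect_equal(sum(prof$density) * 10 * 10 * 0.05, n)
  # uniform particles give a flat profile within Poisson noise
  set.seed(8)
  m <- 20000L
  atu <- data.frame(molecule_id = seq_len(m), residue_name = "W",
                    bead_name = "W", x = runif(m, 0, 10), y = runif(m, 0, 10),
                    z = runif(m, 8, 12))
  pu <- density_profile(cg_frame(atu, box), seq_len(m), s, bin_width = 0.5)
  filled <- pu$counts[pu$counts > 0]
  expect_equal(length(filled), 8L)
  expect_lt(max(abs(filled - 2500)) / 2500, 5 * sqrt(1 / 2500))
})

test_that("orientation profile signs and smoothing behave as documented", {
  box <- sim_box(10, 10, 20)
  s <- flat_surfaces(c(4, 6, 14, 16), box)
  # heads directly above their tails on the external side of bilayer 2
  n <- 50L
  at <- do.call(rbind, lapply(seq_len(n), function(i) {
    x <- runif(1, 0, 10); y <- runif(1, 0, 10)
    rbind(data.frame(molecule_id = i, residue_name = "IMI", bead_name = "RNG",
                     x = x, y = y, z = 18.0),
          data.frame(molecule_id = i, residue_name = "IMI", bead_name = "CT1",
                     x = x, y = y, z = 17.5))
  }))
  tr <- cg_trajectory(list(cg_frame(at, box)))
  prof <- orientation_profile(tr, test_map, s, bilayer = 2L,
                              smooth_window = 1)
  filled <- which(prof$counts > 0)
  expect_length(filled, 1L)
  expect_equal(prof$mean_cos_theta[filled], 1)
  # window 1 is the identity; a wider window still reproduces a constant
  prof4 <- orientation_profile(tr, test_map, s, bilayer = 2L,
                               smooth_window = 4)
  expect_equal(prof4$raw_mean_cos_theta[filled], 1)
  expect_identical(prof$mean_cos_theta[filled],
                   prof$raw_mean_cos_theta[filled])
  # isotropic orientations average to zero
  set.seed(9)
  m <- 1e5L
  u <- matrix(rnorm(3 * m), m, 3)
  u <- u / sqrt(rowSums(u^2)) * 0.4
  hx <- runif(m, 0, 10); hy <- runif(m, 0, 10)
  ati <- rbind(
    data.frame(molecule_id = seq_len(m), residue_name = "IMI",
               bead_name = "RNG", x = hx, y = hy, z = 2.2),
    data.frame(molecule_id = seq_len(m), residue_name = "IMI",
               bead_name = "CT1", x = hx - u[, 1], y = hy - u[, 2],
               z = 2.2 - u[, 3]))
  pi_ <- orientation_profile(cg_trajectory(list(cg_frame(ati, box))),
                             test_map, s, bilayer = 1L, smooth_window = 1)
  pop <- which(pi_$counts > 1000)
  expect_true(all(abs(pi_$raw_mean_cos_theta[pop]) < 0.02))
})

test_that("rdf matches the brute-force pair histogram and an ideal gas", {
  box <- sim_box(8, 8, 8)
  set.seed(4)
  n <- 200L
  at <- data.frame(molecule_id = seq_len(n), residue_name = "W",
                   bead_name = "W", x = runif(n, 0, 8), y = runif(n, 0, 8),
                   z = runif(n, 0, 8))
  fr <- cg_frame(at, box)
  r <- rdf(fr, seq_len(n), seq_len(n), r_max = 3, dr = 0.05)
  edges <- seq(0, 3, by = 0.05)
  ref <- brute_pair_counts(as.matrix(at[, c("x", "y", "z")]), c(8, 8, 8),
                           edges)
  expect_equal(r$counts, ref)
  # ideal gas: g ~= 1 within a 3 sigma Poisson band per bin
  big <- 600L
  set.seed(5)
  atb <- data.frame(molecule_id = seq_len(big), residue_name = "W",
                    bead_name = "W", x = runif(big, 0, 8),
                    y = runif(big, 0, 8), z = runif(big, 0, 8))
  rb <- rdf(cg_frame(atb, box), seq_len(big), seq_len(big), r_max = 3.5,
            dr = 0.1)
  expc <- rb$counts / pmax(rb$g, 1e-12)   # ideal count per bin
  keep <- rb$r > 0.3
  # ordered pair counts double the distinct pairs, so their variance is
  # about twice Poisson
  expect_true(all(abs(rb$counts - expc)[keep] <=
                    3 * sqrt(2 * expc[keep]) + 3))
  # two fixed particles: single peak bin at their separation
  at2 <- data.frame(molecule_id = 1:2, residue_name = "W", bead_name = "W",
                    x = c(1, 1.52), y = 1, z = 1)
  r2 <- rdf(cg_frame(at2, box), 1:2, 1:2, r_max = 2, dr = 0.05)
  expect_equal(r2$r[r2$counts > 0], 0.525)
  expect_equal(sum(r2$counts > 0), 1L)
  expect_error(rdf(fr, 1:10, 1:10, r_max = 5), "half the smallest")
})

test_that("first_minimum finds the planted shell boundary", {
  r <- seq(0.05, 1.5, by = 0.05)
  # excluded core, first-shell peak at 0.5, minimum at 0.7, g -> 1 beyond
  g <- 2.2 * exp(-(r - 0.5)^2 / (2 * 0.06^2)) +
    1 / (1 + exp(-(r - 0.9) / 0.08))
  planted <- structure(list(r = r, g = g, dr = 0.05), class = "rdf")
  expect_equal(first_minimum(planted, smooth = FALSE), 0.7, tolerance = 1e-9)
  # with count-like noise and 3-bin smoothing: within one bin
  set.seed(6)
  noisy <- planted
  noisy$g <- pmax(0, g + rnorm(length(g), 0, 0.03) * sqrt(g))
  expect_equal(first_minimum(noisy, smooth = TRUE), 0.7, tolerance = 0.051)
  mono <- structure(list(r = r, g = seq(0, 2, length.out = length(r)),
                         dr = 0.05), class = "rdf")
  expect_error(first_minimum(mono), "no interior maximum")
})
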