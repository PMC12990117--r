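kT309 <- kT_from_temperature(309)

test_that("a single unbiased window reduces WHAM to Boltzmann inversion", {
  set.seed(20)
  s <- rnorm(20000, 1, 0.4)
  edges <- seq(-0.5, 2.5, by = 0.1)
  w <- umbrella_window(1, 0, s)
  pmf <- wham(list(w), bin_edges = edges, kT = kT309, xi_ref = 1)
  h <- hist(s[s >= -0.5 & s <= 2.5], breaks = edges, plot = FALSE)
  ref <- -kT309 * log(h$counts)
  iref <- which.min(abs(pmf$xi - 1))
  ref <- ref - ref[iref]
  ok <- h$counts > 0
  expect_equal(pmf$G[ok], ref[ok], tolerance = 1e-10)
  expect_true(all(is.na(pmf$G[!ok])))   # empty bins stay undefined
  expect_equal(pmf$G[iref], 0)
})

test_that("WHAM reconstructs a harmonic potential from biased windows", {
  pot <- potential_spec("harmonic", kappa = 50)
  centers <- seq(0, 0.8, length.out = 10)   # ~1.8 sigma window spacing
  w <- sample_umbrella_windows(pot, centers, k = 1000, n_samples = 2000,
                               kT = kT309, seed = 23)
  edges <- seq(-0.2, 1.0, by = 0.05)
  pmf <- wham(w, bin_edges = edges, kT = kT309, xi_ref = 0)
  ok <- !is.na(pmf$G) & pmf$xi >= 0 & pmf$xi <= 0.8
  ref <- eval_potential(pot, pmf$xi)
  ref <- ref - ref[which.min(abs(pmf$xi - pmf$xi_ref))]
  rmse <- sqrt(mean((pmf$G[ok] - ref[ok])^2))
  expect_lt(rmse, 0.5 * kT309)
  # the self-consistency residual fell below tol
  expect_lt(tail(pmf$residual_trace, 1), 1e-7)
  expect_gt(pmf$n_iter, 1)
})

test_that("WHAM is stable under window duplication and thinning", {
  pot <- potential_spec("gaussian_barrier", h = 8, s = 0.3, x0 = 1)
  w1 <- sample_umbrella_windows(pot, seq(0, 2, 0.125), k = 500,
                                n_samples = 1500, kT = kT309, seed = 31)
  edges <- seq(-0.2, 2.2, by = 0.05)
  g1 <- wham(w1, edges, kT = kT309, xi_ref = 0)
  # duplicating every window (same data twice) cannot move the profile:
  # the estimator depends on the pooled histograms and bias weights only
  g2 <- wham(c(w1, w1), edges, kT = kT309, xi_ref = 0)
  expect_equal(g1$G, g2$G, tolerance = 1e-6)
  # thinning every window by half changes G only within statistical noise
  whalf <- lapply(w1, function(w) umbrella_window(w$center, w$k,
                                                  w$samples[seq(1, 1500, 2)]))
  gh <- wham(whalf, edges, kT = kT309, xi_ref = 0)
  ok <- !is.na(gh$G) & !is.na(g1$G) & g1$xi >= 0 & g1$xi <= 2
  expect_lt(sqrt(mean((gh$G[ok] - g1$G[ok])^2)), 0.5 * kT309)
})

test_that("a planted double-well barrier is recovered within bootstrap error", {
  pot <- potential_spec("double_well", h = 10, w = 0.8, x0 = 1)
  centers <- seq(-0.2, 2.2, length.out = 24)
  w <- sample_umbrella_windows(pot, centers, k = 800, n_samples = 2500,
                               kT = kT309, seed = 37)
  edges <- seq(-0.4, 2.4, by = 0.05)
  pmf <- bootstrap_pmf(w, n_blocks = 5, bin_edges = edges, kT = kT309,
                       xi_ref = 1)
  # barrier: G at the central maximum (xi = 1) minus G at a well (xi = 1 +/- 0.8)
  at <- function(x) pmf$G[which.min(abs(pmf$xi - x))]
  se_at <- function(x) pmf$stderr[which.min(abs(pmf$xi - x))]
  barrier <- at(1) - min(at(0.2), at(1.8))
  se <- sqrt(se_at(1)^2 + max(se_at(0.2), se_at(1.8))^2)
  expect_lt(abs(barrier - 10), 3 * max(se, 0.05))
})

test_that("windows that do not overlap trigger a gap warning", {
  set.seed(41)
  w <- list(umbrella_window(0, 1000, rnorm(500, 0, 0.05)),
            umbrella_window(3, 1000, rnorm(500, 3, 0.05)))
  expect_warning(wham(w, seq(-0.2, 3.2, 0.05), kT = kT309, xi_ref = 0),
                 "gap")
})

test_that("bootstrap errors vanish for identical blocks and demand samples", {
  set.seed(43)
  block <- rnorm(400, 1, 0.06)
  w <- list(umbrella_window(1, 1000, rep(block, 5)))
  pmf <- bootstrap_pmf(w, n_blocks = 5, bin_edges = seq(0.5, 1.5, 0.05),
                       kT = kT309, xi_ref = 1)
  ok <- !is.na(pmf$stderr)
  expect_true(any(ok))
  expect_true(all(pmf$stderr[ok] == 0))
  tiny <- list(umbrella_window(1, 1000, rnorm(3)))
  expect_error(bootstrap_pmf(tiny, n_blocks = 5), "fewer samples")
})

test_that("bootstrap bands are calibrated against the analytic profile", {
  pot <- potential_spec("harmonic", kappa = 50)
  w <- sample_umbrella_windows(pot, seq(0, 0.8, length.out = 10), k = 1000,
                               n_samples = 2000, kT = kT309, seed = 47)
  pmf <- bootstrap_pmf(w, n_blocks = 5, bin_edges = seq(-0.2, 1.0, 0.05),
                       kT = kT309, xi_ref = 0)
  ok <- which(!is.na(pmf$G) & pmf$stderr > 0 & pmf$xi >= 0 & pmf$xi <= 0.8)
  ref <- eval_potential(pot, pmf$xi)
  ref <- ref - ref[which.min(abs(pmf$xi - pmf$xi_ref))]
  z <- abs(pmf$G[ok] - ref[ok]) / pmf$stderr[ok]
  # errors should be on the scale the bands claim, not far beyond it
  expect_lt(median(z), 3)
  expect_true(all(pmf$stderr[ok] > 0))
})

test_that("delta_g extracts minima, center values, and the barrier", {
  xi <- seq(0, 4.5, by = 0.1)
  G <- rep(0, length(xi))
  G[which.min(abs(xi - 1.5))] <- -50
  G[which.min(abs(xi - 0))] <- -36
  pmf <- structure(list(xi = xi, G = G, stderr = rep(0, length(xi)),
                        kT = kT309, xi_ref = 4.5), class = "pmf_curve")
  dg <- delta_g(pmf, xi_solution = 4.5, xi_center = 0)
  expect_equal(dg$delta_g_min, -50)
  expect_equal(dg$delta_g_center, -36)
  expect_equal(dg$barrier, 14)
  expect_equal(dg$xi_min, 1.5)
  flat <- structure(list(xi = xi, G = rep(0, length(xi)),
                         stderr = rep(0, length(xi)), kT = kT309,
                         xi_ref = 4.5), class = "pmf_curve")
  dgf <- delta_g(flat)
  expect_equal(dgf$delta_g_min, 0)
  expect_equal(dgf$delta_g_center, 0)
  expect_equal(dgf$barrier, 0)
})

test_that("chain-length regression returns exact coefficients on exact data", {
  n <- c(4, 8, 12, 16)
  dg <- -3.2 * n - 10.6
  fit <- fit_linear(n, dg)
  expect_equal(fit$slope, -3.2)
  expect_equal(fit$intercept, -10.6)
  expect_equal(fit$r_squared, 1)
  # two points: exact interpolation
  f2 <- fit_linear(c(2, 6), c(1, 9))
  expect_equal(f2$slope, 2)
  expect_equal(f2$r_squared, 1)
  # permuting y off the line drops R^2
  set.seed(51)
  fp <- fit_linear(n, sample(dg))
  expect_lt(fp$r_squared, 1)
  expect_error(fit_linear(c(3, 3), c(1, 2)), "distinct")
})

test_that("umbrella windows round-trip through their text format", {
  w <- umbrella_window(1.25, 1000, c(1.2, 1.3, 1.25, 1.27))
  path <- withr::local_tempfile(fileext = ".dat")
  write_umbrella_window(w, path)
  back <- read_umbrella_window(path)
  expect_equal(back$center, 1.25)
  expect_equal(back$k, 1000)
  expect_equal(back$samples, w$samples, tolerance = 1e-7)
})
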