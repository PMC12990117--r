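frame_with_tails <- function(tail_pos, box, kind = "cation") {
  # tail_pos: list per molecule of n x 3 matrices
  res <- if (kind == "cation") "IMI" else "DPPC"
  head_bead <- if (kind == "cation") "RNG" else "PO4"
  tail_names <- if (kind == "cation") paste0("CT", 1:8) else
    c(paste0("C", 1:4, "A"), paste0("C", 1:4, "B"))
  rows <- do.call(rbind, lapply(seq_along(tail_pos), function(i) {
    p <- tail_pos[[i]]
    rbind(data.frame(molecule_id = i, residue_name = res,
                     bead_name = head_bead, x = p[1, 1], y = p[1, 2],
                     z = p[1, 3] + 0.1),
          data.frame(molecule_id = i, residue_name = res,
                     bead_name = tail_names[seq_len(nrow(p))],
                     x = p[, 1], y = p[, 2], z = p[, 3]))
  }))
  cg_frame(rows, box)
}

test_that("contacts follow the tail-bead first-shell rule, with periodicity", {
  box <- sim_box(10, 10, 10)
  fr <- frame_with_tails(list(matrix(c(1, 1, 1), 1), matrix(c(1.5, 1, 1), 1)),
                         box)
  g <- build_contact_graph(fr, test_map, "cation", cutoff = 0.7)
  expect_equal(nrow(g$edges), 1L)
  # beyond the cutoff: no edge
  fr2 <- frame_with_tails(list(matrix(c(1, 1, 1), 1), matrix(c(1.8, 1, 1), 1)),
                          box)
  expect_equal(nrow(build_contact_graph(fr2, test_map, "cation")$edges), 0L)
  # contact across the periodic boundary (0.2 vs 9.9 -> distance 0.3)
  fr3 <- frame_with_tails(list(matrix(c(0.2, 5, 5), 1), matrix(c(9.9, 5, 5), 1)),
                          box)
  expect_equal(nrow(build_contact_graph(fr3, test_map, "cation")$edges), 1L)
  # graph is invariant under rigid translation with rewrap
  set.seed(10)
  pts <- lapply(1:12, function(i) matrix(runif(6, 0, 10), 2, 3))
  fa <- frame_with_tails(pts, box)
  shift <- c(3.7, -2.2, 8.9)
  ptsb <- lapply(pts, function(p) sweep(p, 2, shift, `+`) %% 10)
  fb <- frame_with_tails(ptsb, box)
  ga <- build_contact_graph(fa, test_map, "cation")
  gb <- build_contact_graph(fb, test_map, "cation")
  expect_identical(ga$edges[order(ga$edges[, 1], ga$edges[, 2]), ],
                   gb$edges[order(gb$edges[, 1], gb$edges[, 2]), ])
})

test_that("cell-list pair search agrees with brute force", {
  set.seed(11)
  box <- sim_box(12, 9, 15)
  pos <- cbind(runif(900, 0, 12), runif(900, 0, 9), runif(900, 0, 15))
  fast <- pairs_within(pos, box, cutoff = 0.7, brute_force_below = 10L)
  slow <- pairs_within(pos, box, cutoff = 0.7, brute_force_below = 10000L)
  key <- function(e) sort(paste(e[, 1], e[, 2]))
  expect_identical(key(fast), key(slow))
})

test_that("degree and closeness match hand-derived small-graph values", {
  # path A-B-C
  p3 <- contact_graph_from_edges(1:3, rbind(c(1, 2), c(2, 3)))
  cl <- closeness_values(p3)$closeness
  expect_equal(unname(cl), c(2 / 3, 1, 2 / 3))
  # K4: diameter 1, all closeness 1, all degrees 3
  k4 <- contact_graph_from_edges(1:4, t(combn(4, 2)))
  expect_equal(unname(closeness_values(k4)$closeness), rep(1, 4))
  expect_equal(unname(degree_values(k4)$degree), rep(3L, 4))
  expect_equal(degree_values(k4)$mean, 3)
  # 4 nodes, single edge: endpoints (r-1)/(n-1) * (r-1)/S = 1/3; isolated 0
  e1 <- contact_graph_from_edges(1:4, rbind(c(1, 2)))
  expect_equal(unname(closeness_values(e1)$closeness), c(1 / 3, 1 / 3, 0, 0))
  # empty graph on 5 nodes
  e0 <- contact_graph_from_edges(1:5)
  expect_equal(unname(degree_values(e0)$degree), rep(0L, 5))
  expect_equal(unname(closeness_values(e0)$closeness), rep(0, 5))
})

test_that("centralities agree with the BFS oracle on random graphs", {
  set.seed(12)
  for (i in 1:100) {
    n <- sample(4:50, 1)
    p <- sample(c(0.03, 0.08, 0.2, 0.5), 1)
    edges <- random_er_graph(n, p)
    g <- contact_graph_from_edges(seq_len(n), edges)
    deg <- degree_values(g)
    expect_identical(unname(deg$degree), degree_oracle(n, g$edges))
    expect_equal(sum(deg$degree), 2L * nrow(g$edges))   # handshake lemma
    cl <- closeness_values(g)$closeness
    expect_equal(unname(cl), closeness_oracle(n, g$edges), tolerance = 1e-12)
    expect_true(all(cl >= 0 & cl <= 1))
  }
})

test_that("components recover planted aggregation regimes", {
  sys <- make_small_system(seed = 17)
  dro <- place_ions(sys, ion_placement(25, "core_droplet",
                                       cluster_radius = 1.8), seed = 2)
  g <- build_contact_graph(dro$frame, test_map, "cation", 0.7)
  cc <- connected_components(g)
  truth <- dro$truth$ions
  clustered <- truth$molecule_id[truth$kind == "cation" & !is.na(truth$cluster)]
  expect_equal(cc$n_components, 1L)
  expect_setequal(names(cc$membership), as.character(clustered))
  # two planted micelles via two placement calls -> two components
  two <- place_ions(sys, ion_placement(12, "micelle", cluster_radius = 1.5),
                    seed = 3)
  # second micelle: shift a copy of the droplet construction to the
  # internal solution is not a placement mode; instead verify dispersed
  # cations stay singletons
  disp <- place_ions(sys, ion_placement(8, "dispersed_external"), seed = 4)
  gd <- build_contact_graph(disp$frame, test_map, "cation", 0.7)
  expect_true(all(connected_components(gd)$sizes == 1L))
  gm <- build_contact_graph(two$frame, test_map, "cation", 0.7)
  ccm <- connected_components(gm)
  expect_equal(ccm$sizes[1], 12L)
  # largest-component fraction is monotone non-decreasing in the cutoff
  fr <- disp$frame
  fracs <- vapply(c(0.4, 0.7, 1.2, 2.5, 6), function(rc) {
    connected_components(build_contact_graph(fr, test_map, "cation",
                                             rc))$largest_fraction
  }, 0)
  expect_true(all(diff(fracs) >= 0))
})

test_that("time-averaged centralities pool frames and conserve counts", {
  sys <- place_ions(make_small_system(seed = 19),
                    ion_placement(15, "core_droplet", cluster_radius = 1.6),
                    seed = 5)
  sys <- place_ions(sys, ion_placement(5, "dispersed_external"), seed = 6)
  tr <- cg_trajectory(rep(list(sys$frame), 5))
  stats_ <- centrality_time_average(tr, test_map, "cation",
                                    window = seq_len(5))
  one <- build_contact_graph(sys$frame, test_map, "cation", 0.7)
  expect_equal(stats_$mean_degree, degree_values(one)$mean)
  expect_equal(stats_$mean_closeness, closeness_values(one)$mean)
  # histogram bins sum to n_nodes * n_frames
  expect_equal(sum(stats_$closeness_hist$counts), 20L * 5L)
  # droplet + dispersed: bimodal closeness with a zero mode
  h <- stats_$closeness_hist
  expect_gt(h$counts[1], 0)                       # zero mode (isolated)
  expect_gt(sum(h$counts[h$mids > 0.5]), 0)       # compact-cluster mode
  expect_equal(sum(h$counts[h$mids > 0.05 & h$mids < 0.5]), 0L)
  expect_error(centrality_time_average(tr, test_map, "cation", window = 9:10),
               "window")
})
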