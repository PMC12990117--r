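# Shared builders for small synthetic systems.

test_map <- default_role_map()

# standard small two-bilayer system: 64 lipids/leaflet, 6.4 x 6.4 x 24 box
make_small_system <- function(seed = 7, z_jitter = 0.1, amp = 0,
                              periods = c(1L, 0L), thickness = 4,
                              n = 64L, lz = 24) {
  lxy <- sqrt(n * 0.64)
  box <- sim_box(lxy, lxy, lz)
  s1 <- bilayer_spec(n, 0.64, thickness, z_center = lz / 4,
                     undulation_amplitude = amp, undulation_periods = periods)
  s2 <- bilayer_spec(n, 0.64, thickness, z_center = 3 * lz / 4,
                     undulation_amplitude = amp, undulation_periods = periods)
  generate_two_bilayer_system(s1, s2, box, seed = seed, z_jitter = z_jitter)
}

# hand-built flat four-leaflet surface stack (nx x ny constant grids)
flat_surfaces <- function(z4, box, nx = 8L, ny = 8L) {
  labs <- c("b1_external", "b1_internal", "b2_internal", "b2_external")
  grids <- lapply(1:4, function(k) {
    leaflet_grid(matrix(z4[k], nx, ny), box, labs[k])
  })
  names(grids) <- labs
  s <- structure(list(grids = grids, box = as_sim_box(box)),
                 class = "bilayer_surfaces")
  s$volumes <- compartment_volumes(s)
  s
}

# frame with 4 phosphate molecules per leaflet at exact heights z4,
# on a unit cross-section (plus optional extra atoms rows)
flat_phosphate_frame <- function(z4, box, extra = NULL) {
  xy <- cbind(c(0.25, 0.75, 0.25, 0.75) * box[1],
              c(0.25, 0.25, 0.75, 0.75) * box[2])
  rows <- do.call(rbind, lapply(seq_along(z4), function(k) {
    data.frame(molecule_id = (k - 1L) * 4L + 1:4, residue_name = "DPPC",
               bead_name = "PO4", x = xy[, 1], y = xy[, 2], z = z4[k])
  }))
  if (!is.null(extra)) {
    extra$molecule_id <- extra$molecule_id + max(rows$molecule_id)
    rows <- rbind(rows, extra)
  }
  cg_frame(rows, box)
}
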