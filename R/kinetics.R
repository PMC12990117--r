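# Mean-squared displacement, diffusion coefficients and
# compartment-resolved concentration time series.

# coerce input to a (frames x particles x 3) coordinate array
coord_array <- function(x, indices = NULL) {
  if (is.array(x) && length(dim(x)) == 3L) {
    a <- x
  } else if (inherits(x, "brownian_traj")) {
    a <- x$wrapped
  } else if (inherits(x, "cg_trajectory")) {
    nf <- length(x)
    idx <- if (is.null(indices)) seq_len(nrow(x[[1]]$atoms)) else indices
    a <- array(0, c(nf, length(idx), 3L))
    for (i in seq_len(nf)) a[i, , ] <- frame_positions(x[[i]])[idx, , drop = FALSE]
    return(a)
  } else {
    stop("expected a 3-d coordinate array, brownian_traj or cg_trajectory",
         call. = FALSE)
  }
  if (!is.null(indices)) a <- a[, indices, , drop = FALSE]
  a
}

#' Unwrap periodic coordinates into continuous trajectories
#'
#' Accumulates frame-to-frame minimum-image increments, producing
#' continuous coordinates whose rewrap reproduces the input. Requires every
#' per-frame displacement to be below half the box edge on each axis
#' (otherwise the crossing count is ambiguous and an undersampling error
#' names the bead and frame).
#'
#' @param x Wrapped coordinates: a (frames x particles x 3) array, a
#'   `brownian_traj`, or a `cg_trajectory`.
#' @param box A `sim_box` (taken from the object when it carries one).
#' @param indices Optional particle/bead subset.
#' @return Unwrapped coordinate array (frames x particles x 3).
#' @export
unwrap <- function(x, box = NULL, indices = NULL) {
  if (is.null(box)) {
    if (inherits(x, "brownian_traj")) box <- x$box
    else if (inherits(x, "cg_trajectory")) box <- x[[1]]$box
    else stop("unwrap: box required for plain arrays", call. = FALSE)
  }
  a <- coord_array(x, indices)
  L <- unclass(as_sim_box(box))
  nT <- dim(a)[1]
  if (nT < 2L) return(a)
  out <- a
  for (k in 1:3) {
    d <- a[-1, , k, drop = FALSE] - a[-nT, , k, drop = FALSE]
    shift <- -round(d / L[k])
    near_half <- abs(d + shift * L[k]) >= L[k] / 2 * (1 - 1e-9)
    if (any(near_half)) {
      w <- which(near_half, arr.ind = TRUE)[1, ]
      stop(sprintf(paste0("unwrap: displacement >= half box on axis %d for ",
                          "particle %d between frames %d and %d ",
                          "(trajectory undersampled)"),
                   k, w[2], w[1], w[1] + 1L), call. = FALSE)
    }
    cum <- apply(shift, 2, cumsum)
    if (!is.matrix(cum)) cum <- matrix(cum, nrow = 1L)
    out[-1, , k] <- a[-1, , k] + cum * L[k]
  }
  out
}

#' Mean-squared displacement with sliding time origins
#'
#' `msd(tau)` averages `|r(t + tau) - r(t)|^2` over all particles and all
#' sliding origins `t` (stride `origin_stride`), restricted to the chosen
#' axes. With stride 1 the sum over origins is evaluated with the
#' FFT-based autocorrelation algorithm, so long trajectories stay cheap.
#'
#' @param x Unwrapped coordinates: (frames x particles x 3) array (use
#'   [unwrap()] first for wrapped input).
#' @param dims Axes to include: `"xyz"` (3-D) or `"xy"` (lateral), or an
#'   integer vector of axis indices.
#' @param times Frame times (ps); default unit spacing.
#' @param origin_stride Origin stride (1 = every frame).
#' @param max_lag Largest lag in frames (default all).
#' @return An object of class `msd_series`: list with `lag` (ps), `msd`
#'   (nm^2), `n_origins`, `d` (dimensionality).
#' @export
msd <- function(x, dims = "xyz", times = NULL, origin_stride = 1L,
                max_lag = NULL) {
  a <- coord_array(x)
  nT <- dim(a)[1]
  if (nT < 2L) stop("msd: need >= 2 frames", call. = FALSE)
  axes <- if (is.character(dims)) {
    switch(dims, xyz = 1:3, xy = 1:2,
           stop("msd: dims must be 'xyz', 'xy' or integer axes", call. = FALSE))
  } else as.integer(dims)
  if (is.null(times)) times <- seq_len(nT) - 1
  if (is.null(max_lag)) max_lag <- nT - 1L
  max_lag <- min(max_lag, nT - 1L)
  np <- dim(a)[2]
  acc <- numeric(max_lag)
  nor <- numeric(max_lag)
  if (origin_stride == 1L) {
    for (p in seq_len(np)) for (k in axes) {
      r <- a[, p, k]
      acc <- acc + msd_fft_1d(r, max_lag)
    }
    nor <- (nT - seq_len(max_lag)) * np
  } else {
    origins <- seq.int(1L, nT - 1L, by = origin_stride)
    for (tau in seq_len(max_lag)) {
      o <- origins[origins + tau <= nT]
      if (!length(o)) break
      d2 <- 0
      for (k in axes) {
        dk <- a[o + tau, , k, drop = FALSE] - a[o, , k, drop = FALSE]
        d2 <- d2 + dk^2
      }
      acc[tau] <- sum(d2)
      nor[tau] <- length(o) * np
    }
  }
  keep <- nor > 0
  dt <- times[2] - times[1]
  structure(list(lag = c(0, seq_len(max_lag)[keep] * dt),
                 msd = c(0, acc[keep] / nor[keep]),
                 n_origins = c(nT, nor[keep] / np), d = length(axes)),
            class = "msd_series")
}

# sum over origins of (r(t+tau)-r(t))^2 for tau = 1..max_lag (FFT method)
msd_fft_1d <- function(r, max_lag) {
  nT <- length(r)
  r <- r - mean(r)   # displacement-invariant; keeps the FFT well conditioned
  # autocorrelation S2(tau) = sum_t r(t) r(t+tau) via zero-padded FFT
  f <- stats::fft(c(r, numeric(nT)))
  s2 <- Re(stats::fft(f * Conj(f), inverse = TRUE))[1:nT] / (2 * nT)
  # SS(tau) = sum over valid t of r(t)^2 + r(t+tau)^2
  d <- r^2
  q <- 2 * sum(d)
  ss <- numeric(nT)
  ss[1] <- q
  for (tau in seq_len(nT - 1L)) {
    q <- q - d[tau] - d[nT - tau + 1L]
    ss[tau + 1L] <- q
  }
  (ss[-1] - 2 * s2[-1])[seq_len(max_lag)]
}

#' @export
print.msd_series <- function(x, ...) {
  cat(sprintf("<msd_series> %d lags up to %g ps, d = %d\n",
              length(x$lag), max(x$lag), x$d))
  invisible(x)
}

#' Diffusion coefficient from the Einstein relation
#'
#' Least-squares slope of `msd(tau)` versus `tau` over the stated fraction
#' of the lag range (default 10-50%, skipping the poorly averaged tail and
#' the short-time regime); `D = slope / (2 d)`. Reported both in nm^2/ps
#' and cm^2/s (1 nm^2/ps = 1e-2 cm^2/s).
#'
#' @param x An `msd_series`.
#' @param fit_fraction Length-2 fraction of the maximum lag to fit over.
#' @return List with `D_nm2_ps`, `D_cm2_s`, `slope`, `r_squared`,
#'   `fit_range` (ps).
#' @export
diffusion_coefficient <- function(x, fit_fraction = c(0.1, 0.5)) {
  stopifnot(inherits(x, "msd_series"), length(fit_fraction) == 2L)
  tmax <- max(x$lag)
  sel <- x$lag >= fit_fraction[1] * tmax & x$lag <= fit_fraction[2] * tmax
  if (sum(sel) < 3L) {
    stop("diffusion_coefficient: fewer than 3 points in the fit range",
         call. = FALSE)
  }
  fit <- stats::lm(m ~ t, data = data.frame(t = x$lag[sel], m = x$msd[sel]))
  slope <- unname(stats::coef(fit)[2])
  D <- slope / (2 * x$d)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((x$msd[sel] - mean(x$msd[sel]))^2)
  list(D_nm2_ps = D, D_cm2_s = D * 1e-2, slope = slope,
       r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else 1,
       fit_range = range(x$lag[sel]))
}

#' Compartment-resolved counts and concentrations over time
#'
#' Per frame, each molecule of the group is assigned to one of the four
#' compartments (external, bilayer1, internal, bilayer2) via
#' [locate_compartment()] at its reference site (the anion bead, or the
#' centroid of the cation head beads). Concentrations are
#' `count / (0.6022 * V[nm^3])` mol/L (Avogadro's number folded into the
#' nm^3 to L conversion), using each frame's compartment volumes, and a
#' trailing running mean of `smoothing_frames` is applied to the reported
#' series. Raw counts always sum to the group size in every frame.
#'
#' @param trajectory A `cg_trajectory`.
#' @param map A `role_map`.
#' @param group_role Role whose molecules are tracked (`"anion"` or
#'   `"cation_head"`).
#' @param smoothing_frames Running-mean window in frames (default 12).
#' @param ... Passed to [build_bilayer_surfaces()].
#' @return An object of class `concentration_series`: list with `times`
#'   (ps), `counts` (frames x 4 matrix), `concentration` (smoothed, mol/L),
#'   `volumes` (frames x 4, nm^3), `compartments`, `smoothing_frames`,
#'   and `assignments` (long data.frame frame / molecule / compartment).
#' @export
compartment_series <- function(trajectory, map, group_role = "anion",
                               smoothing_frames = 12, ...) {
  stopifnot(inherits(trajectory, "cg_trajectory"))
  comps <- c("external", "bilayer1", "internal", "bilayer2")
  nf <- length(trajectory)
  counts <- matrix(0L, nf, 4L, dimnames = list(NULL, comps))
  vols <- matrix(NA_real_, nf, 4L, dimnames = list(NULL, comps))
  assigns <- vector("list", nf)
  times <- numeric(nf)
  for (i in seq_len(nf)) {
    fr <- trajectory[[i]]
    surf <- tryCatch(build_bilayer_surfaces(fr, map, ...), error = function(e) {
      stop("compartment_series: frame ", i, ": ", conditionMessage(e),
           call. = FALSE)
    })
    idx <- role_indices(fr, map, group_role)
    ref <- molecule_centroids(fr, idx)
    lab <- if (nrow(ref)) locate_compartment(ref, surf) else character()
    tab <- table(factor(lab, levels = comps))
    counts[i, ] <- as.integer(tab)
    vols[i, ] <- surf$volumes[comps]
    times[i] <- fr$time
    assigns[[i]] <- data.frame(frame = i,
                               molecule_id = as.integer(rownames(ref)),
                               compartment = lab)
  }
  conc_raw <- counts / (0.6022 * vols)
  conc <- apply(conc_raw, 2, running_mean, window = smoothing_frames)
  if (!is.matrix(conc)) conc <- matrix(conc, nrow = nf)
  colnames(conc) <- comps
  structure(list(times = times, counts = counts, concentration = conc,
                 concentration_raw = conc_raw, volumes = vols,
                 compartments = comps, smoothing_frames = smoothing_frames,
                 assignments = do.call(rbind, assigns)),
            class = "concentration_series")
}

#' @export
print.concentration_series <- function(x, ...) {
  cat(sprintf("<concentration_series> %d frames, group size %d\n",
              length(x$times), sum(x$counts[1, ])))
  invisible(x)
}

#' Write series objects as delimited text
#'
#' @param x An `msd_series` or `concentration_series`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_series <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (inherits(x, "msd_series")) {
    writeLines(c(sprintf("# memscope msd series, d= %d", x$d),
                 "# lag_ps\tmsd_nm2"), con)
    utils::write.table(data.frame(x$lag, x$msd), con, sep = "\t",
                       row.names = FALSE, col.names = FALSE, quote = FALSE)
  } else if (inherits(x, "concentration_series")) {
    writeLines(c(sprintf("# memscope concentration series, smoothing= %d frames",
                         x$smoothing_frames),
                 paste0("# time_ps\t",
                        paste0("count_", x$compartments, collapse = "\t"), "\t",
                        paste0("conc_", x$compartments, "_mol_L",
                               collapse = "\t"))), con)
    utils::write.table(data.frame(x$times, x$counts, x$concentration), con,
                       sep = "\t", row.names = FALSE, col.names = FALSE,
                       quote = FALSE)
  } else stop("write_series: unsupported object", call. = FALSE)
  invisible(path)
}
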