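# Weighted histogram analysis method (WHAM) for 1-D umbrella sampling,
# with contiguous-block bootstrap errors and the free-energy summaries
# derived from the reconstructed profile.

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Reconstruct a potential of mean force with WHAM
#'
#' Solves the standard self-consistent WHAM equations for windows biased by
#' `w_j(xi) = 0.5 k_j (xi - xi_j)^2`: the unbiased bin probability is
#' `p_b = sum_j n_j(b) / sum_j N_j exp((F_j - w_j(xi_b)) / kT)` and the
#' window free energies satisfy
#' `F_j = -kT log sum_b p_b exp(-w_j(xi_b) / kT)`, iterated (in log space)
#' until `max |delta F_j| < tol`. The profile is
#' `G(xi_b) = -kT log p_b`, shifted so that `G(xi_ref) = 0` at the bin
#' nearest `xi_ref`. Bins with no samples are reported as `NA`, never
#' imputed.
#'
#' @param windows List of [umbrella_window()]s; consecutive windows (sorted
#'   by center) whose sample ranges do not overlap trigger a gap error.
#' @param bin_edges Uniform histogram bin edges along xi (nm); default 0.1
#'   nm bins spanning the sampled range.
#' @param kT Thermal energy, kJ/mol (default 309 K).
#' @param tol Convergence tolerance on the window free energies, kJ/mol.
#' @param max_iter Maximum iterations.
#' @param xi_ref Reference coordinate where G is zeroed (nm); defaults to
#'   the largest bin center (the aqueous-solution end).
#' @return An object of class `pmf_curve`: list with `xi` (bin centers),
#'   `G` (kJ/mol, `NA` in empty bins), `stderr` (`NA` until
#'   [bootstrap_pmf()] fills it), `kT`, `xi_ref`, `F_windows`,
#'   `n_iter`, `residual_trace`.
#' @export
wham <- function(windows, bin_edges = NULL, kT = kT_from_temperature(),
                 tol = 1e-7, max_iter = 1e5, xi_ref = NULL) {
  stopifnot(length(windows) >= 1, kT > 0)
  lapply(windows, function(w) stopifnot(inherits(w, "umbrella_window")))
  centers <- vapply(windows, `[[`, 0, "center")
  ord <- order(centers)
  rngs <- lapply(windows, function(w) range(w$samples))
  if (length(windows) > 1L) {
    for (i in seq_len(length(windows) - 1L)) {
      a <- rngs[[ord[i]]]; b <- rngs[[ord[i + 1L]]]
      if (a[2] < b[1]) {
        warning(sprintf(paste0("wham: sampling gap between windows at %.3f ",
                               "and %.3f nm (%.3f .. %.3f unsampled)"),
                        centers[ord[i]], centers[ord[i + 1L]], a[2], b[1]))
      }
    }
  }
  if (is.null(bin_edges)) {
    lo <- min(vapply(rngs, `[`, 0, 1)); hi <- max(vapply(rngs, `[`, 0, 2))
    bin_edges <- seq(floor(lo / 0.1) * 0.1, ceiling(hi / 0.1) * 0.1, by = 0.1)
  }
  nb <- length(bin_edges) - 1L
  mids <- (bin_edges[-1] + bin_edges[-length(bin_edges)]) / 2
  J <- length(windows)
  counts <- matrix(0, J, nb)
  N <- integer(J)
  for (j in seq_len(J)) {
    s <- windows[[j]]$samples
    h <- graphics::hist(s[s >= bin_edges[1] & s <= bin_edges[length(bin_edges)]],
                        breaks = bin_edges, plot = FALSE)
    counts[j, ] <- h$counts
    N[j] <- sum(h$counts)
  }
  ntot <- colSums(counts)
  # log bias Boltzmann factors: -w_j(xi_b)/kT
  lw <- matrix(0, J, nb)
  for (j in seq_len(J)) {
    lw[j, ] <- -0.5 * windows[[j]]$k * (mids - windows[[j]]$center)^2 / kT
  }
  lF <- numeric(J)           # F_j / kT
  logN <- log(pmax(N, 1))
  occupied <- ntot > 0
  logntot <- ifelse(occupied, log(ntot), -Inf)
  resid <- numeric(0)
  it <- 0L
  repeat {
    it <- it + 1L
    # log denominator per bin: logsumexp_j(log N_j + F_j/kT + lw[j, b])
    A <- lw + logN + lF       # J x nb (column recycling over rows)
    amax <- apply(A, 2, max)
    logden <- amax + log(colSums(exp(sweep(A, 2, amax))))
    logp <- logntot - logden
    # new F_j/kT = -logsumexp_b(logp + lw[j, ])
    lFnew <- vapply(seq_len(J), function(j) {
      -logsumexp(logp[occupied] + lw[j, occupied])
    }, 0)
    lFnew <- lFnew - lFnew[1]
    d <- max(abs(lFnew - lF)) * kT
    resid <- c(resid, d)
    lF <- lFnew
    if (d < tol || it >= max_iter) break
  }
  if (resid[length(resid)] >= tol) {
    stop(sprintf("wham: no convergence after %d iterations (residual %.3g kJ/mol)",
                 it, resid[length(resid)]), call. = FALSE)
  }
  A <- lw + logN + lF
  amax <- apply(A, 2, max)
  logden <- amax + log(colSums(exp(sweep(A, 2, amax))))
  logp <- logntot - logden
  G <- ifelse(occupied, -kT * logp, NA_real_)
  if (is.null(xi_ref)) xi_ref <- max(mids[occupied])
  iref <- which.min(abs(mids - xi_ref))
  if (!occupied[iref]) {
    stop("wham: reference bin at xi = ", xi_ref, " has no samples",
         call. = FALSE)
  }
  G <- G - G[iref]
  structure(list(xi = mids, G = G, stderr = rep(NA_real_, nb), kT = kT,
                 xi_ref = mids[iref], bin_edges = bin_edges,
                 F_windows = lF * kT, n_iter = it, residual_trace = resid),
            class = "pmf_curve")
}

#' @export
print.pmf_curve <- function(x, ...) {
  ok <- !is.na(x$G)
  cat(sprintf(paste0("<pmf_curve> %d bins over [%.2f, %.2f] nm, kT %.3f kJ/mol,",
                     " min %.2f kJ/mol at xi %.2f (ref %.2f)\n"),
              length(x$xi), min(x$xi), max(x$xi), x$kT,
              min(x$G[ok]), x$xi[ok][which.min(x$G[ok])], x$xi_ref))
  invisible(x)
}

#' Write a PMF curve as delimited text
#'
#' Columns: xi (nm), G (kJ/mol), stderr (kJ/mol); metadata in `#` header
#' lines.
#'
#' @param pmf A `pmf_curve`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pmf <- function(pmf, path) {
  stopifnot(inherits(pmf, "pmf_curve"))
  con <- file(path, "w")
  writeLines(c(sprintf("# kT= %.6f kJ/mol, reference= %.4f nm", pmf$kT,
                       pmf$xi_ref),
               "# xi_nm\tG_kJ_mol\tstderr_kJ_mol"), con)
  utils::write.table(data.frame(pmf$xi, pmf$G, pmf$stderr), con, sep = "\t",
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  close(con)
  invisible(path)
}

#' Block-bootstrap errors for a WHAM profile
#'
#' Divides each window's time-ordered samples into `n_blocks` contiguous
#' blocks (a trailing remainder is dropped), computes one full WHAM profile
#' per block index (block i of every window), and returns the per-bin
#' standard deviation of the resulting profiles. Contiguous blocks respect
#' the autocorrelation of the time series.
#'
#' @param windows List of [umbrella_window()]s.
#' @param n_blocks Number of blocks (default 5).
#' @inheritParams wham
#' @return The `pmf_curve` from the full data with `stderr` filled in and
#'   attribute `"replicates"` (matrix of the block profiles).
#' @export
bootstrap_pmf <- function(windows, n_blocks = 5, bin_edges = NULL,
                          kT = kT_from_temperature(), tol = 1e-7,
                          max_iter = 1e5, xi_ref = NULL) {
  ns <- vapply(windows, function(w) length(w$samples), 0L)
  if (any(ns < n_blocks)) {
    stop("bootstrap_pmf: window with fewer samples (", min(ns),
         ") than blocks (", n_blocks, ")", call. = FALSE)
  }
  full <- wham(windows, bin_edges = bin_edges, kT = kT, tol = tol,
               max_iter = max_iter, xi_ref = xi_ref)
  reps <- matrix(NA_real_, length(full$xi), n_blocks)
  for (b in seq_len(n_blocks)) {
    wb <- lapply(windows, function(w) {
      blk <- length(w$samples) %/% n_blocks
      umbrella_window(w$center, w$k,
                      w$samples[((b - 1L) * blk + 1L):(b * blk)])
    })
    gb <- suppressWarnings(
      wham(wb, bin_edges = full$bin_edges, kT = kT, tol = tol,
           max_iter = max_iter, xi_ref = full$xi_ref))
    reps[, b] <- gb$G
  }
  full$stderr <- apply(reps, 1, function(v) {
    if (anyNA(v)) NA_real_ else stats::sd(v)
  })
  attr(full, "replicates") <- reps
  full
}

#' Free-energy summaries of a PMF
#'
#' `delta_g_min` is the free energy to move from the aqueous solution
#' (`xi_solution`) to the global minimum of the profile, `delta_g_center`
#' to the bilayer center (`xi_center`), and `barrier` their difference
#' (the cost of moving from the minimum to the center). Reference values
#' are looked up at the nearest defined bin.
#'
#' @param pmf A `pmf_curve`.
#' @param xi_solution Aqueous-solution coordinate, nm (default 4.5).
#' @param xi_center Bilayer-center coordinate, nm (default 0).
#' @return List with `delta_g_min`, `delta_g_center`, `barrier` (kJ/mol)
#'   and `xi_min` (nm).
#' @export
delta_g <- function(pmf, xi_solution = 4.5, xi_center = 0) {
  stopifnot(inherits(pmf, "pmf_curve"))
  ok <- which(!is.na(pmf$G))
  if (!length(ok)) stop("delta_g: empty profile", call. = FALSE)
  near <- function(x) {
    i <- ok[which.min(abs(pmf$xi[ok] - x))]
    if (abs(pmf$xi[i] - x) > 2 * mean(diff(pmf$xi))) {
      stop("delta_g: profile undefined near xi = ", x, call. = FALSE)
    }
    i
  }
  isol <- near(xi_solution)
  icen <- near(xi_center)
  imin <- ok[which.min(pmf$G[ok])]
  list(delta_g_min = pmf$G[imin] - pmf$G[isol],
       delta_g_center = pmf$G[icen] - pmf$G[isol],
       barrier = pmf$G[icen] - pmf$G[imin],
       xi_min = pmf$xi[imin])
}

#' Linear fit of transfer free energy versus alkyl chain length
#'
#' Ordinary least squares of `delta_g` on the number of tail carbons,
#' returning slope (kJ/mol per carbon), intercept (kJ/mol) and R^2.
#'
#' @param n_carbons Numeric vector of chain lengths (>= 2 distinct values).
#' @param delta_g_values Free energies (kJ/mol), same length.
#' @return List with `slope`, `intercept`, `r_squared` and the underlying
#'   `stats::lm` fit (`fit`).
#' @export
fit_linear <- function(n_carbons, delta_g_values) {
  stopifnot(length(n_carbons) == length(delta_g_values))
  if (length(unique(n_carbons)) < 2L) {
    stop("fit_linear: need >= 2 distinct chain lengths", call. = FALSE)
  }
  d <- data.frame(n = n_carbons, dg = delta_g_values)
  fit <- stats::lm(dg ~ n, data = d)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((d$dg - mean(d$dg))^2)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else 1,
       fit = fit)
}
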