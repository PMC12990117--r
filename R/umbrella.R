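# Analytic 1-D potentials and Metropolis sampling under harmonic umbrella
# biases: the test oracle for the WHAM machinery.

#' Boltzmann constant times temperature
#'
#' `kT = R_gas * T` in kJ/mol (molar gas constant
#' 0.0083145 kJ mol^-1 K^-1). The default simulation temperature of the
#' systems this package targets is 309 K, giving kT ~= 2.569 kJ/mol.
#'
#' @param temperature Temperature in K.
#' @return kT in kJ/mol.
#' @export
kT_from_temperature <- function(temperature = 309) {
  0.0083145 * temperature
}

#' Analytic 1-D potential specification
#'
#' Forms (all energies kJ/mol, coordinate nm):
#' * `flat`: U = 0.
#' * `harmonic`: `U = 0.5 * kappa * (xi - x0)^2`; params `kappa`, `x0`.
#' * `double_well`: `U = h * ((xi - x0)^2 / w^2 - 1)^2`; params `h`
#'   (barrier height between the wells at `x0 +/- w` and the maximum at
#'   `x0`), `w`, `x0`.
#' * `gaussian_barrier`: `U = h * exp(-(xi - x0)^2 / (2 s^2))`; params
#'   `h`, `s`, `x0`.
#'
#' @param form One of `"flat"`, `"harmonic"`, `"double_well"`,
#'   `"gaussian_barrier"`.
#' @param ... Named parameters of the chosen form (see above); `x0`
#'   defaults to 0.
#' @return An object of class `potential_spec`; evaluate with
#'   [eval_potential()].
#' @export
potential_spec <- function(form = c("flat", "harmonic", "double_well",
                                    "gaussian_barrier"), ...) {
  form <- match.arg(form)
  par <- list(...)
  if (is.null(par$x0)) par$x0 <- 0
  need <- switch(form, flat = character(), harmonic = "kappa",
                 double_well = c("h", "w"), gaussian_barrier = c("h", "s"))
  miss <- setdiff(need, names(par))
  if (length(miss)) {
    stop("potential_spec: missing parameter(s) for ", form, ": ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  structure(list(form = form, par = par), class = "potential_spec")
}

#' @rdname potential_spec
#' @param potential A `potential_spec`.
#' @param xi Coordinate values (nm).
#' @export
eval_potential <- function(potential, xi) {
  stopifnot(inherits(potential, "potential_spec"))
  p <- potential$par
  u <- switch(potential$form,
              flat = rep(0, length(xi)),
              harmonic = 0.5 * p$kappa * (xi - p$x0)^2,
              double_well = p$h * ((xi - p$x0)^2 / p$w^2 - 1)^2,
              gaussian_barrier = p$h * exp(-(xi - p$x0)^2 / (2 * p$s^2)))
  if (any(!is.finite(u))) stop("eval_potential: non-finite energy", call. = FALSE)
  u
}

#' Umbrella window
#'
#' One biased-sampling window: harmonic bias `w(xi) = 0.5 k (xi - center)^2`
#' and the time-ordered samples of the reaction coordinate collected under
#' the total potential `U(xi) + w(xi)`.
#'
#' @param center Bias center (nm).
#' @param k Force constant (kJ mol^-1 nm^-2, >= 0; `k = 0` denotes an
#'   unbiased window, for which WHAM degenerates to direct Boltzmann
#'   inversion of the histogram).
#' @param samples Ordered numeric vector of xi samples (nm).
#' @return An object of class `umbrella_window`.
#' @export
umbrella_window <- function(center, k, samples) {
  stopifnot(is.numeric(samples), length(samples) >= 1, all(is.finite(samples)))
  if (k < 0) stop("umbrella_window: force constant must be >= 0", call. = FALSE)
  structure(list(center = as.numeric(center), k = as.numeric(k),
                 samples = as.numeric(samples)),
            class = "umbrella_window")
}

#' @export
print.umbrella_window <- function(x, ...) {
  cat(sprintf("<umbrella_window> center %.3f nm, k %g kJ/mol/nm^2, %d samples\n",
              x$center, x$k, length(x$samples)))
  invisible(x)
}

#' Metropolis sampling of umbrella windows from an analytic potential
#'
#' For each window center, draws Metropolis samples from the biased density
#' `exp(-(U(xi) + 0.5 k (xi - center)^2) / kT)` using a Gaussian proposal.
#' The default step size `sqrt(kT / k)` (the width of the bias alone) gives
#' near-optimal acceptance for harmonic-dominated targets; `burn_in`
#' initial samples are discarded. Acceptance rates are returned as an
#' attribute and a sampling error is raised if a window accepts nothing
#' after burn-in.
#'
#' @param potential A [potential_spec()].
#' @param window_centers Numeric vector of bias centers (nm).
#' @param k Bias force constant (kJ mol^-1 nm^-2, > 0).
#' @param n_samples Retained samples per window.
#' @param kT Thermal energy (kJ/mol, > 0); see [kT_from_temperature()].
#' @param seed Integer seed.
#' @param burn_in Discarded initial samples (default 1000).
#' @param step_size Gaussian proposal sd (nm); default `sqrt(kT / k)`.
#' @return List of [umbrella_window()]s with attribute
#'   `"acceptance"` (per-window acceptance rates).
#' @export
sample_umbrella_windows <- function(potential, window_centers, k, n_samples,
                                    kT = kT_from_temperature(), seed = 1,
                                    burn_in = 1000L, step_size = NULL) {
  stopifnot(k > 0, kT > 0, n_samples >= 1)
  if (is.null(step_size)) step_size <- sqrt(kT / k)
  set.seed(seed)
  windows <- vector("list", length(window_centers))
  acc <- numeric(length(window_centers))
  ntot <- burn_in + n_samples
  for (j in seq_along(window_centers)) {
    c0 <- window_centers[j]
    energy <- function(x) eval_potential(potential, x) + 0.5 * k * (x - c0)^2
    x <- c0
    e <- energy(x)
    prop <- stats::rnorm(ntot, 0, step_size)
    uacc <- stats::runif(ntot)
    out <- numeric(ntot)
    nacc <- 0L
    for (t in seq_len(ntot)) {
      xn <- x + prop[t]
      en <- energy(xn)
      if (en <= e || uacc[t] < exp((e - en) / kT)) {
        x <- xn; e <- en; nacc <- nacc + 1L
      }
      out[t] <- x
    }
    acc[j] <- nacc / ntot
    post <- nacc  # accepted moves overall; check post-burn-in movement
    if (length(unique(out[(burn_in + 1L):ntot])) == 1L) {
      stop(sprintf(paste0("sample_umbrella_windows: window %d (center %.3f) ",
                          "accepted no moves after burn-in; acceptance %.3f, ",
                          "step_size %.4f"), j, c0, acc[j], step_size),
           call. = FALSE)
    }
    windows[[j]] <- umbrella_window(c0, k, out[(burn_in + 1L):ntot])
  }
  attr(windows, "acceptance") <- acc
  windows
}

#' Read / write umbrella windows as delimited text
#'
#' Dialect: two `#`-prefixed metadata lines (`# center= <nm>` and
#' `# k= <kJ/mol/nm^2>`), then one xi sample (nm) per line.
#'
#' @param path File path (one file per window).
#' @return `read_umbrella_window()` an [umbrella_window()];
#'   `write_umbrella_window()` the path, invisibly.
#' @export
read_umbrella_window <- function(path) {
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  getv <- function(key) {
    m <- grep(paste0("^#\\s*", key, "\\s*="), meta, value = TRUE)
    if (!length(m)) stop("read_umbrella_window: missing '# ", key,
                         "=' header in ", path, call. = FALSE)
    as.numeric(sub(paste0("^#\\s*", key, "\\s*="), "", m[1]))
  }
  vals <- as.numeric(lines[!grepl("^#", lines) & nzchar(trimws(lines))])
  umbrella_window(getv("center"), getv("k"), vals)
}

#' @rdname read_umbrella_window
#' @param window An [umbrella_window()].
#' @export
write_umbrella_window <- function(window, path) {
  stopifnot(inherits(window, "umbrella_window"))
  con <- file(path, "w")
  writeLines(c(sprintf("# center= %.6f", window$center),
               sprintf("# k= %.6f", window$k),
               sprintf("%.8f", window$samples)), con)
  close(con)
  invisible(path)
}
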