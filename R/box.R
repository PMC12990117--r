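#' Orthorhombic simulation box
#'
#' Construct an orthorhombic periodic box. All lengths are in nm; only
#' orthorhombic (rectangular) boxes are supported, matching the systems the
#' package targets.
#'
#' @param lx,ly,lz Box edge lengths along x, y, z (nm); all must be > 0.
#' @return An object of class `sim_box`: a named numeric vector
#'   `c(lx, ly, lz)`.
#' @examples
#' b <- sim_box(10, 10, 20)
#' box_volume(b)  # 2000 nm^3
#' @export
sim_box <- function(lx, ly, lz) {
  edges <- c(lx = as.numeric(lx), ly = as.numeric(ly), lz = as.numeric(lz))
  if (any(!is.finite(edges)) || any(edges <= 0)) {
    stop("sim_box: all edge lengths must be finite and > 0", call. = FALSE)
  }
  structure(edges, class = "sim_box")
}

#' @rdname sim_box
#' @param box A `sim_box`.
#' @export
box_volume <- function(box) {
  unname(prod(unclass(box)))
}

as_sim_box <- function(box) {
  if (inherits(box, "sim_box")) return(box)
  if (is.numeric(box) && length(box) == 3L) return(sim_box(box[1], box[2], box[3]))
  stop("expected a sim_box or a length-3 numeric vector", call. = FALSE)
}

#' Minimum-image displacement
#'
#' Displacement vector from `a` to `b` under periodic boundary conditions,
#' taking the nearest periodic image. Each component of the result lies in
#' `[-L/2, L/2)` (half-open: a separation of exactly `L/2` is reported as
#' `-L/2`), and its norm is the minimum over all periodic images.
#'
#' @param a,b Positions (nm): length-3 vectors or n x 3 matrices.
#' @param box A `sim_box` (or length-3 numeric).
#' @return Displacement `b - a` folded into the minimum image; same shape as
#'   the broadcast of the inputs.
#' @export
min_image_disp <- function(a, b, box) {
  box <- as_sim_box(box)
  a <- if (is.matrix(a)) a else matrix(a, ncol = 3L, byrow = TRUE)
  b <- if (is.matrix(b)) b else matrix(b, ncol = 3L, byrow = TRUE)
  d <- sweep_rows(b, a)
  L <- unclass(box)
  for (k in 1:3) {
    d[, k] <- d[, k] - L[k] * floor(d[, k] / L[k] + 0.5)
  }
  if (nrow(d) == 1L) drop(d) else d
}

# recycle the shorter of two n x 3 matrices row-wise and subtract
sweep_rows <- function(b, a) {
  n <- max(nrow(a), nrow(b))
  if (nrow(a) == 1L && n > 1L) a <- a[rep(1L, n), , drop = FALSE]
  if (nrow(b) == 1L && n > 1L) b <- b[rep(1L, n), , drop = FALSE]
  b - a
}

#' Wrap positions into the primary box
#'
#' Folds coordinates into `[0, L)` on each axis.
#'
#' @param x Positions: length-3 vector or n x 3 matrix (nm).
#' @param box A `sim_box`.
#' @return Wrapped positions, same shape as `x`.
#' @export
wrap_positions <- function(x, box) {
  box <- as_sim_box(box)
  m <- if (is.matrix(x)) x else matrix(x, ncol = 3L, byrow = TRUE)
  L <- unclass(box)
  for (k in 1:3) m[, k] <- m[, k] - L[k] * floor(m[, k] / L[k])
  if (!is.matrix(x)) drop(m) else m
}

# periodic signed offset z - z0 folded into (-Lz/2, Lz/2]
periodic_offset <- function(z, z0, L) {
  d <- z - z0
  d - L * ceiling(d / L - 0.5)
}
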