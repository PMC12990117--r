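#' Coordinate frame for a coarse-grained system
#'
#' A `cg_frame` couples one time point's bead records with the periodic box.
#' Bead records carry a molecule id, residue name, bead name and a position
#' in nm; velocities (if present in the source file) are discarded.
#'
#' @param atoms A data.frame with columns `molecule_id` (integer >= 1),
#'   `residue_name`, `bead_name` (character) and `x`, `y`, `z` (nm).
#' @param box A `sim_box`.
#' @param time Time of the frame in ps (default 0).
#' @return An object of class `cg_frame`: a list with elements `time`,
#'   `box` and `atoms`.
#' @export
cg_frame <- function(atoms, box, time = 0) {
  box <- as_sim_box(box)
  need <- c("molecule_id", "residue_name", "bead_name", "x", "y", "z")
  if (!is.data.frame(atoms) || !all(need %in% names(atoms))) {
    stop("cg_frame: 'atoms' must be a data.frame with columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  pos <- as.matrix(atoms[, c("x", "y", "z")])
  if (any(!is.finite(pos))) stop("cg_frame: non-finite positions", call. = FALSE)
  if (any(atoms$molecule_id < 1L)) stop("cg_frame: molecule_id must be >= 1", call. = FALSE)
  structure(list(time = as.numeric(time), box = box, atoms = atoms),
            class = "cg_frame")
}

#' @export
print.cg_frame <- function(x, ...) {
  L <- unclass(x$box)
  cat(sprintf("<cg_frame> t = %g ps, %d beads, %d molecules, box %.3f x %.3f x %.3f nm\n",
              x$time, nrow(x$atoms), length(unique(x$atoms$molecule_id)),
              L[1], L[2], L[3]))
  invisible(x)
}

#' @rdname cg_frame
#' @param frames A list of `cg_frame` objects with identical bead counts.
#' @export
cg_trajectory <- function(frames) {
  if (!length(frames)) stop("cg_trajectory: no frames", call. = FALSE)
  if (inherits(frames, "cg_frame")) frames <- list(frames)
  stopifnot(all(vapply(frames, inherits, TRUE, "cg_frame")))
  n <- vapply(frames, function(f) nrow(f$atoms), 0L)
  if (length(unique(n)) != 1L) {
    stop("cg_trajectory: bead count varies across frames (",
         paste(unique(n), collapse = ", "), ")", call. = FALSE)
  }
  structure(frames, class = "cg_trajectory")
}

#' @export
print.cg_trajectory <- function(x, ...) {
  cat(sprintf("<cg_trajectory> %d frames x %d beads\n",
              length(x), nrow(x[[1]]$atoms)))
  invisible(x)
}

#' @export
`[.cg_trajectory` <- function(x, i) {
  cg_trajectory(unclass(x)[i])
}

#' Frame positions as a matrix
#' @param frame A `cg_frame`.
#' @return n x 3 numeric matrix of positions (nm).
#' @export
frame_positions <- function(frame) {
  as.matrix(frame$atoms[, c("x", "y", "z")])
}

gro_time_from_title <- function(title) {
  m <- regmatches(title, regexpr("t=\\s*[-0-9.eE+]+", title))
  if (length(m)) as.numeric(sub("t=\\s*", "", m)) else NA_real_
}

#' Read a (multi-frame) GRO coordinate file
#'
#' Parses the fixed-column GRO layout: title, atom count, atom lines
#' (`%5d%-5s%5s%5d%8.3f%8.3f%8.3f` with optional velocity columns, which are
#' discarded), and a final box line. Concatenated blocks yield one frame
#' each; frame times are taken from a `t=` tag in the title when present,
#' otherwise numbered 0, 1, 2, ... ps.
#'
#' Only orthorhombic boxes are accepted: a box line with more than three
#' numbers is rejected unless all off-diagonal terms are zero.
#'
#' @param path Path to a `.gro` file.
#' @return A `cg_trajectory` (use `[[1]]` for a single frame).
#' @export
read_gro <- function(path) {
  if (!file.exists(path)) stop("read_gro: no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  frames <- list()
  i <- 1L
  nline <- length(lines)
  frame_no <- 0L
  while (i <= nline) {
    if (!nzchar(trimws(lines[i])) && i == nline) break
    title <- lines[i]
    if (i + 1L > nline) stop("read_gro: truncated file at line ", i, call. = FALSE)
    natoms <- suppressWarnings(as.integer(trimws(lines[i + 1L])))
    if (is.na(natoms) || natoms < 1L) {
      stop("read_gro: invalid atom count at line ", i + 1L, call. = FALSE)
    }
    if (i + 1L + natoms + 1L > nline) {
      stop("read_gro: truncated frame starting at line ", i, call. = FALSE)
    }
    at <- lines[(i + 2L):(i + 1L + natoms)]
    molecule_id <- suppressWarnings(as.integer(substr(at, 1L, 5L)))
    residue_name <- trimws(substr(at, 6L, 10L))
    bead_name <- trimws(substr(at, 11L, 15L))
    x <- suppressWarnings(as.numeric(substr(at, 21L, 28L)))
    y <- suppressWarnings(as.numeric(substr(at, 29L, 36L)))
    z <- suppressWarnings(as.numeric(substr(at, 37L, 44L)))
    bad <- which(is.na(molecule_id) | is.na(x) | is.na(y) | is.na(z))
    if (length(bad)) {
      stop("read_gro: malformed atom line ", i + 1L + bad[1L], call. = FALSE)
    }
    boxnum <- suppressWarnings(as.numeric(strsplit(trimws(lines[i + 2L + natoms]),
                                                   "\\s+")[[1]]))
    if (any(is.na(boxnum)) || !(length(boxnum) %in% c(3L, 9L))) {
      stop("read_gro: malformed box line ", i + 2L + natoms, call. = FALSE)
    }
    if (length(boxnum) == 9L && any(boxnum[4:9] != 0)) {
      stop("read_gro: triclinic box not supported (line ", i + 2L + natoms, ")",
           call. = FALSE)
    }
    tt <- gro_time_from_title(title)
    if (is.na(tt)) tt <- frame_no
    frames[[length(frames) + 1L]] <- cg_frame(
      data.frame(molecule_id = molecule_id, residue_name = residue_name,
                 bead_name = bead_name, x = x, y = y, z = z,
                 stringsAsFactors = FALSE),
      sim_box(boxnum[1], boxnum[2], boxnum[3]), time = tt)
    frame_no <- frame_no + 1L
    i <- i + 3L + natoms
    while (i <= nline && !nzchar(trimws(lines[i]))) i <- i + 1L
  }
  if (!length(frames)) stop("read_gro: empty file: ", path, call. = FALSE)
  counts <- vapply(frames, function(f) nrow(f$atoms), 0L)
  if (length(unique(counts)) != 1L) {
    stop("read_gro: inconsistent bead count across frames (",
         paste(unique(counts), collapse = ", "), ")", call. = FALSE)
  }
  cg_trajectory(frames)
}

#' Write frames to a GRO file
#'
#' Writes the fixed-column GRO layout with coordinates printed at 3 decimals
#' (nm) using `sprintf("%8.3f", .)`, i.e. round-half-away-from-zero as
#' implemented by C `printf`; output is byte-stable for identical input.
#' Velocities are never written. Only orthorhombic boxes are supported.
#'
#' @param trajectory A `cg_trajectory` or single `cg_frame`.
#' @param path Output path.
#' @param title Title line prefix; the frame time is appended as `t= ...`.
#' @return `path`, invisibly.
#' @export
write_gro <- function(trajectory, path, title = "memscope") {
  if (inherits(trajectory, "cg_frame")) trajectory <- cg_trajectory(list(trajectory))
  stopifnot(inherits(trajectory, "cg_trajectory"))
  con <- file(path, "wb")  # binary mode: fixed "\n", byte-stable output
  on.exit(close(con))
  for (fr in trajectory) {
    a <- fr$atoms
    if (!nrow(a)) stop("write_gro: frame has no beads", call. = FALSE)
    L <- unclass(fr$box)
    writeLines(sprintf("%s t= %.3f", title, fr$time), con)
    writeLines(sprintf("%5d", nrow(a)), con)
    # GRO wraps ids at 5 digits
    writeLines(sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                       a$molecule_id %% 100000L,
                       substr(a$residue_name, 1L, 5L),
                       substr(a$bead_name, 1L, 5L),
                       seq_len(nrow(a)) %% 100000L,
                       a$x, a$y, a$z), con)
    writeLines(sprintf("%10.5f%10.5f%10.5f", L[1], L[2], L[3]), con)
  }
  invisible(path)
}
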