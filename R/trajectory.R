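# Trajectories: n_frames x n_atoms x 3 coordinate arrays with a fixed
# timestep in fs. Frame indexing is 0-based in messages (time convention);
# R storage is 1-based as usual.

#' Construct a trajectory
#'
#' @param coords numeric array `n_frames x n_atoms x 3` (Angstrom), or a
#'   single `n_atoms x 3` matrix for a one-frame trajectory.
#' @param dt timestep between frames, fs (> 0).
#' @param atoms optional [structure3d()] or data frame describing the
#'   atoms (one row per atom, in trajectory order).
#' @param superposed logical flag recording whether the frames have been
#'   superposed onto a reference; consumed by [compute_rmsf()] and
#'   [compute_dccm()].
#' @return Object of class `trajectory`: a list with elements `coords`,
#'   `dt`, `atoms`, `superposed`.
#' @export
trajectory <- function(coords, dt, atoms = NULL, superposed = FALSE) {
  if (is.matrix(coords)) coords <- array(coords, c(1L, dim(coords)))
  stopifnot(is.array(coords), length(dim(coords)) == 3L, dim(coords)[3] == 3L)
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0) {
    stop("trajectory: timestep must be a single positive number (fs)")
  }
  if (dim(coords)[1] < 1L) stop("trajectory: need at least one frame")
  if (!all(is.finite(coords))) stop("trajectory: non-finite coordinates")
  if (!is.null(atoms) && nrow(atoms) != dim(coords)[2]) {
    stop("trajectory: atom table has ", nrow(atoms), " rows but frames have ",
         dim(coords)[2], " atoms")
  }
  out <- list(coords = coords, dt = dt, atoms = atoms,
              superposed = isTRUE(superposed))
  class(out) <- "trajectory"
  out
}

#' @export
print.trajectory <- function(x, ...) {
  d <- dim(x$coords)
  cat(sprintf("trajectory: %d frames x %d atoms, dt = %g fs, span = %g fs%s\n",
              d[1], d[2], x$dt, (d[1] - 1) * x$dt,
              if (x$superposed) " (superposed)" else ""))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj a [trajectory()].
#' @return integer.
#' @export
n_frames <- function(traj) dim(traj$coords)[1]

#' Read a multi-frame XYZ trajectory
#'
#' Standard XYZ dialect: for each frame an atom-count line, a comment
#' line, then one `element x y z` line per atom. All frames must have
#' the same atom count; a deviating frame is reported by its 0-based
#' frame index.
#'
#' @param path path to an XYZ file.
#' @param dt timestep between frames, fs.
#' @return A [trajectory()] whose atom table keeps the element symbols.
#' @export
read_xyz_trajectory <- function(path, dt) {
  if (!file.exists(path)) stop("read_xyz_trajectory: file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!(seq_along(lines) == length(lines) & lines == "")]
  if (!length(lines)) stop("read_xyz_trajectory: empty file")
  n_at <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n_at) || n_at < 1L) {
    stop("read_xyz_trajectory: first line is not a positive atom count")
  }
  block <- n_at + 2L
  pos <- 1L
  frames <- list()
  f <- 0L
  while (pos <= length(lines)) {
    cnt <- suppressWarnings(as.integer(trimws(lines[pos])))
    if (is.na(cnt) || cnt != n_at) {
      stop(sprintf("read_xyz_trajectory: frame %d has atom count '%s', expected %d",
                   f, trimws(lines[pos]), n_at), call. = FALSE)
    }
    if (pos + block - 1L > length(lines)) {
      stop(sprintf("read_xyz_trajectory: frame %d is truncated", f), call. = FALSE)
    }
    body <- lines[(pos + 2L):(pos + block - 1L)]
    fields <- strsplit(trimws(body), "[[:space:]]+")
    nf_ok <- vapply(fields, length, integer(1)) >= 4L
    if (!all(nf_ok)) {
      stop(sprintf("read_xyz_trajectory: frame %d: malformed atom line", f),
           call. = FALSE)
    }
    xyz <- t(vapply(fields, function(z) as.numeric(z[2:4]), numeric(3)))
    if (!all(is.finite(xyz))) {
      stop(sprintf("read_xyz_trajectory: frame %d: non-numeric coordinate", f),
           call. = FALSE)
    }
    f <- f + 1L
    frames[[f]] <- xyz
    if (f == 1L) elements <- vapply(fields, `[`, character(1), 1L)
    pos <- pos + block
  }
  coords <- array(0, c(f, n_at, 3L))
  for (k in seq_len(f)) coords[k, , ] <- frames[[k]]
  atoms <- data.frame(name = elements, resname = "UNK",
                      resno = seq_len(n_at), chain = "A",
                      stringsAsFactors = FALSE)
  trajectory(coords, dt = dt, atoms = atoms)
}

#' Write a trajectory as multi-frame XYZ
#'
#' Coordinates are printed with 10 decimal places so that a write/read
#' round trip reproduces them to well below any physically meaningful
#' tolerance.
#'
#' @param traj a [trajectory()].
#' @param path output path.
#' @param digits decimal places for coordinates.
#' @return `path`, invisibly.
#' @export
write_xyz_trajectory <- function(traj, path, digits = 10L) {
  stopifnot(inherits(traj, "trajectory"))
  d <- dim(traj$coords)
  elements <- if (!is.null(traj$atoms)) .element_from_name(traj$atoms$name)
              else rep("C", d[2])
  fmt <- sprintf("%%-3s %%.%df %%.%df %%.%df", digits, digits, digits)
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_len(d[1])) {
    writeLines(as.character(d[2]), con)
    writeLines(sprintf("frame %d", k - 1L), con)
    writeLines(sprintf(fmt, elements,
                       traj$coords[k, , 1], traj$coords[k, , 2],
                       traj$coords[k, , 3]), con)
  }
  invisible(path)
}
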