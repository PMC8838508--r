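# Least-squares rigid-body superposition (Kabsch, via SVD) and the
# fluctuation statistics derived from it.

#' Optimal rigid-body superposition of two point sets
#'
#' Finds the proper rotation `R` and translation `t` minimizing the
#' (optionally weighted) RMSD between `mobile` transformed as
#' `x R^T + t` and `reference`. The SVD sign correction guarantees
#' `det(R) = +1` (no reflection).
#'
#' @param mobile n x 3 matrix of coordinates (Angstrom).
#' @param reference n x 3 matrix, same n.
#' @param weights optional positive weights (e.g. masses); default
#'   uniform. Weights affect the fit and the reported RMSD.
#' @return List of class `kabsch_fit` with `rotation` (3 x 3),
#'   `translation` (length 3) and `rmsd` (Angstrom).
#' @export
kabsch_fit <- function(mobile, reference, weights = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (!identical(dim(mobile), dim(reference)) || ncol(mobile) != 3L) {
    stop("kabsch_fit: inputs must be n x 3 matrices of equal size")
  }
  n <- nrow(mobile)
  if (n < 3L) stop("kabsch_fit: need at least 3 points")
  w <- if (is.null(weights)) rep(1, n) else as.numeric(weights)
  if (length(w) != n || any(w <= 0)) {
    stop("kabsch_fit: weights must be positive, one per point")
  }
  w <- w / sum(w)
  cm <- colSums(mobile * w)
  cr <- colSums(reference * w)
  P <- sweep(mobile, 2, cm)
  Q <- sweep(reference, 2, cr)
  H <- crossprod(P * w, Q)            # 3 x 3 covariance
  sv <- svd(H)
  if (sv$d[2] <= max(sv$d[1], 1) * 1e-12) {
    stop("kabsch_fit: degenerate covariance (collinear points); ",
         "rotation is not unique", call. = FALSE)
  }
  d <- sign(det(tcrossprod(sv$v, sv$u)))
  if (d == 0) d <- 1
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t_vec <- cr - as.numeric(R %*% cm)
  fitted <- tcrossprod(P, R)          # rotated centered mobile
  rmsd <- sqrt(sum(w * rowSums((fitted - Q)^2)))
  out <- list(rotation = R, translation = t_vec, rmsd = rmsd)
  class(out) <- "kabsch_fit"
  out
}

#' Apply a Kabsch transform to coordinates
#' @param fit a [kabsch_fit()].
#' @param x n x 3 coordinate matrix.
#' @return Transformed n x 3 matrix `x R^T + t`.
#' @export
apply_fit <- function(fit, x) {
  sweep(tcrossprod(as.matrix(x), fit$rotation), 2, fit$translation, `+`)
}

#' @export
print.kabsch_fit <- function(x, ...) {
  cat(sprintf("kabsch_fit: rmsd = %.6g A, det(R) = %+.3f\n",
              x$rmsd, det(x$rotation)))
  invisible(x)
}

.ref_coords <- function(reference) {
  if (inherits(reference, "structure3d")) coords3d(reference)
  else as.matrix(reference)
}

#' Superpose every frame of a trajectory onto a reference
#'
#' Each frame gets its own Kabsch fit computed on the selected atoms;
#' non-selected atoms are carried along by the same rigid transform.
#'
#' @param traj a [trajectory()].
#' @param reference a [structure3d()] or coordinate matrix with the same
#'   atom indexing as the trajectory.
#' @param selection integer indices of the atoms used for the fit
#'   (default: all atoms).
#' @param weights optional per-selected-atom weights.
#' @return A new [trajectory()] with `superposed = TRUE`.
#' @export
superpose_trajectory <- function(traj, reference, selection = NULL,
                                 weights = NULL) {
  stopifnot(inherits(traj, "trajectory"))
  ref <- .ref_coords(reference)
  na <- dim(traj$coords)[2]
  if (is.null(selection)) selection <- seq_len(na)
  if (any(selection < 1L | selection > na) || any(selection > nrow(ref))) {
    stop("superpose_trajectory: selection out of range")
  }
  refsel <- ref[selection, , drop = FALSE]
  out <- traj$coords
  for (k in seq_len(dim(out)[1])) {
    frame <- out[k, , , drop = TRUE]
    fit <- kabsch_fit(frame[selection, , drop = FALSE], refsel, weights)
    out[k, , ] <- apply_fit(fit, frame)
  }
  trajectory(out, dt = traj$dt, atoms = traj$atoms, superposed = TRUE)
}

#' Per-frame RMSD of a trajectory against a reference
#'
#' Mass-unweighted RMSD over the selection, by default after per-frame
#' Kabsch superposition on that same selection.
#'
#' @param traj a [trajectory()].
#' @param reference a [structure3d()] or coordinate matrix.
#' @param selection integer atom indices (default all).
#' @param superpose superpose each frame before measuring (default TRUE);
#'   set FALSE to measure raw deviations.
#' @return Object of class `rmsd_series`: data frame with `time` (fs)
#'   and `rmsd` (Angstrom), one row per frame.
#' @export
compute_rmsd_series <- function(traj, reference, selection = NULL,
                                superpose = TRUE) {
  stopifnot(inherits(traj, "trajectory"))
  ref <- .ref_coords(reference)
  na <- dim(traj$coords)[2]
  if (is.null(selection)) selection <- seq_len(na)
  if (any(selection > nrow(ref)) || any(selection > na)) {
    stop("compute_rmsd_series: selection exceeds atom count of trajectory or reference")
  }
  refsel <- ref[selection, , drop = FALSE]
  nf <- dim(traj$coords)[1]
  rmsd <- numeric(nf)
  for (k in seq_len(nf)) {
    framesel <- traj$coords[k, selection, , drop = TRUE]
    if (is.null(dim(framesel))) framesel <- matrix(framesel, ncol = 3)
    if (superpose) {
      rmsd[k] <- kabsch_fit(framesel, refsel)$rmsd
    } else {
      rmsd[k] <- sqrt(mean(rowSums((framesel - refsel)^2)))
    }
  }
  out <- data.frame(time = (seq_len(nf) - 1) * traj$dt, rmsd = rmsd)
  class(out) <- c("rmsd_series", "data.frame")
  out
}

#' Per-site root mean squared fluctuation
#'
#' RMSF_i = sqrt( < |r_i(t) - <r_i>|^2 > ), the fluctuation of each
#' selected site about its mean position over the entire trajectory.
#' The trajectory is expected to have been superposed onto a reference
#' first (see [superpose_trajectory()]); if its `superposed` flag is not
#' set a warning is emitted, since rigid-body motion would inflate the
#' fluctuations.
#'
#' @param traj a [trajectory()] (>= 2 frames).
#' @param selection integer atom indices (default all).
#' @param resno optional residue numbers for the selected sites; taken
#'   from the atom table when available.
#' @param reference_label text recorded in the output (what the frames
#'   were superposed onto).
#' @return Object of class `fluctuation_profile`: data frame with
#'   `resno` and `rmsf` (Angstrom).
#' @export
compute_rmsf <- function(traj, selection = NULL, resno = NULL,
                         reference_label = "trajectory mean") {
  stopifnot(inherits(traj, "trajectory"))
  if (dim(traj$coords)[1] < 2L) stop("compute_rmsf: need at least 2 frames")
  if (!traj$superposed) {
    warning("compute_rmsf: trajectory is not flagged as superposed; ",
            "rigid-body motion will contaminate the RMSF", call. = FALSE)
  }
  na <- dim(traj$coords)[2]
  if (is.null(selection)) selection <- seq_len(na)
  x <- traj$coords[, selection, , drop = FALSE]
  mean_pos <- apply(x, c(2, 3), mean)
  dev2 <- sweep(x, c(2, 3), mean_pos)^2
  rmsf <- sqrt(apply(dev2, 2, mean) * 3)  # mean over frames & axes, times 3
  if (is.null(resno)) {
    resno <- if (!is.null(traj$atoms)) traj$atoms$resno[selection]
             else seq_along(selection)
  }
  out <- data.frame(resno = resno, rmsf = rmsf)
  attr(out, "reference") <- reference_label
  class(out) <- c("fluctuation_profile", "data.frame")
  out
}

#' @export
plot.fluctuation_profile <- function(x, ...) {
  plot(x$resno, x$rmsf, type = "l", xlab = "residue",
       ylab = "RMSF (Å)", ...)
  invisible(x)
}

#' @export
plot.rmsd_series <- function(x, ...) {
  plot(x$time / 1000, x$rmsd, type = "l", xlab = "time (ps)",
       ylab = "RMSD (Å)", ...)
  invisible(x)
}
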