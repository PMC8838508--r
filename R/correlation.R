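# Dynamical cross-correlation maps: normalized covariances of per-site
# displacement vectors, C_ij = <dr_i . dr_j> / sqrt(<dr_i^2><dr_j^2>),
# with displacements taken about each site's mean position over the
# entire trajectory (single pass, no windowing).

#' Dynamical cross-correlation map of a trajectory
#'
#' For each pair of selected sites,
#' `C_ij = <dr_i . dr_j> / (<dr_i^2> <dr_j^2>)^(1/2)`,
#' where `dr_i(t)` is the 3-vector displacement of site i from its mean
#' position over the entire trajectory and `<.>` averages over frames.
#' `C_ij = 1` means fully correlated motion, `-1` fully anticorrelated.
#' The trajectory should be superposed first so rigid-body motion does
#' not masquerade as correlation.
#'
#' @param traj a [trajectory()] with at least 2 frames.
#' @param selection integer atom indices of the sites (default all).
#' @param resno optional residue numbers for labelling; taken from the
#'   atom table when available.
#' @return Object of class `correlation_matrix`: a symmetric matrix with
#'   unit diagonal and entries in `[-1, 1]`, with residue numbers as
#'   dimnames and in `attr(, "resno")`.
#' @export
compute_dccm <- function(traj, selection = NULL, resno = NULL) {
  stopifnot(inherits(traj, "trajectory"))
  nf <- dim(traj$coords)[1]
  if (nf < 2L) stop("compute_dccm: need at least 2 frames")
  if (!traj$superposed) {
    warning("compute_dccm: trajectory is not flagged as superposed; ",
            "rigid-body motion will contaminate the correlations",
            call. = FALSE)
  }
  na <- dim(traj$coords)[2]
  if (is.null(selection)) selection <- seq_len(na)
  ns <- length(selection)
  if (ns < 2L) stop("compute_dccm: need at least 2 sites")
  if (is.null(resno)) {
    resno <- if (!is.null(traj$atoms)) traj$atoms$resno[selection]
             else seq_len(ns)
  }
  # covariance of displacement vectors, summed over the 3 axes
  num <- matrix(0, ns, ns)
  for (a in 1:3) {
    D <- traj$coords[, selection, a, drop = TRUE]
    if (is.null(dim(D))) D <- matrix(D, nrow = nf)
    D <- sweep(D, 2, colMeans(D))
    num <- num + crossprod(D) / nf
  }
  v <- diag(num)
  zero_var <- v <= 0 | !is.finite(v)
  if (any(zero_var)) {
    stop("compute_dccm: zero displacement variance at residue(s) ",
         paste(resno[zero_var], collapse = ", "),
         "; correlation undefined", call. = FALSE)
  }
  C <- num / sqrt(tcrossprod(v))
  C <- (C + t(C)) / 2
  diag(C) <- 1
  C <- pmin(pmax(C, -1), 1)
  dimnames(C) <- list(resno, resno)
  attr(C, "resno") <- resno
  class(C) <- c("correlation_matrix", "matrix")
  C
}

#' Difference of two cross-correlation maps
#'
#' Element-wise `dC = C_modified - C_wildtype`; positive entries are
#' couplings gained upon modification under the stored
#' `"modified - WT"` convention. Swapping the arguments negates every
#' entry.
#'
#' @param modified,wildtype two `correlation_matrix` objects over the
#'   same residues.
#' @return Object of class `difference_matrix` with zero diagonal and
#'   entries in `[-2, 2]`; the sign convention is kept in
#'   `attr(, "convention")`.
#' @export
compute_delta_dccm <- function(modified, wildtype) {
  stopifnot(inherits(modified, "correlation_matrix"),
            inherits(wildtype, "correlation_matrix"))
  rm_ <- attr(modified, "resno"); rw <- attr(wildtype, "resno")
  if (!identical(dim(modified), dim(wildtype)) || !identical(rm_, rw)) {
    bad <- union(setdiff(rm_, rw), setdiff(rw, rm_))
    stop("compute_delta_dccm: residue indexing differs between maps",
         if (length(bad)) paste0(" (offending residues: ",
                                 paste(bad, collapse = ", "), ")") else "",
         call. = FALSE)
  }
  D <- unclass(modified) - unclass(wildtype)
  diag(D) <- 0
  attr(D, "resno") <- rm_
  attr(D, "convention") <- "modified - WT"
  class(D) <- c("difference_matrix", "matrix")
  D
}

#' Mask sub-threshold entries of a correlation or difference map
#'
#' Display-only semantics: entries with `|value| <= cutoff` are replaced
#' by `NA`, surviving values are untouched. The survivor count tallies
#' unordered off-diagonal pairs with `|value| > cutoff` (strict
#' inequality, so a value exactly at the cutoff is masked).
#'
#' @param m a `correlation_matrix`, `difference_matrix`, or plain
#'   symmetric matrix.
#' @param cutoff non-negative threshold (default 0.25).
#' @return List of class `threshold_mask` with `masked` (matrix with NA
#'   below threshold), `count` (unordered surviving pairs, diagonal
#'   excluded) and `cutoff`.
#' @export
threshold_mask <- function(m, cutoff = 0.25) {
  if (!is.matrix(unclass(m)) || !is.numeric(cutoff) || cutoff < 0) {
    stop("threshold_mask: need a numeric matrix and a cutoff >= 0")
  }
  v <- unclass(m)
  masked <- v
  masked[abs(v) <= cutoff] <- NA_real_
  off <- abs(v) > cutoff
  diag(off) <- FALSE
  count <- sum(off[upper.tri(off)])
  out <- list(masked = masked, count = count, cutoff = cutoff)
  class(out) <- "threshold_mask"
  out
}

#' @export
print.threshold_mask <- function(x, ...) {
  cat(sprintf("threshold_mask: |value| > %g, %d surviving pair(s)\n",
              x$cutoff, x$count))
  invisible(x)
}

#' Extract contiguous feature blocks from a difference map
#'
#' Cells of the strict upper triangle with `|dC| > cutoff` are grouped
#' into 8-connected components (horizontally, vertically and diagonally
#' adjacent cells belong to one feature). Each component is reported as
#' the bounding residue ranges of its rows and columns, the sign of its
#' extremal entry, and the extremal `|dC|`. Components are sorted by
#' extremal value, descending. Only the upper triangle is scanned so a
#' symmetric feature is reported once.
#'
#' @param delta a `difference_matrix` (or symmetric matrix with a
#'   `resno` attribute).
#' @param cutoff threshold (default 0.25, strict `>`).
#' @return Data frame of class `feature_blocks` with columns
#'   `row_start`, `row_end`, `col_start`, `col_end` (residue numbers),
#'   `sign` (+1/-1), `extremal` (max |dC| in the block) and `n_cells`.
#'   Zero rows when nothing survives.
#' @export
extract_feature_blocks <- function(delta, cutoff = 0.25) {
  v <- unclass(delta)
  stopifnot(is.matrix(v), nrow(v) == ncol(v))
  resno <- attr(delta, "resno")
  if (is.null(resno)) resno <- seq_len(nrow(v))
  n <- nrow(v)
  alive <- abs(v) > cutoff
  alive[lower.tri(alive, diag = TRUE)] <- FALSE
  empty <- data.frame(row_start = integer(0), row_end = integer(0),
                      col_start = integer(0), col_end = integer(0),
                      sign = integer(0), extremal = numeric(0),
                      n_cells = integer(0))
  class(empty) <- c("feature_blocks", "data.frame")
  if (!any(alive)) return(empty)
  comp <- matrix(0L, n, n)
  cur <- 0L
  cells <- which(alive, arr.ind = TRUE)
  for (s in seq_len(nrow(cells))) {
    i0 <- cells[s, 1]; j0 <- cells[s, 2]
    if (comp[i0, j0] != 0L) next
    cur <- cur + 1L
    queue <- list(c(i0, j0))
    comp[i0, j0] <- cur
    while (length(queue)) {
      cij <- queue[[length(queue)]]
      queue[[length(queue)]] <- NULL
      for (di in -1:1) for (dj in -1:1) {
        if (di == 0L && dj == 0L) next
        ii <- cij[1] + di; jj <- cij[2] + dj
        if (ii < 1L || jj < 1L || ii > n || jj > n) next
        if (alive[ii, jj] && comp[ii, jj] == 0L) {
          comp[ii, jj] <- cur
          queue[[length(queue) + 1L]] <- c(ii, jj)
        }
      }
    }
  }
  rows <- lapply(seq_len(cur), function(k) {
    cc <- which(comp == k, arr.ind = TRUE)
    vals <- v[comp == k]
    ext_i <- which.max(abs(vals))
    data.frame(row_start = resno[min(cc[, 1])], row_end = resno[max(cc[, 1])],
               col_start = resno[min(cc[, 2])], col_end = resno[max(cc[, 2])],
               sign = as.integer(sign(vals[ext_i])),
               extremal = abs(vals[ext_i]),
               n_cells = nrow(cc))
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$extremal), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("feature_blocks", "data.frame")
  out
}

#' Write a correlation or difference matrix as CSV
#'
#' Residue numbers form the header row and first column.
#'
#' @param m matrix with a `resno` attribute.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_correlation_csv <- function(m, path) {
  v <- unclass(m)
  resno <- attr(m, "resno")
  if (is.null(resno)) resno <- seq_len(nrow(v))
  df <- data.frame(resno = resno, v, check.names = FALSE)
  names(df) <- c("resno", resno)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a correlation matrix written by [write_correlation_csv()]
#' @param path CSV path.
#' @param class_ class to assign (`"correlation_matrix"` or
#'   `"difference_matrix"`).
#' @return The matrix with its `resno` attribute restored.
#' @export
read_correlation_csv <- function(path, class_ = "correlation_matrix") {
  df <- read.csv(path, check.names = FALSE)
  resno <- as.integer(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  dimnames(m) <- list(resno, resno)
  attr(m, "resno") <- resno
  class(m) <- c(class_, "matrix")
  m
}

#' @export
plot.correlation_matrix <- function(x, cutoff = NULL, ...) {
  v <- unclass(x)
  if (!is.null(cutoff)) v[abs(v) <= cutoff] <- NA
  resno <- attr(x, "resno")
  image(resno, resno, t(v), zlim = c(-1, 1),
        col = grDevices::hcl.colors(64, "Blue-Red 3"),
        xlab = "residue", ylab = "residue", ...)
  invisible(x)
}
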