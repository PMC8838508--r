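test_that("perfectly shared and mirrored displacement series give C = +1 / -1", {
  set.seed(5)
  nf <- 100
  base <- matrix(rnorm(nf * 3), nf, 3)
  coords <- array(0, c(nf, 3, 3))
  coords[, 1, ] <- base
  coords[, 2, ] <- base + 5           # same displacements, offset site
  coords[, 3, ] <- -base              # mirrored
  tr <- trajectory(coords, dt = 5, superposed = TRUE)
  C <- compute_dccm(tr)
  expect_equal(unclass(C)[1, 2], 1, tolerance = 1e-12)
  expect_equal(unclass(C)[1, 3], -1, tolerance = 1e-12)
  expect_equal(unclass(C), t(unclass(C)))
  expect_equal(diag(unclass(C)), rep(1, 3), ignore_attr = TRUE)
})

test_that("the vectorized DCCM equals the naive double-loop oracle", {
  set.seed(11)
  nf <- 100; ns <- 10
  coords <- array(rnorm(nf * ns * 3, sd = 0.5), c(nf, ns, 3))
  tr <- trajectory(coords, dt = 5, superposed = TRUE)
  expect_equal(unclass(compute_dccm(tr)), naive_dccm(coords),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("a zero-variance site is reported by residue number", {
  coords <- array(rnorm(10 * 3 * 3), c(10, 3, 3))
  coords[, 2, ] <- 1.5                # frozen site
  tr <- trajectory(coords, dt = 5, superposed = TRUE)
  expect_error(compute_dccm(tr), "zero displacement variance.*2")
})

test_that("difference maps are antisymmetric in their arguments and exactly zero for identical inputs", {
  R <- block_correlation(8, 1:2, 5:6, 0.5)
  ta <- generate_correlated_trajectory(R, n_frames = 400, seed = 1)
  tb <- generate_correlated_trajectory(R, n_frames = 400, seed = 2)
  Ca <- compute_dccm(ta); Cb <- compute_dccm(tb)
  expect_true(all(unclass(compute_delta_dccm(Ca, Ca)) == 0))
  d_ab <- compute_delta_dccm(Ca, Cb)
  d_ba <- compute_delta_dccm(Cb, Ca)
  expect_equal(unclass(d_ab), -unclass(d_ba), tolerance = 0)
  expect_equal(attr(d_ab, "convention"), "modified - WT")
  expect_true(all(diag(unclass(d_ab)) == 0))
})

test_that("mismatched residue indexing is an alignment error", {
  R <- diag(4)
  Ca <- compute_dccm(generate_correlated_trajectory(R, n_frames = 50, seed = 1))
  Cb <- Ca
  attr(Cb, "resno") <- c(1L, 2L, 3L, 9L)
  expect_error(compute_delta_dccm(Ca, Cb), "residue indexing.*9")
})

test_that("threshold masking uses strict inequality and counts unordered pairs", {
  m <- diag(4)
  vals <- c(0.3, 0.2, -0.4, 0.1, 0.25, -0.2)
  m[upper.tri(m)] <- vals
  m <- m + t(m) - diag(diag(m))
  attr(m, "resno") <- 1:4
  class(m) <- c("correlation_matrix", "matrix")
  tm <- threshold_mask(m, cutoff = 0.25)
  expect_equal(tm$count, 2L)          # only 0.3 and -0.4 survive; 0.25 is masked
  surv <- tm$masked[upper.tri(tm$masked)]
  expect_equal(sort(surv[!is.na(surv)]), c(-0.4, 0.3))
  # masking is display-only: surviving values are unaltered
  expect_identical(tm$masked[abs(unclass(m)) > 0.25], unclass(m)[abs(unclass(m)) > 0.25])

  expect_equal(threshold_mask(m, 0)$count, sum(vals != 0))
  expect_equal(threshold_mask(m, 1)$count, 0L)
})

test_that("feature extraction recovers planted blocks with sign and bounds", {
  n <- 30
  D <- matrix(0, n, n)
  D[5:9, 15:18] <- 0.5                 # 5 x 4 positive block
  D <- D + t(D)
  attr(D, "resno") <- seq_len(n)
  class(D) <- c("difference_matrix", "matrix")
  fb <- extract_feature_blocks(D, cutoff = 0.25)
  expect_equal(nrow(fb), 1L)
  expect_equal(fb$row_start, 5); expect_equal(fb$row_end, 9)
  expect_equal(fb$col_start, 15); expect_equal(fb$col_end, 18)
  expect_equal(fb$sign, 1L)
  expect_equal(fb$extremal, 0.5)
  expect_equal(fb$n_cells, 20L)

  # all-zero map: empty list
  Z <- matrix(0, n, n)
  attr(Z, "resno") <- seq_len(n)
  class(Z) <- c("difference_matrix", "matrix")
  expect_equal(nrow(extract_feature_blocks(Z)), 0L)

  # two disjoint blocks of opposite sign, sorted by extremal value
  D2 <- matrix(0, n, n)
  D2[3:5, 10:12] <- -0.6
  D2[20:22, 26:28] <- 0.4
  D2 <- D2 + t(D2)
  attr(D2, "resno") <- seq_len(n)
  class(D2) <- c("difference_matrix", "matrix")
  fb2 <- extract_feature_blocks(D2, cutoff = 0.25)
  expect_equal(nrow(fb2), 2L)
  expect_equal(fb2$sign, c(-1L, 1L))
  expect_equal(fb2$extremal, c(0.6, 0.4))
  expect_equal(fb2$row_start, c(3, 20))
  expect_equal(fb2$col_end, c(12, 28))
})

test_that("diagonally adjacent super-threshold cells join into one 8-connected feature", {
  n <- 10
  D <- matrix(0, n, n)
  D[2, 5] <- 0.5; D[3, 6] <- 0.5      # touch only diagonally
  D <- D + t(D)
  attr(D, "resno") <- seq_len(n)
  class(D) <- c("difference_matrix", "matrix")
  fb <- extract_feature_blocks(D)
  expect_equal(nrow(fb), 1L)
  expect_equal(fb$n_cells, 2L)
})

test_that("correlation matrices survive a CSV round trip with residue labels", {
  R <- block_correlation(6, 1:2, 4:5, 0.4)
  C <- compute_dccm(generate_correlated_trajectory(R, n_frames = 200, seed = 4))
  path <- withr::local_tempfile(fileext = ".csv")
  write_correlation_csv(C, path)
  back <- read_correlation_csv(path)
  expect_equal(unclass(back), unclass(C), tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(attr(back, "resno"), attr(C, "resno"))
})
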