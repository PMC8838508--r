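test_that("mean removal kills the ACF of a constant dipole", {
  mu <- matrix(rep(c(1.5, -0.7, 2.2), each = 64), 64, 3)
  acf <- dipole_acf(dipole_series(mu, dt = 5), max_lag = 100)
  expect_true(all(abs(acf$values) < 1e-12))
})

test_that("the FFT ACF estimator equals the direct double loop", {
  set.seed(13)
  for (n in c(100, 512)) {
    mu <- matrix(rnorm(n * 3), n, 3)
    series <- dipole_series(mu, dt = 2)
    got <- dipole_acf(series, max_lag = (n - 1) * 2 / 2)
    want <- naive_dipole_acf(mu, length(got$lags))
    expect_equal(got$values, want, tolerance = 1e-10)
  }
})

test_that("a cosine dipole has the analytic ACF (A^2/2) cos(omega tau)", {
  dt <- 5
  periods <- 200
  omega <- 2 * pi / (100 * dt)            # period of 100 samples
  n <- 100 * periods
  A <- 1.3
  t <- (seq_len(n) - 1) * dt
  mu <- cbind(A * cos(omega * t), 0, 0)
  acf <- dipole_acf(dipole_series(mu, dt), max_lag = 50 * dt)
  expected <- (A^2 / 2) * cos(omega * acf$lags)
  expect_lt(max(abs(acf$values - expected)), A^2 / 50)
})

test_that("the biased estimator keeps |C(tau)| <= C(0)", {
  set.seed(3)
  for (k in 1:5) {
    mu <- matrix(rnorm(300 * 3, sd = runif(1, 0.1, 3)), 300, 3)
    acf <- dipole_acf(dipole_series(mu, dt = 1), max_lag = 299)
    expect_true(all(abs(acf$values) <= acf$values[1] + 1e-12))
  }
})

test_that("quantum correction factor has the right limits, values, and monotonicity", {
  expect_equal(quantum_correction(0, 300), 1, tolerance = 1e-12)
  expect_equal(quantum_correction(1e-8, 300), 1, tolerance = 1e-6)
  # x = 1 at nu = T / (hc/kB)
  nu_x1 <- 300 / pd_constants$hc_over_kB   # ~208.5 cm^-1 at 300 K
  expect_equal(quantum_correction(nu_x1, 300), 1 / (1 - exp(-1)),
               tolerance = 1e-10)
  # high-frequency limit: factor ~ x
  q2100 <- quantum_correction(2100, 300)
  x2100 <- pd_constants$hc_over_kB * 2100 / 300
  expect_equal(q2100, x2100, tolerance = 1e-4)
  expect_equal(x2100, 10.07, tolerance = 1e-3)

  nus <- seq(0, 4000, by = 10)
  q <- quantum_correction(nus, 300)
  expect_true(all(q >= 1))
  expect_true(all(diff(q) > 0))                 # increasing in wavenumber
  temps <- seq(100, 600, by = 25)
  qt <- vapply(temps, function(T) quantum_correction(1000, T), numeric(1))
  expect_true(all(diff(qt) < 0))                # decreasing in temperature
})

test_that("a windowed cosine ACF peaks at its own frequency within one grid bin", {
  dt <- 5
  nu0 <- 150                                     # cm^-1
  omega <- 2 * pi * nu0 * pd_constants$c_cm_fs   # rad/fs
  lags <- (0:2047) * dt
  acf <- structure(list(lags = lags, values = 0.5 * cos(omega * lags), dt = dt),
                   class = "dipole_acf")
  spec <- ir_spectrum(acf, temperature = 300, zero_pad = 4)
  pk <- peak_metrics(spec, c(50, 250))
  expect_lt(abs(pk$wavenumber_max - nu0), attr(spec, "resolution"))
})

test_that("doubling the covered time halves the wavenumber grid spacing", {
  dt <- 5
  mk <- function(n) structure(list(lags = (seq_len(n) - 1) * dt,
                                   values = exp(-(seq_len(n) - 1) / 50), dt = dt),
                              class = "dipole_acf")
  r1 <- attr(ir_spectrum(mk(512), zero_pad = 4), "resolution")
  r2 <- attr(ir_spectrum(mk(1024), zero_pad = 4), "resolution")
  expect_equal(r1 / r2, 2)
})

test_that("the spectroscopy chain is linear: scaling the dipole by a scales intensity by a^2", {
  set.seed(4)
  mu <- matrix(rnorm(400 * 3), 400, 3)
  s1 <- ir_spectrum(dipole_acf(dipole_series(mu, dt = 5)))
  s3 <- ir_spectrum(dipole_acf(dipole_series(3 * mu, dt = 5)))
  expect_equal(s3$intensity, 9 * s1$intensity, tolerance = 1e-10)
})

test_that("degenerate ACFs are handled per contract", {
  zero <- structure(list(lags = (0:63) * 5, values = numeric(64), dt = 5),
                    class = "dipole_acf")
  spec <- ir_spectrum(zero)
  expect_true(all(spec$intensity == 0))
  bad <- structure(list(lags = (0:63) * 5, values = c(NaN, numeric(63)), dt = 5),
                   class = "dipole_acf")
  expect_error(ir_spectrum(bad), "NaN")
})

test_that("Parseval holds for the windowed, padded ACF before quantum correction", {
  set.seed(6)
  vals <- rnorm(256)
  y <- c(vals * blackman_window(256), numeric(3 * 256))
  F <- fft(y)
  expect_equal(sum(y^2), sum(Mod(F)^2) / length(y), tolerance = 1e-8)
})

test_that("peak metrics: Lorentzian FWHM, delta-peak convention, exact shift", {
  # Lorentzian of half-width gamma on a fine grid -> FWHM = 2 gamma
  dnu <- 0.25; gam <- 12
  wn <- seq(0, 400, by = dnu)
  I <- gam^2 / ((wn - 200)^2 + gam^2)
  spec <- structure(data.frame(wavenumber = wn, intensity = I),
                    class = c("ir_spectrum", "data.frame"),
                    resolution = dnu, window = "none", temperature = 300)
  pk <- peak_metrics(spec, c(100, 300))
  expect_equal(pk$wavenumber_max, 200, tolerance = 0.01)
  expect_equal(pk$fwhm, 2 * gam, tolerance = 0.01 * 2 * gam)

  # single-bin delta peak: FWHM equals one grid spacing by convention
  I2 <- numeric(length(wn)); I2[801] <- 1
  spec2 <- structure(data.frame(wavenumber = wn, intensity = I2),
                     class = c("ir_spectrum", "data.frame"),
                     resolution = dnu, window = "none", temperature = 300)
  pk2 <- peak_metrics(spec2, c(100, 300))
  expect_equal(pk2$fwhm, dnu, tolerance = 1e-10)

  # translated spectrum: peak position moves by exactly the shift
  shift_bins <- 40
  I3 <- c(numeric(shift_bins), I[seq_len(length(I) - shift_bins)])
  spec3 <- structure(data.frame(wavenumber = wn, intensity = I3),
                     class = c("ir_spectrum", "data.frame"),
                     resolution = dnu, window = "none", temperature = 300)
  pk3 <- peak_metrics(spec3, c(100, 350))
  expect_equal(pk3$wavenumber_max - pk$wavenumber_max, shift_bins * dnu,
               tolerance = 1e-6)

  # monotone band: no interior maximum is an error
  expect_error(peak_metrics(spec, c(250, 350)), "no interior maximum")
})

test_that("dipole series round-trip through CSV", {
  set.seed(1)
  s <- dipole_series(matrix(rnorm(30), 10, 3), dt = 5, label = "test")
  path <- withr::local_tempfile(fileext = ".csv")
  write_dipole_csv(s, path)
  back <- read_dipole_csv(path)
  expect_equal(back$values, s$values, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(back$dt, 5)
})
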