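# Infrared spectra from the Fourier transform of the dipole-moment
# autocorrelation function: C(t) = <mu(0) . mu(t)>, Blackman-windowed,
# FFT'd, and multiplied by the harmonic quantum correction factor
# beta*hbar*omega / (1 - exp(-beta*hbar*omega)).

#' Construct a dipole-moment time series
#'
#' @param values n x 3 numeric matrix of dipole vectors (e*A or Debye —
#'   declare in `label`; the spectral shape is unit-independent).
#' @param dt sampling interval, fs.
#' @param label free-text provenance/units tag.
#' @return Object of class `dipole_series`.
#' @export
dipole_series <- function(values, dt, label = "") {
  values <- as.matrix(values)
  stopifnot(ncol(values) == 3L, nrow(values) >= 2L, dt > 0)
  if (!all(is.finite(values))) stop("dipole_series: non-finite components")
  out <- list(values = values, dt = dt, label = label)
  class(out) <- "dipole_series"
  out
}

#' @export
print.dipole_series <- function(x, ...) {
  cat(sprintf("dipole_series: %d samples, dt = %g fs, span = %g fs [%s]\n",
              nrow(x$values), x$dt, (nrow(x$values) - 1) * x$dt, x$label))
  invisible(x)
}

#' Read a dipole series from CSV (`t_fs, mux, muy, muz`)
#' @param path CSV path; the timestep is taken from the time column.
#' @return A [dipole_series()].
#' @export
read_dipole_csv <- function(path) {
  df <- read.csv(path)
  if (ncol(df) < 4L) stop("read_dipole_csv: need columns t_fs, mux, muy, muz")
  dt <- diff(df[[1]][1:2])
  dipole_series(as.matrix(df[, 2:4]), dt = dt, label = path)
}

#' Write a dipole series as CSV
#' @param series a [dipole_series()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dipole_csv <- function(series, path) {
  df <- data.frame(t_fs = (seq_len(nrow(series$values)) - 1) * series$dt,
                   mux = series$values[, 1], muy = series$values[, 2],
                   muz = series$values[, 3])
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Autocorrelation function of a dipole series
#'
#' `C(tau) = < mu(t) . mu(t + tau) >`, averaged over time origins with
#' the FFT-based estimator and *biased* normalization (divide by N for
#' every lag), which keeps the estimator positive semi-definite and
#' guarantees `|C(tau)| <= C(0)`. The static mean dipole is removed
#' first so the zero-frequency artifact does not dwarf the far-infrared
#' region of the spectrum.
#'
#' @param series a [dipole_series()].
#' @param max_lag maximum lag, fs; default one quarter of the series
#'   span (variance control).
#' @return Object of class `dipole_acf`: list with `lags` (fs),
#'   `values` (units of mu^2) and `dt`.
#' @export
dipole_acf <- function(series, max_lag = NULL) {
  stopifnot(inherits(series, "dipole_series"))
  n <- nrow(series$values)
  span <- (n - 1) * series$dt
  if (is.null(max_lag)) max_lag <- span / 4
  if (max_lag > span + 1e-9) {
    stop(sprintf("dipole_acf: max_lag %g fs exceeds series span %g fs",
                 max_lag, span), call. = FALSE)
  }
  n_lags <- floor(max_lag / series$dt) + 1L
  x <- sweep(series$values, 2, colMeans(series$values))
  m <- stats::nextn(2L * n, 2L)
  acf_sum <- numeric(n_lags)
  for (a in 1:3) {
    pad <- c(x[, a], numeric(m - n))
    F <- fft(pad)
    r <- Re(fft(Mod(F)^2, inverse = TRUE)) / m
    acf_sum <- acf_sum + r[seq_len(n_lags)]
  }
  out <- list(lags = (seq_len(n_lags) - 1L) * series$dt,
              values = acf_sum / n, dt = series$dt)
  class(out) <- "dipole_acf"
  out
}

#' @export
print.dipole_acf <- function(x, ...) {
  cat(sprintf("dipole_acf: %d lags up to %g fs, C(0) = %.4g\n",
              length(x$lags), max(x$lags), x$values[1]))
  invisible(x)
}

#' Blackman taper for a one-sided lag window
#'
#' Classic 3-term Blackman coefficients (0.42, 0.5, 0.08; alpha = 0.16)
#' evaluated on the half window: value 1 at lag 0, falling to 0 at the
#' last lag.
#'
#' @param n number of lags.
#' @return Numeric vector of length `n`.
#' @export
blackman_window <- function(n) {
  stopifnot(n >= 1L)
  if (n == 1L) return(1)
  k <- seq_len(n) - 1L
  0.42 + 0.5 * cos(pi * k / (n - 1L)) + 0.08 * cos(2 * pi * k / (n - 1L))
}

#' Harmonic quantum correction factor
#'
#' `Q(nu, T) = x / (1 - exp(-x))` with `x = beta hbar omega =
#' (h c / kB T) nu`, applied to a classical spectral density to
#' approximate the quantum lineshape. The removable singularity at
#' `nu = 0` is handled explicitly (`Q -> 1`). The factor is >= 1,
#' increases with wavenumber at fixed temperature and decreases with
#' temperature at fixed wavenumber.
#'
#' @param wavenumber cm^-1 (vectorized, >= 0).
#' @param temperature K (> 0).
#' @return Dimensionless factor(s).
#' @export
quantum_correction <- function(wavenumber, temperature) {
  if (temperature <= 0) stop("quantum_correction: temperature must be positive")
  if (any(wavenumber < 0)) stop("quantum_correction: wavenumber must be >= 0")
  x <- pd_constants$hc_over_kB * wavenumber / temperature
  out <- ifelse(x == 0, 1, x / (-expm1(-x)))
  as.numeric(out)
}

#' Infrared spectrum from a dipole autocorrelation function
#'
#' The ACF is multiplied by the Blackman taper over `[0, max lag]`,
#' zero-padded by `zero_pad`, Fourier transformed, and the real part is
#' multiplied per bin by [quantum_correction()]. The wavenumber grid has
#' spacing `1 / (c N dt)` for `N` retained (padded) lags; doubling the
#' covered time halves the spacing. No additional omega^2 prefactor is
#' applied.
#'
#' @param acf a [dipole_acf()].
#' @param temperature K, for the quantum correction (default 300).
#' @param zero_pad integer zero-padding factor (default 4).
#' @param normalize `"none"` (default) or `"max"` (peak intensity 1).
#' @return Object of class `ir_spectrum`: data frame with `wavenumber`
#'   (cm^-1, up to the Nyquist limit) and `intensity` (arbitrary
#'   units); attributes `window`, `temperature`, `resolution`.
#' @export
ir_spectrum <- function(acf, temperature = 300, zero_pad = 4L,
                        normalize = c("none", "max")) {
  stopifnot(inherits(acf, "dipole_acf"), zero_pad >= 1L)
  normalize <- match.arg(normalize)
  if (any(!is.finite(acf$values))) stop("ir_spectrum: NaN/Inf in ACF values")
  nl <- length(acf$values)
  y <- acf$values * blackman_window(nl)
  np <- as.integer(zero_pad) * nl
  y <- c(y, numeric(np - nl))
  F <- fft(y)
  n_keep <- np %/% 2 + 1L
  dnu <- 1 / (pd_constants$c_cm_fs * np * acf$dt)
  wavenumber <- (seq_len(n_keep) - 1L) * dnu
  intensity <- Re(F)[seq_len(n_keep)] * quantum_correction(wavenumber, temperature)
  if (normalize == "max" && max(abs(intensity)) > 0) {
    intensity <- intensity / max(intensity)
  }
  out <- data.frame(wavenumber = wavenumber, intensity = intensity)
  attr(out, "window") <- "blackman"
  attr(out, "temperature") <- temperature
  attr(out, "resolution") <- dnu
  class(out) <- c("ir_spectrum", "data.frame")
  out
}

#' @export
plot.ir_spectrum <- function(x, ...) {
  plot(x$wavenumber, x$intensity, type = "l",
       xlab = expression(tilde(nu) ~ (cm^-1)), ylab = "intensity (arb.)", ...)
  invisible(x)
}

#' Peak position and FWHM within a spectral band
#'
#' The maximum-intensity bin inside `band` is refined by 3-point
#' parabolic interpolation; the full width at half maximum comes from
#' linear interpolation of the half-maximum crossings on either side of
#' the peak. A delta-like single-bin peak therefore reports an FWHM of
#' one grid spacing. A band with no interior local maximum (monotone
#' intensity) is an error.
#'
#' @param spectrum an [ir_spectrum()].
#' @param band numeric(2): wavenumber window (cm^-1) inside the grid.
#' @return List with `wavenumber_max` (cm^-1) and `fwhm` (cm^-1; NA
#'   with a warning if a half-maximum crossing lies outside the grid).
#' @export
peak_metrics <- function(spectrum, band) {
  stopifnot(inherits(spectrum, "ir_spectrum"), length(band) == 2L)
  band <- sort(band)
  wn <- spectrum$wavenumber
  if (band[1] < min(wn) || band[2] > max(wn)) {
    stop("peak_metrics: band outside the spectral grid")
  }
  idx <- which(wn >= band[1] & wn <= band[2])
  if (length(idx) < 3L) stop("peak_metrics: band narrower than 3 grid points")
  I <- spectrum$intensity
  k <- idx[which.max(I[idx])]
  if (k == idx[1] || k == idx[length(idx)]) {
    stop("peak_metrics: no interior maximum in band (monotone intensity)",
         call. = FALSE)
  }
  dnu <- attr(spectrum, "resolution")
  # parabolic refinement
  y1 <- I[k - 1]; y2 <- I[k]; y3 <- I[k + 1]
  denom <- y1 - 2 * y2 + y3
  delta <- if (abs(denom) > 0) 0.5 * (y1 - y3) / denom else 0
  delta <- max(-0.5, min(0.5, delta))
  nu_max <- wn[k] + delta * dnu
  peak_height <- y2 - 0.25 * (y1 - y3) * delta
  half <- peak_height / 2
  cross <- function(dir) {
    j <- k
    repeat {
      jn <- j + dir
      if (jn < 1L || jn > length(I)) return(NA_real_)
      if (I[jn] < half) {
        frac <- (I[j] - half) / (I[j] - I[jn])
        return(wn[j] + dir * frac * dnu)
      }
      j <- jn
    }
  }
  lo <- cross(-1L); hi <- cross(+1L)
  if (is.na(lo) || is.na(hi)) {
    warning("peak_metrics: half-maximum crossing outside the grid; FWHM is NA",
            call. = FALSE)
    fwhm <- NA_real_
  } else {
    fwhm <- hi - lo
  }
  list(wavenumber_max = nu_max, fwhm = fwhm)
}

#' Write a spectrum as CSV (`wavenumber_cm.1, intensity`)
#' @param spectrum an [ir_spectrum()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_spectrum_csv <- function(spectrum, path) {
  df <- data.frame(wavenumber_cm.1 = spectrum$wavenumber,
                   intensity = spectrum$intensity)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
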