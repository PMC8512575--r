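#' Clutter profile from the field-free window
#'
#' Estimates the static clutter (antenna crosstalk, mold reflections) of one
#' channel by averaging the IRFs over the observation-time window in which the
#' PMF is off, excluding ramp-flagged samples.
#'
#' @param r A `radargram`.
#' @return An object of class `clutter_profile` with the t axis, the mean IRF
#'   and the number of OFF-window samples used.
#' @export
estimate_clutter <- function(r) {
  stopifnot(inherits(r, "radargram"))
  idx <- which(r$pmf$state == "off" & !r$pmf$ramp & r$pmf$H == 0)
  if (length(idx) == 0) stop("no field-free (OFF, non-ramp) samples to average")
  structure(list(t = r$t,
                 mean = rowMeans(r$values[, idx, drop = FALSE]),
                 n_off = length(idx)),
            class = "clutter_profile")
}

#' Clutter-removed differential radargram
#'
#' Subtracts the OFF-window mean IRF column by column from the raw radargram:
#' `dy(t, T) = y(t, T) - ybar(t)`.
#'
#' @param r A `radargram`.
#' @param clutter A [estimate_clutter()] profile (computed from `r` when
#'   missing).
#' @return An object of class `diff_radargram` (same layout as `radargram`).
#' @export
remove_clutter <- function(r, clutter = estimate_clutter(r)) {
  stopifnot(inherits(r, "radargram"), inherits(clutter, "clutter_profile"))
  if (length(clutter$t) != length(r$t) || any(clutter$t != r$t))
    stop("clutter profile and radargram have mismatched t axes")
  structure(list(tx = r$tx, rx = r$rx, t = r$t, T = r$T,
                 values = r$values - clutter$mean, pmf = r$pmf),
            class = c("diff_radargram", "radargram"))
}

.analysis_window <- function(d) {
  # the modulation analysis window: ON plateaus for two-state modulation,
  # the sinusoid block otherwise; ramp samples excluded
  idx <- which(d$pmf$state == "on" & !d$pmf$ramp)
  if (length(idx) == 0) idx <- which(d$pmf$state == "sin" & !d$pmf$ramp)
  idx
}

#' Mean differential MNP signal
#'
#' Per-t mean of the clutter-removed radargram over the modulation (ON)
#' window, excluding ramp samples: the time-domain MNP response used as the
#' delay-and-sum input in the two-state scenario.
#'
#' @param d A `diff_radargram`.
#' @return An object of class `irf_signal` with fields `t` and `values`.
#' @export
mean_differential <- function(d) {
  stopifnot(inherits(d, "diff_radargram"))
  idx <- .analysis_window(d)
  if (length(idx) == 0) stop("no modulation-window (ON) samples to average")
  structure(list(t = d$t, values = rowMeans(d$values[, idx, drop = FALSE])),
            class = "irf_signal")
}

#' Observation-time spectrum of a differential radargram
#'
#' Discrete Fourier transform along observation time T over the analysis
#' window, per propagation-time bin, normalized by the window length so that a
#' constant maps to its value at nu = 0. The window must be uniformly sampled;
#' by construction it contains an integer number of modulation periods in the
#' sinusoidal scenario, so the modulation harmonics fall exactly on bins.
#' Only nonnegative frequencies up to Nyquist are returned (single-sided);
#' magnitudes of interior bins are doubled by [harmonic_component()].
#'
#' @param d A `diff_radargram`.
#' @param window Integer column indices of the analysis window; defaults to
#'   the modulation window (ON plateaus, or the sinusoid block).
#' @return An object of class `observation_spectrum` with fields `t`, `nu`
#'   and the complex matrix `values` (t x nu).
#' @export
observation_spectrum <- function(d, window = NULL) {
  stopifnot(inherits(d, "diff_radargram"))
  if (is.null(window)) window <- .analysis_window(d)
  if (length(window) < 2) stop("analysis window too short for a spectrum")
  Tw <- d$T[window]
  dT <- diff(Tw)
  if (max(abs(dT - dT[1])) > 1e-9 * dT[1])
    stop("analysis window is not uniformly sampled in T")
  V <- d$values[, window, drop = FALSE]
  n <- ncol(V)
  S <- t(stats::mvfft(t(V))) / n
  keep <- seq_len(floor(n / 2) + 1)
  structure(list(t = d$t, nu = (keep - 1) / (n * dT[1]),
                 values = S[, keep, drop = FALSE],
                 window_n = n),
            class = "observation_spectrum")
}

#' Extract one modulation harmonic from an observation spectrum
#'
#' Returns the single-sided magnitude `|dY(t, nu)|` at the bin nearest to the
#' requested frequency (doubled for nu > 0 to account for the discarded
#' negative-frequency half). The DC bin equals the analysis-window mean.
#'
#' @param s An [observation_spectrum()].
#' @param nu Requested observation frequency (Hz); must not exceed Nyquist.
#' @param tol_bins Maximum allowed distance (in bins) between `nu` and the
#'   nearest bin.
#' @return An `irf_signal` over t (magnitudes), with attributes `nu_actual`
#'   and `bin`.
#' @export
harmonic_component <- function(s, nu, tol_bins = 1) {
  stopifnot(inherits(s, "observation_spectrum"))
  nyq <- max(s$nu)
  if (nu < 0 || nu > nyq + 1e-12)
    stop(sprintf("requested nu = %.3g Hz beyond Nyquist (%.3g Hz)", nu, nyq))
  dnu <- s$nu[2] - s$nu[1]
  bin <- which.min(abs(s$nu - nu))
  if (abs(s$nu[bin] - nu) > tol_bins * dnu + 1e-12)
    stop(sprintf("no bin within %g bins of nu = %.3g Hz", tol_bins, nu))
  vals <- Mod(s$values[, bin])
  is_nyquist <- (s$window_n %% 2 == 0) && bin == ncol(s$values)
  if (bin > 1 && !is_nyquist) vals <- 2 * vals
  structure(list(t = s$t, values = vals),
            class = "irf_signal", nu_actual = s$nu[bin], bin = bin)
}

#' Analytic signal via the FFT
#'
#' Discards the negative-frequency half of the spectrum (doubling interior
#' positive bins), yielding the complex analytic signal whose magnitude is
#' the envelope.
#'
#' @param x Real vector.
#' @return Complex vector of the same length.
#' @export
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Maximum of the signal envelope
#'
#' Envelope maximum of an IRF-like signal (magnitude of its analytic signal);
#' the scalar summary used for the field- and viscosity-sweep response curves.
#'
#' @param x An `irf_signal`, or a numeric/complex vector.
#' @return Nonnegative scalar.
#' @examples
#' tt <- seq(0, 1, length.out = 512)
#' envelope_max(sin(2 * pi * 20 * tt))  # ~1
#' @export
envelope_max <- function(x) {
  v <- if (inherits(x, "irf_signal")) x$values else x
  if (all(v == 0)) return(0)
  if (is.complex(v)) max(Mod(v)) else max(Mod(analytic_signal(v)))
}
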