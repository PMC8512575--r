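#' Maximal-length pseudo-noise sequence (M-sequence)
#'
#' Generates the +/-1 chip sequence of a maximal-length LFSR (Fibonacci form,
#' all-ones seed). A maximal sequence of register order n has period 2^n - 1
#' and the two-valued periodic autocorrelation {N at zero lag, -1 elsewhere}
#' that makes impulse-response recovery by cross-correlation possible.
#'
#' @param order Register length n (2..24).
#' @param taps Feedback tap positions (must form a primitive polynomial;
#'   validated by checking that the achieved period equals 2^n - 1). Default
#'   taps are provided for orders 2-12.
#' @param chip_rate Chip rate in Hz (sets the time axis of recovered IRFs).
#' @return An object of class `msequence` with fields `order`, `taps`,
#'   `chips` (+/-1 vector of length 2^n - 1) and `chip_rate`.
#' @examples
#' m <- generate_msequence(5)
#' length(m$chips)  # 31
#' @export
generate_msequence <- function(order, taps = NULL, chip_rate = 13.3e9) {
  stopifnot(order >= 2, order <= 24, chip_rate > 0)
  if (is.null(taps)) {
    default_taps <- list(`2` = c(2, 1), `3` = c(3, 2), `4` = c(4, 3),
                         `5` = c(5, 3), `6` = c(6, 5), `7` = c(7, 6),
                         `8` = c(8, 6, 5, 4), `9` = c(9, 5), `10` = c(10, 7),
                         `11` = c(11, 9), `12` = c(12, 11, 10, 4))
    taps <- default_taps[[as.character(order)]]
    if (is.null(taps)) stop("no default taps for this order; supply taps")
  }
  if (any(taps < 1) || any(taps > order)) stop("taps must lie in 1..order")
  n_period <- 2^order - 1
  reg <- rep(1L, order)
  bits <- integer(n_period)
  for (k in seq_len(n_period)) {
    bits[k] <- reg[order]
    fb <- Reduce(bitwXor, reg[taps])
    reg <- c(fb, reg[-order])
  }
  # maximality check: the register must return to the seed only after 2^n - 1
  reg2 <- rep(1L, order)
  period <- 0L
  repeat {
    fb <- Reduce(bitwXor, reg2[taps])
    reg2 <- c(fb, reg2[-order])
    period <- period + 1L
    if (all(reg2 == 1L) || period > n_period) break
  }
  if (period != n_period)
    stop(sprintf("taps are not maximal: achieved period %d, expected %d",
                 period, n_period))
  structure(list(order = order, taps = taps,
                 chips = ifelse(bits == 1L, 1, -1), chip_rate = chip_rate),
            class = "msequence")
}

#' @export
print.msequence <- function(x, ...) {
  cat(sprintf("M-sequence: order %d, period %d, taps {%s}, chip rate %.3g Hz\n",
              x$order, length(x$chips), paste(x$taps, collapse = ","),
              x$chip_rate))
  invisible(x)
}

circ_crosscorr <- function(a, b) {
  # sum_k a[k] * b[k + lag] (circular), lags 0..N-1, via FFT
  n <- length(a)
  Re(stats::fft(Conj(stats::fft(a)) * stats::fft(b), inverse = TRUE)) / n
}

#' Impulse-response recovery by M-sequence cross-correlation
#'
#' Recovers the channel impulse response from a periodically acquired
#' received signal by circular cross-correlation with the stimulus chips,
#' normalized by N + 1 so that a unit-delta channel returns amplitude ~1 at
#' its delay tap. In the noiseless case sidelobes are bounded by 1/(N+1) per
#' unit of channel energy (the -1 off-peak value of the two-valued
#' autocorrelation). If `received` contains `n_periods` periods they are
#' averaged before correlation, reducing additive white noise by
#' sqrt(n_periods).
#'
#' @param stimulus An [generate_msequence()] object.
#' @param received Real vector of length `n_periods * (2^order - 1)`.
#' @param n_periods Number of acquired periods to average.
#' @param remove_dc_bias If `TRUE`, subtract the -1/(N+1) correlation offset
#'   (the textbook two-valued identity is kept visible by default).
#' @return An object of class `irf_estimate` with uniform time axis at
#'   spacing `1/chip_rate`.
#' @export
recover_irf <- function(stimulus, received, n_periods = 1,
                        remove_dc_bias = FALSE) {
  stopifnot(inherits(stimulus, "msequence"))
  n <- length(stimulus$chips)
  if (length(received) != n * n_periods)
    stop(sprintf("received length %d != %d periods x %d chips",
                 length(received), n_periods, n))
  if (n_periods > 1)
    received <- rowMeans(matrix(received, nrow = n))
  vals <- circ_crosscorr(stimulus$chips, received) / (n + 1)
  # chips of a maximal sequence sum to +1, so one received period sums to the
  # channel gain sum(h); the off-peak bias of the two-valued correlation is
  # -sum(h)/(N+1)
  if (remove_dc_bias) vals <- vals + sum(received) / (n + 1)
  structure(list(t = (seq_len(n) - 1) / stimulus$chip_rate,
                 values = vals, scale = 1 / (n + 1)),
            class = "irf_estimate")
}
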