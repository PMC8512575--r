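#' Polarizing-magnetic-field (PMF) waveform
#'
#' Describes the drive of the electromagnet over observation time T. Two
#' modulation kinds are supported, plus a field-free reference:
#' * `"onoff"`: two-state modulation; plateaus at 0 and `Hm` joined by linear
#'   ramps (the ramp interval lets the field settle and is excluded from all
#'   averaging windows). The record starts with an OFF block used for clutter
#'   estimation.
#' * `"sin"`: sinusoidal modulation `amplitude*sin(2*pi*nu_sin*T)` over an
#'   integer number of periods, preceded by an OFF block and a (flagged)
#'   transition interval. Over integer periods the waveform has zero mean and
#'   RMS `amplitude/sqrt(2)`.
#' * `"off"`: the same timing as `"sin"` but H = 0 throughout (reference
#'   acquisition without a PMF).
#'
#' Field intensities are given in kA/m at this interface (converted to A/m
#' internally, reported in A/m by [sample_pmf()]).
#'
#' @param kind `"onoff"`, `"sin"` or `"off"`.
#' @param Hm_ka_per_m ON-plateau intensity (kA/m) for `"onoff"`.
#' @param Hrms_ka_per_m RMS intensity (kA/m) for `"sin"`; the amplitude is
#'   `sqrt(2)` times this value.
#' @param nu_sin Modulation frequency (Hz).
#' @param n_periods Number of sinusoid periods in the analysis window.
#' @param t_off OFF-block duration (s).
#' @param t_ramp Ramp / transition duration (s).
#' @param t_on ON-plateau duration (s) for `"onoff"`.
#' @param n_cycles Number of ON/OFF cycles.
#' @param sample_rate IRF acquisition rate (IRFs per second; the deployed
#'   system acquires approximately six per second).
#' @return An object of class `pmf_waveform`.
#' @examples
#' wf <- pmf_waveform("onoff", Hm_ka_per_m = 80)
#' head(sample_pmf(wf))
#' @export
pmf_waveform <- function(kind = c("onoff", "sin", "off"),
                         Hm_ka_per_m = 80, Hrms_ka_per_m = 27,
                         nu_sin = 0.5, n_periods = 12,
                         t_off = 10, t_ramp = 2, t_on = 10, n_cycles = 1,
                         sample_rate = 6) {
  kind <- match.arg(kind)
  stopifnot(t_off > 0, t_ramp >= 0, t_on > 0, n_cycles >= 1,
            nu_sin > 0, n_periods >= 1, sample_rate > 0)
  structure(list(kind = kind, Hm = ka_per_m_to_a_per_m(Hm_ka_per_m),
                 amplitude = ka_per_m_to_a_per_m(Hrms_ka_per_m) * sqrt(2),
                 nu_sin = nu_sin, n_periods = n_periods,
                 t_off = t_off, t_ramp = t_ramp, t_on = t_on,
                 n_cycles = n_cycles, sample_rate = sample_rate),
            class = "pmf_waveform")
}

#' Sample a PMF waveform on the observation-time axis
#'
#' @param wf A [pmf_waveform()].
#' @return A data.frame with columns `T` (s), `H` (A/m, signed for `"sin"`),
#'   `state` (`"off"`, `"ramp"`, `"on"` or `"sin"`) and `ramp` (logical flag;
#'   transition samples are excluded from averaging windows).
#' @export
sample_pmf <- function(wf) {
  stopifnot(inherits(wf, "pmf_waveform"))
  segs <- list()
  add <- function(dur, state) segs[[length(segs) + 1]] <<- list(dur = dur, state = state)
  if (wf$kind == "onoff") {
    add(wf$t_off, "off")
    for (k in seq_len(wf$n_cycles)) {
      add(wf$t_ramp, "ramp_up"); add(wf$t_on, "on")
      add(wf$t_ramp, "ramp_down"); add(wf$t_off, "off")
    }
  } else {
    add(wf$t_off, "off")
    add(wf$t_ramp, "ramp_up")
    add(wf$n_periods / wf$nu_sin, "sin")
  }
  total <- sum(vapply(segs, `[[`, numeric(1), "dur"))
  n <- round(total * wf$sample_rate)
  Tax <- (seq_len(n) - 1) / wf$sample_rate
  H <- numeric(n); state <- character(n); ramp <- logical(n)
  t0 <- 0
  for (s in segs) {
    idx <- which(Tax >= t0 - 1e-9 & Tax < t0 + s$dur - 1e-9)
    frac <- (Tax[idx] - t0) / s$dur
    H[idx] <- switch(s$state,
      off = 0,
      ramp_up = if (wf$kind == "onoff") wf$Hm * frac else 0,
      ramp_down = wf$Hm * (1 - frac),
      on = wf$Hm,
      sin = if (wf$kind == "sin")
        wf$amplitude * sin(2 * pi * wf$nu_sin * (Tax[idx] - t0)) else 0)
    state[idx] <- switch(s$state,
      ramp_up = "ramp", ramp_down = "ramp",
      sin = "sin", off = "off", on = "on")
    ramp[idx] <- s$state %in% c("ramp_up", "ramp_down")
    t0 <- t0 + s$dur
  }
  data.frame(T = Tax, H = H, state = state, ramp = ramp)
}
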