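# shared builders for small, fast simulation fixtures

fast_onoff_pmf <- function(Hm = 80, ...)
  pmf_waveform("onoff", Hm_ka_per_m = Hm, t_off = 5, t_ramp = 1, t_on = 5, ...)

fast_sin_pmf <- function(...)
  pmf_waveform("sin", t_off = 5, t_ramp = 1, n_periods = 6, ...)

one_channel_cfg <- function(...) {
  sim_config(channels = 1, pmf = fast_onoff_pmf(), ...)
}

selection_indices <- function(geometry, selection) {
  match(paste(selection$tx, selection$rx),
        paste(geometry$channels$tx, geometry$channels$rx))
}

# hand-built radargram for demodulation unit tests: values is t x T
manual_radargram <- function(values, states, H = NULL, dT = 1 / 6) {
  nT <- ncol(values)
  stopifnot(length(states) == nT)
  if (is.null(H)) H <- ifelse(states == "on", 80e3, 0)
  pmf <- data.frame(T = (seq_len(nT) - 1) * dT, H = H, state = states,
                    ramp = states == "ramp")
  structure(list(tx = 1, rx = 1, t = seq_len(nrow(values)) * 1e-10 - 1e-10,
                 T = pmf$T, values = values, pmf = pmf),
            class = "radargram")
}

manual_diff_radargram <- function(values, states, H = NULL, dT = 1 / 6) {
  r <- manual_radargram(values, states, H, dT)
  class(r) <- c("diff_radargram", "radargram")
  r
}

# small immobilized-environment closed-form model shared across tests
default_model <- chi_closed_form(mnp_params())
immob <- medium_environment("immobilized")
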