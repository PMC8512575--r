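#' Target material presets for the viscosity bench
#'
#' Embedding media used on the single-channel bench: MNPs diluted in
#' distilled water, embedded in agar, in 10% gelatin, in 0% and 40%
#' oil-gelatin, and an MNP-free distilled-water reference. Solid media
#' immobilize the particles (Brownian relaxation suppressed); the
#' `chi_scale` factors emulate the observed amplitude differences between
#' embedding media (boundary-permittivity and clustering effects).
#'
#' @return A list of material descriptors (`name`, `chi_scale`, `env`).
#' @export
bench_materials <- function() {
  list(
    list(name = "water",       chi_scale = 1.00, env = medium_environment(1e-3)),
    list(name = "agar",        chi_scale = 0.95, env = medium_environment("immobilized")),
    list(name = "gelatin",     chi_scale = 0.60, env = medium_environment("immobilized")),
    list(name = "oil_gel_0",   chi_scale = 0.75, env = medium_environment("immobilized")),
    list(name = "oil_gel_40",  chi_scale = 0.70, env = medium_environment("immobilized")),
    list(name = "reference",   chi_scale = 0.00, env = medium_environment(1e-3))
  )
}

run_seed <- function(base_seed, index) as.integer((base_seed + 7919 * index) %% 2147483629)

config_hash <- function(x) {
  raw <- serialize(x, NULL)
  sprintf("%08x", sum(as.integer(raw) * (seq_along(raw) %% 251)) %% 4294967291)
}

.bench_sim <- function(field_ka, material, seed, noise_sigma, nt = 256,
                       chi_model = NULL) {
  geom <- array_geometry(n_tx = 1, n_rx = 1, tx_ring_z = -0.015,
                         rx_ring_z = -0.025)
  targ <- if (material$chi_scale > 0)
    target_spec(position = c(0.055, 0, -0.02), volume = 15e-6,
                mnp_mass = 100e-6, chi_scale = material$chi_scale)
  else NULL
  args <- list(geometry = geom, target = targ,
               pmf = pmf_waveform("onoff", Hm_ka_per_m = field_ka,
                                  t_off = 5, t_ramp = 1, t_on = 5),
               env = material$env, nt = nt,
               noise_sigma = noise_sigma, seed = seed)
  if (!is.null(chi_model)) args$chi_model <- chi_model
  simulate_radargram(do.call(sim_config, args))[[1]]
}

#' Field-intensity / viscosity sweep bench
#'
#' Emulates the single-channel bench: for every combination of polarizing
#' field intensity, virtual target and repetition, a two-state acquisition is
#' simulated, clutter-removed, and the envelope maximum of the mean
#' differential MNP response is recorded. Eighteen virtual targets (three per
#' material preset) measured eleven times reproduce the 198-record bookkeeping
#' of the bench experiment.
#'
#' @param fields_ka_per_m Field intensities to sweep (kA/m).
#' @param n_targets Number of virtual targets (cycled over
#'   [bench_materials()]).
#' @param repetitions Repeated acquisitions per (field, target).
#' @param base_seed Base RNG seed; each run draws a derived seed.
#' @param noise_sigma Additive noise level of the bench acquisitions.
#' @param chi_model Optional `susceptibility_model` (e.g. a tabulated
#'   fixture); the closed-form default of [sim_config()] when `NULL`.
#' @return A `run_table` data.frame: one record per (field, target,
#'   repetition) with the envelope maximum, the material, the run seed and
#'   the config hash.
#' @export
run_field_sweep <- function(fields_ka_per_m = seq(0, 140, by = 20),
                            n_targets = 6, repetitions = 1,
                            base_seed = 1, noise_sigma = 2e-3,
                            chi_model = NULL) {
  stopifnot(length(fields_ka_per_m) >= 1, n_targets >= 1, repetitions >= 1)
  mats <- bench_materials()
  recs <- list()
  i <- 0L
  for (fld in fields_ka_per_m) for (tg in seq_len(n_targets))
    for (rep_i in seq_len(repetitions)) {
      i <- i + 1L
      mat <- mats[[(tg - 1) %% length(mats) + 1]]
      seed <- run_seed(base_seed, i)
      r <- .bench_sim(fld, mat, seed, noise_sigma, chi_model = chi_model)
      env_max <- envelope_max(mean_differential(remove_clutter(r)))
      recs[[i]] <- data.frame(field_ka_per_m = fld, target = tg,
                              material = mat$name, repetition = rep_i,
                              envelope_max = env_max, seed = seed)
    }
  out <- do.call(rbind, recs)
  attr(out, "config_hash") <- config_hash(list(fields_ka_per_m, n_targets,
                                               repetitions, base_seed,
                                               noise_sigma))
  class(out) <- c("run_table", "data.frame")
  out
}

#' Simulate, demodulate and image one scenario
#'
#' Convenience wrapper over the full chain: simulates the angularly selected
#' imaging channels of the configured scenario, removes clutter, extracts the
#' delay-and-sum input signal (mean differential response by default, or one
#' observation-frequency harmonic), calibrates out the pulse latency and the
#' group delay of the differential-susceptibility kernel, and forms the
#' delay-and-sum image.
#'
#' @param cfg A [sim_config()].
#' @param grid Imaging [voxel_grid()]; default 1 cm pitch over the mold.
#' @param harmonic `NULL` for the time-domain mean differential (its
#'   envelope is used as the DAS input), or an observation frequency in Hz
#'   (e.g. 0 or 1) to image a harmonic magnitude.
#' @return An `image_volume`.
#' @examples
#' \donttest{
#' cfg <- sim_config(pmf = pmf_waveform("onoff", t_off = 5, t_ramp = 1, t_on = 5))
#' img <- image_scenario(cfg)
#' image_argmax(img)
#' }
#' @export
image_scenario <- function(cfg, grid = NULL, harmonic = NULL) {
  .imaging_run(cfg, grid = grid, harmonic = harmonic)
}

.imaging_run <- function(cfg, grid = NULL, harmonic = NULL) {
  # simulate the selected channels, demodulate, and form a DAS image
  geom <- cfg$geometry
  sel <- select_channels(geom)
  idx <- match(paste(sel$tx, sel$rx),
               paste(geom$channels$tx, geom$channels$rx))
  cfg$channels <- idx
  rset <- simulate_radargram(cfg)
  # system calibration: the pulse latency plus the group delay of the
  # band-limited differential-susceptibility kernel (known from the chi model)
  Hpk <- if (cfg$pmf$kind == "onoff") cfg$pmf$Hm else cfg$pmf$amplitude
  t_cal <- cfg$pulse_t0 +
    response_kernel_delay(cfg$chi_model, Hpk, 0, band = cfg$band, env = cfg$env)
  signals <- lapply(rset, function(r) {
    d <- remove_clutter(r)
    s <- if (is.null(harmonic)) mean_differential(d)
    else harmonic_component(observation_spectrum(d), harmonic)
    if (is.null(harmonic))  # band-pass signal: focus on its envelope
      s$values <- Mod(analytic_signal(s$values))
    s$t <- s$t - t_cal
    s
  })
  if (is.null(grid))
    grid <- voxel_grid(c(-0.065, -0.065, -0.065), 0.01, c(14, 14, 7))
  das_image(signals, geom, sel, host_velocity(cfg), grid)
}

#' Target-depth sweep through the full imaging pipeline
#'
#' Simulates the 2 mL target at increasing depth below the mold wall along
#' the y axis, runs the two-state pipeline through delay-and-sum imaging, and
#' records the signal-to-clutter ratio per depth. With path attenuation
#' enabled the S/C ratio decreases with depth (the response sinks towards the
#' noise floor); with attenuation and spreading disabled and homogeneous
#' illumination it is depth-independent.
#'
#' @param depths_cm Target depths below the mold wall (cm).
#' @param base_seed Base RNG seed.
#' @param noise_sigma Acquisition noise level.
#' @param atten Path attenuation (Np/m); 0 disables.
#' @param spreading Spherical-spreading factor on/off.
#' @return A `run_table` with one record per depth (`depth_cm`, `sc_db`,
#'   `seed`).
#' @export
run_depth_sweep <- function(depths_cm = seq(1.0, 5.0, by = 0.5),
                            base_seed = 1, noise_sigma = 2e-3,
                            atten = 15, spreading = TRUE) {
  geom <- array_geometry()
  recs <- lapply(seq_along(depths_cm), function(i) {
    depth <- depths_cm[i] / 100
    pos <- c(0, -(geom$mold$radius - depth), -0.035)
    seed <- run_seed(base_seed, i)
    cfg <- sim_config(geometry = geom, target = target_spec(position = pos),
                      pmf = pmf_waveform("onoff", t_off = 5, t_ramp = 1, t_on = 5),
                      noise_sigma = noise_sigma, seed = seed,
                      atten = atten, spreading = spreading)
    img <- .imaging_run(cfg)
    data.frame(depth_cm = depths_cm[i],
               sc_db = signal_to_clutter(img, pos), seed = seed)
  })
  out <- do.call(rbind, recs)
  attr(out, "config_hash") <- config_hash(list(depths_cm, base_seed,
                                               noise_sigma, atten, spreading))
  class(out) <- c("run_table", "data.frame")
  out
}

#' ON/OFF versus sinusoidal modulation comparison
#'
#' Synthetic twin of the modulation-comparison grid: for each of the five
#' scenarios (two-state modulation with and without target, sinusoidal
#' modulation with and without target, and a field-free reference) the
#' pipeline images the DC component and the second harmonic (nu = 1 Hz) of
#' the observation-time spectrum and records both signal-to-clutter ratios.
#' Both modulated waveforms are matched to the same RMS field intensity.
#'
#' @param Hrms_ka_per_m Common RMS intensity of both modulations (kA/m).
#' @param base_seed Base RNG seed.
#' @param noise_sigma Acquisition noise level.
#' @param disturbance_gain PMF-coupling disturbance gain.
#' @param target_position Target position (m).
#' @return A `run_table` with 10 records (`scenario`, `target`, `nu_hz`,
#'   `sc_db`, `seed`).
#' @export
run_modulation_compare <- function(Hrms_ka_per_m = 27, base_seed = 1,
                                   noise_sigma = 2e-3,
                                   disturbance_gain = 2.5e-8,
                                   target_position = c(0, -0.03, -0.035)) {
  geom <- array_geometry()
  scen <- list(
    list(name = "onoff", kind = "onoff", target = TRUE),
    list(name = "onoff", kind = "onoff", target = FALSE),
    list(name = "sin",   kind = "sin",   target = TRUE),
    list(name = "sin",   kind = "sin",   target = FALSE),
    list(name = "off",   kind = "off",   target = FALSE)
  )
  recs <- list(); i <- 0L
  for (s in scen) {
    pmf <- if (s$kind == "onoff")
      # equal ON/OFF dwell: plateau sqrt(2)*Hrms gives the matched RMS
      pmf_waveform("onoff", Hm_ka_per_m = Hrms_ka_per_m * sqrt(2), t_off = 6,
                   t_ramp = 1, t_on = 6)
    else pmf_waveform(s$kind, Hrms_ka_per_m = Hrms_ka_per_m, t_off = 6,
                      t_ramp = 1, n_periods = 6)
    cfg <- sim_config(geometry = geom,
                      target = if (s$target)
                        target_spec(position = target_position) else NULL,
                      pmf = pmf, noise_sigma = noise_sigma,
                      disturbance_gain = disturbance_gain, seed = base_seed)
    for (nu in c(0, 1)) {
      i <- i + 1L
      img <- .imaging_run(cfg, harmonic = nu)
      recs[[i]] <- data.frame(scenario = s$name, target = s$target,
                              nu_hz = nu,
                              sc_db = signal_to_clutter(img, target_position),
                              seed = base_seed)
    }
  }
  out <- do.call(rbind, recs)
  attr(out, "config_hash") <- config_hash(list(Hrms_ka_per_m, base_seed,
                                               noise_sigma, disturbance_gain,
                                               target_position))
  class(out) <- c("run_table", "data.frame")
  out
}

#' Write a run table to CSV (with its config hash as a comment-free sidecar)
#'
#' @param x A `run_table`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_run_table <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}
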