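#' Tumor-mimicking target specification
#'
#' @param position Target center (m) in mold coordinates (origin at the mold
#'   center, z up towards the array plane). The default emulates the 2 mL
#'   gelatin target used at position `[0, -3, -3.5]` cm.
#' @param volume Target volume (m^3); default 2 mL.
#' @param mnp_mass MNP mass in the target (kg); default 50 mg.
#' @param chi_scale Multiplicative scaling of the target susceptibility
#'   (emulates embedding-medium effects; 0 for an MNP-free reference target).
#' @return An object of class `target_spec`; `concentration` (kg/m^3) is
#'   derived as `mnp_mass/volume` (50 mg in 2 mL = 25 mg/mL).
#' @export
target_spec <- function(position = c(0, -0.03, -0.035), volume = 2e-6,
                        mnp_mass = 50e-6, chi_scale = 1) {
  stopifnot(volume > 0, mnp_mass >= 0, chi_scale >= 0)
  structure(list(position = position, volume = volume, mnp_mass = mnp_mass,
                 concentration = mnp_mass / volume, chi_scale = chi_scale),
            class = "target_spec")
}

#' Raised-cosine band-pass sounding-pulse spectrum
#'
#' Amplitude spectrum flat over the interior of the working band with
#' raised-cosine tapers over a fraction `taper` of the band at each edge, and
#' linear phase delaying the pulse center to `t0`. Any band-limited pulse with
#' 1-4 GHz support is a faithful stand-in for the M-sequence sounding wave;
#' the near-flat spectrum keeps the band-limited differential-response
#' normalization consistent with the imaging chain.
#'
#' @param f Frequency grid (Hz).
#' @param band Working band `c(f_lo, f_hi)` (Hz).
#' @param taper Taper fraction of the band width at each edge.
#' @param t0 Pulse-center delay (s).
#' @return Complex spectrum per frequency.
#' @export
sounding_pulse_spectrum <- function(f, band = c(1e9, 4e9), taper = 0.15,
                                    t0 = 2e-9) {
  B <- band[2] - band[1]
  w <- taper * B
  A <- numeric(length(f))
  A[f >= band[1] + w & f <= band[2] - w] <- 1
  lo <- f >= band[1] & f < band[1] + w
  hi <- f > band[2] - w & f <= band[2]
  A[lo] <- 0.5 * (1 - cos(pi * (f[lo] - band[1]) / w))
  A[hi] <- 0.5 * (1 - cos(pi * (band[2] - f[hi]) / w))
  A * exp(-2i * pi * f * t0)
}

irfft <- function(X, n) {
  # inverse real FFT from the nonnegative-frequency half spectrum
  full <- c(X, Conj(rev(X[2:(n - length(X) + 1)])))
  Re(stats::fft(full, inverse = TRUE)) / n
}

#' Simulation scenario configuration
#'
#' Bundles everything [simulate_radargram()] needs: the array geometry, an
#' optional target, the PMF waveform, the susceptibility model and carrier
#' environment, Debye parameters of host and target dielectrics, the clutter,
#' disturbance, drift and noise levels, and the sampling scheme.
#'
#' The signal model per channel is
#' `y(t, T) = y_cl(t) + y_tar(t, H(T)) + g*H(T)*d(t) + drift(t, T) + noise`,
#' where the MNP target response depends on the field only through
#' `chi(f, |H|)` (even in H), while the disturbance term `g*H(T)*d(t)`
#' emulating PMF-system coupling is odd in H, and `d(t)` is a fixed seeded
#' pulse-like signature per channel.
#'
#' @param geometry An [array_geometry()].
#' @param target A [target_spec()] or `NULL` (no target).
#' @param pmf A [pmf_waveform()].
#' @param chi_model A `susceptibility_model`.
#' @param env Carrier environment of the MNPs in the target (default:
#'   immobilized, gelatin-bound particles).
#' @param host_debye,target_debye Named lists of [debye_spectrum()] parameters
#'   (`eps_inf`, `delta_eps`, `tau`, `sigma_s`).
#' @param clutter_amp Amplitude scale of the static clutter (antenna
#'   crosstalk and mold reflections); the target response is orders of
#'   magnitude below it.
#' @param disturbance_gain Gain `g` of the PMF-coupled disturbance
#'   (per A/m of field intensity).
#' @param drift_rel Relative amplitude of the slow per-channel gain drift
#'   (ramp plus low-frequency random walk) applied to the clutter shape.
#' @param noise_sigma Standard deviation of the additive white noise.
#' @param seed Integer RNG seed; recorded in the output and reused for all
#'   component substreams (so runs differing only in target presence or
#'   disturbance gain share identical clutter, signatures and noise draws).
#' @param fs Propagation-time sampling rate (Hz).
#' @param nt Number of propagation-time samples.
#' @param band Working frequency band (Hz).
#' @param pulse_t0 Built-in latency of the sounding pulse (s): the pulse
#'   center sits at `pulse_t0` plus the channel path delay. Known to the
#'   system, so imaging subtracts it from the propagation-time axis.
#' @param atten Path attenuation coefficient (Np/m) of the host medium;
#'   0 disables attenuation.
#' @param spreading Apply spherical spreading 1/(d1*d2) per channel
#'   (normalized at 5 cm legs); `FALSE` emulates uniform illumination.
#' @param sensing `"ideal"` (the IRFs enter the radargram directly) or
#'   `"msequence"` (each IRF is passed through M-sequence sounding and
#'   recovered by cross-correlation; requires `nt = 2^mseq_order - 1`).
#' @param mseq_order Register order for `sensing = "msequence"`.
#' @param channels Integer indices into `geometry$channels` to simulate
#'   (default: all).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(geometry = array_geometry(),
                       target = target_spec(),
                       pmf = pmf_waveform("onoff"),
                       chi_model = chi_closed_form(mnp_params()),
                       env = medium_environment("immobilized"),
                       host_debye = list(eps_inf = 5, delta_eps = 15,
                                         tau = 18e-12, sigma_s = 0.3),
                       target_debye = list(eps_inf = 6, delta_eps = 40,
                                           tau = 12e-12, sigma_s = 0.7),
                       clutter_amp = 1, disturbance_gain = 0,
                       drift_rel = 0, noise_sigma = 0,
                       seed = 1, fs = 16e9, nt = 512,
                       band = c(1e9, 4e9), pulse_t0 = 2e-9,
                       atten = 15, spreading = TRUE,
                       sensing = c("ideal", "msequence"), mseq_order = 9,
                       channels = NULL) {
  sensing <- match.arg(sensing)
  stopifnot(inherits(geometry, "array_geometry"),
            inherits(pmf, "pmf_waveform"),
            inherits(chi_model, "susceptibility_model"),
            fs > 0, nt >= 16, clutter_amp >= 0, noise_sigma >= 0)
  if (!is.null(target)) {
    stopifnot(inherits(target, "target_spec"))
    if (!in_mold(target$position, geometry))
      stop("target position lies outside the examination mold")
  }
  if (sensing == "msequence") nt <- 2^mseq_order - 1
  if (is.null(channels)) channels <- seq_len(nrow(geometry$channels))
  structure(list(geometry = geometry, target = target, pmf = pmf,
                 chi_model = chi_model, env = env,
                 host_debye = host_debye, target_debye = target_debye,
                 clutter_amp = clutter_amp,
                 disturbance_gain = disturbance_gain,
                 drift_rel = drift_rel, noise_sigma = noise_sigma,
                 seed = as.integer(seed), fs = fs, nt = nt, band = band,
                 pulse_t0 = pulse_t0, atten = atten, spreading = spreading, sensing = sensing,
                 mseq_order = mseq_order, channels = channels),
            class = "sim_config")
}

sim_freq_grid <- function(cfg) (0:(floor(cfg$nt / 2))) * cfg$fs / cfg$nt

#' Propagation velocity in the host medium
#'
#' Single frequency-independent velocity `c/sqrt(Re(eps_host))` at the band
#' center, shared by the forward simulation and the delay-and-sum imaging so
#' the two stay kinematically consistent.
#'
#' @param cfg A [sim_config()].
#' @return Velocity (m/s).
#' @export
host_velocity <- function(cfg) {
  pc <- physical_constants()
  fc <- mean(cfg$band)
  eps <- do.call(debye_spectrum, c(list(freq = fc), cfg$host_debye))$eps_rel
  pc$c / sqrt(Re(eps))
}

# pulse spectrum of one channel path: delay, attenuation, spreading, volume
.channel_pulse_spectrum <- function(cfg, tx, rx, position, volume) {
  f <- sim_freq_grid(cfg)
  d1 <- sqrt(sum((tx - position)^2))
  d2 <- sqrt(sum((position - rx)^2))
  v <- host_velocity(cfg)
  delay <- (d1 + d2) / v
  amp <- volume / 2e-6
  if (cfg$atten > 0) amp <- amp * exp(-cfg$atten * (d1 + d2))
  if (cfg$spreading) amp <- amp * (0.05 / d1) * (0.05 / d2)
  amp * sounding_pulse_spectrum(f, cfg$band, t0 = cfg$pulse_t0) *
    exp(-2i * pi * f * delay)
}

#' Time-domain target response of one channel
#'
#' The band-limited sounding pulse, delayed by the tx-target-rx path at the
#' host phase velocity and attenuated by path loss and spherical spreading,
#' convolved with the time-domain kernel of the reflection coefficient
#' `Gamma(f, H)` at the local field intensity. The susceptibility is
#' evaluated at `|H|` (the MNP response is even in the field).
#'
#' @param cfg A [sim_config()].
#' @param channel Index into `cfg$geometry$channels`.
#' @param H Vector of field intensities (A/m, may be signed).
#' @return Matrix `nt x length(H)` of responses, with the propagation-time
#'   axis `attr(,"t")`.
#' @export
channel_response <- function(cfg, channel, H) {
  stopifnot(inherits(cfg, "sim_config"))
  if (is.null(cfg$target)) {
    out <- matrix(0, cfg$nt, length(H))
  } else {
    ch <- cfg$geometry$channels[channel, ]
    f <- sim_freq_grid(cfg)
    host <- do.call(debye_spectrum, c(list(freq = f), cfg$host_debye))
    targ <- do.call(debye_spectrum, c(list(freq = f), cfg$target_debye))
    P <- .channel_pulse_spectrum(cfg, cfg$geometry$tx[ch$tx, ],
                                 cfg$geometry$rx[ch$rx, ],
                                 cfg$target$position, cfg$target$volume)
    scale_chi <- cfg$target$chi_scale *
      cfg$target$concentration / 25  # reference concentration 25 mg/mL
    model <- cfg$chi_model
    Hu <- unique(abs(H))
    # chi is only needed where the sounding pulse has support; this also keeps
    # tabulated models usable when their hull just covers the working band
    inband <- f >= cfg$band[1] & f <= cfg$band[2]
    G <- vapply(Hu, function(h) {
      chi <- complex(length(f))
      if (scale_chi > 0)
        chi[inband] <- scale_chi * susceptibility(model, f[inband], h, cfg$env)
      mu2 <- 1 + chi
      s <- principal_impedance_sqrt(mu2 * host$eps_rel / targ$eps_rel)
      (s - 1) / (s + 1)
    }, complex(length(f)))
    Y <- matrix(P, ncol = 1)[, rep(1, length(Hu)), drop = FALSE] * G
    resp <- apply(Y, 2, irfft, n = cfg$nt)
    out <- resp[, match(abs(H), Hu), drop = FALSE]
  }
  attr(out, "t") <- (seq_len(cfg$nt) - 1) / cfg$fs
  out
}

.clutter_signal <- function(cfg, channel) {
  # static clutter: direct crosstalk pulse + a mold-wall reflection;
  # amplitudes/delays drawn from a clutter-specific substream
  ch <- cfg$geometry$channels[channel, ]
  f <- sim_freq_grid(cfg)
  set.seed((cfg$seed + 17L * channel) %% 2147483629L)
  d_ct <- sqrt(sum((cfg$geometry$tx[ch$tx, ] - cfg$geometry$rx[ch$rx, ])^2))
  delay_ct <- d_ct / host_velocity(cfg) * 0.6  # crosstalk path partly in the matching layer
  a1 <- cfg$clutter_amp * stats::runif(1, 0.7, 1.3)
  a2 <- cfg$clutter_amp * stats::runif(1, 0.1, 0.3)
  delay_wall <- stats::runif(1, 1.5e-9, 3e-9)
  X <- sounding_pulse_spectrum(f, cfg$band, t0 = cfg$pulse_t0) *
    (a1 * exp(-2i * pi * f * delay_ct) + a2 * exp(-2i * pi * f * delay_wall))
  irfft(X, cfg$nt)
}

.disturbance_signature <- function(cfg, channel) {
  # pulse-like signature at an early (crosstalk-region) delay, fixed per
  # channel; multiplied by g*H(T) it is odd in the field
  f <- sim_freq_grid(cfg)
  set.seed((cfg$seed + 101L * channel + 7L) %% 2147483629L)
  delay <- stats::runif(1, 0.3e-9, 1.2e-9)
  amp <- stats::runif(1, 0.5, 1.5)
  irfft(amp * sounding_pulse_spectrum(f, cfg$band, t0 = cfg$pulse_t0) *
    exp(-2i * pi * f * delay),
        cfg$nt)
}

#' Simulate PMF-modulated radargrams for all configured channels
#'
#' Assembles, per channel, the radargram
#' `y(t, T) = y_cl(t) + y_tar(t, H(T)) + g*H(T)*d(t) + drift(t, T) + noise`
#' over the PMF observation-time schedule. Deterministic given `cfg$seed`;
#' component substreams are keyed by channel and component only, so paired
#' runs (with/without target, with/without disturbance) share identical
#' realizations of the remaining components.
#'
#' @param cfg A [sim_config()].
#' @return An object of class `radargram_set`: a list of `radargram` objects
#'   (fields `tx`, `rx`, `t`, `T`, `values` (t x T), `pmf` sample table) with
#'   the configuration attached.
#' @export
simulate_radargram <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  # component substreams use set.seed internally; restore the caller's RNG
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  pmf <- sample_pmf(cfg$pmf)
  nT <- nrow(pmf)
  tax <- (seq_len(cfg$nt) - 1) / cfg$fs
  mseq <- if (cfg$sensing == "msequence")
    generate_msequence(cfg$mseq_order, chip_rate = cfg$fs) else NULL
  rads <- lapply(cfg$channels, function(chi) {
    chn <- cfg$geometry$channels[chi, ]
    ycl <- .clutter_signal(cfg, chi)
    vals <- matrix(ycl, cfg$nt, nT)
    if (!is.null(cfg$target)) {
      ytar <- channel_response(cfg, chi, pmf$H)
      attr(ytar, "t") <- NULL
      vals <- vals + ytar
    }
    if (cfg$disturbance_gain != 0) {
      d <- .disturbance_signature(cfg, chi)
      vals <- vals + cfg$disturbance_gain * outer(d, pmf$H)
    }
    if (cfg$drift_rel > 0) {
      set.seed((cfg$seed + 211L * chi + 13L) %% 2147483629L)
      w <- pmf$T / max(pmf$T) + cumsum(stats::rnorm(nT)) / sqrt(nT)
      vals <- vals + cfg$drift_rel * outer(ycl, w)
    }
    if (cfg$noise_sigma > 0) {
      set.seed((cfg$seed + 307L * chi + 19L) %% 2147483629L)
      vals <- vals + matrix(stats::rnorm(cfg$nt * nT, sd = cfg$noise_sigma),
                            cfg$nt, nT)
    }
    if (!is.null(mseq)) {
      S <- stats::fft(mseq$chips)
      received <- Re(stats::mvfft(matrix(S, cfg$nt, nT) * stats::mvfft(vals),
                                  inverse = TRUE)) / cfg$nt
      vals <- apply(received, 2, function(col) recover_irf(mseq, col)$values)
    }
    structure(list(tx = chn$tx, rx = chn$rx, t = tax, T = pmf$T,
                   values = vals, pmf = pmf),
              class = "radargram")
  })
  structure(rads, class = "radargram_set", config = cfg, seed = cfg$seed)
}

#' @export
print.radargram_set <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf("Radargram set: %d channels, %d x %d (t x T) samples, PMF '%s', seed %d\n",
              length(x), cfg$nt, length(x[[1]]$T), cfg$pmf$kind, cfg$seed))
  invisible(x)
}

#' @export
print.radargram <- function(x, ...) {
  cat(sprintf("Radargram: channel (tx %d, rx %d), %d x %d samples\n",
              x$tx, x$rx, length(x$t), length(x$T)))
  invisible(x)
}

#' @export
plot.radargram <- function(x, ...) {
  graphics::image(x$T, x$t * 1e9, t(x$values), xlab = "observation time T (s)",
                  ylab = "propagation time t (ns)",
                  main = sprintf("channel (tx %d, rx %d)", x$tx, x$rx), ...)
  invisible(x)
}

#' Voxel grid specification
#'
#' Regular grid of voxel centers: `origin + pitch * (0:(dim-1))` per axis.
#'
#' @param origin Corner voxel center (m), length-3.
#' @param pitch Voxel pitch (m).
#' @param dim Integer grid dimensions, length-3.
#' @return An object of class `voxel_grid`.
#' @export
voxel_grid <- function(origin, pitch, dim) {
  stopifnot(pitch > 0, length(origin) == 3, length(dim) == 3, all(dim >= 1))
  structure(list(origin = origin, pitch = pitch, dim = as.integer(dim)),
            class = "voxel_grid")
}

#' @rdname voxel_grid
#' @param grid A `voxel_grid`.
#' @return For `voxel_coords`: an `prod(dim) x 3` matrix of voxel centers in
#'   array order (first axis fastest).
#' @export
voxel_coords <- function(grid) {
  ax <- lapply(1:3, function(k) grid$origin[k] + grid$pitch * (seq_len(grid$dim[k]) - 1))
  as.matrix(expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]]))
}

#' Synthetic magnetic field map of the electromagnet air gap
#'
#' Smooth stand-in for a Gaussmeter survey of the air gap: superposition of
#' two pole-face disc fields on the y axis (pole faces at `y = +/- gap/2`),
#' with axial falloff `1 - d/sqrt(d^2 + a^2)` and radial falloff
#' `(1 + rho^2/a^2)^(-3/2)`. Maximum at the pole faces, mirror-symmetric
#' across the midplane for the symmetric geometry.
#'
#' @param grid A [voxel_grid()] (default: the 11 x 11 x 10 cm survey volume
#'   at 5 mm pitch, 23 x 23 x 21 nodes).
#' @param H0 Field intensity at a pole face on the axis (A/m).
#' @param gap Air-gap length (m).
#' @param pole_radius Pole-face radius (m).
#' @return An object of class `field_map` with the grid and the 3D array of
#'   `|H|` values (A/m).
#' @export
synth_field_map <- function(grid = voxel_grid(c(-0.055, -0.055, -0.075),
                                              0.005, c(23, 23, 21)),
                            H0 = 100e3, gap = 0.14, pole_radius = 0.05) {
  stopifnot(inherits(grid, "voxel_grid"), H0 >= 0, gap > 0, pole_radius > 0)
  xyz <- voxel_coords(grid)
  rho2 <- xyz[, 1]^2 + xyz[, 3]^2
  radial <- (1 + rho2 / pole_radius^2)^(-1.5)
  pole <- function(yface) {
    d <- abs(xyz[, 2] - yface)
    (1 - d / sqrt(d^2 + pole_radius^2))
  }
  H <- H0 / 2 * (pole(gap / 2) + pole(-gap / 2)) * radial
  structure(list(grid = grid, values = array(H, grid$dim)),
            class = "field_map")
}

#' Field intensity at arbitrary positions from a field map
#'
#' Trilinear interpolation of `|H|(r)`; positions outside the map hull are an
#' error.
#'
#' @param fm A `field_map`.
#' @param pos Length-3 position or n x 3 matrix (m).
#' @return Field intensities (A/m).
#' @export
field_at <- function(fm, pos) {
  stopifnot(inherits(fm, "field_map"))
  pos <- matrix(pos, ncol = 3)
  g <- fm$grid
  idx <- sweep(sweep(pos, 2, g$origin), 2, rep(g$pitch, 3), `/`)
  if (any(idx < -1e-9) || any(idx > rep(g$dim - 1, each = nrow(idx)) + 1e-9))
    stop("position outside the field-map hull")
  idx <- pmax(idx, 0)
  i0 <- pmin(floor(idx), matrix(g$dim - 2, nrow(idx), 3, byrow = TRUE))
  fr <- idx - i0
  out <- numeric(nrow(pos))
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (ifelse(dx == 1, fr[, 1], 1 - fr[, 1]) *
          ifelse(dy == 1, fr[, 2], 1 - fr[, 2]) *
          ifelse(dz == 1, fr[, 3], 1 - fr[, 3]))
    out <- out + w * fm$values[cbind(i0[, 1] + dx + 1, i0[, 2] + dy + 1,
                                     i0[, 3] + dz + 1)]
  }
  out
}
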