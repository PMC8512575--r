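test_that("PMF waveforms hit their plateaus, RMS and reference levels", {
  onoff <- sample_pmf(fast_onoff_pmf(80))
  expect_setequal(unique(onoff$H[!onoff$ramp]), c(0, 80e3))
  expect_true(any(onoff$state == "on"))

  s <- sample_pmf(fast_sin_pmf())
  w <- s[s$state == "sin", ]
  expect_equal(nrow(w), 6 / 0.5 * 6)              # 6 periods at 6 IRFs/s
  expect_equal(mean(w$H), 0, tolerance = 1e-9)    # zero mean, integer periods
  expect_equal(sqrt(mean(w$H^2)), 27e3, tolerance = 1e-9)

  off <- sample_pmf(pmf_waveform("off"))
  expect_true(all(off$H == 0))
  # default acquisition rate: six IRFs per second
  expect_equal(unique(round(diff(onoff$T), 12)), 1 / 6)
})

test_that("array bookkeeping: 8 x 16 gives 128 channels on the mold surface", {
  g <- array_geometry()
  expect_equal(nrow(g$channels), 128)
  r_tx <- sqrt(rowSums(sweep(g$tx, 2, g$mold$center)^2))
  r_rx <- sqrt(rowSums(sweep(g$rx, 2, g$mold$center)^2))
  expect_equal(r_tx, rep(g$mold$radius, 8))
  expect_equal(r_rx, rep(g$mold$radius, 16))
  expect_error(sim_config(target = target_spec(position = c(0, 0, 0.05))),
               "outside")
})

test_that("channel response: kinematics, field parity and convolution oracle", {
  cfg <- one_channel_cfg()
  # a field-independent target (no MNPs) gives a vanishing differential
  cfg0 <- one_channel_cfg(target = target_spec(chi_scale = 0))
  y <- channel_response(cfg0, 1, c(80e3, 0))
  expect_equal(max(abs(y[, 1] - y[, 2])), 0)

  # doubling both path segments doubles the delay (argmax of the envelope)
  geom <- array_geometry()
  v <- host_velocity(cfg)
  peak_t <- function(pos) {
    cfgp <- sim_config(target = target_spec(position = pos, chi_scale = 0),
                       channels = 1, fs = 64e9, nt = 2048)
    yy <- channel_response(cfgp, 1, 0)
    tt <- attr(yy, "t")
    tt[which.max(Mod(analytic_signal(yy[, 1])))] - cfgp$pulse_t0
  }
  tx <- geom$tx[1, ]; rx <- geom$rx[1, ]
  mid <- (tx + rx) / 2
  aim <- c(0, 0, -0.035) - mid  # ray towards a deep interior point
  u <- aim / sqrt(sum(aim^2))
  d <- function(p) sqrt(sum((tx - p)^2)) + sqrt(sum((p - rx)^2))
  p1 <- mid + u * 0.03
  # solve for the point on the same ray whose total path is exactly doubled
  a2 <- uniroot(function(a) d(mid + u * a) - 2 * d(p1), c(0.03, 0.12))$root
  p2 <- mid + u * a2
  expect_equal(peak_t(p2) / peak_t(p1), 2, tolerance = 0.03)

  # frequency-domain product equals a direct time-domain convolution
  cfg2 <- one_channel_cfg(nt = 256)
  y80 <- channel_response(cfg2, 1, c(80e3, 0))
  diff_sim <- y80[, 1] - y80[, 2]
  f <- mnpmwi:::sim_freq_grid(cfg2)
  host <- do.call(debye_spectrum, c(list(freq = f), cfg2$host_debye))
  targ <- do.call(debye_spectrum, c(list(freq = f), cfg2$target_debye))
  inband <- f >= 1e9 & f <= 4e9
  gam_h <- function(h) {
    chi <- complex(length(f))
    chi[inband] <- susceptibility(cfg2$chi_model, f[inband], h, cfg2$env)
    s <- mnpmwi:::principal_impedance_sqrt((1 + chi) * host$eps_rel / targ$eps_rel)
    (s - 1) / (s + 1)
  }
  dgam_t <- mnpmwi:::irfft(gam_h(80e3) - gam_h(0), cfg2$nt)
  pulse_t <- mnpmwi:::irfft(
    mnpmwi:::.channel_pulse_spectrum(cfg2, cfg2$geometry$tx[1, ],
                                     cfg2$geometry$rx[1, ],
                                     cfg2$target$position,
                                     cfg2$target$volume), cfg2$nt)
  n <- cfg2$nt
  conv <- vapply(seq_len(n), function(i)
    sum(pulse_t * dgam_t[((i - seq_len(n)) %% n) + 1]), numeric(1))
  expect_equal(diff_sim, conv, tolerance = 1e-10)
})

test_that("radargram assembly: counts, determinism, superposition, parity", {
  geom <- array_geometry()
  pmf <- pmf_waveform("onoff", t_off = 1, t_ramp = 0, t_on = 1)
  cfg <- sim_config(geometry = geom, pmf = pmf, nt = 128)
  rset <- simulate_radargram(cfg)
  expect_length(rset, 128)

  # no target, no disturbance/drift/noise: constant along observation time
  cfg_c <- sim_config(target = NULL, pmf = pmf, nt = 128, channels = 1:3)
  for (r in simulate_radargram(cfg_c))
    expect_equal(max(abs(r$values - r$values[, 1])), 0)

  # fixed seed: bit-identical repetition
  cfg1 <- one_channel_cfg(noise_sigma = 1e-3, drift_rel = 1e-4,
                          disturbance_gain = 1e-8, seed = 5)
  expect_identical(simulate_radargram(cfg1)[[1]]$values,
                   simulate_radargram(cfg1)[[1]]$values)

  # superposition: (with target) - (without target) = pure target response
  base <- list(pmf = fast_onoff_pmf(), channels = 7L, seed = 9,
               disturbance_gain = 3e-8)
  with_t <- simulate_radargram(do.call(sim_config, base))[[1]]
  no_t <- simulate_radargram(do.call(sim_config, c(base, list(target = NULL))))[[1]]
  cfg_t <- do.call(sim_config, base)
  ytar <- channel_response(cfg_t, 7L, with_t$pmf$H)
  expect_equal(with_t$values - no_t$values, unclass(ytar),
               ignore_attr = TRUE, tolerance = 1e-12)

  # MNP response is even in the field, the disturbance odd
  cfg_s <- sim_config(pmf = fast_sin_pmf(), channels = 1, seed = 2,
                      disturbance_gain = 0)
  r_s <- simulate_radargram(cfg_s)[[1]]
  H <- r_s$pmf$H
  i_pos <- which(abs(H - max(H)) < 1)[1]
  i_neg <- which(abs(H + max(H)) < 1)[1]
  expect_equal(r_s$values[, i_pos], r_s$values[, i_neg], tolerance = 1e-12)

  cfg_d <- sim_config(pmf = fast_sin_pmf(), channels = 1, seed = 2,
                      disturbance_gain = 1e-8, target = NULL)
  r_d <- simulate_radargram(cfg_d)[[1]]
  dist_pos <- r_d$values[, i_pos] - r_d$values[, 1]
  dist_neg <- r_d$values[, i_neg] - r_d$values[, 1]
  expect_equal(dist_pos, -dist_neg, tolerance = 1e-12)
})

test_that("m-sequence sensing reproduces the ideal radargram up to the bias", {
  cfg_i <- sim_config(pmf = pmf_waveform("onoff", t_off = 1, t_ramp = 0, t_on = 1),
                      channels = 1, sensing = "msequence", mseq_order = 9)
  expect_equal(cfg_i$nt, 511)
  r_m <- simulate_radargram(cfg_i)[[1]]
  cfg_ideal <- sim_config(pmf = pmf_waveform("onoff", t_off = 1, t_ramp = 0, t_on = 1),
                          channels = 1, nt = 511)
  r_i <- simulate_radargram(cfg_ideal)[[1]]
  # correlation recovery: h - sum(h)/(N+1) per column
  N <- 511
  want <- r_i$values - matrix(colSums(r_i$values) / (N + 1), N, ncol(r_i$values),
                              byrow = TRUE)
  expect_equal(r_m$values, want, tolerance = 1e-9)
})

test_that("synthetic field maps have pole-face maxima, symmetry and node counts", {
  fm <- synth_field_map()
  expect_equal(fm$grid$dim, c(23L, 23L, 21L))   # 11 x 11 x 10 cm at 5 mm

  # full-gap map: global maximum on the pole axis at a face, mirror symmetry
  g <- voxel_grid(c(-0.05, -0.07, -0.05), 0.005, c(21, 29, 21))
  fm2 <- synth_field_map(g)
  idx <- arrayInd(which.max(fm2$values), g$dim)
  expect_equal(idx[1, c(1, 3)], c(11, 11))       # on the axis (x = z = 0)
  expect_true(idx[1, 2] %in% c(1, 29))           # at a pole face
  expect_equal(fm2$values, fm2$values[, 29:1, ], tolerance = 1e-12)

  # trilinear interpolation reproduces node values
  xyz <- voxel_coords(fm$grid)
  pick <- c(1, 500, 3000)
  expect_equal(field_at(fm, xyz[pick, ]), as.vector(fm$values)[pick],
               tolerance = 1e-12)
  expect_error(field_at(fm, c(1, 0, 0)), "hull")
})
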