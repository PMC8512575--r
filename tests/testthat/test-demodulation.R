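test_that("clutter estimation averages the field-free window", {
  # constant along T: the estimate is exactly that column
  v <- matrix(sin(1:32), 32, 12)
  r <- manual_radargram(v, rep(c("off", "on"), each = 6))
  cl <- estimate_clutter(r)
  expect_equal(cl$mean, v[, 1])
  expect_equal(cl$n_off, 6)

  # linearity in the input radargram
  v2 <- matrix(rnorm(32 * 12), 32, 12)
  r2 <- manual_radargram(v2, rep(c("off", "on"), each = 6))
  r_mix <- manual_radargram(2 * v - 3 * v2, rep(c("off", "on"), each = 6))
  expect_equal(estimate_clutter(r_mix)$mean,
               2 * cl$mean - 3 * estimate_clutter(r2)$mean)

  # Monte-Carlo standard-error bound: within 4*sigma/sqrt(M) per bin
  set.seed(21)
  sigma <- 0.3; M <- 40
  truth <- cos(1:16)
  ok <- replicate(50, {
    vv <- truth + matrix(rnorm(16 * M, sd = sigma), 16, M)
    rr <- manual_radargram(vv, rep("off", M))
    all(abs(estimate_clutter(rr)$mean - truth) <= 4 * sigma / sqrt(M))
  })
  expect_gt(mean(ok), 0.95)

  expect_error(estimate_clutter(manual_radargram(v, rep("on", 12))),
               "field-free")
})

test_that("clutter removal subtracts column by column and is idempotent", {
  states <- rep(c("off", "on"), each = 8)
  v <- outer(sin(1:24), rep(1, 16)) + outer(cos(1:24), as.numeric(states == "on"))
  r <- manual_radargram(v, states)
  d <- remove_clutter(r)
  expect_equal(d$values[, 1:8], matrix(0, 24, 8))
  expect_equal(d$values[, 9], cos(1:24))

  # re-applying removal changes nothing (the OFF-window mean is already zero)
  d2 <- remove_clutter(d)
  expect_equal(d2$values, d$values)

  # target-free noiseless simulation: identically zero differential
  cfg <- sim_config(target = NULL, pmf = fast_onoff_pmf(), channels = 1)
  r0 <- simulate_radargram(cfg)[[1]]
  expect_equal(max(abs(remove_clutter(r0)$values)), 0)

  bad <- estimate_clutter(manual_radargram(v[1:10, ], states))
  expect_error(remove_clutter(r, bad), "mismatch")
})

test_that("mean differential averages the modulation window", {
  states <- c(rep("off", 4), rep("on", 4), rep("ramp", 2), rep("on", 4))
  v <- matrix(0, 8, 14)
  v[, states == "on"] <- rep(c(1, 1, 1, 1, 3, 3, 3, 3), each = 8)
  d <- manual_diff_radargram(v, states)
  expect_equal(mean_differential(d)$values, rep(2, 8))  # (a + b)/2

  dk <- manual_diff_radargram(matrix(5, 8, 14), states)
  expect_equal(mean_differential(dk)$values, rep(5, 8))

  # noise-only: |mean| bounded by 4*sigma/sqrt(M) per bin
  set.seed(3)
  sigma <- 0.5
  ok <- replicate(50, {
    vv <- matrix(rnorm(8 * 14, sd = sigma), 8, 14)
    m <- mean_differential(manual_diff_radargram(vv, states))$values
    all(abs(m) <= 4 * sigma / sqrt(8))
  })
  expect_gt(mean(ok), 0.95)

  expect_error(mean_differential(manual_diff_radargram(v, rep("off", 14))),
               "ON")
})

test_that("observation spectra are normalized, single-sided and Parseval-exact", {
  # constant along the window maps to its value at nu = 0
  d <- manual_diff_radargram(matrix(2.5, 4, 24), rep("on", 24))
  s <- observation_spectrum(d)
  expect_equal(Re(s$values[, 1]), rep(2.5, 4))
  expect_equal(s$nu[2] - s$nu[1], 1 / (24 / 6))  # resolution 1/T_window

  # pure cosine at 1 Hz: unit single-sided magnitude there, ~0 elsewhere
  Tax <- (0:23) / 6
  vc <- matrix(cos(2 * pi * 1 * Tax), 4, 24, byrow = TRUE)
  sc <- observation_spectrum(manual_diff_radargram(vc, rep("on", 24)))
  h1 <- harmonic_component(sc, 1)
  expect_equal(h1$values, rep(1, 4), tolerance = 1e-12)
  others <- Mod(sc$values[1, s$nu != 1])
  expect_lt(max(others), 1e-12)

  # DC bin identity: nu = 0 returns the window mean
  set.seed(8)
  vr <- matrix(rnorm(4 * 24), 4, 24)
  sr <- observation_spectrum(manual_diff_radargram(vr, rep("on", 24)))
  expect_equal(Re(sr$values[, 1]), rowMeans(vr))
  expect_equal(harmonic_component(sr, 0)$values, abs(rowMeans(vr)))

  # Parseval per propagation-time bin (reconstructing the two-sided energy)
  energy_nu <- Mod(sr$values[, 1])^2 +
    2 * rowSums(Mod(sr$values[, 2:12, drop = FALSE])^2) +
    Mod(sr$values[, 13])^2
  expect_equal(energy_nu, rowMeans(vr^2), tolerance = 1e-10)

  expect_error(harmonic_component(sr, 10), "Nyquist")
  d_bad <- manual_diff_radargram(vr, rep("on", 24))
  d_bad$T[5] <- d_bad$T[5] + 0.01
  d_bad$pmf$T <- d_bad$T
  expect_error(observation_spectrum(d_bad), "uniform")
})

test_that("harmonic placement separates even MNP response from odd disturbance", {
  # even response under 0.5 Hz sinusoidal drive: dominant non-DC bin at 1 Hz
  cfg_t <- sim_config(pmf = fast_sin_pmf(), channels = 1, seed = 2)
  r <- simulate_radargram(cfg_t)[[1]]
  s <- observation_spectrum(remove_clutter(r))
  tb <- which.max(rowSums(Mod(s$values)^2))
  mags <- Mod(s$values[tb, ])
  expect_equal(s$nu[1 + which.max(mags[-1])], 1)

  # odd disturbance: energy confined to the 0.5 Hz fundamental
  cfg_d <- sim_config(pmf = fast_sin_pmf(), channels = 1, seed = 2,
                      target = NULL, disturbance_gain = 1e-8)
  sd_ <- observation_spectrum(remove_clutter(simulate_radargram(cfg_d)[[1]]))
  tb2 <- which.max(rowSums(Mod(sd_$values)^2))
  mags2 <- Mod(sd_$values[tb2, ])^2
  expect_equal(sd_$nu[which.max(mags2)], 0.5)
  even_bins <- sd_$nu %in% c(1, 2)
  expect_lt(sum(mags2[even_bins]) / sum(mags2), 1e-6)

  # the 1 Hz component is invariant to the disturbance gain
  h1 <- function(g) {
    cfg <- sim_config(pmf = fast_sin_pmf(), channels = 1, seed = 2,
                      disturbance_gain = g)
    s <- observation_spectrum(remove_clutter(simulate_radargram(cfg)[[1]]))
    harmonic_component(s, 1)$values
  }
  a <- h1(0); b <- h1(5e-8)
  expect_lt(max(abs(a - b)) / max(a), 1e-6)
})

test_that("envelope maximum matches amplitude, scaling and a Gaussian pulse", {
  tt <- seq(0, 1, length.out = 2048)
  x <- 0.7 * sin(2 * pi * 40 * tt)
  expect_equal(envelope_max(x), 0.7, tolerance = 0.01)
  expect_equal(envelope_max(-3 * x), 3 * envelope_max(x), tolerance = 1e-9)
  expect_equal(envelope_max(numeric(16)), 0)

  # Gaussian-envelope band-pass pulse: envelope peak equals the Gaussian peak
  tg <- seq(-1, 1, length.out = 4096)
  g <- exp(-tg^2 / (2 * 0.05^2)) * cos(2 * pi * 100 * tg)
  expect_equal(envelope_max(g), 1, tolerance = 1e-3)
})

test_that("the two-state pipeline recovers the injected differential response", {
  cfg <- one_channel_cfg(seed = 6)
  r <- simulate_radargram(cfg)[[1]]
  md <- mean_differential(remove_clutter(r))
  ytar <- channel_response(cfg, 1, c(cfg$pmf$Hm, 0))
  oracle <- ytar[, 1] - ytar[, 2]
  expect_lt(max(abs(md$values - oracle)) / max(abs(oracle)), 1e-8)
})
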