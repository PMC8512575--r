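# mnpmwi

Magnetic-nanoparticle-enhanced ultra-wideband differential microwave imaging:
a simulation and signal-processing toolchain in R.

## The problem

Microwave breast imaging must find a weak tumor reflection underneath static
clutter (antenna crosstalk, skin and container reflections) that is orders of
magnitude stronger. Magnetic nanoparticles (MNPs) that accumulate in tumorous
tissue act as a *modulatable* contrast agent: their complex magnetic
susceptibility χ(f, H) in the 1–4 GHz band shifts with an external
quasi-static polarizing magnetic field (PMF), while nonmagnetic tissue does
not react at all. Differencing ultra-wideband (UWB) radar acquisitions across
PMF states cancels everything static and isolates the particle response.

`mnpmwi` is aimed at researchers developing this kind of contrast-modulated
radar pipeline. It provides:

* **Particle physics** — Néel/Brownian relaxation times, the
  Debye + ferromagnetic-resonance susceptibility model
  χ = (χ∥ + 2 χ⊥)/3 with its linear resonance shift
  f_res(H) = γ(H_A + H)/2π, tabulated χ(f, H) grids with CSV I/O, and the
  band-limited differential response maximum ΔM(H) used for normalization.
* **Scattering** — plane-wave reflection at the tumor/host boundary,
  Γ = (Z₂ − Z₁)/(Z₂ + Z₁) with Z = Z₀√(μ/ε) and μ₂ = 1 + χ(f, H).
* **Pseudo-noise sensing** — maximal-length sequences with the two-valued
  autocorrelation {N, −1} and impulse-response recovery by circular
  cross-correlation.
* **A synthetic-data generator** — per-channel radargrams
  y(t, T) = clutter + target response + odd PMF-coupled disturbance + drift
  + noise over an 8 × 16 MIMO array (128 channels) on a hemispherical
  examination mold, with ON/OFF and sinusoidal PMF waveforms and synthetic
  magnetic field maps of the electromagnet air gap.
* **Demodulation** — clutter estimation over the field-free window, column
  subtraction, modulation-window means, observation-time Fourier spectra and
  harmonic extraction. The even-in-field MNP response lands at DC and the
  even harmonics; odd PMF-coupling disturbances land at the odd harmonics,
  which is what makes them separable.
* **Imaging** — delay-and-sum beamforming I(r₀) = Σ_ch |Δy_ch(τ_ch(r₀))|,
  dB conversion, signal-to-clutter scoring, PMF reference-image subtraction,
  and the voxelwise field-inhomogeneity correction
  CF_H(r₀) = ΔM(H_ref)/ΔM(H(r₀)).
* **A scenario workbench** — field-intensity/viscosity sweeps, target-depth
  sweeps and the ON/OFF-versus-sinusoidal modulation comparison, as
  reproducible seeded run tables.

## Worked example

Simulate a two-state (0/80 kA/m) acquisition of a 2 mL MNP-loaded target at
[0, −3, −3.5] cm in a cream-like host, demodulate it, and image it:

```r
library(mnpmwi)

cfg <- sim_config(
  target = target_spec(position = c(0, -0.03, -0.035)),
  pmf = pmf_waveform("onoff", Hm_ka_per_m = 80, t_off = 5, t_ramp = 1, t_on = 5),
  noise_sigma = 2e-3, seed = 42)

rset <- simulate_radargram(cfg)
rset
#> Radargram set: 128 channels, 512 x 102 (t x T) samples, PMF 'onoff', seed 42

r <- rset[[49]]
md <- mean_differential(remove_clutter(r))
envelope_max(md)
#> [1] 0.001886538

img <- image_scenario(cfg, grid = voxel_grid(c(-0.065, -0.065, -0.065),
                                             0.005, c(27, 27, 14)))
img
#> Image volume: 27 x 27 x 14 voxels at 5 mm pitch (linear)
#>   range 0.02257 .. 0.1212, argmax at (0, -0.03, -0.04) m

signal_to_clutter(img, cfg$target$position)
#> [1] 7.560568
```

Reading the numbers: each of the 128 radargrams stacks 512-sample impulse
responses over 102 acquisitions (17 s at six per second). After subtracting
the field-free mean, one channel's differential MNP response has an envelope
maximum of ~1.9 × 10⁻³ — about 200× below the static clutter it was buried
in. Delay-and-sum focusing over the 48 selected imaging channels localizes
the target to one 5 mm voxel of its true position, and the target region
stands 7.6 dB above the remaining in-mold clutter.

The field-inhomogeneity correction follows the same API:

```r
fm <- synth_field_map()                      # 23 x 23 x 21 nodes at 5 mm
cf <- correction_matrix(fm, cfg$chi_model)   # CF = 1 at 80 kA/m
```

See the vignette (`vignettes/mnp-microwave-imaging.Rmd`) for the model, its
assumptions, the calibration of the synthetic study conditions, and known
limitations.

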