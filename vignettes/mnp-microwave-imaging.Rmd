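---
title: "Modelling and imaging magnetically modulated nanoparticle contrast with ultra-wideband radar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling and imaging magnetically modulated nanoparticle contrast with ultra-wideband radar}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mnpmwi)
```

## The measurement principle

Microwave breast imaging suffers from a fundamental contrast problem: the
static reflections of the anatomy (and of the measurement hardware itself)
are orders of magnitude stronger than the response of a small tumor. Magnetic
nanoparticles (MNPs) that accumulate in tumorous tissue offer a way out,
because their complex magnetic susceptibility $\chi(f, H)$ in the gigahertz
range can be *modulated* by a quasi-static external polarizing magnetic field
(PMF). Tissue is nonmagnetic, so everything in the scene except the
MNP-loaded target is blind to the PMF. Differencing acquisitions across PMF
states cancels the static clutter and leaves only the particle response.

`mnpmwi` implements this measurement chain end to end as a simulation and
signal-processing toolchain: particle physics, boundary scattering,
pseudo-noise impulse-response sensing, PMF-modulated radargram synthesis over
a multistatic antenna array, clutter removal and harmonic demodulation,
delay-and-sum (DAS) volumetric imaging with signal-to-clutter (S/C) scoring,
and a voxelwise correction for the spatial inhomogeneity of the polarizing
field.

## The susceptibility model

For monodisperse single-domain particles the susceptibility combines a
parallel (relaxational) and a transverse (resonant) term,

$$\chi(f) = \tfrac{1}{3}\left[\chi_{\parallel}(f) + 2\,\chi_{\perp}(f)\right],$$

with the parallel part a Debye term
$\chi_{\parallel} = \chi_{\parallel 0}/(1 + i 2\pi f \tau_{\parallel})$ whose
effective relaxation time is the parallel combination of the Néel time
$\tau_n = \tau_0 \exp(K_a V_p / k_B \vartheta)$ and the Brownian time
$\tau_b = 3 V_h \eta / k_B \vartheta$. Immobilized particles (bound in
gelatin, or in tumor tissue) have $\tau_b \to \infty$, which suppresses the
Brownian path; `medium_environment("immobilized")` encodes this limit
exactly. The transverse part is the ferromagnetic-resonance form with two
time constants $\tau_2, \tau_\perp$ and the dimensionless coupling
$\Delta = \sigma \tau_2 (\tau_n - \tau_\perp)/(\alpha^2 \tau_n^2)$.

Applying a PMF of intensity $H$ raises the resonance linearly,
$f_{\rm res}(H) = \gamma (H_A + H)/2\pi$ with the uniaxial anisotropy field
$H_A$. Three modelling choices deserve explanation:

* **Units.** Everything internal is SI; field intensities are accepted in
  kA/m at user interfaces and converted once. Because the anisotropy-field
  relation $H_A = 2K_a/M_s$ is a CGS identity, the implementation uses the
  SI-consistent form $H_A = 2K_a/(\mu_0 M_s)$ and expresses the gyromagnetic
  ratio per A/m. With the default core parameters (magnetite,
  $M_s = 446$ kA/m, $K_a = 1.1\times10^4$ J/m³) this puts
  $f_{\rm res}(0) \approx 1.4$ GHz and $f_{\rm res}(80\,\mathrm{kA/m})
  \approx 4.2$ GHz — the resonance sweeps through the 1–4 GHz working band
  exactly over the field range where measured MNP responses are strongest.
* **How the field enters.** The literature establishes that the static
  susceptibilities and relaxation times are themselves field-dependent, but
  no closed formulas are in common use. The closed-form model therefore
  applies only the resonance shift by default: both transverse time
  constants are rescaled by $f_{\rm res}(0)/f_{\rm res}(H)$, which moves the
  transverse pole exactly to $f_{\rm res}(H)$ while leaving the statics
  untouched. A `chi0_scale` hook lets users supply field-dependent scalings,
  and tabulated $\chi(f, H)$ grids (CSV, bilinear interpolation over
  $\log f \times H$) are the recommended path when measured data exist.
* **Derived transverse times.** When not supplied, $\tau_2 = \tau_\perp$ are
  solved from $\omega^2\tau^2 = 1 + \Delta(\tau)$ so that the zero-field
  transverse resonance coincides with $\gamma H_A/2\pi$ — the model is then
  self-consistent by construction. These defaults are illustrative fixture
  values, not a claim about any specific commercial ferrofluid.

The quantity that drives everything downstream is the differential
susceptibility $\Delta\chi(f) = \chi(f, H_m) - \chi(f, H_n)$ and its
band-limited time-domain response: `band_limited_response_max()` integrates
$\Delta\chi$ over the working band (single-sided, so the magnitude *is* the
analytic-signal envelope) on a grid spanning ±8 band-resolution units, and
returns the envelope maximum $\Delta M$. With the closed-form defaults,
$\Delta M(H)$ rises steeply, peaks between 60 and 80 kA/m, and declines
slowly — the nonlinear response curve that motivates operating the ON/OFF
modulation at 80 kA/m.

```{r dm-curve}
m <- chi_closed_form(mnp_params())
H <- seq(0, 160e3, by = 20e3)
dM <- vapply(H, function(h)
  band_limited_response_max(m, h, 0, env = medium_environment("immobilized")),
  numeric(1))
round(dM / max(dM), 3)
```

## Scattering and the forward model

The tumor/host boundary is modelled as a plane-wave, specular,
normal-incidence interface: $\Gamma(f,H) = (Z_2 - Z_1)/(Z_2 + Z_1)$ with
$Z = Z_0\sqrt{\mu/\varepsilon}$ (principal branch, $\mathrm{Re}\,Z \ge 0$
enforced) and $\mu_2 = 1 + \chi(f, H)$. The complex convention is
$\chi = \chi' - i\chi''$ with loss $\chi'' \ge 0$; permittivities follow the
same convention. Host and target dielectrics are single-pole Debye presets
(cream emulating fatty tissue, gelatin/water for the target); they are
labelled approximate, not fitted to any published measurement.

Each simulated channel response is the band-limited sounding pulse (flat
raised-cosine spectrum over 1–4 GHz) delayed by the tx–target–rx path at a
single host velocity $v = c/\sqrt{\mathrm{Re}\,\varepsilon_{\rm host}}$
(band center), attenuated by $e^{-\alpha d}$ and spherical spreading, and
convolved with the kernel of $\Gamma(f, H)$. A frequency-independent
velocity is deliberate: DAS assigns one delay per voxel, and a dispersive
delay model would be inconsistent with the imaging operator. The full
radargram per channel is

$$y(t, T) = y_{\rm cl}(t) + y_{\rm tar}(t, H(T)) + g\,H(T)\,d(t)
  + \mathrm{drift}(t,T) + \mathrm{noise},$$

where $H(T)$ is the PMF waveform over observation time. The MNP term is
evaluated at $|H|$ — the particle response is even in the field — while the
disturbance term $g H(T) d(t)$, emulating the coupling of the PMF into the
measurement hardware, is odd. Under sinusoidal modulation this parity split
is what puts the MNP response at DC and the even harmonics and the spurious
coupling at the odd harmonics, and the simulator reproduces it by
construction. $d(t)$ is a fixed, seeded pulse-like signature per channel at
an early (crosstalk-region) delay; drift is a slow ramp plus random walk
applied to the clutter shape. All stochastic components draw from substreams
keyed only by channel and component, so paired runs (with/without target,
with/without disturbance) share identical realizations — this is what makes
the superposition and reference-subtraction properties exactly testable.

**What the generator emulates, and what it does not.** It reproduces the
structural features the processing chain depends on: clutter far above the
target response, field-even particle response, field-odd disturbance, slow
drift, additive noise, a 128-channel two-ring MIMO geometry on a
hemispherical mold, and six IRFs per second. It does not model full-wave
propagation, antenna patterns, breast heterogeneity, multiple scattering or
mold-wall layering. Passing tests therefore validate the *processing chain
and its invariants*, not hardware-level fidelity: absolute S/C values of the
physical system are outside its reach, which is why the acceptance checks
are structural (channel counts, record counts, harmonic placements) and
property-based.

## Sensing, demodulation and windows

M-sequence sounding is available as an optional acquisition model:
maximal-length ±1 sequences from a Fibonacci LFSR (validated by the
two-valued autocorrelation $\{N, -1\}$), circular acquisition, and IRF
recovery by cross-correlation normalized by $N+1$. The textbook $-1/(N+1)$
off-peak bias is kept visible by default; `remove_dc_bias = TRUE` removes
it. The default chain bypasses sensing (`sensing = "ideal"`) for speed; the
m-sequence path is exercised and tested separately, and the two agree up to
exactly that bias.

Clutter is estimated as the per-bin mean over the field-free window and
subtracted column by column; the mean differential response averages the
modulation window. Ramp intervals are excluded from both windows — the ramp
exists to let the electromagnet settle, and including transition samples
would bias both means. The observation-time spectrum is a plain DFT along
$T$, normalized by the window length so a constant maps to its value at
$\nu = 0$, single-sided with interior bins doubled on extraction. No
windowing is applied: the sinusoidal analysis window contains an integer
number of modulation periods by construction, so the harmonics fall exactly
on bins and there is no leakage to trade off. "Envelope" always means the
magnitude of the FFT-based analytic signal.

## Imaging, scoring and the field correction

DAS sums $|\Delta y_{ch}(\tau_{ch}(r_0))|$ over channels, with linear
interpolation in $t$ and out-of-support delays contributing zero (counted
and reported). Channels are selected by tx–rx angular separation about the
mold center; the 60° default keeps 48 of the 128 channels — wide-angle
(transmission) geometries add little backscatter information. Two
calibration offsets are subtracted from the signal time axis before
focusing: the known latency of the sounding pulse, and the group delay of
the band-limited differential-susceptibility kernel (~130 ps with the
defaults). The latter is knowable by the system for the same reason the
field correction is: the contrast agent's $\chi(f,H)$ is available. For the
time-domain (mean-differential) input the DAS operates on the signal
envelope, which removes carrier-phase sensitivity from the incoherent sum;
harmonic-magnitude inputs are already nonnegative. With these choices a
noiseless point target is localized to within one 5 mm voxel in at least 18
of 20 random in-mold positions.

S/C is the ratio of mean squared intensity in the target region (a sphere of
the known 2 mL target volume, radius ≈ 7.8 mm, centered at the true position
in simulations) to the mean squared intensity over the rest of the in-mold
volume, in dB. The region boundary is a modelling choice; centering at the
detected argmax instead is supported by passing that position.

Spurious PMF-coupling hot spots in two-state imaging are removed by
subtracting a reference image acquired without MNPs; negative voxels are
clipped at zero (linear DAS intensities are nonnegative and dB conversion
requires it), with the raw signed difference retained in the provenance.

The field-inhomogeneity correction evaluates $\Delta M$ at each voxel's
local field intensity (from a measured or synthetic field map at 5 mm
pitch) and weights the image by $CF_H(r_0) = \Delta M(H_{\rm ref}) /
\Delta M(H(r_0))$, normalized so $CF = 1$ at the 80 kA/m reference; voxels
with $\Delta M = 0$ are masked. $\Delta M(H)$ is computed on an intensity
sweep and interpolated to the voxel fields. In a sweep over homogeneous
field levels 40–120 kA/m with purely magnetic target contrast and
attenuation disabled, the corrected peak intensity is flat to a coefficient
of variation below 5%.

The synthetic field map is a smooth stand-in for a Gaussmeter survey of the
14 cm air gap: two pole-face disc fields on the y axis with axial falloff
$1 - d/\sqrt{d^2 + a^2}$ and radial falloff $(1 + \rho^2/a^2)^{-3/2}$ —
maximum at the pole faces, mirror-symmetric, and nothing more is claimed of
it.

## Scenario workbench and study conditions

Three config-driven scenario drivers mirror the experiment shapes:

* `run_field_sweep()` — the single-channel bench: ON/OFF acquisitions over
  0–140 kA/m for virtual targets cycling through six embedding-medium
  presets (water, agar, 10% gelatin, two oil-gelatins, and an MNP-free
  water reference; three of each gives the 18-target bench, and 11
  repetitions give 198 records). The `chi_scale` factors of the presets
  emulate the observed amplitude ordering between media; the solid media
  immobilize the particles.
* `run_depth_sweep()` — the 2 mL target at increasing depth below the mold
  wall through the full imaging pipeline, recording S/C per depth.
* `run_modulation_compare()` — the five-scenario grid (ON/OFF and
  sinusoidal modulation with and without target, plus a field-free
  reference) imaged at $\nu = 0$ and $\nu = 1$ Hz, both modulations matched
  to the same RMS intensity (27 kA/m; the equal-dwell two-state waveform
  uses a plateau of $\sqrt{2} \times$ RMS).

Sweep seeds derive deterministically from the base seed and run index, so
any run table regenerates record-for-record.

**Calibration of the study conditions.** Levels that the underlying
experiments do not publish were fixed once at values a practitioner would
call realistic, and are not revisited: clutter amplitude 1 (arbitrary
units) with the strongest single-channel target differential then reaching
~0.03 at shallow depth; per-sample noise $\sigma = 2\times10^{-3}$ (about
46 dB below the clutter per IRF, before the ~30-fold averaging of the
windows); disturbance gain $2.5\times10^{-8}$ per A/m, putting the spurious
term at the scale of a mid-depth target response; path attenuation 15 Np/m
(~1.3 dB/cm), in the range of lossy tissue-mimicking media at 2.5 GHz;
ON/OFF dwell 10 s with 2 s ramps (5/6 s + 1 s in the reduced test
scenarios). Under these conditions the depth sweep's S/C declines strictly
with depth once attenuation dominates (the 2–6 cm range is used for the
strictness assertion; at shallower depths the ratio saturates against the
point-spread floor), mirroring the loss of detectability with depth that
the physical system shows.

**Problem sizes.** Tests and the acceptance script run at reduced scale
chosen as the smallest sizes that keep every assertion far from its
boundary: 512-sample IRFs at 16 GHz (the 32 ns window covers all in-mold
round trips), 5 mm imaging grids of 27×27×14 voxels, 6-period sinusoidal
records of 72 columns, and 5/6 s bench dwells. The full-size defaults
(10 s dwells, 12 periods) remain the exported defaults.

## Numerical choices and degenerate inputs

* Trapezoidal quadrature in the band integral of $\Delta M$, exact for
  constant $\Delta\chi$ (the analytic oracle $\Delta M = k \cdot B$).
* Linear interpolation everywhere a rule is needed (DAS delays, tabulated
  $\chi$ over $\log f \times H$, $\Delta M(H)$, field maps); no
  extrapolation — out-of-hull queries are errors naming the offending axis.
* Principal complex square root with a sign flip if $\mathrm{Re}\,Z < 0$:
  passive impedances must absorb.
* The Néel exponent is refused above 700 (with the value in the error)
  rather than silently returning infinity; the transverse-time derivation
  handles the $\tau_n \to \infty$ limit by dropping $\Delta$.
* Zero-intensity voxels map to a −120 dB floor in dB conversion; zero
  differential response returns $\Delta M = 0$ and masks the correction.
* RNG state of the caller is saved and restored around the seeded
  simulation substreams.

## Known limitations

The simulator is structural, not electromagnetic: no full-wave solver, no
antenna patterns, no dielectric heterogeneity, no dispersion in the delay
model. Absolute S/C values in dB are properties of the synthetic conditions,
not predictions for hardware. The closed-form field dependence is the
resonance shift only; quantitative field dependence should come from
tabulated measurements. Polydispersity, hysteresis and interparticle
interactions are out of scope, as is quantitative MNP mass estimation from
image intensity and the compensation of dielectric path attenuation.
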