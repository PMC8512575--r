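Package: mnpmwi
Title: Magnetic-Nanoparticle-Enhanced Ultra-Wideband Differential Microwave Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and signal-processing toolchain for contrast-enhanced
    microwave breast imaging with magnetic nanoparticles (MNPs) modulated by an
    external polarizing magnetic field (PMF). Implements the field-dependent
    complex magnetic susceptibility of single-domain nanoparticles (Neel and
    Brownian relaxation, ferromagnetic resonance), plane-wave reflection at the
    tumor/host boundary, M-sequence pseudo-noise impulse-response sensing,
    PMF-modulated radargram synthesis over a MIMO antenna array, clutter removal
    and observation-time harmonic demodulation, delay-and-sum 3D image formation
    with signal-to-clutter scoring, PMF reference-image subtraction, and a
    voxelwise correction matrix compensating the inhomogeneity of the polarizing
    magnetic field.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    pracma,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
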