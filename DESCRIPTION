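Package: aoclass
Title: Label-Free Adaptive-Optics Single-Molecule Localization Microscopy Workbench
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis toolkit for reflection-matrix adaptive
    optics in single-molecule localization microscopy (SMLM). Implements the
    closed-loop accumulation of single scattering (CLASS) algorithm that
    recovers pupil-plane aberrations from angle-scanned interferometric
    reflectance images, a scalar Fourier-optics forward model (point spread
    functions, tilted-illumination reflectance fields, off-axis holography),
    Zernike wavefront analysis, a dual-channel blinking-movie simulator with
    an EMCCD noise model, a Gaussian-fit localizer compatible with the
    ThunderSTORM CSV dialect, and quantitative SMLM metrics: nearest-neighbor
    localization-precision fitting, Fourier ring correlation, ensemble PSF
    width, and Nyquist resolution scaling.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    graphics,
    minpack.lm,
    EBImage,
    tiff,
    png,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
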