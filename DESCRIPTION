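Package: dcrheo
Title: Single-Cell Viscoelastic Phenotyping from Deformability Cytometry Image Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for dynamic deformability cytometry: tracks
    suspended cells through a microfluidic channel in high-speed image
    sequences, decomposes each cell contour into radial Fourier shape modes,
    separates even and odd parity to disentangle the inlet peak-stress
    response from the in-channel step-stress response, and extracts apparent
    viscoelastic material parameters (Young's modulus, viscosity, relaxation
    times) per cell by exponential creep fitting under a Kelvin-Voigt model.
    A bundled simulator generates ground-truth synthetic cell trajectories
    and rendered frames so the entire chain can be validated without an
    instrument.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    grDevices,
    jsonlite,
    minpack.lm,
    pracma,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    png,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
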