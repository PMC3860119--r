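Package: tomowave
Title: 3D Continuous Wavelet Transforms via X-Ray Transform Projections
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for realizing the three-dimensional continuous wavelet
    transform of a volume through two-dimensional wavelet transforms of its
    multi-angle parallel-beam X-ray projections. Provides Gaussian-derivative
    and Mexican-hat mother wavelets together with the closed forms of their
    projected two-dimensional counterparts, numerical admissibility
    certificates (admissibility integrals, uniform Fourier bounds, the
    compact-support energy inequality, Parseval checks), a parallel-beam
    projector with per-slice filtered backprojection and a Fourier
    slice-theorem verifier, the projection-convolution identity, wavelet
    modulus-maxima edge detection in the volume and projection domains, and
    synthetic ellipsoid/Gaussian-blob phantoms with analytic projections for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    tiff,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
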