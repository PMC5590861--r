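Package: vsmbeam
Title: Virtual Source Models of Linear Accelerator Photon Beams from
    Phase-Space Files
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives a compact, single-source generative model (a virtual
    source model, VSM) of a megavoltage photon beam from a Monte Carlo
    phase-space file scored on a plane downstream of the source.  The model
    combines an inverse-CDF spline for radial position, radially binned
    energy-spectrum splines, and weighted polynomial surfaces for the
    position-dependent direction statistics (mean direction cosines, their
    spread, and the energy-direction and lateral-cosine correlations).
    Correlations are reproduced at sampling time with the sum-of-uniforms
    method and a correlated-normal mix.  Includes a synthetic beam generator
    with known ground truth, phase-space comparison utilities, a 2D
    gamma-index engine for dose-plane validation, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    splines,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
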