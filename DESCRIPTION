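Package: magtrap
Title: Magnetophoretic Capture Simulation and Fluorescent Object Counting
    in Flow
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Simulation of the magnetic trapping of magnetite-loaded
    polyelectrolyte microcapsules and capsule-laden cells flowing through
    a channel adjacent to a permanent magnet with a field concentrator:
    Stokes drag, field-gradient magnetic force, trajectory integration
    with a capture criterion, and capture-efficiency sweeps over capsule
    size, nanoparticle payload and flow velocity.  Also implements a
    fluorescent-object video-counting pipeline (Sobel edge enhancement,
    border-following contour extraction with Green's-formula areas, frame
    differencing for movers, aggregate decomposition by area division and
    centroid tracking), validated against a synthetic ground-truth
    microscopy video generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    ggplot2,
    jsonlite,
    png,
    stats,
    tiff,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
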