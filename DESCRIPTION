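Package: retinafunc
Title: Functional Characterisation of Retinal Ganglion Cells from
    High-Density Multielectrode-Array Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the functional characterisation of retinal ganglion
    cells recorded on high-density multielectrode arrays under full-field
    chromatic stimulation. Builds stimulus timelines (contrast steps, colour
    steps, exponential chirp, binary chromatic noise), estimates per-LED
    spectral kernels by spike-triggered averaging, computes electrical images
    with axon tracing and conduction-velocity estimation, derives response
    indices (polarity, transience, spectral dominance and tuning, latency,
    high-frequency index, colour opponency), quantifies phase locking against
    a Poisson bootstrap null, applies spike-sorting quality metrics, and
    clusters light responses by block-wise PCA and Gaussian-mixture models
    selected by BIC. Includes a linear-nonlinear-Poisson simulator and
    synthetic electrical-footprint generator providing ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    mclust,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
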