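Package: tractfade
Title: Orientation-Dependent Transparency Rendering for Fiber Tractography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to fade or emphasize white-matter pathways in diffusion MRI
    tractograms as a function of their orientation. Computes local and global
    streamline orientations, scatter-matrix dispersion summaries (linear
    coefficient), and orientation-dependent opacity values; reads and writes
    TRK, TCK and plain-text tractograms with per-point opacity channels;
    provides the bipolar Watson distribution on the sphere (density, sampling,
    mean-axis estimation) and a synthetic fiber phantom generator; and renders
    depth-sorted, alpha-composited 2D images of 3D tractograms so that bundles
    aligned with a chosen opacity axis are selectively hidden or displayed.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    png,
    stats,
    tools
Suggests:
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
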