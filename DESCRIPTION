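Package: retinotract
Title: Tractometry of Retinotopically Organized Thalamo-Cortical Bundles
Version: 0.1.0
Authors@R: person("retinotract", "developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A reproducible tractometry pipeline for studying the
    subdivision of a thalamo-cortical white-matter tract by its cortical
    termination zone. Provides a synthetic diffusion-MRI phantom with two
    ground-truth bundles (dorsal and ventral) terminating in segregated
    zones of a gradient-bearing cortical region of interest, readers and
    writers for NIfTI-1 volumes and TCK/TRK tractograms, diffusion-tensor
    fitting with FA/MD/RD scalar maps, a deterministic curvature-ensemble
    tensor tracker, non-negative least-squares streamline pruning in the
    style of linear fascicle evaluation, endpoint-based and
    exclusion-plane-based bundle subdivision, signal-detection (d-prime)
    quantification of the split, fiber density and cross-subject
    consistency maps, and 100-node tract profiles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
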