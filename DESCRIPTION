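Package: hdfmap
Title: Localization of Stable Highest-Dominant-Frequency Areas from
    Sequentially Mapped Atrial Electrograms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds spatiotemporally stable dominant-frequency (DF) maps of
    the left atrium from sequentially mapped bipolar intracardiac
    electrograms. Per-point DF estimation uses Botteron preprocessing
    (bandpass, rectification, low-pass), Welch power spectral density, and
    an Organization Index (OI) significance gate. Mapping points are
    aggregated into cubic voxel units with time-domain sparse sampling via
    breadth-first traversal of a balanced binary search tree and a trimmed
    mean statistic; the voxel model is smoothed by kd-tree 10-nearest
    neighbor averaging and thresholded at a personalized mean + 1 SD level
    to extract highest-DF (HDF) areas. Includes a synthetic
    sequential-mapping simulator (catheter trajectory, activation pulse
    trains, noise, artifacts, power-line interference) so the full pipeline
    can be exercised and validated without clinical data, plus an
    OI-threshold F1 calibration sweep.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    signal,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
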