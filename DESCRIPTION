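Package: specfuse
Title: Blind Visualization of Task-Related Networks from EEG-fMRI by
    Spectral and Spatiospectral Fusion Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fuses simultaneous EEG and fMRI recordings with voxelwise
    general linear models driven by fluctuations of EEG power spectra.
    Epoched EEG absolute and relative power spectra are decomposed by
    two-stage PCA plus Infomax group ICA with stability runs into
    spatiospectral patterns; task-related patterns are selected by group
    t-statistics against the stimulus schedule; pattern fluctuations are
    convolved with a canonical hemodynamic response function and its two
    temporal derivatives and regressed against BOLD voxel time series,
    yielding group F-maps signed by the reconstructed response shape and
    cluster-level spatial statistics. Includes a synthetic visual oddball
    EEG-fMRI study generator with recorded ground truth, file format
    helpers (BIDS-style events, NIfTI-1, flat EEG containers), a pipeline
    driver covering four fusion models (absolute/relative x
    spectral/spatiospectral), and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    jsonlite,
    signal,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
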