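Package: specfuse
Title: Low-Level Fusion of Raman and MALDI Mass Spectrometry Imaging Data
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for the centralized (low-level) fusion of Raman
    spectroscopic and MALDI mass spectrometric imaging maps of the same
    sample. Provides per-modality preprocessing (SNIP baseline estimation,
    cosmic-spike detection and removal, spectral interpolation, phase
    correction along the m/z axis, mass-relative peak binning, vector and
    total-ion-count normalization), landmark-based affine co-registration
    with nearest-grid-point averaging, block weighting by the ratio of
    matrix l1-norms, and a joint principal component analysis with a
    cumulative-explained-variance criterion for judging weighting quality.
    A synthetic phantom generator produces paired hyperspectral maps with
    known ground truth, including a low-intensity MALDI-only lipid
    component, so the whole pipeline can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    grDevices,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
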