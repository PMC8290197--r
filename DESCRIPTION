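Package: msilazy
Title: Memory-Efficient Analysis of 2D/3D Mass Spectrometry Imaging Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Lazy, memory-efficient access to mass spectrometry imaging (MSI)
    data in imzML format, with the standard MSI processing chain: streaming
    metadata parsing and on-demand binary spectrum access, per-pixel
    normalization (TIC, median, in-file), Savitzky-Golay smoothing,
    morphological (top-hat) and running-median baseline correction,
    MAD-noise sliding-window peak picking, peak binning, Poisson
    monoisotopic harvesting, ion-image generation, continuous-centroid
    export, principal component and delegated t-SNE embeddings, and
    registration-based 3D reconstruction of serial-section stacks using
    Mattes mutual information with rigid and B-spline transforms. Includes
    a deterministic synthetic phantom generator so every step is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    parallel,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    tiff,
    Rtsne
Config/testthat/edition: 3
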