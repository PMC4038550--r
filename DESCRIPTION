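Package: darkbench
Title: Benchmarking Dark Noise in Bacterial Fluorescent Promoter Reporters
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis pipeline for benchmarking the dark noise
    of fluorescent promoter-reporter systems in bacteria by single-cell
    microscopy. Simulates per-cell reporter fluorescence as the sum of
    cellular autofluorescence, spurious-transcription expression and
    promoter-driven signal (with optional transcriptional interference),
    renders and segments synthetic brightfield/fluorescence image fields of
    rod-shaped cells, quantifies background-subtracted per-cell intensities,
    and computes the D (ratio of means) and S (ratio of standard deviations)
    benchmarking statistics of empty-vector controls against autofluorescence,
    with bootstrap uncertainty. Also provides promoter-assay tools:
    transcriptional-interference detection and dark-noise deconvolution of
    promoter signal distributions.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    tiff,
    yaml,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
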